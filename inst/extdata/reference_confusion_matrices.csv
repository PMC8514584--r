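regime,backbone,evaluation,tn,fp,fn,tp
admil,lenet_like,case,98,10,23,191
admil,alexnet_like,case,96,12,15,199
admil,inception_like,case,95,13,27,187
admil,resnet_like,case,99,9,27,187
admil,densenet_like,case,34,74,38,176
supervised,alexnet_like,patch,33542,6013,7114,62813
supervised,alexnet_like,case,77,31,3,211
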