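regime,backbone,evaluation,sensitivity,specificity,accuracy,balanced_accuracy,known_inconsistencies
admil,lenet_like,case,0.893,0.907,0.898,0.900,
mean_mil,lenet_like,case,0.921,0.778,0.873,0.850,
admil,alexnet_like,case,0.930,0.889,0.916,0.910,
mean_mil,alexnet_like,case,0.893,0.750,0.845,0.822,
admil,inception_like,case,0.874,0.880,0.876,0.877,
mean_mil,inception_like,case,0.897,0.528,0.773,0.713,
admil,resnet_like,case,0.874,0.917,0.888,0.900,balanced_accuracy
mean_mil,resnet_like,case,0.921,0.778,0.873,0.850,
admil,densenet_like,case,0.822,0.315,0.652,0.569,
mean_mil,densenet_like,case,1.000,0.000,0.665,0.500,
supervised,alexnet_like,patch,0.898,0.848,0.880,0.873,
supervised,alexnet_like,case,0.985,0.713,0.849,0.849,sensitivity;accuracy
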