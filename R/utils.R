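# Shared numeric helpers.

# Half-up rounding (round() is round-half-even); printed tables use half-up.
round_half_up <- function(x, digits = 3) {
  floor(x * 10^digits + 0.5) / 10^digits
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Stable binary cross-entropy for a sigmoid output given the pre-activation.
bce_loss <- function(p, y) {
  eps <- 1e-12
  -(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
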