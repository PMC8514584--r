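# Reference backbone configurations. The five families mirror the classic
# design lineages (LeNet / AlexNet / inception / residual / dense) at compact
# widths sized for single-core CPU training on 64-128 px patches; an adaptive
# average pool in front of the fully connected layer makes every family accept
# any of the supported patch sizes. Widths are fixed here so results are
# reproducible; they are deliberately small "-like" variants, not
# reconstructions of the full published topologies.

.conv <- function(id, k, cin, cout, pad = 0, relu = FALSE) {
  list(type = "conv", w = paste0(id, "_W"), b = paste0(id, "_b"),
       pad = pad, relu = relu, shape = c(k, k, cin, cout))
}
.relu <- list(type = "relu")
.pool <- function(q = 2L) list(type = "maxpool", q = q)
.fc <- function(id, d_in, d_out) {
  list(type = "fc", w = paste0(id, "_W"), b = paste0(id, "_b"),
       d_in = d_in, d_out = d_out)
}
.adapt <- function(o = 4L) list(type = "adaptpool", oh = o, ow = o)
.flat <- list(type = "flatten")

backbone_names <- function() {
  c("lenet_like", "alexnet_like", "inception_like", "resnet_like", "densenet_like")
}

#' Backbone architecture specification
#'
#' Builds the layer configuration for one of the five reference CNN feature
#' extractors used in the MIL backbone layer. Every backbone maps a
#' `(patch, patch, 3)` instance to a feature vector \eqn{h_k} of length
#' `feature_dim` (ReLU-activated), via an adaptive 4x4 average pool so the
#' same configuration accepts 64, 96 or 128 px patches.
#'
#' @param name One of `"lenet_like"` (two 5x5 conv/maxpool pairs),
#'   `"alexnet_like"` (five 3x3 convolutions with three maxpools),
#'   `"inception_like"` (two plain convolutions then two small
#'   multi-branch inception blocks), `"resnet_like"` (three basic residual
#'   blocks), or `"densenet_like"` (two dense blocks, growth 12, with a 1x1
#'   transition).
#' @param input_size Patch edge length in pixels; one of 64, 96, 128.
#' @param feature_dim Length `L` of the instance feature vector (default 500).
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = backbone_names(), input_size = 64L,
                          feature_dim = 500L) {
  name <- match.arg(name)
  if (!input_size %in% c(64L, 96L, 128L)) {
    stop("input_size must be one of 64, 96, 128")
  }
  L <- as.integer(feature_dim)
  layers <- switch(name,
    lenet_like = list(
      .conv("c1", 5, 3, 8, relu = TRUE), .pool(),
      .conv("c2", 5, 8, 16, relu = TRUE), .pool(),
      .adapt(), .flat, .fc("fc1", 16 * 16, L), .relu
    ),
    alexnet_like = list(
      .conv("c1", 3, 3, 8, pad = 1, relu = TRUE), .pool(),
      .conv("c2", 3, 8, 16, pad = 1, relu = TRUE),
      .conv("c3", 3, 16, 24, pad = 1, relu = TRUE), .pool(),
      .conv("c4", 3, 24, 24, pad = 1, relu = TRUE),
      .conv("c5", 3, 24, 16, pad = 1, relu = TRUE), .pool(),
      .adapt(), .flat, .fc("fc1", 16 * 16, L), .relu
    ),
    inception_like = list(
      .conv("c1", 3, 3, 8, pad = 1, relu = TRUE), .pool(),
      .conv("c2", 3, 8, 16, pad = 1, relu = TRUE), .pool(),
      list(type = "inception", branches = list(
        list(.conv("i1a", 1, 16, 6, relu = TRUE)),
        list(.conv("i1b", 3, 16, 8, pad = 1, relu = TRUE)),
        list(.conv("i1c", 5, 16, 4, pad = 2, relu = TRUE))
      )),
      list(type = "inception", branches = list(
        list(.conv("i2a", 1, 18, 6, relu = TRUE)),
        list(.conv("i2b", 3, 18, 8, pad = 1, relu = TRUE)),
        list(.conv("i2c", 5, 18, 4, pad = 2, relu = TRUE))
      )),
      .adapt(), .flat, .fc("fc1", 18 * 16, L), .relu
    ),
    resnet_like = list(
      .conv("c1", 3, 3, 12, pad = 1, relu = TRUE), .pool(),
      list(type = "residual",
           layers = list(.conv("r1a", 3, 12, 12, pad = 1, relu = TRUE),
                         .conv("r1b", 3, 12, 12, pad = 1))),
      .pool(),
      list(type = "residual",
           layers = list(.conv("r2a", 3, 12, 12, pad = 1, relu = TRUE),
                         .conv("r2b", 3, 12, 12, pad = 1))),
      .pool(),
      list(type = "residual",
           layers = list(.conv("r3a", 3, 12, 12, pad = 1, relu = TRUE),
                         .conv("r3b", 3, 12, 12, pad = 1))),
      .adapt(), .flat, .fc("fc1", 12 * 16, L), .relu
    ),
    densenet_like = list(
      .conv("c1", 3, 3, 12, pad = 1, relu = TRUE), .pool(),
      list(type = "dense_block", layers = list(
        list(.conv("d1a", 3, 12, 12, pad = 1, relu = TRUE)),
        list(.conv("d1b", 3, 24, 12, pad = 1, relu = TRUE))
      )),
      .conv("t1", 1, 36, 18, relu = TRUE), .pool(),
      list(type = "dense_block", layers = list(
        list(.conv("d2a", 3, 18, 12, pad = 1, relu = TRUE)),
        list(.conv("d2b", 3, 30, 12, pad = 1, relu = TRUE))
      )),
      .adapt(), .flat, .fc("fc1", 42 * 16, L), .relu
    )
  )
  structure(list(name = name, input_size = as.integer(input_size),
                 feature_dim = L, layers = layers),
            class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  np <- sum(vapply(collect_param_specs(x$layers),
                   function(s) prod(s$shape), 0))
  cat("CNN backbone '", x$name, "': ", x$input_size, "x", x$input_size,
      " RGB patch -> ", x$feature_dim, " features (",
      format(np, big.mark = ","), " parameters)\n", sep = "")
  invisible(x)
}
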