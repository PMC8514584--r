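# Layer-graph engine: forward/backward over a list of layer descriptors.
# Batches are (H, W, C, N) arrays until `flatten`, then N x P / N x L matrices.
# Parameters live in a flat named list; layers reference them by name, so the
# same engine serves plain sequences, residual blocks, inception branches and
# dense blocks.

cat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

add_grad <- function(genv, name, g) {
  if (is.null(genv$g[[name]])) genv$g[[name]] <- g else genv$g[[name]] <- genv$g[[name]] + g
}

layer_forward <- function(l, params, X) {
  switch(l$type,
    conv = {
      out <- conv2d_fw(X, params[[l$w]], params[[l$b]], l$pad, isTRUE(l$relu))
      # fused ReLU: keep the output for masking in the backward pass
      list(out = out, cache = list(X = X, Y = if (isTRUE(l$relu)) out))
    },
    relu = {
      mask <- X > 0
      out <- X
      out[!mask] <- 0
      list(out = out, cache = mask)
    },
    maxpool = {
      r <- maxpool_fw(X, l$q)
      list(out = r$Y, cache = list(idx = r$idx, xdim = dim(X)))
    },
    adaptpool = list(out = adaptpool_fw(X, l$oh, l$ow), cache = dim(X)),
    flatten = {
      d <- dim(X)
      dim(X) <- c(prod(d[1:3]), d[4])
      list(out = X, cache = d)
    },
    fc = {
      out <- crossprod(X, params[[l$w]])
      out <- out + rep(params[[l$b]], each = nrow(out))
      list(out = out, cache = X)
    },
    residual = {
      inner <- seq_forward(l$layers, params, X)
      s <- inner$out + X
      mask <- s > 0
      s[!mask] <- 0
      list(out = s, cache = list(inner = inner$cache, mask = mask))
    },
    inception = {
      res <- lapply(l$branches, function(br) seq_forward(br, params, X))
      out <- res[[1L]]$out
      for (i in seq_along(res)[-1L]) out <- cat_channels(out, res[[i]]$out)
      list(out = out,
           cache = list(caches = lapply(res, `[[`, "cache"),
                        ch = vapply(res, function(r) dim(r$out)[3], 0)))
    },
    dense_block = {
      cur <- X
      caches <- vector("list", length(l$layers))
      ch_in <- integer(length(l$layers))
      for (i in seq_along(l$layers)) {
        ch_in[i] <- dim(cur)[3]
        r <- seq_forward(l$layers[[i]], params, cur)
        caches[[i]] <- r$cache
        cur <- cat_channels(cur, r$out)
      }
      list(out = cur, cache = list(caches = caches, ch_in = ch_in))
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, params, cache, dOut, genv, need_dx = TRUE) {
  switch(l$type,
    conv = {
      r <- conv2d_bw(cache$X, params[[l$w]], dOut, l$pad, cache$Y, need_dx)
      add_grad(genv, l$w, r$dW)
      add_grad(genv, l$b, r$db)
      r$dX
    },
    relu = {
      dOut[!cache] <- 0
      dOut
    },
    maxpool = maxpool_bw(cache$idx, cache$xdim, dOut),
    adaptpool = adaptpool_bw(cache, l$oh, l$ow, dOut),
    flatten = {
      dim(dOut) <- cache
      dOut
    },
    fc = {
      add_grad(genv, l$w, cache %*% dOut)
      add_grad(genv, l$b, colSums(dOut))
      params[[l$w]] %*% t(dOut)
    },
    residual = {
      ds <- dOut
      ds[!cache$mask] <- 0
      dInner <- seq_backward(l$layers, params, cache$inner, ds, genv)
      dInner + ds
    },
    inception = {
      ch <- cache$ch
      off <- 0L
      dX <- NULL
      for (i in seq_along(l$branches)) {
        dBr <- dOut[, , off + seq_len(ch[i]), , drop = FALSE]
        off <- off + ch[i]
        dXi <- seq_backward(l$branches[[i]], params, cache$caches[[i]], dBr, genv)
        dX <- if (is.null(dX)) dXi else dX + dXi
      }
      dX
    },
    dense_block = {
      dCur <- dOut
      for (i in rev(seq_along(l$layers))) {
        nin <- cache$ch_in[i]
        dPrev <- dCur[, , seq_len(nin), , drop = FALSE]
        dNew <- dCur[, , -seq_len(nin), , drop = FALSE]
        dCur <- dPrev + seq_backward(l$layers[[i]], params, cache$caches[[i]], dNew, genv)
      }
      dCur
    },
    stop("unknown layer type: ", l$type)
  )
}

seq_forward <- function(layers, params, X) {
  cache <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], params, X)
    X <- r$out
    cache[[i]] <- r$cache
  }
  list(out = X, cache = cache)
}

# need_dx = FALSE skips the (unused) input gradient of the outermost first
# layer -- a worthwhile saving since that is the largest convolution.
seq_backward <- function(layers, params, cache, dOut, genv, need_dx = TRUE) {
  for (i in rev(seq_along(layers))) {
    dOut <- layer_backward(layers[[i]], params, cache[[i]], dOut, genv,
                           need_dx = need_dx || i > 1L)
  }
  dOut
}

# -- parameter initialisation --------------------------------------------------

collect_param_specs <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "conv") {
      out[[l$w]] <- list(kind = "conv", shape = l$shape)
      out[[l$b]] <- list(kind = "bias", shape = l$shape[4])
    } else if (l$type == "fc") {
      out[[l$w]] <- list(kind = "fc", shape = c(l$d_in, l$d_out))
      out[[l$b]] <- list(kind = "bias", shape = l$d_out)
    } else if (l$type == "residual") {
      out <- c(out, collect_param_specs(l$layers))
    } else if (l$type == "inception") {
      for (br in l$branches) out <- c(out, collect_param_specs(br))
    } else if (l$type == "dense_block") {
      for (s in l$layers) out <- c(out, collect_param_specs(s))
    }
  }
  out
}

# Glorot-uniform initialisation with zero biases -- the Keras default, which
# the original implementation of this pooling layer relied on. Draws from the
# current RNG stream so callers control determinism with set.seed().
glorot <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

init_layer_params <- function(layers) {
  specs <- collect_param_specs(layers)
  params <- list()
  for (n in names(specs)) {
    s <- specs[[n]]
    params[[n]] <- switch(s$kind,
      conv = {
        rf <- prod(s$shape[1:2])
        array(glorot(prod(s$shape), rf * s$shape[3], rf * s$shape[4]), s$shape)
      },
      fc = matrix(glorot(prod(s$shape), s$shape[1], s$shape[2]),
                  s$shape[1], s$shape[2]),
      bias = numeric(s$shape)
    )
  }
  params
}

# -- MIL pooling and heads -----------------------------------------------------

#' Forward a batch of instances through a CNN backbone
#'
#' Computes the per-instance feature matrix \eqn{H} whose row \eqn{k} is the
#' feature vector \eqn{h_k} of instance \eqn{k}.
#'
#' @param X Numeric array of shape `(patch, patch, 3, K)` with pixel values
#'   scaled to `[0, 1]`.
#' @param spec A [backbone_spec()].
#' @param params Named list of backbone parameters (see `init_layer_params`);
#'   typically taken from a fitted model's `coef()`.
#' @param cache Logical; keep the layer caches needed for backpropagation.
#' @return A list with `H` (a `K x L` feature matrix) and, if requested,
#'   `cache`.
#' @export
backbone_forward <- function(X, spec, params, cache = FALSE) {
  d <- dim(X)
  if (length(d) != 4 || d[3] != 3) {
    stop("instance batch must be a (patch, patch, 3, K) array")
  }
  if (d[1] != spec$input_size || d[2] != spec$input_size) {
    stop("patch size ", d[1], "x", d[2], " does not match backbone input size ",
         spec$input_size)
  }
  r <- seq_forward(spec$layers, params, X)
  if (cache) list(H = r$out, cache = r$cache) else list(H = r$out)
}

#' Attention pooling over instance features
#'
#' Aggregates a bag's instance features into a single bag-level vector
#' \eqn{z = \sum_k a_k h_k}, with softmax attention weights
#' \eqn{a_k \propto \exp\{w^\top \tanh(V h_k)\}}. The weights sum to one per
#' bag and double as the interpretability signal used for attention maps.
#'
#' @param H Numeric matrix `K x L` of instance feature vectors (one row per
#'   instance).
#' @param V Attention parameter matrix `D x L`.
#' @param w Attention parameter vector of length `D`.
#' @return A list with `z` (length-`L` pooled vector), `a` (length-`K` weights
#'   summing to 1), and the intermediates `tanh_VH` and `logits`.
#' @export
attention_pool <- function(H, V, w) {
  if (!is.matrix(H)) H <- matrix(H, nrow = 1)
  if (nrow(H) < 1L) stop("attention_pool: bag must contain at least one instance")
  Th <- tanh(H %*% t(V))              # K x D
  logits <- as.vector(Th %*% w)       # K
  a <- softmax(logits)
  z <- as.vector(crossprod(H, a))
  list(z = z, a = a, tanh_VH = Th, logits = logits)
}

# Gradient of (dz, da-through-z) wrt H, V, w for attention pooling.
attention_pool_backward <- function(H, V, w, pool, dz) {
  a <- pool$a
  Th <- pool$tanh_VH
  da <- as.vector(H %*% dz)                   # d loss / d a_k via z
  dlogits <- a * (da - sum(a * da))           # softmax backward
  dpre <- (dlogits * (1 - Th^2)) * rep(w, each = nrow(H))  # K x D
  list(dH = outer(a, dz) + dpre %*% V,
       dV = crossprod(dpre, H),
       dw = as.vector(crossprod(Th, dlogits)))
}

#' Mean pooling over instance features
#'
#' The conventional MIL baseline: the bag vector is the elementwise arithmetic
#' mean of the instance feature vectors.
#'
#' @inheritParams attention_pool
#' @return A list with `z` (length-`L` mean vector) and `a` (uniform weights
#'   `1/K`).
#' @export
mean_pool <- function(H) {
  if (!is.matrix(H)) H <- matrix(H, nrow = 1)
  if (nrow(H) < 1L) stop("mean_pool: bag must contain at least one instance")
  list(z = colMeans(H), a = rep(1 / nrow(H), nrow(H)))
}

#' Bag-level sigmoid classifier
#'
#' Applies the single-neuron fully connected head to a pooled bag vector:
#' `probability = sigmoid(sum(u * z) + b)`.
#'
#' @param z Pooled bag feature vector (length `L`).
#' @param u Head weight vector (length `L`).
#' @param b Head bias (scalar).
#' @return Malignancy probability in (0, 1).
#' @export
classify_bag <- function(z, u, b) {
  if (length(z) != length(u)) stop("classify_bag: z and u lengths differ")
  plogis(sum(u * z) + b)
}

# -- Adam ----------------------------------------------------------------------

adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st
}

# In-place fused update; the caller owns params/m/v exclusively during
# training (checkpoints are deep-copied with deep_copy_params()).
adam_update <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  idx <- match(names(grads), names(params))
  if (anyNA(idx)) stop("gradient for unknown parameter")
  adam_step_inplace(params, grads, st$m, st$v, idx, st$t, lr, beta1, beta2, eps)
  params
}

deep_copy_params <- function(params) lapply(params, function(x) x + 0)
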