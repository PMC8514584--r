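# Model fitting. mil_fit() trains the attention-based deep MIL classifier
# (or its mean-pooling ablation) on bags with one bag per optimisation step;
# supervised_fit() trains the per-patch supervised baseline whose patches
# inherit their case's weak label. Both select the checkpoint with the lowest
# validation loss, monitored after every epoch.

bag_to_array <- function(bag, patch_size) {
  K <- bag$K
  X <- array(0, c(patch_size, patch_size, 3, K))
  for (k in seq_len(K)) {
    p <- bag$instances[[k]]$pixels
    if (dim(p)[1] != patch_size || dim(p)[2] != patch_size) {
      stop("instance size ", dim(p)[1], "x", dim(p)[2],
           " does not match patch size ", patch_size)
    }
    X[, , , k] <- p
  }
  X
}

init_mil_params <- function(spec, attention_dim) {
  L <- spec$feature_dim
  D <- attention_dim
  params <- init_layer_params(spec$layers)
  # attention scorer and head as Glorot-initialised dense layers (L -> D -> 1
  # and L -> 1), matching the Keras defaults of the original formulation
  params$att_V <- matrix(glorot(D * L, L, D), D, L)
  params$att_w <- glorot(D, D, 1)
  params$head_u <- glorot(L, L, 1)
  params$head_b <- 0
  params
}

# One bag's forward pass; returns probability, attention weights and the
# caches needed for the backward pass.
mil_forward <- function(params, spec, regime, X) {
  r <- seq_forward(spec$layers, params, X)
  H <- r$out
  if (regime == "admil") {
    pool <- attention_pool(H, params$att_V, params$att_w)
  } else {
    pool <- mean_pool(H)
  }
  p <- classify_bag(pool$z, params$head_u, params$head_b)
  list(p = p, a = pool$a, z = pool$z, H = H, pool = pool, cache = r$cache)
}

mil_backward <- function(params, spec, regime, X, fwd, y, genv) {
  dlogit <- fwd$p - y
  genv$g$head_u <- dlogit * fwd$z
  genv$g$head_b <- dlogit
  dz <- dlogit * params$head_u
  if (regime == "admil") {
    ab <- attention_pool_backward(fwd$H, params$att_V, params$att_w, fwd$pool, dz)
    genv$g$att_V <- ab$dV
    genv$g$att_w <- ab$dw
    dH <- ab$dH
  } else {
    K <- nrow(fwd$H)
    dH <- matrix(dz / K, K, length(dz), byrow = TRUE)
  }
  seq_backward(spec$layers, params, fwd$cache, dH, genv, need_dx = FALSE)
  invisible(NULL)
}

#' Fit an attention-based deep MIL classifier
#'
#' Trains the bag-level benign/malignant classifier: a CNN backbone extracts
#' a feature vector per patch instance, attention pooling (or mean pooling
#' for the conventional-MIL baseline) aggregates them into one bag vector,
#' and a single sigmoid neuron produces the malignancy probability. Training
#' minimises bag-level binary cross-entropy with Adam, one bag per step,
#' reshuffling bags every epoch; the returned model is the epoch checkpoint
#' with the lowest validation loss.
#'
#' @param bags Training bags from [build_bags()]; both labels must be present.
#' @param val_bags Validation bags used to monitor loss and select the best
#'   epoch.
#' @param regime `"admil"` (attention pooling) or `"mean_mil"` (mean
#'   pooling).
#' @param backbone Backbone family name (see [backbone_spec()]) or a
#'   `backbone_spec` object.
#' @param patch_size Patch edge length; must match the instances.
#' @param epochs Training epochs (default 100).
#' @param batch_size Bags per optimisation step; MIL training uses 1.
#' @param learning_rate,beta1,beta2 Adam hyperparameters (defaults 5e-4, 0.9,
#'   0.999).
#' @param feature_dim Backbone feature length `L` (default 500).
#' @param attention_dim Attention hidden dimension `D` (default 128).
#' @param seed Seed for weight initialisation and epoch shuffling.
#' @param verbose Print per-epoch losses.
#' @return An object of class `mil_model` with `history` (per-epoch train and
#'   validation loss), `best_epoch`, and the selected parameters.
#' @seealso [predict.mil_model()], [run_cross_validation()]
#' @export
mil_fit <- function(bags, val_bags,
                    regime = c("admil", "mean_mil"),
                    backbone = "lenet_like",
                    patch_size = 64L,
                    epochs = 100L,
                    batch_size = 1L,
                    learning_rate = 5e-4,
                    beta1 = 0.9, beta2 = 0.999,
                    feature_dim = 500L,
                    attention_dim = 128L,
                    seed = 1L,
                    verbose = FALSE) {
  regime <- tryCatch(match.arg(regime), error = function(e) {
    stop("mil_fit handles regimes 'admil' and 'mean_mil' only; ",
         "use supervised_fit() for the supervised baseline")
  })
  if (batch_size != 1L) {
    stop("MIL training uses batch_size 1 (one bag per optimisation step)")
  }
  if (length(bags) == 0 || length(val_bags) == 0) {
    stop("training and validation bag sets must be non-empty")
  }
  y <- vapply(bags, `[[`, 0L, "label")
  if (length(unique(y)) < 2) {
    stop("training error: training bags contain a single class")
  }
  spec <- if (inherits(backbone, "backbone_spec")) backbone else {
    backbone_spec(backbone, input_size = patch_size, feature_dim = feature_dim)
  }
  set.seed(seed)
  params <- init_mil_params(spec, attention_dim)
  st <- adam_init(params)
  Xs <- lapply(bags, bag_to_array, patch_size = spec$input_size)
  Xv <- lapply(val_bags, bag_to_array, patch_size = spec$input_size)
  yv <- vapply(val_bags, `[[`, 0L, "label")

  n <- length(bags)
  history <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                        val_loss = NA_real_)
  best <- list(loss = Inf, epoch = NA_integer_, params = NULL)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tl <- 0
    for (i in ord) {
      fwd <- mil_forward(params, spec, regime, Xs[[i]])
      tl <- tl + bce_loss(fwd$p, y[i])
      genv <- new.env(parent = emptyenv())
      genv$g <- list()
      mil_backward(params, spec, regime, Xs[[i]], fwd, y[i], genv)
      params <- adam_update(params, genv$g, st, learning_rate, beta1, beta2)
    }
    vl <- mean(vapply(seq_along(Xv), function(i) {
      bce_loss(mil_forward(params, spec, regime, Xv[[i]])$p, yv[i])
    }, 0))
    history$train_loss[ep] <- tl / n
    history$val_loss[ep] <- vl
    if (is.finite(vl) && vl < best$loss) {
      best <- list(loss = vl, epoch = ep, params = deep_copy_params(params))
    }
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                      history$train_loss[ep], vl))
    }
  }
  if (is.null(best$params)) {  # all validation losses non-finite
    best <- list(loss = history$val_loss[epochs], epoch = epochs,
                 params = deep_copy_params(params))
  }
  structure(list(
    regime = regime, backbone = spec, params = best$params,
    feature_dim = spec$feature_dim, attention_dim = attention_dim,
    patch_size = spec$input_size, epochs = epochs,
    learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
    seed = seed, history = history, best_epoch = best$epoch,
    n_train = n, n_val = length(val_bags),
    call = match.call()
  ), class = "mil_model")
}

#' Predict malignancy probabilities for bags
#'
#' @param object A fitted [mil_fit()] model.
#' @param bags A list of bags, or a single bag.
#' @param attention Attach per-bag attention weight vectors as the
#'   `"attention"` attribute of the result.
#' @param ... Unused.
#' @return A data frame with `case_id`, `probability`, `predicted_label`
#'   (malignant iff probability >= 0.5) and, when available, `true_label`.
#' @export
predict.mil_model <- function(object, bags, attention = FALSE, ...) {
  if (inherits(bags, "bag")) bags <- list(bags)
  preds <- lapply(bags, function(b) predict_bag(object, b))
  out <- data.frame(
    case_id = vapply(preds, `[[`, "", "case_id"),
    probability = vapply(preds, `[[`, 0, "probability"),
    predicted_label = vapply(preds, `[[`, "", "predicted_label"),
    true_label = vapply(bags, function(b) {
      if (is.null(b$label)) NA_character_ else
        if (b$label == 1) "malignant" else "benign"
    }, ""),
    stringsAsFactors = FALSE
  )
  if (attention) {
    att <- lapply(preds, `[[`, "attention_weights")
    names(att) <- out$case_id
    attr(out, "attention") <- att
  }
  out
}

#' Classify a single bag, returning the full prediction object
#'
#' @param model A fitted [mil_fit()] model.
#' @param bag A `bag` object.
#' @return An object of class `bag_prediction` with `case_id`, `probability`,
#'   `attention_weights` (length `K`, summing to 1; uniform for the
#'   mean-pooling regime) and `predicted_label`.
#' @export
predict_bag <- function(model, bag) {
  X <- bag_to_array(bag, model$patch_size)
  fwd <- mil_forward(model$params, model$backbone, model$regime, X)
  structure(list(
    case_id = bag$case_id,
    probability = fwd$p,
    attention_weights = fwd$a,
    predicted_label = if (fwd$p >= 0.5) "malignant" else "benign",
    instances = bag$instances
  ), class = "bag_prediction")
}

#' @export
print.bag_prediction <- function(x, ...) {
  cat("Bag", x$case_id, "->", x$predicted_label,
      sprintf("(p = %.3f, K = %d)\n", x$probability, length(x$attention_weights)))
  invisible(x)
}

# ---- supervised baseline -----------------------------------------------------

#' Fit the supervised per-patch baseline
#'
#' Ordinary supervised learning on individual patches, each labelled with its
#' case's label (weak-label broadcast): backbone features, one extra fully
#' connected layer to two units, and a softmax. Training uses minibatches
#' (default 16 patches) with Adam, and returns the checkpoint with the lowest
#' validation loss.
#'
#' @param instances List of patch instances (training set).
#' @param labels Integer vector (0 benign / 1 malignant), one per instance.
#' @param val_instances,val_labels Validation patches and labels.
#' @param backbone Backbone family name or `backbone_spec` (default
#'   `"alexnet_like"`, the family used for this baseline).
#' @param patch_size Patch edge length.
#' @param epochs Training epochs (default 100).
#' @param batch_size Patches per minibatch (default 16).
#' @param learning_rate,beta1,beta2 Adam hyperparameters (defaults 5e-5, 0.9,
#'   0.999).
#' @param feature_dim Backbone feature length `L`.
#' @param seed Seed for initialisation and shuffling.
#' @param verbose Print per-epoch losses.
#' @return An object of class `supervised_model`.
#' @export
supervised_fit <- function(instances, labels, val_instances, val_labels,
                           backbone = "alexnet_like",
                           patch_size = 64L,
                           epochs = 100L,
                           batch_size = 16L,
                           learning_rate = 5e-5,
                           beta1 = 0.9, beta2 = 0.999,
                           feature_dim = 500L,
                           seed = 1L,
                           verbose = FALSE) {
  if (length(instances) != length(labels)) {
    stop("instances and labels lengths differ")
  }
  if (length(unique(labels)) < 2) {
    stop("training error: training patches contain a single class")
  }
  spec <- if (inherits(backbone, "backbone_spec")) backbone else {
    backbone_spec(backbone, input_size = patch_size, feature_dim = feature_dim)
  }
  set.seed(seed)
  L <- spec$feature_dim
  params <- init_layer_params(spec$layers)
  params$out_W <- matrix(rnorm(L * 2, sd = sqrt(1 / L)), L, 2)
  params$out_b <- numeric(2)
  st <- adam_init(params)

  stack <- function(inst) {
    X <- array(0, c(patch_size, patch_size, 3, length(inst)))
    for (k in seq_along(inst)) {
      p <- inst[[k]]$pixels
      if (dim(p)[1] != patch_size || dim(p)[2] != patch_size) {
        stop("instance size ", dim(p)[1], "x", dim(p)[2],
             " does not match patch size ", patch_size)
      }
      X[, , , k] <- p
    }
    X
  }
  Xall <- stack(instances)
  Xval <- stack(val_instances)

  soft_fwd <- function(params, X) {
    r <- seq_forward(spec$layers, params, X)
    logits <- r$out %*% params$out_W +
      rep(params$out_b, each = nrow(r$out))
    pm <- exp(logits - apply(logits, 1, max))
    pm <- pm / rowSums(pm)
    list(probs = pm, H = r$out, cache = r$cache)
  }
  ce <- function(probs, y) -mean(log(pmax(probs[cbind(seq_along(y), y + 1L)], 1e-12)))

  n <- length(instances)
  history <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                        val_loss = NA_real_)
  best <- list(loss = Inf, epoch = NA_integer_, params = NULL)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    tl <- 0
    for (bi in batches) {
      X <- Xall[, , , bi, drop = FALSE]
      y <- labels[bi]
      fwd <- soft_fwd(params, X)
      tl <- tl + ce(fwd$probs, y) * length(bi)
      dlogits <- fwd$probs
      dlogits[cbind(seq_along(y), y + 1L)] <-
        dlogits[cbind(seq_along(y), y + 1L)] - 1
      dlogits <- dlogits / length(bi)
      genv <- new.env(parent = emptyenv())
      genv$g <- list(out_W = crossprod(fwd$H, dlogits),
                     out_b = colSums(dlogits))
      dH <- dlogits %*% t(params$out_W)
      seq_backward(spec$layers, params, fwd$cache, dH, genv, need_dx = FALSE)
      params <- adam_update(params, genv$g, st, learning_rate, beta1, beta2)
    }
    vfwd <- soft_fwd(params, Xval)
    vl <- ce(vfwd$probs, val_labels)
    history$train_loss[ep] <- tl / n
    history$val_loss[ep] <- vl
    if (is.finite(vl) && vl < best$loss) {
      best <- list(loss = vl, epoch = ep, params = deep_copy_params(params))
    }
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                      history$train_loss[ep], vl))
    }
  }
  if (is.null(best$params)) {
    best <- list(loss = history$val_loss[epochs], epoch = epochs,
                 params = deep_copy_params(params))
  }
  structure(list(
    backbone = spec, params = best$params, patch_size = as.integer(patch_size),
    epochs = epochs, batch_size = batch_size, learning_rate = learning_rate,
    seed = seed, history = history, best_epoch = best$epoch,
    call = match.call()
  ), class = "supervised_model")
}

#' Per-patch malignancy probabilities from the supervised baseline
#'
#' @param object A fitted [supervised_fit()] model.
#' @param instances List of patch instances.
#' @param ... Unused.
#' @return A data frame with `image_id`, `p_benign` and `probability` (the
#'   softmax malignancy probability; the two sum to one) per patch.
#' @export
predict.supervised_model <- function(object, instances, ...) {
  ps <- object$patch_size
  X <- array(0, c(ps, ps, 3, length(instances)))
  for (k in seq_along(instances)) {
    p <- instances[[k]]$pixels
    if (dim(p)[1] != ps || dim(p)[2] != ps) {
      stop("instance size ", dim(p)[1], "x", dim(p)[2],
           " does not match patch size ", ps)
    }
    X[, , , k] <- p
  }
  r <- seq_forward(object$backbone$layers, object$params, X)
  logits <- r$out %*% object$params$out_W +
    rep(object$params$out_b, each = nrow(r$out))
  pm <- exp(logits - apply(logits, 1, max))
  pm <- pm / rowSums(pm)
  data.frame(
    image_id = vapply(instances, `[[`, "", "image_id"),
    p_benign = pm[, 1],
    probability = pm[, 2],
    stringsAsFactors = FALSE
  )
}

#' Case-level max aggregation of malignancy probabilities
#'
#' In clinical reading a case is malignant if any of its images contains
#' malignant cells, so the supervised baseline aggregates per-image (and, one
#' level down, per-patch) probabilities by their maximum.
#'
#' @param probabilities Numeric vector of malignancy probabilities for one
#'   case.
#' @return The maximum probability; the case is predicted malignant iff this
#'   maximum is at least 0.5.
#' @export
case_max_aggregate <- function(probabilities) {
  if (length(probabilities) == 0) {
    stop("case_max_aggregate: no probabilities supplied")
  }
  max(probabilities)
}

# ---- cross-validation --------------------------------------------------------

#' Cross-validated out-of-fold evaluation
#'
#' Trains one model per fold on that fold's training bags (with its
#' validation subset for epoch selection) and predicts the held-out test
#' cases, so every case receives exactly one out-of-fold prediction; results
#' are concatenated across folds into a single case-level table, from which
#' one pooled confusion matrix can be formed. Train/test disjointness by case
#' is asserted at runtime for every fold.
#'
#' For `regime = "supervised"`, patches of the training cases inherit their
#' case label, a per-patch classifier is trained, and the case probability is
#' the maximum patch probability over all the case's images
#' ([case_max_aggregate()]).
#'
#' @param bags All bags.
#' @param splits A [make_cv_splits()] covering exactly these bags.
#' @param regime `"admil"`, `"mean_mil"` or `"supervised"`.
#' @param backbone Backbone family name (default `"lenet_like"` for MIL,
#'   `"alexnet_like"` for supervised).
#' @param epochs,learning_rate,batch_size Passed to the fitting function;
#'   `NULL` uses that regime's default.
#' @param seed Base seed; fold `f` trains with seed `seed + f`.
#' @param patch_size,feature_dim,attention_dim Model dimensions.
#' @param keep_attention For MIL regimes, attach each case's out-of-fold
#'   attention weights as the `"attention"` attribute (a named list).
#' @param verbose Print fold progress.
#' @return A data frame of case results (`case_id`, `fold`, `true_label`,
#'   `probability`, `predicted_label`, `regime`), one row per case.
#' @export
run_cross_validation <- function(bags, splits,
                                 regime = c("admil", "mean_mil", "supervised"),
                                 backbone = NULL,
                                 epochs = 100L,
                                 learning_rate = NULL,
                                 batch_size = NULL,
                                 seed = 1L,
                                 patch_size = 64L,
                                 feature_dim = 500L,
                                 attention_dim = 128L,
                                 keep_attention = FALSE,
                                 verbose = FALSE) {
  regime <- match.arg(regime)
  if (is.null(backbone)) {
    backbone <- if (regime == "supervised") "alexnet_like" else "lenet_like"
  }
  by_case <- stats::setNames(bags, vapply(bags, `[[`, "", "case_id"))
  covered <- sort(names(by_case))
  if (!identical(covered, sort(splits$assignment$case_id))) {
    stop("splits do not cover exactly the supplied bags")
  }
  results <- NULL
  attention <- list()
  for (f in seq_len(splits$n_folds)) {
    fold <- splits$folds[[f]]
    stopifnot(length(intersect(fold$test, fold$train)) == 0,
              length(intersect(fold$test, fold$validation)) == 0)
    if (verbose) message("fold ", f, "/", splits$n_folds)
    fold_seed <- seed + f
    test_bags <- by_case[fold$test]
    if (regime == "supervised") {
      flat <- function(ids) {
        inst <- unlist(lapply(by_case[ids], `[[`, "instances"), recursive = FALSE)
        labs <- unlist(lapply(by_case[ids], function(b) rep(b$label, b$K)))
        list(inst = inst, labs = labs)
      }
      tr <- flat(fold$train)
      va <- flat(fold$validation)
      fit <- supervised_fit(tr$inst, tr$labs, va$inst, va$labs,
                            backbone = backbone, patch_size = patch_size,
                            epochs = epochs,
                            batch_size = batch_size %||% 16L,
                            learning_rate = learning_rate %||% 5e-5,
                            feature_dim = feature_dim, seed = fold_seed)
      prob <- vapply(test_bags, function(b) {
        pp <- predict(fit, b$instances)
        img_max <- tapply(pp$probability, pp$image_id, max)
        case_max_aggregate(as.numeric(img_max))
      }, 0)
    } else {
      fit <- mil_fit(by_case[fold$train], by_case[fold$validation],
                     regime = regime, backbone = backbone,
                     patch_size = patch_size, epochs = epochs,
                     batch_size = batch_size %||% 1L,
                     learning_rate = learning_rate %||% 5e-4,
                     feature_dim = feature_dim, attention_dim = attention_dim,
                     seed = fold_seed)
      pr <- predict(fit, test_bags, attention = keep_attention)
      prob <- pr$probability
      if (keep_attention) attention <- c(attention, attr(pr, "attention"))
    }
    results <- rbind(results, data.frame(
      case_id = fold$test,
      fold = f,
      true_label = ifelse(vapply(test_bags, `[[`, 0L, "label") == 1,
                          "malignant", "benign"),
      probability = prob,
      predicted_label = ifelse(prob >= 0.5, "malignant", "benign"),
      regime = regime,
      stringsAsFactors = FALSE
    ))
  }
  rownames(results) <- NULL
  stopifnot(!anyDuplicated(results$case_id),
            nrow(results) == length(bags))
  if (keep_attention) attr(results, "attention") <- attention
  results
}
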