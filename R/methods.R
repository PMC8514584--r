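# Standard modelling-object methods for fitted models.

#' @export
print.mil_model <- function(x, ...) {
  cat("Attention-based deep MIL classifier\n")
  cat("  regime:  ", if (x$regime == "admil") "attention pooling (AD MIL)"
      else "mean pooling (conventional MIL)", "\n")
  cat("  backbone:", x$backbone$name, "-", x$patch_size, "px patches ->",
      x$feature_dim, "features\n")
  cat(sprintf("  trained:  %d epochs on %d bags (Adam, lr %g, batch 1)\n",
              x$epochs, x$n_train, x$learning_rate))
  cat(sprintf("  selected: epoch %d (validation loss %.4f)\n",
              x$best_epoch, x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
summary.mil_model <- function(object, ...) {
  structure(list(model = object), class = "summary.mil_model")
}

#' @export
print.summary.mil_model <- function(x, ...) {
  m <- x$model
  print(m)
  h <- m$history
  cat("\nLoss trajectory:\n")
  show <- unique(c(1, m$best_epoch, nrow(h)))
  print(h[show, ], row.names = FALSE)
  np <- sum(vapply(m$params, length, 0L))
  cat("\nParameters:", format(np, big.mark = ","),
      sprintf("(attention D = %d)\n", m$attention_dim))
  invisible(x)
}

#' Model parameters of a fitted MIL classifier
#'
#' @param object A fitted [mil_fit()] model.
#' @param ... Unused.
#' @return Named list of parameter arrays: backbone weights, the attention
#'   parameters `att_V` (D x L) and `att_w` (D), and the sigmoid head
#'   `head_u`, `head_b`.
#' @export
coef.mil_model <- function(object, ...) object$params

#' Plot training and validation loss curves
#'
#' @param x A fitted [mil_fit()] or [supervised_fit()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mil_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
print.supervised_model <- function(x, ...) {
  cat("Supervised per-patch baseline (", x$backbone$name, ", softmax head)\n",
      sep = "")
  cat(sprintf("  trained:  %d epochs (Adam, lr %g, batch %d)\n",
              x$epochs, x$learning_rate, x$batch_size))
  cat(sprintf("  selected: epoch %d (validation loss %.4f)\n",
              x$best_epoch, x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' @rdname plot.mil_model
#' @export
plot.supervised_model <- function(x, ...) plot.mil_model(x, ...)

.onLoad <- function(libname, pkgname) {
  # keep large scratch blocks heap-resident and pin BLAS to one thread (see
  # src/layers.cpp); skip when the compiled code is unavailable (e.g. source
  # loads during development)
  tryCatch({
    tune_allocator()
    limit_blas_threads()
  }, error = function(e) NULL)
}
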