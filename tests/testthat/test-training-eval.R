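# Training behaviour on a small planted-signal dataset. Sizes are kept small
# (12 cases, few epochs) so these run in seconds; the full-scale experiment
# lives in test-acceptance.R.

get_tiny <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- small_dataset(n_cases = 12, seed = 31)
    cache
  }
})

split_tiny <- function(d, fold = 1, n_folds = 3, seed = 31) {
  sp <- make_cv_splits(d$bags, n_folds = n_folds, seed = seed)
  by_case <- setNames(d$bags, vapply(d$bags, `[[`, "", "case_id"))
  f <- sp$folds[[fold]]
  list(splits = sp, by_case = by_case, fold = f)
}

test_that("MIL training reduces validation loss on a learnable signal", {
  d <- get_tiny()
  s <- split_tiny(d)
  fit <- mil_fit(s$by_case[s$fold$train], s$by_case[s$fold$validation],
                 regime = "admil", backbone = "lenet_like",
                 epochs = 12, seed = 7)
  h <- fit$history
  expect_equal(nrow(h), 12)
  expect_lt(h$val_loss[fit$best_epoch], h$val_loss[1])
  expect_true(all(is.finite(h$train_loss)))
})

test_that("training is deterministic for a fixed seed", {
  d <- get_tiny()
  s <- split_tiny(d)
  f1 <- mil_fit(s$by_case[s$fold$train], s$by_case[s$fold$validation],
                regime = "mean_mil", epochs = 4, seed = 11)
  f2 <- mil_fit(s$by_case[s$fold$train], s$by_case[s$fold$validation],
                regime = "mean_mil", epochs = 4, seed = 11)
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
  expect_equal(f1$params, f2$params, tolerance = 1e-12)
})

test_that("contract guards reject invalid MIL training setups", {
  d <- get_tiny()
  s <- split_tiny(d)
  tr <- s$by_case[s$fold$train]
  va <- s$by_case[s$fold$validation]
  expect_error(mil_fit(tr, va, regime = "supervised"), "supervised_fit")
  expect_error(mil_fit(tr, va, batch_size = 4), "batch_size 1")
  onecls <- Filter(function(b) b$label == 1, tr)
  expect_error(mil_fit(onecls, va), "single class")
  expect_error(mil_fit(list(), va), "non-empty")
})

test_that("supervised baseline trains, normalises softmax, guards shapes", {
  d <- get_tiny()
  s <- split_tiny(d)
  flat <- function(ids) {
    bs <- s$by_case[ids]
    list(inst = unlist(lapply(bs, `[[`, "instances"), recursive = FALSE),
         labs = unlist(lapply(bs, function(b) rep(b$label, b$K))))
  }
  tr <- flat(s$fold$train)
  va <- flat(s$fold$validation)
  fit <- supervised_fit(tr$inst, tr$labs, va$inst, va$labs,
                        backbone = "alexnet_like", epochs = 12,
                        feature_dim = 60, seed = 3)
  h <- fit$history
  # the small supervised learning rate moves slowly; training loss must
  # still have decreased over the run
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  pr <- predict(fit, va$inst)
  expect_equal(pr$p_benign + pr$probability, rep(1, nrow(pr)), tolerance = 1e-9)
  expect_true(all(pr$probability > 0 & pr$probability < 1))
  bad <- list(fake_instance("x", 0, 0, patch_size = 32L))
  expect_error(predict(fit, bad), "does not match")
  expect_error(supervised_fit(tr$inst, rep(1L, length(tr$inst)),
                              va$inst, va$labs),
               "single class")
})

test_that("case-level max aggregation follows the clinical rule", {
  expect_equal(case_max_aggregate(c(0.2, 0.9, 0.4)), 0.9)
  expect_true(case_max_aggregate(c(0.2, 0.9, 0.4)) >= 0.5)
  expect_true(case_max_aggregate(c(0.1, 0.3, 0.45)) < 0.5)
  expect_equal(case_max_aggregate(0.37), 0.37)
  expect_error(case_max_aggregate(numeric(0)), "no probabilities")
})

test_that("cross-validation covers every case exactly once without leakage", {
  d <- get_tiny()
  sp <- make_cv_splits(d$bags, n_folds = 3, seed = 13)
  res <- run_cross_validation(d$bags, sp, regime = "admil",
                              backbone = "lenet_like", epochs = 3,
                              seed = 13, keep_attention = TRUE)
  expect_equal(nrow(res), length(d$bags))
  expect_equal(anyDuplicated(res$case_id), 0)
  expect_setequal(res$case_id, vapply(d$bags, `[[`, "", "case_id"))
  expect_true(all(res$probability > 0 & res$probability < 1))
  expect_equal(res$predicted_label,
               ifelse(res$probability >= 0.5, "malignant", "benign"))
  att <- attr(res, "attention")
  expect_length(att, length(d$bags))
  Ks <- vapply(d$bags, `[[`, 0L, "K")
  names(Ks) <- vapply(d$bags, `[[`, "", "case_id")
  for (cid in names(att)) {
    expect_length(att[[cid]], Ks[[cid]])
    expect_equal(sum(att[[cid]]), 1, tolerance = 1e-6)
  }
})

test_that("cross-validation rejects splits that do not match the bags", {
  d <- get_tiny()
  sp <- make_cv_splits(d$bags, n_folds = 3, seed = 13)
  expect_error(run_cross_validation(d$bags[-1], sp, regime = "admil",
                                    epochs = 2, seed = 1),
               "do not cover")
})
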