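# Scaled-down end-to-end experiment shared by the acceptance tests: 40
# synthetic cases (small 256 x 192 profile, planted malignant signal),
# lenet-like backbone, 30 epochs, 10-fold case-stratified CV, attention and
# mean-pooling regimes. Results are cached per seed within the test session.

.experiment_cache <- new.env(parent = emptyenv())

scaled_experiment <- function(seed) {
  key <- paste0("seed", seed)
  if (!is.null(.experiment_cache[[key]])) return(.experiment_cache[[key]])
  cfg <- synth_config(n_cases = 40, seed = seed)
  dir <- file.path(tempdir(), paste0("admil_exp_", seed))
  gen <- generate_dataset(cfg, dir)
  ex <- extract_dataset(gen$manifest, dir, extraction_config(64))
  bags <- build_bags(ex$instances, ex$manifest)
  splits <- make_cv_splits(bags, n_folds = 10, seed = seed)
  res_admil <- run_cross_validation(bags, splits, regime = "admil",
                                    backbone = "lenet_like", epochs = 30,
                                    seed = seed, keep_attention = TRUE)
  res_mean <- run_cross_validation(bags, splits, regime = "mean_mil",
                                   backbone = "lenet_like", epochs = 30,
                                   seed = seed)
  out <- list(
    bags = bags,
    admil = res_admil,
    mean_mil = res_mean,
    admil_balacc = compute_metrics(results_to_confusion(res_admil))$balanced_accuracy,
    mean_balacc = compute_metrics(results_to_confusion(res_mean))$balanced_accuracy,
    localization = attention_localization(bags, res_admil, gen$ground_truth, 64)
  )
  .experiment_cache[[key]] <- out
  out
}

experiment_seeds <- c(1L, 2L, 3L)
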