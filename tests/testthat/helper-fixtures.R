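# Fabricated in-memory fixtures: patch instances, bags, and an independent
# brute-force Otsu oracle. All randomness is seeded inside each test.

fake_instance <- function(image_id, grid_row, grid_col, patch_size = 8L,
                          value = 0.5) {
  px <- if (length(value) == 1) {
    array(value, c(patch_size, patch_size, 3))
  } else {
    array(value, c(patch_size, patch_size, 3))
  }
  structure(list(pixels = px, image_id = image_id,
                 grid_row = grid_row, grid_col = grid_col,
                 origin_x = grid_col * patch_size,
                 origin_y = grid_row * patch_size,
                 foreground_fraction = 0.5),
            class = "patch_instance")
}

random_instance <- function(image_id, grid_row = 0L, grid_col = 0L,
                            patch_size = 8L) {
  fake_instance(image_id, grid_row, grid_col, patch_size,
                value = runif(patch_size * patch_size * 3))
}

fake_bag <- function(case_id, label, K, patch_size = 8L, random = FALSE) {
  image_id <- paste0(case_id, "_img01")
  inst <- lapply(seq_len(K) - 1L, function(k) {
    if (random) random_instance(image_id, grid_row = 0L, grid_col = k,
                                patch_size = patch_size)
    else fake_instance(image_id, grid_row = 0L, grid_col = k, patch_size)
  })
  structure(list(case_id = case_id, label = as.integer(label),
                 instances = inst, K = K), class = "bag")
}

# independent oracle: scan all 256 candidate thresholds, recomputing class
# means directly from the pixels (foreground = strictly below t)
otsu_brute <- function(gray) {
  n <- length(gray)
  best <- -Inf
  best_t <- NA_real_
  for (t in 1:255) {
    fg <- gray < t
    n0 <- sum(fg)
    if (n0 == 0 || n0 == n) next
    w0 <- n0 / n
    s <- w0 * (1 - w0) * (mean(gray[fg]) - mean(gray[!fg]))^2
    if (s > best) {
      best <- s
      best_t <- t
    }
  }
  best_t
}

# small synthetic dataset on disk (generated fresh per seed, cached per
# session directory)
small_dataset <- function(n_cases, seed, patch_size = 64L) {
  dir <- file.path(tempdir(), sprintf("admil_tiny_%d_%d", n_cases, seed))
  cfg <- synth_config(n_cases = n_cases, seed = seed)
  gen <- if (dir.exists(dir)) {
    list(manifest = read.csv(file.path(dir, "manifest.csv"),
                             stringsAsFactors = FALSE),
         ground_truth = jsonlite::fromJSON(file.path(dir, "ground_truth.json"),
                                           simplifyVector = TRUE),
         dir = dir)
  } else {
    generate_dataset(cfg, dir)
  }
  ex <- extract_dataset(gen$manifest, dir, extraction_config(patch_size))
  bags <- build_bags(ex$instances, ex$manifest)
  list(config = cfg, gen = gen, extraction = ex, bags = bags, dir = dir)
}
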