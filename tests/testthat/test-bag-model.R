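make_instances_map <- function(cases, images_per_case, patches_per_image) {
  inst <- list()
  manifest <- NULL
  for (ci in seq_along(cases)) {
    for (ii in seq_len(images_per_case)) {
      img_id <- sprintf("%s_img%02d", cases[ci], ii)
      inst[[img_id]] <- lapply(seq_len(patches_per_image) - 1L, function(k) {
        fake_instance(img_id, grid_row = 0L, grid_col = k)
      })
      manifest <- rbind(manifest, data.frame(
        case_id = cases[ci], image_id = img_id,
        label = if (ci %% 2 == 0) "malignant" else "benign",
        stringsAsFactors = FALSE))
    }
  }
  list(instances = inst, manifest = manifest)
}

test_that("bags collect all retained patches of a case in stable order", {
  m <- make_instances_map(c("caseA", "caseB"), images_per_case = 3,
                          patches_per_image = 4)
  bags <- build_bags(m$instances, m$manifest)
  expect_length(bags, 2)
  expect_equal(vapply(bags, `[[`, 0L, "K"), c(12L, 12L))
  b <- bags[[1]]
  key <- data.frame(img = vapply(b$instances, `[[`, "", "image_id"),
                    row = vapply(b$instances, `[[`, 0, "grid_row"),
                    col = vapply(b$instances, `[[`, 0, "grid_col"))
  expect_equal(order(key$img, key$row, key$col), seq_len(12))
  expect_true(all(grepl("^caseA", key$img)))
})

test_that("cases without retained instances are excluded with a warning", {
  m <- make_instances_map(c("caseA", "caseB"), 1, 2)
  m$instances[["caseB_img01"]] <- list()
  expect_warning(bags <- build_bags(m$instances, m$manifest), "caseB")
  expect_length(bags, 1)
  expect_equal(bags[[1]]$case_id, "caseA")
})

test_that("a single retained patch still forms a valid bag", {
  m <- make_instances_map("caseZ", 1, 1)
  bags <- build_bags(m$instances, m$manifest)
  expect_equal(bags[[1]]$K, 1L)
})

test_that("instances from an image missing in the manifest are an error", {
  m <- make_instances_map("caseA", 1, 2)
  m$instances[["orphan_img01"]] <- list(fake_instance("orphan_img01", 0, 0))
  expect_error(build_bags(m$instances, m$manifest), "manifest error")
})

test_that("splits are stratified, balanced, disjoint and deterministic", {
  bags <- c(lapply(1:10, function(i) fake_bag(sprintf("b%02d", i), 0, 1)),
            lapply(1:10, function(i) fake_bag(sprintf("m%02d", i), 1, 1)))
  sp <- make_cv_splits(bags, n_folds = 10, seed = 4)
  tab <- table(sp$assignment$fold, sp$assignment$label)
  expect_true(all(tab == 1))                    # 1 benign + 1 malignant per fold
  sp2 <- make_cv_splits(bags, n_folds = 10, seed = 4)
  expect_identical(sp$assignment, sp2$assignment)
  sp3 <- make_cv_splits(bags, n_folds = 10, seed = 5)
  expect_false(identical(sp$assignment$fold, sp3$assignment$fold))
  # partition property
  all_test <- unlist(lapply(sp$folds, `[[`, "test"))
  expect_setequal(all_test, sp$assignment$case_id)
  expect_equal(anyDuplicated(all_test), 0)
  for (f in sp$folds) {
    expect_length(intersect(f$test, f$train), 0)
    expect_length(intersect(f$test, f$validation), 0)
    expect_length(intersect(f$train, f$validation), 0)
  }
})

test_that("the 322-case mix (108 benign / 214 malignant) gives folds of 32-33", {
  bags <- c(lapply(1:108, function(i) fake_bag(sprintf("b%03d", i), 0, 1)),
            lapply(1:214, function(i) fake_bag(sprintf("m%03d", i), 1, 1)))
  sp <- make_cv_splits(bags, n_folds = 10, seed = 1)
  sizes <- as.vector(table(sp$assignment$fold))
  expect_true(all(sizes %in% c(32, 33)))
  frac <- tapply(sp$assignment$label, sp$assignment$fold, mean)
  glob <- 214 / 322
  # per-fold malignant count within one case of perfect stratification
  expect_true(all(abs(frac * sizes - glob * sizes) <= 1.5))
})

test_that("more folds than bags is a configuration error", {
  bags <- lapply(1:5, function(i) fake_bag(paste0("c", i), i %% 2, 1))
  expect_error(make_cv_splits(bags, n_folds = 10, seed = 1), "folds")
})

test_that("splits serialise to JSON with seed and membership", {
  bags <- lapply(1:6, function(i) fake_bag(paste0("c", i), i %% 2, 1))
  sp <- make_cv_splits(bags, n_folds = 3, seed = 9)
  path <- tempfile(fileext = ".json")
  write_splits(sp, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$seed, 9)
  expect_equal(back$n_folds, 3)
  expect_setequal(back$assignment$case_id, paste0("c", 1:6))
})
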