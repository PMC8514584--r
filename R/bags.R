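# Bag assembly and case-stratified cross-validation. A bag is the unit of
# weak supervision: all retained patch instances from all images of one case,
# carrying a single benign/malignant label. Splits are always by case, never
# by image or patch, so no case can leak between train and test.

#' Assemble per-case bags from extracted instances
#'
#' @param instances Per-image list of instance lists as returned by
#'   [extract_dataset()] (`$instances`), named by image id.
#' @param manifest Data frame with columns `case_id`, `image_id`, `label`
#'   (`benign`/`malignant`).
#' @return A list of `bag` objects with fields `case_id`, `label` (0 benign /
#'   1 malignant), `instances` (ordered by image id, grid row, grid column)
#'   and `K`. Cases whose images retained no instances are excluded with a
#'   warning.
#' @export
build_bags <- function(instances, manifest) {
  if (!all(c("case_id", "image_id", "label") %in% names(manifest))) {
    stop("manifest must have columns case_id, image_id, label")
  }
  unknown <- setdiff(names(instances), manifest$image_id)
  if (length(unknown) > 0) {
    stop("manifest error: image(s) without a case: ",
         paste(unknown, collapse = ", "))
  }
  case_ids <- unique(manifest$case_id)
  bags <- list()
  for (cid in case_ids) {
    imgs <- sort(manifest$image_id[manifest$case_id == cid])
    inst <- unlist(lapply(imgs, function(im) instances[[im]]), recursive = FALSE)
    if (length(inst) == 0) {
      warning("case ", cid, " has no retained instances; excluded from bags")
      next
    }
    ord <- order(vapply(inst, `[[`, "", "image_id"),
                 vapply(inst, `[[`, 0, "grid_row"),
                 vapply(inst, `[[`, 0, "grid_col"))
    inst <- inst[ord]
    lab <- unique(manifest$label[manifest$case_id == cid])
    if (length(lab) != 1 || !lab %in% c("benign", "malignant")) {
      stop("case ", cid, " has inconsistent or unknown label")
    }
    bags[[cid]] <- structure(list(
      case_id = cid,
      label = if (lab == "malignant") 1L else 0L,
      instances = inst,
      K = length(inst)
    ), class = "bag")
  }
  unname(bags)
}

#' @export
print.bag <- function(x, ...) {
  cat("Bag", x$case_id, "-", if (x$label == 1) "malignant" else "benign",
      "-", x$K, "instances\n")
  invisible(x)
}

# Deal each label class round-robin into folds, giving each class's remainder
# to the folds with the smallest running totals, so per-fold class counts
# differ by at most one from perfect stratification and total fold sizes by
# at most one overall.
stratified_assign <- function(labels, n_folds) {
  fold <- integer(length(labels))
  totals <- integer(n_folds)
  for (lab in sort(unique(labels))) {
    idx <- which(labels == lab)          # caller shuffles beforehand
    n <- length(idx)
    base <- n %/% n_folds
    rem <- n %% n_folds
    quota <- rep(base, n_folds)
    if (rem > 0) {
      extra <- order(totals, seq_len(n_folds))[seq_len(rem)]
      quota[extra] <- quota[extra] + 1L
    }
    f <- rep.int(seq_len(n_folds), quota)
    fold[idx] <- f
    totals <- totals + quota
  }
  fold
}

#' Case-stratified cross-validation splits
#'
#' Assigns each bag (case) to exactly one test fold, stratified by label so
#' every fold's benign/malignant ratio matches the global ratio to within one
#' case, with fold sizes differing by at most one. Within each fold, a
#' fraction of the training cases (default 10%) is further set aside as a
#' validation set by the same seeded stratified procedure.
#'
#' @param bags List of bags from [build_bags()].
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @param val_fraction Fraction of each fold's training cases used for
#'   validation-loss monitoring.
#' @return An object of class `cv_splits`: a table of case ids, labels and
#'   fold numbers, plus per-fold `train`/`validation`/`test` case id lists.
#' @export
make_cv_splits <- function(bags, n_folds = 10L, seed = 1L, val_fraction = 0.1) {
  n <- length(bags)
  if (n_folds > n) {
    stop("configuration error: more folds (", n_folds, ") than bags (", n, ")")
  }
  case_id <- vapply(bags, `[[`, "", "case_id")
  label <- vapply(bags, `[[`, 0L, "label")
  set.seed(seed)
  perm <- sample.int(n)
  fold <- integer(n)
  fold[perm] <- stratified_assign(label[perm], n_folds)
  assignment <- data.frame(case_id = case_id, label = label, fold = fold,
                           stringsAsFactors = FALSE)
  folds <- lapply(seq_len(n_folds), function(f) {
    test <- case_id[fold == f]
    pool_idx <- which(fold != f)
    # stratified validation subset of the training cases
    pool_perm <- pool_idx[sample.int(length(pool_idx))]
    n_val <- max(1L, round(val_fraction * length(pool_idx)))
    val_sel <- integer(0)
    for (lab in sort(unique(label[pool_perm]))) {
      cand <- pool_perm[label[pool_perm] == lab]
      k <- round(n_val * length(cand) / length(pool_idx))
      k <- min(max(k, if (length(cand) > 1) 1L else 0L), length(cand) - 1L)
      val_sel <- c(val_sel, cand[seq_len(k)])
    }
    list(train = case_id[setdiff(pool_perm, val_sel)],
         validation = case_id[val_sel],
         test = test)
  })
  structure(list(assignment = assignment, folds = folds,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 val_fraction = val_fraction),
            class = "cv_splits")
}

#' @export
print.cv_splits <- function(x, ...) {
  tab <- table(factor(x$assignment$fold, levels = seq_len(x$n_folds)),
               ifelse(x$assignment$label == 1, "malignant", "benign"))
  cat(x$n_folds, "-fold case-stratified cross-validation of ",
      nrow(x$assignment), " cases (seed ", x$seed, ")\n", sep = "")
  print(tab)
  invisible(x)
}

#' Write cross-validation splits to JSON
#'
#' Records fold membership per case id together with the seed and fold count,
#' so a run can be reproduced exactly.
#'
#' @param splits A [make_cv_splits()] object.
#' @param path Output JSON file path.
#' @export
write_splits <- function(splits, path) {
  jsonlite::write_json(list(
    n_folds = splits$n_folds, seed = splits$seed,
    val_fraction = splits$val_fraction,
    assignment = splits$assignment,
    folds = splits$folds
  ), path, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
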