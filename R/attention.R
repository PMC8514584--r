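# Attention-map rendering: the per-instance attention weights of a
# classified bag, shaded tile-by-tile over the source specimen image.
# Rendering is a pure function of (image, weights, normalisation), so maps
# are exactly reproducible from a saved model.

#' Sequential attention colormap
#'
#' Maps normalised weights in `[0, 1]` through an ordered blue-yellow-red
#' ramp (low attention cold, high attention hot). The red channel is
#' non-decreasing and the blue channel non-increasing in the weight, so
#' colour warmth is monotone in attention.
#'
#' @param t Numeric vector in `[0, 1]`.
#' @param colors Ramp anchor colours.
#' @return A matrix with one RGB row (in `[0, 1]`) per element of `t`.
#' @export
attention_colors <- function(t, colors = c("blue", "yellow", "red")) {
  ramp <- grDevices::colorRamp(colors)
  ramp(pmin(pmax(t, 0), 1)) / 255
}

#' Render an attention map for one specimen image
#'
#' Places each retained instance's attention weight at its tile position
#' (using the instance's recorded pixel origin), normalises the weights, and
#' alpha-blends the colormapped tiles onto the source image. Tiles without a
#' retained instance are left unshaded.
#'
#' @param image `(H, W, 3)` RGB array in `[0, 1]` (or `[0, 255]`).
#' @param prediction A [predict_bag()] result; its attention weights align
#'   1:1 with its instance list.
#' @param instances Instance list aligned with the prediction's weights;
#'   defaults to the instances stored in `prediction`.
#' @param image_id If given, only instances from this image are drawn (the
#'   usual case: one map per specimen image of the bag).
#' @param normalization `"per_image"` divides by the maximum weight among the
#'   displayed image's instances; `"per_bag"` by the bag-wide maximum.
#' @param alpha Overlay opacity in `[0, 1]`.
#' @param colors Colormap anchors, see [attention_colors()].
#' @return An object of class `attention_map`: `weights` (data frame with
#'   `grid_row`, `grid_col`, `raw_weight`, `normalized_weight`), `grid` (a
#'   weight matrix with `NA` at non-retained tiles) and `overlay` (the
#'   blended `(H, W, 3)` array).
#' @export
render_attention_map <- function(image, prediction, instances = NULL,
                                 image_id = NULL,
                                 normalization = c("per_image", "per_bag"),
                                 alpha = 0.45,
                                 colors = c("blue", "yellow", "red")) {
  normalization <- match.arg(normalization)
  if (is.list(image) && !is.null(image$pixels)) {
    if (is.null(image_id)) image_id <- image$image_id
    image <- image$pixels
  }
  if (max(image) > 1) image <- image / 255
  if (is.null(instances)) instances <- prediction$instances
  a <- prediction$attention_weights
  if (length(instances) != length(a)) {
    stop("attention weights (", length(a), ") and instances (",
         length(instances), ") do not align")
  }
  keep <- if (is.null(image_id)) seq_along(instances) else {
    which(vapply(instances, `[[`, "", "image_id") == image_id)
  }
  if (length(keep) == 0) stop("no instances for image ", image_id)
  inst <- instances[keep]
  raw <- a[keep]
  denom <- if (normalization == "per_image") max(raw) else max(a)
  norm <- raw / denom

  ps <- dim(inst[[1]]$pixels)[1]
  H <- dim(image)[1]
  W <- dim(image)[2]
  grid <- matrix(NA_real_, H %/% ps, W %/% ps)
  overlay <- image
  cols <- attention_colors(norm, colors)
  for (i in seq_along(inst)) {
    r <- inst[[i]]$grid_row
    c <- inst[[i]]$grid_col
    grid[r + 1, c + 1] <- norm[i]
    ys <- inst[[i]]$origin_y + seq_len(ps)
    xs <- inst[[i]]$origin_x + seq_len(ps)
    for (ch in 1:3) {
      overlay[ys, xs, ch] <- (1 - alpha) * overlay[ys, xs, ch] + alpha * cols[i, ch]
    }
  }
  structure(list(
    image_id = image_id %||% inst[[1]]$image_id,
    case_id = prediction$case_id,
    probability = prediction$probability,
    weights = data.frame(
      grid_row = vapply(inst, `[[`, 0, "grid_row"),
      grid_col = vapply(inst, `[[`, 0, "grid_col"),
      raw_weight = raw,
      normalized_weight = norm
    ),
    grid = grid,
    overlay = overlay,
    normalization = normalization
  ), class = "attention_map")
}

#' @export
print.attention_map <- function(x, ...) {
  cat("Attention map for image", x$image_id, "(case", x$case_id,
      sprintf(", p = %.3f)", x$probability), "\n")
  cat(" ", nrow(x$weights), "shaded tiles;", x$normalization, "normalization\n")
  invisible(x)
}

#' @export
plot.attention_map <- function(x, ...) {
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  plot(0, 0, type = "n", xlim = c(0, ncol(x$overlay)),
       ylim = c(nrow(x$overlay), 0), asp = 1, axes = FALSE,
       xlab = "", ylab = "",
       main = sprintf("%s  (p = %.3f)", x$image_id, x$probability), ...)
  graphics::rasterImage(x$overlay, 0, nrow(x$overlay), ncol(x$overlay), 0)
  invisible(x)
}

#' Attention localization against planted ground truth
#'
#' For each correctly classified malignant bag, compares the mean normalised
#' attention weight (per-bag max normalisation) over planted malignant-like
#' tiles with the mean over the remaining (background/benign-like) tiles.
#' On synthetic data with known cell positions this quantifies whether the
#' attention layer looks at the cells that carry the malignancy signal.
#'
#' @param bags The evaluated bags.
#' @param results Case-result data frame carrying the `"attention"` attribute
#'   (see [run_cross_validation()] with `keep_attention = TRUE`).
#' @param ground_truth Ground-truth list from [generate_dataset()], or the
#'   path of a `ground_truth.json` written by it.
#' @param patch_size Patch size whose ground-truth labels to use.
#' @return A data frame with one row per correctly classified malignant bag:
#'   `case_id`, `n_planted`, `n_background`, `mean_planted`,
#'   `mean_background`.
#' @export
attention_localization <- function(bags, results, ground_truth,
                                   patch_size = 64L) {
  if (is.character(ground_truth)) {
    ground_truth <- jsonlite::fromJSON(ground_truth, simplifyVector = TRUE)
  }
  attention <- attr(results, "attention")
  if (is.null(attention)) {
    stop("results carry no attention weights; ",
         "run run_cross_validation(..., keep_attention = TRUE)")
  }
  key <- paste0("patch_", patch_size)
  planted_patch <- function(image_id, grid_row, grid_col) {
    pl <- ground_truth[[image_id]]$patch_labels[[key]]
    hit <- pl$grid_row == grid_row & pl$grid_col == grid_col
    any(as.logical(pl$malignant_like)[hit])
  }
  by_case <- stats::setNames(bags, vapply(bags, `[[`, "", "case_id"))
  ok <- results$true_label == "malignant" &
    results$predicted_label == "malignant"
  rows <- lapply(results$case_id[ok], function(cid) {
    bag <- by_case[[cid]]
    a <- attention[[cid]]
    if (is.null(a) || length(a) != bag$K) {
      stop("attention weights missing or misaligned for case ", cid)
    }
    norm <- a / max(a)
    planted <- vapply(bag$instances, function(ins) {
      planted_patch(ins$image_id, ins$grid_row, ins$grid_col)
    }, TRUE)
    data.frame(case_id = cid,
               n_planted = sum(planted),
               n_background = sum(!planted),
               mean_planted = if (any(planted)) mean(norm[planted]) else NA_real_,
               mean_background = if (any(!planted)) mean(norm[!planted]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(case_id = character(), n_planted = integer(),
                      n_background = integer(), mean_planted = numeric(),
                      mean_background = numeric())
  }
  out
}

#' Save an attention map as PNG plus a per-tile CSV
#'
#' @param map An [render_attention_map()] result.
#' @param png_path Output PNG path for the overlay (optional).
#' @param csv_path Output CSV path for the per-tile weights (optional).
#' @export
save_attention_map <- function(map, png_path = NULL, csv_path = NULL) {
  if (!is.null(png_path)) png::writePNG(map$overlay, png_path)
  if (!is.null(csv_path)) write.csv(map$weights, csv_path, row.names = FALSE)
  invisible(map)
}
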