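# Instance generation: grid tiling of specimen images into fixed-size patch
# candidates, per-image Otsu binarisation, and the >10% cell-area retention
# rule. Stained cells are darker than the illuminated background, so
# foreground = intensity strictly below the Otsu threshold.

#' Instance extraction configuration
#'
#' @param patch_size Patch edge length in pixels; one of 64 (baseline), 96,
#'   128.
#' @param min_cell_fraction Minimum foreground (cell-area) fraction a patch
#'   must exceed -- strictly -- to be retained as an instance. Default 0.10.
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(patch_size = 64L, min_cell_fraction = 0.10) {
  if (!patch_size %in% c(64L, 96L, 128L)) {
    stop("patch_size must be one of 64, 96, 128")
  }
  if (min_cell_fraction < 0 || min_cell_fraction >= 1) {
    stop("min_cell_fraction must be in [0, 1)")
  }
  structure(list(patch_size = as.integer(patch_size),
                 min_cell_fraction = min_cell_fraction,
                 edge_policy = "drop_partial"),
            class = "extraction_config")
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Rec. 601 luminance, `Y = 0.299 R + 0.587 G + 0.114 B`, rounded half-up to
#' the nearest integer in 0-255.
#'
#' @param image Numeric `(H, W, 3)` array with values in `[0, 255]`, or in
#'   `[0, 1]` (as returned by [png::readPNG()]), which is rescaled first.
#' @return Integer-valued `(H, W)` matrix in 0-255.
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    stop("to_grayscale: input must be an (H, W, 3) RGB array")
  }
  if (max(image) <= 1) image <- image * 255
  y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  floor(y + 0.5)
}

#' Otsu threshold of a grayscale image
#'
#' Selects the threshold `t` in 0-255 maximising the between-class variance
#' of the 256-bin intensity histogram; pixels with intensity strictly below
#' `t` are foreground (cells). Ties are broken toward the lowest `t`. For a
#' constant image no split exists and `NA` is returned, which downstream
#' extraction treats as "no foreground".
#'
#' @param gray Numeric matrix of integer intensities in 0-255.
#' @return The threshold (numeric scalar), or `NA` if the image is constant.
#' @export
otsu_threshold <- function(gray) {
  if (length(gray) == 0) stop("otsu_threshold: empty input")
  counts <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  n <- sum(counts)
  levels <- 0:255
  csum <- cumsum(counts)            # pixels with intensity < t for t = 1..256
  cmean <- cumsum(counts * levels)
  mu_total <- cmean[256] / n
  # candidate thresholds t = 1..255: class0 = {< t}, class1 = {>= t}
  w0 <- csum[1:255] / n
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) return(NA_real_)
  mu0 <- cmean[1:255] / csum[1:255]
  mu1 <- (cmean[256] - cmean[1:255]) / (n - csum[1:255])
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  sigma_b[!valid] <- -Inf
  as.numeric(which.max(sigma_b))   # index i is threshold t = i; lowest on ties
}

#' Extract patch instances from a specimen image
#'
#' Tiles the image in a non-overlapping grid from the top-left corner
#' (partial tiles at the right/bottom edges are dropped), computes each
#' tile's foreground fraction against the whole-image Otsu threshold, and
#' retains tiles whose foreground fraction strictly exceeds
#' `config$min_cell_fraction`. Retained instances are ordered row-major.
#'
#' @param image Either an `(H, W, 3)` RGB array (values in `[0, 1]` or
#'   `[0, 255]`) or a list with fields `pixels` (such an array) and
#'   `image_id`.
#' @param config An [extraction_config()].
#' @param image_id Identifier recorded on the instances (overrides any id in
#'   `image`).
#' @return A list of `patch_instance` objects (fields: `pixels` in `[0, 1]`,
#'   `image_id`, `grid_row`, `grid_col`, `origin_x`, `origin_y`,
#'   `foreground_fraction`), with the full candidate-tile table (including
#'   dropped tiles) attached as attribute `"candidates"`.
#' @export
extract_instances <- function(image, config = extraction_config(),
                              image_id = NULL) {
  if (is.list(image)) {
    if (is.null(image_id)) image_id <- image$image_id
    image <- image$pixels
  }
  if (is.null(image_id)) image_id <- "image"
  if (max(image) > 1) image <- image / 255
  ps <- config$patch_size
  H <- dim(image)[1]
  W <- dim(image)[2]
  n_row <- H %/% ps
  n_col <- W %/% ps
  if (n_row < 1 || n_col < 1) {
    warning("image ", image_id, " (", W, "x", H, ") is smaller than patch size ",
            ps, "; no instances extracted")
    out <- list()
    attr(out, "candidates") <- data.frame()
    return(out)
  }
  gray <- to_grayscale(image)
  thr <- otsu_threshold(gray)
  fg <- if (is.na(thr)) matrix(FALSE, H, W) else gray < thr

  cand <- expand.grid(grid_col = 0:(n_col - 1), grid_row = 0:(n_row - 1))
  cand <- cand[, c("grid_row", "grid_col")]
  cand$origin_x <- cand$grid_col * ps
  cand$origin_y <- cand$grid_row * ps
  cand$foreground_fraction <- mapply(function(r, c) {
    mean(fg[r * ps + seq_len(ps), c * ps + seq_len(ps)])
  }, cand$grid_row, cand$grid_col)
  cand$retained <- cand$foreground_fraction > config$min_cell_fraction
  cand <- data.frame(image_id = image_id, cand, stringsAsFactors = FALSE)

  kept <- cand[cand$retained, , drop = FALSE]
  instances <- lapply(seq_len(nrow(kept)), function(i) {
    r <- kept$grid_row[i]
    c <- kept$grid_col[i]
    structure(list(
      pixels = image[r * ps + seq_len(ps), c * ps + seq_len(ps), , drop = FALSE],
      image_id = image_id,
      grid_row = r, grid_col = c,
      origin_x = kept$origin_x[i], origin_y = kept$origin_y[i],
      foreground_fraction = kept$foreground_fraction[i]
    ), class = "patch_instance")
  })
  attr(instances, "candidates") <- cand
  instances
}

#' Read a specimen image from disk
#'
#' PNG images are read with \pkg{png}; JPEG is supported when \pkg{EBImage}
#' is installed.
#'
#' @param path Image file path.
#' @return An `(H, W, 3)` array with values in `[0, 1]`.
#' @export
read_specimen_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package")
    }
    img <- aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  } else {
    stop("unsupported image format: ", path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Extract instances for every image in a dataset manifest
#'
#' Reads each PNG/JPEG image listed in a case manifest and runs
#' [extract_instances()] on it.
#'
#' @param manifest Data frame with columns `case_id`, `image_path`, `label`,
#'   or the path of a `manifest.csv` with those columns.
#' @param dir Directory that `image_path` entries are relative to.
#' @param config An [extraction_config()].
#' @return A list with `instances` (per-image list of instance lists, named
#'   by image id), `candidates` (row-bound candidate table across images)
#'   and `manifest` (with an `image_id` column added).
#' @export
extract_dataset <- function(manifest, dir = ".", config = extraction_config()) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  manifest$image_id <- sub("\\.[a-zA-Z]+$", "", basename(manifest$image_path))
  res <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_specimen_image(file.path(dir, manifest$image_path[i]))
    extract_instances(img, config, image_id = manifest$image_id[i])
  })
  names(res) <- manifest$image_id
  cands <- do.call(rbind, lapply(res, attr, "candidates"))
  rownames(cands) <- NULL
  list(instances = res, candidates = cands, manifest = manifest)
}
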