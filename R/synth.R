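# Synthetic specimen generator. Emulates Papanicolaou-stained microscopy
# fields at the geometry level only: a bright background with scattered
# darker cell nuclei drawn as filled rotated ellipses, loosely clustered the
# way cytology cells group on a slide. "Malignant" fields additionally carry
# a planted subpopulation of larger, darker, more eccentric nuclei, so the
# benign/malignant distinction is learnable from patch appearance while the
# per-cell ground truth remains known exactly.

#' Configuration for the synthetic specimen generator
#'
#' Defines the study conditions under which synthetic datasets are drawn:
#' image geometry, case mix, per-image cell counts, and the appearance
#' ranges that separate benign-like from malignant-like nuclei. The
#' `"small"` profile (256 x 192 px) is a fast preset for experiments and
#' tests; `"full"` mirrors common microscope-camera geometry (1280 x 960 px).
#'
#' @param n_cases Number of patient cases to simulate.
#' @param malignant_fraction Proportion of cases labelled malignant.
#' @param profile `"small"` (256 x 192) or `"full"` (1280 x 960); sets the
#'   defaults below, each of which can still be overridden.
#' @param image_width,image_height Image size in pixels.
#' @param images_per_case Integer range `c(min, max)` of fields per case.
#' @param cells_per_image Integer range of nuclei per field.
#' @param benign_nucleus_radius,malignant_nucleus_radius Pixel ranges for the
#'   nucleus semi-axes; the malignant range must lie strictly above the
#'   benign range so the planted signal is separable.
#' @param benign_intensity,malignant_intensity Base fill intensity ranges
#'   (0-255); malignant nuclei are darker, as hyperchromatic nuclei are under
#'   Papanicolaou staining.
#' @param malignant_cell_fraction Fraction of nuclei in a malignant field
#'   that are malignant-like (at least one is always planted); must be > 0.
#' @param background_intensity Background grey level (0-255), strictly above
#'   both cell intensity ranges (cells are darker than the illuminated
#'   background).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer seed; fixes every random choice the generator makes.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_cases = 40L,
                         malignant_fraction = 0.5,
                         profile = c("small", "full"),
                         image_width = NULL,
                         image_height = NULL,
                         images_per_case = c(2L, 2L),
                         cells_per_image = c(15L, 22L),
                         benign_nucleus_radius = c(6, 10),
                         malignant_nucleus_radius = c(12, 17),
                         benign_intensity = c(110, 160),
                         malignant_intensity = c(30, 80),
                         malignant_cell_fraction = 0.25,
                         background_intensity = 235,
                         noise_sd = 8,
                         seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(image_width)) image_width <- if (profile == "full") 1280L else 256L
  if (is.null(image_height)) image_height <- if (profile == "full") 960L else 192L
  cfg <- structure(list(
    n_cases = as.integer(n_cases),
    malignant_fraction = malignant_fraction,
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    images_per_case = as.integer(images_per_case),
    cells_per_image = as.integer(cells_per_image),
    benign_nucleus_radius = benign_nucleus_radius,
    malignant_nucleus_radius = malignant_nucleus_radius,
    benign_intensity = benign_intensity,
    malignant_intensity = malignant_intensity,
    malignant_cell_fraction = malignant_cell_fraction,
    background_intensity = background_intensity,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  chk_range <- function(x, nm) {
    if (length(x) != 2 || x[1] > x[2]) stop("invalid range for '", nm, "'")
  }
  if (cfg$n_cases < 1) stop("invalid 'n_cases': must be >= 1")
  if (cfg$malignant_fraction < 0 || cfg$malignant_fraction > 1) {
    stop("invalid 'malignant_fraction': must be in [0, 1]")
  }
  chk_range(cfg$images_per_case, "images_per_case")
  chk_range(cfg$cells_per_image, "cells_per_image")
  chk_range(cfg$benign_nucleus_radius, "benign_nucleus_radius")
  chk_range(cfg$malignant_nucleus_radius, "malignant_nucleus_radius")
  if (cfg$malignant_nucleus_radius[1] <= cfg$benign_nucleus_radius[2]) {
    stop("invalid 'malignant_nucleus_radius': range must lie strictly above ",
         "'benign_nucleus_radius' (separable planted signal)")
  }
  for (nm in c("benign_intensity", "malignant_intensity")) {
    chk_range(cfg[[nm]], nm)
    if (cfg[[nm]][1] < 0 || cfg[[nm]][2] > 255) {
      stop("invalid '", nm, "': values must be in [0, 255]")
    }
  }
  if (cfg$background_intensity < 0 || cfg$background_intensity > 255) {
    stop("invalid 'background_intensity': must be in [0, 255]")
  }
  if (cfg$background_intensity <= max(cfg$benign_intensity[2], cfg$malignant_intensity[2])) {
    stop("invalid 'background_intensity': must be strictly above both cell ",
         "intensity ranges (cells darker than background)")
  }
  if (cfg$malignant_cell_fraction <= 0 || cfg$malignant_cell_fraction > 1) {
    stop("invalid 'malignant_cell_fraction': must be in (0, 1]; ",
         "0 would leave malignant cases without signal")
  }
  if (cfg$noise_sd < 0) stop("invalid 'noise_sd': must be >= 0")
  invisible(cfg)
}

# Channel tints give a vaguely haematoxylin-purple nucleus on a pale field.
.cell_tint <- c(0.88, 0.72, 1.00)
.bg_tint <- c(1.00, 0.985, 1.02)

# Draw the cells of one field. Cells are placed around a few cluster centres
# (cytology cells sediment in loose groups); malignant-like cells get larger
# radii, darker and more variable fill, and stronger axis/eccentricity jitter.
synth_cells <- function(cfg, n_cells, n_malignant) {
  W <- cfg$image_width
  H <- cfg$image_height
  n_clusters <- max(1L, round(n_cells / 6))
  ccx <- runif(n_clusters, 0.15 * W, 0.85 * W)
  ccy <- runif(n_clusters, 0.15 * H, 0.85 * H)
  cl <- sample.int(n_clusters, n_cells, replace = TRUE)
  spread <- 0.09 * min(W, H)
  cx <- pmin(pmax(ccx[cl] + rnorm(n_cells, sd = spread), 2), W - 2)
  cy <- pmin(pmax(ccy[cl] + rnorm(n_cells, sd = spread), 2), H - 2)
  is_mal <- rep(FALSE, n_cells)
  if (n_malignant > 0) is_mal[sample.int(n_cells, n_malignant)] <- TRUE
  r_lo <- ifelse(is_mal, cfg$malignant_nucleus_radius[1], cfg$benign_nucleus_radius[1])
  r_hi <- ifelse(is_mal, cfg$malignant_nucleus_radius[2], cfg$benign_nucleus_radius[2])
  base_r <- runif(n_cells, r_lo, r_hi)
  ecc <- ifelse(is_mal, runif(n_cells, 0.45, 0.95), runif(n_cells, 0.75, 1.0))
  rx <- base_r
  ry <- base_r * ecc
  theta <- runif(n_cells, 0, pi)
  i_lo <- ifelse(is_mal, cfg$malignant_intensity[1], cfg$benign_intensity[1])
  i_hi <- ifelse(is_mal, cfg$malignant_intensity[2], cfg$benign_intensity[2])
  intensity <- runif(n_cells, i_lo, i_hi)
  data.frame(cx = cx, cy = cy, rx = rx, ry = ry, theta = theta,
             intensity = intensity,
             class = ifelse(is_mal, "malignant_like", "benign_like"),
             stringsAsFactors = FALSE)
}

# Rasterise one field: pixel (x, y) has x rightward in [1, W], y downward in
# [1, H]; returned as an (H, W, 3) array in [0, 1] for png::writePNG.
render_image <- function(cfg, cells) {
  W <- cfg$image_width
  H <- cfg$image_height
  lum <- matrix(cfg$background_intensity, nrow = H, ncol = W)
  is_cell <- matrix(FALSE, nrow = H, ncol = W)
  for (i in seq_len(nrow(cells))) {
    r <- max(cells$rx[i], cells$ry[i])
    x0 <- max(1L, floor(cells$cx[i] - r)); x1 <- min(W, ceiling(cells$cx[i] + r))
    y0 <- max(1L, floor(cells$cy[i] - r)); y1 <- min(H, ceiling(cells$cy[i] + r))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(rep(1, length(ys)), xs - cells$cx[i])
    dy <- outer(ys - cells$cy[i], rep(1, length(xs)))
    ct <- cos(cells$theta[i]); st <- sin(cells$theta[i])
    u <- (dx * ct + dy * st) / cells$rx[i]
    v <- (-dx * st + dy * ct) / cells$ry[i]
    inside <- (u * u + v * v) <= 1
    if (!any(inside)) next
    sub <- lum[ys, xs, drop = FALSE]
    # darker cell wins where nuclei overlap
    sub[inside] <- pmin(sub[inside], cells$intensity[i])
    lum[ys, xs] <- sub
    sc <- is_cell[ys, xs, drop = FALSE]
    sc[inside] <- TRUE
    is_cell[ys, xs] <- sc
  }
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    tint <- ifelse(is_cell, .cell_tint[ch], .bg_tint[ch])
    plane <- lum * tint + rnorm(H * W, sd = cfg$noise_sd)
    img[, , ch] <- pmin(pmax(round(plane), 0), 255) / 255
  }
  img
}

# Per-patch ground-truth labels for one image at a given patch size: a patch
# is malignant-like iff at least one malignant-like cell centre falls inside
# it. Patches are the non-overlapping grid used by extract_instances().
patch_labels_for <- function(cells, width, height, patch_size) {
  n_col <- width %/% patch_size
  n_row <- height %/% patch_size
  if (n_col < 1 || n_row < 1) {
    return(data.frame(grid_row = integer(), grid_col = integer(),
                      malignant_like = logical()))
  }
  mal <- cells[cells$class == "malignant_like", , drop = FALSE]
  grid <- expand.grid(grid_row = 0:(n_row - 1), grid_col = 0:(n_col - 1))
  grid <- grid[order(grid$grid_row, grid$grid_col), ]
  lab <- logical(nrow(grid))
  if (nrow(mal) > 0) {
    # centre (cx, cy) in 1-based pixels -> 0-based tile index
    tc <- floor((mal$cx - 1) / patch_size)
    tr <- floor((mal$cy - 1) / patch_size)
    ok <- tc < n_col & tr < n_row
    key <- paste(tr[ok], tc[ok])
    lab <- paste(grid$grid_row, grid$grid_col) %in% key
  }
  data.frame(grid, malignant_like = lab, row.names = NULL)
}

#' Generate a synthetic specimen dataset
#'
#' Draws a seeded synthetic dataset of specimen images with a case manifest
#' and exact ground truth. Writes PNG images (lossless, so repeated runs are
#' byte-identical), `manifest.csv` (case_id, image_path, label) and
#' `ground_truth.json` (per-image cell records plus per-patch labels for
#' each supported patch size) under `dir`.
#'
#' Benign cases contain only benign-like cells; every image of a malignant
#' case carries at least one malignant-like cell whose centre lies inside
#' the tiled area, so the planted signal survives tiling at any supported
#' patch size.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if missing).
#' @param patch_sizes Patch sizes for which per-patch ground-truth labels are
#'   recorded.
#' @return Invisibly, a list with `manifest` (data frame), `ground_truth`
#'   (per-image list), and `dir`.
#' @export
generate_dataset <- function(config, dir, patch_sizes = c(64L, 96L, 128L)) {
  validate_synth_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  set.seed(config$seed)

  n_mal <- round(config$n_cases * config$malignant_fraction)
  labels <- rep(c("malignant", "benign"), c(n_mal, config$n_cases - n_mal))
  labels <- labels[sample.int(config$n_cases)]
  case_ids <- sprintf("case%03d", seq_len(config$n_cases))

  manifest <- NULL
  ground_truth <- list()
  for (ci in seq_len(config$n_cases)) {
    n_img <- sample(seq(config$images_per_case[1], config$images_per_case[2]), 1)
    for (ii in seq_len(n_img)) {
      n_cells <- sample(seq(config$cells_per_image[1], config$cells_per_image[2]), 1)
      n_mal_cells <- if (labels[ci] == "malignant") {
        max(1L, round(config$malignant_cell_fraction * n_cells))
      } else 0L
      cells <- synth_cells(config, n_cells, n_mal_cells)
      if (n_mal_cells > 0) {
        # anchor one malignant cell inside the tiled region for every
        # supported patch size (tiles start at the image top-left)
        w_max <- max(patch_sizes) * max(1L, config$image_width %/% max(patch_sizes))
        h_max <- max(patch_sizes) * max(1L, config$image_height %/% max(patch_sizes))
        k <- which(cells$class == "malignant_like")[1]
        cells$cx[k] <- runif(1, 2, min(w_max, config$image_width) - 2)
        cells$cy[k] <- runif(1, 2, min(h_max, config$image_height) - 2)
      }
      img <- render_image(config, cells)
      image_id <- sprintf("%s_img%02d", case_ids[ci], ii)
      rel_path <- file.path("images", paste0(image_id, ".png"))
      png::writePNG(img, file.path(dir, rel_path))
      manifest <- rbind(manifest, data.frame(
        case_id = case_ids[ci], image_path = rel_path, label = labels[ci],
        stringsAsFactors = FALSE))
      pl <- lapply(patch_sizes, function(ps) {
        patch_labels_for(cells, config$image_width, config$image_height, ps)
      })
      names(pl) <- paste0("patch_", patch_sizes)
      ground_truth[[image_id]] <- list(case_id = case_ids[ci],
                                       label = labels[ci],
                                       cells = cells,
                                       patch_labels = pl)
    }
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(list(manifest = manifest, ground_truth = ground_truth, dir = dir))
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic specimen configuration\n")
  cat("  cases:", x$n_cases,
      sprintf("(malignant fraction %.2f)", x$malignant_fraction), "\n")
  cat("  image:", x$image_width, "x", x$image_height, "px;",
      x$images_per_case[1], "-", x$images_per_case[2], "images/case\n")
  cat("  cells/image:", x$cells_per_image[1], "-", x$cells_per_image[2],
      sprintf("(malignant-like fraction %.2f in malignant fields)",
              x$malignant_cell_fraction), "\n")
  cat("  nucleus radius: benign", paste(x$benign_nucleus_radius, collapse = "-"),
      "px, malignant", paste(x$malignant_nucleus_radius, collapse = "-"), "px\n")
  cat("  intensity: benign", paste(x$benign_intensity, collapse = "-"),
      ", malignant", paste(x$malignant_intensity, collapse = "-"),
      ", background", x$background_intensity, "\n")
  cat("  noise sd:", x$noise_sd, " seed:", x$seed, "\n")
  invisible(x)
}
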