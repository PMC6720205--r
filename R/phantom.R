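#' Phantom image configuration
#'
#' Parameters of the seeded embryo-phantom simulator. A phantom frame shows a
#' bright-rimmed circular culture well on a dark background, containing 1, 2
#' or 4 translucent cell discs with darker membranes, a mild zero-mean
#' illumination gradient, additive Gaussian noise and salt-and-pepper
#' corruption. The same `(config, seed)` pair always yields a bit-identical
#' image.
#'
#' @param image_size pixels per side (square frame, default 600).
#' @param cell_count number of cells, one of 1, 2, 4.
#' @param well_radius_frac well radius as a fraction of the half-width.
#' @param cell_radius_range min/max cell radius as fractions of the well
#'   radius.
#' @param rim_contrast intensity drop of the cell membrane relative to the
#'   cell interior (storage intensity units).
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param salt_pepper_frac fraction of pixels replaced by 0 or 255.
#' @param gradient_amp peak amplitude of the zero-mean horizontal
#'   illumination ramp (0 disables it).
#' @param allow_overlap permit overlapping cells (cell division look); when
#'   `FALSE`, centers are rejection-sampled until all discs are disjoint.
#' @param seed RNG seed for this image.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(image_size = 600, cell_count = 1,
                           well_radius_frac = 0.85,
                           cell_radius_range = c(0.18, 0.32),
                           rim_contrast = 60, noise_sigma = 6,
                           salt_pepper_frac = 0.002, gradient_amp = 8,
                           allow_overlap = TRUE, seed = 1L) {
  if (!cell_count %in% c(1, 2, 4))
    stopf("cell_count must be 1, 2 or 4 (got %s)", cell_count)
  fr <- c(well_radius_frac, cell_radius_range, salt_pepper_frac)
  if (any(fr < 0 | fr > 1)) stopf("fractional parameters must lie in [0, 1]")
  if (cell_radius_range[1] > cell_radius_range[2])
    stopf("cell_radius_range must be increasing")
  if (image_size < 8) stopf("image_size too small")
  if (noise_sigma < 0) stopf("noise_sigma must be non-negative")
  structure(list(image_size = as.integer(image_size),
                 cell_count = as.integer(cell_count),
                 well_radius_frac = well_radius_frac,
                 cell_radius_range = cell_radius_range,
                 rim_contrast = rim_contrast, noise_sigma = noise_sigma,
                 salt_pepper_frac = salt_pepper_frac,
                 gradient_amp = gradient_amp, allow_overlap = allow_overlap,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Intensity levels of the drawn layers (storage units). Cells are translucent:
# their interiors brighten the underlying well medium; membranes darken it.
PHANTOM_LEVELS <- list(background = 45, well = 95, well_rim = 225,
                       cell_boost = 24)

#' Generate one phantom embryo image
#'
#' Draws the layered phantom described in [phantom_config()] and attaches the
#' ground-truth cell mask (integer matrix: 0 background, k inside cell k;
#' overlapping pixels keep the later label) plus per-cell geometry as
#' attributes.
#'
#' @param config a [phantom_config()].
#' @return a `gray_image` in `[0, 255]` with attributes `mask` (integer
#'   matrix), `cells` (data frame of centers/radii in pixels), `well`
#'   (center/radius), and `levels` (the drawn intensity levels).
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  n <- config$image_size
  set.seed(config$seed)
  cx <- (n + 1) / 2
  col_idx <- matrix(rep(seq_len(n), each = n), n)
  row_idx <- matrix(rep(seq_len(n), times = n), n)
  d_center <- sqrt((row_idx - cx)^2 + (col_idx - cx)^2)

  well_r <- config$well_radius_frac * n / 2
  rim_w <- max(2, round(0.01 * n))

  img <- matrix(PHANTOM_LEVELS$background, n, n)
  inside_well <- d_center <= well_r
  img[inside_well] <- PHANTOM_LEVELS$well
  on_rim <- d_center > well_r & d_center <= well_r + rim_w
  img[on_rim] <- PHANTOM_LEVELS$well_rim

  # cell geometry: radii then centers, rejection-sampled to stay in the well
  k <- config$cell_count
  radii <- stats::runif(k, config$cell_radius_range[1],
                        config$cell_radius_range[2]) * well_r
  centers <- matrix(0, k, 2)
  for (i in seq_len(k)) {
    for (try in seq_len(2000L)) {
      rmax <- max(0, well_r - radii[i] - rim_w)
      u <- stats::runif(1); th <- stats::runif(1, 0, 2 * pi)
      pt <- cx + sqrt(u) * rmax * c(cos(th), sin(th))
      if (config$allow_overlap || i == 1L) break
      sep <- sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                             matrix(pt, i - 1L, 2, byrow = TRUE))^2))
      if (all(sep > radii[i] + radii[seq_len(i - 1L)] + 2)) break
      if (try == 2000L) stopf("could not place %d non-overlapping cells", k)
    }
    centers[i, ] <- pt
  }

  mask <- matrix(0L, n, n)
  memb_w <- pmax(2, round(0.12 * radii))
  for (i in seq_len(k)) {
    d <- sqrt((row_idx - centers[i, 1])^2 + (col_idx - centers[i, 2])^2)
    interior <- d <= radii[i] - memb_w[i]
    membrane <- d > radii[i] - memb_w[i] & d <= radii[i]
    img[interior] <- PHANTOM_LEVELS$well + PHANTOM_LEVELS$cell_boost
    img[membrane] <- PHANTOM_LEVELS$well + PHANTOM_LEVELS$cell_boost -
      config$rim_contrast
    mask[d <= radii[i]] <- i
  }

  # zero-mean horizontal illumination ramp
  if (config$gradient_amp > 0)
    img <- img + config$gradient_amp * (2 * (col_idx - cx) / n)

  if (config$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sigma), n)
  if (config$salt_pepper_frac > 0) {
    m <- round(config$salt_pepper_frac * n * n)
    if (m > 0) {
      idx <- sample.int(n * n, m)
      half <- seq_len(m %/% 2)
      img[idx[half]] <- 0
      img[idx[-half]] <- 255
    }
  }

  out <- gray_image(clamp(img, 0, 255))
  attr(out, "mask") <- mask
  attr(out, "cells") <- data.frame(row = centers[, 1], col = centers[, 2],
                                   radius = radii, membrane_width = memb_w)
  attr(out, "well") <- list(center = c(cx, cx), radius = well_r,
                            rim_width = rim_w)
  attr(out, "levels") <- unlist(PHANTOM_LEVELS)
  out
}

PHANTOM_CLASSES <- c("one-cell", "two-cells", "four-cells")
PHANTOM_CELLS <- c(`one-cell` = 1L, `two-cells` = 2L, `four-cells` = 4L)

#' Generate a labeled phantom dataset
#'
#' Produces `counts[1]` one-cell, `counts[2]` two-cell and `counts[3]`
#' four-cell phantoms. Each image uses a seed derived deterministically from
#' `(base_seed, class, index)`, so any subset is reproducible independently
#' of the rest.
#'
#' @param counts non-negative integer vector of length 3 (one-, two-,
#'   four-cell image counts).
#' @param base_seed integer master seed.
#' @param config template [phantom_config()] supplying all non-class
#'   parameters (its `cell_count` and `seed` are overridden per image).
#' @return an [image_set()] with provenance `"phantom"` and ground-truth
#'   masks.
#' @export
generate_dataset <- function(counts, base_seed = 1L,
                             config = phantom_config()) {
  if (length(counts) != 3L || any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be 3 non-negative integers (one-, two-, four-cell)")
  total <- sum(counts)
  images <- vector("list", total)
  masks <- vector("list", total)
  labels <- character(total)
  pos <- 0L
  for (ci in 1:3) {
    for (i in seq_len(counts[ci])) {
      pos <- pos + 1L
      cfg <- config
      cfg$cell_count <- PHANTOM_CELLS[[ci]]
      cfg$seed <- derive_seed(base_seed, ci, i)
      img <- generate_phantom(cfg)
      masks[[pos]] <- attr(img, "mask")
      attributes(img)[c("mask", "cells", "well", "levels")] <- NULL
      images[[pos]] <- img
      labels[pos] <- PHANTOM_CLASSES[ci]
    }
  }
  image_set(images, labels, provenance = "phantom", masks = masks)
}
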