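#' Grayscale image container
#'
#' A grayscale image is a numeric matrix (rows = image rows, origin top-left)
#' with a declared intensity range. Storage convention is `[0, 255]`; the
#' network domain is `[-1, 1]` (see [normalize_image()]).
#'
#' @param pixels numeric matrix of intensities.
#' @param range length-2 numeric, declared `[min, max]` intensity range.
#' @return a `gray_image`: the matrix with a `range` attribute.
#' @export
gray_image <- function(pixels, range = c(0, 255)) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("pixels must be a numeric matrix")
  if (any(dim(pixels) < 1L)) stopf("image dimensions must be positive")
  if (length(range) != 2L || range[1] >= range[2])
    stopf("range must be c(min, max) with min < max")
  structure(pixels, range = as.numeric(range),
            class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  r <- img_range(x)
  cat(sprintf("<gray_image %dx%d, range [%g, %g], mean %.2f>\n",
              nrow(x), ncol(x), r[1], r[2], mean(x)))
  invisible(x)
}

#' Declared intensity range of an image
#' @param img a matrix or `gray_image`.
#' @return length-2 numeric range (defaults to `c(0, 255)` for bare matrices).
#' @export
img_range <- function(img) attr(img, "range") %||% c(0, 255)

#' Labeled image set
#'
#' An ordered collection of equally sized grayscale images with one class
#' label per image and a provenance flag.
#'
#' @param images list of matrices / `gray_image`s sharing dimensions.
#' @param labels character vector, one label per image (NA allowed).
#' @param provenance one of `"phantom"`, `"real"`, `"generated"`, `"noise"`.
#' @param masks optional list of ground-truth label matrices (phantoms).
#' @return an `image_set` object.
#' @export
image_set <- function(images, labels = rep(NA_character_, length(images)),
                      provenance = "real", masks = NULL) {
  if (!is.list(images)) stopf("images must be a list")
  if (length(labels) != length(images))
    stopf("need one label per image (%d labels, %d images)",
          length(labels), length(images))
  if (length(images) > 0L) {
    d <- dim(images[[1L]])
    ok <- vapply(images, function(m) identical(dim(m), d), logical(1))
    if (!all(ok)) stopf("all images in a set must share dimensions")
  }
  structure(list(images = images, labels = as.character(labels),
                 provenance = provenance, masks = masks),
            class = "image_set")
}

#' @export
length.image_set <- function(x) length(x$images)

#' @export
print.image_set <- function(x, ...) {
  d <- if (length(x) > 0L) paste(dim(x$images[[1L]]), collapse = "x") else "-"
  cat(sprintf("<image_set: %d images (%s), provenance %s>\n",
              length(x), d, x$provenance))
  if (length(x) > 0L && !all(is.na(x$labels)))
    print(table(x$labels, useNA = "ifany"))
  invisible(x)
}

# Luma weights for RGB -> grayscale conversion (ITU-R BT.601).
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

rgb_to_gray <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  nc <- dim(arr)[3L]
  if (nc == 1L) return(arr[, , 1L])
  # alpha channel (if any) is ignored
  LUMA_WEIGHTS[1] * arr[, , 1L] + LUMA_WEIGHTS[2] * arr[, , 2L] +
    LUMA_WEIGHTS[3] * arr[, , 3L]
}

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '%s' (%s)", ext, basename(path))
  )
  gray_image(rgb_to_gray(arr) * 255)
}

#' Load a directory of grayscale images
#'
#' Reads every PNG/TIFF in `dir` (sorted by filename), converts RGB frames to
#' a single channel with BT.601 luma weights, and checks dimensions. Labels
#' are taken from an optional manifest CSV with columns `filename,label`.
#'
#' @param dir directory path.
#' @param expected_size optional side length; images of any other size are an
#'   error, reported with the offending filename.
#' @param manifest optional path to a manifest CSV (defaults to
#'   `manifest.csv` inside `dir` when present).
#' @param provenance provenance flag for the returned set.
#' @return a labeled [image_set()].
#' @export
load_images <- function(dir, expected_size = NULL, manifest = NULL,
                        provenance = "real") {
  if (!dir.exists(dir)) stopf("directory not found: %s", dir)
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  files <- files[!grepl("_mask\\.", basename(files))]
  if (length(files) == 0L) {
    warning("no images found in ", dir)
    return(image_set(list(), character(0), provenance = provenance))
  }
  imgs <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- tryCatch(read_gray(files[i]),
                    error = function(e) stopf("failed to read %s: %s",
                                              basename(files[i]),
                                              conditionMessage(e)))
    if (!is.null(expected_size) &&
        !all(dim(img) == expected_size))
      stopf("size mismatch for %s: got %dx%d, expected %dx%d",
            basename(files[i]), nrow(img), ncol(img),
            expected_size, expected_size)
    imgs[[i]] <- img
  }
  labels <- rep(NA_character_, length(files))
  mf <- manifest %||% file.path(dir, "manifest.csv")
  if (file.exists(mf)) {
    man <- utils::read.csv(mf, stringsAsFactors = FALSE)
    idx <- match(basename(files), man$filename)
    labels[!is.na(idx)] <- man$label[idx[!is.na(idx)]]
  }
  image_set(imgs, labels, provenance = provenance)
}

#' Write an image set to PNG files
#'
#' @param set an [image_set()].
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @param write_masks also write ground-truth masks (phantoms) as
#'   `<name>_mask.png`.
#' @return invisibly, the manifest data frame (`filename,label`), which is
#'   also written as `manifest.csv`.
#' @export
write_images <- function(set, dir, prefix = "img", write_masks = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(set)
  fnames <- sprintf("%s_%04d.png", prefix, seq_len(n))
  for (i in seq_len(n)) {
    m <- clamp(unclass(set$images[[i]]), 0, 255) / 255
    attributes(m) <- list(dim = dim(m))
    png::writePNG(m, file.path(dir, fnames[i]))
    if (write_masks && !is.null(set$masks)) {
      mk <- set$masks[[i]]
      png::writePNG(mk / max(1, max(mk)), file.path(
        dir, sub("\\.png$", "_mask.png", fnames[i])))
    }
  }
  man <- data.frame(filename = fnames, label = set$labels,
                    stringsAsFactors = FALSE)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

# Exact 90-degree counter-clockwise grid rotation (a pixel permutation).
rot90_ccw <- function(m) {
  mm <- t(unclass(m))
  mm[rev(seq_len(nrow(mm))), , drop = FALSE]
}

#' 4-fold rotation augmentation
#'
#' Expands a set of square images with their 90, 180 and 270 degree grid
#' rotations. Grid rotations are pixel permutations, hence lossless; labels
#' are carried over, so the output holds exactly four times as many images.
#'
#' @param set an [image_set()] of square images.
#' @return an [image_set()] of size `4 * length(set)`; for each input image
#'   the four orientations (0, 90, 180, 270 degrees counter-clockwise) appear
#'   consecutively.
#' @export
augment_rotations <- function(set) {
  if (length(set) == 0L) return(set)
  for (img in set$images)
    if (!is_square(img)) stopf("rotation augmentation requires square images")
  out <- vector("list", 4L * length(set))
  labels <- rep(set$labels, each = 4L)
  for (i in seq_along(set$images)) {
    rng <- img_range(set$images[[i]])
    m0 <- gray_image(unclass(set$images[[i]]) + 0, rng)
    m90 <- gray_image(rot90_ccw(m0), rng)
    m180 <- gray_image(rot90_ccw(m90), rng)
    m270 <- gray_image(rot90_ccw(m180), rng)
    out[(4L * (i - 1L) + 1L):(4L * i)] <- list(m0, m90, m180, m270)
  }
  image_set(out, labels, provenance = set$provenance)
}

block_mean <- function(m, factor) {
  n <- nrow(m)
  g <- rep(seq_len(n / factor), each = factor)
  r <- rowsum(unclass(m), g) / factor          # collapse rows
  t(rowsum(t(r), g) / factor)                  # collapse columns
}

bilinear_resize <- function(m, side) {
  n <- nrow(m)
  # target pixel centers mapped into source coordinates (align centers)
  src <- (seq_len(side) - 0.5) * n / side - 0.5
  src <- clamp(src, 0, n - 1)
  i0 <- clamp(floor(src), 0, n - 2)
  f <- src - i0
  i0 <- i0 + 1L                                 # 1-based
  m <- unclass(m)
  rows <- m[i0, , drop = FALSE] * (1 - f) + m[i0 + 1L, , drop = FALSE] * f
  out <- rows[, i0, drop = FALSE] * rep(1 - f, each = side) +
    rows[, i0 + 1L, drop = FALSE] * rep(f, each = side)
  out
}

#' Resize a square image to network resolution
#'
#' When the input side is an exact integer multiple of the target the
#' downscale is a block mean (e.g. 600 -> 200 averages disjoint 3x3 blocks),
#' which is deterministic and directly checkable against brute-force
#' averaging. Other ratios fall back to bilinear interpolation. Upscaling is
#' rejected unless explicitly allowed.
#'
#' @param img square grayscale image.
#' @param side target side length in pixels (default 200, the network input).
#' @param allow_upscale permit `side` larger than the input side.
#' @return a `gray_image` of dimension `side x side` in the same range.
#' @export
resize_to_network <- function(img, side = 200, allow_upscale = FALSE) {
  if (!is_square(img)) stopf("resize_to_network requires a square image")
  n <- nrow(img)
  if (side > n && !allow_upscale)
    stopf("upscaling %d -> %d rejected (set allow_upscale = TRUE)", n, side)
  if (side == n) return(gray_image(unclass(img) + 0, img_range(img)))
  out <- if (side < n && n %% side == 0L) block_mean(img, n %/% side)
         else bilinear_resize(img, side)
  gray_image(out, img_range(img))
}

#' Map image intensities between storage and network ranges
#'
#' Affine map from the declared range (default storage `[0, 255]`) onto the
#' network domain `[-1, 1]`, paired with the generator's tanh output.
#' `denormalize_image()` is the inverse, clamped to the storage range;
#' the round trip is exact up to one 8-bit quantization step.
#'
#' @param img grayscale image (matrix).
#' @param from,to length-2 source and target ranges.
#' @return a `gray_image` in the target range.
#' @export
normalize_image <- function(img, from = img_range(img), to = c(-1, 1)) {
  out <- (unclass(img) - from[1]) / (from[2] - from[1]) * (to[2] - to[1]) +
    to[1]
  gray_image(out, to)
}

#' @rdname normalize_image
#' @export
denormalize_image <- function(img, from = img_range(img), to = c(0, 255)) {
  out <- (unclass(img) - from[1]) / (from[2] - from[1]) * (to[2] - to[1]) +
    to[1]
  gray_image(clamp(out, to[1], to[2]), to)
}
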