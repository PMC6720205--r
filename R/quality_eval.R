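#' Average intensity histogram of an image set
#'
#' Each image is histogrammed over its declared range into `bins` equal-width
#' bins and normalized to a probability vector; the set histogram is the
#' elementwise mean of the per-image histograms (hence it also sums to 1).
#' With `mode = "sum2"` each per-image histogram is instead normalized to
#' sum 2, a compatibility mode for pipelines that normalize over the pair of
#' histograms being compared.
#'
#' @param set an [image_set()] (non-empty, common value range).
#' @param bins number of intensity bins (default 256, the native 8-bit
#'   resolution).
#' @param mode `"probability"` (default) or `"sum2"`.
#' @return numeric vector of length `bins` with attributes `breaks` and
#'   `mode`.
#' @export
average_histogram <- function(set, bins = 256, mode = c("probability",
                                                        "sum2")) {
  mode <- match.arg(mode)
  if (length(set) == 0L) stopf("average_histogram: empty image set")
  rng <- img_range(set$images[[1L]])
  acc <- numeric(bins)
  for (img in set$images) {
    h <- image_histogram(img, bins, rng)
    acc <- acc + h / sum(h)
  }
  out <- acc / length(set)
  if (mode == "sum2") out <- 2 * out
  structure(out, breaks = seq(rng[1], rng[2], length.out = bins + 1L),
            mode = mode)
}

image_histogram <- function(img, bins, rng = img_range(img)) {
  scaled <- (as.vector(unclass(img)) - rng[1]) / (rng[2] - rng[1])
  idx <- clamp(floor(scaled * bins) + 1L, 1L, bins)
  tabulate(idx, nbins = bins)
}

check_hist_pair <- function(h1, h2) {
  if (length(h1) != length(h2))
    stopf("histograms must have equal bin counts (%d vs %d)",
          length(h1), length(h2))
  if (any(h1 < 0) || any(h2 < 0)) stopf("histogram masses must be >= 0")
}

#' Histogram comparison metrics
#'
#' Four bin-wise comparisons between two average histograms `H1` (reference)
#' and `H2` (generated):
#' * `hist_correlation()` — Pearson correlation over bins; 1 for identical
#'   (non-constant) histograms. A zero-variance histogram makes the value
#'   undefined: `NA` is returned with a warning.
#' * `hist_chi_square()` — `sum((H1 - H2)^2 / H1)` over bins with `H1 > 0`
#'   (bins where the reference mass is zero are skipped); non-negative, 0
#'   for identical histograms.
#' * `hist_intersection()` — `sum(pmin(H1, H2))`; equals 1 for identical
#'   probability histograms and 0 for disjoint supports.
#' * `hist_bhattacharyya()` — `sqrt(1 - sum(sqrt(H1 * H2)) /
#'   sqrt(mean(H1) * mean(H2) * N^2))`, in `[0, 1]`; 0 for identical
#'   histograms, 1 for disjoint supports. For probability histograms the
#'   normalizer reduces to 1.
#'
#' @param h1,h2 numeric histograms with equal bin counts.
#' @return scalar metric value.
#' @name histogram_metrics
NULL

#' @rdname histogram_metrics
#' @export
hist_correlation <- function(h1, h2) {
  check_hist_pair(h1, h2)
  if (stats::sd(h1) == 0 || stats::sd(h2) == 0) {
    warning("histogram correlation undefined for a zero-variance histogram")
    return(NA_real_)
  }
  stats::cor(as.numeric(h1), as.numeric(h2))
}

#' @rdname histogram_metrics
#' @export
hist_chi_square <- function(h1, h2) {
  check_hist_pair(h1, h2)
  keep <- h1 > 0
  sum((h1[keep] - h2[keep])^2 / h1[keep])
}

#' @rdname histogram_metrics
#' @export
hist_intersection <- function(h1, h2) {
  check_hist_pair(h1, h2)
  sum(pmin(as.numeric(h1), as.numeric(h2)))
}

#' @rdname histogram_metrics
#' @export
hist_bhattacharyya <- function(h1, h2) {
  check_hist_pair(h1, h2)
  s1 <- sum(h1); s2 <- sum(h2)
  if (s1 == 0 || s2 == 0) stopf("all-zero histogram")
  inner <- sum(sqrt(as.numeric(h1) * as.numeric(h2))) / sqrt(s1 * s2)
  sqrt(clamp(1 - inner, 0, 1))
}

#' Histogram comparison report
#'
#' Convenience wrapper computing all four metrics of
#' [histogram_metrics] between the average histograms of two image sets.
#'
#' @param real,fake image sets sharing a value range.
#' @param bins number of intensity bins.
#' @return named list `correlation`, `chi_square`, `intersection`,
#'   `bhattacharyya`.
#' @export
compare_histograms <- function(real, fake, bins = 256) {
  h1 <- average_histogram(real, bins)
  h2 <- average_histogram(fake, bins)
  list(correlation = hist_correlation(h1, h2),
       chi_square = hist_chi_square(h1, h2),
       intersection = hist_intersection(h1, h2),
       bhattacharyya = hist_bhattacharyya(h1, h2))
}

# ---------------------------------------------------------------------------
# GLCM and Haralick statistics

ANGLE_OFFSETS <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
                      `135` = c(-1L, -1L))

#' Grey-level co-occurrence matrix
#'
#' Quantizes the image to `levels` grey levels and tabulates how often level
#' pairs co-occur at the given pixel offset(s). The matrix is made symmetric
#' (both directions of each offset counted) and normalized to sum 1; with
#' `average = TRUE` (default) the per-angle matrices are averaged.
#'
#' @param img grayscale image.
#' @param levels number of quantization levels (>= 2; default 64).
#' @param distance offset length in pixels (default 1).
#' @param angles subset of `c(0, 45, 90, 135)` degrees.
#' @param average average the per-angle matrices; otherwise return a list.
#' @return `levels x levels` normalized matrix (or list of them).
#' @export
glcm <- function(img, levels = 64, distance = 1,
                 angles = c(0, 45, 90, 135), average = TRUE) {
  if (levels < 2) stopf("glcm requires at least 2 grey levels")
  if (!all(angles %in% c(0, 45, 90, 135)))
    stopf("angles must be a subset of {0, 45, 90, 135}")
  rng <- img_range(img)
  m <- unclass(img)
  q <- clamp(floor((m - rng[1]) / (rng[2] - rng[1]) * levels) + 1L,
             1L, levels)
  nr <- nrow(q); nc <- ncol(q)
  per_angle <- lapply(angles, function(a) {
    off <- ANGLE_OFFSETS[[as.character(a)]] * distance
    r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
    c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
    i <- q[r1, c1, drop = FALSE]
    j <- q[r1 + off[1], c1 + off[2], drop = FALSE]
    cnt <- tabulate((i - 1L) * levels + j, nbins = levels * levels)
    P <- matrix(cnt, levels, levels, byrow = TRUE)
    P <- P + t(P)                          # symmetric: count both directions
    P / sum(P)
  })
  if (!average) {
    names(per_angle) <- as.character(angles)
    return(per_angle)
  }
  Reduce(`+`, per_angle) / length(per_angle)
}

#' The 14 Haralick texture statistics
#'
#' Computes Haralick's second-order texture features from a normalized GLCM:
#' energy (angular second moment), contrast, correlation, variance (sum of
#' squares), homogeneity (inverse difference moment), sum average, sum
#' variance, sum entropy, entropy, difference variance, difference entropy,
#' the two information measures of correlation, and the maximal correlation
#' coefficient. Entropies use the natural logarithm with `0 log 0 = 0`. The
#' sum-variance second moment is taken about the sum average. For a
#' degenerate GLCM with a single nonzero cell the entropy features are 0 and
#' correlation-type features are undefined (`NA` with a warning).
#'
#' @param P normalized (sum 1) co-occurrence matrix from [glcm()].
#' @return named numeric vector of length 14.
#' @export
haralick_features <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stopf("GLCM must be normalized to sum 1")
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mx <- sum(seq_len(ng) * px); my <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - my)^2 * py))
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

  # p_{x+y}(k), k = 2..2*ng and p_{x-y}(k), k = 0..ng-1
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(P[i + j == k]), numeric(1))
  pxy_dif <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]),
                    numeric(1))

  energy <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  degenerate <- sx == 0 || sy == 0
  correlation <- if (degenerate) {
    warning("GLCM correlation undefined (zero marginal variance)")
    NA_real_
  } else (sum(i * j * P) - mx * my) / (sx * sy)
  variance <- sum((i - mx)^2 * P)
  homogeneity <- sum(P / (1 + (i - j)^2))
  ks <- 2:(2 * ng)
  sum_average <- sum(ks * pxy_sum)
  sum_variance <- sum((ks - sum_average)^2 * pxy_sum)
  sum_entropy <- -sum(xlogx(pxy_sum))
  entropy <- -sum(xlogx(P))
  kd <- 0:(ng - 1)
  dif_mean <- sum(kd * pxy_dif)
  difference_variance <- sum((kd - dif_mean)^2 * pxy_dif)
  difference_entropy <- -sum(xlogx(pxy_dif))

  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(ifelse(pxpy > 0, P * log(pxpy), 0))
  hxy2 <- -sum(xlogx(pxpy))
  imc1 <- if (max(hx, hy) == 0) {
    warning("information measure of correlation I undefined")
    NA_real_
  } else (entropy - hxy1) / max(hx, hy)
  imc2 <- sqrt(clamp(1 - exp(-2 * (hxy2 - entropy)), 0, 1))

  mcc <- if (degenerate) NA_real_ else {
    # Q(a, b) = sum_k p(a,k) p(b,k) / (px(a) py(k))
    A <- P
    A[px > 0, ] <- P[px > 0, , drop = FALSE] / px[px > 0]
    B <- P
    B[, py > 0] <- sweep(P[, py > 0, drop = FALSE], 2, py[py > 0], `/`)
    Q <- A %*% t(B)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(clamp(ev[2], 0, 1))
  }

  c(energy = energy, contrast = contrast, correlation = correlation,
    variance = variance, homogeneity = homogeneity,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, entropy = entropy,
    difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2,
    mcc = mcc)
}

#' Haralick feature matrix for an image set
#'
#' @param set an [image_set()].
#' @param ... passed to [glcm()].
#' @return `length(set) x 14` matrix, one Haralick vector per image.
#' @export
haralick_matrix <- function(set, ...) {
  t(vapply(set$images,
           function(img) suppressWarnings(haralick_features(glcm(img, ...))),
           numeric(14)))
}

#' Per-feature two-sample comparison of Haralick vectors
#'
#' Welch's two-sample t-test (the default; pooled-variance Student's test
#' available) per feature column, flagging features whose two-sided p-value
#' falls below `alpha`. If both groups are constant for a feature the test
#' is undefined: equal constants are reported as `t = 0, p = 1`, unequal
#' constants as significant with `p = 0`, each with a note.
#'
#' @param real,fake feature matrices with matching columns (rows = images).
#' @param alpha significance level (default 0.01).
#' @param var_equal use the pooled-variance test.
#' @return data frame `feature, t, p, significant, note`.
#' @export
compare_feature_sets <- function(real, fake, alpha = 0.01,
                                 var_equal = FALSE) {
  if (nrow(real) < 2L || nrow(fake) < 2L)
    stopf("need at least 2 samples per group")
  if (ncol(real) != ncol(fake)) stopf("feature columns must match")
  nm <- colnames(real) %||% paste0("f", seq_len(ncol(real)))
  res <- lapply(seq_len(ncol(real)), function(k) {
    a <- real[, k]; b <- fake[, k]
    if (anyNA(a) || anyNA(b))
      return(data.frame(feature = nm[k], t = NA_real_, p = NA_real_,
                        significant = NA, note = "undefined feature values"))
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      return(data.frame(feature = nm[k], t = if (eq) 0 else Inf,
                        p = if (eq) 1 else 0, significant = !eq,
                        note = "zero within-group variance in both groups"))
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(feature = nm[k], t = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value < alpha, note = "")
  })
  do.call(rbind, res)
}

#' Compare first principal components of two feature sets
#'
#' Fits a PCA (covariance form) separately to each feature matrix, reports
#' the percentage of variance explained by PC1 in each set, and the absolute
#' Pearson correlation between the two PC1 loading vectors (absolute because
#' an eigenvector's sign is arbitrary).
#'
#' @param real,fake feature matrices with matching columns, >= 2 rows each.
#' @return list `explained_var_real`, `explained_var_fake` (percent) and
#'   `pc1_correlation` (absolute value in `[0, 1]`).
#' @export
pca_pc1_compare <- function(real, fake) {
  if (nrow(real) < 2L || nrow(fake) < 2L) stopf("need >= 2 samples per set")
  if (ncol(real) != ncol(fake)) stopf("feature columns must match")
  keep <- !apply(real, 2, anyNA) & !apply(fake, 2, anyNA)
  real <- real[, keep, drop = FALSE]; fake <- fake[, keep, drop = FALSE]
  p1 <- stats::prcomp(real, center = TRUE, scale. = FALSE)
  p2 <- stats::prcomp(fake, center = TRUE, scale. = FALSE)
  if (p1$sdev[1] == 0 || p2$sdev[1] == 0)
    stopf("rank-deficient input: no variance along PC1")
  list(explained_var_real = 100 * p1$sdev[1]^2 / sum(p1$sdev^2),
       explained_var_fake = 100 * p2$sdev[1]^2 / sum(p2$sdev^2),
       pc1_correlation = abs(stats::cor(p1$rotation[, 1], p2$rotation[, 1])))
}

#' Expert tally
#'
#' Per-class counts of generated images and of images a human evaluator
#' accepted (i.e. could identify the correct cell count — the visual Turing
#' protocol's "good" images).
#'
#' @param generated integer vector of generated counts per class.
#' @param accepted integer vector of accepted counts per class.
#' @param classes class names.
#' @return an `expert_tally` data frame.
#' @export
expert_tally <- function(generated, accepted,
                         classes = PHANTOM_CLASSES) {
  if (length(generated) != length(accepted) ||
      length(generated) != length(classes))
    stopf("generated, accepted and classes must have equal length")
  if (any(accepted < 0) || any(accepted > generated))
    stopf("need 0 <= accepted <= generated per class")
  structure(data.frame(class = classes, generated = generated,
                       accepted = accepted, stringsAsFactors = FALSE),
            class = c("expert_tally", "data.frame"))
}

#' Expert-selection scores
#'
#' True recognition rate per class, `TRR = 100 * accepted / generated`, and
#' the overall misclassification rate
#' `100 * sum(generated - accepted) / sum(generated)`. Values are exact;
#' use [round_half_up()] for 1-decimal reporting.
#'
#' @param tally an [expert_tally()].
#' @return list with `trr` (named percent vector) and `misclassification`
#'   (percent scalar).
#' @export
expert_score <- function(tally) {
  if (any(tally$generated == 0))
    stopf("TRR undefined for a class with zero generated images")
  trr <- 100 * tally$accepted / tally$generated
  names(trr) <- tally$class
  list(trr = trr,
       misclassification = 100 * sum(tally$generated - tally$accepted) /
         sum(tally$generated))
}

#' Aggregate a judgment CSV into an expert tally
#'
#' Consumes rows `image, class, judge, accepted` (accepted in `{0, 1}`).
#' Each image is accepted when a strict majority of its judges accepted it;
#' the per-class generated count is the number of distinct images.
#'
#' @param judgments data frame or path to a CSV.
#' @return an [expert_tally()].
#' @export
tally_from_judgments <- function(judgments) {
  if (is.character(judgments))
    judgments <- utils::read.csv(judgments, stringsAsFactors = FALSE)
  need <- c("image", "class", "judge", "accepted")
  if (!all(need %in% names(judgments)))
    stopf("judgment table needs columns: %s", paste(need, collapse = ", "))
  per_image <- stats::aggregate(accepted ~ image + class, judgments,
                                function(x) mean(x) > 0.5)
  cls <- sort(unique(per_image$class))
  gen <- as.integer(table(factor(per_image$class, levels = cls)))
  acc <- vapply(cls, function(cc)
    sum(per_image$accepted[per_image$class == cc]), numeric(1))
  expert_tally(gen, as.integer(acc), classes = cls)
}

#' Median filter
#'
#' Per-pixel median over an odd square window; the image border is handled
#' by edge replication. Removes salt-and-pepper corruption from otherwise
#' smooth regions.
#'
#' @param img grayscale image.
#' @param window odd window side (default 3).
#' @return filtered `gray_image` in the same range.
#' @export
median_filter <- function(img, window = 3) {
  if (window %% 2 == 0) stopf("median filter window must be odd")
  m <- unclass(img)
  r <- (window - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  pad_r <- clamp(seq(1L - r, nr + r), 1L, nr)
  pad_c <- clamp(seq(1L - r, nc + r), 1L, nc)
  mp <- m[pad_r, pad_c, drop = FALSE]
  stack <- matrix(0, nr * nc, window^2)
  k <- 0L
  for (dr in 0:(window - 1L)) for (dc in 0:(window - 1L)) {
    k <- k + 1L
    stack[, k] <- as.vector(mp[(1L + dr):(nr + dr), (1L + dc):(nc + dc)])
  }
  out <- matrix(apply(stack, 1L, stats::median), nr, nc)
  gray_image(out, img_range(img))
}
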