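test_that("average histogram is the mean of per-image probability histograms", {
  u <- gray_image(matrix(100, 4, 4))       # all mass in bin floor(100/255*256)+1
  h <- average_histogram(image_set(list(u), "x"))
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_equal(sum(h > 0), 1)
  expect_equal(which(h > 0), floor(100 / 255 * 256) + 1)
  # two images: elementwise mean of their individual histograms
  a <- gray_image(matrix(0, 2, 2)); b <- gray_image(matrix(255, 2, 2))
  h2 <- average_histogram(image_set(list(a, b), c("x", "y")))
  expect_equal(as.numeric(h2[c(1, 256)]), c(0.5, 0.5))
  expect_equal(sum(h2), 1, tolerance = 1e-12)
  expect_error(average_histogram(image_set(list(), character(0))), "empty")
  # sum=2 compatibility mode
  h3 <- average_histogram(image_set(list(a, b), c("x", "y")), mode = "sum2")
  expect_equal(sum(h3), 2, tolerance = 1e-12)
})

test_that("any phantom set yields a probability histogram", {
  s <- generate_dataset(c(3, 2, 0), base_seed = 6,
                        config = phantom_config(image_size = 16))
  h <- average_histogram(s)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_true(all(h >= 0))
})

test_that("all four metrics hit their identity values simultaneously", {
  s <- generate_dataset(c(4, 0, 0), base_seed = 2,
                        config = phantom_config(image_size = 16))
  h <- average_histogram(s)
  expect_equal(hist_correlation(h, h), 1)
  expect_equal(hist_chi_square(h, h), 0)
  expect_equal(hist_intersection(h, h), 1, tolerance = 1e-12)
  expect_equal(hist_bhattacharyya(h, h), 0, tolerance = 1e-7)
})

test_that("histogram correlation detects reversal, affinity and degeneracy", {
  expect_equal(hist_correlation(c(.5, .5, 0, 0), c(0, 0, .5, .5)), -1)
  h <- c(.1, .2, .3, .4)
  expect_equal(hist_correlation(h, 2 * h + 0.05), 1)
  expect_warning(r <- hist_correlation(rep(.25, 4), h), "zero-variance")
  expect_true(is.na(r))
  expect_error(hist_correlation(h, h[1:3]), "equal bin counts")
})

test_that("chi-square matches direct evaluation and skips empty bins", {
  expect_equal(hist_chi_square(c(.5, .5), c(.25, .75)), 0.25)
  expect_gte(hist_chi_square(runif(8), runif(8)), 0)
  # H1 zero-mass bins are skipped rather than dividing by zero
  expect_equal(hist_chi_square(c(.5, .5, 0), c(.25, .75, .1)), 0.25)
})

test_that("intersection and Bhattacharyya match direct evaluation", {
  expect_equal(hist_intersection(c(.5, .5), c(.25, .75)), 0.75)
  expect_equal(hist_intersection(c(.5, .5, 0, 0), c(0, 0, .5, .5)), 0)
  h1 <- c(.5, .5); h2 <- c(.25, .75)
  direct <- sqrt(1 - sum(sqrt(h1 * h2)) /
                   sqrt(mean(h1) * mean(h2) * length(h1)^2))
  expect_equal(hist_bhattacharyya(h1, h2), direct, tolerance = 1e-12)
  expect_equal(hist_bhattacharyya(c(.5, .5, 0, 0), c(0, 0, .5, .5)), 1)
  expect_error(hist_bhattacharyya(c(0, 0), c(1, 0)), "all-zero")
})

test_that("metrics are invariant to appending empty bins to both histograms", {
  h1 <- c(.2, .3, .5); h2 <- c(.4, .4, .2)
  pad <- function(h) c(h, 0, 0)
  expect_equal(hist_correlation(pad(h1), pad(h2)),
               stats::cor(pad(h1), pad(h2)))  # correlation changes by design
  expect_equal(hist_chi_square(pad(h1), pad(h2)), hist_chi_square(h1, h2))
  expect_equal(hist_intersection(pad(h1), pad(h2)), hist_intersection(h1, h2))
  expect_equal(hist_bhattacharyya(pad(h1), pad(h2)),
               hist_bhattacharyya(h1, h2), tolerance = 1e-12)
})

test_that("GLCM matches brute-force pair enumeration on tiny images", {
  img <- toy_texture_image()
  q <- unclass(img) + 1
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  per <- glcm(img, levels = 4, average = FALSE)
  for (a in names(offs)) {
    expect_equal(per[[a]], naive_glcm(q, 4, offs[[a]][1], offs[[a]][2]),
                 tolerance = 1e-12, info = paste("angle", a))
    expect_equal(sum(per[[a]]), 1, tolerance = 1e-12)
    expect_equal(per[[a]], t(per[[a]]))   # symmetric
  }
  avg <- glcm(img, levels = 4)
  expect_equal(avg, Reduce(`+`, per) / 4, tolerance = 1e-12)
  # 2x2 worked example, horizontal: pairs (0,1) and (0,1), symmetric
  g2 <- glcm(gray_image(matrix(c(0, 0, 1, 1), 2, 2), range = c(0, 1)),
             levels = 2, angles = 0)
  expect_equal(g2, matrix(c(0, .5, .5, 0), 2, 2))
  expect_error(glcm(img, levels = 1), "at least 2")
})

test_that("constant images concentrate all GLCM mass on the diagonal", {
  g <- glcm(gray_image(matrix(7, 5, 5)), levels = 8)
  expect_equal(sum(diag(g)), 1, tolerance = 1e-12)
  expect_equal(sum(g), 1, tolerance = 1e-12)
})

test_that("the 14 Haralick features match an independent brute-force oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    img <- gray_image(matrix(sample(0:7, 64, replace = TRUE), 8, 8),
                      range = c(0, 7))
    P <- glcm(img, levels = 8, angles = c(0, 90))
    f <- haralick_features(P)
    expect_equal(unname(f), naive_haralick(P), tolerance = 1e-6)
  }
})

test_that("Haralick features match frozen scikit-image reference values", {
  # graycomatrix/graycoprops (symmetric, normed, distance 1, angle 0) on the
  # 4-level toy image
  f <- haralick_features(glcm(toy_texture_image(), levels = 4, angles = 0))
  expect_equal(unname(f["contrast"]), 2.1999999999999997, tolerance = 1e-6)
  expect_equal(unname(f["energy"]), 0.08611111111111112, tolerance = 1e-6)
  expect_equal(unname(f["correlation"]), 0.082483781278962, tolerance = 1e-6)
  expect_equal(unname(f["homogeneity"]), 0.5, tolerance = 1e-6)
})

test_that("degenerate and checkerboard textures hit their closed forms", {
  fc <- suppressWarnings(
    haralick_features(glcm(gray_image(matrix(3, 6, 6)), levels = 8)))
  expect_equal(unname(fc["energy"]), 1)
  expect_equal(unname(fc["contrast"]), 0)
  expect_equal(unname(fc["entropy"]), 0)
  expect_true(is.na(fc["correlation"]))
  # checkerboard at distance 1, horizontal: contrast = (levels-1)^2 under
  # 2-level quantization
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2) * 255
  f2 <- haralick_features(glcm(gray_image(cb), levels = 2, angles = 0))
  expect_equal(unname(f2["contrast"]), 1)
  f4 <- haralick_features(glcm(gray_image(cb / 255 * 255), levels = 2,
                               angles = 0))
  expect_equal(unname(f4["contrast"]), (2 - 1)^2)
})

test_that("feature t-tests: identical groups never flagged, shifts detected", {
  set.seed(8)
  m <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  same <- compare_feature_sets(m, m)
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1))
  expect_false(any(same$significant))
  # a large shift in one feature is flagged at alpha = 0.01, others are not
  shifted <- m; shifted[, 2] <- shifted[, 2] + 50
  r <- compare_feature_sets(m, shifted, alpha = 0.01)
  expect_true(r$significant[2])
  expect_equal(r$significant, r$p < 0.01)
})

test_that("t-test rejection rate under a known shift matches analytic power", {
  # Welch t at n = 25/25, true shift 1 sd, alpha 0.01 => power ~ 0.80
  set.seed(42)
  rej <- mean(vapply(1:400, function(i) {
    a <- matrix(rnorm(25), 25, 1); b <- matrix(rnorm(25) + 1, 25, 1)
    compare_feature_sets(a, b, alpha = 0.01)$significant
  }, logical(1)))
  pw <- stats::power.t.test(n = 25, delta = 1, sd = 1, sig.level = 0.01)$power
  expect_lt(abs(rej - pw), 0.07)          # Monte-Carlo band
})

test_that("constant-in-both-groups features are reported, not crashed", {
  a <- cbind(x = rep(1, 5), y = rnorm(5))
  b <- cbind(x = rep(1, 5), y = rnorm(5))
  r <- compare_feature_sets(a, b)
  expect_equal(r$t[1], 0); expect_equal(r$p[1], 1)
  expect_match(r$note[1], "zero within-group variance")
  b2 <- cbind(x = rep(2, 5), y = rnorm(5))
  r2 <- compare_feature_sets(a, b2)
  expect_true(r2$significant[1])
})

test_that("PC1 comparison: identity, rank-1 and an eigen oracle", {
  set.seed(5)
  m <- matrix(rnorm(60), 15, 4)
  r <- pca_pc1_compare(m, m)
  expect_equal(r$pc1_correlation, 1)
  expect_equal(r$explained_var_real, r$explained_var_fake)
  # exactly rank-1 data: PC1 explains 100%
  v <- outer(rnorm(10), c(1, 2, 3, 4))
  r1 <- pca_pc1_compare(v, v)
  expect_equal(r1$explained_var_real, 100, tolerance = 1e-8)
  # loadings match a direct eigen-decomposition of the covariance matrix
  m2 <- matrix(rnorm(60), 15, 4)
  r2 <- pca_pc1_compare(m, m2)
  ev <- eigen(stats::cov(m))$vectors[, 1]
  ev2 <- eigen(stats::cov(m2))$vectors[, 1]
  expect_equal(r2$pc1_correlation, abs(stats::cor(ev, ev2)),
               tolerance = 1e-8)
})

test_that("expert scores reproduce the published tally arithmetic", {
  tally <- expert_tally(c(500, 500, 500), c(481, 434, 400))
  sc <- expert_score(tally)
  expect_equal(round_half_up(unname(sc$trr), 1), c(96.2, 86.8, 80))
  expect_equal(sprintf("%.2f", sc$trr[3]), "80.00")
  expect_equal(round_half_up(sc$misclassification, 1), 12.3)
  # all accepted -> no misclassification
  sc0 <- expert_score(expert_tally(c(10, 10, 10), c(10, 10, 10)))
  expect_equal(sc0$misclassification, 0)
  expect_error(expert_tally(c(5, 5, 5), c(6, 0, 0)), "accepted")
  expect_error(expert_score(expert_tally(c(0, 1, 1), c(0, 1, 1))),
               "undefined")
})

test_that("judgment CSVs aggregate by per-image majority vote", {
  j <- data.frame(
    image = rep(c("a", "b", "c", "d"), each = 3),
    class = rep(c("one-cell", "one-cell", "two-cells", "two-cells"),
                each = 3),
    judge = rep(1:3, 4),
    accepted = c(1, 1, 0,   0, 0, 1,   1, 1, 1,   0, 0, 0))
  t <- tally_from_judgments(j)
  expect_equal(t$generated, c(2, 2))
  expect_equal(t$accepted, c(1, 1))
})

test_that("median filter restores impulse noise and matches brute force", {
  u <- gray_image(matrix(9, 7, 7))
  expect_equal(unclass(median_filter(u)), unclass(u), ignore_attr = TRUE)
  spike <- u; spike[4, 4] <- 255
  expect_equal(unclass(median_filter(spike)), unclass(u),
               ignore_attr = TRUE)
  set.seed(12)
  m <- matrix(runif(15 * 15, 0, 255), 15, 15)
  for (w in c(3, 5))
    expect_equal(unclass(median_filter(gray_image(m), w)),
                 naive_median_filter(m, w), tolerance = 1e-12,
                 ignore_attr = TRUE)
  expect_error(median_filter(u, window = 4), "odd")
})

test_that("self-evaluation of a phantom set is clean; noise is distinguished", {
  s <- generate_dataset(c(8, 0, 0), base_seed = 31,
                        config = phantom_config(image_size = 32))
  fm <- haralick_matrix(s, levels = 16)
  r <- compare_feature_sets(fm, fm)
  expect_false(any(r$significant, na.rm = TRUE))
  p <- pca_pc1_compare(fm, fm)
  expect_equal(p$pc1_correlation, 1)
  # pure noise: histogram correlation drops below the self-match value and
  # at least one texture feature differs at p < 0.01
  noise <- uniform_noise_set(8, 32, seed = 77)
  hs <- average_histogram(s)
  hn <- average_histogram(noise)
  expect_lt(hist_correlation(hs, hn), hist_correlation(hs, hs))
  rn <- compare_feature_sets(fm, haralick_matrix(noise, levels = 16))
  expect_gte(sum(rn$significant, na.rm = TRUE), 1)
})
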