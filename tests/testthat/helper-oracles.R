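# Independent brute-force oracles used by the tests. These deliberately share
# no code with the package: explicit loops, direct formula evaluation.

# block-mean downscale by explicit looping over blocks
naive_block_mean <- function(m, side) {
  k <- nrow(m) / side
  out <- matrix(0, side, side)
  for (i in seq_len(side)) for (j in seq_len(side)) {
    out[i, j] <- mean(m[((i - 1) * k + 1):(i * k), ((j - 1) * k + 1):(j * k)])
  }
  out
}

# per-pixel median with replicated edges, sorting each window explicitly
naive_median_filter <- function(m, window = 3) {
  r <- (window - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), nr); jj <- min(max(j + dj, 1), nc)
      vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- sort(vals)[(window^2 + 1) / 2]
  }
  out
}

# GLCM by enumerating every pixel pair at the offset, both directions
naive_glcm <- function(q, levels, dr, dc) {
  P <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + dr; jj <- j + dc
    if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
      P[q[i, j], q[ii, jj]] <- P[q[i, j], q[ii, jj]] + 1
      P[q[ii, jj], q[i, j]] <- P[q[ii, jj], q[i, j]] + 1
    }
  }
  P / sum(P)
}

# all 14 Haralick statistics by direct double-sum evaluation
naive_haralick <- function(P) {
  ng <- nrow(P)
  px <- py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j]
  }
  mx <- sum((1:ng) * px); my <- sum((1:ng) * py)
  sx <- sqrt(sum((1:ng - mx)^2 * px)); sy <- sqrt(sum((1:ng - my)^2 * py))
  psum <- numeric(2 * ng); pdif <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  f1 <- sum(P^2)
  f2 <- 0; for (i in 1:ng) for (j in 1:ng) f2 <- f2 + (i - j)^2 * P[i, j]
  f3 <- 0; for (i in 1:ng) for (j in 1:ng) f3 <- f3 + i * j * P[i, j]
  f3 <- (f3 - mx * my) / (sx * sy)
  f4 <- 0; for (i in 1:ng) for (j in 1:ng) f4 <- f4 + (i - mx)^2 * P[i, j]
  f5 <- 0; for (i in 1:ng) for (j in 1:ng) f5 <- f5 + P[i, j] / (1 + (i - j)^2)
  f6 <- sum((2:(2 * ng)) * psum[2:(2 * ng)])
  f7 <- sum(((2:(2 * ng)) - f6)^2 * psum[2:(2 * ng)])
  f8 <- ent(psum)
  f9 <- ent(P)
  dmean <- sum((0:(ng - 1)) * pdif)
  f10 <- sum(((0:(ng - 1)) - dmean)^2 * pdif)
  f11 <- ent(pdif)
  hx <- ent(px); hy <- ent(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pp <- px[i] * py[j]
    if (pp > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log(pp)
      hxy2 <- hxy2 - pp * log(pp)
    }
  }
  f12 <- (f9 - hxy1) / max(hx, hy)
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9))))
  Q <- matrix(0, ng, ng)
  for (a in 1:ng) for (b in 1:ng) for (k in 1:ng) {
    if (px[a] > 0 && py[k] > 0)
      Q[a, b] <- Q[a, b] + P[a, k] * P[b, k] / (px[a] * py[k])
  }
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  f14 <- sqrt(max(0, min(1, ev[2])))
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13, f14)
}

# 4-connected component labeling by flood fill
naive_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (si in seq_len(nr)) for (sj in seq_len(nc)) {
    if (!mask[si, sj] || lab[si, sj] != 0L) next
    cur <- cur + 1L
    stack <- list(c(si, sj)); lab[si, sj] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- p[1] + d[1]; jj <- p[2] + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# morphological opening (3x3 erosion then dilation) on a logical matrix
naive_open3 <- function(mask) {
  pad <- function(m, v) {
    out <- matrix(v, nrow(m) + 2, ncol(m) + 2)
    out[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    out
  }
  shift_all <- function(m, fun, v) {
    mp <- pad(m, v)
    acc <- NULL
    for (di in 0:2) for (dj in 0:2) {
      s <- mp[(1 + di):(nrow(m) + di), (1 + dj):(ncol(m) + dj)]
      acc <- if (is.null(acc)) s else fun(acc, s)
    }
    acc
  }
  er <- shift_all(mask, `&`, FALSE)
  shift_all(er, `|`, FALSE)
}

# the 4-level toy image whose scikit-image co-occurrence statistics are
# frozen in the tests
toy_texture_image <- function() {
  m <- matrix(c(
    0, 1, 2, 3, 0, 1,
    1, 2, 3, 0, 1, 2,
    2, 2, 1, 0, 3, 3,
    3, 0, 0, 1, 2, 2,
    0, 1, 3, 2, 1, 0,
    1, 3, 2, 0, 0, 1), 6, 6, byrow = TRUE)
  gray_image(m, range = c(0, 3))
}

# small fast phantom settings shared across tests
tiny_phantom <- function(cell_count = 1, seed = 1, size = 32, ...) {
  generate_phantom(phantom_config(image_size = size, cell_count = cell_count,
                                  seed = seed, ...))
}

uniform_noise_set <- function(n, side, seed) {
  set.seed(seed)
  image_set(lapply(seq_len(n), function(i)
    gray_image(matrix(stats::runif(side * side, 0, 255), side, side))),
    provenance = "noise")
}
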