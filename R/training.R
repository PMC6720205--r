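#' Adversarial training configuration
#'
#' @param iterations number of adversarial iterations (default 200000; each
#'   iteration performs one discriminator and one generator update).
#' @param batch_size images per batch (default 256). Each iteration the
#'   discriminator sees `batch_size` real plus `batch_size` generated images
#'   in one combined update.
#' @param checkpoint_every iterations between checkpoints (default 25000).
#' @param lr Adam learning rate (default 2e-5).
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer.
#' @param seed master RNG seed governing initialization, latent draws and
#'   batch shuffling.
#' @param side network image side (default 200; reducible for desk-scale
#'   runs).
#' @param latent latent dimension (default 100).
#' @param d_widths,g_widths hidden dense widths for the two networks.
#' @param g_loss generator objective: `"non-saturating"` (default; maximize
#'   `log D(G(z))` via the cross-entropy against label 1) or `"saturating"`
#'   (minimize `log(1 - D(G(z)))` literally).
#' @param out_dir optional directory for loss CSV and checkpoint sample
#'   grids.
#' @param sample_grid_n images per checkpoint sample grid.
#' @return a `train_config` list.
#' @export
train_config <- function(iterations = 200000, batch_size = 256,
                         checkpoint_every = 25000, lr = 2e-5, beta1 = 0.7,
                         beta2 = 0.999, adam_eps = 1e-8, seed = 1L,
                         side = 200, latent = 100,
                         d_widths = c(512, 256), g_widths = c(256, 512, 1024),
                         g_loss = c("non-saturating", "saturating"),
                         out_dir = NULL, sample_grid_n = 16) {
  g_loss <- match.arg(g_loss)
  if (iterations < 0 || batch_size < 1 || checkpoint_every < 1)
    stopf("iterations, batch_size and checkpoint_every must be positive")
  if (iterations > 0 && checkpoint_every > iterations)
    checkpoint_every <- iterations
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 checkpoint_every = as.integer(checkpoint_every),
                 lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 seed = as.integer(seed), side = as.integer(side),
                 latent = as.integer(latent), d_widths = d_widths,
                 g_widths = g_widths, g_loss = g_loss, out_dir = out_dir,
                 sample_grid_n = sample_grid_n),
            class = "train_config")
}

set_to_matrix <- function(set, normalize = TRUE) {
  n <- length(set)
  if (n == 0L) stopf("empty image set")
  d <- length(set$images[[1L]])
  X <- matrix(0, n, d)
  for (i in seq_len(n)) {
    img <- set$images[[i]]
    if (normalize) img <- normalize_image(img)
    X[i, ] <- as.vector(unclass(img))
  }
  X
}

#' Train the adversarial pair
#'
#' Runs the two-player minimax game: per iteration the discriminator is
#' updated once on a combined batch of real images (label 1) and generated
#' images (label 0) under binary cross-entropy, then the generator is
#' updated once through the discriminator (non-saturating objective by
#' default). Losses are logged per iteration; parameter snapshots and sample
#' grids are emitted every `checkpoint_every` iterations. The run is fully
#' deterministic under `cfg$seed` in single-threaded execution.
#'
#' @param data an [image_set()] of square images matching `cfg$side`.
#' @param cfg a [train_config()].
#' @param resume optional result of a previous (shorter) `train_gan()` call
#'   with the same config; training continues from its state, reproducing
#'   the single-run loss history bit-for-bit.
#' @return a `gan_fit` list: generator/discriminator `network_params`
#'   (`g`, `d`), Adam states, `history` data frame
#'   (`iteration, g_loss, d_loss_real, d_loss_fake`), `checkpoints` (list of
#'   iteration-stamped generator snapshots), the config, and the closing RNG
#'   state.
#' @export
train_gan <- function(data, cfg = train_config(), resume = NULL) {
  if (length(data) == 0L) stopf("training data must be non-empty")
  if (!all(dim(data$images[[1L]]) == cfg$side))
    stopf("training images are %dx%d but cfg$side is %d",
          nrow(data$images[[1L]]), ncol(data$images[[1L]]), cfg$side)
  X <- set_to_matrix(data)
  nreal <- nrow(X)

  if (is.null(resume)) {
    set.seed(cfg$seed)
    g <- init_network_params(generator_spec(latent = cfg$latent,
                                            side = cfg$side,
                                            widths = cfg$g_widths))
    d <- init_network_params(discriminator_spec(side = cfg$side,
                                                widths = cfg$d_widths))
    opt_g <- adam_init(trainable_params(g), lr = cfg$lr, beta1 = cfg$beta1,
                       beta2 = cfg$beta2, eps = cfg$adam_eps)
    opt_d <- adam_init(trainable_params(d), lr = cfg$lr, beta1 = cfg$beta1,
                       beta2 = cfg$beta2, eps = cfg$adam_eps)
    start <- 0L
    hist_g <- hist_dr <- hist_df <- numeric(0)
    checkpoints <- list()
  } else {
    g <- resume$g; d <- resume$d
    opt_g <- resume$opt_g; opt_d <- resume$opt_d
    start <- nrow(resume$history)
    hist_g <- resume$history$g_loss
    hist_dr <- resume$history$d_loss_real
    hist_df <- resume$history$d_loss_fake
    checkpoints <- resume$checkpoints
    assign(".Random.seed", resume$rng_state, envir = globalenv())
  }

  bs <- cfg$batch_size
  iters <- cfg$iterations
  if (iters > start) {
    for (it in (start + 1L):iters) {
      # --- discriminator update on combined real + fake batch
      idx <- sample.int(nreal, bs, replace = bs > nreal)
      z <- matrix(stats::rnorm(bs * cfg$latent), bs, cfg$latent)
      gf <- net_forward(z, g, training = TRUE)
      g <- gf$params                       # batch-norm running stats advance
      xb <- rbind(X[idx, , drop = FALSE], gf$output)
      yb <- c(rep(1, bs), rep(0, bs))
      df <- net_forward(xb, d, training = TRUE)
      p <- as.vector(df$output)
      d_loss_real <- bce_loss(yb[1:bs], p[1:bs])
      d_loss_fake <- bce_loss(yb[-(1:bs)], p[-(1:bs)])
      dL <- matrix(bce_grad(yb, p), ncol = 1L)
      db <- net_backward(dL, d, df$caches)
      sd_ <- adam_step(trainable_params(d), db$grads, opt_d)
      d <- set_trainable(d, sd_$params); opt_d <- sd_$state

      # --- generator update through the (fresh) discriminator
      z <- matrix(stats::rnorm(bs * cfg$latent), bs, cfg$latent)
      gf <- net_forward(z, g, training = TRUE)
      g <- gf$params
      df <- net_forward(gf$output, d, training = FALSE)
      p <- as.vector(df$output)
      if (cfg$g_loss == "non-saturating") {
        g_loss <- bce_loss(rep(1, bs), p)
        dL <- matrix(bce_grad(rep(1, bs), p), ncol = 1L)
      } else {
        # minimize mean(log(1 - D(G(z)))): d/dp = -1 / (1 - p) / N
        pc <- clamp(p, 1e-7, 1 - 1e-7)
        g_loss <- mean(log(1 - pc))
        dL <- matrix(-1 / (1 - pc) / bs, ncol = 1L)
      }
      dimg <- net_backward(dL, d, df$caches)$dx
      gb <- net_backward(dimg, g, gf$caches)
      sg_ <- adam_step(trainable_params(g), gb$grads, opt_g)
      g <- set_trainable(g, sg_$params); opt_g <- sg_$state

      if (!all(is.finite(c(g_loss, d_loss_real, d_loss_fake)))) {
        stopf(paste0("non-finite loss at iteration %d ",
                     "(g=%g, d_real=%g, d_fake=%g); aborting"),
              it, g_loss, d_loss_real, d_loss_fake)
      }
      hist_g <- c(hist_g, g_loss)
      hist_dr <- c(hist_dr, d_loss_real)
      hist_df <- c(hist_df, d_loss_fake)

      if (it %% cfg$checkpoint_every == 0L) {
        checkpoints[[length(checkpoints) + 1L]] <-
          list(iteration = it, g = g)
        if (!is.null(cfg$out_dir))
          write_checkpoint_outputs(cfg, it, g,
                                   data.frame(iteration = seq_len(it),
                                              g_loss = hist_g,
                                              d_loss_real = hist_dr,
                                              d_loss_fake = hist_df))
      }
    }
  }

  structure(list(g = g, d = d, opt_g = opt_g, opt_d = opt_d,
                 history = data.frame(iteration = seq_len(length(hist_g)),
                                      g_loss = hist_g,
                                      d_loss_real = hist_dr,
                                      d_loss_fake = hist_df),
                 checkpoints = checkpoints, cfg = cfg,
                 rng_state = get(".Random.seed", envir = globalenv())),
            class = "gan_fit")
}

write_checkpoint_outputs <- function(cfg, it, g, history) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(history, file.path(cfg$out_dir, "loss_history.csv"),
                   row.names = FALSE)
  smp <- sample_generator(g, cfg$sample_grid_n,
                          seed = derive_seed(cfg$seed, 7919L, it))
  write_images(smp, file.path(cfg$out_dir, sprintf("checkpoint_%07d", it)),
               prefix = "sample")
}

#' @export
print.gan_fit <- function(x, ...) {
  cat(sprintf("<gan_fit: %d iterations, side %d, final g_loss %.4f>\n",
              nrow(x$history), x$cfg$side,
              if (nrow(x$history)) x$history$g_loss[nrow(x$history)] else NA))
  invisible(x)
}

#' Sample images from a generator
#'
#' Draws `n` standard-normal latent vectors under `seed`, runs the generator
#' in inference mode (running batch-norm statistics) and denormalizes the
#' outputs to the storage range `[0, 255]`.
#'
#' @param params generator `network_params` (or a `gan_fit`, whose generator
#'   is used).
#' @param n number of images.
#' @param seed RNG seed for the latent draws.
#' @return an [image_set()] with provenance `"generated"`.
#' @export
sample_generator <- function(params, n, seed = 1L) {
  if (inherits(params, "gan_fit")) params <- params$g
  if (n == 0L) return(image_set(list(), character(0),
                                provenance = "generated"))
  set.seed(seed)
  latent <- params$spec$input_dim
  side <- params$spec$side
  z <- matrix(stats::rnorm(n * latent), n, latent)
  out <- net_forward(z, params, training = FALSE)$output
  imgs <- lapply(seq_len(n), function(i)
    denormalize_image(gray_image(matrix(out[i, ], side, side), c(-1, 1))))
  image_set(imgs, provenance = "generated")
}

#' Pairwise-diversity score for mode-collapse detection
#'
#' Mean over all unordered image pairs of the normalized Euclidean distance
#' `||a - b|| / (range * sqrt(H * W))`. The score is 0 iff all samples are
#' identical; a generator stuck emitting one image scores 0. Two images
#' differing in a single pixel by the full range score `1 / sqrt(H * W)`.
#'
#' @param samples an [image_set()] with at least 2 images.
#' @return non-negative scalar.
#' @export
mode_collapse_score <- function(samples) {
  if (length(samples) < 2L)
    stopf("mode_collapse_score needs at least 2 samples")
  rng <- img_range(samples$images[[1L]])
  M <- set_to_matrix(samples, normalize = FALSE)
  hw <- ncol(M)
  mean(stats::dist(M)) / ((rng[2] - rng[1]) * sqrt(hw))
}
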