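#' Leaky rectified linear activation
#'
#' Elementwise `max(x, 0) + alpha * min(x, 0)`: positive inputs pass through,
#' negative inputs are scaled by `alpha` so the unit keeps a small gradient
#' when inactive.
#'
#' @param x numeric scalar, vector or matrix.
#' @param alpha slope for negative inputs (default 0.2).
#' @return same shape as `x`.
#' @export
leaky_relu <- function(x, alpha = 0.2) pmax(x, 0) + alpha * pmin(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binary cross-entropy loss
#'
#' `-(1/N) * sum(y * log(yhat) + (1 - y) * log(1 - yhat))` with predicted
#' probabilities clipped into `[clip, 1 - clip]` to keep the logs finite.
#'
#' @param y labels in `{0, 1}`.
#' @param y_hat predicted probabilities, same length as `y`.
#' @param clip probability floor (documented clipping bound, default 1e-7).
#' @return scalar loss.
#' @export
bce_loss <- function(y, y_hat, clip = 1e-7) {
  if (length(y) == 0L) stopf("bce_loss: empty input")
  if (length(y) != length(y_hat)) stopf("bce_loss: length mismatch")
  p <- clamp(y_hat, clip, 1 - clip)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# dL/dy_hat of bce_loss (after clipping), used by the training loop.
bce_grad <- function(y, y_hat, clip = 1e-7) {
  p <- clamp(y_hat, clip, 1 - clip)
  (p - y) / (p * (1 - p)) / length(y)
}

#' Batch normalization state
#'
#' Holds the learned scale/shift and the running statistics used at
#' inference. The running averages are updated as
#' `running <- momentum * running + (1 - momentum) * batch` (momentum 0.8).
#'
#' @param d number of features.
#' @param momentum running-average weight in `[0, 1]`.
#' @param eps variance stabilizer, must be positive.
#' @return a `batch_norm_state` list.
#' @export
batch_norm_state <- function(d, momentum = 0.8, eps = 1e-5) {
  if (eps <= 0) stopf("eps must be positive")
  if (momentum < 0 || momentum > 1) stopf("momentum must lie in [0, 1]")
  structure(list(gamma = rep(1, d), beta = rep(0, d),
                 running_mean = rep(0, d), running_var = rep(1, d),
                 momentum = momentum, eps = eps),
            class = "batch_norm_state")
}

#' Batch normalization forward pass
#'
#' In training mode each feature is standardized with the batch mean and
#' (biased) batch variance, then scaled and shifted; the running statistics
#' are updated with the state's momentum. In inference mode the running
#' statistics are used instead.
#'
#' @param batch `N x d` activation matrix (`N >= 2` in training mode).
#' @param state a [batch_norm_state()].
#' @param training logical flag.
#' @return list with `output` (`N x d`), updated `state`, and `cache`
#'   (internal values reused by backpropagation).
#' @export
batch_norm_forward <- function(batch, state, training = TRUE) {
  if (!is.matrix(batch)) batch <- matrix(batch, nrow = 1L)
  n <- nrow(batch)
  if (training) {
    if (n < 2L) stopf("batch normalization needs a batch of >= 2 in training")
    mu <- colMeans(batch)
    v <- colMeans(batch^2) - mu^2            # biased variance
    v <- pmax(v, 0)
    state$running_mean <- state$momentum * state$running_mean +
      (1 - state$momentum) * mu
    state$running_var <- state$momentum * state$running_var +
      (1 - state$momentum) * v
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  inv_sd <- 1 / sqrt(v + state$eps)
  xhat <- sweep(sweep(batch, 2, mu), 2, inv_sd, `*`)
  out <- sweep(sweep(xhat, 2, state$gamma, `*`), 2, state$beta, `+`)
  list(output = out, state = state,
       cache = list(x = batch, mu = mu, var = v, xhat = xhat,
                    inv_sd = inv_sd, training = training))
}

batch_norm_backward <- function(dout, state, cache) {
  n <- nrow(cache$x)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, state$gamma, `*`)
  if (!cache$training) {
    dx <- sweep(dxhat, 2, cache$inv_sd, `*`)
  } else {
    # gradient through the batch statistics themselves
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
    dx <- sweep(t1 - t2, 2, cache$inv_sd, `*`)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---------------------------------------------------------------------------
# Network specifications

#' Discriminator network specification
#'
#' A six-layer fully connected classifier: the square image is flattened to a
#' row vector, passed through two dense+LeakyReLU(0.2) stages and a final
#' single-unit dense layer with sigmoid output giving the probability that
#' the image is real (1) rather than generated (0).
#'
#' @param side input image side length (default 200).
#' @param widths hidden dense widths (default `c(512, 256)`).
#' @param alpha LeakyReLU negative slope.
#' @return a `network_spec`.
#' @export
discriminator_spec <- function(side = 200, widths = c(512, 256),
                               alpha = 0.2) {
  layers <- list(list(op = "flatten"))
  for (w in widths) {
    layers <- c(layers, list(list(op = "dense", units = w),
                             list(op = "lrelu", alpha = alpha)))
  }
  layers <- c(layers, list(list(op = "dense", units = 1L),
                           list(op = "activation", fun = "sigmoid")))
  structure(list(kind = "discriminator", side = as.integer(side),
                 input_dim = as.integer(side)^2, layers = layers),
            class = "network_spec")
}

#' Generator network specification
#'
#' An 11-layer fully connected generator: a length-100 latent vector passes
#' through three dense + LeakyReLU(0.2) + batch-norm(momentum 0.8) stages,
#' then a dense layer of `side^2` units with tanh output reshaped into a
#' `side x side` image in `[-1, 1]`.
#'
#' @param latent latent dimension (default 100).
#' @param side output image side (default 200).
#' @param widths hidden dense widths (default `c(256, 512, 1024)`).
#' @param alpha LeakyReLU negative slope.
#' @param bn_momentum batch-norm running-average momentum (default 0.8).
#' @param out_activation `"tanh"` (pairs with `[-1, 1]` images) or
#'   `"sigmoid"` (pairs with `[0, 1]`).
#' @return a `network_spec`.
#' @export
generator_spec <- function(latent = 100, side = 200,
                           widths = c(256, 512, 1024), alpha = 0.2,
                           bn_momentum = 0.8,
                           out_activation = c("tanh", "sigmoid")) {
  out_activation <- match.arg(out_activation)
  layers <- list()
  for (w in widths) {
    layers <- c(layers, list(list(op = "dense", units = w),
                             list(op = "lrelu", alpha = alpha),
                             list(op = "bn", momentum = bn_momentum)))
  }
  layers <- c(layers, list(list(op = "dense", units = as.integer(side)^2),
                           list(op = "activation", fun = out_activation),
                           list(op = "reshape", shape = c(side, side))))
  structure(list(kind = "generator", side = as.integer(side),
                 input_dim = as.integer(latent), layers = layers),
            class = "network_spec")
}

#' Initialize network parameters
#'
#' Dense weights use Glorot-uniform initialization, biases start at zero;
#' batch-norm layers start as the identity map (scale 1, shift 0) with zeroed
#' running mean and unit running variance.
#'
#' @param spec a `network_spec`.
#' @param seed optional RNG seed for reproducible initialization.
#' @return a `network_params` list parallel to `spec$layers`.
#' @export
init_network_params <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  din <- spec$input_dim
  params <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$op == "dense") {
      dout <- ly$units
      lim <- sqrt(6 / (din + dout))
      params[[i]] <- list(W = matrix(stats::runif(din * dout, -lim, lim),
                                     din, dout),
                          b = rep(0, dout))
      din <- dout
    } else if (ly$op == "bn") {
      params[[i]] <- batch_norm_state(din, momentum = ly$momentum)
    }
  }
  structure(list(spec = spec, layers = params), class = "network_params")
}

#' Count trainable parameters of a network
#' @param params a `network_params`.
#' @return integer count of trainable scalars (dense weights/biases and
#'   batch-norm scale/shift).
#' @export
count_parameters <- function(params) {
  tot <- 0
  for (p in params$layers) {
    if (is.null(p)) next
    if (inherits(p, "batch_norm_state"))
      tot <- tot + length(p$gamma) + length(p$beta)
    else tot <- tot + length(p$W) + length(p$b)
  }
  tot
}

# Generic forward pass over a batch (rows = samples). Returns output matrix,
# per-layer caches, and params (batch-norm running stats may have advanced).
net_forward <- function(x, params, training = FALSE) {
  spec <- params$spec
  caches <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$op == "flatten" || ly$op == "reshape") {
      # batch rows already hold the flattened image
    } else if (ly$op == "dense") {
      p <- params$layers[[i]]
      caches[[i]] <- list(x = x)
      x <- x %*% p$W
      x <- sweep(x, 2, p$b, `+`)
    } else if (ly$op == "lrelu") {
      caches[[i]] <- list(x = x)
      x <- leaky_relu(x, ly$alpha)
    } else if (ly$op == "bn") {
      r <- batch_norm_forward(x, params$layers[[i]], training = training)
      params$layers[[i]] <- r$state
      caches[[i]] <- r$cache
      x <- r$output
    } else if (ly$op == "activation") {
      x <- if (ly$fun == "sigmoid") sigmoid(x) else tanh(x)
      caches[[i]] <- list(out = x, fun = ly$fun)
    }
  }
  list(output = x, caches = caches, params = params)
}

# Generic backward pass; `dout` is dL/d(output). Returns per-layer gradients
# (same shape as trainable params) and dL/d(input).
net_backward <- function(dout, params, caches) {
  spec <- params$spec
  grads <- vector("list", length(spec$layers))
  d <- dout
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    if (ly$op == "dense") {
      p <- params$layers[[i]]
      grads[[i]] <- list(W = crossprod(caches[[i]]$x, d), b = colSums(d))
      d <- d %*% t(p$W)
    } else if (ly$op == "lrelu") {
      d <- d * ifelse(caches[[i]]$x > 0, 1, ly$alpha)
    } else if (ly$op == "bn") {
      r <- batch_norm_backward(d, params$layers[[i]], caches[[i]])
      grads[[i]] <- r$grads
      d <- r$dx
    } else if (ly$op == "activation") {
      o <- caches[[i]]$out
      d <- if (caches[[i]]$fun == "sigmoid") d * o * (1 - o)
           else d * (1 - o^2)
    }
  }
  list(grads = grads, dx = d)
}

as_batch <- function(img, dim_expected) {
  if (is.matrix(img) && !inherits(img, "gray_image") &&
      ncol(img) == dim_expected) return(unclass(img))
  m <- unclass(img)
  if (length(m) != dim_expected)
    stopf("input has %d values, expected %d", length(m), dim_expected)
  matrix(as.vector(m), nrow = 1L)
}

#' Discriminator forward pass
#'
#' Scores an image (or a batch of flattened images, one per row) with the
#' probability that it is real. Inputs are expected in the network domain
#' `[-1, 1]`.
#'
#' @param img a `side x side` image, or an `N x side^2` matrix of flattened
#'   images.
#' @param params discriminator `network_params`.
#' @return numeric vector of probabilities in `(0, 1)`.
#' @export
discriminator_forward <- function(img, params) {
  x <- as_batch(img, params$spec$input_dim)
  as.vector(net_forward(x, params, training = FALSE)$output)
}

#' Generator forward pass
#'
#' Maps latent vectors to images in the network range (tanh output in
#' `[-1, 1]` by default). A single latent vector yields a `gray_image`; an
#' `N x latent` matrix yields an `N x side^2` matrix of flattened images.
#'
#' @param z numeric latent vector of the spec's latent length, or an
#'   `N x latent` matrix.
#' @param params generator `network_params`.
#' @param training use batch statistics (and update running averages) rather
#'   than the stored running statistics.
#' @return `gray_image` or matrix of flattened images.
#' @export
generator_forward <- function(z, params, training = FALSE) {
  latent <- params$spec$input_dim
  single <- !is.matrix(z)
  if (single) {
    if (length(z) != latent)
      stopf("latent vector must have length %d (got %d)", latent, length(z))
    z <- matrix(z, nrow = 1L)
  } else if (ncol(z) != latent) {
    stopf("latent matrix must have %d columns (got %d)", latent, ncol(z))
  }
  out <- net_forward(z, params, training = training)$output
  if (single) {
    side <- params$spec$side
    gray_image(matrix(as.vector(out), side, side), c(-1, 1))
  } else out
}

# ---------------------------------------------------------------------------
# Adam optimizer (first/second moment estimates with bias correction)

adam_zero_like <- function(x) {
  if (is.list(x)) lapply(x, adam_zero_like)
  else { y <- x; y[] <- 0; y }
}

#' Initialize Adam optimizer state
#'
#' @param params numeric array, or arbitrarily nested list of numeric
#'   arrays, whose structure the gradients will mirror.
#' @param lr learning rate `a` (default 2e-5).
#' @param beta1 first-moment decay (default 0.7).
#' @param beta2 second-moment decay (default 0.999).
#' @param eps denominator stabilizer (default 1e-8).
#' @return an `adam_state` with zeroed moments `m`, `v` and step counter
#'   `t = 0`.
#' @export
adam_init <- function(params, lr = 2e-5, beta1 = 0.7, beta2 = 0.999,
                      eps = 1e-8) {
  structure(list(m = adam_zero_like(params), v = adam_zero_like(params),
                 t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adam_state")
}

adam_apply <- function(p, g, m, v, st) {
  if (is.list(p)) {
    for (k in seq_along(g)) {
      if (is.null(g[[k]])) next
      r <- adam_apply(p[[k]], g[[k]], m[[k]], v[[k]], st)
      p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  if (length(p) != length(g))
    stopf("adam_step: gradient shape does not match parameter shape")
  m <- st$beta1 * m + (1 - st$beta1) * g
  v <- st$beta2 * v + (1 - st$beta2) * g^2
  mhat <- m / (1 - st$beta1^st$t)
  vhat <- v / (1 - st$beta2^st$t)
  p <- p - st$lr * mhat / (sqrt(vhat) + st$eps)
  list(p = p, m = m, v = v)
}

#' One Adam update step
#'
#' Updates the biased moment estimates
#' `m <- beta1 * m + (1 - beta1) * g`, `v <- beta2 * v + (1 - beta2) * g^2`,
#' applies the bias corrections `1 / (1 - beta1^t)` and `1 / (1 - beta2^t)`,
#' and moves the parameters by `-lr * mhat / (sqrt(vhat) + eps)`.
#'
#' @param params numeric array or nested list of numeric arrays.
#' @param grads gradients with the same structure as `params`.
#' @param state an [adam_init()] state.
#' @return list with updated `params` and `state` (step counter advanced).
#' @export
adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  r <- adam_apply(params, grads, state$m, state$v, state)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# Extract/replace the trainable leaves of network params as a nested list the
# Adam walker can traverse (running statistics excluded).
trainable_params <- function(params) {
  lapply(params$layers, function(p) {
    if (is.null(p)) NULL
    else if (inherits(p, "batch_norm_state")) list(gamma = p$gamma,
                                                   beta = p$beta)
    else list(W = p$W, b = p$b)
  })
}

set_trainable <- function(params, new) {
  for (i in seq_along(new)) {
    if (is.null(new[[i]])) next
    for (nm in names(new[[i]])) params$layers[[i]][[nm]] <- new[[i]][[nm]]
  }
  params
}
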