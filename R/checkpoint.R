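CKPT_MAGIC <- "EMBRYOGAN-CKPT-1"

params_to_list <- function(params) {
  list(spec = unclass(params$spec),
       layers = lapply(params$layers, function(p) {
         if (is.null(p)) return(list(.type = "none"))
         if (inherits(p, "batch_norm_state"))
           c(list(.type = "bn"), unclass(p))
         else list(.type = "dense", dimW = dim(p$W), W = as.vector(p$W),
                   b = p$b)
       }))
}

#' Save / load a generator checkpoint
#'
#' Checkpoints are JSON containers holding a versioned magic string, the
#' network specification header, and the flat parameter arrays (including
#' batch-norm running statistics), written at full double precision.
#'
#' @param params generator `network_params` (or a `gan_fit`, whose generator
#'   is saved).
#' @param path file path.
#' @param iteration optional iteration stamp stored in the header.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the `network_params`.
#' @export
save_checkpoint <- function(params, path, iteration = NA) {
  if (inherits(params, "gan_fit")) {
    iteration <- nrow(params$history)
    params <- params$g
  }
  obj <- list(magic = CKPT_MAGIC, iteration = iteration,
              params = params_to_list(params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$magic, CKPT_MAGIC))
    stopf("not an embryogan checkpoint (magic '%s')",
          if (is.character(obj$magic)) obj$magic else "?")
  p <- obj$params
  spec <- p$spec
  spec$side <- as.integer(spec$side)
  spec$input_dim <- as.integer(spec$input_dim)
  spec$layers <- lapply(spec$layers, function(ly) {
    ly[names(ly) != "op"] <- lapply(ly[names(ly) != "op"], function(v)
      if (is.list(v)) unlist(v) else v)
    ly
  })
  spec <- structure(spec, class = "network_spec")
  layers <- lapply(p$layers, function(ly) {
    num <- function(x) as.numeric(unlist(x))
    switch(ly$.type,
      none = NULL,
      bn = structure(list(gamma = num(ly$gamma), beta = num(ly$beta),
                          running_mean = num(ly$running_mean),
                          running_var = num(ly$running_var),
                          momentum = ly$momentum, eps = ly$eps),
                     class = "batch_norm_state"),
      dense = {
        dimW <- as.integer(unlist(ly$dimW))
        list(W = matrix(num(ly$W), dimW[1], dimW[2]), b = num(ly$b))
      },
      stopf("unknown layer record '%s' in checkpoint", ly$.type))
  })
  structure(list(spec = spec, layers = layers), class = "network_params")
}
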