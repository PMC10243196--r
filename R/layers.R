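# Parameter containers, initializers, the Adam optimizer and checkpointing.

#' He-normal initialized convolution weights
#' @keywords internal
init_conv_w <- function(kh, kw, cin, cout, zero = FALSE) {
  n <- kh * kw * cin * cout
  v <- if (zero) numeric(n) else stats::rnorm(n, sd = sqrt(2 / (kh * kw * cin)))
  array(v, dim = c(kh, kw, cin, cout))
}

#' @keywords internal
nn_conv <- function(kh, kw, cin, cout, bias = TRUE, zero = FALSE) {
  list(w = ag_param(init_conv_w(kh, kw, cin, cout, zero = zero)),
       b = if (bias) ag_param(numeric(cout)) else NULL)
}

#' Depthwise conv layer: one kh x kw filter per channel
#' @keywords internal
nn_dwconv <- function(kh, kw, C, bias = TRUE, zero = FALSE) {
  n <- kh * kw * C
  v <- if (zero) numeric(n) else stats::rnorm(n, sd = sqrt(2 / (kh * kw)))
  list(w = ag_param(array(v, dim = c(kh, kw, C))),
       b = if (bias) ag_param(numeric(C)) else NULL)
}

#' Normalization layer (instance or batch), affine, gamma = 1, beta = 0
#' @keywords internal
nn_norm <- function(C, type = c("instance", "batch")) {
  type <- match.arg(type)
  st <- new.env(parent = emptyenv())
  st$rm <- numeric(C)
  st$rv <- rep(1, C)
  list(gamma = ag_param(rep(1, C)), beta = ag_param(numeric(C)),
       state = st, norm_type = type)
}

#' @keywords internal
apply_norm <- function(tape, x, nm, training = TRUE) {
  if (nm$norm_type == "instance") {
    ag_instance_norm(tape, x, nm$gamma, nm$beta)
  } else {
    ag_batch_norm(tape, x, nm$gamma, nm$beta, nm$state, training = training)
  }
}

#' Collect every trainable parameter node in a (nested) module
#' @param module a nested list containing `ag_param` nodes
#' @return flat list of parameter nodes
#' @export
collect_params <- function(module) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "ag_param")) {
      out[[length(out) + 1L]] <<- x
    } else if (is.list(x) && !is.environment(x)) {
      for (el in x) if (!is.null(el)) walk(el)
    }
  }
  walk(module)
  out
}

#' Count trainable parameters of a model
#' @param module model object (e.g. from [wranet()] or [unet()])
#' @return integer number of scalar parameters
#' @export
count_params <- function(module) {
  sum(vapply(collect_params(module), function(p) length(p$v), numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# -- Adam ---------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p$v) %||% length(p$v))),
       v = lapply(params, function(p) array(0, dim = dim(p$v) %||% length(p$v))),
       t = 0L)
}

adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$g
    if (is.null(g)) next
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    p$v <- p$v - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
  }
  st
}

# -- checkpoints --------------------------------------------------------------

#' Serialize a model's parameters and running statistics
#'
#' Writes the weights in R's native serialization format plus a JSON
#' architecture descriptor sidecar (`<path>.json`) so checkpoints are
#' self-describing.
#'
#' @param model a model from [wranet()] or [unet()]
#' @param path file to write (conventionally `.rds`)
#' @export
save_checkpoint <- function(model, path) {
  params <- collect_params(model)
  states <- collect_norm_states(model)
  obj <- list(descriptor = model$descriptor,
              params = lapply(params, function(p) p$v),
              norm_states = lapply(states, function(s) list(rm = s$rm, rv = s$rv)))
  saveRDS(obj, path)
  jsonlite::write_json(model$descriptor, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load parameters saved with [save_checkpoint()] into a compatible model
#'
#' @param model freshly constructed model with matching architecture
#' @param path checkpoint path
#' @export
load_checkpoint <- function(model, path) {
  obj <- readRDS(path)
  if (!identical(unname(unlist(obj$descriptor)), unname(unlist(model$descriptor))))
    stop("checkpoint/architecture mismatch: descriptor differs")
  params <- collect_params(model)
  if (length(params) != length(obj$params))
    stop("checkpoint/architecture mismatch: parameter count differs")
  for (i in seq_along(params)) {
    if (length(params[[i]]$v) != length(obj$params[[i]]))
      stop("checkpoint/architecture mismatch at parameter ", i)
    params[[i]]$v <- obj$params[[i]]
  }
  states <- collect_norm_states(model)
  for (i in seq_along(states)) {
    states[[i]]$rm <- obj$norm_states[[i]]$rm
    states[[i]]$rv <- obj$norm_states[[i]]$rv
  }
  invisible(model)
}

collect_norm_states <- function(module) {
  out <- list()
  walk <- function(x) {
    if (is.list(x) && !is.environment(x)) {
      if (!is.null(x$norm_type) && is.environment(x$state)) {
        out[[length(out) + 1L]] <<- x$state
      }
      for (el in x) if (!is.null(el)) walk(el)
    }
  }
  walk(module)
  out
}
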