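## Layer objects: environments holding trainable tensor leaves. A "module"
## is any environment with class "pt_module" whose `params()` returns its
## leaves; composite modules simply aggregate children.

new_module <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$children <- list()
  class(e) <- "pt_module"
  e
}

#' Collect every trainable tensor leaf of a module tree
#' @keywords internal
module_params <- function(m) {
  out <- list()
  if (!is.null(m$weight)) out <- c(out, list(m$weight))
  if (!is.null(m$bias)) out <- c(out, list(m$bias))
  if (!is.null(m$gamma)) out <- c(out, list(m$gamma))
  if (!is.null(m$beta)) out <- c(out, list(m$beta))
  for (ch in m$children) out <- c(out, module_params(ch))
  out
}

## Collect numeric state (weights + batch-norm running stats) for
## checkpointing; `module_set_state` is its inverse.
module_state <- function(m) {
  st <- list(params = lapply(module_params(m), function(p) p$value),
             running = list())
  collect_bn <- function(mm) {
    out <- list()
    if (identical(mm$type, "bn")) {
      out <- list(list(mean = mm$running_mean, var = mm$running_var))
    }
    for (ch in mm$children) out <- c(out, collect_bn(ch))
    out
  }
  st$running <- collect_bn(m)
  st
}

module_set_state <- function(m, st) {
  ps <- module_params(m)
  stopifnot(length(ps) == length(st$params))
  for (k in seq_along(ps)) {
    stopifnot(length(ps[[k]]$value) == length(st$params[[k]]))
    ps[[k]]$value <- st$params[[k]]
  }
  k <- 0L
  assign_bn <- function(mm) {
    if (identical(mm$type, "bn")) {
      k <<- k + 1L
      mm$running_mean <- st$running[[k]]$mean
      mm$running_var <- st$running[[k]]$var
    }
    for (ch in mm$children) assign_bn(ch)
  }
  assign_bn(m)
  invisible(m)
}

#' 2-D convolution layer with He-initialized weights
#'
#' @param c_in,c_out channel counts.
#' @param k kernel size (square).
#' @param stride spatial stride.
#' @param pad implicit zero padding; defaults to `(k-1)/2` ("same" at stride 1).
#' @keywords internal
conv_layer <- function(c_in, c_out, k = 3L, stride = 1L, pad = NULL) {
  m <- new_module("conv")
  fan_in <- k * k * c_in
  sd <- sqrt(2 / fan_in)
  m$weight <- pt_param(array(stats::rnorm(k * k * c_in * c_out, sd = sd),
                             dim = c(k, k, c_in, c_out)))
  m$bias <- pt_param(numeric(c_out))
  m$stride <- as.integer(stride)
  m$pad <- if (is.null(pad)) (k - 1L) %/% 2L else as.integer(pad)
  m$forward <- function(x) op_conv2d(x, m$weight, m$bias, m$stride, m$pad)
  m
}

#' Batch-normalization layer (per-channel spatial statistics)
#' @keywords internal
bn_layer <- function(c) {
  m <- new_module("bn")
  m$gamma <- pt_param(rep(1, c))
  m$beta <- pt_param(numeric(c))
  m$running_mean <- numeric(c)
  m$running_var <- rep(1, c)
  m$forward <- function(x, training = TRUE) {
    op_batchnorm(x, m, training = training)
  }
  m
}

## conv -> BN -> optional ReLU, the workhorse composite
cbr_layer <- function(c_in, c_out, k = 3L, stride = 1L, relu = TRUE) {
  m <- new_module("cbr")
  m$children <- list(conv = conv_layer(c_in, c_out, k, stride),
                     bn = bn_layer(c_out))
  m$relu <- relu
  m$forward <- function(x, training = TRUE) {
    h <- m$children$conv$forward(x)
    h <- m$children$bn$forward(h, training)
    if (m$relu) h <- op_relu(h) else h
  }
  m
}

#' Run a forward pass without building gradient history
#'
#' Temporarily marks all parameters as constants so the tape stays empty.
#' @keywords internal
with_no_grad <- function(params, expr) {
  old <- vapply(params, function(p) p$requires_grad, logical(1))
  for (p in params) p$requires_grad <- FALSE
  on.exit(for (k in seq_along(params)) {
    params[[k]]$requires_grad <- old[k]
  })
  force(expr)
}
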