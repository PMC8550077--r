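## Reverse-mode automatic differentiation on dense arrays.
##
## A tensor node ("pt") is an environment holding `value` (an [H, W, C] array
## or a scalar), a list of `parents`, and a `backward` closure mapping the
## node's upstream gradient to one gradient per parent. The graph is rebuilt
## on every forward pass; `pt_backward()` topologically sorts it and
## accumulates gradients into the leaves.

.pt_state <- new.env(parent = emptyenv())
.pt_state$counter <- 0

pt_new <- function(value, parents = list(), backward = NULL,
                   requires_grad = NULL) {
  if (is.null(requires_grad)) {
    requires_grad <- length(parents) > 0 &&
      any(vapply(parents, function(p) p$requires_grad, logical(1)))
  }
  e <- new.env(parent = emptyenv())
  .pt_state$counter <- .pt_state$counter + 1
  e$id <- as.character(.pt_state$counter)
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  e$requires_grad <- requires_grad
  class(e) <- "pt"
  e
}

#' Create a trainable tensor leaf
#'
#' @param value numeric array holding the initial value.
#' @return a tensor node with `requires_grad = TRUE`.
#' @keywords internal
pt_param <- function(value) pt_new(value, requires_grad = TRUE)

pt_const <- function(value) pt_new(value, requires_grad = FALSE)

is_pt <- function(x) inherits(x, "pt")

as_pt <- function(x) if (is_pt(x)) x else pt_const(x)

#' @export
print.pt <- function(x, ...) {
  d <- dim(x$value)
  cat("<tensor", if (is.null(d)) paste0("scalar=", signif(x$value, 6)) else
    paste(d, collapse = "x"),
    if (x$requires_grad) "grad" else "", ">\n")
  invisible(x)
}

## Topological order by iterative depth-first search over parents.
pt_topo <- function(root) {
  order <- vector("list", 64L)
  n <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (top$expanded) {
      n <- n + 1L
      if (n > length(order)) order <- c(order, vector("list", length(order)))
      order[[n]] <- node
      next
    }
    if (!is.null(seen[[node$id]])) next
    seen[[node$id]] <- TRUE
    stack[[length(stack) + 1L]] <- list(node = node, expanded = TRUE)
    for (p in node$parents) {
      if (p$requires_grad && is.null(seen[[p$id]])) {
        stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
      }
    }
  }
  order[seq_len(n)]
}

#' Backpropagate from a scalar loss node
#'
#' Accumulates `grad` on every reachable node with `requires_grad`.
#' @keywords internal
pt_backward <- function(loss) {
  stopifnot(is_pt(loss), length(loss$value) == 1L)
  order <- pt_topo(loss)
  for (node in order) node$grad <- NULL
  loss$grad <- 1
  for (node in rev(order)) {
    if (is.null(node$backward) || is.null(node$grad)) next
    gs <- node$backward(node$grad)
    for (k in seq_along(node$parents)) {
      p <- node$parents[[k]]
      if (!p$requires_grad || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(loss)
}

pt_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- elementwise ops --------------------------------------------------

op_add <- function(a, b) {
  a <- as_pt(a); b <- as_pt(b)
  pt_new(a$value + b$value, list(a, b),
         function(g) list(g, g))
}

op_sub <- function(a, b) {
  a <- as_pt(a); b <- as_pt(b)
  pt_new(a$value - b$value, list(a, b),
         function(g) list(g, -g))
}

op_mul <- function(a, b) {
  a <- as_pt(a); b <- as_pt(b)
  av <- a$value; bv <- b$value
  pt_new(av * bv, list(a, b),
         function(g) list(g * bv, g * av))
}

op_scale <- function(a, k) {
  a <- as_pt(a)
  pt_new(a$value * k, list(a), function(g) list(g * k))
}

op_relu <- function(a) {
  m <- a$value > 0
  pt_new(a$value * m, list(a), function(g) list(g * m))
}

op_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  pt_new(s, list(a), function(g) list(g * s * (1 - s)))
}

## 1 - x, used by the reverse-attention "reverse operation"
op_one_minus <- function(a) {
  pt_new(1 - a$value, list(a), function(g) list(-g))
}

op_sum <- function(a) {
  d <- dim(a$value)
  pt_new(sum(a$value), list(a),
         function(g) list(array(g, d)))
}

op_mean <- function(a) {
  d <- dim(a$value); n <- length(a$value)
  pt_new(sum(a$value) / n, list(a),
         function(g) list(array(g / n, d)))
}

## Channel concatenation of [H, W, C_k] tensors.
op_concat_c <- function(tensors) {
  vals <- lapply(tensors, function(t) t$value)
  dims <- lapply(vals, dim)
  h <- dims[[1]][1]; w <- dims[[1]][2]
  cs <- vapply(dims, function(d) d[3], numeric(1))
  out <- array(unlist(vals, use.names = FALSE), dim = c(h, w, sum(cs)))
  ends <- cumsum(cs); starts <- c(1, head(ends, -1) + 1)
  pt_new(out, tensors, function(g) {
    lapply(seq_along(tensors), function(k) {
      g[, , starts[k]:ends[k], drop = FALSE]
    })
  })
}

## Channel slice x[, , from:to] keeping the 3-D shape.
op_slice_c <- function(a, from, to) {
  d <- dim(a$value)
  out <- a$value[, , from:to, drop = FALSE]
  pt_new(out, list(a), function(g) {
    gx <- array(0, dim = d)
    gx[, , from:to] <- g
    list(gx)
  })
}

## Broadcast a single-channel map across C channels (attention expansion).
op_expand_c <- function(a, C) {
  v <- a$value
  stopifnot(dim(v)[3] == 1L)
  out <- array(v, dim = c(dim(v)[1], dim(v)[2], C))
  pt_new(out, list(a), function(g) {
    list(array(rowSums(matrix(g, ncol = C)), dim = dim(v)))
  })
}

## ---- linear spatial maps: Y_c = A %*% X_c %*% t(B) --------------------
## Bilinear resizing and adaptive average pooling are both separable linear
## maps, so they share this op; the backward pass is the transposed map.
op_linmap <- function(a, A, B) {
  v <- a$value
  d <- dim(v); C <- d[3]
  Ho <- nrow(A); Wo <- nrow(B)
  out <- array(0, dim = c(Ho, Wo, C))
  for (c in seq_len(C)) out[, , c] <- A %*% v[, , c] %*% t(B)
  pt_new(out, list(a), function(g) {
    gx <- array(0, dim = d)
    for (c in seq_len(C)) gx[, , c] <- t(A) %*% g[, , c] %*% B
    list(gx)
  })
}

#' Row-interpolation matrix for bilinear resizing (half-pixel centers)
#' @keywords internal
interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  if (n_in == 1L) { A[, 1] <- 1; return(A) }
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5       # 0-based source coordinate
    src <- min(max(src, 0), n_in - 1)
    lo <- floor(src); hi <- min(lo + 1, n_in - 1); t <- src - lo
    A[i, lo + 1] <- A[i, lo + 1] + (1 - t)
    A[i, hi + 1] <- A[i, hi + 1] + t
  }
  A
}

#' Averaging matrix for adaptive average pooling
#' @keywords internal
avg_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- floor((i - 1) * n_in / n_out) + 1
    hi <- ceiling(i * n_in / n_out)
    A[i, lo:hi] <- 1 / (hi - lo + 1)
  }
  A
}

op_resize_bilinear <- function(a, h_out, w_out) {
  d <- dim(a$value)
  if (d[1] == h_out && d[2] == w_out) return(a)
  op_linmap(a, interp_matrix(h_out, d[1]), interp_matrix(w_out, d[2]))
}

op_adaptive_avgpool <- function(a, h_out, w_out) {
  d <- dim(a$value)
  if (d[1] == h_out && d[2] == w_out) return(a)
  op_linmap(a, avg_matrix(h_out, d[1]), avg_matrix(w_out, d[2]))
}

## ---- 2x2 max pooling, stride 2 ----------------------------------------
op_maxpool2 <- function(a) {
  v <- a$value
  d <- dim(v); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  io <- seq(1, H, by = 2); jo <- seq(1, W, by = 2)
  cand <- array(0, dim = c(H / 2, W / 2, C, 4))
  cand[, , , 1] <- v[io, jo, , drop = FALSE]
  cand[, , , 2] <- v[io + 1, jo, , drop = FALSE]
  cand[, , , 3] <- v[io, jo + 1, , drop = FALSE]
  cand[, , , 4] <- v[io + 1, jo + 1, , drop = FALSE]
  out <- pmax(cand[, , , 1], cand[, , , 2], cand[, , , 3], cand[, , , 4])
  out <- array(out, dim = c(H / 2, W / 2, C))
  ## first argmax wins on ties (deterministic)
  which4 <- array(1L, dim = c(H / 2, W / 2, C))
  best <- cand[, , , 1]
  for (k in 2:4) {
    better <- cand[, , , k] > best
    which4[better] <- k
    best[better] <- cand[, , , k][better]
  }
  pt_new(out, list(a), function(g) {
    gx <- array(0, dim = d)
    for (k in 1:4) {
      m <- which4 == k
      di <- c(0L, 1L, 0L, 1L)[k]; dj <- c(0L, 0L, 1L, 1L)[k]
      sub <- gx[io + di, jo + dj, , drop = FALSE]
      sub[m] <- g[m]
      gx[io + di, jo + dj, ] <- sub
    }
    list(gx)
  })
}

## ---- convolution (C++ kernels) ----------------------------------------
op_conv2d <- function(x, weight, bias, stride = 1L, pad = NULL) {
  wv <- weight$value
  if (is.null(pad)) pad <- (dim(wv)[1] - 1L) %/% 2L
  xv <- x$value
  out <- conv2d_fwd_cpp(xv, wv, bias$value, as.integer(stride),
                        as.integer(pad))
  pt_new(out, list(x, weight, bias), function(g) {
    r <- conv2d_bwd_cpp(xv, wv, g, as.integer(stride), as.integer(pad))
    list(r$gx, r$gw, r$gb)
  })
}

## ---- batch normalization ----------------------------------------------
## Per-channel over the spatial grid. In training mode statistics come from
## the current activation (and running stats are updated as a side effect on
## the layer environment); in eval mode the stored running stats are used.
op_batchnorm <- function(x, layer, training = TRUE, eps = 1e-5,
                         momentum = 0.1) {
  v <- x$value
  d <- dim(v); n <- d[1] * d[2]; C <- d[3]
  gamma <- layer$gamma; beta <- layer$beta
  if (training) {
    mu <- apply(v, 3, mean)
    va <- apply(v, 3, function(m) mean((m - mean(m))^2))
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    layer$running_var <- (1 - momentum) * layer$running_var + momentum * va
  } else {
    mu <- layer$running_mean
    va <- layer$running_var
  }
  istd <- 1 / sqrt(va + eps)
  mu_a <- array(rep(mu, each = n), dim = d)
  istd_a <- array(rep(istd, each = n), dim = d)
  xhat <- (v - mu_a) * istd_a
  g_a <- array(rep(gamma$value, each = n), dim = d)
  b_a <- array(rep(beta$value, each = n), dim = d)
  out <- g_a * xhat + b_a
  pt_new(out, list(x, gamma, beta), function(g) {
    dgamma <- vapply(seq_len(C), function(c) sum(g[, , c] * xhat[, , c]),
                     numeric(1))
    dbeta <- vapply(seq_len(C), function(c) sum(g[, , c]), numeric(1))
    if (training) {
      gx <- array(0, dim = d)
      for (c in seq_len(C)) {
        gc <- g[, , c]
        xh <- xhat[, , c]
        gx[, , c] <- gamma$value[c] * istd[c] *
          (gc - mean(gc) - xh * mean(gc * xh))
      }
    } else {
      gx <- g * g_a * istd_a
    }
    list(gx, dgamma, dbeta)
  })
}
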