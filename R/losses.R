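## Loss stack: plain IoU / BCE baselines, the boundary weight map derived
## from a sliding-window average of the ground-truth mask, the weighted IoU
## and weighted BCE losses built on it, their sum (the per-map segmentation
## loss), the edge-branch BCE, and the deep-supervision total.

.EPS <- 1e-7

clamp01 <- function(p, eps = .EPS) pmin(pmax(p, eps), 1 - eps)

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(as_matrix_like(a)), dim(as_matrix_like(b)))) {
    stop(sprintf("%s must share the same shape (got %s vs %s)", what,
                 paste(dim(as_matrix_like(a)), collapse = "x"),
                 paste(dim(as_matrix_like(b)), collapse = "x")))
  }
}

as_matrix_like <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else x
}

check_binary <- function(b, name = "mask") {
  if (!all(b %in% c(0, 1))) {
    stop(sprintf("%s must be binary (0/1)", name))
  }
}

#' Sliding-window pooling specification
#'
#' Output sizes follow the usual floor arithmetic
#' `H_out = floor((H_in + 2*padding - kernel)/stride + 1)`; the boundary
#' weight map additionally requires the spec to be size-preserving.
#'
#' @param kernel_size integer window size, one value or `c(kh, kw)`.
#' @param stride window stride, one value or `c(sh, sw)`.
#' @param padding implicit zero padding (counted in the average), one value
#'   or `c(ph, pw)`. Default `(kernel_size - 1)/2`.
#' @return an object of class `pooling_spec`.
#' @export
pooling_spec <- function(kernel_size = 31L, stride = 1L, padding = NULL) {
  k <- rep(as.integer(kernel_size), length.out = 2)
  s <- rep(as.integer(stride), length.out = 2)
  p <- if (is.null(padding)) (k - 1L) %/% 2L
       else rep(as.integer(padding), length.out = 2)
  if (any(k < 1) || any(s < 1) || any(p < 0)) {
    stop("pooling_spec: kernel_size/stride must be >= 1, padding >= 0")
  }
  structure(list(kernel_size = k, stride = s, padding = p),
            class = "pooling_spec")
}

pool_out_size <- function(n_in, k, s, p) floor((n_in + 2 * p - k) / s + 1)

## Zero-padded sliding box mean (padding counted in the denominator),
## computed with an integral image; stride-1 only, which is all the
## size-preserving case permits.
box_mean <- function(x, k, p) {
  H <- nrow(x); W <- ncol(x)
  xp <- matrix(0, H + 2 * p[1], W + 2 * p[2])
  xp[(p[1] + 1):(p[1] + H), (p[2] + 1):(p[2] + W)] <- x
  S <- apply(apply(xp, 2, cumsum), 1, cumsum)      # transposed integral
  S <- t(S)
  Sz <- matrix(0, nrow(S) + 1, ncol(S) + 1)
  Sz[-1, -1] <- S
  Ho <- nrow(xp) - k[1] + 1; Wo <- ncol(xp) - k[2] + 1
  i0 <- 1:Ho; j0 <- 1:Wo
  sums <- Sz[i0 + k[1], j0 + k[2], drop = FALSE] -
    Sz[i0, j0 + k[2], drop = FALSE] -
    Sz[i0 + k[1], j0, drop = FALSE] + Sz[i0, j0, drop = FALSE]
  sums / (k[1] * k[2])
}

#' Boundary weight map for complex-pixel emphasis
#'
#' Computes `1 + gain * |avgpool(B) - B|`: pixels whose local neighbourhood
#' disagrees with their own label (i.e. pixels near the mask boundary) get
#' weights up to `1 + gain`; deep-interior and far-background pixels get 1.
#'
#' @param B binary ground-truth mask (matrix).
#' @param pool a [pooling_spec()]; must be size-preserving.
#' @param gain weighting gain (default 5, giving weights in `[1, 6]`).
#' @return numeric matrix of per-pixel weights, same shape as `B`.
#' @export
boundary_weight_map <- function(B, pool = pooling_spec(), gain = 5) {
  B <- as_matrix_like(B)
  check_binary(B, "B")
  ho <- pool_out_size(nrow(B), pool$kernel_size[1], pool$stride[1],
                      pool$padding[1])
  wo <- pool_out_size(ncol(B), pool$kernel_size[2], pool$stride[2],
                      pool$padding[2])
  if (ho != nrow(B) || wo != ncol(B)) {
    stop(sprintf(paste0(
      "pooling spec changes the map size (%dx%d -> %dx%d); the boundary ",
      "weight map needs floor((n + 2*padding - kernel)/stride + 1) == n"),
      nrow(B), ncol(B), ho, wo))
  }
  avg <- box_mean(B, pool$kernel_size, pool$padding)
  1 + gain * abs(avg - B)
}

## ---- plain baselines ---------------------------------------------------

#' Soft intersection-over-union loss
#'
#' `1 - |A.B| / |A+B-A.B|` with soft (probabilistic) intersection and union.
#' @param P prediction in `[0,1]`; `B` binary mask.
#' @export
plain_iou_loss <- function(P, B) {
  check_same_shape(P, B, "P and B")
  inter <- sum(P * B)
  union <- sum(P) + sum(B) - inter
  if (union == 0) return(0)
  1 - inter / union
}

#' Binary cross-entropy loss
#'
#' @param P prediction probabilities; clamped to `[eps, 1-eps]` before logs.
#' @param B binary mask.
#' @param reduction `"mean"` (default) or `"sum"` over pixels.
#' @export
plain_bce_loss <- function(P, B, reduction = c("mean", "sum"), eps = .EPS) {
  reduction <- match.arg(reduction)
  check_same_shape(P, B, "P and B")
  P <- clamp01(P, eps)
  l <- -(B * log(P) + (1 - B) * log(1 - P))
  if (reduction == "mean") mean(l) else sum(l)
}

#' Edge-branch loss: BCE between the predicted edge map and the edge truth
#'
#' The predicted map is resized bilinearly to the truth's resolution first.
#' @param S_e predicted edge probabilities (matrix, any resolution).
#' @param G_e binary edge truth map.
#' @inheritParams plain_bce_loss
#' @export
edge_loss <- function(S_e, G_e, reduction = c("mean", "sum"), eps = .EPS) {
  reduction <- match.arg(reduction)
  S_e <- as_matrix_like(S_e); G_e <- as_matrix_like(G_e)
  check_binary(G_e, "G_e")
  if (!identical(dim(S_e), dim(G_e))) {
    S_e <- resize_matrix(S_e, nrow(G_e), ncol(G_e))
  }
  plain_bce_loss(S_e, G_e, reduction, eps)
}

## ---- weighted losses ---------------------------------------------------

#' Weighted IoU loss
#'
#' With `inter = sum(W*P*B)` and `total = sum(W*(P+B))`, returns
#' `1 - (inter + 1)/(total - inter + 1)`; `total - inter` is the weighted
#' soft union, so a perfect binary prediction scores exactly 0.
#' @param P prediction in `[0,1]`; `B` binary mask; `W` weight map.
#' @export
weighted_iou_loss <- function(P, B, W) {
  check_same_shape(P, B, "P and B")
  check_same_shape(P, W, "P and W")
  inter <- sum(W * P * B)
  total <- sum(W * (P + B))
  1 - (inter + 1) / (total - inter + 1)
}

#' Weighted BCE loss (weighted mean of per-pixel cross-entropy)
#'
#' @inheritParams weighted_iou_loss
#' @export
weighted_bce_loss <- function(P, B, W, eps = .EPS) {
  check_same_shape(P, B, "P and B")
  check_same_shape(P, W, "P and W")
  P <- clamp01(P, eps)
  l <- -(B * log(P) + (1 - B) * log(1 - P))
  sum(l * W) / sum(W)
}

#' Per-map segmentation loss: weighted IoU + weighted BCE
#'
#' The weight map is derived internally from `B` via [boundary_weight_map()].
#' @inheritParams weighted_iou_loss
#' @param pool pooling spec for the weight map.
#' @param gain weight gain.
#' @export
seg_loss <- function(P, B, pool = pooling_spec(), gain = 5) {
  W <- boundary_weight_map(B, pool, gain)
  weighted_iou_loss(P, B, W) + weighted_bce_loss(P, B, W)
}

#' Deep-supervision total loss
#'
#' Sums the segmentation loss of the global map and of the three
#' reverse-attention side outputs (all upsampled to ground-truth resolution)
#' plus the edge-branch BCE.
#'
#' @param outputs named list with probability maps `S_e`, `S_g`, `S_5`,
#'   `S_4`, `S_3`, each at (or resizable to) ground-truth resolution.
#' @param G_s binary lesion mask; `G_e` binary edge truth map.
#' @inheritParams seg_loss
#' @return list with components `l_edge`, `l_seg` (named per map),
#'   `l_total`.
#' @export
total_loss <- function(outputs, G_s, G_e, pool = pooling_spec(), gain = 5) {
  need <- c("S_e", "S_g", "S_5", "S_4", "S_3")
  missing_out <- setdiff(need, names(outputs))
  if (length(missing_out) > 0) {
    stop("total_loss: missing side outputs: ",
         paste(missing_out, collapse = ", "))
  }
  G_s <- as_matrix_like(G_s)
  W <- boundary_weight_map(G_s, pool, gain)
  seg_one <- function(P) {
    P <- as_matrix_like(P)
    if (!identical(dim(P), dim(G_s))) P <- resize_matrix(P, nrow(G_s), ncol(G_s))
    weighted_iou_loss(P, G_s, W) + weighted_bce_loss(P, G_s, W)
  }
  l_seg <- vapply(c("S_g", "S_5", "S_4", "S_3"),
                  function(nm) seg_one(outputs[[nm]]), numeric(1))
  l_edge <- edge_loss(outputs$S_e, G_e)
  list(l_edge = l_edge, l_seg = l_seg,
       l_total = unname(sum(l_seg) + l_edge))
}

## ---- autodiff counterparts (used by the training loop) ------------------

## Weighted BCE on a probability node; B and W are constants.
op_wbce_loss <- function(Pnode, B, W, eps = .EPS) {
  P <- clamp01(Pnode$value, eps)
  l <- -(B * log(P) + (1 - B) * log(1 - P))
  sw <- sum(W)
  pt_new(sum(l * W) / sw, list(Pnode), function(g) {
    inside <- Pnode$value > eps & Pnode$value < 1 - eps
    dP <- (-B / P + (1 - B) / (1 - P)) * W / sw * inside
    list(g * dP)
  })
}

## Weighted IoU on a probability node.
op_wiou_loss <- function(Pnode, B, W) {
  P <- Pnode$value
  inter <- sum(W * P * B)
  total <- sum(W * (P + B))
  num <- inter + 1; den <- total - inter + 1
  pt_new(1 - num / den, list(Pnode), function(g) {
    dnum <- W * B
    dden <- W * (1 - B)
    list(g * (-(dnum * den - num * dden) / den^2))
  })
}

## Mean BCE on a probability node (edge branch).
op_bce_mean <- function(Pnode, G, eps = .EPS) {
  P <- clamp01(Pnode$value, eps)
  n <- length(P)
  l <- -(G * log(P) + (1 - G) * log(1 - P))
  pt_new(sum(l) / n, list(Pnode), function(g) {
    inside <- Pnode$value > eps & Pnode$value < 1 - eps
    list(g * (-G / P + (1 - G) / (1 - P)) / n * inside)
  })
}

## Differentiable total loss over the model's upsampled logit nodes.
ad_total_loss <- function(up_logits, G_s, G_e, pool = pooling_spec(),
                          gain = 5) {
  W <- boundary_weight_map(G_s, pool, gain)
  dim3 <- function(m) array(m, dim = c(nrow(m), ncol(m), 1))
  B3 <- dim3(G_s); W3 <- dim3(W); E3 <- dim3(G_e)
  seg_one <- function(node) {
    P <- op_sigmoid(node)
    op_add(op_wiou_loss(P, B3, W3), op_wbce_loss(P, B3, W3))
  }
  terms <- list(
    edge = op_bce_mean(op_sigmoid(up_logits$S_e), E3),
    S_g = seg_one(up_logits$S_g),
    S_5 = seg_one(up_logits$S_5),
    S_4 = seg_one(up_logits$S_4),
    S_3 = seg_one(up_logits$S_3))
  total <- terms$edge
  for (nm in c("S_g", "S_5", "S_4", "S_3")) total <- op_add(total, terms[[nm]])
  list(total = total,
       terms = vapply(terms, function(t) t$value, numeric(1)))
}

#' Bilinear resize of a plain matrix
#' @keywords internal
resize_matrix <- function(x, h_out, w_out) {
  if (nrow(x) == h_out && ncol(x) == w_out) return(x)
  interp_matrix(h_out, nrow(x)) %*% x %*% t(interp_matrix(w_out, ncol(x)))
}
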