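# Naive straight-line oracles, written independently of the package's
# vectorized/C++ paths: plain R loops over pixels and channels.

# direct-loop cross-correlation with zero padding
naive_conv2d <- function(x, w, b, stride = 1L, pad = NULL) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  H <- dim(x)[1]; W <- dim(x)[2]
  Ho <- (H + 2 * pad - kh) %/% stride + 1L
  Wo <- (W + 2 * pad - kw) %/% stride + 1L
  y <- array(0, dim = c(Ho, Wo, cout))
  for (co in seq_len(cout)) {
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- b[co]
      for (ci in seq_len(cin)) for (dh in seq_len(kh)) for (dw in seq_len(kw)) {
        hi <- (ho - 1L) * stride - pad + dh
        wi <- (wo - 1L) * stride - pad + dw
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          acc <- acc + x[hi, wi, ci] * w[dh, dw, ci, co]
        }
      }
      y[ho, wo, co] <- acc
    }
  }
  y
}

# batch norm over the spatial grid, training-mode statistics
naive_bn <- function(x, gamma, beta, eps = 1e-5) {
  y <- x
  for (c in seq_len(dim(x)[3])) {
    m <- mean(x[, , c])
    v <- mean((x[, , c] - m)^2)
    y[, , c] <- gamma[c] * (x[, , c] - m) / sqrt(v + eps) + beta[c]
  }
  y
}

naive_relu <- function(x) pmax(x, 0)

# applies a cbr module's weights through the naive ops
naive_cbr <- function(mod, x) {
  h <- naive_conv2d(x, mod$children$conv$weight$value,
                    mod$children$conv$bias$value,
                    mod$children$conv$stride, mod$children$conv$pad)
  h <- naive_bn(h, mod$children$bn$gamma$value, mod$children$bn$beta$value)
  if (mod$relu) naive_relu(h) else h
}

naive_bilinear <- function(x, ho, wo) {
  A <- ppaseg:::interp_matrix(ho, dim(x)[1])
  B <- ppaseg:::interp_matrix(wo, dim(x)[2])
  out <- array(0, dim = c(ho, wo, dim(x)[3]))
  for (c in seq_len(dim(x)[3])) out[, , c] <- A %*% x[, , c] %*% t(B)
  out
}

# per-pixel double-loop loss oracles (Eqs. written out one pixel at a time)
oracle_bce <- function(P, B, eps = 1e-7) {
  s <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    p <- min(max(P[i, j], eps), 1 - eps)
    s <- s - (B[i, j] * log(p) + (1 - B[i, j]) * log(1 - p))
  }
  s / (nrow(P) * ncol(P))
}

oracle_iou <- function(P, B) {
  inter <- 0; su <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    inter <- inter + P[i, j] * B[i, j]
    su <- su + P[i, j] + B[i, j]
  }
  if (su - inter == 0) 0 else 1 - inter / (su - inter)
}

oracle_weight_map <- function(B, k, pad) {
  H <- nrow(B); W <- ncol(B)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (di in seq_len(k)) for (dj in seq_len(k)) {
      ii <- i - pad + di - 1L; jj <- j - pad + dj - 1L
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) acc <- acc + B[ii, jj]
    }
    out[i, j] <- 1 + 5 * abs(acc / (k * k) - B[i, j])
  }
  out
}

oracle_wiou <- function(P, B, W) {
  inter <- 0; total <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    inter <- inter + W[i, j] * P[i, j] * B[i, j]
    total <- total + W[i, j] * (P[i, j] + B[i, j])
  }
  1 - (inter + 1) / (total - inter + 1)
}

oracle_wbce <- function(P, B, W, eps = 1e-7) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    p <- min(max(P[i, j], eps), 1 - eps)
    num <- num - W[i, j] * (B[i, j] * log(p) + (1 - B[i, j]) * log(1 - p))
    den <- den + W[i, j]
  }
  num / den
}

# O(n^2) concordant-pair AUC oracle with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg) {
    s <- s + (p > n) + 0.5 * (p == n)
  }
  s / (length(pos) * length(neg))
}

# exhaustive per-angle ray scan of lesion extent beyond the disc rim
oracle_ray_width <- function(mask, disc_mask, cx, cy) {
  best <- 0
  n <- nrow(mask)
  for (ang in seq(0, 2 * pi, length.out = 1441L)[-1441L]) {
    dx <- cos(ang); dy <- sin(ang)
    r_disc <- 0; r_mask <- NA
    for (t in seq(0.5, n, by = 0.25)) {
      xi <- round(cx + t * dx); yi <- round(cy + t * dy)
      if (xi < 1 || xi > n || yi < 1 || yi > n) break
      if (disc_mask[yi, xi] == 1) r_disc <- t
      if (mask[yi, xi] == 1) r_mask <- t
    }
    if (!is.na(r_mask)) best <- max(best, r_mask - r_disc)
  }
  best
}
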