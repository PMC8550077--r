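## Synthetic fundus generator. Emulates the visual situation the segmenter
## faces: a bright, slightly elliptical optic disc; an adjacent
## crescent-shaped parapapillary atrophy ring of intermediate brightness
## whose radial width is controlled relative to the papilla diameter; dark
## vessel curves radiating from the disc; tessellated ("leopard") fundus
## speckle; and Gaussian blur. Ground-truth lesion mask, edge map, disc
## mask and disc geometry are exact by construction.

#' Parameters of the synthetic fundus generator
#'
#' @param canvas_size square image side in pixels (>= 64).
#' @param disc_radius_range optic-disc semi-axis range, pixels.
#' @param ppa_width_fraction_range maximal radial extent of the atrophy
#'   beyond the disc rim, as a fraction of the papilla diameter; within
#'   `(0, 1.5]`.
#' @param crescent_angular_span angular span of the crescent in degrees
#'   (scalar or range); 0 produces an empty lesion.
#' @param vessel_count number of vessel curves.
#' @param speckle_strength amplitude of the tessellated-fundus speckle.
#' @param blur_sigma Gaussian blur applied to the rendered image, pixels.
#' @param seed default seed used when [generate_sample()] is not given one.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(canvas_size = 352L,
                         disc_radius_range = c(28, 44),
                         ppa_width_fraction_range = c(0.15, 0.6),
                         crescent_angular_span = c(140, 300),
                         vessel_count = 6L,
                         speckle_strength = 0.12,
                         blur_sigma = 1.2,
                         seed = 0L) {
  p <- list(canvas_size = as.integer(canvas_size),
            disc_radius_range = as.numeric(rep(disc_radius_range,
                                               length.out = 2)),
            ppa_width_fraction_range = as.numeric(
              rep(ppa_width_fraction_range, length.out = 2)),
            crescent_angular_span = as.numeric(rep(crescent_angular_span,
                                                   length.out = 2)),
            vessel_count = as.integer(vessel_count),
            speckle_strength = as.numeric(speckle_strength),
            blur_sigma = as.numeric(blur_sigma),
            seed = as.integer(seed))
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  fail <- function(field, why) {
    stop(sprintf("invalid synth_params$%s: %s", field, why))
  }
  if (p$canvas_size < 64) fail("canvas_size", "must be >= 64")
  rng_ok <- function(r) length(r) == 2 && !any(is.na(r)) && r[1] <= r[2]
  if (!rng_ok(p$disc_radius_range) || p$disc_radius_range[1] <= 0) {
    fail("disc_radius_range", "need 0 < low <= high")
  }
  r <- p$ppa_width_fraction_range
  if (!rng_ok(r) || r[1] <= 0 || r[2] > 1.5) {
    fail("ppa_width_fraction_range", "need low <= high within (0, 1.5]")
  }
  if (!rng_ok(p$crescent_angular_span) || p$crescent_angular_span[1] < 0 ||
      p$crescent_angular_span[2] > 360) {
    fail("crescent_angular_span", "need 0 <= low <= high <= 360 degrees")
  }
  if (p$vessel_count < 0) fail("vessel_count", "must be >= 0")
  if (p$speckle_strength < 0) fail("speckle_strength", "must be >= 0")
  if (p$blur_sigma < 0) fail("blur_sigma", "must be >= 0")
  invisible(p)
}

## Evaluate an expression under a local, seeded RNG without disturbing the
## caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate one synthetic fundus sample
#'
#' @param params a [synth_params()] object.
#' @param seed integer seed; identical `(params, seed)` pairs reproduce
#'   bit-identical samples.
#' @return an object of class `fundus_sample`: list with `image` (matrix in
#'   `[0,1]`), `mask`, `edge`, `disc_mask` (binary matrices),
#'   `papilla_diameter`, `ppa_width` (realized maximal radial extent,
#'   pixels), `disc_center`, `size_class`.
#' @export
generate_sample <- function(params = synth_params(), seed = params$seed) {
  validate_synth_params(params)
  with_local_seed(seed, generate_sample_impl(params))
}

generate_sample_impl <- function(p) {
  n <- p$canvas_size
  cx <- n / 2 + stats::runif(1, -n / 12, n / 12)
  cy <- n / 2 + stats::runif(1, -n / 12, n / 12)
  r0 <- stats::runif(1, p$disc_radius_range[1], p$disc_radius_range[2])
  ecc <- stats::runif(1, 0.85, 1.0)        # mild ellipticity
  a <- r0; b <- r0 * ecc                   # semi-axes (x, y)
  papilla_diameter <- 2 * max(a, b)
  frac <- stats::runif(1, p$ppa_width_fraction_range[1],
                       p$ppa_width_fraction_range[2])
  w_max <- frac * papilla_diameter
  span <- stats::runif(1, p$crescent_angular_span[1],
                       p$crescent_angular_span[2]) * pi / 180
  theta0 <- stats::runif(1, -pi, pi)

  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  dx <- xs - cx; dy <- ys - cy
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  ## ellipse boundary radius along each pixel's direction
  r_disc <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  disc_mask <- (r <= r_disc) * 1

  dtheta <- atan2(sin(theta - theta0), cos(theta - theta0))  # wrapped
  w_theta <- if (span <= 0) matrix(0, n, n) else {
    pmax(0, w_max * cos(pi * dtheta / span) * (abs(dtheta) <= span / 2))
  }
  mask <- (r > r_disc & r <= r_disc + w_theta) * 1
  ## realized maximal radial extent beyond the rim, from the rasterized mask
  ppa_width <- if (sum(mask) == 0) 0 else max((r - r_disc)[mask == 1])
  edge <- mask_to_edge(mask, 1L)

  ## ---- render the intensity image -------------------------------------
  img <- matrix(0.33, n, n)
  img <- img + 0.05 * (1 - (r / (0.75 * n))^2)          # soft vignette
  if (p$speckle_strength > 0) {                          # leopard speckle
    noise <- matrix(stats::rnorm(n * n), n, n)
    img <- img + p$speckle_strength * gaussian_blur(noise, sigma = 5) * 4
  }
  for (k in seq_len(p$vessel_count)) {                   # vessels
    img <- draw_vessel(img, cx, cy, max(a, b))
  }
  ramp <- pmin(pmax((r_disc + w_theta - r) / 6, 0), 1)   # soft outer edge
  ppa_int <- 0.62 + 0.04 * cos(2 * theta)
  img[mask == 1] <- (ppa_int * ramp + 0.33 * (1 - ramp))[mask == 1]
  img[disc_mask == 1] <- 0.92 - 0.1 * (r / pmax(r_disc, 1))[disc_mask == 1]^2
  if (p$blur_sigma > 0) img <- gaussian_blur(img, p$blur_sigma)
  img <- img + 0.01 * matrix(stats::rnorm(n * n), n, n)
  img <- pmin(pmax(img, 0), 1)

  s <- structure(list(image = img, mask = mask, edge = edge,
                      disc_mask = disc_mask,
                      papilla_diameter = papilla_diameter,
                      ppa_width = ppa_width,
                      disc_center = c(x = cx, y = cy)),
                 class = "fundus_sample")
  s$size_class <- classify_lesion_size(s)
  s
}

## Separable Gaussian blur via banded row/column smoothing matrices.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  smooth_mat <- function(n) {
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      A[i, j[ok]] <- kern[ok] / sum(kern[ok])
    }
    A
  }
  smooth_mat(nrow(x)) %*% x %*% t(smooth_mat(ncol(x)))
}

## One dark quadratic-Bezier vessel starting at the disc rim.
draw_vessel <- function(img, cx, cy, r_disc) {
  n <- nrow(img)
  ang <- stats::runif(1, -pi, pi)
  p0 <- c(cx + r_disc * cos(ang), cy + r_disc * sin(ang))
  len <- stats::runif(1, 0.3, 0.6) * n
  p2 <- p0 + len * c(cos(ang), sin(ang)) +
    stats::rnorm(2, sd = n / 10)
  p1 <- (p0 + p2) / 2 + stats::rnorm(2, sd = n / 14)
  t <- seq(0, 1, length.out = 4 * ceiling(len))
  bez <- function(i) (1 - t)^2 * p0[i] + 2 * t * (1 - t) * p1[i] + t^2 * p2[i]
  px <- round(bez(1)); py <- round(bez(2))
  width <- sample(1:2, 1)
  for (ddx in -width:width) for (ddy in -width:width) {
    if (ddx^2 + ddy^2 > width^2) next
    xi <- px + ddx; yi <- py + ddy
    ok <- xi >= 1 & xi <= n & yi >= 1 & yi <= n
    img[cbind(yi[ok], xi[ok])] <- img[cbind(yi[ok], xi[ok])] - 0.12
  }
  img
}

#' Inner morphological boundary of a binary mask
#'
#' Returns `mask - erosion(mask)`, where the erosion uses a cross-shaped
#' structuring element of size `2*thickness + 1` (pixels outside the image
#' count as background, so mask pixels on the border are boundary pixels).
#' The result is a subset of the mask.
#'
#' @param mask binary matrix.
#' @param thickness boundary thickness in pixels (>= 1).
#' @return binary matrix of boundary pixels.
#' @export
mask_to_edge <- function(mask, thickness = 1L) {
  mask <- as_matrix_like(mask)
  check_binary(mask, "mask")
  t <- as.integer(thickness)
  if (t < 1) stop("thickness must be >= 1")
  shift <- function(m, di, dj) {
    out <- matrix(0, nrow(m), ncol(m))
    src_i <- seq_len(nrow(m)) + di; src_j <- seq_len(ncol(m)) + dj
    ok_i <- src_i >= 1 & src_i <= nrow(m)
    ok_j <- src_j >= 1 & src_j <= ncol(m)
    out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
    out
  }
  eroded <- mask
  for (d in seq_len(t)) {   # erode along the cross arms
    eroded <- eroded * shift(mask, d, 0) * shift(mask, -d, 0) *
      shift(mask, 0, d) * shift(mask, 0, -d)
  }
  mask - eroded
}

#' Split a dataset into train and test indices by an integer ratio
#'
#' A seeded uniform permutation is cut so that
#' `|train| = round(n * ratio_train/(ratio_train + ratio_test))`.
#'
#' @param n number of samples (>= `ratio_train + ratio_test`).
#' @param ratio_train,ratio_test positive integer ratio parts (default
#'   4:1).
#' @param seed RNG seed.
#' @return list with sorted integer vectors `train` and `test` (1-based,
#'   disjoint, covering `1..n`).
#' @export
split_dataset <- function(n, ratio_train = 4L, ratio_test = 1L, seed = 0L) {
  n <- as.integer(n)
  if (ratio_train < 1 || ratio_test < 1) {
    stop("ratio_train and ratio_test must be positive integers")
  }
  if (n < ratio_train + ratio_test) {
    stop(sprintf("n = %d is too small for a %d:%d split", n,
                 ratio_train, ratio_test))
  }
  n_train <- round(n * ratio_train / (ratio_train + ratio_test))
  perm <- with_local_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1):n]))
}

#' Measure the maximal radial extent of the atrophy beyond the disc rim
#'
#' For every lesion pixel, its radial distance from the disc centroid minus
#' the disc's own radius in that direction (from a 720-bin angular profile
#' of the disc mask); the maximum over lesion pixels is the lesion width.
#'
#' @param mask binary lesion mask; `disc_mask` binary optic-disc mask.
#' @return width in pixels (0 for an empty lesion mask).
#' @export
measure_ppa_width <- function(mask, disc_mask) {
  check_binary(mask, "mask"); check_binary(disc_mask, "disc_mask")
  if (sum(disc_mask) == 0) stop("disc_mask is empty")
  if (sum(mask) == 0) return(0)
  idx_d <- which(disc_mask == 1, arr.ind = TRUE)
  cy <- mean(idx_d[, 1]); cx <- mean(idx_d[, 2])
  nb <- 720L
  ang_d <- atan2(idx_d[, 1] - cy, idx_d[, 2] - cx)
  rad_d <- sqrt((idx_d[, 1] - cy)^2 + (idx_d[, 2] - cx)^2)
  bin_d <- pmin(nb, floor((ang_d + pi) / (2 * pi) * nb) + 1L)
  r_disc <- rep(0, nb)
  agg <- tapply(rad_d, bin_d, max)
  r_disc[as.integer(names(agg))] <- agg
  ## fill empty bins by nearest non-empty neighbour (circular)
  if (any(r_disc == 0)) {
    filled <- which(r_disc > 0)
    for (i in which(r_disc == 0)) {
      d <- pmin(abs(filled - i), nb - abs(filled - i))
      r_disc[i] <- r_disc[filled[which.min(d)]]
    }
  }
  idx_m <- which(mask == 1, arr.ind = TRUE)
  ang_m <- atan2(idx_m[, 1] - cy, idx_m[, 2] - cx)
  rad_m <- sqrt((idx_m[, 1] - cy)^2 + (idx_m[, 2] - cx)^2)
  bin_m <- pmin(nb, floor((ang_m + pi) / (2 * pi) * nb) + 1L)
  max(pmax(rad_m - r_disc[bin_m], 0))
}

#' Classify a lesion as small or large relative to the papilla diameter
#'
#' A lesion is `small` when its maximal radial extent beyond the disc rim
#' is at most one third of the papilla diameter (the maximal chord of the
#' disc mask), `large` otherwise. An empty lesion mask is `small`.
#'
#' @param sample a `fundus_sample`, or any list with `mask` and
#'   `disc_mask` (binary matrices); `papilla_diameter` and `ppa_width` are
#'   used when present and measured otherwise.
#' @return `"small"` or `"large"`.
#' @export
classify_lesion_size <- function(sample) {
  if (is.null(sample$disc_mask) || sum(sample$disc_mask) == 0) {
    stop("classify_lesion_size: disc_mask is empty")
  }
  if (is.null(sample$mask)) stop("classify_lesion_size: mask is missing")
  if (sum(sample$mask) == 0) return("small")
  pd <- sample$papilla_diameter
  if (is.null(pd)) pd <- max_chord(sample$disc_mask)
  w <- sample$ppa_width
  if (is.null(w)) w <- measure_ppa_width(sample$mask, sample$disc_mask)
  if (w <= pd / 3) "small" else "large"
}

## Maximal chord of a binary mask, from the convex hull of its pixels.
max_chord <- function(mask) {
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 1) return(1)
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  pts <- idx[hull, , drop = FALSE]
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2))
}

#' Generate and write a synthetic dataset with manifest
#'
#' Writes grayscale image, mask, edge and disc PNGs per sample plus a
#' manifest CSV (`id, image_path, mask_path, edge_path, disc_path,
#' papilla_diameter, ppa_width, size_class, split`).
#'
#' @param n number of samples.
#' @param params a [synth_params()].
#' @param out_dir output directory (created if missing).
#' @param ratio integer `c(train, test)` split ratio (default 4:1).
#' @param seed base seed; sample `i` uses `seed + i`.
#' @return the manifest as a data frame (invisibly written to
#'   `manifest.csv`).
#' @export
write_fundus_dataset <- function(n, params = synth_params(),
                                 out_dir, ratio = c(4L, 1L), seed = 0L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  split <- split_dataset(n, ratio[1], ratio[2], seed = seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_sample(params, seed = seed + i)
    paths <- file.path(out_dir, sprintf(
      c("img_%03d.png", "mask_%03d.png", "edge_%03d.png", "disc_%03d.png"),
      i))
    write_image_png(s$image, paths[1])
    write_image_png(s$mask, paths[2])
    write_image_png(s$edge, paths[3])
    write_image_png(s$disc_mask, paths[4])
    rows[[i]] <- data.frame(
      id = i, image_path = paths[1], mask_path = paths[2],
      edge_path = paths[3], disc_path = paths[4],
      papilla_diameter = s$papilla_diameter, ppa_width = s$ppa_width,
      size_class = s$size_class,
      split = if (i %in% split$train) "train" else "test")
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
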