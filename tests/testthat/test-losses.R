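# Loss stack: analytic values, double-loop oracles, exhaustive small-grid
# properties, and differentiability.

test_that("boundary weight map: bounds, zero mask, hand-computed example", {
  # all-zero mask: local averages are 0 everywhere, weights exactly 1
  expect_equal(boundary_weight_map(matrix(0, 9, 9), pooling_spec(3)),
               matrix(1, 9, 9))
  # single centre pixel, 3x3 window, zero-padded count-including average
  B <- matrix(0, 5, 5); B[3, 3] <- 1
  W <- boundary_weight_map(B, pooling_spec(3))
  expect_equal(W[3, 3], 1 + 5 * abs(1 / 9 - 1))
  expect_equal(W[1, 1], 1)
  expect_equal(W[3, 2], 1 + 5 * (1 / 9))    # neighbour sees the pixel
  # bounds on random masks
  set.seed(51)
  for (rep in 1:200) {
    W <- boundary_weight_map(random_binary_matrix(8, 8), pooling_spec(3))
    expect_true(min(W) >= 1 && max(W) <= 6)
  }
})

test_that("weight map oracle equivalence and size-preservation check", {
  set.seed(52)
  for (rep in 1:10) {
    B <- random_binary_matrix(7, 9)
    expect_equal(boundary_weight_map(B, pooling_spec(5)),
                 oracle_weight_map(B, 5L, 2L), tolerance = 1e-12)
  }
  expect_error(boundary_weight_map(matrix(0, 8, 8),
                                   pooling_spec(4, padding = 0)),
               "size")
  expect_error(boundary_weight_map(matrix(0.5, 4, 4)), "binary")
})

test_that("losses match per-pixel double-loop oracles on random fixtures", {
  set.seed(53)
  for (rep in 1:20) {
    P <- matrix(runif(64), 8, 8)
    B <- random_binary_matrix(8, 8)
    W <- boundary_weight_map(B, pooling_spec(3))
    expect_equal(plain_bce_loss(P, B), oracle_bce(P, B), tolerance = 1e-6)
    expect_equal(plain_iou_loss(P, B), oracle_iou(P, B), tolerance = 1e-6)
    expect_equal(edge_loss(P, B), oracle_bce(P, B), tolerance = 1e-6)
    expect_equal(weighted_iou_loss(P, B, W), oracle_wiou(P, B, W),
                 tolerance = 1e-6)
    expect_equal(weighted_bce_loss(P, B, W), oracle_wbce(P, B, W),
                 tolerance = 1e-6)
    expect_equal(seg_loss(P, B, pooling_spec(3)),
                 oracle_wiou(P, B, W) + oracle_wbce(P, B, W),
                 tolerance = 1e-6)
  }
})

test_that("analytic loss values hold", {
  B <- random_binary_matrix(6, 6)
  expect_equal(plain_bce_loss(matrix(0.5, 6, 6), B), log(2))
  expect_equal(edge_loss(matrix(0.5, 6, 6), B), log(2))
  # perfect prediction
  W <- boundary_weight_map(B, pooling_spec(3))
  expect_equal(weighted_iou_loss(B, B, W), 0)
  expect_lt(weighted_bce_loss(B, B, W), 2e-7)
  expect_lt(plain_bce_loss(B, B), 2e-7)
  expect_equal(plain_iou_loss(B, B), 0)
  # total miss: inter = 0
  P <- 1 - B
  T <- sum(W * (P + B))
  expect_equal(weighted_iou_loss(P, B, W), 1 - 1 / (T + 1))
})

test_that("uniform weights collapse weighted BCE onto plain BCE exactly", {
  set.seed(54)
  P <- matrix(runif(48), 6, 8)
  B <- random_binary_matrix(6, 8)
  expect_identical(weighted_bce_loss(P, B, matrix(1, 6, 8)),
                   plain_bce_loss(P, B))
})

test_that("shape mismatches are rejected", {
  expect_error(weighted_iou_loss(matrix(0.5, 3, 3), matrix(1, 4, 4),
                                 matrix(1, 3, 3)), "shape")
  expect_error(plain_bce_loss(matrix(0.5, 3, 3), matrix(1, 3, 4)), "shape")
})

test_that("total loss sums its five reported terms", {
  set.seed(55)
  G_s <- random_binary_matrix(16, 16)
  G_e <- mask_to_edge(G_s)
  outputs <- list(S_e = matrix(runif(256), 16, 16),
                  S_g = matrix(runif(256), 16, 16),
                  S_5 = matrix(runif(16), 4, 4),   # resized internally
                  S_4 = matrix(runif(64), 8, 8),
                  S_3 = matrix(runif(256), 16, 16))
  rep <- total_loss(outputs, G_s, G_e, pooling_spec(5))
  expect_equal(rep$l_total, sum(rep$l_seg) + rep$l_edge, tolerance = 1e-9)
  # term-by-term against independent calls
  expect_equal(unname(rep$l_seg["S_g"]),
               seg_loss(outputs$S_g, G_s, pooling_spec(5)), tolerance = 1e-9)
  expect_equal(rep$l_edge, edge_loss(outputs$S_e, G_e), tolerance = 1e-9)
  up5 <- ppaseg:::resize_matrix(outputs$S_5, 16, 16)
  expect_equal(unname(rep$l_seg["S_5"]), seg_loss(up5, G_s, pooling_spec(5)),
               tolerance = 1e-9)
  expect_error(total_loss(outputs[-2], G_s, G_e), "S_g")
})

test_that("weighted IoU is zero iff prediction equals mask (2x2 exhaustive)", {
  grids <- expand.grid(rep(list(0:1), 4))
  for (i in seq_len(16)) for (j in seq_len(16)) {
    P <- matrix(as.numeric(grids[i, ]), 2, 2)
    B <- matrix(as.numeric(grids[j, ]), 2, 2)
    W <- boundary_weight_map(B, pooling_spec(3))
    l <- weighted_iou_loss(P, B, W)
    if (i == j) expect_equal(l, 0) else expect_gt(l, 0)
  }
})

test_that("flipping one correct pixel never decreases seg_loss (3x3)", {
  grids <- expand.grid(rep(list(0:1), 9))
  pool <- pooling_spec(3)
  for (i in seq_len(512)) {
    B <- matrix(as.numeric(grids[i, ]), 3, 3)
    base <- seg_loss(B, B, pool)
    for (px in 1:9) {
      P <- B; P[px] <- 1 - P[px]
      expect_gte(seg_loss(P, B, pool), base)
    }
  }
})

test_that("loss gradients are finite and non-NaN on random fixtures", {
  set.seed(56)
  for (rep in 1:5) {
    B <- array(random_binary_matrix(8, 8), dim = c(8, 8, 1))
    W <- array(boundary_weight_map(B[, , 1], pooling_spec(3)),
               dim = c(8, 8, 1))
    Pn <- ppaseg:::pt_param(array(runif(64, 0.01, 0.99), dim = c(8, 8, 1)))
    L <- ppaseg:::op_add(ppaseg:::op_wiou_loss(Pn, B, W),
                         ppaseg:::op_wbce_loss(Pn, B, W))
    ppaseg:::pt_backward(L)
    expect_true(all(is.finite(Pn$grad)))
  }
})
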