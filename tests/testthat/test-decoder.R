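# Decoder modules: shape contracts, the reversal identity, straight-line
# oracles for the partial decoder and reverse attention, and full-model
# assembly.

test_that("edge attention emits reduced features and a 1-channel logit map", {
  set.seed(41)
  ea <- edge_attention_module(8L, reduce = 8L)
  f2 <- rand_tensor(16, 16, 8)
  out <- ea$forward(f2, training = TRUE)
  expect_identical(dim(out$e_att$value), c(16L, 16L, 8L))
  expect_identical(dim(out$S_e$value), c(16L, 16L, 1L))
  # zero input: batch-norm collapses to beta, so S_e is constant
  z <- ppaseg:::pt_const(array(0, dim = c(16, 16, 8)))
  sz <- ea$forward(z, training = TRUE)$S_e$value
  expect_equal(max(sz) - min(sz), 0)
  # determinism
  out2 <- ea$forward(f2, training = TRUE)
  expect_identical(out$e_att$value, out2$e_att$value)
})

test_that("partial decoder fuses the three coarse levels to /8 logits", {
  set.seed(42)
  pd <- partial_decoder_module(16L, 16L, 32L, reduce = 8L)
  f3 <- rand_tensor(8, 8, 16); f4 <- rand_tensor(4, 4, 16)
  f5 <- rand_tensor(2, 2, 32)
  sg <- pd$forward(f3, f4, f5, training = TRUE)
  expect_identical(dim(sg$value), c(8L, 8L, 1L))
  # all-zero f5 annihilates the gated branches: S_g becomes constant
  z5 <- ppaseg:::pt_const(array(0, dim = c(2, 2, 32)))
  sz <- pd$forward(f3, f4, z5, training = TRUE)$value
  expect_equal(max(sz) - min(sz), 0)
})

test_that("partial decoder equals a straight-line composition oracle", {
  set.seed(43)
  pd <- partial_decoder_module(8L, 8L, 16L, reduce = 4L)
  f3 <- rand_tensor(8, 8, 8); f4 <- rand_tensor(4, 4, 8)
  f5 <- rand_tensor(2, 2, 16)
  got <- pd$forward(f3, f4, f5, training = TRUE)$value
  ch <- pd$children
  g3 <- naive_cbr(ch$red3, f3$value)
  g4 <- naive_cbr(ch$red4, f4$value)
  g5 <- naive_cbr(ch$red5, f5$value)
  g4p <- g4 * naive_bilinear(naive_cbr(ch$c54, g5), 4, 4)
  g3p <- g3 * naive_bilinear(naive_cbr(ch$c43, g4), 8, 8) *
    naive_bilinear(naive_cbr(ch$c53, g5), 8, 8)
  cat3 <- array(c(g3p, naive_bilinear(g4p, 8, 8), naive_bilinear(g5, 8, 8)),
                dim = c(8, 8, 12))
  fused <- naive_cbr(ch$fuse, cat3)
  sg <- naive_conv2d(fused, ch$proj$weight$value, ch$proj$bias$value, 1L, 0L)
  expect_equal(got, sg, tolerance = 1e-6)
})

test_that("reverse attention obeys A + sigmoid(resized higher map) = 1", {
  set.seed(44)
  ra <- reverse_attention_module(16L, e_att_channels = 8L, reduce = 8L,
                                 level = 4L)
  f4 <- rand_tensor(4, 4, 16)
  s_high <- rand_tensor(2, 2, 1)
  e_att <- rand_tensor(16, 16, 8)
  out <- ra$forward(f4, s_high, e_att, training = TRUE)
  s_res <- ppaseg:::op_resize_bilinear(s_high, 4L, 4L)$value
  expect_equal(out$A$value + 1 / (1 + exp(-s_res)),
               array(1, dim = c(4, 4, 1)))
  expect_identical(dim(out$S$value), c(4L, 4L, 1L))
  expect_identical(dim(out$R$value), c(4L, 4L, 16L))  # reduced + e_att
  expect_error(reverse_attention_module(16L, level = 2L), "level")
})

test_that("saturated higher logits suppress the gated features entirely", {
  set.seed(45)
  ra <- reverse_attention_module(8L, e_att_channels = 4L, reduce = 4L,
                                 level = 5L)
  f5 <- rand_tensor(2, 2, 8)
  e_att <- ppaseg:::pt_const(array(0, dim = c(8, 8, 4)))
  s_high <- ppaseg:::pt_const(array(1e6, dim = c(2, 2, 1)))
  out <- ra$forward(f5, s_high, e_att, training = TRUE)
  expect_equal(max(abs(out$A$value)), 0)
  gated <- out$R$value[, , 1:4]
  expect_equal(max(abs(gated)), 0)
  # S_i collapses to a constant refinement added to the higher map
  delta <- out$S$value - 1e6
  expect_equal(max(delta) - min(delta), 0, tolerance = 1e-6)
})

test_that("reverse attention equals its naive unfused composition", {
  set.seed(46)
  ra <- reverse_attention_module(8L, e_att_channels = 4L, reduce = 4L,
                                 level = 3L)
  f3 <- rand_tensor(8, 8, 8)
  s_high <- rand_tensor(4, 4, 1)
  e_att <- rand_tensor(16, 16, 4)
  got <- ra$forward(f3, s_high, e_att, training = TRUE)
  s_res <- naive_bilinear(s_high$value, 8, 8)
  A <- 1 - 1 / (1 + exp(-s_res))
  f_red <- naive_cbr(ra$children$red, f3$value)
  gated <- f_red * array(A, dim = c(8, 8, 4))
  A8 <- ppaseg:::avg_matrix(8L, 16L)
  e_dn <- array(0, dim = c(8, 8, 4))
  for (c in 1:4) e_dn[, , c] <- A8 %*% e_att$value[, , c] %*% t(A8)
  R <- array(c(gated, e_dn), dim = c(8, 8, 8))
  h <- naive_cbr(ra$children$a, R)
  h <- naive_cbr(ra$children$b, h)
  S <- naive_conv2d(h, ra$children$proj$weight$value,
                    ra$children$proj$bias$value, 1L, 0L) + s_res
  expect_equal(got$R$value, R, tolerance = 1e-6)
  expect_equal(got$S$value, S, tolerance = 1e-6)
})

test_that("assembled model emits all side outputs at input resolution", {
  m <- tiny_model(seed = 47L)
  img <- matrix(runif(64 * 64), 64, 64)
  out <- ppa_unet_forward(m, img)
  expect_named(out$up, c("S_e", "S_g", "S_5", "S_4", "S_3"))
  for (u in out$up) expect_identical(dim(u), c(64L, 64L))
  expect_identical(dim(out$prob), c(64L, 64L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  # native side-output resolutions: /4, /8, /32, /16, /8
  expect_identical(vapply(out$side, nrow, integer(1)),
                   c(S_e = 16L, S_g = 8L, S_5 = 2L, S_4 = 4L, S_3 = 8L))
  # eval-mode forward is deterministic
  out2 <- ppa_unet_forward(m, img)
  expect_identical(out$prob, out2$prob)
  expect_error(ppa_unet_forward(m, matrix(0.1, 50, 50)), "divisible")
})

test_that("side outputs stay finite under extreme inputs", {
  m <- tiny_model(seed = 48L)
  for (scale in c(1e3, -1e3)) {
    img <- matrix(scale, 64, 64) + matrix(runif(64 * 64), 64, 64)
    out <- ppa_unet_forward(m, img, training = TRUE)
    expect_true(all(vapply(out$up, function(u) all(is.finite(u)),
                           logical(1))))
    expect_true(all(is.finite(out$prob)))
  }
})
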