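# Synthetic fundus generator, edge derivation, dataset splitting and
# lesion-size classification.

test_that("generation is bit-identical for identical (params, seed)", {
  p <- synth_params(canvas_size = 96)
  a <- generate_sample(p, seed = 5)
  b <- generate_sample(p, seed = 5)
  expect_identical(a, b)
  c <- generate_sample(p, seed = 6)
  expect_false(identical(a$image, c$image))
})

test_that("invalid parameters are rejected naming the offending field", {
  expect_error(synth_params(canvas_size = 32), "canvas_size")
  expect_error(synth_params(ppa_width_fraction_range = c(0.5, 0.2)),
               "ppa_width_fraction_range")
  expect_error(synth_params(ppa_width_fraction_range = c(0.5, 2)),
               "ppa_width_fraction_range")
  expect_error(synth_params(disc_radius_range = c(-1, 5)),
               "disc_radius_range")
  expect_error(synth_params(blur_sigma = -1), "blur_sigma")
})

test_that("structural invariants hold across random samples", {
  p <- synth_params(canvas_size = 96, disc_radius_range = c(12, 18))
  for (seed in 1:50) {
    s <- generate_sample(p, seed = seed)
    expect_identical(dim(s$image), dim(s$mask))
    expect_identical(dim(s$mask), dim(s$edge))
    expect_identical(dim(s$mask), dim(s$disc_mask))
    expect_equal(sum(s$mask * s$disc_mask), 0)        # atrophy outside disc
    expect_true(all(s$edge <= s$mask))                 # edge subset of mask
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_gt(s$papilla_diameter, 0)
  }
})

test_that("atrophy is brighter than background and darker than the disc", {
  p <- synth_params(canvas_size = 128, disc_radius_range = c(16, 22))
  s <- generate_sample(p, seed = 9)
  bg <- s$image[s$mask == 0 & s$disc_mask == 0]
  expect_gt(mean(s$image[s$mask == 1]), mean(bg))
  expect_gt(mean(s$image[s$disc_mask == 1]), mean(s$image[s$mask == 1]))
})

test_that("realized lesion width matches the requested fraction (ray scan)", {
  p <- synth_params(canvas_size = 160, disc_radius_range = c(30, 30),
                    ppa_width_fraction_range = c(0.2, 0.2),
                    crescent_angular_span = c(200, 200))
  for (seed in c(2, 4)) {
    s <- generate_sample(p, seed = seed)
    requested <- 0.2 * s$papilla_diameter
    expect_lt(abs(s$ppa_width - requested), 2)
    scanned <- oracle_ray_width(s$mask, s$disc_mask,
                                s$disc_center["x"], s$disc_center["y"])
    expect_lt(abs(scanned - requested), 2)
  }
})

test_that("zero angular span produces an empty lesion and empty edge", {
  p <- synth_params(canvas_size = 96, crescent_angular_span = c(0, 0))
  s <- generate_sample(p, seed = 1)
  expect_equal(sum(s$mask), 0)
  expect_equal(sum(s$edge), 0)
  expect_identical(s$size_class, "small")
})

test_that("mask_to_edge returns the inner morphological boundary", {
  expect_equal(sum(mask_to_edge(matrix(0, 5, 5))), 0)
  # all-ones: erosion removes exactly the border frame
  e <- mask_to_edge(matrix(1, 7, 7), 1)
  inner <- e[2:6, 2:6]
  expect_equal(sum(e), 49 - 25)
  expect_true(all(inner == 0))
  # centered 3x3 square in 7x7: the 8 perimeter pixels remain
  m <- matrix(0, 7, 7); m[3:5, 3:5] <- 1
  e <- mask_to_edge(m, 1)
  expect_equal(sum(e), 8)
  expect_equal(e[4, 4], 0)
  expect_error(mask_to_edge(matrix(0.5, 3, 3)), "binary")
})

test_that("mask_to_edge agrees with a brute-force erosion oracle", {
  set.seed(21)
  naive_edge <- function(m, t) {
    H <- nrow(m); W <- ncol(m)
    er <- matrix(0, H, W)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      if (m[i, j] == 0) next
      keep <- TRUE
      for (d in seq_len(t)) {
        for (off in list(c(d, 0), c(-d, 0), c(0, d), c(0, -d))) {
          ii <- i + off[1]; jj <- j + off[2]
          v <- if (ii < 1 || ii > H || jj < 1 || jj > W) 0 else m[ii, jj]
          if (v == 0) keep <- FALSE
        }
      }
      er[i, j] <- as.numeric(keep)
    }
    m - er
  }
  for (rep in 1:10) {
    m <- random_binary_matrix(9, 9, 0.6)
    for (t in 1:2) {
      expect_equal(mask_to_edge(m, t), naive_edge(m, t))
    }
  }
})

test_that("mask_to_edge is stable on its own 1-pixel-thick output", {
  m <- matrix(0, 9, 9); m[3:7, 3:7] <- 1
  e <- mask_to_edge(m, 1)
  expect_equal(mask_to_edge(e, 1), e)
})

test_that("split_dataset applies the ratio exactly and reproducibly", {
  s <- split_dataset(360, 4, 1, seed = 3)
  expect_length(s$train, 288)
  expect_length(s$test, 72)
  s2 <- split_dataset(5, 4, 1, seed = 1)
  expect_length(s2$train, 4)
  expect_length(s2$test, 1)
  expect_identical(split_dataset(10, 4, 1, seed = 7),
                   split_dataset(10, 4, 1, seed = 7))
  expect_error(split_dataset(3, 4, 1), "too small")
})

test_that("split sizes sum to n with disjoint covering index sets", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(5:500, 1)
    s <- split_dataset(n, 4, 1, seed = sample.int(1e6, 1))
    expect_length(intersect(s$train, s$test), 0)
    expect_identical(sort(c(s$train, s$test)), seq_len(n))
  }
})

test_that("lesion size classification follows the one-third-PD rule", {
  fake <- function(w, pd) {
    list(mask = matrix(c(0, 1, 0, 0), 2, 2),
         disc_mask = matrix(c(1, 0, 0, 0), 2, 2),
         ppa_width = w, papilla_diameter = pd)
  }
  expect_identical(classify_lesion_size(fake(10, 30)), "small")  # boundary
  expect_identical(classify_lesion_size(fake(10.1, 30)), "large")
  empty <- fake(0, 30); empty$mask <- matrix(0, 2, 2)
  expect_identical(classify_lesion_size(empty), "small")
  bad <- fake(1, 3); bad$disc_mask <- matrix(0, 2, 2)
  expect_error(classify_lesion_size(bad), "disc_mask")
})

test_that("dataset writer round-trips samples and manifest", {
  dir <- tempfile("synthds_")
  p <- synth_params(canvas_size = 96, disc_radius_range = c(12, 16))
  man <- write_fundus_dataset(10, p, dir, ratio = c(4L, 1L), seed = 11)
  expect_equal(nrow(man), 10)
  expect_equal(sum(man$split == "train"), 8)
  expect_equal(sum(man$split == "test"), 2)
  expect_true(all(file.exists(man$image_path)))
  man2 <- read_manifest(file.path(dir, "manifest.csv"),
                        require_edges = TRUE)
  expect_equal(nrow(man2), 10)
  # masks survive the 8-bit PNG round trip exactly
  s <- generate_sample(p, seed = 11 + 1)
  expect_equal(round(read_image_png(man$mask_path[1])), s$mask)
  expect_lt(max(abs(read_image_png(man$image_path[1]) - s$image)), 1 / 255)
  unlink(dir, recursive = TRUE)
})
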