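test_that("gaussian maps have unit peak and the closed-form falloff", {
  m <- gaussian_map(c(5, 5), c(11, 11), 1)
  expect_equal(m[6, 6], 1.0)
  expect_equal(m[6, 7], exp(-0.5)) # one pixel right of the peak
  expect_equal(m[7, 6], exp(-0.5))
  expect_false(attr(m, "off_grid"))
  corner <- gaussian_map(c(0, 0), c(11, 11), 1)
  expect_equal(corner[1, 1], 1.0)
  expect_true(all(corner >= 0 & corner <= 1))
  off <- gaussian_map(c(-3, 5), c(11, 11), 1)
  expect_true(attr(off, "off_grid"))
  expect_error(gaussian_map(c(5, 5), c(11, 11), 0), "positive")
})

test_that("pyramids downsample coordinates, shapes and sigma together", {
  kps <- keypoint_set("SXLAX", matrix(c(128, 100, 60, 200,
                                        128, 90, 50, 210), 4, 2))
  pyr <- build_pyramid(kps, c(256, 256), scales = c(1/8, 1/4, 1/2))
  expect_equal(names(pyr$maps), c("0.125", "0.25", "0.5"))
  expect_equal(dim(pyr$maps[["0.125"]]), c(32, 32, 4))
  expect_equal(dim(pyr$maps[["0.25"]]), c(64, 64, 4))
  expect_equal(dim(pyr$maps[["0.5"]]), c(128, 128, 4))
  # point (128,128) at scale 1/2 peaks at cell (64,64) (0-based)
  peak <- which(pyr$maps[["0.5"]][, , 1] ==
                max(pyr$maps[["0.5"]][, , 1]), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(65, 65))
  # pyramid consistency: scale-s peak within 1/s px of the full-res point
  for (sn in names(pyr$maps)) {
    s <- as.numeric(sn)
    for (k in 1:4) {
      pk <- which(pyr$maps[[sn]][, , k] == max(pyr$maps[[sn]][, , k]),
                  arr.ind = TRUE)[1, ]
      full_xy <- c(pk[2] - 1, pk[1] - 1) / s
      expect_lt(sqrt(sum((full_xy - kps$points[k, ])^2)), 1 / s + 1e-9)
    }
  }
  expect_error(build_pyramid(kps, c(256, 256), scales = c(1/2, 1/4)),
               "ascending")
})

test_that("pair/triplet maps are maxima: counts, dominance, permutation", {
  kp3 <- keypoint_set("PSSAX", matrix(c(5, 15, 25, 10, 10, 20), 3, 2))
  aas <- build_aas_targets(kp3, c(32, 32), sigma_px = 2)
  expect_equal(dim(aas$pair_maps)[3], 3)    # C(3,2)
  expect_equal(dim(aas$triplet_maps)[3], 1) # C(3,3)
  kp4 <- keypoint_set("A4C", matrix(c(5, 15, 2, 28, 10, 10, 8, 12), 4, 2))
  aas4 <- build_aas_targets(kp4, c(32, 32), sigma_px = 2)
  expect_equal(dim(aas4$pair_maps)[3], 6)    # C(4,2)
  expect_equal(dim(aas4$triplet_maps)[3], 4) # C(4,3)
  # dominance: each pair map >= its constituent single maps everywhere
  singles <- lapply(1:3, function(k)
    gaussian_map(kp3$points[k, ], c(32, 32), 2))
  for (j in 1:3) {
    i1 <- aas$pairs[1, j]; i2 <- aas$pairs[2, j]
    expect_true(all(aas$pair_maps[, , j] >= singles[[i1]] - 1e-12))
    expect_true(all(aas$pair_maps[, , j] >= singles[[i2]] - 1e-12))
    expect_true(all(aas$pair_maps[, , j] <=
                    pmax(singles[[i1]], singles[[i2]]) + 1e-12))
  }
  # coincident pair equals the single-point map
  kp_co <- keypoint_set("PSSAX", matrix(c(5, 5, 25, 10, 10, 20), 3, 2))
  aas_co <- build_aas_targets(kp_co, c(32, 32), sigma_px = 2)
  expect_equal(aas_co$pair_maps[, , 1],
               unclass(gaussian_map(c(5, 10), c(32, 32), 2)),
               ignore_attr = TRUE)
})

test_that("decoding recovers encoded points to half a pixel", {
  # ideal gaussian at an integer position decodes exactly
  m <- array(gaussian_map(c(20, 10), c(32, 32), 2), dim = c(32, 32, 1))
  stack <- array(0, dim = c(32, 32, 3))
  for (k in 1:3) stack[, , k] <- m[, , 1]
  dec <- decode_heatmaps(stack, "PSSAX")
  expect_equal(unname(dec$points[1, ]), c(20, 10))
  # sub-pixel sweep on a coarse grid of in-bounds points
  for (x in seq(0.5, 30.5, by = 3.75)) {
    for (y in seq(0.25, 30.25, by = 5)) {
      g <- array(gaussian_map(c(x, y), c(32, 32), 2), dim = c(32, 32, 1))
      s <- array(rep(g, 3), dim = c(32, 32, 3))
      d <- decode_heatmaps(s, "PSSAX")
      expect_lt(max(abs(d$points[1, ] - c(x, y))), 0.5 + 1e-12)
    }
  }
})

test_that("degenerate heatmaps fall back to the centre with a flag", {
  flat <- array(0.3, dim = c(16, 16, 3))
  dec <- decode_heatmaps(flat, "PSSAX")
  expect_true(all(attr(dec, "low_confidence")))
  expect_equal(unname(dec$points[1, ]), c(7.5, 7.5))
})

test_that("decoding is equivariant under image transposition", {
  set.seed(31)
  for (i in 1:25) {
    m <- matrix(runif(24 * 24), 24, 24)
    a <- dks:::.decode_channel(m)
    b <- dks:::.decode_channel(t(m))
    expect_equal(a$xy, rev(b$xy))
  }
})

test_that("round trip through encode and decode preserves the convention", {
  # zero-noise round trip guards the shared coordinate convention
  kps <- keypoint_set("A4C", matrix(c(12, 40, 5, 50, 30, 31, 28, 33), 4, 2))
  pyr <- build_pyramid(kps, c(64, 64), scales = 1)
  dec <- decode_heatmaps(pyr$maps[["1"]], "A4C")
  expect_lt(max(abs(dec$points - kps$points)), 0.5 + 1e-12)
})
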