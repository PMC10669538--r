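test_that("iterated 3x3 dilation equals the Chebyshev-ball definition", {
  # single pixel, 7 iterations -> solid 15x15 square
  m <- matrix(FALSE, 31, 31); m[16, 16] <- TRUE
  d7 <- dilate_mask(m, 7)
  expect_equal(sum(d7), 15L * 15L)
  expect_true(all(d7[9:23, 9:23]))
  # 0 iterations is the identity
  expect_equal(dilate_mask(m, 0), m)
  # random masks vs the brute-force neighborhood oracle
  set.seed(7)
  for (i in 1:5) {
    rm <- matrix(runif(32 * 32) < 0.05, 32, 32)
    if (!any(rm)) rm[17, 9] <- TRUE
    expect_equal(dilate_mask(rm, 3), oracle_dilate(rm, 3))
  }
  expect_error(dilate_mask(matrix(FALSE, 4, 4), 2), "empty")
})

test_that("dilation is extensive and monotone", {
  set.seed(8)
  a <- matrix(runif(32 * 32) < 0.04, 32, 32); a[5, 5] <- TRUE
  b <- a; b[runif(length(b)) < 0.04] <- TRUE
  da <- dilate_mask(a, 2); db <- dilate_mask(b, 2)
  expect_true(all(da[a]))          # output contains input
  expect_true(all(db[da]))         # A subset B => dilate(A) subset dilate(B)
})

test_that("crop box is the clipped bounding box of the 7-fold dilation", {
  img <- matrix(runif(64 * 64), 64, 64)
  m <- matrix(FALSE, 64, 64); m[21, 21] <- TRUE   # (20,20) 0-based
  cr <- crop_to_mask(img, m)
  expect_equal(unname(cr$box), c(14, 28, 14, 28))  # 15x15 box, 1-based inclusive
  expect_equal(dim(cr$values), c(15L, 15L))
  # mask touching the border: box clipped to image
  m2 <- matrix(FALSE, 64, 64); m2[1, 1] <- TRUE
  cr2 <- crop_to_mask(img, m2)
  expect_equal(unname(cr2$box), c(1, 8, 1, 8))
  # property: box contains the undilated bounding box with margin <= 7
  set.seed(9)
  for (i in 1:10) {
    mm <- matrix(FALSE, 64, 64)
    r0 <- sample(5:50, 1); c0 <- sample(5:50, 1)
    mm[r0:(r0 + sample(3:8, 1)), c0:(c0 + sample(3:8, 1))] <- TRUE
    b <- crop_to_mask(img, mm)$box
    rr <- range(which(rowSums(mm) > 0)); cc <- range(which(colSums(mm) > 0))
    expect_true(b["row0"] <= rr[1] && b["row1"] >= rr[2])
    expect_true(b["row0"] >= rr[1] - 7 && b["row1"] <= rr[2] + 7)
    expect_true(b["col0"] >= cc[1] - 7 && b["col1"] <= cc[2] + 7)
  }
})

test_that("the tabulated KDE equals the direct Gaussian sum at grid nodes", {
  f <- estimate_density(c(0.2, 0.2, 0.8), bandwidth = 0.1)
  direct <- oracle_kde(f$grid, c(0.2, 0.2, 0.8), 0.1)
  expect_lt(max(abs(f$dens - direct)), 1e-12)
  # evaluation at a node is the node value
  expect_equal(density_eval(f, 0.2), f$dens[which.min(abs(f$grid - 0.2))],
               tolerance = 1e-9)
  # far tails vanish; symmetric samples give symmetric densities
  g <- estimate_density(c(0.3, 0.7), bandwidth = 0.02)
  expect_lt(density_eval(g, 0.999), 1e-8)
  expect_equal(density_eval(g, 0.3), density_eval(g, 0.7), tolerance = 1e-9)
  expect_error(estimate_density(0.5), "at least 2")
  expect_error(estimate_density(c(0.1, 0.2), bandwidth = -1), "positive")
})

test_that("interpolation error of the density lookup is bounded by grid resolution", {
  set.seed(10)
  s <- runif(200)
  f <- estimate_density(s, bandwidth = 0.05)
  at <- runif(500)
  err <- max(abs(density_eval(f, at) - oracle_kde(at, s, 0.05)))
  # |f''| <= 1/(h^3 sqrt(2*pi)) per unit mass; linear interp error <= delta^2/8 * |f''|
  delta <- 1 / 255
  expect_lt(err, delta^2 / 8 / (0.05^3 * sqrt(2 * pi)) + 1e-12)
})

test_that("Scott's rule bandwidth is floored", {
  f <- estimate_density(rep(c(0.5, 0.5001), 50))
  expect_equal(f$bandwidth, 0.01)
  set.seed(14)
  s <- runif(1000)
  g <- estimate_density(s)
  expect_equal(g$bandwidth, max(1000^(-1 / 5) * sd(s), 0.01))
})

test_that("intensity adjustment elevates organ-like values and normalizes to 1", {
  set.seed(12)
  # two-region phantom: organ 0.7, background 0.2
  img <- matrix(0.2 + rnorm(64 * 64, 0, 0.01), 64, 64)
  org <- matrix(FALSE, 64, 64); org[20:44, 20:44] <- TRUE
  img[org] <- 0.7 + rnorm(sum(org), 0, 0.01)
  img <- pmin(pmax(img, 0), 1)
  seed <- matrix(FALSE, 64, 64); seed[30:34, 30:34] <- TRUE
  x <- adjust_intensity(img, seed)
  expect_equal(max(x), 1)
  expect_gte(min(x), 0)
  expect_gt(mean(x[org]), mean(x[!org]))
  # direct-summation check of the ordering at the two modes
  cr <- crop_to_mask(img, seed)
  s <- cr$values[cr$values > 0]
  h <- max(length(s)^(-1 / 5) * sd(s), 0.01)
  expect_gt(oracle_kde(0.7, s, h), oracle_kde(0.2, s, h))
  # constant-valued crop: fallback still produces a valid remap
  flat <- matrix(0.5, 32, 32)
  seed2 <- matrix(FALSE, 32, 32); seed2[16:17, 16:17] <- TRUE
  x2 <- adjust_intensity(flat, seed2)
  expect_equal(max(x2), 1)
  expect_true(all(x2 == 1))   # all pixels share the modal value
})

test_that("pixels at the density mode receive the maximal adjusted value", {
  set.seed(13)
  img <- matrix(0.25, 48, 48)
  img[10:30, 10:30] <- 0.6
  seed <- matrix(FALSE, 48, 48); seed[18:22, 18:22] <- TRUE
  x <- adjust_intensity(img, seed)
  expect_equal(unique(x[img == 0.6]), 1)
})
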