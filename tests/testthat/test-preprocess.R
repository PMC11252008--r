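test_that("contrast stretch maps the percentile window to [0,1]", {
  ## degenerate window
  const <- Volume(array(5, c(6, 6, 6)))
  expect_warning(out <- contrastStretch(const, 1, 99), "degenerate")
  expect_true(all(voxelData(out) == 0))

  ## ramp 0..999 against the sort/interpolation oracle
  ramp <- Volume(array(seq(0, 999), c(10, 10, 10)))
  st <- contrastStretch(ramp, 1, 99)
  p1 <- oracle_percentile(seq(0, 999), 1)
  p99 <- oracle_percentile(seq(0, 999), 99)
  expected <- pmin(1, pmax(0, (seq(0, 999) - p1) / (p99 - p1)))
  expect_equal(as.vector(voxelData(st)), expected, tolerance = 1e-12)
  mid <- voxelData(st)[which(seq(0, 999) == 500)]
  expect_equal(mid, (500 - p1) / (p99 - p1), tolerance = 1e-12)

  ## full window hits min/max exactly
  full <- contrastStretch(ramp, 0, 100)
  expect_identical(range(voxelData(full)), c(0, 1))

  ## monotone where not clipped
  set.seed(11)
  v <- Volume(array(runif(343), c(7, 7, 7)))
  s <- contrastStretch(v, 10, 90)
  inner <- voxelData(s) > 0 & voxelData(s) < 1
  expect_equal(order(voxelData(v)[inner]), order(voxelData(s)[inner]))
})

test_that("difference-of-Gaussians background subtraction", {
  ## constants are Gaussian-invariant
  const <- Volume(array(3.2, c(12, 12, 12)))
  expect_lt(max(abs(voxelData(dogSubtract(const, 4, 1)))), 1e-12)

  ## central impulse: centre value equals the difference of kernel centre
  ## weights, cross-checked by direct dense convolution
  n <- 21
  imp <- array(0, c(n, n, n)); imp[11, 11, 11] <- 1
  out <- dogSubtract(Volume(imp), sigmaBg = 2, sigmaSig = 0.5)
  gk <- function(s) {
    r <- max(1, ceiling(4 * s)); k <- exp(-(-r:r)^2 / (2 * s^2)); k / sum(k)
  }
  dense_center <- function(s) {
    k <- gk(s); r <- (length(k) - 1) / 2
    k[r + 1]^3  # separable kernel centre weight
  }
  expect_equal(voxelData(out)[11, 11, 11],
               max(0, dense_center(0.5) - dense_center(2)), tolerance = 1e-10)

  ## negatives are clipped
  expect_true(min(voxelData(out)) >= 0)

  ## the published sigmas remove a slow gradient under a punctum
  g <- expand.grid(z = 1:48, y = 1:48, x = 1:48)
  punct <- array(exp(-((g$z - 24)^2 + (g$y - 24)^2 + (g$x - 24)^2) / 18),
                 c(48, 48, 48))
  grad <- array(g$z / 96, c(48, 48, 48))
  withG <- dogSubtract(Volume(punct + grad), 15, 1)
  noG <- dogSubtract(Volume(punct), 15, 1)
  ## compare away from the faces: with a 15-voxel background sigma the
  ## reflect boundary leaves a gradient residue in the outer two sigma
  crop <- function(a) a[13:36, 13:36, 13:36]
  expect_gt(cor(as.vector(crop(voxelData(withG))),
                as.vector(crop(voxelData(noG)))), 0.99)
})

test_that("grayscale erosion matches the brute-force ball minimum", {
  const <- Volume(array(7, c(6, 6, 6)))
  expect_equal(voxelData(grayscaleErode(const, 1)), voxelData(const))

  spike <- array(0, c(7, 7, 7)); spike[4, 4, 4] <- 10
  er <- grayscaleErode(Volume(spike), 1)
  expect_equal(max(voxelData(er)), 0)

  set.seed(5)
  r6 <- array(runif(216), c(6, 6, 6))
  er6 <- grayscaleErode(Volume(r6), 1)
  expect_equal(voxelData(er6), oracle_erode(r6, 1), tolerance = 1e-12)

  ## erosion never increases intensities
  expect_true(all(voxelData(er6) <= r6 + 1e-12))
})

test_that("adaptive histogram equalisation is contrast-limited CLAHE", {
  const <- Volume(array(0.4, c(30, 30, 30)))
  out <- equalizeAdaptive(const)
  expect_equal(sd(voxelData(out)), 0)

  ## a two-level volume gets a flatter histogram (entropy increases)
  x <- array(c(rep(0.3, 13500), rep(0.7, 13500)), c(30, 30, 30))
  eq <- equalizeAdaptive(Volume(x))
  entropy <- function(a) {
    h <- tabulate(pmin(64L, floor(a * 64) + 1L), 64L)
    p <- h[h > 0] / sum(h)
    -sum(p * log(p))
  }
  expect_gt(entropy(voxelData(eq)), entropy(x))

  ## clip limit -> 0 approaches the identity
  set.seed(2)
  y <- array(runif(27000), c(30, 30, 30))
  id <- equalizeAdaptive(Volume(y), clipLimit = 1e-7)
  expect_lt(max(abs(voxelData(id) - y)), 0.06)  # 256-bin quantisation floor
})

test_that("percentile-formula threshold agrees with the sort oracle", {
  expect_equal(percentileThreshold(Volume(array(4, c(5, 5, 5))), 95, 0.3), 4)

  x <- rep(1:100, each = 1)
  thr <- percentileThreshold(x, 95, 0.65)
  p95 <- oracle_percentile(x, 95)
  expect_equal(thr, p95 + 0.65 * (100 - p95), tolerance = 1e-12)

  expect_equal(percentileThreshold(x, 95, 1), 100)

  ## non-decreasing in s
  svals <- seq(0, 1, by = 0.1)
  thrs <- vapply(svals, function(s) percentileThreshold(x, 95, s), 0)
  expect_true(all(diff(thrs) >= 0))

  expect_error(percentileThreshold(numeric(0), 95, 0.5), "empty")
  expect_error(percentileThreshold(x, 100, 0.5))
})
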