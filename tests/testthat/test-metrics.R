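test_that("voxel-wise Pearson correlation", {
  set.seed(21)
  a <- array(rnorm(64), c(4, 4, 4))
  expect_equal(voxelPearson(a, a), 1, tolerance = 1e-12)
  expect_equal(voxelPearson(a, -a + 2), -1, tolerance = 1e-12)

  b <- array(rnorm(64), c(4, 4, 4))
  av <- as.vector(a); bv <- as.vector(b)
  closed <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(voxelPearson(a, b), closed, tolerance = 1e-12)

  expect_error(voxelPearson(array(1, c(4, 4, 4)), b), "variance")
  expect_error(voxelPearson(a, array(rnorm(125), c(5, 5, 5))), "mismatch")
})

test_that("object matching scores IOU and Dice and keeps the best pair", {
  d <- c(4, 4, 4)
  lab <- array(0L, d); lab[1:2, 1, 1] <- 1L; lab[4, 4, 4] <- 2L
  self <- matchObjects(LabelMap(lab), LabelMap(lab))
  expect_true(all(self$iou == 1) && all(self$dice == 1))

  ## row fixture: ref voxels 1-10, test voxels 6-15 in a 1 x 1 x 20 row
  ref <- array(0L, c(1, 1, 20)); ref[1, 1, 1:10] <- 1L
  test <- array(0L, c(1, 1, 20)); test[1, 1, 6:15] <- 1L
  m <- matchObjects(LabelMap(ref), LabelMap(test))
  expect_identical(m$overlap_voxels, 5L)
  expect_equal(m$iou, 5 / 15)
  expect_equal(m$dice, 0.5)

  ## a reference overlapping two test segments keeps only the larger IOU
  ref2 <- array(0L, c(1, 1, 20)); ref2[1, 1, 3:12] <- 1L
  test2 <- array(0L, c(1, 1, 20))
  test2[1, 1, 1:8] <- 1L    # overlap 6, union 12  -> iou 0.5
  test2[1, 1, 11:18] <- 2L  # overlap 2, union 16  -> iou 0.125
  m2 <- matchObjects(LabelMap(ref2), LabelMap(test2))
  expect_identical(nrow(m2), 1L)
  expect_identical(m2$test_id, 1L)
})

test_that("precision/recall/F1 curves follow the counting scheme", {
  ref <- array(0L, c(1, 1, 20)); ref[1, 1, 1:10] <- 1L
  test <- array(0L, c(1, 1, 20)); test[1, 1, 6:15] <- 1L
  pairs <- matchObjects(LabelMap(ref), LabelMap(test))
  pr <- prfCurve(pairs, nRef = 1, nTest = 1, thresholds = c(0.2, 0.4))
  expect_identical(pr$n_tp, c(1L, 0L))
  expect_identical(pr$n_fp, c(0L, 1L))
  expect_identical(pr$n_fn, c(0L, 1L))
  expect_identical(pr$f1, c(1, 0))

  ## identical maps: F1 = 1 at every threshold <= 1
  lab <- array(0L, c(4, 4, 4)); lab[2, 2, 1:3] <- 1L; lab[4, 1, 1] <- 2L
  prs <- prfCurve(matchObjects(LabelMap(lab), LabelMap(lab)), 2, 2,
                  thresholds = seq(0.1, 1, 0.1))
  expect_true(all(prs$f1 == 1))

  ## count identities and degenerate inputs
  expect_identical(pr$n_tp + pr$n_fp, c(1L, 1L))
  expect_identical(pr$n_tp + pr$n_fn, c(1L, 1L))
  expect_warning(d0 <- prfCurve(pairs[0, ], 0, 0, 0.2), "degenerate")
  expect_identical(d0$f1, 0)
})

test_that("matcher and curve equal the brute-force oracle on random maps", {
  set.seed(77)
  ths <- seq(0.1, 0.9, 0.1)
  for (i in 1:100) {
    ref <- random_label_map()
    test <- random_label_map()
    got <- matchObjects(LabelMap(ref), LabelMap(test))
    curve <- prfCurve(got, length(setdiff(unique(as.vector(ref)), 0L)),
                      length(setdiff(unique(as.vector(test)), 0L)), ths)
    want <- oracle_match_prf(ref, test, ths)
    expect_identical(curve$n_tp, want$curve$n_tp)
    expect_identical(curve$n_fp, want$curve$n_fp)
    expect_identical(curve$n_fn, want$curve$n_fn)
    expect_equal(curve$f1, want$curve$f1, tolerance = 1e-12)
    ## the Dice-IOU identity holds as an exact rational identity
    if (nrow(got)) {
      expect_equal(got$dice, 2 * got$iou / (1 + got$iou), tolerance = 1e-12)
      expect_true(all(got$iou > 0 & got$iou <= got$dice & got$dice <= 1))
    }
    ## F1 never increases with the threshold
    expect_true(all(diff(curve$f1) <= 1e-12))
  }
})

test_that("Fisher-z confidence intervals reproduce reported bounds", {
  ci1 <- pearsonCI(0.844, 30)
  expect_equal(unname(round(ci1[2], 3)), 0.923)
  ci2 <- pearsonCI(0.841, 30)
  expect_equal(unname(round(ci2[2], 3)), 0.922)

  ## symmetric around 0
  ci0 <- pearsonCI(0, 20)
  expect_equal(unname(ci0[1]), -unname(ci0[2]), tolerance = 1e-12)

  ## bounds bracket r; width shrinks monotonically with n
  for (r in c(-0.6, 0.2, 0.9)) {
    widths <- vapply(c(10, 30, 100, 1000), function(n) {
      ci <- pearsonCI(r, n)
      expect_true(ci[1] < r && r < ci[2])
      unname(diff(ci))
    }, 0)
    expect_true(all(diff(widths) < 0))
  }
  expect_error(pearsonCI(1, 30))
  expect_error(pearsonCI(0.5, 3))
})

test_that("least-squares statistics match the normal equations", {
  x <- c(1, 2, 3); y <- 2 * x + 1
  ex <- linregStats(x, y)
  expect_equal(ex$r, 1, tolerance = 1e-12)
  expect_equal(ex$r_squared, 1, tolerance = 1e-12)

  expect_error(linregStats(rep(1, 5), rnorm(5)), "constant")

  x6 <- c(0.5, 1.1, 2.3, 3.0, 4.8, 5.1)
  y6 <- c(1.0, 1.9, 2.2, 3.9, 4.1, 6.0)
  fit <- linregStats(x6, y6)
  X <- cbind(1, x6)
  beta <- solve(t(X) %*% X, t(X) %*% y6)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-12)
  expect_equal(fit$slope, beta[2], tolerance = 1e-12)
  rr <- cor(x6, y6)
  expect_equal(fit$r, rr, tolerance = 1e-12)
  tval <- rr * sqrt(4 / (1 - rr^2))
  expect_equal(fit$p_two_tailed, 2 * pt(-abs(tval), 4), tolerance = 1e-12)
})
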