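test_that("superposing a set onto itself gives the identity transform", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  tf <- kabschSuperpose(x, x)
  expect_equal(tf@rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf@translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("a planted rotation plus translation is inverted exactly", {
  set.seed(2)
  ref <- matrix(rnorm(30), 10, 3)
  mobile <- sweep(ref %*% t(rotZ(-90)), 2, c(-1, 0, 0))
  tf <- kabschSuperpose(mobile, ref)
  recovered <- applyTransform(mobile, tf)
  rmsd <- sqrt(mean(rowSums((recovered - ref)^2)))
  expect_lt(rmsd, 1e-8)
})

test_that("random planted rotations are recovered to 1e-6", {
  set.seed(3)
  for (rep in 1:5) {
    ref <- matrix(rnorm(30), 10, 3)
    R <- randomRotation()
    tvec <- rnorm(3)
    mobile <- sweep(ref %*% t(R), 2, -tvec)   # ref rotated by R, shifted
    tf <- kabschSuperpose(mobile, ref)
    # oracle: apply the recovered transform and compare coordinates
    expect_lt(max(abs(applyTransform(mobile, tf) - ref)), 1e-6)
  }
})

test_that("unweighted superposition agrees with an independent fitter", {
  set.seed(4)
  ref <- matrix(rnorm(24), 8, 3)
  mobile <- sweep(ref %*% t(randomRotation()), 2, rnorm(3)) +
    matrix(rnorm(24, sd = 0.05), 8, 3)
  tf <- kabschSuperpose(mobile, ref)
  ours <- applyTransform(mobile, tf)
  theirs <- matrix(bio3d::fit.xyz(
    fixed = as.vector(t(ref)), mobile = as.vector(t(mobile)),
    fixed.inds = 1:24, mobile.inds = 1:24), ncol = 3, byrow = TRUE)
  expect_lt(max(abs(ours - theirs)), 1e-6)
})

test_that("degenerate point sets are rejected", {
  expect_error(kabschSuperpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "fewer than 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line), "collinear")
  expect_error(kabschSuperpose(matrix(rnorm(9), 3, 3),
                               matrix(rnorm(9), 3, 3),
                               weights = c(0, 0, 0)), "positive sum")
})

test_that("superposition residual survives any rigid pre-transform", {
  set.seed(5)
  ref <- matrix(rnorm(30), 10, 3)
  mobile <- ref + matrix(rnorm(30, sd = 0.1), 10, 3)
  resid <- function(m) {
    a <- applyTransform(m, kabschSuperpose(m, ref))
    sqrt(mean(rowSums((a - ref)^2)))
  }
  r0 <- resid(mobile)
  for (rep in 1:3) {
    pre <- sweep(mobile %*% t(randomRotation()), 2, rnorm(3))
    expect_equal(resid(pre), r0, tolerance = 1e-8)
  }
})

test_that("superposition never increases the weighted RMSD", {
  set.seed(6)
  for (rep in 1:5) {
    ref <- matrix(rnorm(30), 10, 3)
    mobile <- sweep(ref %*% t(randomRotation()), 2, rnorm(3)) +
      matrix(rnorm(30, sd = 0.2), 10, 3)
    w <- runif(10)
    wr <- function(m) sqrt(sum(w * rowSums((m - ref)^2)) / sum(w))
    after <- applyTransform(mobile,
                            kabschSuperpose(mobile, ref, w))
    expect_lte(wr(after), wr(mobile) + 1e-12)
  }
})

test_that("a rigidly drifting copy aligns back onto its reference", {
  ref <- generateReferenceChain(30)
  set.seed(8)
  tfs <- lapply(1:20, function(f)
    list(R = randomRotation(), t = rnorm(3, sd = 2)))
  drifting <- makeNoisyTraj(ref, 20, sigma = 0, transforms = tfs,
                            seed = 8)
  aligned <- alignToReference(drifting, frameCoords(ref, 1),
                              "backbone")
  rms <- seriesValues(rmsdSeries(aligned, frameCoords(ref, 1),
                                 "backbone")) / 10   # back to nm
  expect_lt(max(rms), 1e-8)
})

test_that("alignment is idempotent", {
  ref <- generateReferenceChain(20)
  tr <- makeNoisyTraj(ref, 10, sigma = 0.1, seed = 9)
  once <- alignToReference(tr, frameCoords(ref, 1), "backbone")
  twice <- alignToReference(once, frameCoords(ref, 1), "backbone")
  expect_lt(max(abs(trajCoords(twice) - trajCoords(once))), 1e-8)
})

test_that("post-alignment RMSD tracks internal noise, not drift", {
  ref <- generateReferenceChain(30)
  set.seed(10)
  tfs <- lapply(1:50, function(f)
    list(R = randomRotation(), t = rnorm(3, sd = 5)))
  still <- makeNoisyTraj(ref, 50, sigma = 0.05, seed = 11)
  drifting <- makeNoisyTraj(ref, 50, sigma = 0.05, transforms = tfs,
                            seed = 11)
  r1 <- seriesValues(rmsdSeries(
    alignToReference(still, frameCoords(ref, 1), "backbone"),
    frameCoords(ref, 1), "backbone"))
  r2 <- seriesValues(rmsdSeries(
    alignToReference(drifting, frameCoords(ref, 1), "backbone"),
    frameCoords(ref, 1), "backbone"))
  # same noise draws, so alignment must strip the drift entirely
  expect_equal(r2, r1, tolerance = 1e-6)
  expect_lt(abs(mean(r1) / 10 - 0.05 * sqrt(3)), 0.02)
})

test_that("rigid-body-only pairs converge immediately with flat weights", {
  ref <- generateReferenceChain(20)
  set.seed(12)
  mk <- function(seed) {
    tfs <- lapply(1:15, function(f)
      list(R = randomRotation(), t = rnorm(3)))
    makeNoisyTraj(ref, 15, sigma = 0, transforms = tfs, seed = seed)
  }
  res <- iterativeAlign(mk(1), mk(2), ref, "backbone")
  expect_true(res$A@converged)
  expect_lte(res$A@iterations, 2)
  expect_equal(res$A@weights, rep(max(res$A@weights), 20),
               tolerance = 1e-6)
})

test_that("iterative reweighting suppresses a planted mobile loop", {
  ref <- generateReferenceChain(40)
  sigma <- rep(0.05, 40); sigma[15:20] <- 0.5   # hot loop
  a <- makeNoisyTraj(ref, 150, sigma, seed = 13, label = "A")
  b <- makeNoisyTraj(ref, 150, sigma, seed = 14, label = "B")
  res <- iterativeAlign(a, b, ref, "backbone")
  w <- res$A@weights
  expect_true(all(w[15:20] < median(w)))
})

test_that("a single iteration reduces to plain alignment", {
  ref <- generateReferenceChain(20)
  tr <- makeNoisyTraj(ref, 10, sigma = 0.1, seed = 15)
  res <- iterativeAlign(tr, tr, ref, "backbone", maxIter = 1)
  plain <- alignToReference(tr, frameCoords(ref, 1), "backbone")
  expect_equal(trajCoords(res$A@trajectory), trajCoords(plain),
               tolerance = 1e-12)
  expect_equal(res$A@weights, rep(1, 20))
})
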