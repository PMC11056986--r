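test_that("RMSD is zero at the reference and exact for rigid offsets", {
  ref <- generateReferenceChain(10)
  tr <- Trajectory(beads(ref), frameCoords(ref, 1), label = "same")
  expect_equal(seriesValues(rmsdSeries(tr, frameCoords(ref, 1),
                                       "backbone")), 0)
  shifted <- Trajectory(beads(ref),
                        sweep(frameCoords(ref, 1), 2, c(-0.3, 0, 0)),
                        label = "shift")
  expect_equal(seriesValues(rmsdSeries(shifted, frameCoords(ref, 1),
                                       "backbone")), 3.0,
               tolerance = 1e-10)
})

test_that("RMSD equals the direct per-bead summation", {
  set.seed(1)
  ref <- generateReferenceChain(10)
  pert <- matrix(rnorm(30, sd = 0.2), 10, 3)
  tr <- Trajectory(beads(ref), frameCoords(ref, 1) + pert,
                   label = "pert")
  got <- seriesValues(rmsdSeries(tr, frameCoords(ref, 1), "backbone"))
  # oracle: explicit sum over beads
  acc <- 0
  for (i in 1:10) acc <- acc + sum(pert[i, ]^2)
  expect_equal(got, sqrt(acc / 10) * 10, tolerance = 1e-10)
})

test_that("RMSD obeys the triangle-type bound", {
  set.seed(2)
  ref <- generateReferenceChain(12)
  mk <- function() frameCoords(ref, 1) + matrix(rnorm(36, sd = 0.3),
                                                12, 3)
  for (rep in 1:5) {
    A <- mk(); B <- mk(); C <- mk()
    r <- function(x, y) sqrt(mean(rowSums((x - y)^2)))
    expect_lte(r(A, C), r(A, B) + r(B, C) + 1e-12)
  }
})

test_that("center of mass averages positions with the given masses", {
  frame <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1, 1))
  expect_equal(centerOfMass(frame, 1:2), c(1, 0, 0))
  expect_equal(centerOfMass(frame, 1:2, masses = c(1, 3, 1)),
               c(1.5, 0, 0))
  set.seed(3)
  pos <- matrix(rnorm(15), 5, 3)
  m <- runif(5)
  oracle <- c(sum(pos[, 1] * m), sum(pos[, 2] * m),
              sum(pos[, 3] * m)) / sum(m)
  expect_equal(centerOfMass(pos, 1:5, masses = m), oracle,
               tolerance = 1e-12)
  expect_error(centerOfMass(pos, 1:2, masses = c(0, 0, 1, 1, 1)),
               "zero total mass")
  expect_error(centerOfMass(pos, integer(0)), "empty")
})

test_that("distance series are symmetric, rigid-invariant and exact", {
  ref <- generateReferenceChain(20)
  tr <- Trajectory(beads(ref),
                   array(rep(frameCoords(ref, 1), each = 5),
                         dim = c(5, 20, 3)), label = "static")
  d <- distanceSeries(tr, "resid 1-3", "resid 15-17")
  expect_equal(min(seriesValues(d)), max(seriesValues(d)))
  dsw <- distanceSeries(tr, "resid 15-17", "resid 1-3")
  expect_equal(seriesValues(d), seriesValues(dsw))
  s <- summary(d)
  expect_equal(unname(s["min"]), unname(s["max"]))
  # global rigid motion leaves COM-COM distances untouched
  set.seed(4)
  tfs <- lapply(1:5, function(f) list(R = randomRotation(),
                                      t = rnorm(3, sd = 3)))
  moved <- makeNoisyTraj(ref, 5, sigma = 0, transforms = tfs)
  dmoved <- distanceSeries(moved, "resid 1-3", "resid 15-17")
  expect_equal(seriesValues(dmoved), seriesValues(d),
               tolerance = 1e-9)
})

test_that("a two-state flip gives a bimodal distance histogram", {
  cfg <- syntheticConfig(nResidues = 30, nFrames = 500,
                         baselineSigma = 0.05, seed = 5,
                         events = list(event("flip_pair", 20:22, 1,
                                             switchFrame = 251,
                                             partner = 27:29)))
  p <- generatePair(cfg)
  d <- seriesValues(distanceSeries(p$B, "resid 1-3", "resid 20-22"))
  R0 <- frameCoords(p$reference, 1)
  dRef <- function(g) sqrt(sum((colMeans(R0[1:3, ]) -
                                  colMeans(R0[g, ]))^2)) * 10
  d1 <- dRef(20:22); d2 <- dRef(27:29)
  lo <- d[1:250]; hi <- d[251:500]
  expect_equal(mean(lo), d1, tolerance = 0.05 * d1)
  expect_equal(mean(hi), d2, tolerance = 0.05 * d2)
  # the two modes are separated: no overlap of the central mass
  expect_gt(abs(mean(hi) - mean(lo)), 4 * stats::sd(lo))
})

test_that("an isolated bead reproduces the analytic sphere area", {
  tr <- Trajectory(data.frame(name = "TGT", resid = 1,
                              resname = "TGT", radius = 0.26),
                   matrix(0, 1, 3), label = "lone")
  s <- sasa(tr, "name TGT", context = "name TGT", probe = 0.26)
  expect_equal(seriesValues(s), 4 * pi * 0.52^2, tolerance = 0.01)
})

test_that("non-touching beads add their full areas", {
  b <- data.frame(name = c("A1", "A2"), resid = 1:2,
                  resname = "X", radius = 0.26)
  tr <- Trajectory(b, rbind(c(0, 0, 0), c(3, 0, 0)), label = "two")
  s <- sasa(tr, "name A1 A2", probe = 0.26)
  expect_equal(seriesValues(s), 2 * 4 * pi * 0.52^2,
               tolerance = 0.01)
})

test_that("overlapping beads match a Monte-Carlo surface oracle", {
  for (dist in c(0.5, 0.8)) {
    b <- data.frame(name = c("A1", "A2"), resid = 1:2,
                    resname = "X", radius = 0.26)
    x2 <- c(dist, 0, 0)
    tr <- Trajectory(b, rbind(c(0, 0, 0), x2), label = "pair")
    s <- sasa(tr, "name A1", probe = 0.26)
    mc <- mcSasaTwoBeads(c(0, 0, 0), x2, 0.26, 0.26, 0.26)
    expect_equal(seriesValues(s), mc, tolerance = 0.02)
  }
})

test_that("moving an occluder closer never raises the target SASA", {
  b <- data.frame(name = c("TGT", "OCC"), resid = 1:2,
                  resname = "X", radius = 0.26)
  dists <- seq(1.2, 0.1, by = -0.1)
  areas <- vapply(dists, function(d) {
    tr <- Trajectory(b, rbind(c(0, 0, 0), c(d, 0, 0)), label = "m")
    seriesValues(sasa(tr, "name TGT", probe = 0.26))
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("invalid radii are reported with the bead name", {
  b <- data.frame(name = c("TGT", "OCC"), resid = 1:2,
                  resname = "X", radius = c(0.26, -1))
  tr <- Trajectory(b, rbind(c(0, 0, 0), c(0.5, 0, 0)), label = "bad")
  expect_error(sasa(tr, "name TGT"), "OCC")
})
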