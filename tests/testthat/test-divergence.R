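statPair <- function(nRes = 20, nFrames = 300, seedA = 1, seedB = 2,
                     sigma = 0.1) {
  ref <- generateReferenceChain(nRes)
  list(ref = ref,
       A = makeNoisyTraj(ref, nFrames, sigma, seed = seedA,
                         label = "A"),
       B = makeNoisyTraj(ref, nFrames, sigma, seed = seedB,
                         label = "B"))
}

test_that("histograms place all mass where the frames are", {
  ref <- generateReferenceChain(10)
  # every frame identical: one bin holds everything
  tr <- makeNoisyTraj(ref, 50, sigma = 0, seed = 1)
  spec <- binningSpec()
  box <- jointBoundingBox(tr, tr, 5, spec)
  d <- buildDistribution(tr, 5, 1:50, spec, box)
  expect_equal(max(d@counts), 50)
  expect_equal(sum(d@counts > 0), 1)
  expect_equal(sum(d@prob), 1, tolerance = 1e-12)
  expect_error(buildDistribution(tr, 5, integer(0), spec, box),
               "empty window")
})

test_that("uniform occupancy of 8 bin centers gives p close to 1/8", {
  # 8 corners of a cube, visited equally often
  corners <- as.matrix(expand.grid(c(0.05, 0.35), c(0.05, 0.35),
                                   c(0.05, 0.35)))
  nRep <- 500   # pseudocount smear shrinks as counts grow
  coords <- array(0, dim = c(8 * nRep, 1, 3))
  coords[, 1, ] <- corners[rep(1:8, nRep), ]
  tr <- Trajectory(toyBeads(1), coords, label = "cube")
  spec <- binningSpec(binWidth = 0.1, pseudocount = 0.5)
  box <- jointBoundingBox(tr, tr, 1, spec)
  d <- buildDistribution(tr, 1, seq_len(8 * nRep), spec, box)
  occupied <- d@prob[d@counts > 0]
  expect_length(occupied, 8)
  expect_equal(occupied, rep(1 / 8, 8), tolerance = 0.05)
  expect_equal(d@counts[d@counts > 0], rep(nRep, 8))
})

test_that("histogram counts match direct per-bin counting", {
  set.seed(3)
  n <- 1000
  coords <- array(rnorm(n * 3, mean = 0.5, sd = 0.1),
                  dim = c(n, 1, 3))
  tr <- Trajectory(toyBeads(1), coords, label = "gauss")
  spec <- binningSpec(binWidth = 0.05)
  box <- jointBoundingBox(tr, tr, 1, spec)
  d <- buildDistribution(tr, 1, 1:n, spec, box)
  # oracle: explicit per-bin triple loop count
  oracle <- integer(prod(box$dims))
  for (f in 1:n) {
    ijk <- floor((coords[f, 1, ] - box$origin) / spec@binWidth)
    lin <- ijk[1] + box$dims[1] * (ijk[2] + box$dims[2] * ijk[3]) + 1
    oracle[lin] <- oracle[lin] + 1L
  }
  expect_identical(d@counts, oracle)
})

test_that("kld matches the printed two-bin direct summation", {
  P <- makeDistProb(c(0.5, 0.5), counts = c(5, 5))
  Q <- makeDistProb(c(0.9, 0.1), counts = c(9, 1))
  expected <- 0.9 * log(0.9 / 0.5) + 0.1 * log(0.1 / 0.5)
  expect_equal(kld(P, Q), expected, tolerance = 1e-12)
  expect_equal(symmetrizedKld(P, Q),
               0.5 * (expected + 0.5 * log(0.5 / 0.9) +
                        0.5 * log(0.5 / 0.1)),
               tolerance = 1e-12)
  expect_equal(kld(P, P), 0, tolerance = 1e-12)
})

test_that("bits rescale nats by 1/ln 2 and geometry mismatches error", {
  P <- makeDist(c(5L, 3L, 2L))
  Q <- makeDist(c(1L, 4L, 5L))
  expect_equal(kld(P, Q, base = "bits"), kld(P, Q) / log(2),
               tolerance = 1e-12)
  Q2 <- makeDist(c(1L, 4L, 5L), binWidth = 0.2)
  expect_error(kld(P, Q2), "geometry")
})

test_that("mass hitting pseudocount-only bins grows as pseudocount shrinks", {
  vals <- vapply(c(0.5, 0.1, 0.01), function(a) {
    P <- makeDist(c(100L, 0L), pseudocount = a)
    Q <- makeDist(c(0L, 100L), pseudocount = a)
    kld(P, Q)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(is.finite(vals)))
})

test_that("kld and symmetrizedKld equal direct summation on random pairs", {
  set.seed(4)
  for (rep in 1:25) {
    K <- sample(2:64, 1)
    nA <- sample(20:200, 1)
    cA <- as.integer(tabulate(sample(K, nA, replace = TRUE),
                              nbins = K))
    cB <- as.integer(tabulate(sample(K, nA, replace = TRUE,
                                     prob = runif(K)), nbins = K))
    P <- makeDist(cA, dims = c(K, 1L, 1L))
    Q <- makeDist(cB, dims = c(K, 1L, 1L))
    expect_equal(kld(P, Q), directKld(P@prob, Q@prob),
                 tolerance = 1e-12)
    expect_equal(symmetrizedKld(P, Q),
                 0.5 * (directKld(P@prob, Q@prob) +
                          directKld(Q@prob, P@prob)),
                 tolerance = 1e-12)
    expect_equal(symmetrizedKld(P, Q), symmetrizedKld(Q, P),
                 tolerance = 1e-14)
  }
})

test_that("self-comparison profiles vanish and profiles are nonnegative", {
  st <- statPair(nRes = 15, nFrames = 100)
  prof <- divergenceProfile(st$A, st$A)
  expect_true(all(divergenceValues(prof) < 1e-12))
  prof2 <- divergenceProfile(st$A, st$B)
  expect_true(all(divergenceValues(prof2) >= 0))
  expect_equal(profileResidues(prof2), 1:15)
})

test_that("a planted mean shift dominates the profile", {
  cfg <- syntheticConfig(nResidues = 40, nFrames = 600, seed = 21,
                         events = list(event("mean_shift", 18:23,
                                             0.5)))
  p <- generatePair(cfg)
  al <- iterativeAlign(p$A, p$B, p$A, "backbone")
  prof <- divergenceProfile(al$A@trajectory, al$B@trajectory)
  top <- order(divergenceValues(prof), decreasing = TRUE)[1:6]
  expect_setequal(profileResidues(prof)[top], 18:23)
})

test_that("equally mobile but identically distributed residues score low", {
  # same per-residue distribution in both trajectories, high motility
  ref <- generateReferenceChain(20)
  a <- makeNoisyTraj(ref, 800, sigma = 0.4, seed = 31, label = "A")
  b <- makeNoisyTraj(ref, 800, sigma = 0.4, seed = 32, label = "B")
  profHot <- divergenceProfile(a, b)
  cfgShift <- syntheticConfig(nResidues = 20, nFrames = 800,
                              baselineSigma = 0.05,
                              driftRot = 0, driftTrans = 0,
                              seed = 33,
                              events = list(event("mean_shift", 10L,
                                                  0.4)))
  shifted <- generatePair(cfgShift)
  profShift <- divergenceProfile(shifted$A, shifted$B)
  # motility alone scores well below an actual distributional change
  expect_lt(max(divergenceValues(profHot)),
            max(divergenceValues(profShift)) / 3)
})

test_that("the moving window grows, slides and shrinks as specified", {
  st <- statPair(nRes = 12, nFrames = 200)
  m <- windowedDivergence(st$A, st$B, W = 50)
  wr <- windowRanges(m)
  expect_equal(nrow(wr), 200 + 50 - 1)
  expect_equal(unlist(wr[49, c("start", "end")]), c(start = 1, end = 49))
  expect_equal(unlist(wr[50, c("start", "end")]), c(start = 1, end = 50))
  expect_equal(unlist(wr[51, c("start", "end")]), c(start = 2, end = 51))
  expect_equal(unlist(wr[249, c("start", "end")]),
               c(start = 200, end = 200))
  expect_error(windowedDivergence(st$A, st$B, W = 1), "W must be >= 2")
})

test_that("a full-width window reproduces the whole-trajectory profile", {
  st <- statPair(nRes = 10, nFrames = 80)
  m <- windowedDivergence(st$A, st$B, W = 100)
  prof <- divergenceProfile(st$A, st$B)
  full <- which(m@windowStart == 1 & m@windowEnd == 80)[1]
  expect_identical(m@values[full, ], unname(divergenceValues(prof)))
})

test_that("stationary identical pairs stay near zero in every window", {
  st <- statPair(nRes = 10, nFrames = 150)
  m <- windowedDivergence(st$A, st$A, W = 30)
  expect_true(all(m@values < 1e-12))
})

test_that("a two-state switch shows up as a windowed change point", {
  cfg <- syntheticConfig(nResidues = 30, nFrames = 600, seed = 41,
                         events = list(event("two_state_switch",
                                             12:16, 0.5,
                                             switchFrame = 300)))
  p <- generatePair(cfg)
  al <- iterativeAlign(p$A, p$B, p$A, "backbone")
  m <- windowedDivergence(al$A@trajectory, al$B@trajectory, W = 50)
  plateau <- mean(rowMeans(m@values[, 12:16])[
    m@windowStart >= 350 & m@windowEnd <= 600])
  before <- mean(rowMeans(m@values[, 12:16])[m@windowEnd <= 250])
  expect_gt(plateau, 1.5 * before)   # the switch lifts the signal
  cp <- detectChangePoint(m, residues = 12:16)
  expect_lte(abs(cp$frame - 300), 50)
  # unplanted residues show no step of comparable size
  cpNull <- detectChangePoint(m, residues = c(1:5, 25:30))
  expect_lt(cpNull$plateau - cpNull$baseline,
            0.5 * (cp$plateau - cp$baseline))
})

test_that("global normalization rescales jointly and keeps argmax", {
  st <- statPair(nRes = 10, nFrames = 120, seedB = 5)
  m1 <- windowedDivergence(st$A, st$B, W = 40)
  st2 <- statPair(nRes = 10, nFrames = 120, seedA = 7, seedB = 8,
                  sigma = 0.3)
  m2 <- windowedDivergence(st2$A, st2$B, W = 40)
  g <- max(max(m1@values), max(m2@values))
  nm <- normalizeMaps(list(m1, m2))
  expect_equal(max(max(nm[[1]]@values), max(nm[[2]]@values)), 1.0)
  expect_equal(nm[[1]]@values, m1@values / g)
  expect_equal(nm[[1]]@normConstant, g)
  expect_identical(which.max(nm[[1]]@values), which.max(m1@values))
  expect_identical(which.max(nm[[2]]@values), which.max(m2@values))
  # single map with known max 2.0 halves everywhere
  m3 <- m1
  m3@values <- m1@values * (2 / max(m1@values))
  n3 <- normalizeMaps(m3)
  expect_equal(max(n3@values), 1.0)
  expect_equal(n3@values, m3@values / 2)
  z <- m1; z@values[] <- 0
  expect_warning(normalizeMaps(z), "zero")
})

test_that("null-profile tails shrink as the snapshot count grows", {
  q99 <- vapply(c(100, 400, 1600), function(nf) {
    ref <- generateReferenceChain(15)
    a <- makeNoisyTraj(ref, nf, 0.1, seed = 51, label = "A")
    b <- makeNoisyTraj(ref, nf, 0.1, seed = 52, label = "B")
    unname(quantile(divergenceValues(divergenceProfile(a, b)), 0.99))
  }, numeric(1))
  expect_true(all(diff(q99) < 0))
})
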