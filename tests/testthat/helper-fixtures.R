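# fixtures are built in code at test time; nothing binary ships with the
# package

toyBeads <- function(n, name = "BB") {
  data.frame(name = name, resid = seq_len(n), resname = "ALA",
             radius = 0.26)
}

# small random-walk trajectory, nm scale
makeToyTraj <- function(nRes = 5, nFrames = 4, seed = 42,
                        label = "toy") {
  set.seed(seed)
  coords <- array(rnorm(nFrames * nRes * 3, sd = 0.3),
                  dim = c(nFrames, nRes, 3))
  Trajectory(toyBeads(nRes), coords, label = label)
}

# reference chain plus per-residue gaussian noise (sigma may vary by
# residue) and optional rigid per-frame transforms
makeNoisyTraj <- function(ref, nFrames, sigma, transforms = NULL,
                          label = "noisy", seed = 7) {
  set.seed(seed)
  R0 <- frameCoords(ref, 1)
  n <- nrow(R0)
  sig <- rep(sigma, length.out = n)
  coords <- array(0, dim = c(nFrames, n, 3))
  for (f in seq_len(nFrames)) {
    x <- R0 + rnorm(n * 3) * sig
    if (!is.null(transforms)) {
      tf <- transforms[[f]]
      x <- x %*% t(tf$R) + rep(tf$t, each = n)
    }
    coords[f, , ] <- x
  }
  Trajectory(beads(ref), coords, label = label)
}

rotZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

randomRotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) -> Q
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# ---- independent oracles -------------------------------------------------

# direct-summation KLD of Q from P: explicit loop over bins, no shortcuts
directKld <- function(p, q) {
  acc <- 0
  for (k in seq_along(p)) acc <- acc + q[k] * log(q[k] / p[k])
  acc
}

# build a ResidueDistribution by hand from raw counts on a tiny 3-D grid
makeDist <- function(counts, dims = c(length(counts), 1L, 1L),
                     pseudocount = 0.5, binWidth = 0.1,
                     origin = c(0, 0, 0), residue = 1L) {
  counts <- as.integer(counts)
  n <- sum(counts)
  K <- prod(dims)
  stopifnot(length(counts) == K)
  prob <- (counts + pseudocount) / (n + K * pseudocount)
  new("ResidueDistribution", residue = as.integer(residue),
      counts = counts, prob = prob, n = as.integer(n),
      origin = origin, dims = as.integer(dims), binWidth = binWidth,
      pseudocount = pseudocount)
}

# distribution with probabilities fixed directly (for printed examples)
makeDistProb <- function(prob, counts = NULL) {
  K <- length(prob)
  if (is.null(counts)) counts <- as.integer(round(prob * 10))
  new("ResidueDistribution", residue = 1L, counts = as.integer(counts),
      prob = prob, n = as.integer(sum(counts)),
      origin = c(0, 0, 0), dims = c(K, 1L, 1L), binWidth = 0.1,
      pseudocount = 0.5)
}

# Monte-Carlo SASA of bead 1 of a two-bead system: random surface points
# instead of the deterministic spiral the implementation uses
mcSasaTwoBeads <- function(x1, x2, r1, r2, probe, nMC = 1e5,
                           seed = 99) {
  set.seed(seed)
  R1 <- r1 + probe; R2 <- r2 + probe
  v <- matrix(rnorm(nMC * 3), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  pts <- sweep(v * R1, 2, x1, "+")
  buried <- rowSums(sweep(pts, 2, x2)^2) < R2^2
  mean(!buried) * 4 * pi * R1^2
}

# minimal CHARMM/X-PLOR-style DCD writer (coordinates in Angstrom),
# independent of the reader under test
writeDCDFixture <- function(coords, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- dim(coords)[1]; n <- dim(coords)[2]
  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(sprintf("%-80s", "synthetic fixture"), con, 80,
              eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(n), con, size = 4), 4)
  for (f in seq_len(nf)) for (k in 1:3)
    rec(function() writeBin(as.numeric(coords[f, , k]), con,
                            size = 4), 4 * n)
  invisible(path)
}

writeToyGRO <- function(path, nRes = 3) {
  i <- seq_len(nRes)
  writeLines(c("toy system",
               sprintf("%5d", nRes),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       i, "ALA", "BB", i, 0.1 * i, 0.2 * i, 0.3 * i),
               "   5.0   5.0   5.0"), path)
  invisible(path)
}

writeToyPDB <- function(path, xyzA) {
  n <- nrow(xyzA)
  lines <- sprintf(
    "ATOM  %5d  BB  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(n), seq_len(n), xyzA[, 1], xyzA[, 2], xyzA[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
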