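#' Synthetic trajectory-pair configuration
#'
#' Defines the generative model used to validate the divergence pipeline:
#' a bead-per-residue chain whose residues fluctuate as independent
#' isotropic Gaussians about a fixed reference geometry, an independent
#' rigid-body random walk per trajectory (so superposition is actually
#' exercised), and a list of planted conformational differences.
#'
#' @param nResidues chain length, >= 10 (default 100).
#' @param nFrames snapshots per trajectory, >= 10 (default 2000).
#' @param baselineSigma thermal fluctuation per residue in nm
#'   (default 0.1, a typical coarse-grained backbone-bead RMSF scale).
#' @param driftRot rotation random-walk step in radians/frame
#'   (default 0.02).
#' @param driftTrans translation random-walk step in nm/frame
#'   (default 0.01).
#' @param events list of planted \code{\link{event}}s (default none).
#' @param seed RNG seed recorded in all outputs.
#' @return A \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nResidues = 100, nFrames = 2000,
                            baselineSigma = 0.1, driftRot = 0.02,
                            driftTrans = 0.01, events = list(),
                            seed = 1) {
  new("SyntheticConfig", nResidues = as.integer(nResidues),
      nFrames = as.integer(nFrames), baselineSigma = baselineSigma,
      driftRot = driftRot, driftTrans = driftTrans, events = events,
      seed = as.integer(seed))
}

#' Describe a planted conformational event
#'
#' Three event kinds model the phenomenology the divergence analysis is
#' meant to detect:
#' \itemize{
#'   \item \code{mean_shift}: the event residues' mean positions in
#'     trajectory B are displaced by \code{magnitude} nm along a random
#'     direction for the whole trajectory (a persistently moved loop);
#'   \item \code{two_state_switch}: the displacement switches on at
#'     \code{switchFrame} (an open/closed transition);
#'   \item \code{flip_pair}: two equal-size residue groups exchange mean
#'     positions from \code{switchFrame} on (a side-chain-flip analog);
#'     \code{magnitude} in (0, 1] is the fraction of the full exchange
#'     (1 = complete swap).
#' }
#'
#' @param kind one of \code{"mean_shift"}, \code{"two_state_switch"},
#'   \code{"flip_pair"}.
#' @param residues 1-based residue indices of the event group.
#' @param magnitude displacement in nm (\code{mean_shift},
#'   \code{two_state_switch}) or exchange fraction (\code{flip_pair}).
#' @param switchFrame frame at which the change switches on (required
#'   for \code{two_state_switch} and \code{flip_pair}).
#' @param partner partner residue group for \code{flip_pair}; must have
#'   the same size as \code{residues}.
#' @param stateBOnly apply the event to trajectory B only (default);
#'   if \code{FALSE}, both trajectories get it (a planted null).
#' @return event description (list) for \code{\link{syntheticConfig}}.
#' @export
event <- function(kind = c("mean_shift", "two_state_switch", "flip_pair"),
                  residues, magnitude, switchFrame = NULL,
                  partner = NULL, stateBOnly = TRUE) {
  kind <- match.arg(kind)
  if (kind %in% c("two_state_switch", "flip_pair") &&
      is.null(switchFrame))
    stop(kind, " events need a switchFrame")
  if (kind == "flip_pair") {
    if (is.null(partner)) stop("flip_pair events need a partner group")
    if (length(partner) != length(residues))
      stop("flip_pair groups must have equal size")
    if (magnitude > 1)
      stop("flip_pair magnitude is an exchange fraction in (0, 1]")
  }
  list(kind = kind, residues = as.integer(residues),
       magnitude = magnitude,
       switchFrame = if (is.null(switchFrame)) NULL
                     else as.integer(switchFrame),
       partner = if (is.null(partner)) NULL else as.integer(partner),
       stateBOnly = isTRUE(stateBOnly))
}

#' Ideal-helix reference chain
#'
#' Lays one backbone bead per residue on an ideal helix (rise 0.15 nm,
#' radius 0.23 nm, 100 degrees per residue) so residue ranges and
#' selections have a meaningful, non-degenerate geometry. The geometry is
#' seed-independent; the seed only labels the output (dynamics draw from
#' it later).
#'
#' @param nResidues chain length, >= 10.
#' @param seed seed recorded in the label.
#' @return a single-frame \linkS4class{Trajectory}.
#' @export
generateReferenceChain <- function(nResidues, seed = 1) {
  if (nResidues < 10) stop("nResidues must be >= 10")
  i <- seq_len(nResidues)
  theta <- i * 100 * pi / 180
  xyz <- cbind(0.23 * cos(theta), 0.23 * sin(theta), 0.15 * i)
  Trajectory(data.frame(name = "BB", resid = i, resname = "ALA",
                        radius = 0.26),
             xyz, label = sprintf("ref_chain_seed%d", seed))
}

rotationMatrixAxisAngle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

randomUnitVector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# cumulative rigid-body random walk applied in place to a frames x n x 3
# array; draws consumed: per frame 3 (axis) + 1 (angle) + 3 (translation)
applyDriftWalk <- function(coords, center, rotStep, transStep) {
  nf <- dim(coords)[1]
  Rcum <- diag(3)
  Tcum <- c(0, 0, 0)
  for (f in seq_len(nf)) {
    axis <- randomUnitVector()
    ang <- stats::rnorm(1, 0, rotStep)
    Rcum <- rotationMatrixAxisAngle(axis, ang) %*% Rcum
    Tcum <- Tcum + stats::rnorm(3, 0, transStep)
    x <- coords[f, , , drop = TRUE]
    dim(x) <- dim(coords)[2:3]
    coords[f, , ] <- sweep(sweep(x, 2, center) %*% t(Rcum), 2,
                           -(center + Tcum))
  }
  coords
}

#' Generate a synthetic trajectory pair with planted differences
#'
#' Both trajectories share the same baseline statistics — independent
#' isotropic Gaussian fluctuation of each residue about the ideal-helix
#' reference — and carry independent rigid-body random walks. Planted
#' events perturb trajectory B's (or both trajectories') residue means as
#' described in \code{\link{event}}. A single RNG stream is seeded once
#' and consumed in a fixed order (baseline A, drift A, baseline B, drift
#' B, then event directions), so adding an event never changes any other
#' residue's draws.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with elements \code{A}, \code{B} (the two
#'   \linkS4class{Trajectory} objects), \code{reference} (the helix
#'   chain) and \code{groundTruth} (the events, with the drawn
#'   displacement directions attached).
#' @export
generatePair <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  n <- config@nResidues; nf <- config@nFrames
  ref <- generateReferenceChain(n, config@seed)
  R0 <- frameCoords(ref, 1)
  c0 <- colMeans(R0)

  set.seed(config@seed)
  noiseA <- array(stats::rnorm(nf * n * 3, 0, config@baselineSigma),
                  dim = c(nf, n, 3))
  coordsA <- noiseA + rep(R0, each = nf)
  coordsA <- applyDriftWalk(coordsA, c0, config@driftRot,
                            config@driftTrans)

  noiseB <- array(stats::rnorm(nf * n * 3, 0, config@baselineSigma),
                  dim = c(nf, n, 3))
  coordsB <- noiseB + rep(R0, each = nf)
  # event phase: draw directions, then displace means (noise stays put)
  truth <- vector("list", length(config@events))
  shiftsB <- shiftsA <- NULL
  for (k in seq_along(config@events)) {
    ev <- config@events[[k]]
    ev$direction <- if (ev$kind == "flip_pair") NULL else randomUnitVector()
    truth[[k]] <- ev
    frames <- if (is.null(ev$switchFrame)) seq_len(nf)
              else ev$switchFrame:nf
    if (ev$kind == "flip_pair") {
      d1 <- (R0[ev$partner, , drop = FALSE] -
             R0[ev$residues, , drop = FALSE]) * ev$magnitude
      coordsB[frames, ev$residues, ] <-
        coordsB[frames, ev$residues, , drop = FALSE] +
        rep(d1, each = length(frames))
      coordsB[frames, ev$partner, ] <-
        coordsB[frames, ev$partner, , drop = FALSE] -
        rep(d1, each = length(frames))
    } else {
      delta <- matrix(ev$direction, nrow = length(ev$residues),
                      ncol = 3, byrow = TRUE) * ev$magnitude
      coordsB[frames, ev$residues, ] <-
        coordsB[frames, ev$residues, , drop = FALSE] +
        rep(delta, each = length(frames))
      if (!ev$stateBOnly)
        coordsA[, ev$residues, ] <-
          coordsA[, ev$residues, , drop = FALSE] +
          rep(delta, each = nf)
    }
  }
  coordsB <- applyDriftWalk(coordsB, c0, config@driftRot,
                            config@driftTrans)

  mkTraj <- function(coords, which) {
    Trajectory(beads(ref), coords,
               label = sprintf("synthetic_%s_seed%d", which,
                               config@seed))
  }
  list(A = mkTraj(coordsA, "A"), B = mkTraj(coordsB, "B"),
       reference = ref, groundTruth = truth)
}

#' Synthetic gate system for SASA validation
#'
#' A single target bead surrounded by a shell of occluder beads whose
#' radial distance contracts (closing), expands (opening) or stays fixed
#' (static) linearly over the frames — a minimal analog of a loop gate
#' closing over a buried cofactor. With the default geometry the closing
#' run takes the target from fully exposed to fully buried.
#'
#' @param nFrames number of frames (default 100).
#' @param nOccluders shell beads (default 64).
#' @param rStart,rEnd shell radius at the first/last frame in nm
#'   (defaults 1.3 and 0.6; at 1.3 nm a 0.26 nm bead probed at 0.26 nm
#'   is untouched, at 0.6 nm it is sealed).
#' @param mode "closing", "opening" or "static".
#' @return a \linkS4class{Trajectory}; the target is bead 1
#'   (\code{"name TGT"}), occluders are \code{"name OCC"}. All radii are
#'   0.26 nm.
#' @export
generateGateSystem <- function(nFrames = 100, nOccluders = 64,
                               rStart = 1.3, rEnd = 0.6,
                               mode = c("closing", "opening",
                                        "static")) {
  mode <- match.arg(mode)
  if (nFrames < 2) stop("nFrames must be >= 2")
  shell <- spherePoints(nOccluders)
  radius <- switch(mode,
    closing = seq(rStart, rEnd, length.out = nFrames),
    opening = seq(rEnd, rStart, length.out = nFrames),
    static = rep(rStart, nFrames))
  coords <- array(0, dim = c(nFrames, nOccluders + 1, 3))
  for (f in seq_len(nFrames))
    coords[f, -1, ] <- shell * radius[f]
  b <- data.frame(name = c("TGT", rep("OCC", nOccluders)),
                  resid = seq_len(nOccluders + 1),
                  resname = c("TGT", rep("OCC", nOccluders)),
                  radius = 0.26)
  Trajectory(b, coords, label = sprintf("gate_%s", mode))
}
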