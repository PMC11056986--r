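#' Joint bounding box for one residue over two trajectories
#'
#' The axis-aligned box spanning the positions of the residue's bead in
#' both trajectories, padded by one bin on every side. Both trajectories
#' are histogrammed on this shared geometry so their distributions are
#' directly comparable.
#'
#' @param trajA,trajB aligned \linkS4class{Trajectory} objects.
#' @param bead bead index (1-based) of the residue's backbone bead in
#'   both trajectories.
#' @param spec a \linkS4class{BinningSpec}.
#' @param frames optional frame range to restrict the box to (defaults to
#'   all frames of each trajectory).
#' @return list with \code{origin} (nm), \code{dims} (bins per axis) and
#'   \code{binWidth}.
#' @export
jointBoundingBox <- function(trajA, trajB, bead, spec,
                             frames = NULL) {
  h <- spec@binWidth
  xa <- trajA@coords[if (is.null(frames)) TRUE else frames, bead, ,
                     drop = FALSE]
  xb <- trajB@coords[if (is.null(frames)) TRUE else frames, bead, ,
                     drop = FALSE]
  lo <- pmin(apply(xa, 3, min), apply(xb, 3, min))
  hi <- pmax(apply(xa, 3, max), apply(xb, 3, max))
  origin <- lo - h                       # one-bin pad below
  dims <- floor((hi - origin) / h) + 2L  # one-bin pad above
  list(origin = origin, dims = as.integer(dims), binWidth = h)
}

# linear (x-fastest) 1-based bin indices of one bead's positions
linearBinIndices <- function(traj, bead, frames, box) {
  h <- box$binWidth
  ix <- floor((traj@coords[frames, bead, 1] - box$origin[1]) / h)
  iy <- floor((traj@coords[frames, bead, 2] - box$origin[2]) / h)
  iz <- floor((traj@coords[frames, bead, 3] - box$origin[3]) / h)
  ix <- pmin(pmax(ix, 0), box$dims[1] - 1)
  iy <- pmin(pmax(iy, 0), box$dims[2] - 1)
  iz <- pmin(pmax(iz, 0), box$dims[3] - 1)
  as.integer(ix + box$dims[1] * (iy + box$dims[2] * iz) + 1)
}

#' Discretized positional distribution of one residue
#'
#' Histograms the residue's backbone-bead positions over a frame range on
#' the supplied joint-box geometry, then adds the pseudocount to every
#' bin and normalizes to probabilities.
#'
#' @param traj an aligned \linkS4class{Trajectory}.
#' @param residue 1-based residue index; its \code{BB} bead is used (or
#'   the residue's single bead if it has exactly one).
#' @param frames integer frame indices to histogram.
#' @param spec a \linkS4class{BinningSpec}.
#' @param box joint box from \code{\link{jointBoundingBox}} (must cover
#'   both trajectories being compared).
#' @return A \linkS4class{ResidueDistribution}.
#' @export
buildDistribution <- function(traj, residue, frames, spec, box) {
  stopifnot(is(traj, "Trajectory"), is(spec, "BinningSpec"))
  if (!length(frames)) stop("empty window: no frames to histogram")
  bead <- residueBackboneBead(traj, residue)
  K <- prod(box$dims)
  lin <- linearBinIndices(traj, bead, frames, box)
  counts <- tabulate(lin, nbins = K)
  n <- length(frames)
  prob <- (counts + spec@pseudocount) / (n + K * spec@pseudocount)
  new("ResidueDistribution", residue = as.integer(residue),
      counts = as.integer(counts), prob = prob, n = as.integer(n),
      origin = box$origin, dims = box$dims, binWidth = box$binWidth,
      pseudocount = spec@pseudocount)
}

residueBackboneBead <- function(traj, residue) {
  b <- beads(traj)
  hit <- which(b$resid == residue & b$name == "BB")
  if (!length(hit)) hit <- which(b$resid == residue)
  if (!length(hit)) stop("no bead found for residue ", residue)
  if (length(hit) > 1)
    stop("residue ", residue, " has ", length(hit),
         " candidate beads and no BB bead")
  hit
}

checkSameGeometry <- function(P, Q) {
  if (!isTRUE(all.equal(P@origin, Q@origin, tolerance = 1e-12)) ||
      !identical(P@dims, Q@dims) ||
      P@binWidth != Q@binWidth)
    stop("bin geometry mismatch: distributions were built on ",
         "different boxes")
  invisible(TRUE)
}

#' Kullback-Leibler divergence between two residue distributions
#'
#' \code{kld(P, Q)} is the divergence of Q from P,
#' \eqn{\sum_k q_k \ln(q_k / p_k)}, over the shared bin geometry; the
#' pseudocount keeps it finite. \code{symmetrizedKld} averages the two
#' directions, \eqn{\frac{1}{2}[KLD(P,Q) + KLD(Q,P)]}, giving a measure
#' symmetric in its arguments.
#'
#' @param P,Q \linkS4class{ResidueDistribution} objects on identical bin
#'   geometry.
#' @param base "nats" (natural log, default) or "bits".
#' @return divergence (nonnegative scalar).
#' @export
kld <- function(P, Q, base = c("nats", "bits")) {
  base <- match.arg(base)
  checkSameGeometry(P, Q)
  v <- sum(Q@prob * log(Q@prob / P@prob))
  max(v, 0) * logBaseFactor(base)
}

#' @rdname kld
#' @export
symmetrizedKld <- function(P, Q, base = c("nats", "bits")) {
  base <- match.arg(base)
  0.5 * (kld(P, Q, base) + kld(Q, P, base))
}

logBaseFactor <- function(base) if (base == "bits") 1 / log(2) else 1

# shared precomputation for profile / windowed map: per selected bead,
# linear bin indices of both trajectories on the joint box over the first
# N paired snapshots
pairBins <- function(trajA, trajB, sel, spec) {
  selA <- if (is.character(sel)) resolveSelection(trajA, sel) else sel
  selB <- if (is.character(sel)) resolveSelection(trajB, sel) else sel
  idxA <- selIndices(selA); idxB <- selIndices(selB)
  if (length(idxA) != length(idxB))
    stop("selection resolves to ", length(idxA), " beads on '",
         trajLabel(trajA), "' but ", length(idxB), " on '",
         trajLabel(trajB), "'")
  nA <- nFrames(trajA); nB <- nFrames(trajB)
  N <- min(nA, nB)
  if (nA != nB)
    warning("frame counts differ (", nA, " vs ", nB,
            "); truncating both to ", N, " snapshots")
  frames <- seq_len(N)
  res <- lapply(seq_along(idxA), function(j) {
    box <- jointBoundingBoxPair(trajA, trajB, idxA[j], idxB[j], spec,
                                frames)
    list(binsA = linearBinIndices(trajA, idxA[j], frames, box),
         binsB = linearBinIndices(trajB, idxB[j], frames, box),
         K = prod(box$dims))
  })
  list(perBead = res, N = N,
       residues = as.integer(beads(trajA)$resid[idxA]))
}

# joint box when the bead sits at different indices in the two bead tables
jointBoundingBoxPair <- function(trajA, trajB, beadA, beadB, spec,
                                 frames) {
  h <- spec@binWidth
  xa <- trajA@coords[frames, beadA, , drop = FALSE]
  xb <- trajB@coords[frames, beadB, , drop = FALSE]
  lo <- pmin(apply(xa, 3, min), apply(xb, 3, min))
  hi <- pmax(apply(xa, 3, max), apply(xb, 3, max))
  origin <- lo - h
  dims <- floor((hi - origin) / h) + 2L
  list(origin = origin, dims = as.integer(dims), binWidth = h)
}

#' Per-residue symmetrized divergence profile between two trajectories
#'
#' For every selected residue, the positions of its backbone bead in the
#' two (aligned) trajectories are histogrammed on the residue's joint
#' bounding box and the symmetrized Kullback-Leibler divergence is
#' computed over the full paired frame sets. High profile values flag
#' residues whose positional distributions differ between the two
#' simulations; a residue that is mobile in both but moves the same way
#' scores low.
#'
#' @param trajA,trajB \linkS4class{Trajectory} objects aligned to a
#'   common reference; unequal frame counts are truncated to the shorter
#'   with a warning.
#' @param sel a \linkS4class{Selection} or expression picking one bead
#'   per residue (typically \code{"backbone"}).
#' @param spec a \linkS4class{BinningSpec}.
#' @return A \linkS4class{DivergenceProfile}.
#' @export
divergenceProfile <- function(trajA, trajB, sel = "backbone",
                              spec = binningSpec()) {
  pb <- pairBins(trajA, trajB, sel, spec)
  vals <- vapply(pb$perBead, function(pbj) {
    windowed_skld_cpp(pbj$binsA, pbj$binsB, pbj$K, spec@pseudocount,
                      1L, pb$N)
  }, numeric(1))
  vals <- pmax(vals, 0) * logBaseFactor(spec@base)
  new("DivergenceProfile", residues = pb$residues, values = vals,
      labels = c(trajLabel(trajA), trajLabel(trajB)),
      base = spec@base, symmetrization = "mean")
}

#' Time-resolved windowed divergence map
#'
#' Computes the symmetrized per-residue divergence in a moving window of
#' at most \code{W} snapshots: window \code{w} covers snapshots
#' \code{max(1, w-W+1)..min(w, N)}. The window grows from a single
#' snapshot to \code{W}, slides along the trajectory, and shrinks from
#' the left once the trajectory end is reached (down to a single
#' snapshot), so the map has \code{N + W - 1} rows. For example, with
#' \code{W = 50} window 49 covers snapshots 1-49, window 50 covers 1-50
#' and window 51 covers 2-51. All windows of one residue share the joint
#' bounding box computed over the full paired frame sets, so a window
#' covering all snapshots reproduces \code{\link{divergenceProfile}}
#' exactly.
#'
#' @inheritParams divergenceProfile
#' @param W maximum window size in snapshots (default 50); must be >= 2.
#' @return A \linkS4class{WindowedDivergenceMap} (unnormalized; see
#'   \code{\link{normalizeMaps}}).
#' @export
windowedDivergence <- function(trajA, trajB, sel = "backbone",
                               spec = binningSpec(), W = 50) {
  if (W < 2) stop("window size W must be >= 2")
  pb <- pairBins(trajA, trajB, sel, spec)
  N <- pb$N
  w <- seq_len(N + W - 1)
  starts <- pmax(1L, as.integer(w - W + 1L))
  ends <- pmin(as.integer(w), as.integer(N))
  vals <- vapply(pb$perBead, function(pbj) {
    windowed_skld_cpp(pbj$binsA, pbj$binsB, pbj$K, spec@pseudocount,
                      starts, ends)
  }, numeric(length(w)))
  vals <- pmax(vals, 0) * logBaseFactor(spec@base)
  new("WindowedDivergenceMap", values = vals, residues = pb$residues,
      windowStart = starts, windowEnd = ends, W = as.integer(W),
      labels = c(trajLabel(trajA), trajLabel(trajB)),
      base = spec@base, normConstant = NA_real_)
}

#' Locate a conformational change point in a windowed divergence map
#'
#' Detects when a region's divergence signal steps from its baseline to a
#' plateau. The per-window signal is the mean divergence over the chosen
#' residues; the detection threshold is the midpoint between a baseline
#' estimate (lower quantile of the signal) and a plateau estimate (upper
#' quantile), and the change point is the first window from which the
#' signal stays above threshold for \code{persistence} consecutive
#' windows. The midpoint rule reduces to "half the plateau" when the
#' baseline vanishes, but stays meaningful at finite window sizes, where
#' the small-sample bias of the histogram KLD estimator puts the baseline
#' well above zero (see the methods vignette).
#'
#' @param map a \linkS4class{WindowedDivergenceMap}.
#' @param residues residue indices to average over (default: all).
#' @param persistence consecutive windows required above threshold
#'   (default 5), guarding against single-window noise spikes.
#' @param baselineQ,plateauQ signal quantiles estimating the baseline
#'   and plateau levels (defaults 0.25 and 0.9).
#' @return list with \code{frame} (right-edge snapshot of the detected
#'   window, \code{NA} if no crossing), \code{window}, \code{threshold},
#'   \code{baseline}, \code{plateau} and the per-window \code{signal}.
#' @export
detectChangePoint <- function(map, residues = NULL, persistence = 5,
                              baselineQ = 0.25, plateauQ = 0.9) {
  stopifnot(is(map, "WindowedDivergenceMap"))
  cols <- if (is.null(residues)) seq_along(map@residues)
          else match(residues, map@residues)
  if (anyNA(cols)) stop("residues not present in the map")
  sig <- rowMeans(map@values[, cols, drop = FALSE])
  baseline <- unname(stats::quantile(sig, baselineQ))
  plateau <- unname(stats::quantile(sig, plateauQ))
  thr <- 0.5 * (baseline + plateau)
  runs <- rle(sig >= thr)
  pos <- cumsum(runs$lengths) - runs$lengths + 1
  hit <- which(runs$values & runs$lengths >= persistence)[1]
  list(frame = if (is.na(hit)) NA_integer_
               else map@windowEnd[pos[hit]],
       window = if (is.na(hit)) NA_integer_ else pos[hit],
       threshold = thr, baseline = baseline, plateau = plateau,
       signal = sig)
}

#' Globally normalize a set of windowed divergence maps
#'
#' Divides every map by the single largest value found across all of
#' them, so 1.0 marks the largest overall difference in the whole
#' comparison set and 0.0 no difference; relative magnitudes between maps
#' are preserved. If every map is identically zero the maps are returned
#' unchanged with a warning.
#'
#' @param maps a list of \linkS4class{WindowedDivergenceMap} objects (a
#'   single map is accepted and returned as a single map).
#' @return the normalized maps, each with \code{normConstant} set.
#' @export
normalizeMaps <- function(maps) {
  single <- is(maps, "WindowedDivergenceMap")
  if (single) maps <- list(maps)
  stopifnot(all(vapply(maps, is, logical(1), "WindowedDivergenceMap")))
  gmax <- max(vapply(maps, function(m) max(m@values), numeric(1)))
  if (gmax == 0) {
    warning("all maps are zero; nothing to normalize")
    return(if (single) maps[[1]] else maps)
  }
  out <- lapply(maps, function(m) {
    m@values <- m@values / gmax
    m@normConstant <- gmax
    m
  })
  if (single) out[[1]] else out
}
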