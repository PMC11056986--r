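#' Weighted Kabsch superposition
#'
#' Finds the proper rotation and translation minimizing the weighted sum
#' of squared deviations between a mobile point set and a reference, via
#' SVD of the weighted cross-covariance with the usual sign correction so
#' reflections are never returned.
#'
#' @param mobile n x 3 matrix (nm).
#' @param reference n x 3 matrix (nm).
#' @param weights nonnegative per-point weights with positive sum;
#'   uniform when \code{NULL}.
#' @return A \linkS4class{RigidTransform} mapping \code{mobile} onto
#'   \code{reference} as \code{x' = R x + t}.
#' @export
kabschSuperpose <- function(mobile, reference, weights = NULL) {
  k <- kabschCore(as.matrix(mobile), as.matrix(reference), weights)
  new("RigidTransform", rotation = k$R, translation = k$t)
}

# fast path shared with frame loops: plain list, no S4 validity overhead
kabschCore <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  if (nrow(reference) != n)
    stop("point counts differ: ", n, " vs ", nrow(reference))
  if (n < 3) stop("degenerate superposition: fewer than 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length must equal point count")
  if (any(weights < 0)) stop("weights must be nonnegative")
  sw <- sum(weights)
  if (sw <= 0) stop("weights must have positive sum")
  w <- weights / sw

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  Xm <- mobile - rep(cm, each = n)
  Xr <- reference - rep(cr, each = n)
  H <- crossprod(Xm * w, Xr)   # 3x3 weighted cross-covariance
  sv <- svd(H)
  # a rotation is pinned only if the spread has two independent
  # directions; collinear (or coincident) point sets leave H rank <= 1
  if (sv$d[2] <= max(sv$d[1] * 1e-10, 1e-300))
    stop("degenerate superposition: points are collinear")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cr - R %*% cm))
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix or frames x beads x 3 array.
#' @param transform a \linkS4class{RigidTransform}.
#' @return transformed coordinates, same shape.
#' @export
applyTransform <- function(coords, transform) {
  stopifnot(is(transform, "RigidTransform"))
  R <- transform@rotation; tvec <- transform@translation
  if (is.matrix(coords))
    return(sweep(coords %*% t(R), 2, -tvec))
  d <- dim(coords)
  flat <- matrix(coords, nrow = d[1] * d[2], ncol = 3)
  out <- sweep(flat %*% t(R), 2, -tvec)
  array(out, dim = d)
}

#' Rotation angle of a 3x3 rotation matrix
#' @param R rotation matrix.
#' @return angle in radians in [0, pi].
#' @export
rotationAngle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' Each frame is superposed on \code{refFrame} by weighted Kabsch over the
#' selected beads; non-selected beads are carried along by the same rigid
#' transform, so internal geometry is untouched.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param refFrame beads x 3 reference coordinates (nm) covering the same
#'   bead model, or a matrix restricted to the selection.
#' @param sel a \linkS4class{Selection} (or selection expression).
#' @param weights optional per-selected-bead weights.
#' @param returnTransforms also return the per-frame transforms.
#' @return The aligned \linkS4class{Trajectory}; with
#'   \code{returnTransforms}, a list with elements \code{trajectory} and
#'   \code{transforms}.
#' @export
alignToReference <- function(traj, refFrame, sel, weights = NULL,
                             returnTransforms = FALSE) {
  stopifnot(is(traj, "Trajectory"))
  if (is.character(sel)) sel <- resolveSelection(traj, sel)
  idx <- selIndices(sel)
  if (any(idx > nBeads(traj)))
    stop("selection indices exceed bead count")
  refSel <- if (nrow(refFrame) == nBeads(traj)) refFrame[idx, , drop = FALSE]
            else refFrame
  if (nrow(refSel) != length(idx))
    stop("reference frame does not cover the selection")
  core <- alignFramesCore(traj, refSel, idx, weights)
  aligned <- Trajectory(beads(traj), core$coords,
                        label = trajLabel(traj), times = traj@times)
  if (returnTransforms)
    list(trajectory = aligned,
         transforms = mapply(function(R, t)
           new("RigidTransform", rotation = R, translation = t),
           core$rotations, core$translations, SIMPLIFY = FALSE),
         rotations = core$rotations)
  else aligned
}

alignFramesCore <- function(traj, refSel, idx, weights) {
  out <- traj@coords
  nf <- dim(out)[1]; nb <- dim(out)[2]; ns <- length(idx)
  rotations <- vector("list", nf)
  translations <- vector("list", nf)
  for (f in seq_len(nf)) {
    mob <- out[f, idx, ]
    dim(mob) <- c(ns, 3)
    k <- tryCatch(kabschCore(mob, refSel, weights),
                  error = function(e)
                    stop("alignment failed at frame ", f, ": ",
                         conditionMessage(e)))
    fc <- out[f, , ]
    dim(fc) <- c(nb, 3)
    out[f, , ] <- fc %*% t(k$R) + rep(k$t, each = nb)
    rotations[[f]] <- k$R
    translations[[f]] <- k$t
  }
  list(coords = out, rotations = rotations,
       translations = translations)
}

#' Iterative variance-reweighted pairwise alignment
#'
#' Aligns two trajectories onto the first frame of a reference trajectory
#' the way divergence comparison requires: (1) uniform-weight
#' superposition of every frame over the selection, (2) per-selected-bead
#' positional variance pooled over both aligned trajectories,
#' (3) reweighting with \code{w_i = 1/(variance_i + eps)} (scaled to
#' max 1) so mobile residues stop steering the fit, (4) realignment.
#' Iteration stops when the mean per-frame rotation change drops below
#' \code{tol} radians or after \code{maxIter} iterations; running out of
#' iterations is flagged, not an error.
#'
#' @param trajA,trajB the two \linkS4class{Trajectory} objects to compare.
#' @param ref reference \linkS4class{Trajectory}; its first frame is the
#'   superposition target.
#' @param sel a \linkS4class{Selection} or expression, resolvable on all
#'   three trajectories (residue correspondence is by index).
#' @param maxIter iteration cap (default 10).
#' @param tol convergence tolerance on the mean frame-rotation angle
#'   change, radians (default 1e-3).
#' @param eps variance regularizer in nm^2 (default 1e-4), bounding the
#'   weight contrast on near-rigid beads.
#' @return list with elements \code{A} and \code{B}, each an
#'   \linkS4class{AlignmentResult} (shared weights and convergence
#'   diagnostics).
#' @export
iterativeAlign <- function(trajA, trajB, ref, sel, maxIter = 10,
                           tol = 1e-3, eps = 1e-4) {
  stopifnot(is(trajA, "Trajectory"), is(trajB, "Trajectory"),
            is(ref, "Trajectory"))
  nResA <- length(unique(beads(trajA)$resid))
  nResB <- length(unique(beads(trajB)$resid))
  if (nResA != nResB)
    stop("residue counts differ: ", nResA, " vs ", nResB)
  if (maxIter < 1) stop("maxIter must be >= 1")
  selA <- if (is.character(sel)) resolveSelection(trajA, sel) else sel
  selB <- if (is.character(sel)) resolveSelection(trajB, sel) else sel
  if (length(selIndices(selA)) != length(selIndices(selB)))
    stop("selection resolves to different bead counts on the two ",
         "trajectories")
  refFrame <- frameCoords(ref, 1)
  refSel <- if (is.character(sel)) resolveSelection(ref, sel) else sel
  refPts <- refFrame[selIndices(refSel), , drop = FALSE]

  nsel <- length(selIndices(selA))
  weights <- rep(1, nsel)
  history <- list()
  prevRot <- NULL
  converged <- FALSE
  iter <- 0
  alignedA <- trajA; alignedB <- trajB
  repeat {
    iter <- iter + 1
    history[[iter]] <- weights
    ra <- alignFramesCore(trajA, refPts, selIndices(selA), weights)
    rb <- alignFramesCore(trajB, refPts, selIndices(selB), weights)
    alignedA <- Trajectory(beads(trajA), ra$coords,
                           label = trajLabel(trajA),
                           times = trajA@times)
    alignedB <- Trajectory(beads(trajB), rb$coords,
                           label = trajLabel(trajB),
                           times = trajB@times)
    rots <- c(ra$rotations, rb$rotations)
    if (!is.null(prevRot)) {
      dAng <- mapply(function(Rn, Ro)
        rotationAngle(Rn %*% t(Ro)), rots, prevRot)
      if (mean(dAng) < tol) { converged <- TRUE; break }
    }
    prevRot <- rots
    if (iter >= maxIter) break
    weights <- reweightByVariance(alignedA, alignedB, selA, selB, eps)
  }
  if (!converged && maxIter > 1)
    warning("iterative alignment did not converge in ", maxIter,
            " iterations")
  if (maxIter == 1) converged <- TRUE  # single pass: nothing to iterate
  mk <- function(tr) new("AlignmentResult", trajectory = tr,
                         weights = weights, weightHistory = history,
                         iterations = as.integer(iter),
                         converged = converged)
  list(A = mk(alignedA), B = mk(alignedB))
}

# per-selected-bead positional variance (trace of covariance), pooled
# over both aligned trajectories, mapped to weights 1/(var+eps), max 1
reweightByVariance <- function(alignedA, alignedB, selA, selB, eps) {
  va <- beadVariances(alignedA, selIndices(selA))
  vb <- beadVariances(alignedB, selIndices(selB))
  nA <- nFrames(alignedA); nB <- nFrames(alignedB)
  pooled <- (va * nA + vb * nB) / (nA + nB)
  w <- 1 / (pooled + eps)
  w / max(w)
}

beadVariances <- function(traj, idx) {
  x <- traj@coords[, idx, , drop = FALSE]
  mu <- colMeans(x)                          # beads x 3 mean positions
  dev2 <- sweep(x, c(2, 3), mu)^2
  apply(dev2, 2, sum) / dim(x)[1]            # E|x - mu|^2 per bead
}
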