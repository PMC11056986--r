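#' Per-frame RMSD of a selection from a reference frame
#'
#' Root-mean-square deviation of the selected beads from the reference
#' coordinates, frame by frame, with no further superposition — so a
#' region series computed on a globally aligned trajectory reports how
#' the region moves relative to the rest of the protein. Values are
#' reported in Angstrom.
#'
#' @param traj an (already aligned) \linkS4class{Trajectory}.
#' @param refFrame beads x 3 reference coordinates in nm (full bead
#'   model or restricted to the selection).
#' @param sel a \linkS4class{Selection} or selection expression.
#' @param reference label recorded in the result.
#' @return An \linkS4class{RmsdSeries} in Angstrom.
#' @export
rmsdSeries <- function(traj, refFrame, sel, reference = "reference") {
  stopifnot(is(traj, "Trajectory"))
  if (is.character(sel)) sel <- resolveSelection(traj, sel)
  idx <- selIndices(sel)
  ref <- if (nrow(refFrame) == nBeads(traj)) refFrame[idx, , drop = FALSE]
         else refFrame
  if (nrow(ref) != length(idx))
    stop("reference frame does not cover the selection")
  x <- traj@coords[, idx, , drop = FALSE]
  dev2 <- sweep(x, c(2, 3), ref)^2
  vals <- sqrt(apply(dev2, 1, sum) / length(idx)) * ANGSTROM_PER_NM
  new("RmsdSeries", values = vals, selection = sel@spec,
      reference = reference)
}

#' Center of mass of a bead group in one frame
#'
#' @param frame beads x 3 coordinate matrix in nm.
#' @param group a \linkS4class{Selection} or integer bead indices.
#' @param masses optional per-bead masses for the whole frame (uniform
#'   when \code{NULL}; coarse-grained bead masses are rarely needed).
#' @return length-3 position in nm.
#' @export
centerOfMass <- function(frame, group, masses = NULL) {
  idx <- if (is(group, "Selection")) selIndices(group) else as.integer(group)
  if (!length(idx)) stop("empty group")
  m <- if (is.null(masses)) rep(1, length(idx)) else masses[idx]
  tm <- sum(m)
  if (tm <= 0) stop("zero total mass")
  colSums(frame[idx, , drop = FALSE] * m) / tm
}

#' Per-frame center-of-mass distance between two bead groups
#'
#' The Euclidean distance between the centers of mass of two groups —
#' e.g. the flavin cofactor (beads FLA1-FLA5) and one tryptophan of the
#' electron-transfer tetrad — evaluated for every frame. Distances are
#' reported in Angstrom; \code{summary} on the result gives the min, max
#' and mean that distance-distribution plots are built from.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param groupA,groupB \linkS4class{Selection}s or expressions (e.g.
#'   \code{"name FLA1 FLA2 FLA3 FLA4 FLA5"}, \code{"resid 369"}).
#' @param masses optional per-bead masses (uniform by default).
#' @return A \linkS4class{DistanceSeries} in Angstrom.
#' @export
distanceSeries <- function(traj, groupA, groupB, masses = NULL) {
  stopifnot(is(traj, "Trajectory"))
  if (is.character(groupA)) groupA <- resolveSelection(traj, groupA)
  if (is.character(groupB)) groupB <- resolveSelection(traj, groupB)
  ia <- selIndices(groupA); ib <- selIndices(groupB)
  ma <- if (is.null(masses)) rep(1, length(ia)) else masses[ia]
  mb <- if (is.null(masses)) rep(1, length(ib)) else masses[ib]
  if (sum(ma) <= 0 || sum(mb) <= 0) stop("zero total mass")
  wa <- ma / sum(ma); wb <- mb / sum(mb)
  xa <- traj@coords[, ia, , drop = FALSE]
  xb <- traj@coords[, ib, , drop = FALSE]
  comA <- apply(sweep(xa, 2, wa, "*"), c(1, 3), sum)
  comB <- apply(sweep(xb, 2, wb, "*"), c(1, 3), sum)
  d <- sqrt(rowSums((comA - comB)^2)) * ANGSTROM_PER_NM
  new("DistanceSeries", values = d, groupA = groupA@spec,
      groupB = groupB@spec)
}

#' @describeIn distanceSeries min/max/mean summary of a distance series
#'   (Angstrom).
#' @param object a \linkS4class{DistanceSeries}.
#' @param ... ignored.
#' @export
setMethod("summary", "DistanceSeries", function(object, ...) {
  c(min = min(object@values), max = max(object@values),
    mean = mean(object@values))
})

# deterministic generalized-spiral (Fibonacci) point set on the unit
# sphere; nearly uniform, reproducible
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Rolls a probe sphere over the inflated bead surfaces: for each target
#' bead, a deterministic spiral point set is placed on the sphere of
#' radius \code{r_i + probe} and the fraction of points not buried inside
#' any other inflated bead is converted to area. Context beads occlude
#' but contribute no area. The default probe of 0.26 nm corresponds to a
#' regular Martini coarse-grained bead, the convention for coarse-grained
#' flavin-pocket accessibility.
#'
#' @param traj a \linkS4class{Trajectory} (all frames are evaluated).
#' @param target \linkS4class{Selection} or expression: beads whose area
#'   is summed.
#' @param context \linkS4class{Selection} or expression: additional
#'   occluding beads (default \code{"all"}).
#' @param probe probe radius in nm (default 0.26).
#' @param nPoints quadrature points per bead (default 960).
#' @param radii optional per-bead radii in nm overriding the bead table;
#'   beads with no radius anywhere default to 0.26 nm (regular Martini
#'   bead).
#' @return A \linkS4class{SasaResult} with per-frame totals in nm^2.
#' @export
sasa <- function(traj, target, context = "all", probe = 0.26,
                 nPoints = 960, radii = NULL) {
  stopifnot(is(traj, "Trajectory"))
  if (is.character(target)) target <- resolveSelection(traj, target)
  if (is.character(context)) context <- resolveSelection(traj, context)
  it <- selIndices(target)
  involved <- union(it, selIndices(context))
  r <- beadRadii(traj, radii, involved)
  pts <- spherePoints(nPoints)
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    sasaFrame(frameCoords(traj, f), r, it, involved, probe, pts)
  }, numeric(1))
  new("SasaResult", values = vals, probe = probe,
      nPoints = as.integer(nPoints), target = target@spec)
}

beadRadii <- function(traj, radii, involved) {
  r <- beads(traj)$radius
  if (!is.null(radii)) {
    if (length(radii) == 1) r[] <- radii
    else if (length(radii) == nBeads(traj)) r <- radii
    else stop("radii must be length 1 or one per bead")
  }
  if (anyNA(r[involved])) r[involved][is.na(r[involved])] <- 0.26
  if (anyNA(r[involved]) || any(r[involved] <= 0)) {
    bad <- involved[is.na(r[involved]) | r[involved] <= 0][1]
    stop("no valid radius for bead ", bad, " ('",
         beads(traj)$name[bad], "')")
  }
  r
}

sasaFrame <- function(x, r, targetIdx, involved, probe, pts) {
  inflated <- r + probe
  total <- 0
  for (i in targetIdx) {
    Ri <- inflated[i]
    surf <- sweep(pts * Ri, 2, x[i, ], "+")
    occluders <- setdiff(involved, i)
    # only beads whose inflated spheres can reach this surface matter
    if (length(occluders)) {
      d2 <- rowSums(sweep(x[occluders, , drop = FALSE], 2, x[i, ])^2)
      occluders <- occluders[d2 < (Ri + inflated[occluders])^2]
    }
    buried <- rep(FALSE, nrow(surf))
    for (j in occluders) {
      if (all(buried)) break
      dj2 <- rowSums(sweep(surf, 2, x[j, ])^2)
      buried <- buried | dj2 < inflated[j]^2
    }
    total <- total + mean(!buried) * 4 * pi * Ri^2
  }
  total
}
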