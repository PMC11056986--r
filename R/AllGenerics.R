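#' Number of frames in a trajectory
#' @param x a \linkS4class{Trajectory}.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' Number of beads in a trajectory
#' @param x a \linkS4class{Trajectory}.
#' @return integer bead count.
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))

#' @rdname nBeads
#' @export
setMethod("nBeads", "Trajectory", function(x) dim(x@coords)[2])

#' Bead metadata table
#' @param x a \linkS4class{Trajectory}.
#' @return data.frame with columns name, resid, resname, radius.
#' @export
setGeneric("beads", function(x) standardGeneric("beads"))

#' @rdname beads
#' @export
setMethod("beads", "Trajectory", function(x) x@beads)

#' Coordinate array (frames x beads x 3, nm)
#' @param x a \linkS4class{Trajectory}.
#' @return numeric array.
#' @export
setGeneric("trajCoords", function(x) standardGeneric("trajCoords"))

#' @rdname trajCoords
#' @export
setMethod("trajCoords", "Trajectory", function(x) x@coords)

#' Trajectory label
#' @param x a \linkS4class{Trajectory}.
#' @return character label.
#' @export
setGeneric("trajLabel", function(x) standardGeneric("trajLabel"))

#' @rdname trajLabel
#' @export
setMethod("trajLabel", "Trajectory", function(x) x@label)

#' Coordinates of one frame
#' @param x a \linkS4class{Trajectory}.
#' @param i frame index (1-based).
#' @return beads x 3 matrix in nm.
#' @export
frameCoords <- function(x, i) {
  stopifnot(is(x, "Trajectory"))
  if (i < 1 || i > nFrames(x))
    stop("frame index ", i, " out of range 1..", nFrames(x))
  m <- x@coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

#' Resolved bead indices of a selection
#' @param x a \linkS4class{Selection}.
#' @return integer vector of 1-based bead indices.
#' @export
setGeneric("selIndices", function(x) standardGeneric("selIndices"))

#' @rdname selIndices
#' @export
setMethod("selIndices", "Selection", function(x) x@indices)

#' Region map of a RegionSet
#' @param x a \linkS4class{RegionSet}.
#' @return named list of residue index vectors.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname regions
#' @export
setMethod("regions", "RegionSet", function(x) x@regions)

#' Divergence values of a profile or windowed map
#' @param x a \linkS4class{DivergenceProfile} or
#'   \linkS4class{WindowedDivergenceMap}.
#' @return numeric vector (profile) or windows x residues matrix (map).
#' @export
setGeneric("divergenceValues", function(x) standardGeneric("divergenceValues"))

#' @rdname divergenceValues
#' @export
setMethod("divergenceValues", "DivergenceProfile", function(x) {
  stats::setNames(x@values, x@residues)
})

#' @rdname divergenceValues
#' @export
setMethod("divergenceValues", "WindowedDivergenceMap", function(x) x@values)

#' Residue axis of a divergence result
#' @param x a \linkS4class{DivergenceProfile} or
#'   \linkS4class{WindowedDivergenceMap}.
#' @return integer residue indices.
#' @export
setGeneric("profileResidues", function(x) standardGeneric("profileResidues"))

#' @rdname profileResidues
#' @export
setMethod("profileResidues", "DivergenceProfile", function(x) x@residues)

#' @rdname profileResidues
#' @export
setMethod("profileResidues", "WindowedDivergenceMap", function(x) x@residues)

#' Window snapshot ranges of a windowed map
#' @param x a \linkS4class{WindowedDivergenceMap}.
#' @return data.frame with columns window, start, end.
#' @export
windowRanges <- function(x) {
  stopifnot(is(x, "WindowedDivergenceMap"))
  data.frame(window = seq_along(x@windowStart),
             start = x@windowStart, end = x@windowEnd)
}

#' Per-frame values of a series result
#' @param x an \linkS4class{RmsdSeries}, \linkS4class{DistanceSeries} or
#'   \linkS4class{SasaResult}.
#' @return numeric vector, one value per frame.
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname seriesValues
#' @export
setMethod("seriesValues", "RmsdSeries", function(x) x@values)

#' @rdname seriesValues
#' @export
setMethod("seriesValues", "DistanceSeries", function(x) x@values)

#' @rdname seriesValues
#' @export
setMethod("seriesValues", "SasaResult", function(x) x@values)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory '%s': %d frames, %d beads (%d residues)\n",
              object@label, nFrames(object), nBeads(object),
              length(unique(object@beads$resid))))
})

setMethod("show", "Selection", function(object) {
  cat(sprintf("Selection '%s': %d beads\n", object@spec,
              length(object@indices)))
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet:\n")
  for (nm in names(object@regions)) {
    v <- object@regions[[nm]]
    cat(sprintf("  %-4s %d residues (%d..%d)\n", nm, length(v),
                min(v), max(v)))
  }
})

setMethod("show", "DivergenceProfile", function(object) {
  cat(sprintf("DivergenceProfile [%s vs %s], %d residues, %s\n",
              object@labels[1], object@labels[2],
              length(object@residues), object@base))
  cat(sprintf("  max %.4g at residue %d\n", max(object@values),
              object@residues[which.max(object@values)]))
})

setMethod("show", "WindowedDivergenceMap", function(object) {
  norm <- if (is.na(object@normConstant)) "unnormalized"
          else sprintf("normalized by %.6g", object@normConstant)
  cat(sprintf(
    "WindowedDivergenceMap [%s vs %s], %d windows x %d residues (W=%d), %s\n",
    object@labels[1], object@labels[2], nrow(object@values),
    ncol(object@values), object@W, norm))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object@rotation)
  cat(sprintf("RigidTransform: rotation %.4g rad, translation (%s) nm\n",
              ang, paste(sprintf("%.4g", object@translation),
                         collapse = ", ")))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    "AlignmentResult: %d iterations, %s; weights in [%.3g, %.3g]\n",
    object@iterations,
    if (object@converged) "converged" else "not converged",
    min(object@weights), max(object@weights)))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d residues x %d frames, sigma=%.3g nm, %d event(s), seed=%d\n",
    object@nResidues, object@nFrames, object@baselineSigma,
    length(object@events), object@seed))
})
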