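#' @import methods
NULL

#' Trajectory: coordinates of a bead model over time
#'
#' Central container of the package: an ordered set of beads (one or more
#' per residue of a coarse-grained protein model) and a stack of frames
#' holding their Cartesian coordinates. All coordinates are stored in
#' nanometres; readers convert Angstrom-based formats (PDB, DCD) at the
#' boundary.
#'
#' @slot beads data.frame with one row per bead and columns \code{name}
#'   (bead name, e.g. \code{"BB"}, \code{"FLA1"}), \code{resid} (1-based
#'   residue index), \code{resname} (residue name) and \code{radius}
#'   (bead radius in nm, \code{NA} when unknown; used only by
#'   \code{\link{sasa}}).
#' @slot coords numeric array of dimension frames x beads x 3, in nm.
#' @slot times numeric vector of frame times in microseconds, or empty.
#' @slot label character label identifying the simulation.
#'
#' @seealso \code{\link{readStructure}}, \code{\link{readTrajectory}},
#'   \code{\link{resolveSelection}}
#' @export
setClass("Trajectory",
  slots = c(beads = "data.frame", coords = "array",
            times = "numeric", label = "character"))

setValidity("Trajectory", function(object) {
  b <- object@beads
  d <- dim(object@coords)
  if (!all(c("name", "resid", "resname", "radius") %in% names(b)))
    return("beads must have columns name, resid, resname, radius")
  if (nrow(b) < 1) return("at least one bead required")
  if (any(!nzchar(b$name))) return("bead names must be non-empty")
  if (any(b$resid < 1)) return("residue indices must be >= 1")
  if (length(d) != 3 || d[3] != 3)
    return("coords must be a frames x beads x 3 array")
  if (d[1] < 1) return("at least one frame required")
  if (d[2] != nrow(b))
    return(sprintf("coords has %d beads but beads table has %d rows",
                   d[2], nrow(b)))
  if (!all(is.finite(object@coords)))
    return("all coordinates must be finite")
  if (length(object@times) && length(object@times) != d[1])
    return("times length must equal frame count")
  TRUE
})

#' Construct a Trajectory
#'
#' @param beads data.frame of bead metadata; see \linkS4class{Trajectory}.
#'   Missing \code{resname}/\code{radius} columns are filled with
#'   \code{"UNK"} / \code{NA}.
#' @param coords frames x beads x 3 array in nm, or a beads x 3 matrix for
#'   a single frame.
#' @param label simulation label.
#' @param times optional per-frame times in microseconds.
#' @return A \linkS4class{Trajectory}.
#' @export
Trajectory <- function(beads, coords, label = "", times = numeric(0)) {
  if (is.matrix(coords))
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  if (is.null(beads$resname)) beads$resname <- "UNK"
  if (is.null(beads$radius)) beads$radius <- NA_real_
  beads <- as.data.frame(beads)[, c("name", "resid", "resname", "radius")]
  new("Trajectory", beads = beads, coords = coords,
      times = as.numeric(times), label = as.character(label))
}

#' Selection: a resolved set of bead indices
#'
#' Produced by \code{\link{resolveSelection}} from a selection expression
#' such as \code{"backbone and resid 440-460"}. Indices are 1-based
#' positions into the bead table, strictly increasing.
#'
#' @slot indices integer vector of bead indices (1-based, increasing).
#' @slot spec the selection expression the indices were resolved from.
#' @export
setClass("Selection",
  slots = c(indices = "integer", spec = "character"))

setValidity("Selection", function(object) {
  i <- object@indices
  if (length(i) < 1) return("selection must contain at least one bead")
  if (any(i < 1)) return("indices must be >= 1")
  if (any(diff(i) <= 0)) return("indices must be strictly increasing")
  TRUE
})

#' RegionSet: named residue ranges driving regional reporting
#'
#' Maps region names (conventionally PBL, EEE, OPP, CT) to 1-based
#' inclusive residue index vectors. See \code{\link{regionSet}} and
#' \code{\link{defaultRegionSet}}.
#'
#' @slot regions named list of integer vectors of residue indices.
#' @export
setClass("RegionSet", slots = c(regions = "list"))

setValidity("RegionSet", function(object) {
  r <- object@regions
  if (length(r) < 1) return("at least one region required")
  if (is.null(names(r)) || any(!nzchar(names(r))))
    return("all regions must be named")
  if (anyDuplicated(names(r))) return("region names must be unique")
  for (nm in names(r)) {
    v <- r[[nm]]
    if (length(v) < 1) return(sprintf("region %s is empty", nm))
    if (any(v < 1)) return(sprintf("region %s has residue index < 1", nm))
  }
  TRUE
})

#' BinningSpec: discretization policy for positional distributions
#'
#' Controls how the 3-D positional cloud of a residue is turned into a
#' histogram: cubic bins of width \code{binWidth} on the joint axis-aligned
#' bounding box of both trajectories (padded by one bin on every side), an
#' additive pseudocount per bin applied before normalization so divergences
#' stay finite, and the logarithm base.
#'
#' @slot binWidth bin edge length in nm.
#' @slot pseudocount additive count per bin, > 0.
#' @slot base "nats" (natural log) or "bits" (log2).
#' @export
setClass("BinningSpec",
  slots = c(binWidth = "numeric", pseudocount = "numeric",
            base = "character"))

setValidity("BinningSpec", function(object) {
  if (object@binWidth <= 0) return("binWidth must be > 0")
  if (object@pseudocount <= 0) return("pseudocount must be > 0")
  if (!object@base %in% c("nats", "bits"))
    return("base must be 'nats' or 'bits'")
  TRUE
})

#' @param binWidth bin edge length in nm (default 0.1, one Martini bead
#'   diameter per ~2.6 bins).
#' @param pseudocount additive count per bin before normalization
#'   (default 0.5).
#' @param base logarithm base for divergences: "nats" or "bits".
#' @return A \linkS4class{BinningSpec}.
#' @rdname BinningSpec-class
#' @export
binningSpec <- function(binWidth = 0.1, pseudocount = 0.5,
                        base = c("nats", "bits")) {
  new("BinningSpec", binWidth = binWidth, pseudocount = pseudocount,
      base = match.arg(base))
}

#' ResidueDistribution: discretized positional distribution of one residue
#'
#' A 3-D histogram of a residue's (backbone-bead) positions over a set of
#' snapshots, on a shared joint-box geometry, with pseudocount-regularized
#' probabilities.
#'
#' @slot residue residue index the distribution belongs to.
#' @slot counts integer bin counts (linearized x-fastest), summing to n.
#' @slot prob probabilities after pseudocount regularization, summing to 1.
#' @slot n number of snapshots histogrammed.
#' @slot origin lower corner of the binning box (nm).
#' @slot dims integer bin counts along x, y, z.
#' @slot binWidth bin edge length (nm).
#' @slot pseudocount additive count used.
#' @export
setClass("ResidueDistribution",
  slots = c(residue = "integer", counts = "integer", prob = "numeric",
            n = "integer", origin = "numeric", dims = "integer",
            binWidth = "numeric", pseudocount = "numeric"))

setValidity("ResidueDistribution", function(object) {
  K <- prod(object@dims)
  if (length(object@counts) != K || length(object@prob) != K)
    return("counts/prob length must equal prod(dims)")
  if (sum(object@counts) != object@n)
    return("counts must total n")
  if (abs(sum(object@prob) - 1) > 1e-12)
    return("probabilities must sum to 1 within 1e-12")
  TRUE
})

#' DivergenceProfile: per-residue symmetrized KLD between two trajectories
#'
#' @slot residues residue indices (profile axis).
#' @slot values symmetrized divergence per residue, >= 0, in the unit set
#'   by \code{base}.
#' @slot labels labels of the two compared trajectories (P then Q).
#' @slot base "nats" or "bits".
#' @slot symmetrization how the two directed divergences were combined
#'   (always "mean" in this package; recorded so outputs are
#'   self-describing).
#' @export
setClass("DivergenceProfile",
  slots = c(residues = "integer", values = "numeric",
            labels = "character", base = "character",
            symmetrization = "character"))

setValidity("DivergenceProfile", function(object) {
  if (length(object@values) != length(object@residues))
    return("values and residues must have equal length")
  if (any(object@values < 0)) return("divergence values must be >= 0")
  TRUE
})

#' WindowedDivergenceMap: time-resolved divergence matrix
#'
#' Window-by-residue matrix of symmetrized KLD values from the moving
#' window scheme: windows grow from a single snapshot to at most W
#' snapshots, slide, then shrink from the left when the trajectory end is
#' reached. After \code{\link{normalizeMaps}}, the global maximum across
#' the normalized set equals 1.
#'
#' @slot values matrix, windows x residues, >= 0.
#' @slot residues residue indices (columns).
#' @slot windowStart,windowEnd 1-based inclusive snapshot range per window.
#' @slot W maximum window size in snapshots.
#' @slot labels labels of the compared trajectories.
#' @slot base "nats" or "bits".
#' @slot normConstant the global constant the map was divided by, or
#'   \code{NA_real_} if unnormalized.
#' @export
setClass("WindowedDivergenceMap",
  slots = c(values = "matrix", residues = "integer",
            windowStart = "integer", windowEnd = "integer",
            W = "integer", labels = "character", base = "character",
            normConstant = "numeric"))

setValidity("WindowedDivergenceMap", function(object) {
  if (ncol(object@values) != length(object@residues))
    return("one column per residue required")
  if (nrow(object@values) != length(object@windowStart) ||
      nrow(object@values) != length(object@windowEnd))
    return("one window range per row required")
  if (any(object@values < 0)) return("divergence values must be >= 0")
  if (any(object@windowEnd < object@windowStart))
    return("window end must be >= window start")
  TRUE
})

#' RigidTransform: proper rotation plus translation
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 vector in nm.
#' @seealso \code{\link{kabschSuperpose}}, \code{\link{applyTransform}}
#' @export
setClass("RigidTransform",
  slots = c(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation columns must be orthonormal within 1e-8")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation determinant must be +1 within 1e-8")
  if (length(object@translation) != 3)
    return("translation must have length 3")
  TRUE
})

#' AlignmentResult: an aligned trajectory with alignment diagnostics
#'
#' @slot trajectory the aligned \linkS4class{Trajectory}.
#' @slot weights final per-selected-bead alignment weights in [0, 1].
#' @slot weightHistory list of weight vectors, one per iteration.
#' @slot iterations number of alignment iterations performed.
#' @slot converged whether the mean frame-rotation change fell below the
#'   tolerance before the iteration cap.
#' @export
setClass("AlignmentResult",
  slots = c(trajectory = "Trajectory", weights = "numeric",
            weightHistory = "list", iterations = "integer",
            converged = "logical"))

setValidity("AlignmentResult", function(object) {
  w <- object@weights
  if (any(w < 0 | w > 1)) return("weights must lie in [0, 1]")
  if (all(w == 0)) return("weights must not all be zero")
  TRUE
})

#' RmsdSeries: per-frame RMSD of a selection from a reference frame
#'
#' Values are reported in Angstrom (the convention of the figures this
#' analysis feeds); internal computation is in nm.
#'
#' @slot values per-frame RMSD in Angstrom.
#' @slot selection selection expression the series was computed over.
#' @slot reference label of the reference.
#' @export
setClass("RmsdSeries",
  slots = c(values = "numeric", selection = "character",
            reference = "character"))

setValidity("RmsdSeries", function(object) {
  if (any(object@values < 0)) return("RMSD values must be >= 0")
  TRUE
})

#' DistanceSeries: per-frame center-of-mass distance between two groups
#'
#' @slot values per-frame COM-COM distance in Angstrom.
#' @slot groupA,groupB selection expressions of the two groups.
#' @export
setClass("DistanceSeries",
  slots = c(values = "numeric", groupA = "character",
            groupB = "character"))

setValidity("DistanceSeries", function(object) {
  if (any(object@values <= 0)) return("distances must be > 0")
  TRUE
})

#' SasaResult: per-frame solvent accessible surface area of a target group
#'
#' @slot values per-frame total SASA in nm^2.
#' @slot probe probe radius in nm.
#' @slot nPoints quadrature points per bead.
#' @slot target selection expression of the area-contributing group.
#' @export
setClass("SasaResult",
  slots = c(values = "numeric", probe = "numeric", nPoints = "integer",
            target = "character"))

setValidity("SasaResult", function(object) {
  if (any(object@values < 0)) return("SASA must be >= 0")
  if (object@probe < 0) return("probe radius must be >= 0")
  TRUE
})

#' SyntheticConfig: parameters of the synthetic trajectory-pair generator
#'
#' @slot nResidues chain length (>= 10), one backbone bead per residue.
#' @slot nFrames number of snapshots (>= 10).
#' @slot baselineSigma isotropic thermal fluctuation per residue, nm.
#' @slot driftRot rigid-body random-walk rotation step, radians/frame.
#' @slot driftTrans rigid-body random-walk translation step, nm/frame.
#' @slot events list of planted \code{\link{event}} descriptions.
#' @slot seed RNG seed, recorded in all generated outputs.
#' @export
setClass("SyntheticConfig",
  slots = c(nResidues = "integer", nFrames = "integer",
            baselineSigma = "numeric", driftRot = "numeric",
            driftTrans = "numeric", events = "list", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nResidues < 10) return("nResidues must be >= 10")
  if (object@nFrames < 10) return("nFrames must be >= 10")
  if (object@baselineSigma <= 0) return("baselineSigma must be > 0")
  if (object@driftRot < 0 || object@driftTrans < 0)
    return("drift steps must be >= 0")
  for (ev in object@events) {
    if (!is.list(ev) || is.null(ev$kind))
      return("events must be created with event()")
    if (any(ev$residues < 1 | ev$residues > object@nResidues))
      return("event residues outside chain")
    if (!is.null(ev$partner) &&
        any(ev$partner < 1 | ev$partner > object@nResidues))
      return("event partner residues outside chain")
    if (ev$magnitude <= 0) return("event magnitude must be > 0")
    if (!is.null(ev$switchFrame) &&
        (ev$switchFrame < 1 || ev$switchFrame > object@nFrames))
      return("switchFrame outside trajectory")
  }
  touched <- unlist(lapply(object@events,
                           function(e) c(e$residues, e$partner)))
  if (anyDuplicated(touched))
    return("events overlap on the same residues")
  TRUE
})
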