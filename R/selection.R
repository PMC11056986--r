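#' Resolve a selection expression against a trajectory's beads
#'
#' The selection mini-language intersects whitespace-separated clauses
#' joined by \code{and}:
#' \itemize{
#'   \item \code{all} — every bead;
#'   \item \code{backbone} — beads named \code{BB};
#'   \item \code{name N1 N2 ...} — beads with any of the given names
#'     (e.g. \code{name FLA1 FLA2 FLA3 FLA4 FLA5} for the flavin);
#'   \item \code{resname R1 R2 ...} — beads in residues of the given
#'     names (e.g. \code{resname FAD});
#'   \item \code{resid 440-460 480} — beads in the given 1-based residue
#'     ranges or single residues.
#' }
#' Clause order does not affect the result. An expression matching no
#' beads is an error, never a silent empty selection.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param spec selection expression, e.g. \code{"backbone and resid
#'   440-460"}.
#' @return A \linkS4class{Selection} with strictly increasing 1-based
#'   bead indices.
#' @export
resolveSelection <- function(traj, spec) {
  stopifnot(is(traj, "Trajectory"))
  if (!is.character(spec) || length(spec) != 1 || !nzchar(trimws(spec)))
    stop("selection expression must be a non-empty string")
  b <- beads(traj)
  keep <- rep(TRUE, nrow(b))
  clauses <- strsplit(trimws(spec), "[[:space:]]+and[[:space:]]+")[[1]]
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "[[:space:]]+")[[1]]
    kw <- toks[1]
    args <- toks[-1]
    keep <- keep & switch(kw,
      all = rep(TRUE, nrow(b)),
      backbone = b$name == "BB",
      name = {
        if (!length(args)) stop("'name' clause needs at least one name")
        b$name %in% args
      },
      resname = {
        if (!length(args)) stop("'resname' clause needs at least one name")
        b$resname %in% args
      },
      resid = {
        if (!length(args)) stop("'resid' clause needs at least one range")
        b$resid %in% parseRanges(args)
      },
      stop("unknown selection keyword: '", kw, "'"))
  }
  idx <- which(keep)
  if (!length(idx))
    stop("empty selection: '", spec, "' matches no beads")
  new("Selection", indices = as.integer(idx), spec = spec)
}

#' Construct a RegionSet
#'
#' @param x named list mapping region names to 1-based residue index
#'   vectors (ranges are inclusive).
#' @param nResidues optional chain length; when given, ranges are checked
#'   to lie within the chain.
#' @return A \linkS4class{RegionSet}.
#' @export
regionSet <- function(x, nResidues = NULL) {
  x <- lapply(x, function(v) sort(unique(as.integer(v))))
  if (!is.null(nResidues)) {
    for (nm in names(x))
      if (any(x[[nm]] > nResidues))
        stop("region ", nm, " extends past residue ", nResidues)
  }
  new("RegionSet", regions = x)
}

#' Default cryptochrome region taxonomy
#'
#' The regions used in regional divergence reporting: the EEE region
#' (residues 440-460, containing the linear EEE motif at 450-452), the
#' OPP surface patch (residues 80-90), and the flexible C-terminal region
#' (residue 480 to the chain end). The phosphate-binding loop (PBL) span
#' is structure-specific and has no default: it must be supplied.
#'
#' @param nResidues chain length (the C-terminal region runs to it).
#' @param pbl residue indices of the phosphate-binding loop.
#' @return A \linkS4class{RegionSet} with regions PBL, EEE, OPP, CT.
#' @export
defaultRegionSet <- function(nResidues, pbl) {
  if (missing(pbl) || !length(pbl))
    stop("the phosphate-binding loop span has no default; supply pbl")
  if (nResidues < 481)
    stop("default regions assume a chain of at least 481 residues; ",
         "use regionSet() for shorter chains")
  regionSet(list(PBL = pbl, EEE = 440:460, OPP = 80:90,
                 CT = 480:nResidues),
            nResidues = nResidues)
}
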