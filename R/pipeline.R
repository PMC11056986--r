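#' Define a comparison plan
#'
#' A plan bundles everything one divergence study needs: the reference
#' trajectory, the set of comparison trajectories (each compared to the
#' reference, mirroring a redox-state simulation series compared to a
#' common dark-state run), the selection driving alignment and
#' histogramming, the region taxonomy for reporting, the binning policy
#' and the window size.
#'
#' @param reference the reference \linkS4class{Trajectory}.
#' @param comparisons named list of \linkS4class{Trajectory} objects to
#'   compare against the reference; names are the comparison labels and
#'   must be unique.
#' @param selection selection expression for alignment and divergence
#'   (default \code{"backbone"}).
#' @param regions a \linkS4class{RegionSet} for regional reporting, or
#'   \code{NULL} to skip it.
#' @param binning a \linkS4class{BinningSpec}.
#' @param W moving-window size in snapshots (default 50).
#' @param normalize "joint" (default: one global constant across all
#'   comparisons, so maps are mutually comparable) or "per-comparison".
#' @param outDir optional directory for TSV artifacts.
#' @param seed seed recorded in output metadata (the pipeline itself is
#'   deterministic; randomness lives in synthetic generation only).
#' @return a ComparisonPlan (list with class attribute).
#' @export
comparisonPlan <- function(reference, comparisons,
                           selection = "backbone", regions = NULL,
                           binning = binningSpec(), W = 50,
                           normalize = c("joint", "per-comparison"),
                           outDir = NULL, seed = NA_integer_) {
  stopifnot(is(reference, "Trajectory"))
  if (!length(comparisons) || is.null(names(comparisons)) ||
      any(!nzchar(names(comparisons))))
    stop("comparisons must be a non-empty named list")
  if (anyDuplicated(names(comparisons)))
    stop("comparison labels must be unique")
  if (trajLabel(reference) %in% names(comparisons))
    stop("the reference label must not also name a comparison")
  structure(list(reference = reference, comparisons = comparisons,
                 selection = selection, regions = regions,
                 binning = binning, W = as.integer(W),
                 normalize = match.arg(normalize), outDir = outDir,
                 seed = seed),
            class = "ComparisonPlan")
}

planFingerprint <- function(plan) {
  fnv1a(c(trajLabel(plan$reference), names(plan$comparisons),
          plan$selection, plan$binning@binWidth,
          plan$binning@pseudocount, plan$binning@base, plan$W,
          plan$normalize, plan$seed))
}

#' Run a full comparison plan
#'
#' Executes the comparison workflow end to end: iterative
#' variance-reweighted alignment of each (reference, comparison) pair
#' onto the reference's first frame, per-residue divergence profile and
#' windowed divergence map per comparison, global normalization of the
#' maps across the whole plan (so 1.0 marks the largest difference seen
#' anywhere in the set), whole-selection and per-region RMSD series, and
#' a regional summary ranking the regions by mean divergence. When
#' \code{outDir} is set, every table is written as TSV with a
#' \code{#}-prefixed metadata header carrying the plan fingerprint, seed,
#' normalization constant and alignment convergence flags; on error all
#' partial outputs are removed.
#'
#' @param plan a plan from \code{\link{comparisonPlan}}.
#' @return list with \code{profiles}, \code{maps} (normalized),
#'   \code{rmsd} (per comparison: whole selection and per region),
#'   \code{report} (data.frame: comparison, region, meanDivergence,
#'   maxDivergence, meanRmsd, rank), \code{normConstant},
#'   \code{alignment} (per-comparison diagnostics).
#' @export
runComparison <- function(plan) {
  stopifnot(inherits(plan, "ComparisonPlan"))
  written <- character(0)
  cleanup <- function() if (length(written)) unlink(written)
  stage <- "setup"
  res <- tryCatch(
    runComparisonStages(plan, function(p) written <<- c(written, p),
                        function(s) stage <<- s),
    error = function(e) {
      cleanup()
      stop("comparison failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
  res
}

runComparisonStages <- function(plan, noteFile, noteStage) {
  ref <- plan$reference
  fp <- planFingerprint(plan)
  meta0 <- c(sprintf("plan: %s", fp),
             sprintf("seed: %s", plan$seed),
             sprintf("reference: %s", trajLabel(ref)))
  profiles <- list(); maps <- list(); rmsd <- list(); alignInfo <- list()

  for (lab in names(plan$comparisons)) {
    noteStage(paste0("align[", lab, "]"))
    comp <- plan$comparisons[[lab]]
    al <- iterativeAlign(ref, comp, ref, plan$selection)
    alignInfo[[lab]] <- list(iterations = al$A@iterations,
                             converged = al$A@converged)
    message(sprintf(
      "[%s] aligned: %d+%d frames, %d iterations, converged=%s",
      lab, nFrames(ref), nFrames(comp), al$A@iterations,
      al$A@converged))

    noteStage(paste0("profile[", lab, "]"))
    profiles[[lab]] <- divergenceProfile(al$A@trajectory,
                                         al$B@trajectory,
                                         plan$selection, plan$binning)
    noteStage(paste0("window[", lab, "]"))
    maps[[lab]] <- windowedDivergence(al$A@trajectory,
                                      al$B@trajectory,
                                      plan$selection, plan$binning,
                                      plan$W)
    noteStage(paste0("rmsd[", lab, "]"))
    refFrame <- frameCoords(ref, 1)
    rl <- list(whole = rmsdSeries(al$B@trajectory, refFrame,
                                  plan$selection,
                                  reference = trajLabel(ref)))
    if (!is.null(plan$regions)) {
      for (rn in names(regions(plan$regions))) {
        rr <- regions(plan$regions)[[rn]]
        selSpec <- sprintf("backbone and resid %s",
                           paste(collapseRanges(rr), collapse = " "))
        rl[[rn]] <- rmsdSeries(al$B@trajectory, refFrame, selSpec,
                               reference = trajLabel(ref))
      }
    }
    rmsd[[lab]] <- rl
  }

  noteStage("normalize")
  normConstant <- NA_real_
  if (plan$normalize == "joint") {
    maps <- suppressWarnings(normalizeMaps(maps))
    normConstant <- maps[[1]]@normConstant
  } else {
    maps <- lapply(maps, function(m)
      suppressWarnings(normalizeMaps(list(m))[[1]]))
  }
  message(sprintf("normalization constant: %s",
                  format(normConstant)))

  noteStage("report")
  report <- regionReport(profiles, rmsd, plan$regions)

  if (!is.null(plan$outDir)) {
    noteStage("write")
    dir.create(plan$outDir, showWarnings = FALSE, recursive = TRUE)
    for (lab in names(profiles)) {
      p <- file.path(plan$outDir, sprintf("profile_%s.tsv", lab))
      prof <- profiles[[lab]]
      writeTSVWithMeta(
        data.frame(residue = prof@residues,
                   kld_nats = sprintf("%.9g", prof@values)),
        p, meta = c(meta0, sprintf("comparison: %s", lab),
                    sprintf("base: %s", prof@base),
                    sprintf("symmetrization: %s",
                            prof@symmetrization)))
      noteFile(p)
      m <- maps[[lab]]
      pw <- file.path(plan$outDir, sprintf("window_%s.tsv", lab))
      wr <- windowRanges(m)
      long <- data.frame(
        window_right_edge = rep(wr$end, ncol(m@values)),
        residue = rep(m@residues, each = nrow(m@values)),
        value = sprintf("%.9g", as.vector(m@values)))
      writeTSVWithMeta(long, pw,
        meta = c(meta0, sprintf("comparison: %s", lab),
                 sprintf("W: %d", m@W),
                 sprintf("normalization_constant: %s",
                         format(m@normConstant)),
                 sprintf("converged: %s",
                         alignInfo[[lab]]$converged)))
      noteFile(pw)
      pr <- file.path(plan$outDir, sprintf("rmsd_%s.tsv", lab))
      rs <- rmsd[[lab]]$whole
      writeTSVWithMeta(
        data.frame(frame = seq_along(rs@values),
                   rmsd_A = sprintf("%.6g", rs@values)),
        pr, meta = c(meta0, sprintf("comparison: %s", lab),
                     sprintf("selection: %s", rs@selection)))
      noteFile(pr)
    }
    if (!is.null(report)) {
      prp <- file.path(plan$outDir, "report.tsv")
      writeTSVWithMeta(report, prp, meta = meta0)
      noteFile(prp)
    }
  }
  list(profiles = profiles, maps = maps, rmsd = rmsd,
       report = report, normConstant = normConstant,
       alignment = alignInfo, fingerprint = fp)
}

# 5 7:9 -> c("5", "7-9")
collapseRanges <- function(v) {
  v <- sort(unique(v))
  brk <- c(0, which(diff(v) != 1), length(v))
  vapply(seq_len(length(brk) - 1), function(i) {
    seg <- v[(brk[i] + 1):brk[i + 1]]
    if (length(seg) == 1) as.character(seg)
    else sprintf("%d-%d", seg[1], seg[length(seg)])
  }, character(1))
}

#' Regional divergence summary
#'
#' Aggregates per-residue divergence profiles into the region taxonomy:
#' for each comparison and region, the mean and maximum divergence over
#' the region's residues, the mean region RMSD, and the region's rank by
#' mean divergence within the comparison (1 = most divergent). Degenerate
#' rankings (all regions essentially zero, e.g. a self-comparison) are
#' flagged in the \code{degenerate} column.
#'
#' @param profiles named list of \linkS4class{DivergenceProfile}s.
#' @param rmsd optional named list (per comparison) of named
#'   \linkS4class{RmsdSeries} lists, as produced by
#'   \code{\link{runComparison}}.
#' @param regionset a \linkS4class{RegionSet} or \code{NULL}.
#' @return data.frame, or \code{NULL} when \code{regionset} is
#'   \code{NULL}.
#' @export
regionReport <- function(profiles, rmsd = NULL, regionset = NULL) {
  if (is.null(regionset)) return(NULL)
  rs <- regions(regionset)
  out <- do.call(rbind, lapply(names(profiles), function(lab) {
    prof <- profiles[[lab]]
    rows <- do.call(rbind, lapply(names(rs), function(rn) {
      inRegion <- prof@residues %in% rs[[rn]]
      if (!any(inRegion))
        stop("region ", rn, " has no residues in the profile")
      v <- prof@values[inRegion]
      mr <- if (!is.null(rmsd) && !is.null(rmsd[[lab]][[rn]]))
        mean(rmsd[[lab]][[rn]]@values) else NA_real_
      data.frame(comparison = lab, region = rn,
                 meanDivergence = mean(v), maxDivergence = max(v),
                 meanRmsd = mr)
    }))
    rows$rank <- rank(-rows$meanDivergence, ties.method = "first")
    rows$degenerate <- max(rows$meanDivergence) < 1e-9
    rows
  }))
  rownames(out) <- NULL
  out
}
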