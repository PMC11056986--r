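#' Read a structure file into a single-frame Trajectory
#'
#' Reads a GRO or PDB file. GRO coordinates are already in nm; PDB
#' coordinates are converted from Angstrom to nm at the boundary, following
#' the coarse-grained (Martini) convention of working in nm internally.
#'
#' @param path file path.
#' @param format "gro" or "pdb"; guessed from the file extension when
#'   omitted.
#' @param label trajectory label (defaults to the file name).
#' @return A single-frame \linkS4class{Trajectory} with bead order
#'   preserved from the file.
#' @examples
#' gro <- tempfile(fileext = ".gro")
#' writeLines(c("toy", " 2",
#'   "    1ALA    BB    1   0.100   0.200   0.300",
#'   "    2ALA    BB    2   0.400   0.500   0.600",
#'   "  2.0  2.0  2.0"), gro)
#' readStructure(gro)
#' @export
readStructure <- function(path, format = c("auto", "gro", "pdb"),
                          label = basename(path)) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("gro", "pdb"))
      stop("cannot guess format from extension '", ext,
           "'; pass format explicitly")
    format <- ext
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         gro = readGRO(path, label),
         pdb = readPDBStructure(path, label))
}

readGRO <- function(path, label) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("GRO parse error: file has fewer than 3 lines")
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 1)
    stop("GRO parse error at line 2: invalid atom count '",
         trimws(lines[2]), "'")
  if (length(lines) < 2 + natoms)
    stop("GRO parse error: atom count ", natoms, " but only ",
         length(lines) - 2, " atom lines present (truncated file)")
  atom <- lines[3:(2 + natoms)]
  # fixed columns: resid(1-5) resname(6-10) atomname(11-15) atomnum(16-20)
  # x(21-28) y(29-36) z(37-44), positions in nm
  resid <- suppressWarnings(as.integer(substr(atom, 1, 5)))
  resname <- trimws(substr(atom, 6, 10))
  name <- trimws(substr(atom, 11, 15))
  xyz <- cbind(suppressWarnings(as.numeric(substr(atom, 21, 28))),
               suppressWarnings(as.numeric(substr(atom, 29, 36))),
               suppressWarnings(as.numeric(substr(atom, 37, 44))))
  bad <- which(is.na(resid) | !nzchar(name) | rowSums(is.na(xyz)) > 0)
  if (length(bad))
    stop("GRO parse error at line ", 2 + bad[1], ": '", atom[bad[1]], "'")
  Trajectory(data.frame(name = name, resid = resid, resname = resname,
                        radius = NA_real_),
             xyz, label = label)
}

readPDBStructure <- function(path, label) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  xyz <- cbind(a$x, a$y, a$z) * NM_PER_ANGSTROM
  Trajectory(data.frame(name = trimws(a$elety), resid = a$resno,
                        resname = trimws(a$resid), radius = NA_real_),
             xyz, label = label)
}

#' Append trajectory frames from a file onto a structure
#'
#' Takes the bead model from \code{structure} and reads frames from a
#' trajectory file: a binary DCD, a multi-model PDB, or the package's
#' plain-text TSV fixture format (columns \code{frame bead x y z} in nm,
#' \code{#} comment lines allowed). DCD and PDB coordinates are converted
#' from Angstrom to nm.
#'
#' @param structure a \linkS4class{Trajectory} defining the bead model
#'   (its own frames are discarded).
#' @param path trajectory file path.
#' @param format "dcd", "multi-model-pdb" or "tsv"; guessed from the
#'   extension when omitted.
#' @return A \linkS4class{Trajectory} with frames in file order.
#' @export
readTrajectory <- function(structure,
                           path,
                           format = c("auto", "dcd", "multi-model-pdb",
                                      "tsv")) {
  stopifnot(is(structure, "Trajectory"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, dcd = "dcd", pdb = "multi-model-pdb",
                     tsv = "tsv",
                     stop("cannot guess trajectory format from '", ext,
                          "'"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  nb <- nBeads(structure)
  coords <- switch(format,
    dcd = {
      xyz <- bio3d::read.dcd(path, verbose = FALSE)
      checkBeadCount(ncol(xyz) / 3, nb, path)
      xyzToArray(xyz) * NM_PER_ANGSTROM
    },
    `multi-model-pdb` = {
      pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
      xyz <- pdb$xyz
      checkBeadCount(ncol(xyz) / 3, nb, path)
      xyzToArray(xyz) * NM_PER_ANGSTROM
    },
    tsv = readTrajectoryTSV(path, nb))
  Trajectory(beads(structure), coords, label = trajLabel(structure))
}

checkBeadCount <- function(found, expected, path) {
  if (found != expected)
    stop("bead count mismatch: structure has ", expected,
         " beads but ", path, " has ", found)
  invisible(TRUE)
}

# bio3d xyz matrix (frames x 3N, x1 y1 z1 x2 ...) -> frames x N x 3
xyzToArray <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  nb <- ncol(xyz) / 3
  arr <- array(0, dim = c(nf, nb, 3))
  for (k in 1:3) arr[, , k] <- xyz[, seq(k, ncol(xyz), by = 3),
                                   drop = FALSE]
  arr
}

readTrajectoryTSV <- function(path, nb) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  need <- c("frame", "bead", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("TSV fixture must have columns: ", paste(need, collapse = " "))
  fr <- sort(unique(df$frame))
  if (!identical(fr, seq_along(fr)))
    stop("TSV fixture frames must be 1..N without gaps")
  perFrame <- table(df$frame)
  if (any(perFrame != nb))
    stop("bead count mismatch: structure has ", nb,
         " beads but fixture frame has ", perFrame[[1]])
  df <- df[order(df$frame, df$bead), ]
  arr <- array(0, dim = c(length(fr), nb, 3))
  arr[, , 1] <- matrix(df$x, nrow = length(fr), byrow = TRUE)
  arr[, , 2] <- matrix(df$y, nrow = length(fr), byrow = TRUE)
  arr[, , 3] <- matrix(df$z, nrow = length(fr), byrow = TRUE)
  arr
}

#' Write a trajectory in the TSV fixture format
#'
#' Plain whitespace-delimited text, one row per (frame, bead) with
#' coordinates in nm at 9 significant digits; round-trips through
#' \code{\link{readTrajectory}} to well below 1e-6 nm.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output path.
#' @param meta optional extra metadata lines for the \code{#} header.
#' @return the path, invisibly.
#' @export
writeTrajectoryTSV <- function(traj, path, meta = character(0)) {
  stopifnot(is(traj, "Trajectory"))
  nf <- nFrames(traj); nb <- nBeads(traj)
  df <- data.frame(
    frame = rep(seq_len(nf), each = nb),
    bead = rep(seq_len(nb), nf),
    x = sprintf("%.9g", as.vector(t(traj@coords[, , 1]))),
    y = sprintf("%.9g", as.vector(t(traj@coords[, , 2]))),
    z = sprintf("%.9g", as.vector(t(traj@coords[, , 3]))))
  writeTSVWithMeta(df, path,
                   meta = c(sprintf("label: %s", trajLabel(traj)),
                            "units: nm", meta))
}

#' Write a single frame as a GRO file
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output path.
#' @param frame frame index to write (default 1).
#' @return the path, invisibly.
#' @export
writeGRO <- function(traj, path, frame = 1) {
  stopifnot(is(traj, "Trajectory"))
  x <- frameCoords(traj, frame)
  b <- beads(traj)
  lines <- c(trajLabel(traj), sprintf("%5d", nBeads(traj)),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     b$resid, b$resname, b$name, seq_len(nrow(b)),
                     x[, 1], x[, 2], x[, 3]),
             sprintf("%10.5f%10.5f%10.5f",
                     max(x[, 1]) - min(x[, 1]) + 1,
                     max(x[, 2]) - min(x[, 2]) + 1,
                     max(x[, 3]) - min(x[, 3]) + 1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a region configuration file
#'
#' YAML key-value file mapping region names to residue ranges, e.g.
#' \preformatted{
#' PBL: 231-250
#' EEE: 440-460
#' OPP: 80-90
#' CT: 480-end
#' }
#' Ranges are 1-based inclusive; \code{end} resolves to \code{nResidues}.
#' The phosphate-binding-loop span has no default and must be supplied
#' here or via \code{\link{regionSet}}.
#'
#' @param path YAML file path.
#' @param nResidues chain length, used to resolve \code{end}.
#' @return A \linkS4class{RegionSet}.
#' @export
readRegionConfig <- function(path, nResidues) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg)) stop("region config is empty")
  lst <- lapply(cfg, function(v) {
    v <- gsub("end", as.character(nResidues), as.character(v))
    parseRanges(strsplit(trimws(v), "[,[:space:]]+")[[1]])
  })
  regionSet(lst, nResidues = nResidues)
}
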