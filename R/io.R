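## Structure and trajectory I/O: PDB (multi-model, read via bio3d, written
## with fixed-width records) and XYZ (concatenated frames, full double
## precision so endpoint frames round-trip bit-for-bit).

.roleFromName <- function(atomName) {
  vapply(atomName, function(a) {
    switch(a, N = "N", CA = "CA", C = "C", O = "O",
           H = "H", HN = "H", H1 = "H", "side")
  }, character(1), USE.NAMES = FALSE)
}

.elementFromName <- function(atomName) {
  el <- substr(gsub("^[0-9]+", "", atomName), 1L, 1L)
  toupper(el)
}

#' Build a MolecularSystem from per-atom records
#'
#' @param atomNames PDB-style atom names.
#' @param resid residue index per atom.
#' @param resname residue name per atom (default `"ALA"`).
#' @param elements element symbols; inferred from the atom names (with a
#'   warning) when missing.
#' @param masses per-atom masses; from the element table when missing.
#' @return a [MolecularSystem].
#' @export
molecularSystem <- function(atomNames, resid, resname = NULL,
                            elements = NULL, masses = NULL) {
  if (is.null(elements)) {
    elements <- .elementFromName(atomNames)
    warning("elements inferred from atom names")
  }
  if (is.null(masses)) masses <- elementMass(elements)
  if (is.null(resname)) resname <- rep("ALA", length(atomNames))
  new("MolecularSystem", atomNames = as.character(atomNames),
      elements = as.character(elements), masses = as.numeric(masses),
      resid = as.integer(resid), resname = as.character(resname),
      role = .roleFromName(atomNames))
}

#' Read a structure or trajectory file
#'
#' PDB files are parsed with bio3d (all models); XYZ files with a built-in
#' reader.  Multi-model input with at least three frames additionally
#' yields a [Path] (with unit time step).
#'
#' @param file path of the input file.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param delta time step recorded on the returned path.
#' @return list with `system` (a [MolecularSystem], or `NULL` for element
#'   only XYZ input), `elements`, `frames` (frames x 3N coordinate matrix),
#'   `coords` (first frame, atoms x 3) and `path` (a [Path] or `NULL`).
#' @export
readStructure <- function(file, format = c("auto", "pdb", "xyz"), delta = 1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", file, ignore.case = TRUE)) "xyz" else "pdb"
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
    atoms <- pdb$atom
    elements <- atoms$elesy
    if (is.null(elements) || all(is.na(elements)) || all(elements == "")) {
      elements <- .elementFromName(atoms$elety)
      warning("element column missing; inferred from atom names")
    }
    elements[is.na(elements) | elements == ""] <-
      .elementFromName(atoms$elety)[is.na(elements) | elements == ""]
    system <- new("MolecularSystem",
                  atomNames = atoms$elety, elements = elements,
                  masses = elementMass(elements),
                  resid = as.integer(atoms$resno), resname = atoms$resid,
                  role = .roleFromName(atoms$elety))
    frames <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1L)
  } else {
    parsed <- .readXYZ(file)
    elements <- parsed$elements
    system <- NULL
    frames <- parsed$frames
  }
  path <- if (nrow(frames) >= 3L)
    newPath(frames, delta = delta,
            masses = if (!is.null(system)) system@masses
                     else elementMass(elements),
            adim = 3L, system = system)
  else NULL
  list(system = system, elements = elements, frames = frames,
       coords = matrix(frames[1L, ], ncol = 3L, byrow = TRUE), path = path)
}

.readXYZ <- function(file) {
  lines <- readLines(file)
  frames <- list()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*$", lines[i])) {
      n <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(n))
        stop("malformed XYZ atom count at line ", i, ": '", lines[i], "'")
      if (i + 1L + n > length(lines))
        stop("truncated XYZ frame starting at line ", i)
      block <- lines[(i + 2L):(i + 1L + n)]
      tok <- strsplit(trimws(block), "\\s+")
      bad <- which(lengths(tok) < 4L)
      if (length(bad))
        stop("malformed XYZ atom record at line ", i + 1L + bad[1L])
      el <- vapply(tok, `[[`, character(1), 1L)
      xyz <- t(vapply(tok, function(t)
        suppressWarnings(as.numeric(t[2:4])), numeric(3)))
      if (anyNA(xyz))
        stop("non-numeric coordinate in XYZ frame starting at line ", i)
      if (is.null(elements)) elements <- el
      frames[[length(frames) + 1L]] <- as.numeric(t(xyz))
      i <- i + 2L + n
    } else i <- i + 1L
  }
  if (!length(frames)) stop("no frames found in XYZ file")
  list(elements = elements, frames = do.call(rbind, frames))
}

#' Write a trajectory
#'
#' Multi-model PDB (one MODEL/ENDMDL block per frame, fixed-width columns)
#' or concatenated XYZ.  Frame index and time stamp are recorded in REMARK
#' (PDB) or comment (XYZ) lines.  XYZ coordinates are written with full
#' double precision so the endpoint frames survive a round trip exactly.
#'
#' @param path a [Path] (or a bare frames x 3N matrix).
#' @param file destination file.
#' @param system a [MolecularSystem] (required for PDB; defaults to the
#'   path's own).
#' @param format `"pdb"` or `"xyz"`.
#' @param delta time per step for the stamps (default: the path's).
#' @return the file name, invisibly.
#' @export
writeTrajectory <- function(path, file, system = NULL,
                            format = c("pdb", "xyz"), delta = NULL) {
  format <- match.arg(format)
  if (is(path, "Path")) {
    frames <- path@frames
    if (is.null(system)) system <- path@system
    if (is.null(delta)) delta <- path@delta
  } else {
    frames <- as.matrix(path)
    if (is.null(delta)) delta <- 1
  }
  if (format == "pdb") {
    if (is.null(system)) stop("PDB output requires a MolecularSystem")
    con <- file(file, "w")
    on.exit(close(con))
    for (f in seq_len(nrow(frames))) {
      writeLines(sprintf("REMARK   6 FRAME %d TIME %.6f", f - 1L,
                         (f - 1L) * delta), con)
      writeLines(sprintf("MODEL     %4d", f), con)
      x <- matrix(frames[f, ], ncol = 3L, byrow = TRUE)
      nm <- system@atomNames
      nm4 <- ifelse(nchar(nm) < 4L,
                    formatC(paste0(" ", nm), width = -4), nm)
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(nrow(x)), nm4, substr(system@resname, 1L, 3L), "A",
        system@resid, x[, 1L], x[, 2L], x[, 3L], 1, 0,
        system@elements), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    con <- file(file, "w")
    on.exit(close(con))
    elements <- if (!is.null(system)) system@elements
                else rep("C", ncol(frames) %/% 3L)
    for (f in seq_len(nrow(frames))) {
      x <- matrix(frames[f, ], ncol = 3L, byrow = TRUE)
      writeLines(as.character(nrow(x)), con)
      writeLines(sprintf("frame %d time %.6f", f - 1L, (f - 1L) * delta), con)
      writeLines(sprintf("%-2s %.17g %.17g %.17g", elements,
                         x[, 1L], x[, 2L], x[, 3L]), con)
    }
  }
  invisible(file)
}
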