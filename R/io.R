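#' Construct a conformation
#'
#' A conformation pairs an atom table with one set of 3D coordinates in nm.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `resno`, `chain`, `element`, `vdw_radius` (nm).
#' @param xyz numeric n x 3 matrix of coordinates in nm.
#' @return object of class `conformation`.
#' @export
new_conformation <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(atoms) != nrow(xyz))
    stop("atom table has ", nrow(atoms), " rows but coordinates have ",
         nrow(xyz))
  if (ncol(xyz) != 3) stop("coordinates must be an n x 3 matrix")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (any(atoms$resno < 1)) stop("residue indices must be >= 1")
  if (any(!nzchar(atoms$name))) stop("empty atom name")
  structure(list(atoms = atoms, xyz = xyz), class = "conformation")
}

#' Construct an ensemble
#'
#' An ensemble is an ordered set of conformations (frames) sharing one
#' topology, e.g. the frames of an MD trajectory.
#'
#' @param topology atom data.frame as in [new_conformation()].
#' @param frames list of n x 3 coordinate matrices (nm), one per frame.
#' @param frame_labels optional character vector of frame names.
#' @return object of class `ensemble`.
#' @export
new_ensemble <- function(topology, frames, frame_labels = NULL) {
  if (length(frames) < 1) stop("an ensemble needs at least one frame")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f); storage.mode(f) <- "double"; f
  })
  n <- nrow(topology)
  ok <- vapply(frames, function(f) nrow(f) == n && ncol(f) == 3, logical(1))
  if (!all(ok))
    stop("frame(s) ", paste(which(!ok), collapse = ", "),
         " do not match the topology atom count (", n, ")")
  if (!is.null(frame_labels) && length(frame_labels) != length(frames))
    stop("frame_labels length does not match the number of frames")
  structure(list(topology = topology, frames = frames,
                 frame_labels = frame_labels), class = "ensemble")
}

#' Number of frames in an ensemble
#' @param ensemble an `ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Extract one frame of an ensemble as a conformation
#' @param ensemble an `ensemble`.
#' @param i frame index (1-based).
#' @return a `conformation`.
#' @export
get_frame <- function(ensemble, i) {
  if (i < 1 || i > n_frames(ensemble)) stop("frame index out of range")
  new_conformation(ensemble$topology, ensemble$frames[[i]])
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", n_frames(x), "frames,", nrow(x$topology), "atoms,",
      length(unique(x$topology$resno)), "residues\n")
  invisible(x)
}

#' @export
print.conformation <- function(x, ...) {
  cat("conformation:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resno)), "residues\n")
  invisible(x)
}

.element_from_name <- function(name) {
  # PDB convention: first character of the stripped atom name, after
  # dropping leading digits (e.g. "1HB" -> H)
  el <- sub("^[0-9]*", "", trimws(name))
  toupper(substr(el, 1, 1))
}

.assign_radii <- function(element, radii = NULL) {
  tab <- .vdw_radii_nm
  if (!is.null(radii)) tab[names(radii)] <- radii
  r <- unname(tab[element])
  r
}

#' Read a multi-model PDB file as an ensemble
#'
#' Each MODEL block becomes one frame; a single-structure file yields a
#' one-frame ensemble. Coordinates are converted from Angstrom to nm and
#' van der Waals radii are assigned per element from a bundled table
#' (C 0.170, N 0.155, O 0.152, H 0.120, S 0.180 nm).
#'
#' @param path PDB file path.
#' @param radii optional named vector (element -> nm) overriding the
#'   bundled radii.
#' @return an `ensemble`.
#' @export
read_multimodel_pdb <- function(path, radii = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  el <- at$elesy
  missing_el <- is.na(el) | !nzchar(trimws(el))
  el[missing_el] <- .element_from_name(at$elety[missing_el])
  el <- toupper(trimws(el))
  topology <- data.frame(
    serial = at$eleno, name = trimws(at$elety), resname = trimws(at$resid),
    resno = at$resno, chain = ifelse(is.na(at$chain), "A", at$chain),
    element = el, vdw_radius = .assign_radii(el, radii),
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nat <- nrow(topology)
  if (ncol(xyz) != 3 * nat)
    stop("topology mismatch: models carry ", ncol(xyz) / 3,
         " atoms but the first model has ", nat)
  frames <- lapply(seq_len(nrow(xyz)), function(m) {
    matrix(xyz[m, ], ncol = 3, byrow = TRUE) / 10  # Angstrom -> nm
  })
  new_ensemble(topology, frames)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are converted from nm to Angstrom. The inverse of
#' [read_multimodel_pdb()] up to the fixed-width precision of the PDB
#' format (1e-3 Angstrom).
#'
#' @param ensemble an `ensemble`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  top <- ensemble$topology
  xyz <- do.call(rbind, lapply(ensemble$frames,
                               function(f) as.vector(t(f)) * 10))
  bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM",
                   resno = top$resno, resid = top$resname,
                   eleno = top$serial, elety = top$name,
                   chain = top$chain, elesy = top$element)
  invisible(path)
}

#' Write a single conformation as a PDB file
#' @param conformation a `conformation`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pdb_conformation <- function(conformation, path) {
  write_multimodel_pdb(new_ensemble(conformation$atoms,
                                    list(conformation$xyz)), path)
}

#' Select atoms of an ensemble by a named selection
#'
#' `backbone5` keeps the peptide backbone atoms N, H, CA, C, O (H silently
#' reduced to 4 atoms/residue with a warning when absent from the
#' topology); `calpha` keeps CA only; `all` is the identity.
#'
#' @param ensemble an `ensemble`.
#' @param selection one of `"backbone5"`, `"calpha"`, `"all"`.
#' @return the sub-ensemble, frame order preserved.
#' @export
select_atoms <- function(ensemble, selection = c("backbone5", "calpha", "all")) {
  selection <- match.arg(selection)
  if (selection == "all") return(ensemble)
  want <- switch(selection, backbone5 = c("N", "H", "CA", "C", "O"),
                 calpha = "CA")
  keep <- ensemble$topology$name %in% want
  if (!any(keep)) stop("selection '", selection, "' matches no atoms")
  if (selection == "backbone5" && !any(ensemble$topology$name == "H"))
    warning("topology has no amide H atoms; backbone5 selection reduces ",
            "to 4 atoms per residue")
  new_ensemble(ensemble$topology[keep, , drop = FALSE],
               lapply(ensemble$frames, function(f) f[keep, , drop = FALSE]),
               ensemble$frame_labels)
}

#' Write a per-frame descriptor table as TSV
#'
#' Tab-separated text with a header row and full double precision
#' (17 significant digits), so a read-back is numerically identical.
#'
#' @param table data.frame; must contain a `frame` column.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_descriptor_table <- function(table, path) {
  if (is.null(table) || nrow(table) == 0) stop("empty descriptor table")
  fmt <- lapply(table, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  out <- do.call(cbind, fmt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(table), collapse = "\t"), con)
  writeLines(apply(out, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a descriptor table written by [write_descriptor_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_descriptor_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}
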