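#' Read a (multi-model) PDB file into an ensemble
#'
#' Parses `ATOM` and `HETATM` records from a fixed-column PDB file.
#' `MODEL`/`ENDMDL` records delimit frames; a file without `MODEL` records
#' yields a single-frame ensemble. All frames must share one topology
#' (identical atom ordering and count), the natural representation for a
#' trajectory written as a multi-model PDB or a crystal structure.
#'
#' @param path Path to a PDB file.
#' @param source_label Label identifying the trajectory or molecule the
#'   frames come from (e.g. `"GBS1"`, `"free-C"`). Defaults to the file
#'   name without extension.
#' @return An object of class `pdb_ensemble`: a list with
#'   \describe{
#'     \item{atoms}{data frame of per-atom metadata (`serial`, `atom_name`,
#'       `alt_loc`, `residue_name`, `chain_id`, `residue_number`,
#'       `occupancy`, `b_factor`, `record`), constant across frames;}
#'     \item{xyz}{numeric matrix, one row per frame, `3 * n_atoms` columns
#'       ordered x1, y1, z1, x2, ...;}
#'     \item{source_label}{character scalar.}
#'   }
#' @details Insertion codes are not supported and raise an error. Malformed
#'   coordinate fields raise a parse error naming the offending line. A file
#'   with zero `ATOM`/`HETATM` records raises an empty-structure error.
#' @seealso [write_pdb()], [select_atoms()]
#' @export
read_pdb <- function(path, source_label = NULL) {
  if (!file.exists(path)) {
    cf_stop("confens_io_error", "file not found: ", path)
  }
  if (is.null(source_label)) {
    source_label <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(rec, "MODEL")
  is_endmdl <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) {
    cf_stop("confens_empty_structure_error",
            "no ATOM/HETATM records found in ", path)
  }

  # frame id per line: 0 before any MODEL record, else running MODEL count
  model_no <- cumsum(is_model)
  atom_idx <- which(is_atom)
  frame_of_atom <- model_no[atom_idx]
  if (any(is_model)) {
    # atoms before the first MODEL record (frame 0) are not allowed to mix
    # with modelled atoms
    if (any(frame_of_atom == 0) && any(frame_of_atom > 0)) {
      cf_stop("confens_parse_error",
              "ATOM records appear both before and inside MODEL blocks")
    }
  }
  frame_ids <- sort(unique(frame_of_atom))
  n_frames <- length(frame_ids)

  atom_lines <- lines[atom_idx]
  parse_num <- function(txt, what, width_lines) {
    out <- suppressWarnings(as.numeric(txt))
    bad <- is.na(out) & trimws(txt) != ""
    if (any(bad)) {
      ln <- atom_idx[which(bad)[1]]
      cf_stop("confens_parse_error", "malformed ", what,
              " field at line ", ln, ": '", trimws(txt[which(bad)[1]]), "'")
    }
    out
  }
  x <- parse_num(substr(atom_lines, 31, 38), "x coordinate")
  y <- parse_num(substr(atom_lines, 39, 46), "y coordinate")
  z <- parse_num(substr(atom_lines, 47, 54), "z coordinate")
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    ln <- atom_idx[which(is.na(x) | is.na(y) | is.na(z))[1]]
    cf_stop("confens_parse_error", "missing coordinate at line ", ln)
  }
  icode <- substr(atom_lines, 27, 27)
  if (any(icode != " " & icode != "")) {
    ln <- atom_idx[which(icode != " " & icode != "")[1]]
    cf_stop("confens_parse_error",
            "insertion codes are not supported (line ", ln, ")")
  }
  occ <- parse_num(substr(atom_lines, 55, 60), "occupancy")
  occ[is.na(occ)] <- 1
  bfac <- parse_num(substr(atom_lines, 61, 66), "B-factor")
  bfac[is.na(bfac)] <- 0
  serial <- suppressWarnings(as.integer(substr(atom_lines, 7, 11)))
  resno <- suppressWarnings(as.integer(substr(atom_lines, 23, 26)))
  if (anyNA(resno)) {
    ln <- atom_idx[which(is.na(resno))[1]]
    cf_stop("confens_parse_error", "malformed residue number at line ", ln)
  }
  atoms_all <- data.frame(
    serial = serial,
    atom_name = trimws(substr(atom_lines, 13, 16)),
    alt_loc = trimws(substr(atom_lines, 17, 17)),
    residue_name = trimws(substr(atom_lines, 18, 20)),
    chain_id = substr(atom_lines, 22, 22),
    residue_number = resno,
    occupancy = occ,
    b_factor = bfac,
    record = trimws(substr(atom_lines, 1, 6)),
    stringsAsFactors = FALSE
  )

  split_frames <- split(seq_along(atom_idx), frame_of_atom)
  n_atoms <- length(split_frames[[1]])
  if (!all(vapply(split_frames, length, 1L) == n_atoms)) {
    cf_stop("confens_topology_error",
            "models in ", path, " differ in atom count; ",
            "a multi-model ensemble must have constant topology")
  }
  first <- split_frames[[1]]
  atoms <- atoms_all[first, , drop = FALSE]
  rownames(atoms) <- NULL
  # topology constant across frames: same names/residues in same order
  key <- function(i) paste(atoms_all$chain_id[i], atoms_all$residue_number[i],
                           atoms_all$atom_name[i], atoms_all$alt_loc[i])
  k1 <- key(first)
  for (f in split_frames[-1]) {
    if (!identical(key(f), k1)) {
      cf_stop("confens_topology_error",
              "models in ", path, " differ in atom ordering")
    }
  }
  dupl <- duplicated(k1)
  if (any(dupl)) {
    cf_stop("confens_parse_error",
            "duplicate atom record within one model: ", k1[dupl][1])
  }

  xyz <- matrix(NA_real_, nrow = n_frames, ncol = 3L * n_atoms)
  for (i in seq_len(n_frames)) {
    sel <- split_frames[[i]]
    xyz[i, ] <- as.vector(rbind(x[sel], y[sel], z[sel]))
  }
  new_pdb_ensemble(atoms, xyz, source_label)
}

new_pdb_ensemble <- function(atoms, xyz, source_label) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3L * nrow(atoms))
  if (!all(is.finite(xyz))) {
    cf_stop("confens_validation_error", "coordinates must be finite")
  }
  structure(
    list(atoms = atoms, xyz = xyz, source_label = source_label),
    class = "pdb_ensemble"
  )
}

#' Number of frames in an ensemble
#' @param x A `pdb_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "pdb_ensemble"))
  nrow(x$xyz)
}

#' Extract one frame's coordinates as an N x 3 matrix
#' @param x A `pdb_ensemble`.
#' @param i Frame index (1-based).
#' @return Numeric matrix with one row per atom (columns x, y, z).
#' @export
frame_coords <- function(x, i = 1L) {
  stopifnot(inherits(x, "pdb_ensemble"))
  if (i < 1L || i > nrow(x$xyz)) {
    cf_stop("confens_validation_error", "frame index out of range: ", i)
  }
  matrix(x$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Keep a subset of frames
#' @param x A `pdb_ensemble`.
#' @param i Integer vector of frame indices.
#' @return A `pdb_ensemble` with the selected frames.
#' @export
subset_frames <- function(x, i) {
  stopifnot(inherits(x, "pdb_ensemble"))
  if (any(i < 1L | i > nrow(x$xyz))) {
    cf_stop("confens_validation_error", "frame index out of range")
  }
  out <- x
  out$xyz <- x$xyz[i, , drop = FALSE]
  lab <- attr(x, "state_labels")
  if (!is.null(lab)) attr(out, "state_labels") <- lab[i]
  out
}

#' @export
print.pdb_ensemble <- function(x, ...) {
  cat("<pdb_ensemble> '", x$source_label, "': ",
      nrow(x$xyz), " frame(s), ", nrow(x$atoms), " atoms, chains: ",
      paste(unique(x$atoms$chain_id), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write an ensemble to a multi-model PDB file
#'
#' Frames are written as `MODEL`/`ENDMDL` blocks when there is more than
#' one; coordinates use the standard fixed-width `%8.3f` fields, so a
#' read/write round trip reproduces coordinates to 0.001 Angstrom.
#'
#' @param x A `pdb_ensemble` (or list of single-frame ensembles sharing one
#'   topology, which are stacked).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (is.list(x) && !inherits(x, "pdb_ensemble")) {
    if (length(x) == 0L) {
      cf_stop("confens_validation_error", "empty frame list")
    }
    if (!all(vapply(x, inherits, TRUE, "pdb_ensemble"))) {
      cf_stop("confens_validation_error",
              "all elements must be pdb_ensemble objects")
    }
    na <- vapply(x, function(e) nrow(e$atoms), 1L)
    if (length(unique(na)) != 1L) {
      cf_stop("confens_topology_error",
              "frames to write have inconsistent atom counts: ",
              paste(unique(na), collapse = ", "))
    }
    xyz <- do.call(rbind, lapply(x, function(e) e$xyz))
    x <- new_pdb_ensemble(x[[1]]$atoms, xyz, x[[1]]$source_label)
  }
  stopifnot(inherits(x, "pdb_ensemble"))
  if (nrow(x$xyz) == 0L) {
    cf_stop("confens_validation_error", "empty frame list")
  }
  a <- x$atoms
  # atom-name column quirk: names shorter than 4 chars start in column 14
  fmt_name <- ifelse(nchar(a$atom_name) >= 4L,
                     sprintf("%-4s", a$atom_name),
                     sprintf(" %-3s", a$atom_name))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- nrow(x$xyz) > 1L
  for (f in seq_len(nrow(x$xyz))) {
    if (multi) writeLines(sprintf("MODEL %8d", f), con)
    co <- matrix(x$xyz[f, ], ncol = 3L, byrow = TRUE)
    writeLines(sprintf(
      "%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      a$record, a$serial %% 100000L, fmt_name, a$alt_loc, a$residue_name,
      a$chain_id, a$residue_number, co[, 1], co[, 2], co[, 3],
      a$occupancy, a$b_factor), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
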