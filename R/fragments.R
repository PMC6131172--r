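#' Define a named atom selection (fragment)
#'
#' A fragment is a residue range plus an atom-name filter, used to pick the
#' coordinates that superposition, fluctuation and clustering operate on
#' (e.g. the lever-arm C-alpha atoms).
#'
#' @param name Fragment name.
#' @param residue_range Inclusive `c(first, last)` range in PDB author
#'   numbering.
#' @param chain_id Optional single chain to restrict to.
#' @param atom_names Character vector of atom names to keep
#'   (default `"CA"`).
#' @return An object of class `fragment_spec`.
#' @examples
#' fragment_spec("lever_arm", c(450, 456))
#' @export
fragment_spec <- function(name, residue_range, chain_id = NULL,
                          atom_names = "CA") {
  if (length(residue_range) != 2L || residue_range[1] > residue_range[2]) {
    cf_stop("confens_validation_error",
            "residue_range must be c(first, last) with first <= last")
  }
  if (length(atom_names) < 1L) {
    cf_stop("confens_validation_error", "atom_names must be non-empty")
  }
  structure(
    list(name = as.character(name),
         residue_range = as.integer(residue_range),
         chain_id = chain_id,
         atom_names = as.character(atom_names)),
    class = "fragment_spec"
  )
}

#' @export
format.fragment_spec <- function(x, ...) {
  paste0("fragment '", x$name, "': residues ", x$residue_range[1], "-",
         x$residue_range[2],
         if (!is.null(x$chain_id)) paste0(", chain ", x$chain_id) else "",
         ", atoms {", paste(x$atom_names, collapse = ","), "}")
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Built-in fragment presets for the GR DNA-binding domain
#'
#' Presets follow human GR author numbering: the lever arm (450-456), the
#' core DBD (421-491), the core DBD as truncated for simulation work
#' (421-490), the dimerization loop (457-465) and the short distorted
#' helix of the second zinc finger (469-473). All are C-alpha selections.
#'
#' @param name One of `"lever_arm"`, `"core_dbd"`, `"core_dbd_md"`,
#'   `"d_loop"`, `"zf_helix"`.
#' @return A [fragment_spec()].
#' @export
fragment_preset <- function(name = c("lever_arm", "core_dbd", "core_dbd_md",
                                     "d_loop", "zf_helix")) {
  name <- match.arg(name)
  ranges <- list(
    lever_arm  = c(450L, 456L),
    core_dbd   = c(421L, 491L),
    core_dbd_md = c(421L, 490L),
    d_loop     = c(457L, 465L),
    zf_helix   = c(469L, 473L)
  )
  fragment_spec(name, ranges[[name]])
}

canonical_atom_rank <- function(atom_name) {
  r <- match(atom_name, c("N", "CA", "C", "O"))
  r[is.na(r)] <- 5L
  r
}

#' Resolve a fragment into an ordered atom selection
#'
#' Selects the atoms of an ensemble matching a [fragment_spec()]. Only
#' `ATOM` records are considered (heteroatoms such as the structural Zn2+
#' are parsed but never enter fitting selections). Atoms are returned in
#' ascending (chain, residue number, canonical backbone order N, CA, C, O,
#' then remaining names alphabetically). For alternate-location duplicates
#' the highest-occupancy conformer is kept (ties broken by alphabetical
#' alt-loc label).
#'
#' @param x A `pdb_ensemble`.
#' @param spec A [fragment_spec()].
#' @param allow_missing If `FALSE` (default), a residue present in the
#'   range but lacking one of the requested atom names raises an error;
#'   if `TRUE`, such residues are dropped from the selection.
#' @return An object of class `atom_selection`: list with `index` (row
#'   indices into `x$atoms`), `atoms` (the selected metadata) and `spec`.
#' @export
select_atoms <- function(x, spec, allow_missing = FALSE) {
  stopifnot(inherits(x, "pdb_ensemble"), inherits(spec, "fragment_spec"))
  a <- x$atoms
  in_range <- a$record == "ATOM" &
    a$residue_number >= spec$residue_range[1] &
    a$residue_number <= spec$residue_range[2]
  if (!is.null(spec$chain_id)) in_range <- in_range & a$chain_id == spec$chain_id
  cand <- which(in_range & a$atom_name %in% spec$atom_names)
  if (length(cand) == 0L) {
    cf_stop("confens_empty_selection_error",
            "no atoms match ", format(spec))
  }
  # alt-loc resolution: one atom per (chain, residue, name)
  key <- paste(a$chain_id[cand], a$residue_number[cand], a$atom_name[cand])
  keep <- unlist(lapply(split(cand, key), function(idx) {
    if (length(idx) == 1L) return(idx)
    occ <- a$occupancy[idx]
    best <- idx[occ == max(occ)]
    best[order(a$alt_loc[best])][1]
  }), use.names = FALSE)

  # completeness per residue actually present in the range
  res_present <- unique(paste(a$chain_id[in_range], a$residue_number[in_range]))
  have <- split(a$atom_name[keep], paste(a$chain_id[keep], a$residue_number[keep]))
  incomplete <- res_present[vapply(res_present, function(k) {
    !all(spec$atom_names %in% have[[k]])
  }, TRUE)]
  if (length(incomplete) > 0L) {
    if (!allow_missing) {
      cf_stop("confens_missing_atom_error",
              "residue(s) ", paste(incomplete, collapse = ", "),
              " lack requested atom(s) for ", format(spec),
              "; use allow_missing = TRUE to drop them")
    }
    keep <- keep[!(paste(a$chain_id[keep], a$residue_number[keep]) %in% incomplete)]
    if (length(keep) == 0L) {
      cf_stop("confens_empty_selection_error",
              "all residues dropped as incomplete for ", format(spec))
    }
  }

  ord <- order(a$chain_id[keep], a$residue_number[keep],
               canonical_atom_rank(a$atom_name[keep]), a$atom_name[keep])
  keep <- keep[ord]
  structure(
    list(index = keep, atoms = a[keep, , drop = FALSE], spec = spec),
    class = "atom_selection"
  )
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("<atom_selection> ", length(x$index), " atoms for ", format(x$spec),
      "\n", sep = "")
  invisible(x)
}

#' Coordinates of a selection for one or all frames
#'
#' @param x A `pdb_ensemble`.
#' @param sel An `atom_selection` from [select_atoms()], or a
#'   [fragment_spec()] (resolved on the fly).
#' @param frames Frame indices (default all).
#' @return A list of N x 3 coordinate matrices, one per requested frame.
#' @export
selection_coords <- function(x, sel, frames = seq_len(nrow(x$xyz))) {
  stopifnot(inherits(x, "pdb_ensemble"))
  if (inherits(sel, "fragment_spec")) sel <- select_atoms(x, sel)
  stopifnot(inherits(sel, "atom_selection"))
  cols <- as.vector(rbind(3L * (sel$index - 1L) + 1L,
                          3L * (sel$index - 1L) + 2L,
                          3L * (sel$index - 1L) + 3L))
  lapply(frames, function(f) {
    matrix(x$xyz[f, cols], ncol = 3L, byrow = TRUE)
  })
}

#' Treat each chain of a structure as one conformation
#'
#' Splits a single-model, multi-chain structure (e.g. a crystal asymmetric
#' unit with several copies of the molecule) into per-chain coordinate
#' sets for a fragment, so the copies can be compared by pairwise RMSD.
#'
#' @param x A `pdb_ensemble` (first frame is used).
#' @param spec A [fragment_spec()] without chain restriction.
#' @param allow_missing Drop residues that are not complete in every chain
#'   (default `FALSE`: mismatched residue sets raise an error).
#' @return Named list of N x 3 matrices, one per chain; names are chain ids.
#' @export
chains_as_conformations <- function(x, spec, allow_missing = FALSE) {
  stopifnot(inherits(x, "pdb_ensemble"), inherits(spec, "fragment_spec"))
  chains <- unique(x$atoms$chain_id[x$atoms$record == "ATOM"])
  sels <- list()
  for (ch in chains) {
    sp <- spec
    sp$chain_id <- ch
    sel <- tryCatch(select_atoms(x, sp, allow_missing = allow_missing),
                    confens_empty_selection_error = function(e) NULL)
    if (!is.null(sel)) sels[[ch]] <- sel
  }
  if (length(sels) < 1L) {
    cf_stop("confens_empty_selection_error",
            "no chain matches ", format(spec))
  }
  res_sets <- lapply(sels, function(s) {
    paste(s$atoms$residue_number, s$atoms$atom_name)
  })
  common <- Reduce(intersect, res_sets)
  mismatched <- any(vapply(res_sets, function(r) length(r) != length(common),
                           TRUE))
  if (mismatched) {
    if (!allow_missing) {
      cf_stop("confens_topology_error",
              "chains cover different residue sets for ", format(spec),
              "; use allow_missing = TRUE to take the intersection")
    }
    if (length(common) == 0L) {
      cf_stop("confens_empty_selection_error",
              "chains share no atoms for ", format(spec))
    }
  }
  out <- lapply(names(sels), function(ch) {
    s <- sels[[ch]]
    keep <- paste(s$atoms$residue_number, s$atoms$atom_name) %in% common
    idx <- s$index[keep]
    cols <- as.vector(rbind(3L * (idx - 1L) + 1L, 3L * (idx - 1L) + 2L,
                            3L * (idx - 1L) + 3L))
    matrix(x$xyz[1, cols], ncol = 3L, byrow = TRUE)
  })
  names(out) <- names(sels)
  out
}
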