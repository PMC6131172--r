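#' Per-frame RMSD time series
#'
#' RMSD of a fragment in every frame to a reference conformation after
#' optimal superposition, the standard stability diagnostic for a
#' trajectory.
#'
#' @param x A `pdb_ensemble`.
#' @param spec A [fragment_spec()] selecting the atoms fitted and measured.
#' @param reference Either a frame index (default 1, i.e. the first frame)
#'   or an N x 3 matrix matching the selection.
#' @return A data frame of class `rmsd_series` with columns `frame` and
#'   `rmsd` (Angstrom); attributes `fit_fragment` and `reference_label`.
#' @export
rmsd_timeseries <- function(x, spec, reference = 1L) {
  stopifnot(inherits(x, "pdb_ensemble"))
  coords <- selection_coords(x, spec)
  if (is.matrix(reference)) {
    ref <- reference
    ref_label <- "external"
  } else {
    if (reference < 1L || reference > length(coords)) {
      cf_stop("confens_validation_error",
              "reference frame index out of range: ", reference)
    }
    ref <- coords[[reference]]
    ref_label <- paste0("frame", reference)
  }
  if (nrow(ref) != nrow(coords[[1]])) {
    cf_stop("confens_topology_error",
            "reference has ", nrow(ref), " atoms, selection has ",
            nrow(coords[[1]]))
  }
  rmsd <- vapply(seq_along(coords), function(f) {
    tryCatch(fitted_rmsd(coords[[f]], ref),
             confens_error = function(e) {
               cf_stop(class(e)[1], "frame ", f, ": ", conditionMessage(e))
             })
  }, 0)
  structure(
    data.frame(frame = seq_along(coords), rmsd = rmsd),
    class = c("rmsd_series", "data.frame"),
    fit_fragment = spec, reference_label = ref_label
  )
}

#' Per-residue RMSF profile
#'
#' Root mean square fluctuation of each residue about its mean position.
#' All frames are first superposed, on the `fit_spec` atoms, onto the
#' iteratively fitted [average_structure()] of that selection; the same
#' transforms are then applied to the `measure_spec` atoms and
#' `RMSF_i = sqrt(mean_t ||x_i(t) - <x_i>||^2)` is evaluated there. A
#' residue contributing several selected atoms reports the RMS of their
#' atomic RMSFs. Fitting on a rigid core while measuring everywhere keeps
#' flexible-region fluctuation from being absorbed into the fit.
#'
#' @param x A `pdb_ensemble` with >= 2 frames.
#' @param fit_spec [fragment_spec()] defining the superposition atoms
#'   (typically the rigid core, C-alpha).
#' @param measure_spec [fragment_spec()] defining the atoms profiled;
#'   default `NULL` measures every `CA` atom in the structure.
#' @return Data frame of class `rmsf_profile` with columns
#'   `residue_number` and `rmsf` (Angstrom); attribute `n_frames`.
#' @export
rmsf <- function(x, fit_spec, measure_spec = NULL) {
  stopifnot(inherits(x, "pdb_ensemble"))
  if (nrow(x$xyz) < 2L) {
    cf_stop("confens_validation_error", "RMSF needs at least 2 frames")
  }
  if (is.null(measure_spec)) {
    rng <- range(x$atoms$residue_number[x$atoms$record == "ATOM"])
    measure_spec <- fragment_spec("all_ca", rng, atom_names = "CA")
  }
  fit_coords <- selection_coords(x, fit_spec)
  msel <- select_atoms(x, measure_spec)
  mcoords <- selection_coords(x, msel)
  avg <- average_structure(fit_coords)
  moved <- vector("list", length(fit_coords))
  for (f in seq_along(fit_coords)) {
    tr <- kabsch_fit(fit_coords[[f]], avg)
    moved[[f]] <- apply_transform(tr, mcoords[[f]])
  }
  mean_pos <- Reduce(`+`, moved) / length(moved)
  sq <- Reduce(`+`, lapply(moved, function(m) {
    d <- m - mean_pos
    rowSums(d * d)
  })) / length(moved)
  atom_rmsf <- sqrt(sq)
  res <- msel$atoms$residue_number
  per_res <- vapply(split(atom_rmsf, res), function(v) sqrt(mean(v^2)), 0)
  structure(
    data.frame(residue_number = as.integer(names(per_res)),
               rmsf = unname(per_res)),
    class = c("rmsf_profile", "data.frame"),
    n_frames = nrow(x$xyz), fit_fragment = fit_spec,
    measure_fragment = measure_spec
  )
}

#' Write an RMSD series or RMSF profile as TSV with a metadata header
#' @param x An `rmsd_series` or `rmsf_profile`.
#' @param path Output path.
#' @param meta Named list of extra metadata recorded as `# key: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path, meta = list()) {
  stopifnot(is.data.frame(x))
  con <- file(path, "w")
  on.exit(close(con))
  base_meta <- list(n_rows = nrow(x))
  fit <- attr(x, "fit_fragment")
  if (!is.null(fit)) base_meta$fit_fragment <- format(fit)
  for (nm in names(c(base_meta, meta))) {
    writeLines(sprintf("# %s: %s", nm, c(base_meta, meta)[[nm]]), con)
  }
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
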