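#' Compare conformations of one or more structures by pairwise RMSD
#'
#' Treats each chain (default) or each model of the input structure(s) as
#' one conformation of the molecule, resolves the fragment selection in
#' each, and reports the full Kabsch-fitted RMSD matrix with its mean --
#' the standard summary of how similar crystallographically independent
#' copies are.
#'
#' @param x A `pdb_ensemble`, a path to a PDB file, or a list of either
#'   (conformations are pooled across inputs).
#' @param fragment A [fragment_spec()] (default core DBD 421-491,
#'   C-alpha).
#' @param by `"chain"` (each chain of model 1 is a conformation) or
#'   `"model"` (each model is a conformation).
#' @param allow_missing Drop residues not complete in every conformation.
#' @return An `rmsd_matrix` (see [pairwise_rmsd_matrix()]).
#' @export
compare_structures <- function(x, fragment = fragment_preset("core_dbd"),
                               by = c("chain", "model"),
                               allow_missing = FALSE) {
  by <- match.arg(by)
  if (!is.list(x) || inherits(x, "pdb_ensemble")) x <- list(x)
  confs <- list()
  for (item in x) {
    ens <- if (inherits(item, "pdb_ensemble")) item else read_pdb(item)
    if (by == "chain") {
      cc <- chains_as_conformations(ens, fragment,
                                    allow_missing = allow_missing)
      names(cc) <- paste0(ens$source_label, ":", names(cc))
    } else {
      sel <- select_atoms(ens, fragment, allow_missing = allow_missing)
      cc <- selection_coords(ens, sel)
      names(cc) <- paste0(ens$source_label, ":model", seq_along(cc))
    }
    confs <- c(confs, cc)
  }
  pairwise_rmsd_matrix(confs)
}

#' Full single-trajectory analysis bundle
#'
#' Runs the complete per-trajectory pipeline: even subsampling, RMSD time
#' series of the fit fragment, per-residue RMSF, per-residue phi/psi
#' variability, angular-state assignment of one chosen dihedral, and
#' fixed-radius RMSD clustering of the analysis fragment.
#'
#' @param x A `pdb_ensemble` (trajectory frames).
#' @param config A [cluster_config()]; `config$fragment` is the clustered
#'   fragment and the RMSD-series fragment.
#' @param fit_fragment Fragment for RMSF superposition (default: all
#'   C-alpha atoms present, i.e. the whole chain as rigid core).
#' @param state_residue Residue number whose psi series is classified
#'   into `states`; `NULL` skips state assignment.
#' @param states List of [angular_state()]s (default [his453_states()]).
#' @param n_frames Frames to subsample (default
#'   `min(config$n_frames_single, n_frames(x))`).
#' @return List of class `trajectory_analysis` with elements `rmsd`,
#'   `rmsf`, `variability`, `states`, `clusters`, `meta`.
#' @export
analyze_trajectory <- function(x, config = cluster_config(),
                               fit_fragment = NULL,
                               state_residue = NULL,
                               states = his453_states(),
                               n_frames = NULL) {
  stopifnot(inherits(x, "pdb_ensemble"), inherits(config, "cluster_config"))
  stage <- "subsample"
  out <- tryCatch({
    if (is.null(n_frames)) {
      n_frames <- min(config$n_frames_single, nrow(x$xyz))
    }
    traj <- subsample_evenly(x, n_frames)
    if (is.null(fit_fragment)) {
      rng <- range(traj$atoms$residue_number[traj$atoms$record == "ATOM"])
      fit_fragment <- fragment_spec("all_ca", rng, atom_names = "CA")
    }
    stage <- "rmsd_timeseries"
    rmsd_ser <- rmsd_timeseries(traj, config$fragment)
    stage <- "rmsf"
    rmsf_prof <- rmsf(traj, fit_fragment)
    stage <- "dihedral_variability"
    vari <- variability_profile(traj)
    stage <- "state_assignment"
    st <- NULL
    if (!is.null(state_residue)) {
      di <- backbone_dihedrals(traj, c(state_residue, state_residue))
      psi <- di[di$angle == "psi", ]
      st <- assign_states(psi$value, states)
    }
    stage <- "clustering"
    cl <- kclust(traj, config)
    list(rmsd = rmsd_ser, rmsf = rmsf_prof, variability = vari,
         states = st, clusters = cl)
  }, confens_error = function(e) {
    cf_stop(class(e)[1], "stage '", stage, "' failed for '",
            x$source_label, "': ", conditionMessage(e))
  })
  out$meta <- list(
    source_label = x$source_label,
    n_frames_input = nrow(x$xyz),
    n_frames_analyzed = n_frames,
    config_hash = config_hash(config),
    version = as.character(utils::packageVersion("confens"))
  )
  class(out) <- "trajectory_analysis"
  out
}

#' @export
print.trajectory_analysis <- function(x, ...) {
  cat("<trajectory_analysis> '", x$meta$source_label, "': ",
      x$meta$n_frames_analyzed, " frames analyzed\n", sep = "")
  cat("  mean RMSD ", round(mean(x$rmsd$rmsd), 3), " A; mean RMSF ",
      round(mean(x$rmsf$rmsf), 3), " A; ", length(x$clusters$sizes),
      " cluster(s)\n", sep = "")
  if (!is.null(x$states)) {
    cat("  state transitions:", attr(x$states, "n_transitions"), "\n")
  }
  invisible(x)
}

#' Combined clustering of several trajectories with overlap report
#'
#' Convenience wrapper: [combined_cluster()] on the named trajectories
#' followed by [overlap_report()] at the configured occupancy floor.
#'
#' @param trajectories Named list of `pdb_ensemble`s (or lists of
#'   coordinate matrices).
#' @param config A [cluster_config()].
#' @return List of class `combined_analysis` with elements `model`,
#'   `occupancy`, `overlap`, `meta`.
#' @export
combine_trajectories <- function(trajectories, config = cluster_config()) {
  res <- combined_cluster(trajectories, config)
  ov <- overlap_report(res$occupancy, config$occupancy_floor)
  structure(
    list(model = res$model, occupancy = res$occupancy, overlap = ov,
         meta = list(config_hash = config_hash(config),
                     sources = rownames(res$occupancy),
                     version = as.character(utils::packageVersion("confens")))),
    class = "combined_analysis"
  )
}

#' @export
print.combined_analysis <- function(x, ...) {
  cat("<combined_analysis> sources:",
      paste(x$meta$sources, collapse = ", "), "\n")
  print(x$model)
  print(x$overlap)
  invisible(x)
}

config_hash <- function(config) {
  fnv1a32(paste(
    config$radius, format(config$fragment), config$n_frames_single,
    config$n_frames_combined_per_source, config$max_iter,
    config$occupancy_floor, collapse = "|"
  ))
}

#' Write a trajectory or combined analysis to disk
#'
#' Emits machine-readable outputs, each stamped with the config hash:
#' TSVs for the RMSD series, RMSF profile, variability profile, state
#' assignments and cluster assignments; JSON for the overlap report;
#' a multi-model PDB is not written for synthetic C-alpha centroids --
#' centroid coordinates go into `centroids.tsv`. On any failure, files
#' already written for this call are removed.
#'
#' @param x A `trajectory_analysis` or `combined_analysis`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit <- function(rel, writer) {
    path <- file.path(dir, rel)
    writer(path)
    written <<- c(written, path)
  }
  cleanup_on_error <- function(expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(e)
    })
  }
  if (inherits(x, "trajectory_analysis")) {
    meta <- list(config_hash = x$meta$config_hash,
                 source = x$meta$source_label,
                 version = x$meta$version)
    cleanup_on_error({
      emit("rmsd_series.tsv", function(p) write_profile_tsv(x$rmsd, p, meta))
      emit("rmsf_profile.tsv", function(p) write_profile_tsv(x$rmsf, p, meta))
      emit("variability.tsv",
           function(p) write_profile_tsv(x$variability, p, meta))
      if (!is.null(x$states)) {
        emit("state_assignments.tsv",
             function(p) write_profile_tsv(x$states, p, meta))
      }
      emit("cluster_assignments.tsv", function(p) {
        df <- data.frame(frame = seq_along(x$clusters$assignments),
                         source = x$clusters$source_labels,
                         cluster = x$clusters$assignments)
        write_profile_tsv(df, p, meta)
      })
    })
  } else if (inherits(x, "combined_analysis")) {
    meta <- list(config_hash = x$meta$config_hash, version = x$meta$version)
    cleanup_on_error({
      emit("cluster_assignments.tsv", function(p) {
        df <- data.frame(frame = seq_along(x$model$assignments),
                         source = x$model$source_labels,
                         cluster = x$model$assignments)
        write_profile_tsv(df, p, meta)
      })
      emit("occupancy.tsv", function(p) {
        con <- file(p, "w"); on.exit(close(con))
        writeLines(sprintf("# config_hash: %s", meta$config_hash), con)
        utils::write.table(as.data.frame(unclass(x$occupancy)), con,
                           sep = "\t", quote = FALSE, col.names = NA)
      })
      emit("overlap.json", function(p) {
        jsonlite::write_json(
          list(config_hash = meta$config_hash,
               floor = attr(x$overlap, "floor"),
               pairs = lapply(unclass(x$overlap), function(pp) {
                 list(sources = pp$sources, n_shared = pp$n_shared,
                      shared_clusters = pp$shared_clusters)
               })),
          p, auto_unbox = TRUE, digits = NA)
      })
    })
  } else {
    cf_stop("confens_validation_error",
            "write_outputs handles trajectory_analysis or combined_analysis")
  }
  invisible(written)
}
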