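#' Configuration for fixed-radius RMSD clustering
#'
#' Bundles the parameters of the conformational clustering analysis. The
#' defaults reproduce the published protocol: a 2.3 Angstrom RMSD cutoff
#' radius on lever-arm C-alpha conformations, 50,000 evenly spaced
#' snapshots per single trajectory, 5,000 per source in combined runs,
#' and a 10% occupancy floor for calling a cluster shared between
#' sources.
#'
#' @param radius Cluster cutoff radius in Angstrom (> 0; default 2.3).
#' @param fragment [fragment_spec()] clustered on (default lever arm
#'   450-456, C-alpha).
#' @param n_frames_single Snapshots drawn from a single trajectory
#'   (default 50000).
#' @param n_frames_combined_per_source Snapshots per source in combined
#'   clustering (default 5000).
#' @param max_iter Maximum refinement iterations (default 100).
#' @param occupancy_floor Minimum per-source occupancy for a shared
#'   cluster (default 0.10).
#' @return Object of class `cluster_config`.
#' @export
cluster_config <- function(radius = 2.3,
                           fragment = fragment_preset("lever_arm"),
                           n_frames_single = 50000L,
                           n_frames_combined_per_source = 5000L,
                           max_iter = 100L,
                           occupancy_floor = 0.10) {
  if (!is_scalar_num(radius) || radius <= 0) {
    cf_stop("confens_validation_error", "radius must be > 0")
  }
  if (n_frames_single < 1L || n_frames_combined_per_source < 1L) {
    cf_stop("confens_validation_error", "frame counts must be >= 1")
  }
  if (!is_scalar_num(occupancy_floor) ||
      occupancy_floor <= 0 || occupancy_floor >= 1) {
    cf_stop("confens_validation_error", "occupancy_floor must be in (0, 1)")
  }
  stopifnot(inherits(fragment, "fragment_spec"))
  structure(
    list(radius = radius, fragment = fragment,
         n_frames_single = as.integer(n_frames_single),
         n_frames_combined_per_source = as.integer(n_frames_combined_per_source),
         max_iter = as.integer(max_iter),
         occupancy_floor = occupancy_floor),
    class = "cluster_config"
  )
}

#' Evenly spaced subsample of a trajectory
#'
#' Deterministic subsampling at indices `floor(j * L / n)` for
#' `j = 0 ... n-1` (1-based in R: index `floor(j * L / n) + 1`), so the
#' first frame is always included and coverage is uniform in time.
#'
#' @param x A `pdb_ensemble`, a list of frames, or an integer trajectory
#'   length `L`.
#' @param n Number of frames to keep (`1 <= n <= L`).
#' @return Object of the same kind as `x` subset to `n` frames, or, when
#'   `x` is a length, the integer index vector itself.
#' @export
subsample_evenly <- function(x, n) {
  len <- if (inherits(x, "pdb_ensemble")) nrow(x$xyz)
         else if (is.list(x)) length(x)
         else as.integer(x)
  n <- as.integer(n)
  if (n < 1L || n > len) {
    cf_stop("confens_validation_error",
            "cannot draw ", n, " frames from a trajectory of length ", len)
  }
  idx <- as.integer(floor((seq_len(n) - 1L) * len / n)) + 1L
  if (inherits(x, "pdb_ensemble")) return(subset_frames(x, idx))
  if (is.list(x)) return(x[idx])
  idx
}

#' Fixed-radius RMSD k-means clustering of conformations
#'
#' Clusters fragment conformations in pairwise Kabsch-fitted RMSD space,
#' in the style of the MMTSB `kclust` tool. Two phases:
#' \enumerate{
#'   \item Seeding: frames are scanned in order; each frame joins the
#'     nearest existing centroid if its fitted RMSD is within `radius`,
#'     otherwise it seeds a new cluster at itself.
#'   \item Refinement (k-means): each centroid is recomputed as the
#'     coordinate-wise mean of its members after fitting each member onto
#'     the current centroid; every frame is then reassigned to its
#'     nearest centroid (no radius test); emptied clusters are dropped.
#'     Iterate until assignments stop changing or `max_iter`.
#' }
#' The algorithm is deterministic given the frame order. Clusters are
#' reported in decreasing size order, ties broken by seeding order.
#'
#' @param frames List of N x 3 coordinate matrices (equal atom counts), or
#'   a `pdb_ensemble` (then `config$fragment` selects the atoms).
#' @param config A [cluster_config()]; or pass `radius`/`max_iter`
#'   directly.
#' @param radius,max_iter Convenience overrides of the config values.
#' @param source_labels Optional per-frame provenance labels.
#' @return Object of class `kclust`: list with `centroids` (list of N x 3
#'   matrices), `assignments` (per-frame cluster index, size-ordered ids),
#'   `sizes`, `source_labels`, `radius`, `converged`, `n_iterations`.
#' @examples
#' refs <- make_reference_states(n_atoms = 12, k_states = 2,
#'                               inter_state_rmsd_target = 6, seed = 1)
#' frames <- rep(refs, each = 5)
#' fit <- kclust(frames, radius = 2.3)
#' fit$sizes
#' @export
kclust <- function(frames, config = cluster_config(),
                   radius = config$radius, max_iter = config$max_iter,
                   source_labels = NULL) {
  if (inherits(frames, "pdb_ensemble")) {
    if (is.null(source_labels)) {
      source_labels <- rep(frames$source_label, nrow(frames$xyz))
    }
    frames <- selection_coords(frames, config$fragment)
  }
  if (!is.list(frames) || length(frames) < 1L) {
    cf_stop("confens_validation_error", "need at least 1 frame")
  }
  nf <- length(frames)
  frames <- lapply(frames, as.matrix)
  dims <- vapply(frames, nrow, 1L)
  if (length(unique(dims)) != 1L) {
    cf_stop("confens_topology_error",
            "frames differ in atom count: ", paste(unique(dims), collapse = ", "))
  }
  if (is.null(source_labels)) source_labels <- rep("frames", nf)

  dist_to <- function(f, centroid) {
    tryCatch(fitted_rmsd(frames[[f]], centroid),
             error = function(e) {
               cf_stop("confens_degenerate_geometry_error",
                       "frame ", f, ": ", conditionMessage(e))
             })
  }

  # --- seeding pass ---
  centroids <- list(frames[[1]])
  assign_vec <- integer(nf)
  assign_vec[1] <- 1L
  if (nf > 1L) {
    for (f in 2:nf) {
      d <- vapply(centroids, function(cen) dist_to(f, cen), 0)
      best <- which.min(d)
      if (d[best] <= radius) {
        assign_vec[f] <- best
      } else {
        centroids[[length(centroids) + 1L]] <- frames[[f]]
        assign_vec[f] <- length(centroids)
      }
    }
  }
  seed_order <- seq_along(centroids)

  # --- k-means refinement ---
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # recompute centroids as fitted member means
    for (k in seq_along(centroids)) {
      members <- which(assign_vec == k)
      fitted <- lapply(members, function(f) {
        apply_transform(kabsch_fit(frames[[f]], centroids[[k]]), frames[[f]])
      })
      centroids[[k]] <- Reduce(`+`, fitted) / length(fitted)
    }
    new_assign <- vapply(seq_len(nf), function(f) {
      which.min(vapply(centroids, function(cen) dist_to(f, cen), 0))
    }, 1L)
    # drop emptied clusters, keep seed-order bookkeeping
    occupied <- sort(unique(new_assign))
    if (length(occupied) < length(centroids)) {
      remap <- match(seq_along(centroids), occupied)
      new_assign <- remap[new_assign]
      centroids <- centroids[occupied]
      seed_order <- seed_order[occupied]
    }
    if (length(new_assign) == length(assign_vec) &&
        all(new_assign == assign_vec)) {
      assign_vec <- new_assign
      converged <- TRUE
      break
    }
    assign_vec <- new_assign
  }

  sizes <- tabulate(assign_vec, nbins = length(centroids))
  ord <- order(-sizes, seed_order)
  rank_of <- match(seq_along(centroids), ord)
  structure(
    list(centroids = centroids[ord],
         assignments = rank_of[assign_vec],
         sizes = sizes[ord],
         source_labels = source_labels,
         radius = radius,
         converged = converged,
         n_iterations = it),
    class = "kclust"
  )
}

#' @export
print.kclust <- function(x, ...) {
  cat("<kclust> ", length(x$sizes), " cluster(s), ",
      length(x$assignments), " frames, radius ", x$radius, " A",
      if (!x$converged) "  [NOT converged]" else "", "\n", sep = "")
  cat("sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.kclust <- function(object, ...) {
  occ <- object$sizes / length(object$assignments)
  out <- data.frame(cluster = seq_along(object$sizes),
                    size = object$sizes,
                    fraction = occ)
  cat("Fixed-radius RMSD clustering (radius ", object$radius, " A): ",
      length(object$sizes), " clusters over ", length(object$assignments),
      " frames; converged after ", object$n_iterations, " iteration(s)\n",
      sep = "")
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
#' @importFrom graphics barplot
plot.kclust <- function(x, ...) {
  graphics::barplot(x$sizes / length(x$assignments),
                    names.arg = seq_along(x$sizes),
                    xlab = "cluster (decreasing frequency)",
                    ylab = "fraction of frames", ...)
  invisible(x)
}

#' @export
fitted.kclust <- function(object, ...) object$assignments

#' Combined clustering across labeled trajectories
#'
#' Subsamples `config$n_frames_combined_per_source` evenly spaced frames
#' from each source, pools them with their provenance labels, runs one
#' [kclust()] on the pool, and tabulates per-source cluster occupancies,
#' revealing which conformations different molecules share.
#'
#' @param trajectories Named list; each element is a list of N x 3
#'   matrices or a `pdb_ensemble` (selected via `config$fragment`).
#' @param config A [cluster_config()].
#' @return List with `model` (a `kclust`) and `occupancy` (class
#'   `occupancy_table`: matrix source x cluster, rows summing to 1).
#' @export
combined_cluster <- function(trajectories, config = cluster_config()) {
  if (!is.list(trajectories) || length(trajectories) < 2L) {
    cf_stop("confens_validation_error", "need at least 2 sources")
  }
  labs <- names(trajectories)
  if (is.null(labs) || any(labs == "")) {
    labs <- paste0("source", seq_along(trajectories))
  }
  per_source <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    if (inherits(tr, "pdb_ensemble")) {
      tr <- selection_coords(tr, config$fragment)
    }
    n <- min(config$n_frames_combined_per_source, length(tr))
    if (config$n_frames_combined_per_source > length(tr)) {
      cf_stop("confens_validation_error",
              "source '", labs[i], "' has ", length(tr),
              " frames, fewer than the ", config$n_frames_combined_per_source,
              " requested")
    }
    subsample_evenly(tr, n)
  })
  dims <- vapply(per_source, function(s) nrow(s[[1]]), 1L)
  if (length(unique(dims)) != 1L) {
    bad <- paste(labs, dims, collapse = ", ")
    cf_stop("confens_topology_error",
            "sources have incompatible fragment topology (atoms): ", bad)
  }
  pool <- do.call(c, per_source)
  pool_labels <- rep(labs, vapply(per_source, length, 1L))
  model <- kclust(pool, config, source_labels = pool_labels)
  k <- length(model$sizes)
  occ <- matrix(0, length(labs), k,
                dimnames = list(labs, paste0("cluster", seq_len(k))))
  for (s in labs) {
    in_s <- model$source_labels == s
    occ[s, ] <- tabulate(model$assignments[in_s], nbins = k) / sum(in_s)
  }
  out_occ <- structure(occ, class = c("occupancy_table", "matrix"))
  list(model = model, occupancy = out_occ)
}

#' @export
print.occupancy_table <- function(x, digits = 3, ...) {
  cat("<occupancy_table> fraction of each source's frames per cluster\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Shared clusters between sources
#'
#' A cluster is shared by a pair of sources when both occupy it with at
#' least `floor` of their frames (strict `>=`).
#'
#' @param table An `occupancy_table` from [combined_cluster()].
#' @param floor Occupancy floor (default 0.10).
#' @return Object of class `overlap_report`: list with one element per
#'   unordered source pair, each holding `sources`, `shared_clusters`
#'   (integer ids), `occupancies` (2 x n matrix) and `n_shared`.
#' @export
overlap_report <- function(table, floor = 0.10) {
  stopifnot(inherits(table, "occupancy_table"))
  if (any(table < 0 | table > 1) ||
      any(abs(rowSums(table) - 1) > 1e-9)) {
    cf_stop("confens_validation_error",
            "occupancy rows must lie in [0,1] and sum to 1")
  }
  src <- rownames(table)
  pairs <- utils::combn(seq_along(src), 2, simplify = FALSE)
  out <- lapply(pairs, function(p) {
    shared <- which(table[p[1], ] >= floor & table[p[2], ] >= floor)
    list(sources = src[p],
         shared_clusters = as.integer(shared),
         occupancies = table[p, shared, drop = FALSE],
         n_shared = length(shared))
  })
  names(out) <- vapply(pairs, function(p) paste(src[p], collapse = "|"), "")
  structure(out, class = "overlap_report", floor = floor)
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> occupancy floor:", attr(x, "floor"), "\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %d shared cluster(s)%s\n", nm, x[[nm]]$n_shared,
                if (x[[nm]]$n_shared > 0)
                  paste0(" [", paste(x[[nm]]$shared_clusters, collapse = ","), "]")
                else ""))
  }
  invisible(x)
}
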