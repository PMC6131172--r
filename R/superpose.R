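#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two paired coordinate sets, via SVD of the cross-covariance matrix.
#' Reflections are excluded: when the optimal orthogonal matrix would be
#' improper, the sign of the smallest singular vector is flipped, so
#' molecular chirality is always preserved.
#'
#' @param mobile N x 3 matrix moved onto the reference.
#' @param reference N x 3 matrix.
#' @return A list of class `rigid_transform` with elements `rotation`
#'   (3 x 3 proper orthogonal), `translation` (length-3), and `rmsd`
#'   (Angstrom). The transform maps `x` to `x %*% rotation + translation`.
#' @details Requires N >= 3 non-collinear points: the centered
#'   configuration must have rank >= 2 or a degenerate-geometry error is
#'   raised.
#' @examples
#' p <- matrix(rnorm(12), 4, 3)
#' kabsch_fit(p, p)$rmsd  # 0
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference))) {
    cf_stop("confens_validation_error",
            "coordinate sets differ in size: ", nrow(mobile), " vs ",
            nrow(reference), " atoms")
  }
  n <- nrow(mobile)
  if (n < 3L) {
    cf_stop("confens_degenerate_geometry_error",
            "superposition needs at least 3 atoms, got ", n)
  }
  cm_p <- colMeans(mobile); cm_q <- colMeans(reference)
  p <- sweep(mobile, 2, cm_p); q <- sweep(reference, 2, cm_q)
  dp <- svd(p, nu = 0, nv = 0)$d; dq <- svd(q, nu = 0, nv = 0)$d
  scale <- max(dp[1], dq[1], 1e-12)
  if (dp[2] < 1e-8 * scale || dq[2] < 1e-8 * scale) {
    cf_stop("confens_degenerate_geometry_error",
            "centered configuration has rank < 2 (collinear points); ",
            "rotation is not determined")
  }
  h <- crossprod(p, q)                       # 3x3 cross-covariance
  sv <- svd(h)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  rot <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  trans <- as.vector(cm_q - cm_p %*% rot)
  diff <- p %*% rot - q
  rmsd <- sqrt(sum(diff * diff) / n)
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform A `rigid_transform` from [kabsch_fit()].
#' @param x N x 3 coordinate matrix.
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  sweep(as.matrix(x) %*% transform$rotation, 2, -transform$translation)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

# rmsd only, skipping transform construction (hot path for clustering)
fitted_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  # the singular-value identity below carries ~1e-7 cancellation noise;
  # identical inputs (e.g. the reference frame of a time series) are 0
  if (identical(dim(mobile), dim(reference)) && all(mobile == reference)) {
    return(0)
  }
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  d <- svd(crossprod(p, q), nu = 3, nv = 3)
  s <- sign(det(d$u %*% t(d$v)))
  if (s == 0) s <- 1
  msd <- (sum(p * p) + sum(q * q) - 2 * (d$d[1] + d$d[2] + s * d$d[3])) / n
  sqrt(max(msd, 0))
}

#' All-against-all fitted RMSD matrix
#'
#' Computes the Kabsch-fitted RMSD between every unordered pair of
#' conformations, plus the mean over the upper triangle, the standard
#' summary of structural spread in an ensemble of crystallographically
#' independent copies.
#'
#' @param frames List of N x 3 matrices with equal atom counts (>= 2).
#' @param labels Optional character labels (default names of `frames` or
#'   `"frame<i>"`).
#' @return A symmetric matrix of class `rmsd_matrix` with zero diagonal;
#'   attribute `mean_offdiag` holds the mean over the C(n,2) pairs.
#' @export
pairwise_rmsd_matrix <- function(frames, labels = NULL) {
  if (!is.list(frames) || length(frames) < 2L) {
    cf_stop("confens_validation_error", "need at least 2 conformations")
  }
  if (is.null(labels)) {
    labels <- names(frames)
    if (is.null(labels)) labels <- paste0("frame", seq_along(frames))
  }
  n <- length(frames)
  dims <- vapply(frames, nrow, 1L)
  if (length(unique(dims)) != 1L) {
    cf_stop("confens_topology_error", "conformations differ in atom count: ",
            paste(unique(dims), collapse = ", "))
  }
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      r <- tryCatch(
        kabsch_fit(frames[[i]], frames[[j]])$rmsd,
        confens_error = function(e) {
          cf_stop(class(e)[1], "pair (", labels[i], ", ", labels[j], "): ",
                  conditionMessage(e))
        })
      m[i, j] <- m[j, i] <- r
    }
  }
  structure(m, class = c("rmsd_matrix", "matrix"),
            mean_offdiag = mean(m[upper.tri(m)]))
}

#' @export
print.rmsd_matrix <- function(x, digits = 3, ...) {
  cat("<rmsd_matrix> (Angstrom),", nrow(x), "conformations\n")
  print(round(unclass(x), digits))
  cat("mean pairwise RMSD:",
      format(attr(x, "mean_offdiag"), digits = 4), "A\n")
  invisible(x)
}

#' Write an RMSD matrix as TSV (labels in header) or JSON
#' @param x An `rmsd_matrix`.
#' @param path Output path; format chosen by extension (`.json` or TSV).
#' @return `path`, invisibly.
#' @export
write_rmsd_matrix <- function(x, path) {
  stopifnot(inherits(x, "rmsd_matrix"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(labels = rownames(x), values = unclass(x),
           mean_pairwise_rmsd = attr(x, "mean_offdiag")),
      path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  } else {
    utils::write.table(as.data.frame(unclass(x)), path, sep = "\t",
                       quote = FALSE, row.names = TRUE, col.names = NA)
  }
  invisible(path)
}

#' Iteratively fitted average structure of an ensemble
#'
#' Computes the mean conformation: every frame is superposed onto the
#' running mean (initialized at the first frame), the coordinate-wise mean
#' is recomputed, and the two steps repeat until the mean moves by less
#' than `tol` or `max_iter` is reached.
#'
#' @param frames List of N x 3 matrices (>= 1).
#' @param tol Convergence threshold on the maximum per-coordinate shift of
#'   the mean, in Angstrom (default 1e-6).
#' @param max_iter Maximum iterations (default 50).
#' @return N x 3 matrix with attributes `iterations` and `converged`. On
#'   non-convergence the result is still returned with
#'   `converged = FALSE`.
#' @export
average_structure <- function(frames, tol = 1e-6, max_iter = 50L) {
  if (!is.list(frames) || length(frames) < 1L) {
    cf_stop("confens_validation_error", "need at least 1 frame")
  }
  ref <- as.matrix(frames[[1]])
  if (length(frames) == 1L) {
    attr(ref, "iterations") <- 0L
    attr(ref, "converged") <- TRUE
    return(ref)
  }
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    fitted <- lapply(frames, function(f) {
      apply_transform(kabsch_fit(as.matrix(f), ref), as.matrix(f))
    })
    new_mean <- Reduce(`+`, fitted) / length(fitted)
    shift <- max(abs(new_mean - ref))
    ref <- new_mean
    if (shift < tol) { converged <- TRUE; break }
  }
  attr(ref, "iterations") <- it
  attr(ref, "converged") <- converged
  ref
}
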