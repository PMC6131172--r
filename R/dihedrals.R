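#' Signed torsion angle of four points
#'
#' The dihedral about the p2-p3 axis via the atan2 formulation, IUPAC sign
#' convention: cis = 0, trans = 180, positive for clockwise rotation of
#' the far bond viewed from p2 towards p3. Returned in degrees in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  scale <- max(vnorm(b1), vnorm(b2), vnorm(b3))
  if (min(vnorm(b1), vnorm(b2), vnorm(b3)) < 1e-9 * max(scale, 1)) {
    cf_stop("confens_degenerate_geometry_error",
            "coincident consecutive points in dihedral")
  }
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (vnorm(n1) < 1e-9 * scale^2 || vnorm(n2) < 1e-9 * scale^2) {
    cf_stop("confens_degenerate_geometry_error",
            "three consecutive points are collinear; dihedral undefined")
  }
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * b2) / vnorm(b2)
  wrap180(rad2deg(atan2(y, x)))
}

#' Backbone phi/psi angles over all frames
#'
#' Computes the backbone torsions per residue and frame:
#' phi(i) from C(i-1), N(i), CA(i), C(i) and psi(i) from N(i), CA(i),
#' C(i), N(i+1). Angles undefined at chain termini, or whose supporting
#' atoms are absent, are reported as `NA` rather than fabricated.
#'
#' @param x A `pdb_ensemble`.
#' @param residue_range Inclusive `c(first, last)` residue range.
#' @param chain_id Chain to analyze; required when the range spans several
#'   chains.
#' @return Data frame with columns `frame`, `residue_number`, `angle`
#'   (`"phi"`/`"psi"`) and `value` (degrees in (-180, 180], `NA` if
#'   undefined).
#' @export
backbone_dihedrals <- function(x, residue_range = NULL, chain_id = NULL) {
  stopifnot(inherits(x, "pdb_ensemble"))
  a <- x$atoms
  prot <- a$record == "ATOM"
  if (is.null(residue_range)) {
    residue_range <- range(a$residue_number[prot])
  }
  if (is.null(chain_id)) {
    ch <- unique(a$chain_id[prot & a$residue_number >= residue_range[1] &
                              a$residue_number <= residue_range[2]])
    if (length(ch) > 1L) {
      cf_stop("confens_validation_error",
              "residue range spans chains ", paste(ch, collapse = ", "),
              "; specify chain_id")
    }
    chain_id <- ch
  }
  # lookup: atom row for (residue, name), backbone only, alt-loc resolved
  bb <- which(prot & a$chain_id == chain_id &
                a$atom_name %in% c("N", "CA", "C"))
  key <- paste(a$residue_number[bb], a$atom_name[bb])
  row_of <- vapply(split(bb, key), function(idx) {
    if (length(idx) == 1L) return(idx)
    occ <- a$occupancy[idx]
    best <- idx[occ == max(occ)]
    best[order(a$alt_loc[best])][1]
  }, 1L)
  get_row <- function(resno, name) {
    r <- row_of[paste(resno, name)]
    if (is.na(r)) NA_integer_ else r
  }
  residues <- seq(residue_range[1], residue_range[2])
  nf <- nrow(x$xyz)
  coords_at <- function(f, row) x$xyz[f, (3 * (row - 1) + 1):(3 * row)]
  recs <- vector("list", 2L * length(residues))
  k <- 0L
  for (resno in residues) {
    phi_rows <- c(get_row(resno - 1L, "C"), get_row(resno, "N"),
                  get_row(resno, "CA"), get_row(resno, "C"))
    psi_rows <- c(get_row(resno, "N"), get_row(resno, "CA"),
                  get_row(resno, "C"), get_row(resno + 1L, "N"))
    for (ang in c("phi", "psi")) {
      rows <- if (ang == "phi") phi_rows else psi_rows
      k <- k + 1L
      if (anyNA(rows)) {
        recs[[k]] <- data.frame(frame = seq_len(nf), residue_number = resno,
                                angle = ang, value = NA_real_)
      } else {
        vals <- vapply(seq_len(nf), function(f) {
          dihedral_angle(coords_at(f, rows[1]), coords_at(f, rows[2]),
                         coords_at(f, rows[3]), coords_at(f, rows[4]))
        }, 0)
        recs[[k]] <- data.frame(frame = seq_len(nf), residue_number = resno,
                                angle = ang, value = vals)
      }
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Circular mean and standard deviation of angles
#'
#' Directional statistics for angles in degrees: the mean is
#' `atan2(<sin>, <cos>)` and the SD is `sqrt(-2 log R) * 180/pi`, with R
#' the mean resultant length.
#'
#' @param values Angles in degrees (>= 1, NA removed).
#' @return List with `mean` and `sd`, both in degrees (mean in
#'   (-180, 180]).
#' @details A resultant length below 1e-12 (angles uniform on the circle)
#'   raises an undefined-mean error.
#' @export
circular_mean_sd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) {
    cf_stop("confens_validation_error", "need at least one angle")
  }
  rad <- deg2rad(values)
  s <- mean(sin(rad)); c <- mean(cos(rad))
  r <- sqrt(s^2 + c^2)
  if (r < 1e-12) {
    cf_stop("confens_undefined_mean_error",
            "resultant length ~ 0: circular mean undefined (uniform angles)")
  }
  list(mean = wrap180(rad2deg(atan2(s, c))),
       sd = rad2deg(sqrt(-2 * log(min(r, 1)))))
}

# circular median: the observed angle minimizing summed circular distance;
# ties broken by first occurrence
circular_median <- function(values) {
  values <- values[!is.na(values)]
  tot <- vapply(values, function(v) sum(circ_dist(v, values)), 0)
  values[which.min(tot)]
}

#' Per-residue phi/psi variability (circular IQR)
#'
#' For every residue and angle type, the observations are unwrapped about
#' their circular median (each value shifted by a multiple of 360 into
#' (median - 180, median + 180]) and the ordinary interquartile range is
#' taken, making box-plot-style variability well defined near the +/-180
#' seam.
#'
#' @param x A `pdb_ensemble` with >= 2 frames/models.
#' @param residue_range Inclusive residue range.
#' @param chain_id Optional chain restriction (see [backbone_dihedrals()]).
#' @return Data frame of class `variability_profile` with columns
#'   `residue_number`, `phi_iqr`, `psi_iqr` (degrees; `NA` where the angle
#'   is undefined in all models).
#' @export
variability_profile <- function(x, residue_range = NULL, chain_id = NULL) {
  stopifnot(inherits(x, "pdb_ensemble"))
  if (nrow(x$xyz) < 2L) {
    cf_stop("confens_validation_error",
            "variability needs at least 2 conformations")
  }
  di <- backbone_dihedrals(x, residue_range, chain_id)
  one <- function(vals) {
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2L) return(NA_real_)
    med <- circular_median(vals)
    unwrapped <- med + wrap180(vals - med)
    # type-2 quantiles so that for two observations the IQR is their range
    q <- stats::quantile(unwrapped, c(0.25, 0.75), type = 2, names = FALSE)
    q[2] - q[1]
  }
  residues <- sort(unique(di$residue_number))
  phi <- vapply(residues, function(r) {
    one(di$value[di$residue_number == r & di$angle == "phi"])
  }, 0)
  psi <- vapply(residues, function(r) {
    one(di$value[di$residue_number == r & di$angle == "psi"])
  }, 0)
  structure(
    data.frame(residue_number = residues, phi_iqr = phi, psi_iqr = psi),
    class = c("variability_profile", "data.frame"),
    n_conformations = nrow(x$xyz)
  )
}

#' Define a labeled angular state
#'
#' A circular distribution (mean, SD) with an assignment window of
#' mean +/- `width_multiplier * sd`, used to classify dihedral
#' observations into named conformational states.
#'
#' @param label State name.
#' @param mean Circular mean, degrees.
#' @param sd Circular SD, degrees (> 0).
#' @param width_multiplier Half-width of the assignment window in units of
#'   `sd` (default 2).
#' @return An object of class `angular_state`.
#' @export
angular_state <- function(label, mean, sd, width_multiplier = 2) {
  if (!is_scalar_num(sd) || sd <= 0) {
    cf_stop("confens_validation_error", "sd must be > 0")
  }
  if (!is_scalar_num(width_multiplier) || width_multiplier <= 0) {
    cf_stop("confens_validation_error", "width_multiplier must be > 0")
  }
  structure(list(label = as.character(label), mean = wrap180(mean),
                 sd = sd, width_multiplier = width_multiplier),
            class = "angular_state")
}

#' @export
print.angular_state <- function(x, ...) {
  cat(sprintf("<angular_state> '%s': %.1f +/- %.1f deg (window %.0f sd)\n",
              x$label, x$mean, x$sd, x$width_multiplier))
  invisible(x)
}

#' His453 backbone-psi state presets
#'
#' The two main conformations of the GR DBD lever-arm residue His453, as
#' characterized by its backbone psi dihedral: "out" at 143 +/- 20 degrees
#' and "in" at -28 +/- 11 degrees. An on-pathway intermediate at
#' 119 +/- 13 degrees can be included but is off by default because its
#' window overlaps "out".
#'
#' @param include_intermediate Include the intermediate state
#'   (default `FALSE`).
#' @return List of [angular_state()] objects.
#' @export
his453_states <- function(include_intermediate = FALSE) {
  st <- list(angular_state("out", 143, 20),
             angular_state("in", -28, 11))
  if (include_intermediate) {
    st <- c(st, list(angular_state("intermediate", 119, 13)))
  }
  st
}

#' Classify a dihedral series into angular states
#'
#' Each observation is labeled with the state of smallest circular
#' distance to its mean, among the states whose window
#' (mean +/- width_multiplier * sd) contains the observation; values
#' covered by no window are `"unassigned"`. Exact distance ties go to the
#' state listed first. Transitions are counted between consecutive
#' distinct assigned labels, skipping unassigned gaps (a ->
#' unassigned -> b counts as one a -> b transition).
#'
#' @param values Numeric vector of angles in degrees (a dihedral time
#'   series), or a data frame with a `value` column.
#' @param states List of [angular_state()] objects (>= 1).
#' @return Object of class `state_assignment`: data frame with columns
#'   `frame`, `value`, `state`; attributes `n_transitions` (count) and
#'   `transition_table` (from/to contingency table).
#' @export
assign_states <- function(values, states) {
  if (is.data.frame(values)) values <- values$value
  if (!is.list(states) || length(states) < 1L ||
      !all(vapply(states, inherits, TRUE, "angular_state"))) {
    cf_stop("confens_validation_error",
            "states must be a non-empty list of angular_state objects")
  }
  means <- vapply(states, `[[`, 0, "mean")
  halfw <- vapply(states, function(s) s$width_multiplier * s$sd, 0)
  labels <- vapply(states, `[[`, "", "label")
  assigned <- vapply(values, function(v) {
    if (is.na(v)) return(NA_character_)
    d <- circ_dist(v, means)
    inside <- d <= halfw
    if (!any(inside)) return("unassigned")
    cand <- which(inside)
    labels[cand[which.min(d[cand])]]  # which.min takes the first on ties
  }, "")
  run <- assigned[!is.na(assigned) & assigned != "unassigned"]
  if (length(run) > 1L) {
    change <- run[-1] != run[-length(run)]
    n_trans <- sum(change)
    tt <- table(from = run[-length(run)][change], to = run[-1][change])
  } else {
    n_trans <- 0L
    tt <- table(from = character(0), to = character(0))
  }
  structure(
    data.frame(frame = seq_along(values), value = values, state = assigned),
    class = c("state_assignment", "data.frame"),
    n_transitions = n_trans, transition_table = tt
  )
}

#' @export
print.state_assignment <- function(x, ...) {
  tab <- table(x$state, useNA = "ifany")
  cat("<state_assignment>", nrow(x), "frames;",
      attr(x, "n_transitions"), "transitions\n")
  print(tab)
  invisible(x)
}
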