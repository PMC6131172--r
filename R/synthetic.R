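#' Specification of a synthetic conformational ensemble
#'
#' Describes a ground-truth ensemble: `k_states` reference conformations
#' of an `n_atoms` chain, a Markov switching process between them,
#' isotropic Gaussian coordinate noise, and (optionally) an arbitrary
#' proper rigid-body motion per frame. Used to emulate the statistical
#' structure of a molecular-dynamics trajectory with known state labels,
#' so clustering and fluctuation analyses can be validated exactly.
#'
#' @param n_atoms Number of (C-alpha) atoms (>= 4).
#' @param k_states Number of reference conformations (>= 1).
#' @param inter_state_rmsd_target Pairwise Kabsch-fitted RMSD between all
#'   reference pairs, Angstrom; every realized pair lands within 5% of
#'   this.
#' @param noise_sd Gaussian noise SD per coordinate, Angstrom (>= 0).
#' @param n_frames Number of frames.
#' @param transition_matrix k x k row-stochastic matrix; default
#'   [markov_matrix()] with stay probability 0.99.
#' @param rigid_motion Apply a random proper rigid motion to every frame
#'   (default `TRUE`).
#' @param seed RNG seed; identical specs give bit-identical ensembles.
#' @return Object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_atoms, k_states, inter_state_rmsd_target = 6,
                          noise_sd = 0.3, n_frames = 1000L,
                          transition_matrix = NULL, rigid_motion = TRUE,
                          seed = 1L) {
  if (n_atoms < 4L) {
    cf_stop("confens_validation_error", "n_atoms must be >= 4")
  }
  if (k_states < 1L) {
    cf_stop("confens_validation_error", "k_states must be >= 1")
  }
  if (noise_sd < 0) {
    cf_stop("confens_validation_error", "noise_sd must be >= 0")
  }
  if (is.null(transition_matrix)) {
    transition_matrix <- markov_matrix(k_states, 0.99)
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!identical(dim(transition_matrix), c(as.integer(k_states),
                                           as.integer(k_states))) ||
      any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    cf_stop("confens_validation_error",
            "transition_matrix must be k x k row-stochastic")
  }
  structure(
    list(n_atoms = as.integer(n_atoms), k_states = as.integer(k_states),
         inter_state_rmsd_target = inter_state_rmsd_target,
         noise_sd = noise_sd, n_frames = as.integer(n_frames),
         transition_matrix = transition_matrix,
         rigid_motion = isTRUE(rigid_motion), seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

#' Symmetric Markov transition matrix with a given stay probability
#' @param k Number of states.
#' @param p_stay Probability of remaining in the current state; the rest
#'   is spread uniformly over the other states.
#' @return k x k row-stochastic matrix.
#' @export
markov_matrix <- function(k, p_stay = 0.99) {
  if (k == 1L) return(matrix(1, 1, 1))
  m <- matrix((1 - p_stay) / (k - 1), k, k)
  diag(m) <- p_stay
  m
}

# deterministic pseudo-random coil: consecutive C-alpha spacing exactly
# 3.8 A, direction a correlated random walk
random_coil <- function(n_atoms) {
  coords <- matrix(0, n_atoms, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n_atoms) {
    dir <- dir + 0.9 * stats::rnorm(3)
    dir <- dir / vnorm(dir)
    coords[i, ] <- coords[i - 1, ] + 3.8 * dir
  }
  coords
}

#' Construct k reference conformations at a fixed mutual RMSD
#'
#' State 1 is a deterministic pseudo-random coil with realistic C-alpha
#' spacing (3.8 Angstrom between consecutive atoms). States 2..k displace
#' a contiguous block of atoms along mutually equidistant directions (a
#' regular simplex in the block's coordinate space), globally rescaled so
#' that every pairwise Kabsch-fitted RMSD falls within 5% of
#' `inter_state_rmsd_target`. Displaced states are abstract conformers:
#' their RMSD geometry is exact by construction, their bond geometry is
#' not preserved.
#'
#' @param n_atoms,k_states,inter_state_rmsd_target,seed As in
#'   [ensemble_spec()]; alternatively pass an `ensemble_spec` as the first
#'   argument.
#' @param block Integer vector of displaced atom indices; default the
#'   middle half of the chain. Must satisfy `3 * length(block) >= k`.
#' @return List of `k_states` N x 3 matrices.
#' @export
make_reference_states <- function(n_atoms, k_states = NULL,
                                  inter_state_rmsd_target = NULL,
                                  seed = NULL, block = NULL) {
  if (inherits(n_atoms, "ensemble_spec")) {
    spec <- n_atoms
    n_atoms <- spec$n_atoms
    if (is.null(k_states)) k_states <- spec$k_states
    if (is.null(inter_state_rmsd_target))
      inter_state_rmsd_target <- spec$inter_state_rmsd_target
    if (is.null(seed)) seed <- spec$seed
  }
  if (is.null(seed)) seed <- 1L
  k <- as.integer(k_states)
  if (k >= 2L && (!is_scalar_num(inter_state_rmsd_target) ||
                  inter_state_rmsd_target <= 0)) {
    cf_stop("confens_validation_error",
            "inter_state_rmsd_target must be > 0 for k_states > 1")
  }
  if (is.null(block)) {
    block <- seq(floor(n_atoms / 4) + 1L, floor(n_atoms / 4) + ceiling(n_atoms / 2))
  }
  m <- 3L * length(block)
  if (k > 1L && m < k) {
    cf_stop("confens_validation_error",
            "displaced block too small: need 3*length(block) >= k_states")
  }
  # the edge-correction iteration is not guaranteed to close the 5% band
  # for every draw of displacement directions; retry deterministically on
  # derived sub-seeds before declaring the request infeasible
  last_err <- NULL
  for (attempt in 0:7) {
    sub_seed <- as.integer((seed + 7919 * attempt) %% 2147483647)
    res <- tryCatch(
      make_reference_states_once(n_atoms, k, inter_state_rmsd_target,
                                 sub_seed, block, m),
      confens_infeasible_error = function(e) e)
    if (!inherits(res, "condition")) return(res)
    last_err <- res
  }
  stop(last_err)
}

make_reference_states_once <- function(n_atoms, k, inter_state_rmsd_target,
                                       seed, block, m) {
  with_seed(seed, {
    base <- random_coil(n_atoms)
    if (k == 1L) {
      list(base)
    } else {
    target <- inter_state_rmsd_target
    # rigid-motion subspace of the block (3 translations + 3 infinitesimal
    # rotations about the block centroid); displacement fields are kept
    # orthogonal to it so the Kabsch fit cannot absorb them and fitted
    # RMSD tracks the constructed displacement uniformly across pairs
    bc <- sweep(base[block, , drop = FALSE], 2,
                colMeans(base[block, , drop = FALSE]))
    rigid <- cbind(
      as.vector(t(cbind(1, 0, 0)[rep(1, length(block)), ])),
      as.vector(t(cbind(0, 1, 0)[rep(1, length(block)), ])),
      as.vector(t(cbind(0, 0, 1)[rep(1, length(block)), ])),
      as.vector(t(cbind(0, -bc[, 3], bc[, 2]))),
      as.vector(t(cbind(bc[, 3], 0, -bc[, 1]))),
      as.vector(t(cbind(-bc[, 2], bc[, 1], 0)))
    )
    if (m < k + 6L) {
      cf_stop("confens_validation_error",
              "displaced block too small: need 3*length(block) >= k_states + 6")
    }
    # orthonormal basis of the rigid complement carrying the displacement
    # directions; displacement fields are embedded coordinates in it
    raw <- matrix(stats::rnorm(m * (k - 1L)), m, k - 1L)
    qrig <- qr.Q(qr(rigid))
    raw <- raw - qrig %*% crossprod(qrig, raw)
    basis <- qr.Q(qr(raw))                     # m x (k-1)
    build <- function(y) {
      # y: k x (k-1) embedded coordinates, one row per state
      lapply(seq_len(k), function(j) {
        st <- base
        st[block, ] <- st[block, ] +
          matrix(basis %*% (y[j, ] - y[1, ]), ncol = 3, byrow = TRUE)
        st
      })
    }
    # start from a regular simplex whose edge gives the target as unfitted
    # RMSD, then iteratively correct each edge for the residual fitted /
    # constructed gap, re-embedding by classical MDS each round
    edge <- matrix(target * sqrt(n_atoms), k, k); diag(edge) <- 0
    states <- NULL; pr_mat <- NULL
    for (iter in 1:120) {
      y <- stats::cmdscale(stats::as.dist(edge), k = k - 1L)
      if (ncol(y) < k - 1L) {
        y <- cbind(y, matrix(0, k, k - 1L - ncol(y)))
      }
      states <- build(y)
      pr_mat <- matrix(0, k, k)
      for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
        pr_mat[i, j] <- pr_mat[j, i] <- fitted_rmsd(states[[i]], states[[j]])
      }
      dev <- abs(pr_mat[upper.tri(pr_mat)] - target) / target
      if (max(dev) < 0.02) break
      # damped multiplicative correction; cmdscale re-projects the tweaked
      # matrix onto realizable (Euclidean) distance sets each round
      ratio <- (target / pr_mat)^0.5
      diag(ratio) <- 1
      edge <- edge * pmin(pmax(ratio, 0.8), 1.25)
    }
    pr <- pr_mat[upper.tri(pr_mat)]
    if (any(abs(pr - target) > 0.05 * target)) {
      cf_stop("confens_infeasible_error",
              "could not realize all pairwise RMSDs within 5% of ",
              target, " A (got ", paste(round(range(pr), 2), collapse = "-"),
              "); enlarge the block or n_atoms")
    }
    states
    }
  })
}

#' Generate a synthetic ensemble with ground-truth state labels
#'
#' Simulates the Markov chain of an [ensemble_spec()] over its reference
#' states (initial state uniform), adds i.i.d. Gaussian noise per
#' coordinate, and optionally applies an arbitrary proper rigid motion to
#' each frame.
#'
#' @param spec An [ensemble_spec()].
#' @param residue_start First residue number of the synthetic C-alpha
#'   topology (default 1).
#' @param source_label Provenance label for the frames.
#' @return A `pdb_ensemble` of C-alpha pseudo-atoms with attributes
#'   `state_labels` (integer ground truth per frame) and
#'   `reference_states` (the list from [make_reference_states()]).
#' @export
generate_ensemble <- function(spec, residue_start = 1L,
                              source_label = "synthetic") {
  stopifnot(inherits(spec, "ensemble_spec"))
  refs <- make_reference_states(spec)
  n <- spec$n_atoms
  with_seed(spec$seed + 1L, {
    states <- integer(spec$n_frames)
    states[1] <- sample.int(spec$k_states, 1L)
    if (spec$n_frames > 1L) {
      for (t in 2:spec$n_frames) {
        states[t] <- sample.int(spec$k_states, 1L,
                                prob = spec$transition_matrix[states[t - 1], ])
      }
    }
    xyz <- matrix(NA_real_, spec$n_frames, 3L * n)
    for (t in seq_len(spec$n_frames)) {
      fr <- refs[[states[t]]]
      if (spec$noise_sd > 0) {
        fr <- fr + matrix(stats::rnorm(3L * n, sd = spec$noise_sd), n, 3)
      }
      if (spec$rigid_motion) {
        fr <- fr %*% random_rotation() +
          matrix(stats::rnorm(3, sd = 10), n, 3, byrow = TRUE)
      }
      xyz[t, ] <- as.vector(t(fr))
    }
    atoms <- data.frame(
      serial = seq_len(n), atom_name = "CA", alt_loc = "",
      residue_name = "ALA", chain_id = "A",
      residue_number = seq(residue_start, length.out = n),
      occupancy = 1, b_factor = 0, record = "ATOM",
      stringsAsFactors = FALSE
    )
    ens <- new_pdb_ensemble(atoms, xyz, source_label)
    attr(ens, "state_labels") <- states
    attr(ens, "reference_states") <- refs
    ens
  })
}

#' Generate a state-switching dihedral time series
#'
#' Markov chain over a list of [angular_state()]s; each frame emits a
#' wrapped-Gaussian angle with the current state's mean and SD, wrapped
#' to (-180, 180]. Emulates, e.g., the His453 backbone-psi flipping
#' between its "in" and "out" conformations.
#'
#' @param states List of [angular_state()] objects.
#' @param n_frames Series length.
#' @param transition_matrix Row-stochastic matrix (default
#'   [markov_matrix()] with stay probability 0.99).
#' @param seed RNG seed.
#' @return Data frame with columns `frame`, `value` (degrees); attribute
#'   `state_labels` holds the ground-truth state label per frame.
#' @export
generate_dihedral_series <- function(states, n_frames = 10000L,
                                     transition_matrix = NULL, seed = 1L) {
  if (!is.list(states) || length(states) < 1L ||
      !all(vapply(states, inherits, TRUE, "angular_state"))) {
    cf_stop("confens_validation_error",
            "states must be a non-empty list of angular_state objects")
  }
  k <- length(states)
  if (is.null(transition_matrix)) transition_matrix <- markov_matrix(k, 0.99)
  transition_matrix <- as.matrix(transition_matrix)
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    cf_stop("confens_validation_error",
            "transition_matrix must be row-stochastic")
  }
  with_seed(seed, {
    chain <- integer(n_frames)
    chain[1] <- sample.int(k, 1L)
    if (n_frames > 1L) {
      for (t in 2:n_frames) {
        chain[t] <- sample.int(k, 1L, prob = transition_matrix[chain[t - 1], ])
      }
    }
    means <- vapply(states, `[[`, 0, "mean")
    sds <- vapply(states, `[[`, 0, "sd")
    vals <- wrap180(stats::rnorm(n_frames, means[chain], sds[chain]))
    structure(
      data.frame(frame = seq_len(n_frames), value = vals),
      state_labels = vapply(states, `[[`, "", "label")[chain]
    )
  })
}

#' Build an ideal peptide backbone at fixed (phi, psi)
#'
#' Constructs an all-backbone (N, CA, C, O) poly-alanine chain by
#' sequential internal-coordinate placement with ideal bond lengths and
#' angles, every residue at the requested (phi, psi) and omega = 180.
#' Serves as a constructive oracle: running [backbone_dihedrals()] on the
#' result recovers the inputs to well under 0.5 degrees.
#'
#' @param n_residues Chain length (>= 2).
#' @param phi,psi Backbone torsions in degrees; scalars apply to every
#'   residue, or give one value per residue.
#' @return A single-frame `pdb_ensemble`.
#' @examples
#' helix <- build_helical_peptide(10, -57, -47)
#' @export
build_helical_peptide <- function(n_residues, phi = -57, psi = -47) {
  if (n_residues < 2L) {
    cf_stop("confens_validation_error", "n_residues must be >= 2")
  }
  phi <- rep_len(phi, n_residues)
  psi <- rep_len(psi, n_residues)
  # ideal backbone geometry (lengths in A, angles in degrees)
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7; a_ca_c_o <- 120.8
  omega <- 180

  place <- function(pa, pb, pc, bond, angle, torsion) {
    th <- deg2rad(angle); tor <- deg2rad(torsion)
    bc <- pc - pb; bc <- bc / vnorm(bc)
    ab <- pb - pa
    n <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
    n <- n / vnorm(n)
    m2 <- c(n[2] * bc[3] - n[3] * bc[2],
            n[3] * bc[1] - n[1] * bc[3],
            n[1] * bc[2] - n[2] * bc[1])
    d2 <- c(-bond * cos(th), bond * sin(th) * cos(tor),
            bond * sin(th) * sin(tor))
    pc + cbind(bc, m2, n) %*% d2
  }

  pos <- list()
  pos[["N1"]] <- c(0, 0, 0)
  pos[["CA1"]] <- c(b_n_ca, 0, 0)
  th <- deg2rad(a_n_ca_c)
  pos[["C1"]] <- pos[["CA1"]] + b_ca_c * c(-cos(th), sin(th), 0)
  for (i in 2:n_residues) {
    pos[[paste0("N", i)]] <- as.vector(place(
      pos[[paste0("N", i - 1)]], pos[[paste0("CA", i - 1)]],
      pos[[paste0("C", i - 1)]], b_c_n, a_ca_c_n, psi[i - 1]))
    pos[[paste0("CA", i)]] <- as.vector(place(
      pos[[paste0("CA", i - 1)]], pos[[paste0("C", i - 1)]],
      pos[[paste0("N", i)]], b_n_ca, a_c_n_ca, omega))
    pos[[paste0("C", i)]] <- as.vector(place(
      pos[[paste0("C", i - 1)]], pos[[paste0("N", i)]],
      pos[[paste0("CA", i)]], b_ca_c, a_n_ca_c, phi[i]))
  }
  # carbonyl O: torsion N-CA-C-O = psi + 180 (anti to the next N)
  for (i in seq_len(n_residues)) {
    pos[[paste0("O", i)]] <- as.vector(place(
      pos[[paste0("N", i)]], pos[[paste0("CA", i)]],
      pos[[paste0("C", i)]], b_c_o, a_ca_c_o, psi[i] + 180))
  }

  names_per_res <- c("N", "CA", "C", "O")
  atom_name <- rep(names_per_res, n_residues)
  resno <- rep(seq_len(n_residues), each = 4L)
  coords <- t(vapply(paste0(atom_name, resno), function(k) pos[[k]],
                     numeric(3)))
  atoms <- data.frame(
    serial = seq_along(atom_name), atom_name = atom_name, alt_loc = "",
    residue_name = "ALA", chain_id = "A", residue_number = resno,
    occupancy = 1, b_factor = 0, record = "ATOM", stringsAsFactors = FALSE
  )
  new_pdb_ensemble(atoms, matrix(as.vector(t(coords)), nrow = 1),
                   "ideal_peptide")
}

#' Three-ensemble stand-in presets mimicking free / IR-GBS / GBS behavior
#'
#' Bundles three [ensemble_spec()]s with 12, 6 and 2 accessible lever-arm
#' states, emulating the qualitative trend that conformational sampling
#' is greatest for the free DNA-binding domain, intermediate for the
#' inverted-repeat-bound form and smallest for the dimer-bound form.
#' States are mutually well separated (8 Angstrom fitted RMSD) relative
#' to the default 2.3 Angstrom cluster radius, so recovered cluster
#' counts equal the state counts.
#'
#' @param seed Base RNG seed; each ensemble derives its own from it.
#' @param n_frames_per_state Frames simulated per accessible state
#'   (default 200).
#' @return Named list of `ensemble_spec`s: `free` (12 states), `ir_gbs`
#'   (6), `gbs` (2).
#' @export
fig_standin_specs <- function(seed = 1L, n_frames_per_state = 200L) {
  ks <- c(free = 12L, ir_gbs = 6L, gbs = 2L)
  out <- lapply(seq_along(ks), function(i) {
    k <- ks[[i]]
    ensemble_spec(
      n_atoms = 30L, k_states = k, inter_state_rmsd_target = 8,
      noise_sd = 0.3, n_frames = n_frames_per_state * k,
      transition_matrix = markov_matrix(k, 0.9),
      rigid_motion = TRUE, seed = as.integer(seed) + i
    )
  })
  names(out) <- names(ks)
  out
}

#' Write a synthetic ensemble plus its ground-truth labels
#'
#' @param ens A `pdb_ensemble` from [generate_ensemble()].
#' @param pdb_path Multi-model PDB output path.
#' @param labels_path TSV output path for `(frame, state)` ground truth.
#' @return `pdb_path`, invisibly.
#' @export
write_synthetic_ensemble <- function(ens, pdb_path, labels_path) {
  write_pdb(ens, pdb_path)
  lab <- attr(ens, "state_labels")
  if (is.null(lab)) {
    cf_stop("confens_validation_error", "ensemble carries no state labels")
  }
  utils::write.table(
    data.frame(frame = seq_along(lab), state = lab),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pdb_path)
}
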