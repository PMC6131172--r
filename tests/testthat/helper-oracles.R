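# Independent oracles and small fixture builders used across tests.

# --- brute-force rotation-grid RMSD oracle -------------------------------
# Exhaustive search over a ZYZ Euler grid. For centered sets P (mobile) and
# Q (reference), rmsd(R)^2 = (|P|^2 + |Q|^2 - 2 tr(R' H)) / n with
# H = P' Q, so each grid rotation costs one inner product. Entirely
# independent of the SVD solver it checks.

euler_grid <- function(step_deg) {
  a <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  b <- seq(0, 180, by = step_deg) * pi / 180
  g <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  gr <- expand.grid(a = a, b = b, g = g)
  ca <- cos(gr$a); sa <- sin(gr$a)
  cb <- cos(gr$b); sb <- sin(gr$b)
  cg <- cos(gr$g); sg <- sin(gr$g)
  # columns ordered as as.vector() of the 3x3 matrix (column-major)
  cbind(
    ca * cb * cg - sa * sg,   # R11
    sa * cb * cg + ca * sg,   # R21
    -sb * cg,                 # R31
    -ca * cb * sg - sa * cg,  # R12
    -sa * cb * sg + ca * cg,  # R22
    sb * sg,                  # R32
    ca * sb,                  # R13
    sa * sb,                  # R23
    cb                        # R33
  )
}

grid_rmsd_oracle <- function(mobile, reference, step_deg = 4,
                             grid = NULL) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  h <- crossprod(p, q)
  if (is.null(grid)) grid <- euler_grid(step_deg)
  tr_vals <- as.vector(grid %*% as.vector(h))
  msd <- (sum(p * p) + sum(q * q) - 2 * max(tr_vals)) / nrow(p)
  rmsd <- sqrt(max(msd, 0))
  # nearest grid rotation is within 3*step/2 of the optimum; each centered
  # point then moves by at most 2 sin(delta/2) * |p_i|
  delta <- 3 * (step_deg * pi / 180) / 2
  bound <- 2 * sin(delta / 2) * sqrt(mean(rowSums(p * p)))
  list(rmsd = rmsd, bound = bound)
}

# chunked variant for fine grids that do not fit in memory at once
grid_rmsd_oracle_chunked <- function(mobile, reference, step_deg = 1) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  h <- as.vector(crossprod(p, q))
  a_vals <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  b <- seq(0, 180, by = step_deg) * pi / 180
  g <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  gr <- expand.grid(b = b, g = g)
  cb <- cos(gr$b); sb <- sin(gr$b); cg <- cos(gr$g); sg <- sin(gr$g)
  best <- -Inf
  for (a in a_vals) {
    ca <- cos(a); sa <- sin(a)
    m <- cbind(ca * cb * cg - sa * sg, sa * cb * cg + ca * sg, -sb * cg,
               -ca * cb * sg - sa * cg, -sa * cb * sg + ca * cg, sb * sg,
               ca * sb, sa * sb, cb)
    best <- max(best, max(m %*% h))
  }
  msd <- (sum(p * p) + sum(q * q) - 2 * best) / nrow(p)
  delta <- 3 * (step_deg * pi / 180) / 2
  list(rmsd = sqrt(max(msd, 0)),
       bound = 2 * sin(delta / 2) * sqrt(mean(rowSums(p * p))))
}

# --- rotation helpers ----------------------------------------------------
rodrigues_rotate <- function(v, axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  v * cos(th) +
    c(a[2] * v[3] - a[3] * v[2],
      a[3] * v[1] - a[1] * v[3],
      a[1] * v[2] - a[2] * v[1]) * sin(th) +
    a * sum(a * v) * (1 - cos(th))
}

random_proper_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# --- tiny PDB text fixtures ----------------------------------------------
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, b = 0, alt = " ", record = "ATOM") {
  fmt_name <- if (nchar(name) >= 4) sprintf("%-4s", name)
              else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, fmt_name, alt, resname, chain, resno,
          x, y, z, occ, b)
}

write_tmp_pdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# an ensemble -> list of per-frame coordinate matrices
all_frame_coords <- function(ens) {
  lapply(seq_len(nrow(ens$xyz)), function(i) frame_coords(ens, i))
}

# best-matching label agreement between ground truth and cluster labels
label_agreement <- function(truth, assigned) {
  tab <- table(truth, assigned)
  sum(apply(tab, 1, max)) / length(truth)
}

# stack single-frame ensembles with shared topology into one multi-frame
# ensemble (exact coordinates, no PDB round trip)
stack_frames <- function(...) {
  frames <- list(...)
  xyz <- do.call(rbind, lapply(frames, function(f) f$xyz))
  confens:::new_pdb_ensemble(frames[[1]]$atoms, xyz, frames[[1]]$source_label)
}

# ideal peptide with per-residue psi values
build_helical_peptide_psis <- function(n, phi, psis) {
  build_helical_peptide(n, phi, psis)
}

# single-model, multi-chain PDB where each chain is one noisy copy of a
# base conformation -- the geometry of a crystal asymmetric unit with
# several molecules
make_multichain_pdb <- function(n_chains = 3, n_res = 20, noise = 0.3,
                                resno_start = 421, seed = 50) {
  confens:::with_seed(seed, {
    base_spec <- ensemble_spec(n_atoms = n_res, k_states = 1, noise_sd = 0,
                               n_frames = 1, rigid_motion = FALSE, seed = seed)
    base <- frame_coords(generate_ensemble(base_spec), 1)
    lines <- character(0)
    serial <- 0
    for (ch in LETTERS[seq_len(n_chains)]) {
      co <- base + matrix(rnorm(3 * n_res, sd = noise), n_res, 3)
      for (i in seq_len(n_res)) {
        serial <- serial + 1
        lines <- c(lines, pdb_atom_line(serial, "CA", "ALA", ch,
                                        resno_start + i - 1,
                                        co[i, 1], co[i, 2], co[i, 3]))
      }
    }
    write_tmp_pdb(lines)
  })
}
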