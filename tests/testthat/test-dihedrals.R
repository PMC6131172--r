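test_that("dihedral_angle reproduces planar and constructed angles", {
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, -1, 0)), 180)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, 1, 0)), 0)
  # p4 constructed by rotating p1's image +60 degrees about the p2-p3 axis
  for (ang in c(60, -60, 150, -179, 180)) {
    p4 <- p3 + rodrigues_rotate(p1 - p2, p3 - p2, ang)
    expect_equal(dihedral_angle(p1, p2, p3, p4), ang, tolerance = 1e-8)
  }
})

test_that("dihedral_angle rejects degenerate geometry", {
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               class = "confens_degenerate_geometry_error")
  expect_error(dihedral_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)),
               class = "confens_degenerate_geometry_error")
})

test_that("dihedral symmetries: proper motions, reversal, reflection", {
  set.seed(10)
  mirror <- diag(c(1, 1, -1))
  for (i in 1:20) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    val <- tryCatch(
      dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
      confens_degenerate_geometry_error = function(e) NULL)
    if (is.null(val)) next
    # invariant under any proper rigid motion of all four points
    r <- random_proper_rotation()
    t <- runif(3, -5, 5)
    moved <- pts %*% r + matrix(t, 4, 3, byrow = TRUE)
    expect_equal(dihedral_angle(moved[1, ], moved[2, ], moved[3, ], moved[4, ]),
                 val, tolerance = 1e-8)
    # invariant under full point-order reversal (IUPAC convention)
    rev_val <- dihedral_angle(pts[4, ], pts[3, ], pts[2, ], pts[1, ])
    expect_equal(rev_val, val, tolerance = 1e-8)
    # anti-symmetric under reflection (up to the +180 seam)
    ref <- pts %*% mirror
    mir_val <- dihedral_angle(ref[1, ], ref[2, ], ref[3, ], ref[4, ])
    expect_equal(confens:::wrap180(mir_val + val), 0, tolerance = 1e-8)
  }
})

test_that("backbone_dihedrals recovers builder inputs and terminal rules", {
  helix <- build_helical_peptide(10, -57, -47)
  di <- backbone_dihedrals(helix)
  phi <- di$value[di$angle == "phi"]
  psi <- di$value[di$angle == "psi"]
  expect_true(is.na(phi[1]))                  # no C(i-1) at the N-terminus
  expect_true(is.na(psi[length(psi)]))        # no N(i+1) at the C-terminus
  expect_lt(max(abs(phi[-1] + 57)), 0.5)
  expect_lt(max(abs(psi[-length(psi)] + 47)), 0.5)

  two <- backbone_dihedrals(build_helical_peptide(2, -57, -47))
  expect_equal(sum(!is.na(two$value[two$angle == "phi"])), 1L)
  expect_equal(sum(!is.na(two$value[two$angle == "psi"])), 1L)
})

test_that("a missing bridging atom flags exactly the dependent angles", {
  helix <- build_helical_peptide(8, -57, -47)
  # remove the C atom of residue 5
  drop <- which(helix$atoms$residue_number == 5 & helix$atoms$atom_name == "C")
  helix$atoms <- helix$atoms[-drop, ]
  helix$xyz <- helix$xyz[, -c(3 * (drop - 1) + 1:3), drop = FALSE]
  di <- backbone_dihedrals(helix)
  get <- function(res, ang) di$value[di$residue_number == res & di$angle == ang]
  expect_true(is.na(get(5, "phi")))   # needs C(5)
  expect_true(is.na(get(5, "psi")))   # needs C(5)
  expect_true(is.na(get(6, "phi")))   # needs C(5) as the bridging atom
  expect_false(is.na(get(4, "psi")))  # unaffected
  expect_false(is.na(get(6, "psi")))  # unaffected
})

test_that("backbone torsions agree with bio3d on an ideal helix", {
  skip_if_not_installed("bio3d")
  path <- tempfile(fileext = ".pdb")
  write_pdb(build_helical_peptide(8, -57, -47), path)
  ref <- bio3d::torsion.pdb(bio3d::read.pdb(path))
  di <- backbone_dihedrals(read_pdb(path))
  ours_phi <- di$value[di$angle == "phi"]
  theirs_phi <- ref$phi
  ok <- !is.na(ours_phi) & !is.na(theirs_phi)
  expect_gt(sum(ok), 4)
  expect_lt(max(abs(ours_phi[ok] - theirs_phi[ok])), 0.01)
})

test_that("circular_mean_sd handles wrap-around and recovers generators", {
  expect_equal(circular_mean_sd(c(10, 350))$mean, 0, tolerance = 1e-9)
  const <- circular_mean_sd(rep(143, 50))
  expect_equal(const$mean, 143, tolerance = 1e-9)
  expect_equal(const$sd, 0, tolerance = 1e-6)
  # 1e5 wrapped-Gaussian samples at mu = 143, sigma = 20
  ser <- generate_dihedral_series(list(angular_state("out", 143, 20)),
                                  n_frames = 1e5, seed = 42)
  est <- circular_mean_sd(ser$value)
  expect_equal(est$mean, 143, tolerance = 0.5)
  expect_equal(est$sd, 20, tolerance = 0.5)
  # uniform angles have no defined mean
  expect_error(circular_mean_sd(c(0, 90, 180, -90)),
               class = "confens_undefined_mean_error")
})

test_that("circular mean is rotation-equivariant", {
  set.seed(11)
  vals <- confens:::wrap180(rnorm(500, 150, 30))
  m0 <- circular_mean_sd(vals)$mean
  for (delta in c(10, 90, 180, -77)) {
    m1 <- circular_mean_sd(confens:::wrap180(vals + delta))$mean
    expect_equal(confens:::wrap180(m1 - m0 - delta), 0, tolerance = 1e-9)
  }
})

test_that("variability_profile localizes variability and handles two-point IQR", {
  # 8 models: psi of residues 4-6 perturbed, others identical
  set.seed(12)
  frames <- lapply(1:8, function(i) {
    psis <- rep(-47, 10)
    if (i > 1) psis[4:6] <- -47 + runif(3, -60, 60)
    ens <- build_helical_peptide_psis(10, -57, psis)
    ens
  })
  ens <- do.call(stack_frames, frames)
  vp <- variability_profile(ens)
  psi_ok <- !is.na(vp$psi_iqr)
  expect_equal(vp$residue_number[psi_ok][which.max(vp$psi_iqr[psi_ok])] %in% 4:6,
               TRUE)
  # untouched residues have (near-)zero IQR
  quiet <- vp$psi_iqr[vp$residue_number %in% c(2, 8)]
  expect_lt(max(quiet, na.rm = TRUE), 1e-6)

  # two models differing by 10 degrees in one psi -> IQR exactly 10
  f2 <- list(build_helical_peptide_psis(6, -57, rep(-47, 6)),
             build_helical_peptide_psis(6, -57, c(-47, -47, -37, -47, -47, -47)))
  ens2 <- do.call(stack_frames, f2)
  vp2 <- variability_profile(ens2)
  expect_equal(vp2$psi_iqr[vp2$residue_number == 3], 10, tolerance = 1e-6)

  # identical models -> all-zero IQR
  ens3 <- do.call(stack_frames, list(frames[[1]], frames[[1]]))
  vp3 <- variability_profile(ens3)
  expect_lt(max(abs(vp3$psi_iqr), na.rm = TRUE), 1e-9)
})

test_that("variability is invariant to +/-360 relabeling of inputs", {
  vals <- c(170, -175, 178, -170, 165)
  shifted <- vals + c(360, 0, -360, 720, 0)
  one_iqr <- function(v) {
    med <- confens:::circular_median(confens:::wrap180(v))
    u <- med + confens:::wrap180(v - med)
    q <- stats::quantile(u, c(0.25, 0.75), type = 2, names = FALSE)
    q[2] - q[1]
  }
  expect_equal(one_iqr(vals), one_iqr(shifted), tolerance = 1e-9)
})

test_that("state assignment follows the windowed nearest-mean rule", {
  states <- his453_states()
  asn <- assign_states(c(-28, 143, 90, 175, -39, 163), states)
  expect_equal(asn$state,
               c("in", "out", "unassigned", "out", "in", "out"))
  # -28 +/- 11 window: edge at 2 sd
  edge <- assign_states(c(-28 + 22, -28 + 23), states)
  expect_equal(edge$state, c("in", "unassigned"))
  # exact tie between two equidistant states goes to the first listed
  sym <- list(angular_state("a", 0, 10), angular_state("b", 40, 10))
  expect_equal(assign_states(20, sym)$state, "a")
  # transitions skip unassigned gaps
  tr <- assign_states(c(-28, 90, 143, 90, -28, -28), states)
  expect_equal(attr(tr, "n_transitions"), 2L)
})

test_that("state classifier recovers a Markov ground truth", {
  states <- his453_states()
  ser <- generate_dihedral_series(states, n_frames = 1e4,
                                  transition_matrix = markov_matrix(2, 0.99),
                                  seed = 7)
  truth <- attr(ser, "state_labels")
  asn <- assign_states(ser, states)
  assigned <- asn$state != "unassigned"
  acc <- mean(asn$state[assigned] == truth[assigned])
  expect_gt(acc, 0.95)
  # overall accuracy counting unassigned as errors still clears 95%
  expect_gt(mean(asn$state == truth), 0.95)
  # transition count within +/-20% of the ground truth
  true_trans <- sum(truth[-1] != truth[-length(truth)])
  expect_lt(abs(attr(asn, "n_transitions") - true_trans), 0.2 * true_trans)
})
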