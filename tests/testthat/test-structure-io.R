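test_that("a minimal one-atom PDB yields one frame with one atom", {
  path <- write_tmp_pdb(pdb_atom_line(1, "CA", "ALA", "A", 1, 1.5, -2.25, 3))
  ens <- read_pdb(path)
  expect_s3_class(ens, "pdb_ensemble")
  expect_equal(n_frames(ens), 1L)
  expect_equal(nrow(ens$atoms), 1L)
  expect_equal(frame_coords(ens, 1), matrix(c(1.5, -2.25, 3), 1, 3))
  expect_equal(ens$atoms$atom_name, "CA")
  expect_equal(ens$atoms$residue_number, 1L)
})

test_that("MODEL/ENDMDL records delimit frames", {
  mk_model <- function(i, shift) c(
    sprintf("MODEL %8d", i),
    pdb_atom_line(1, "N", "GLY", "A", 1, 0 + shift, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.5 + shift, 0, 0),
    pdb_atom_line(3, "C", "GLY", "A", 1, 3 + shift, 0, 0),
    "ENDMDL")
  path <- write_tmp_pdb(c(mk_model(1, 0), mk_model(2, 10)))
  ens <- read_pdb(path)
  expect_equal(n_frames(ens), 2L)
  expect_equal(nrow(ens$atoms), 3L)
  expect_equal(frame_coords(ens, 2)[, 1], frame_coords(ens, 1)[, 1] + 10)
})

test_that("parse failures are reported with context", {
  bad <- pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 2, 3)
  substr(bad, 33, 35) <- "abc"  # corrupt the x field
  expect_error(read_pdb(write_tmp_pdb(bad)),
               class = "confens_parse_error")
  expect_error(read_pdb(write_tmp_pdb(bad)), "line 1")

  expect_error(read_pdb(write_tmp_pdb(c("HEADER    NOTHING", "END"))),
               class = "confens_empty_structure_error")

  with_icode <- pdb_atom_line(1, "CA", "ALA", "A", 12, 1, 2, 3)
  substr(with_icode, 27, 27) <- "A"
  expect_error(read_pdb(write_tmp_pdb(with_icode)),
               class = "confens_parse_error")
})

test_that("write/read round trip preserves coordinates at PDB precision", {
  set.seed(7)
  spec <- ensemble_spec(n_atoms = 10, k_states = 1, noise_sd = 0.2,
                        n_frames = 2, seed = 3)
  ens <- generate_ensemble(spec)
  path <- tempfile(fileext = ".pdb")
  write_pdb(ens, path)
  back <- read_pdb(path)
  expect_equal(n_frames(back), 2L)
  expect_lt(max(abs(back$xyz - round(ens$xyz, 3))), 1e-9)
  expect_lt(max(abs(back$xyz - ens$xyz)), 0.001)
  # two frames produce MODEL 1 / MODEL 2 records
  txt <- readLines(path)
  expect_equal(sum(startsWith(txt, "MODEL")), 2L)
  # empty input is rejected
  expect_error(write_pdb(list(), tempfile()),
               class = "confens_validation_error")
})

test_that("read_pdb agrees with bio3d on a multi-model fixture", {
  skip_if_not_installed("bio3d")
  spec <- ensemble_spec(n_atoms = 8, k_states = 2,
                        inter_state_rmsd_target = 5, noise_sd = 0.1,
                        n_frames = 3, seed = 11)
  path <- tempfile(fileext = ".pdb")
  write_pdb(generate_ensemble(spec), path)
  ours <- read_pdb(path)
  ref <- bio3d::read.pdb(path, multi = TRUE)
  expect_equal(dim(ref$xyz), dim(ours$xyz))
  expect_lt(max(abs(ref$xyz - ours$xyz)), 1e-9)
  expect_equal(ref$atom$resno, ours$atoms$residue_number)
})

test_that("fragment presets carry the published residue ranges", {
  expect_equal(fragment_preset("lever_arm")$residue_range, c(450L, 456L))
  expect_equal(fragment_preset("core_dbd")$residue_range, c(421L, 491L))
  expect_equal(fragment_preset("core_dbd_md")$residue_range, c(421L, 490L))
  expect_equal(fragment_preset("d_loop")$residue_range, c(457L, 465L))
  expect_equal(fragment_preset("zf_helix")$residue_range, c(469L, 473L))
})

test_that("lever-arm selection on residues 440-470 returns 7 CA atoms", {
  lines <- unlist(lapply(440:470, function(r) {
    pdb_atom_line(r, "CA", "ALA", "A", r, r * 1.0, 0, 0)
  }))
  ens <- read_pdb(write_tmp_pdb(lines))
  sel <- select_atoms(ens, fragment_preset("lever_arm"))
  expect_equal(length(sel$index), 7L)
  expect_equal(sel$atoms$residue_number, 450:456)
})

test_that("selection errors and alt-loc resolution follow the stated rules", {
  lines <- c(
    pdb_atom_line(1, "N", "HIS", "A", 453, 0, 0, 0),
    pdb_atom_line(2, "CA", "HIS", "A", 453, 1, 0, 0, occ = 0.6, alt = "A"),
    pdb_atom_line(3, "CA", "HIS", "A", 453, 1.4, 0, 0, occ = 0.4, alt = "B"),
    pdb_atom_line(4, "CA", "ALA", "A", 454, 2, 0, 0)
  )
  ens <- read_pdb(write_tmp_pdb(lines))
  # alt-loc duplicates resolve to the higher occupancy conformer
  sel <- select_atoms(ens, fragment_spec("f", c(453, 454)))
  expect_equal(sel$atoms$alt_loc, c("A", ""))
  expect_equal(selection_coords(ens, sel)[[1]][1, 1], 1)
  # occupancy tie resolves to the alphabetically first label
  ens2 <- ens
  ens2$atoms$occupancy[ens2$atoms$alt_loc %in% c("A", "B")] <- 0.5
  sel2 <- select_atoms(ens2, fragment_spec("f", c(453, 454)))
  expect_equal(sel2$atoms$alt_loc, c("A", ""))
  # nothing matches -> empty-selection error naming the spec
  expect_error(select_atoms(ens, fragment_spec("nope", c(900, 910))),
               class = "confens_empty_selection_error")
  expect_error(select_atoms(ens, fragment_spec("nope", c(900, 910))),
               "nope")
})

test_that("missing requested atoms error by default and drop with allow_missing", {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1, 0, 0),
    pdb_atom_line(3, "N", "ALA", "A", 2, 2, 0, 0),  # residue 2 has no CA
    pdb_atom_line(4, "CA", "ALA", "A", 3, 3, 0, 0)
  )
  ens <- read_pdb(write_tmp_pdb(lines))
  spec <- fragment_spec("ca13", c(1, 3))
  expect_error(select_atoms(ens, spec),
               class = "confens_missing_atom_error")
  sel <- select_atoms(ens, spec, allow_missing = TRUE)
  expect_equal(sel$atoms$residue_number, c(1L, 3L))
})

test_that("selection ordering is canonical and deterministic", {
  # atoms deliberately scrambled in file order
  lines <- c(
    pdb_atom_line(1, "C", "ALA", "B", 5, 1, 0, 0),
    pdb_atom_line(2, "N", "ALA", "B", 5, 2, 0, 0),
    pdb_atom_line(3, "O", "ALA", "B", 5, 3, 0, 0),
    pdb_atom_line(4, "CA", "ALA", "B", 5, 4, 0, 0),
    pdb_atom_line(5, "CA", "ALA", "A", 6, 5, 0, 0),
    pdb_atom_line(6, "CA", "ALA", "A", 5, 6, 0, 0)
  )
  ens <- read_pdb(write_tmp_pdb(lines))
  # backbone selection: scrambled file order comes back as N, CA, C, O
  bb <- fragment_spec("bb", c(5, 6), atom_names = c("N", "CA", "C", "O"))
  sel <- select_atoms(ens, bb, allow_missing = TRUE)
  expect_equal(paste(sel$atoms$chain_id, sel$atoms$residue_number,
                     sel$atoms$atom_name),
               c("B 5 N", "B 5 CA", "B 5 C", "B 5 O"))
  # CA selection: ascending (chain, residue) order
  ca <- fragment_spec("ca", c(5, 6))
  sel_ca <- select_atoms(ens, ca)
  expect_equal(paste(sel_ca$atoms$chain_id, sel_ca$atoms$residue_number),
               c("A 5", "A 6", "B 5"))
  # pure function of (frame topology, spec)
  expect_identical(select_atoms(ens, bb, allow_missing = TRUE)$index,
                   sel$index)
})

test_that("HETATM records never enter protein selections", {
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "ZN", "ZN", "A", 1, 5, 5, 5, record = "HETATM")
  )
  ens <- read_pdb(write_tmp_pdb(lines))
  expect_equal(nrow(ens$atoms), 2L)           # Zn parsed into the table
  expect_equal(ens$atoms$record[2], "HETATM")
  sel <- select_atoms(ens, fragment_spec("f", c(1, 1)))
  expect_equal(nrow(sel$atoms), 1L)           # but never enters a selection
  expect_equal(sel$atoms$record, "ATOM")
})
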