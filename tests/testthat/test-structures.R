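test_that("PQR write/read round trip preserves coordinates and charges", {
  sys <- make_toy_polypeptide(toy_spec(n_residues = 8, seed = 4,
                                       residue_net_charges = c(0, -1, 1, 0, 0, 0, -1, 0)))
  f <- withr::local_tempfile(fileext = ".pqr")
  write_structure(sys, f)
  back <- read_structure(f, dialect = "pqr")
  expect_equal(coords(back), coords(sys), tolerance = 1e-6)
  expect_equal(back$atoms$charge, sys$atoms$charge, tolerance = 1e-6)
  expect_identical(back$atoms$serial, sys$atoms$serial)
  expect_identical(back$atoms$name, sys$atoms$name)
})

test_that("toy PQR parses charges in order and classifies segments", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM      1  O   HOH A     1       0.000   0.000   0.000  0.5000 1.55",
    "ATOM      2  H1  HOH A     1       1.000   0.000   0.000 -0.5000 1.00",
    "ATOM      3  C1  XYZ A     2       2.000   0.000   0.000  0.0000 1.70",
    "END"), f)
  sys <- read_structure(f, dialect = "pqr")
  expect_equal(sys$atoms$charge, c(0.5, -0.5, 0.0))
  expect_equal(sys$atoms$segment, c("solvent", "solvent", "ligand"))
})

test_that("segment classification is a total partition with overrides", {
  names <- c("ALA", "HOH", "WAT", "NA+", "MG", "LIG", "TYR", "19N")
  seg <- classify_segment(names)
  expect_true(all(seg %in% c("protein", "solvent", "ion", "ligand")))
  expect_equal(seg[1:5], c("protein", "solvent", "solvent", "ion", "ion"))
  expect_equal(classify_segment("XYZ", overrides = c(XYZ = "solvent")),
               "solvent")
})

test_that("malformed and duplicate-serial PQR rows are rejected with context", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM      1  N   ALA     1       0.000   0.000   0.000 -0.4000 1.55",
    "ATOM      2  CA  ALA     1       not_a_number 0.0   0.000  0.1000 1.70",
    "END"), f)
  expect_error(read_structure(f, "pqr"), "line 2")
  writeLines(c(
    "ATOM      1  N   ALA     1       0.000   0.000   0.000 -0.4000 1.55",
    "ATOM      1  CA  ALA     1       1.000   0.000   0.000  0.1000 1.70",
    "END"), f)
  expect_error(read_structure(f, "pqr"), "duplicate")
})

test_that("charge assignment honours the table, defaults and error policy", {
  sys <- make_toy_polypeptide(toy_spec(n_residues = 8))
  zeroed <- assign_charges(sys, data.frame(
    resname = "TOY", name = c("N", "CA", "C", "O", "CB"), charge = 0))
  expect_equal(sum(zeroed$atoms$charge), 0)

  # designed per-residue sums are recovered by brute-force summation
  tab <- toy_charge_table(net_cb = 0.25 - 1)   # net -1 per residue
  sys2 <- assign_charges(sys, tab)
  sums <- tapply(sys2$atoms$charge, sys2$atoms$resid, sum)
  expect_equal(as.vector(sums), rep(-1, 8), tolerance = 1e-12)
  expect_equal(sum(sys2$atoms$charge), -8, tolerance = 1e-12)

  incomplete <- tab[tab$name != "CB", ]
  expect_error(assign_charges(sys, incomplete), "CB")
  ok <- assign_charges(sys, incomplete, default = 0)
  expect_equal(as.vector(tapply(ok$atoms$charge, ok$atoms$resid, sum)),
               rep(-0.25, 8), tolerance = 1e-12)
})

test_that("trajectory round trip and model validation", {
  spec <- toy_spec(n_residues = 5, seed = 9, jitter_sigma = 0.02,
                   n_frames = 10)
  sys <- make_toy_polypeptide(spec)
  traj <- make_trajectory(sys, spec)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  back <- read_trajectory(f, sys)
  expect_equal(n_frames(back), 10)
  # PDB prints 3 decimals
  expect_equal(back$xyz, traj$xyz, tolerance = 1e-3)

  # single model (no MODEL records) is one frame
  f1 <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(f)
  first_model <- lines[grep("^ATOM", lines)[seq_len(nrow(sys$atoms))]]
  writeLines(c(first_model, "END"), f1)
  expect_equal(n_frames(read_trajectory(f1, sys)), 1)

  # drop one atom from model 2: error names the model
  lines <- readLines(f)
  atom_lines <- grep("^ATOM", lines)
  bad <- lines[-atom_lines[nrow(sys$atoms) + 3]]
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f2)
  expect_error(read_trajectory(f2, sys), "model 2")
})

test_that("residue_min_distance matches geometry and brute force", {
  sys <- point_system(rbind(c(0, 0, 0), c(3, 4, 0)), c(1, 1))
  expect_equal(residue_min_distance(sys, 1L, 2L), 5.0)

  # translation along the closest-pair axis adds exactly t
  sys2 <- point_system(rbind(c(0, 0, 0), c(5, 0, 0)), c(1, 1))
  sys3 <- point_system(rbind(c(0, 0, 0), c(7.5, 0, 0)), c(1, 1))
  expect_equal(residue_min_distance(sys3, 1L, 2L),
               residue_min_distance(sys2, 1L, 2L) + 2.5)

  # random 5-atom groups vs exhaustive pairwise minimum; symmetry
  set.seed(11)
  xyz <- matrix(rnorm(30, sd = 5), ncol = 3)
  sysr <- point_system(xyz, rep(0, 10))
  ia <- 1:5; ib <- 6:10
  brute <- min(apply(expand.grid(ia, ib), 1, function(p)
    sqrt(sum((xyz[p[1], ] - xyz[p[2], ])^2))))
  expect_equal(residue_min_distance(sysr, ia, ib), brute)
  expect_equal(residue_min_distance(sysr, ib, ia), brute)
  expect_gte(brute, 0)
  expect_error(residue_min_distance(sysr, ia, ia), "disjoint")
})

test_that("PDB dialect reads with zero charges and solvent classification", {
  spec <- toy_spec(n_residues = 4)
  sys <- make_toy_polypeptide(spec)
  traj <- make_trajectory(sys, spec)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  got <- read_structure(f, dialect = "pdb")
  expect_true(all(got$atoms$charge == 0))
  expect_equal(nrow(got$atoms), nrow(sys$atoms))
  expect_true(all(got$atoms$segment == "protein"))
})
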