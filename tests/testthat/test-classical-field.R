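test_that("esp_at_point matches closed forms and brute force", {
  sys <- point_system(c(0, 0, 0), 1)
  expect_equal(esp_at_point(sys, c(1, 0, 0)), 14.399645,
               tolerance = 1e-12)
  # empty system and exact cancellation
  empty <- point_system(matrix(numeric(0), ncol = 3), numeric(0))
  expect_equal(esp_at_point(empty, c(1, 1, 1)), 0)
  pm <- point_system(rbind(c(-1, 0, 0), c(1, 0, 0)), c(1, -1))
  expect_equal(esp_at_point(pm, c(0, 5, 0)), 0, tolerance = 1e-12)

  # random system vs independent loop implementation
  set.seed(21)
  xyz <- matrix(rnorm(60, sd = 4), ncol = 3)
  q <- runif(20, -1, 1)
  sysr <- point_system(xyz, q)
  p <- c(9, -2, 3)
  expect_equal(esp_at_point(sysr, p), brute_esp(sysr, p),
               tolerance = 1e-12)
  # singular point is refused with the clashing atom named
  expect_error(esp_at_point(sysr, xyz[7, ]), "serial 7")
})

test_that("field linearity, charge scaling and dielectric scaling", {
  set.seed(22)
  xyzA <- matrix(rnorm(30, sd = 5), ncol = 3)
  xyzB <- matrix(rnorm(30, sd = 5) + 10, ncol = 3)
  qA <- runif(10, -1, 1); qB <- runif(10, -1, 1)
  probe_xyz <- rbind(c(30, 0, 0), c(31.23, 0, 0))

  mk <- function(xyz, q) {
    s <- point_system(rbind(xyz, probe_xyz), c(q, 0, 0))
    n <- nrow(s$atoms)
    list(sys = s, probe = probe_bond(s, n - 1, n),
         excl = exclusion_set(s, c(n - 1, n)))
  }
  A <- mk(xyzA, qA); B <- mk(xyzB, qB); AB <- mk(rbind(xyzA, xyzB), c(qA, qB))
  fA <- bond_field(A$sys, A$probe, A$excl)$field_MVcm
  fB <- bond_field(B$sys, B$probe, B$excl)$field_MVcm
  fAB <- bond_field(AB$sys, AB$probe, AB$excl)$field_MVcm
  expect_equal(fAB, fA + fB, tolerance = 1e-12)

  dbl <- mk(xyzA, 2 * qA)
  expect_equal(bond_field(dbl$sys, dbl$probe, dbl$excl)$field_MVcm,
               2 * fA, tolerance = 1e-12)

  half <- A; half$sys$eps_eff <- 2
  expect_equal(bond_field(half$sys, half$probe, half$excl)$field_MVcm,
               fA / 2, tolerance = 1e-12)
})

test_that("bond field respects exclusions, offsets and sign convention", {
  lig <- make_probe_ligand(ring = TRUE)
  excl <- exclusion_set(lig$system, lig$exclusion)
  # the ring + C=O are the only charges: default exclusion leaves nothing
  r <- bond_field(lig$system, lig$probe, excl)
  expect_equal(r$field_MVcm, 0)
  # without exclusion, the probe's own charges dominate (finite value)
  expect_error(bond_field(lig$system, lig$probe, integer()))

  # sign convention: a positive charge behind the carbon makes phi_C >
  # phi_O, so the projected field is positive
  b <- make_field_benchmark("single_charge")
  r2 <- bond_field(b$system, b$probe,
                   excl = exclusion_set(b$system, b$exclusion))
  expect_gt(r2$field_MVcm, 0)
  expect_equal(r2$field_MVcm,
               (r2$phi_c_V - r2$phi_o_V) / r2$length_A * 100,
               tolerance = 1e-9)

  # offset moves the evaluation points toward the midpoint
  r3 <- bond_field(b$system, b$probe, offset = 0.1,
                   excl = exclusion_set(b$system, b$exclusion))
  k <- 14.399645
  expect_equal(r3$phi_c_V, k / 3.1, tolerance = 1e-12)
  expect_equal(r3$phi_o_V, k / 3.9, tolerance = 1e-12)
  expect_error(bond_field(b$system, b$probe, offset = 0.7,
                          excl = exclusion_set(b$system, b$exclusion)),
               "half the bond length")
})

test_that("finite-difference of the potential converges to the Coulomb field", {
  # single charge scene: E_x at x = 3.5 is k/3.5^2 (V/A); the centred
  # difference -(phi(p+h) - phi(p-h))/(2h) must converge to it
  sys <- point_system(c(0, 0, 0), 1)
  exact <- 14.399645 / 3.5^2
  # projection of E on +x: -dphi/dx = (phi(p-h) - phi(p+h))/(2h)
  fd <- function(h) (esp_at_point(sys, c(3.5 - h, 0, 0)) -
                     esp_at_point(sys, c(3.5 + h, 0, 0))) / (2 * h)
  e1 <- abs(fd(0.1) - exact); e2 <- abs(fd(0.01) - exact)
  e3 <- abs(fd(0.001) - exact)
  expect_gt(e1, e2); expect_gt(e2, e3)
  expect_lt(e3 / exact, 1e-5)
})

test_that("field series averages frames and respects zero jitter", {
  spec <- toy_spec(n_residues = 5, seed = 7, jitter_sigma = 0,
                   n_frames = 6)
  prot <- make_toy_polypeptide(spec)
  lig <- make_probe_ligand(position = c(8, 8, 8), ring = FALSE,
                           serial_offset = max(prot$atoms$serial))
  sys <- merge_systems(prot, lig$system)
  probe <- probe_bond(sys, lig$system$atoms$serial[1],
                      lig$system$atoms$serial[2])
  excl <- exclusion_set(sys, lig$system$atoms$serial)
  traj <- make_trajectory(sys, spec)
  fs <- field_series(traj, probe, excl)
  expect_equal(nrow(fs$records), 6)
  expect_true(all(abs(fs$records$field_MVcm - fs$records$field_MVcm[1]) < 1e-12))
  expect_equal(fs$mean_field, mean(fs$records$field_MVcm))

  # with jitter the mean equals the brute-force average of frame values
  spec2 <- toy_spec(n_residues = 5, seed = 8, jitter_sigma = 0.05,
                    n_frames = 12)
  traj2 <- make_trajectory(sys, spec2)
  fs2 <- field_series(traj2, probe, excl)
  per_frame <- vapply(1:12, function(t)
    bond_field(sys, probe, excl,
               xyz = frame_coords(traj2, t))$field_MVcm, numeric(1))
  expect_equal(fs2$records$field_MVcm, per_frame, tolerance = 1e-12)
  expect_equal(fs2$mean_field, mean(per_frame), tolerance = 1e-12)
})

test_that("capacitor field average under jitter stays near the analytic value", {
  cap <- make_field_benchmark("capacitor", plate_half_width = 30,
                              plate_spacing = 1, plate_sep = 6)
  excl <- exclusion_set(cap$system, cap$exclusion)
  spec <- toy_spec(n_residues = 3, seed = 13, jitter_sigma = 0.02,
                   n_frames = 8)
  traj <- make_trajectory(cap$system, spec)
  fs <- field_series(traj, cap$probe, excl)
  se <- sd(fs$records$field_MVcm) / sqrt(8)
  ref <- bond_field(cap$system, cap$probe, excl)$field_MVcm
  expect_lt(abs(fs$mean_field - ref), max(3 * se, 1e-6))
})

test_that("decomposition is additive over any partition", {
  set.seed(23)
  sys <- make_toy_polypeptide(toy_spec(n_residues = 6,
                                       residue_net_charges = runif(6, -1, 1),
                                       seed = 23))
  lig <- make_probe_ligand(position = c(12, 4, 2), ring = TRUE,
                           serial_offset = max(sys$atoms$serial))
  full <- merge_systems(sys, lig$system)
  probe <- probe_bond(full, lig$system$atoms$serial[1],
                      lig$system$atoms$serial[2])
  excl <- exclusion_set(full, lig$exclusion)

  groups <- residue_groups(full, excl = excl)
  dec <- decompose_field(full, probe, groups, excl = excl)
  total <- dec$field_MVcm[dec$group == "total"]
  expect_equal(sum(dec$field_MVcm[dec$group != "total"]), total,
               tolerance = 1e-9 * abs(total))

  # random partition equals per-atom brute-force regrouping
  included <- setdiff(seq_len(nrow(full$atoms)), excl)
  set.seed(24)
  lab <- sample(1:3, length(included), replace = TRUE)
  rnd <- split(included, lab)
  dec2 <- decompose_field(full, probe, rnd, excl = excl)
  for (g in names(rnd)) {
    per_atom <- sum(vapply(rnd[[g]], function(i)
      bond_field(full, probe,
                 excl = setdiff(seq_len(nrow(full$atoms)), i))$field_MVcm,
      numeric(1)))
    expect_equal(dec2$field_MVcm[dec2$group == g], per_atom,
                 tolerance = 1e-9)
  }

  # overlapping groups are refused
  bad <- rnd; bad[[1]] <- c(bad[[1]], bad[[2]][1])
  expect_error(decompose_field(full, probe, bad, excl = excl), "overlap")

  # single group covering everything equals the total
  dec3 <- decompose_field(full, probe, list(all = included), excl = excl)
  expect_equal(dec3$field_MVcm[dec3$group == "all"], total,
               tolerance = 1e-12)
})

test_that("hbond occupancy boundary cases and histogram", {
  spec <- toy_spec(n_residues = 3, seed = 1, n_frames = 5)
  sys <- make_toy_polypeptide(spec)
  mk <- function(d) {
    xyz <- array(rep(coords(sys), 5), dim = c(nrow(sys$atoms), 3, 5))
    xyz[1, , ] <- xyz[2, , ] + c(d, 0, 0)
    trajectory(sys, xyz)
  }
  s1 <- sys$atoms$serial[1]; s2 <- sys$atoms$serial[2]
  expect_equal(hbond_series(mk(3.0), list(c(s1, s2)))[[1]]$occupancy, 1.0)
  expect_equal(hbond_series(mk(3.6), list(c(s1, s2)))[[1]]$occupancy, 0.0)
  # cutoff is inclusive
  expect_equal(hbond_series(mk(3.5), list(c(s1, s2)))[[1]]$occupancy, 1.0)
  h <- hbond_series(mk(3.0), list(c(s1, s2)), bin_width = 0.1)[[1]]$hist
  expect_equal(sum(h$counts), 5)
  expect_error(hbond_series(mk(3.0), list(c(s1, s1))), "identical")
})
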