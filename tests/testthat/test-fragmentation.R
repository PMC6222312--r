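test_that("fragment counts follow the assembly index ranges", {
  sys5 <- make_toy_polypeptide(toy_spec(n_residues = 5))
  sch5 <- fragment_protein(sys5)
  kinds <- vapply(sch5$fragments, `[[`, "", "kind")
  expect_equal(sum(kinds == "capped_fragment"), 3)  # i = 2..N-1
  expect_equal(sum(kinds == "concap"), 2)           # i = 2..N-2

  sys3 <- make_toy_polypeptide(toy_spec(n_residues = 3))
  sch3 <- fragment_protein(sys3)
  kinds3 <- vapply(sch3$fragments, `[[`, "", "kind")
  expect_equal(sum(kinds3 == "capped_fragment"), 1)
  expect_equal(sum(kinds3 == "concap"), 0)
  expect_error(fragment_protein(
    point_system(matrix(rnorm(9), 3), rep(0, 3), segment = "protein")))
})

test_that("telescoping closure: signed per-atom multiplicity is exactly 1", {
  for (seed in c(31, 32, 33)) {
    sys <- random_peptide(seed)
    sch <- build_gconcaps(sys, fragment_protein(sys))
    mult <- scheme_multiplicity(sch, sys)
    expect_true(all(mult == 1L))
  }
})

test_that("link atoms sit on the cut-bond axis at element-specific distances", {
  h <- place_link_atom(c(0, 0, 0), c(1.33, 0, 0), "C")
  expect_equal(h, c(1.09, 0, 0), tolerance = 1e-12)
  h2 <- place_link_atom(c(1.33, 0, 0), c(0, 0, 0), "N")
  expect_equal(h2, c(1.33 - 1.01, 0, 0), tolerance = 1e-12)
  expect_error(place_link_atom(c(0, 0, 0), c(0, 0, 0), "C"), "zero")

  # rigid-motion equivariance: rotate + translate the bond, the link
  # atom follows
  set.seed(41)
  ang <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
  t0 <- rnorm(3)
  a <- rnorm(3); b <- rnorm(3)
  h_then <- as.numeric(R %*% place_link_atom(a, b, "C")) + t0
  h_after <- place_link_atom(as.numeric(R %*% a) + t0,
                             as.numeric(R %*% b) + t0, "C")
  expect_equal(h_then, h_after, tolerance = 1e-12)
})

test_that("concap cap atoms are coordinate-identical to adjacent fragment caps", {
  sys <- make_toy_polypeptide(toy_spec(n_residues = 7, seed = 42))
  sch <- fragment_protein(sys)
  frags <- sch$fragments
  kinds <- vapply(frags, `[[`, "", "kind")
  centers <- lapply(frags, `[[`, "center")
  for (ci in which(kinds == "concap")) {
    i <- centers[[ci]][1]
    # concap i shares its C-side piece with capped fragment i+1 and its
    # N-side piece with capped fragment i
    f_next <- frags[[which(kinds == "capped_fragment" &
                           vapply(centers, `[[`, 0, 1) == i + 1)]]
    f_this <- frags[[which(kinds == "capped_fragment" &
                           vapply(centers, `[[`, 0, 1) == i)]]
    expect_true(all(frags[[ci]]$cap_idx %in%
                    c(f_next$cap_idx, f_this$cap_idx)))
    # link positions in the concap all appear among the two fragments'
    # links (bit-identical coordinates)
    all_links <- rbind(f_next$links, f_this$links)
    for (r in seq_len(nrow(frags[[ci]]$links))) {
      lk <- frags[[ci]]$links[r, c("x", "y", "z")]
      hits <- apply(all_links[, c("x", "y", "z")], 1, function(v)
        identical(as.numeric(v), as.numeric(lk)))
      expect_true(any(hits))
    }
  }
})

test_that("gconcap pairing obeys sequence and distance constraints", {
  # hairpin: distant-in-sequence residues touch in space
  sys <- make_toy_polypeptide(toy_spec(n_residues = 8,
                                       geometry = "hairpin"))
  sch <- build_gconcaps(sys, fragment_protein(sys))
  prs <- sch$gconcap_pairs
  expect_gt(nrow(prs), 0)
  prot_prs <- prs[prs$partner == "protein", ]
  expect_true(all(prot_prs$j > prot_prs$i + 2))   # j > i+2, never i+1/i+2
  expect_true(all(prot_prs$dist <= sch$lambda))
  expect_true(any(prot_prs$i == 2 & prot_prs$j == 6))

  # lambda monotonicity: enlarging lambda never removes a pair
  sch6 <- build_gconcaps(sys, fragment_protein(sys, lambda = 6))
  key <- function(p) paste(p$i, p$j)
  p4 <- key(sch$gconcap_pairs[sch$gconcap_pairs$partner == "protein", ])
  p6 <- key(sch6$gconcap_pairs[sch6$gconcap_pairs$partner == "protein", ])
  expect_true(all(p4 %in% p6))

  # ligand within lambda is paired as a whole
  lig <- make_probe_ligand(position = c(2, 6.0, 0), ring = FALSE,
                           serial_offset = max(sys$atoms$serial))
  full <- merge_systems(sys, lig$system)
  schl <- build_gconcaps(full, fragment_protein(full),
                         include_ligand = TRUE)
  expect_true(any(schl$gconcap_pairs$partner == "ligand"))
})

test_that("embedding backgrounds are complements without link atoms", {
  sys <- random_peptide(44)
  lig <- make_probe_ligand(position = c(5, 5, 5), ring = TRUE,
                           serial_offset = max(sys$atoms$serial))
  full <- merge_systems(sys, lig$system)
  sch <- build_gconcaps(full, fragment_protein(full))
  pool <- which(full$atoms$segment %in% c("protein", "ligand"))
  for (f in sch$fragments) {
    bg <- embedding_charges(sch, f, full)
    own <- full$atoms$serial[c(f$real_idx, f$cap_idx)]
    expect_equal(nrow(bg), length(pool) - length(unique(c(f$real_idx, f$cap_idx))))
    expect_length(intersect(bg$serial, own), 0)
  }
})

test_that("scheme construction is independent of atom input order", {
  sys <- make_toy_polypeptide(toy_spec(n_residues = 6, seed = 45,
                                       geometry = "hairpin",
                                       residue_net_charges = c(0, 1, 0, -1, 0, 0)))
  set.seed(46)
  perm <- sample(nrow(sys$atoms))
  shuf <- charged_system(sys$atoms[perm, ], eps_eff = sys$eps_eff)
  pt <- c(7, 2, 4)
  a1 <- assemble_esp(build_gconcaps(sys, fragment_protein(sys)),
                     "surrogate", pt, sys)
  a2 <- assemble_esp(build_gconcaps(shuf, fragment_protein(shuf)),
                     "surrogate", pt, shuf)
  expect_equal(a1$potentials, a2$potentials, tolerance = 1e-12)
  expect_equal(nrow(a1$ledger), nrow(a2$ledger))
})
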