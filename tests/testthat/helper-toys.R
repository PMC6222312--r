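# shared builders for the test suite; everything is generated in code

# a bare point-charge system: one row per charge
point_system <- function(xyz, q, segment = "ion") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  charged_system(data.frame(
    serial = seq_len(n), name = rep("Q", n), element = rep("X", n),
    resid = seq_len(n), resname = rep("CHG", n),
    segment = rep(segment, n), chain = rep("S", n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = q,
    stringsAsFactors = FALSE))
}

# direct Coulomb potential, written independently of esp_at_point:
# plain loop over atoms (the brute-force oracle)
brute_esp <- function(sys, point, excl = integer()) {
  a <- sys$atoms
  keep <- setdiff(seq_len(nrow(a)), excl)
  v <- 0
  for (i in keep) {
    r <- sqrt((a$x[i] - point[1])^2 + (a$y[i] - point[2])^2 +
              (a$z[i] - point[3])^2)
    v <- v + a$charge[i] / r
  }
  14.399645 / sys$eps_eff * v
}

# a random folded peptide with ligand-free topology for assembly tests
random_peptide <- function(seed, n_min = 3, n_max = 15) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  geom <- sample(c("extended", "helixlike", "hairpin"), 1)
  q <- round(stats::runif(n, -1, 1), 3)
  make_toy_polypeptide(toy_spec(n_residues = n, residue_net_charges = q,
                                geometry = geom, seed = seed))
}

# toy charge table matching the 5-atom template, with designed
# per-residue sums
toy_charge_table <- function(net_cb = 0.25) {
  data.frame(resname = "TOY",
             name = c("N", "CA", "C", "O", "CB"),
             charge = c(-0.40, 0.10, 0.60, -0.55, net_cb),
             stringsAsFactors = FALSE)
}
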