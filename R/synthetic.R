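#' Specification of a synthetic test system
#'
#' Collects every knob of the toy generators in one validated object:
#' chain length, designed per-residue net charges, backbone geometry,
#' positional jitter, trajectory length, and an optional two-state
#' hydrogen-bond distance model with designed occupancy.
#'
#' @param n_residues chain length (>= 3; interior residues are needed
#'   for peptide-bond fragmentation)
#' @param residue_net_charges numeric vector of designed per-residue net
#'   charges (e); recycled to `n_residues`
#' @param geometry `"extended"` (straight chain, no long-range
#'   contacts), `"helixlike"` (tight coil bringing i/i+3 neighbours into
#'   contact) or `"hairpin"` (chain folds back on itself at 3.5 A)
#' @param seed integer master seed; per-stream seeds are derived by
#'   fixed offsets
#' @param jitter_sigma per-atom Gaussian positional jitter, Angstrom
#' @param n_frames number of trajectory frames
#' @param hbond_model optional list with `donor`, `acceptor` (atom
#'   serials), `r_bound`, `r_broken` (Angstrom), `p_bound` in \[0, 1\]
#' @return object of class `toy_spec`
#' @export
toy_spec <- function(n_residues = 8, residue_net_charges = 0,
                     geometry = c("extended", "helixlike", "hairpin"),
                     seed = 1L, jitter_sigma = 0, n_frames = 1L,
                     hbond_model = NULL) {
  geometry <- match.arg(geometry)
  if (n_residues < 3)
    stop("n_residues must be >= 3 (peptide-bond fragmentation needs interior residues)")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!is.null(hbond_model)) {
    stopifnot(all(c("donor", "acceptor", "r_bound", "r_broken", "p_bound")
                  %in% names(hbond_model)))
    if (hbond_model$p_bound < 0 || hbond_model$p_bound > 1)
      stop("p_bound must be in [0, 1]")
  }
  structure(list(
    n_residues = as.integer(n_residues),
    residue_net_charges = rep_len(residue_net_charges, n_residues),
    geometry = geometry, seed = as.integer(seed),
    jitter_sigma = jitter_sigma, n_frames = as.integer(n_frames),
    hbond_model = hbond_model), class = "toy_spec")
}

# five-atom model residue template in its local frame (CA at origin,
# chain axis along +x): backbone N, CA, C, carbonyl O, side-centroid CB.
# template charges sum to zero; designed net charge is added on CB.
.toy_template <- data.frame(
  name    = c("N", "CA", "C", "O", "CB"),
  element = c("N", "C", "C", "O", "C"),
  dx = c(-1.20, 0.00, 1.20, 1.45, -0.10),
  dy = c( 0.50, 0.00, 0.50, 1.65, -1.40),
  dz = c( 0.00, 0.00, 0.00, 0.20,  0.60),
  charge = c(-0.40, 0.10, 0.60, -0.55, 0.25),
  stringsAsFactors = FALSE)

# residue frames for each toy geometry: origin + orthonormal basis per residue
.toy_frames <- function(n, geometry) {
  origins <- matrix(0, n, 3)
  ex <- matrix(rep(c(1, 0, 0), n), n, 3, byrow = TRUE)
  ey <- matrix(rep(c(0, 1, 0), n), n, 3, byrow = TRUE)
  ez <- matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE)
  if (geometry == "extended") {
    origins[, 1] <- (seq_len(n) - 1) * 3.9
    # alternate the y direction so carbonyls zig-zag as in a strand
    flip <- rep_len(c(1, -1), n)
    ey <- ey * flip
    ez <- ez * flip
  } else if (geometry == "helixlike") {
    # tight coil: i and i+3 come within the 4 A contact threshold
    theta <- (seq_len(n) - 1) * 100 * pi / 180
    r <- 2.3; rise <- 1.15
    origins[, 1] <- r * cos(theta)
    origins[, 2] <- r * sin(theta)
    origins[, 3] <- (seq_len(n) - 1) * rise
    # local frame: tangent-ish x, radial y
    ex[, 1] <- -sin(theta); ex[, 2] <- cos(theta); ex[, 3] <- 0
    ey[, 1] <- cos(theta);  ey[, 2] <- sin(theta); ey[, 3] <- 0
    ez[, 1] <- 0; ez[, 2] <- 0; ez[, 3] <- 1
  } else { # hairpin: out along +x, turn, back along -x offset 3.5 A in y
    half <- ceiling(n / 2)
    for (i in seq_len(n)) {
      if (i <= half) {
        origins[i, ] <- c((i - 1) * 3.9, 0, 0)
      } else {
        origins[i, ] <- c((n - i) * 3.9 + 1.0, 3.5, 0)
        ex[i, ] <- c(-1, 0, 0); ey[i, ] <- c(0, -1, 0)  # reversed strand
      }
    }
  }
  list(origins = origins, ex = ex, ey = ey, ez = ez)
}

#' Generate an idealized toy polypeptide
#'
#' A single chain of `n_residues` five-atom model residues (backbone N,
#' CA, C, O plus a side-centroid pseudo-atom) with fixed internal
#' coordinates and designed per-residue net charges. The generator is a
#' deterministic function of the spec.
#'
#' @param spec a [toy_spec()]
#' @return a [charged_system()] with segment `"protein"`
#' @export
make_toy_polypeptide <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  n <- spec$n_residues
  fr <- .toy_frames(n, spec$geometry)
  tpl <- .toy_template
  m <- nrow(tpl)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    xyz <- fr$origins[rep(i, m), ] +
      outer(tpl$dx, fr$ex[i, ]) + outer(tpl$dy, fr$ey[i, ]) +
      outer(tpl$dz, fr$ez[i, ])
    q <- tpl$charge
    q[tpl$name == "CB"] <- q[tpl$name == "CB"] + spec$residue_net_charges[i]
    data.frame(serial = (i - 1L) * m + seq_len(m), name = tpl$name,
               element = tpl$element, resid = i, resname = "TOY",
               segment = "protein", chain = "A",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = q,
               stringsAsFactors = FALSE)
  }))
  charged_system(atoms)
}

#' Generate a probe-bearing toy ligand
#'
#' A carbonyl C=O pair 1.23 Angstrom apart along `direction`, optionally
#' bonded to a neutral planar six-membered ring. The returned
#' `exclusion` element lists the atom serials of the canonical probe
#' exclusion set (the C=O and, when present, the ring it is bonded to).
#'
#' @param position 3-vector, position of the probe carbon (Angstrom)
#' @param direction unit 3-vector, C -> O direction
#' @param ring attach a six-membered ring to the probe carbon?
#' @param q_c,q_o partial charges on the probe carbon and oxygen (e)
#' @param serial_offset added to all atom serials (for merging systems)
#' @return list with `system` (a `charged_system`, segment `"ligand"`),
#'   `probe` (a [probe_bond()]) and `exclusion` (atom serials)
#' @export
make_probe_ligand <- function(position = c(0, 0, 0),
                              direction = c(1, 0, 0), ring = TRUE,
                              q_c = 0.5, q_o = -0.5,
                              serial_offset = 0L) {
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("direction must be a non-zero vector")
  if (abs(nd - 1) > 1e-12) stop("direction must have unit norm")
  u <- direction
  # orthonormal frame around the bond axis
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u; v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  c_xyz <- position
  o_xyz <- position + 1.23 * u
  rows <- list(
    data.frame(serial = 1L, name = "C19", element = "C",
               x = c_xyz[1], y = c_xyz[2], z = c_xyz[3], charge = q_c),
    data.frame(serial = 2L, name = "O19", element = "O",
               x = o_xyz[1], y = o_xyz[2], z = o_xyz[3], charge = q_o))
  if (ring) {
    # planar hexagon in the (-u, w) plane, bonded to the probe carbon
    centre <- position - 2.90 * u
    ang <- (0:5) * pi / 3
    ring_xyz <- t(vapply(ang, function(a)
      centre + 1.40 * (cos(a) * (-u) + sin(a) * w), numeric(3)))
    rows[[3]] <- data.frame(serial = 2L + 1:6,
                            name = paste0("CR", 1:6), element = "C",
                            x = ring_xyz[, 1], y = ring_xyz[, 2],
                            z = ring_xyz[, 3], charge = 0)
  }
  at <- do.call(rbind, rows)
  at$serial <- at$serial + serial_offset
  at$resid <- 1L; at$resname <- "LIG"; at$segment <- "ligand"
  at$chain <- "L"
  at <- at[, c("serial", "name", "element", "resid", "resname",
               "segment", "chain", "x", "y", "z", "charge")]
  sys <- charged_system(at)
  list(system = sys,
       probe = probe_bond(sys, at$serial[1], at$serial[2]),
       exclusion = at$serial)
}

#' Merge charged systems into one
#'
#' Atoms are concatenated in the order given; serials must not collide.
#'
#' @param ... `charged_system` objects
#' @param eps_eff dielectric of the merged system
#' @return a `charged_system`
#' @export
merge_systems <- function(..., eps_eff = 1.0) {
  parts <- list(...)
  atoms <- do.call(rbind, lapply(parts, function(s) s$atoms))
  charged_system(atoms, eps_eff = eps_eff)
}

#' Generate a synthetic trajectory
#'
#' Frame t = reference coordinates + i.i.d. Gaussian jitter of standard
#' deviation `spec$jitter_sigma`. If `spec$hbond_model` is set, the
#' designated donor atom is repositioned each frame along the reference
#' donor->acceptor axis so that the donor-acceptor distance is exactly
#' `r_bound` with probability `p_bound` and `r_broken` otherwise
#' (independent frames, so occupancy estimators are exactly binomial).
#' Deterministic given `spec$seed`.
#'
#' @param system a `charged_system` supplying topology and reference
#'   coordinates
#' @param spec a [toy_spec()] (fields `n_frames`, `jitter_sigma`,
#'   `hbond_model`, `seed`)
#' @return a [trajectory()]
#' @export
make_trajectory <- function(system, spec) {
  stopifnot(inherits(spec, "toy_spec"))
  ref <- coords(system)
  n_at <- nrow(ref)
  nf <- spec$n_frames
  xyz <- array(rep(ref, nf), dim = c(n_at, 3, nf))
  if (spec$jitter_sigma > 0) {
    set.seed(spec$seed + 1000L)
    xyz <- xyz + array(stats::rnorm(n_at * 3 * nf, sd = spec$jitter_sigma),
                       dim = c(n_at, 3, nf))
  }
  hb <- spec$hbond_model
  if (!is.null(hb)) {
    di <- match(hb$donor, system$atoms$serial)
    ai <- match(hb$acceptor, system$atoms$serial)
    if (is.na(di) || is.na(ai))
      stop("hbond_model donor/acceptor serial not in system")
    axis <- ref[di, ] - ref[ai, ]
    axis <- axis / sqrt(sum(axis^2))
    set.seed(spec$seed + 2000L)
    bound <- stats::runif(nf) < hb$p_bound
    r <- ifelse(bound, hb$r_bound, hb$r_broken)
    for (t in seq_len(nf))
      xyz[di, , t] <- xyz[ai, , t] + r[t] * axis
    attr(xyz, "hbond_bound") <- bound
  }
  traj <- trajectory(system, xyz)
  traj$hbond_bound <- attr(xyz, "hbond_bound")
  traj
}

#' Analytic electric-field benchmark scenes
#'
#' Small scenes whose exact bond-projected field is known in closed
#' form, used as oracles for the Coulomb engine.
#'
#' * `single_charge`: +1 e at the origin, probe C at (3,0,0) and O at
#'   (4,0,0); mean field 14.399645 x (1/3 - 1/4) x 100 MV/cm.
#' * `dipole_pair`: +/-1 e placed symmetrically so the field is exactly
#'   perpendicular to the probe bond; projected field 0.
#' * `capacitor`: two parallel square lattices of point charges; the
#'   analytic value is the infinite-sheet uniform-field formula
#'   4 pi k sigma, which the discrete scene approaches for plates much
#'   wider than their separation.
#'
#' @param kind one of `"single_charge"`, `"dipole_pair"`, `"capacitor"`
#' @param plate_half_width,plate_spacing,plate_sep,q_site capacitor
#'   geometry: half-width and lattice spacing of each plate (Angstrom),
#'   plate separation, and charge per lattice site (e)
#' @return list with `system` (sources plus probe atoms), `probe`,
#'   `exclusion` (the probe atoms' serials) and `analytic_MVcm`
#' @export
make_field_benchmark <- function(kind = c("single_charge", "dipole_pair",
                                          "capacitor"),
                                 plate_half_width = 200,
                                 plate_spacing = 1, plate_sep = 6,
                                 q_site = 0.01) {
  kind <- match.arg(kind)
  k <- sf_constants$coulomb_VA_e
  probe_atoms <- function(c_xyz, o_xyz, serial0) {
    data.frame(serial = serial0 + 0:1, name = c("C19", "O19"),
               element = c("C", "O"), resid = 1L, resname = "LIG",
               segment = "ligand", chain = "L",
               x = c(c_xyz[1], o_xyz[1]), y = c(c_xyz[2], o_xyz[2]),
               z = c(c_xyz[3], o_xyz[3]), charge = 0,
               stringsAsFactors = FALSE)
  }
  src <- function(xyz, q) {
    n <- nrow(xyz)
    data.frame(serial = seq_len(n), name = "Q", element = "X",
               resid = seq_len(n), resname = "CHG", segment = "ion",
               chain = "S", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               charge = q, stringsAsFactors = FALSE)
  }
  if (kind == "single_charge") {
    sources <- src(matrix(c(0, 0, 0), 1), 1)
    pa <- probe_atoms(c(3, 0, 0), c(4, 0, 0), 2L)
    analytic <- k * (1 / 3 - 1 / 4) / 1.0 * sf_constants$VA_to_MVcm
  } else if (kind == "dipole_pair") {
    # +/- charges mirror-symmetric about the y axis; probe along y sees
    # a field in x only, so the bond projection vanishes
    sources <- src(rbind(c(-2, 0, 0), c(2, 0, 0)), c(1, -1))
    pa <- probe_atoms(c(0, 1, 0), c(0, 2.23, 0), 3L)
    analytic <- 0
  } else {
    g <- seq(-plate_half_width, plate_half_width, by = plate_spacing)
    lat <- as.matrix(expand.grid(x = g, y = g))
    half <- plate_sep / 2
    xyz <- rbind(cbind(lat, z = -half), cbind(lat, z = half))
    q <- c(rep(q_site, nrow(lat)), rep(-q_site, nrow(lat)))
    sources <- src(xyz, q)
    mid <- 1.23 / 2
    pa <- probe_atoms(c(0, 0, -mid), c(0, 0, mid), nrow(xyz) + 1L)
    sigma <- q_site / plate_spacing^2
    # uniform-field formula E = sigma/eps0 = 4 pi k sigma, pointing
    # +z between the plates; phi decreases along C->O so the projected
    # field (phiC - phiO)/L is positive
    analytic <- 4 * pi * k * sigma * sf_constants$VA_to_MVcm
  }
  atoms <- rbind(sources, pa)
  atoms$serial <- seq_len(nrow(atoms))     # renumber to be safe
  sys <- charged_system(atoms)
  n <- nrow(atoms)
  list(system = sys,
       probe = probe_bond(sys, atoms$serial[n - 1], atoms$serial[n]),
       exclusion = atoms$serial[c(n - 1, n)],
       analytic_MVcm = analytic)
}
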