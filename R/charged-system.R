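#' Construct a charged system
#'
#' A `charged_system` is the universe every electrostatic sum runs over:
#' an ordered atom table with coordinates (Angstrom) and partial charges
#' (elementary charge units), a residue grouping, and an effective
#' dielectric constant.
#'
#' @param atoms data.frame with columns `serial` (integer id), `name`
#'   (atom name), `element` (symbol), `resid` (1-based residue index),
#'   `resname`, `segment` (one of `"protein"`, `"ligand"`, `"solvent"`,
#'   `"ion"`), `chain`, `x`, `y`, `z` (Angstrom), `charge` (e).
#' @param eps_eff effective dielectric constant (> 0); 1.0 when explicit
#'   solvent is present in the atom table.
#' @return object of class `charged_system`
#' @export
charged_system <- function(atoms, eps_eff = 1.0) {
  required <- c("serial", "name", "element", "resid", "resname",
                "segment", "chain", "x", "y", "z", "charge")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    stop("atoms table lacks columns: ", paste(missing, collapse = ", "))
  if (!is.numeric(eps_eff) || length(eps_eff) != 1 || eps_eff <= 0)
    stop("eps_eff must be a single positive number")
  if (nrow(atoms) > 0) {
    if (anyDuplicated(atoms$serial))
      stop("duplicate atom serial(s): ",
           paste(unique(atoms$serial[duplicated(atoms$serial)]), collapse = ", "))
    if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
      stop("non-finite coordinates in atom table")
    if (any(!nzchar(atoms$element)))
      stop("empty element symbol in atom table")
    if (any(atoms$resid < 1))
      stop("residue indices must be >= 1")
    bad <- !atoms$segment %in% c("protein", "ligand", "solvent", "ion")
    if (any(bad))
      stop("unknown segment label(s): ",
           paste(unique(atoms$segment[bad]), collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, eps_eff = eps_eff),
            class = "charged_system")
}

#' @export
print.charged_system <- function(x, ...) {
  a <- x$atoms
  cat("charged_system:", nrow(a), "atoms,",
      length(unique(residue_keys(x))), "residues\n")
  tab <- table(a$segment)
  cat("  segments:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  cat("  total charge:", format(sum(a$charge), digits = 6), "e;  eps_eff:",
      x$eps_eff, "\n")
  invisible(x)
}

#' Residue group keys
#'
#' One key per atom identifying its residue group
#' (`segment:chain:resid`). Every atom belongs to exactly one group.
#'
#' @param sys a `charged_system`
#' @return character vector, one element per atom
#' @export
residue_keys <- function(sys) {
  a <- sys$atoms
  paste(a$segment, a$chain, a$resid, sep = ":")
}

#' Atom indices of one residue group
#'
#' @param sys a `charged_system`
#' @param key residue key as produced by [residue_keys()]
#' @return integer row indices into `sys$atoms`
#' @export
residue_atoms <- function(sys, key) {
  idx <- which(residue_keys(sys) == key)
  if (length(idx) == 0) stop("no atoms in residue group '", key, "'")
  idx
}

#' Coordinates of a system as an n x 3 matrix
#' @param sys a `charged_system`
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(sys) {
  m <- as.matrix(sys$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Classify a residue name into a segment
#'
#' Water residue names map to `"solvent"`, common counter-ion names to
#' `"ion"`, standard amino-acid names (plus Amber protonation variants)
#' to `"protein"`, anything else to `"ligand"`.
#'
#' @param resname character vector of residue names
#' @param overrides optional named character vector mapping residue names
#'   to segments, applied before the built-in rules
#' @return character vector of segments
#' @export
classify_segment <- function(resname, overrides = NULL) {
  resname <- toupper(trimws(resname))
  seg <- rep("ligand", length(resname))
  seg[resname %in% .aa3] <- "protein"
  seg[resname %in% .solvent_names] <- "solvent"
  seg[resname %in% .ion_names] <- "ion"
  if (!is.null(overrides)) {
    hit <- resname %in% names(overrides)
    seg[hit] <- unname(overrides[resname[hit]])
  }
  seg
}

#' Define a probe bond
#'
#' The two atoms of a carbonyl (C=O) vibrational probe. Geometry (bond
#' length and the C->O unit vector) is evaluated per frame with
#' [probe_geometry()].
#'
#' @param sys a `charged_system`
#' @param c_atom,o_atom atom serial numbers of the carbon and oxygen
#' @return object of class `probe_bond` holding atom row indices
#' @export
probe_bond <- function(sys, c_atom, o_atom) {
  ci <- match(c_atom, sys$atoms$serial)
  oi <- match(o_atom, sys$atoms$serial)
  if (is.na(ci)) stop("probe C atom serial ", c_atom, " not in system")
  if (is.na(oi)) stop("probe O atom serial ", o_atom, " not in system")
  if (ci == oi) stop("probe atoms must be distinct")
  structure(list(c_idx = ci, o_idx = oi,
                 c_serial = c_atom, o_serial = o_atom),
            class = "probe_bond")
}

#' Per-frame probe geometry
#'
#' @param xyz n x 3 coordinate matrix for the frame
#' @param probe a `probe_bond`
#' @return list with `c_xyz`, `o_xyz`, `length` (Angstrom) and
#'   `direction` (unit vector C->O)
#' @export
probe_geometry <- function(xyz, probe) {
  c_xyz <- unname(xyz[probe$c_idx, ])
  o_xyz <- unname(xyz[probe$o_idx, ])
  d <- o_xyz - c_xyz
  len <- sqrt(sum(d^2))
  if (len <= 0) stop("probe bond has zero length")
  list(c_xyz = c_xyz, o_xyz = o_xyz, length = len, direction = d / len)
}

#' Minimum inter-group atom distance
#'
#' Minimum Euclidean distance over all atom pairs between two residue
#' groups; the contact criterion used when selecting generalized-concap
#' partners.
#'
#' @param sys a `charged_system`
#' @param frame optional n x 3 coordinate matrix (defaults to the
#'   system's own coordinates)
#' @param group_a,group_b residue keys (see [residue_keys()]) or integer
#'   atom index vectors
#' @param heavy_only if `TRUE`, hydrogen atoms are ignored
#' @return minimum distance in Angstrom
#' @export
residue_min_distance <- function(sys, group_a, group_b, frame = NULL,
                                 heavy_only = FALSE) {
  ia <- if (is.character(group_a)) residue_atoms(sys, group_a) else as.integer(group_a)
  ib <- if (is.character(group_b)) residue_atoms(sys, group_b) else as.integer(group_b)
  if (length(ia) == 0 || length(ib) == 0) stop("empty atom group")
  if (length(intersect(ia, ib)) > 0)
    stop("groups must be disjoint (identical or overlapping groups given)")
  if (heavy_only) {
    ia <- ia[sys$atoms$element[ia] != "H"]
    ib <- ib[sys$atoms$element[ib] != "H"]
    if (length(ia) == 0 || length(ib) == 0)
      stop("no heavy atoms left in a group")
  }
  xyz <- if (is.null(frame)) coords(sys) else frame
  pa <- xyz[ia, , drop = FALSE]
  pb <- xyz[ib, , drop = FALSE]
  # pairwise squared distances without forming loops in R
  cross <- pa %*% t(pb)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * cross
  sqrt(max(0, min(d2)))
}
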