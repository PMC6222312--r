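#' Build an exclusion set
#'
#' Atom serials excluded from every electrostatic-potential sum: by
#' convention the probe C=O and the ring it is bonded to (their own
#' charges would dominate the potential at the evaluation points with
#' non-physical self-terms), plus optionally whole segments.
#'
#' @param sys a `charged_system`
#' @param serials atom serials to exclude
#' @param segments segment names to exclude wholesale
#' @return integer vector of atom row indices, class `exclusion_set`
#' @export
exclusion_set <- function(sys, serials = integer(), segments = character()) {
  idx <- integer()
  if (length(serials) > 0) {
    m <- match(serials, sys$atoms$serial)
    if (anyNA(m))
      stop("exclusion serial(s) not in system: ",
           paste(serials[is.na(m)], collapse = ", "))
    idx <- c(idx, m)
  }
  if (length(segments) > 0)
    idx <- c(idx, which(sys$atoms$segment %in% segments))
  structure(sort(unique(idx)), class = "exclusion_set")
}

#' Point-charge electrostatic potential at a point
#'
#' Coulomb sum `(1/eps_eff) * k * sum_j q_j / |r - r_j|` in volts over
#' every atom not excluded, with `k = 14.399645` V*A/e. No cutoff and no
#' periodic images: the sum runs over all atoms present.
#'
#' @param sys a `charged_system`
#' @param point 3-vector, Angstrom
#' @param excl atom row indices to exclude (e.g. an [exclusion_set()])
#' @param xyz optional n x 3 coordinate matrix overriding the system's
#'   coordinates (a trajectory frame)
#' @return potential in volts
#' @export
esp_at_point <- function(sys, point, excl = integer(), xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(sys)
  keep <- setdiff(seq_len(nrow(sys$atoms)), excl)
  if (length(keep) == 0) return(0)
  xyz <- xyz[keep, , drop = FALSE]
  q <- sys$atoms$charge[keep]
  d <- sqrt((xyz[, 1] - point[1])^2 + (xyz[, 2] - point[2])^2 +
            (xyz[, 3] - point[3])^2)
  if (any(d <= 1e-6)) {
    at <- sys$atoms[keep[which.min(d)], ]
    stop("evaluation point coincides with atom serial ", at$serial,
         " (", at$name, " ", at$resname, " ", at$resid, ")")
  }
  sf_constants$coulomb_VA_e / sys$eps_eff * sum(q / d)
}

#' Bond-projected mean electric field
#'
#' Evaluates the potential at points on the probe bond axis (the C and O
#' centers, each optionally moved `offset` Angstrom toward the bond
#' midpoint) and returns the mean field along the bond,
#' `(phi_C - phi_O) / |r_CO|`, converted to MV/cm. The sign convention
#' is literal: negative values mean the field points from O to C.
#'
#' @param sys a `charged_system`
#' @param probe a [probe_bond()]
#' @param excl atom row indices excluded from the potential sums
#' @param offset Angstrom; evaluation points move this far from the
#'   atomic centers toward the bond midpoint (must be < half the bond
#'   length)
#' @param xyz optional coordinate frame
#' @param frame_index,group provenance labels carried into the record
#' @return one-row data.frame (a field record) with columns `frame`,
#'   `group`, `phi_c_V`, `phi_o_V`, `length_A`, `field_MVcm`
#' @export
bond_field <- function(sys, probe, excl = integer(), offset = 0,
                       xyz = NULL, frame_index = NA_integer_,
                       group = "total") {
  if (is.null(xyz)) xyz <- coords(sys)
  g <- probe_geometry(xyz, probe)
  if (offset < 0) stop("offset must be >= 0")
  if (offset >= g$length / 2)
    stop("offset (", offset, " A) must be smaller than half the bond length (",
         format(g$length / 2, digits = 4), " A)")
  p_c <- g$c_xyz + offset * g$direction
  p_o <- g$o_xyz - offset * g$direction
  phi_c <- esp_at_point(sys, p_c, excl = excl, xyz = xyz)
  phi_o <- esp_at_point(sys, p_o, excl = excl, xyz = xyz)
  data.frame(frame = frame_index, group = group,
             phi_c_V = phi_c, phi_o_V = phi_o, length_A = g$length,
             field_MVcm = (phi_c - phi_o) / g$length * sf_constants$VA_to_MVcm,
             stringsAsFactors = FALSE)
}

#' Field along the probe bond over a trajectory
#'
#' One field record per frame plus the unweighted arithmetic mean over
#' frames (the time average; saved frames are treated as equally
#' spaced).
#'
#' @inheritParams bond_field
#' @param traj a [trajectory()]
#' @return list of class `field_series`: `records` (data.frame, one row
#'   per frame) and `mean_field` (MV/cm)
#' @export
field_series <- function(traj, probe, excl = integer(), offset = 0,
                         group = "total") {
  nf <- n_frames(traj)
  if (nf < 1) stop("trajectory has no frames")
  recs <- do.call(rbind, lapply(seq_len(nf), function(t)
    bond_field(traj$topology, probe, excl = excl, offset = offset,
               xyz = frame_coords(traj, t), frame_index = t,
               group = group)))
  structure(list(records = recs, mean_field = mean(recs$field_MVcm)),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat("field_series:", nrow(x$records), "frames; mean",
      format(x$mean_field, digits = 6), "MV/cm\n")
  invisible(x)
}

#' Decompose the bond field by source group
#'
#' Splits the included atoms into disjoint groups (for example per
#' residue, or protein vs solvent) and reports each group's
#' contribution to the bond-projected field. Contributions are exactly
#' additive: their sum equals the total field.
#'
#' @inheritParams bond_field
#' @param groups named list of atom row-index vectors; must partition
#'   the included (non-excluded) atoms
#' @return data.frame of field records, one row per group plus a final
#'   `"total"` row
#' @export
decompose_field <- function(sys, probe, groups, excl = integer(),
                            offset = 0, xyz = NULL,
                            frame_index = NA_integer_) {
  if (is.null(xyz)) xyz <- coords(sys)
  all_idx <- sort(unlist(groups, use.names = FALSE))
  if (anyDuplicated(all_idx))
    stop("groups overlap: atom indices appear in more than one group")
  included <- setdiff(seq_len(nrow(sys$atoms)), excl)
  if (!identical(sort(included), all_idx))
    stop("groups must partition the included atoms exactly")
  n <- nrow(sys$atoms)
  rows <- lapply(names(groups), function(gname) {
    keep <- groups[[gname]]
    bond_field(sys, probe, excl = setdiff(seq_len(n), keep),
               offset = offset, xyz = xyz, frame_index = frame_index,
               group = gname)
  })
  out <- do.call(rbind, rows)
  total <- bond_field(sys, probe, excl = excl, offset = offset,
                      xyz = xyz, frame_index = frame_index,
                      group = "total")
  rbind(out, total)
}

#' Group atoms by residue
#'
#' Convenience partition for [decompose_field()]: one group per residue
#' of the selected segments, excluding any atoms in `excl`.
#'
#' @param sys a `charged_system`
#' @param segments segments to cover
#' @param excl atom row indices to drop from the partition
#' @return named list of atom index vectors
#' @export
residue_groups <- function(sys, segments = c("protein", "ligand",
                                             "solvent", "ion"),
                           excl = integer()) {
  keys <- residue_keys(sys)
  keep <- which(sys$atoms$segment %in% segments)
  keep <- setdiff(keep, excl)
  split(keep, keys[keep])
}

#' Hydrogen-bond distance series, occupancy and histograms
#'
#' For each heavy-atom donor/acceptor pair, the per-frame distance, the
#' occupancy (fraction of frames at or below the break cutoff; a
#' hydrogen bond is considered broken beyond 3.5 Angstrom), and a
#' distance histogram.
#'
#' @param traj a [trajectory()]
#' @param pairs list of length-2 vectors of atom serials, or a two-column
#'   matrix/data.frame of serials
#' @param cutoff break criterion, Angstrom (> 0)
#' @param bin_width histogram bin width, Angstrom
#' @return list of class `hbond_series`, one element per pair: list with
#'   `pair`, `distance` (per frame), `occupancy`, `hist` (counts +
#'   breaks)
#' @export
hbond_series <- function(traj, pairs, cutoff = 3.5, bin_width = 0.1) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.matrix(pairs) || is.data.frame(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i) unlist(pairs[i, 1:2]))
  serials <- traj$topology$atoms$serial
  out <- lapply(pairs, function(p) {
    if (p[1] == p[2]) stop("hydrogen-bond pair has identical atoms: ", p[1])
    i <- match(p[1], serials); j <- match(p[2], serials)
    if (is.na(i) || is.na(j))
      stop("pair atom serial not in topology: ", p[c(is.na(i), is.na(j))])
    di <- matrix(traj$xyz[i, , ], nrow = 3)
    dj <- matrix(traj$xyz[j, , ], nrow = 3)
    d <- sqrt(colSums((di - dj)^2))
    brks <- seq(floor(min(d) / bin_width) * bin_width,
                ceiling(max(d) / bin_width) * bin_width + bin_width,
                by = bin_width)
    h <- graphics::hist(d, breaks = brks, plot = FALSE)
    list(pair = p, distance = d, occupancy = mean(d <= cutoff),
         hist = list(breaks = h$breaks, counts = h$counts,
                     mids = h$mids))
  })
  names(out) <- vapply(pairs, function(p) paste(p, collapse = "-"), "")
  structure(out, class = "hbond_series")
}
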