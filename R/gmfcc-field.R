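#' Assemble the fragment-based electrostatic potential
#'
#' Evaluates the backend on every fragment of the scheme and combines
#' the results with their signs: capped fragments (+), conjugate caps
#' (-), and for every generalized-concap set the two-body correction
#' pair - single_i - single_j. With the additive surrogate backend the
#' assembly telescopes to the direct whole-system Coulomb potential at
#' machine precision, and every two-body correction is exactly zero.
#'
#' @param scheme a `fragment_scheme`
#' @param backend backend function from [esp_backend()], or its name
#' @param points matrix (n x 3) or single 3-vector of evaluation points
#' @param sys the `charged_system` the scheme was built on
#' @param include_solvent_background embed solvent atoms in fragment
#'   backgrounds (QM backends only; the surrogate ignores backgrounds)
#' @return object of class `assembled_esp`: `potentials` (volts, per
#'   point) and `ledger` (data.frame: fragment, kind, sign, one column
#'   per point)
#' @export
assemble_esp <- function(scheme, backend, points, sys,
                         include_solvent_background = FALSE) {
  if (is.character(backend)) backend <- esp_backend(backend)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  np <- nrow(points)
  vals <- matrix(NA_real_, length(scheme$fragments), np)
  for (k in seq_along(scheme$fragments)) {
    f <- scheme$fragments[[k]]
    bg <- embedding_charges(scheme, f, sys,
                            include_solvent = include_solvent_background)
    req <- esp_request(f, sys, bg, points)
    res <- tryCatch(backend(req), error = function(e)
      stop("ESP backend failed on fragment ", f$id, ": ",
           conditionMessage(e), call. = FALSE))
    vals[k, ] <- res$potentials
  }
  signs <- vapply(scheme$fragments, `[[`, numeric(1), "sign")
  total <- as.numeric(t(vals) %*% signs)
  ledger <- data.frame(
    fragment = vapply(scheme$fragments, `[[`, "", "id"),
    kind = vapply(scheme$fragments, `[[`, "", "kind"),
    sign = signs, stringsAsFactors = FALSE)
  for (p in seq_len(np)) ledger[[paste0("V", p)]] <- vals[, p]
  structure(list(potentials = total, ledger = ledger),
            class = "assembled_esp")
}

#' @export
print.assembled_esp <- function(x, ...) {
  cat("assembled_esp:", length(x$potentials), "point(s);",
      nrow(x$ledger), "fragment terms\n")
  cat("  V =", paste(format(x$potentials, digits = 8), collapse = ", "),
      "volts\n")
  invisible(x)
}

#' Net two-body (gconcap) correction of an assembly
#'
#' Sums the signed gconcap terms of the ledger per point; with an
#' additive backend this is exactly zero.
#'
#' @param assembled an `assembled_esp`
#' @return numeric vector, volts per point
#' @export
gconcap_correction <- function(assembled) {
  led <- assembled$ledger
  g <- led$kind %in% c("gconcap_pair", "gconcap_single")
  vcols <- grep("^V[0-9]+$", names(led), value = TRUE)
  if (!any(g)) return(rep(0, length(vcols)))
  as.numeric(colSums(led[g, vcols, drop = FALSE] * led$sign[g]))
}

#' Select the representative trajectory frame
#'
#' The single-snapshot protocol: from a per-frame field series, pick
#' the frame whose field lies closest to the time-average value; ties
#' break toward the earliest frame.
#'
#' @param series a `field_series`, or a numeric vector of per-frame
#'   fields
#' @return frame index (1-based)
#' @export
select_representative_frame <- function(series) {
  f <- if (inherits(series, "field_series")) series$records$field_MVcm
       else as.numeric(series)
  if (length(f) == 0) stop("empty field series")
  which.min(abs(f - mean(f)))   # which.min takes the first minimum
}

#' Fragment-based bond field with classical amendments
#'
#' The full protocol for one probe bond: the protein contribution comes
#' from the fragment-assembled potential (evaluated at points slightly
#' off the atomic centers along the bond), while the ligand (probe ring
#' excluded) and solvent contributions are classical point-charge time
#' averages over the trajectory. The three components are reported
#' separately and sum to the total.
#'
#' @param sys the full `charged_system` (protein + ligand + solvent)
#' @param traj a [trajectory()] of the system
#' @param probe a [probe_bond()]
#' @param ring_excl atom row indices of the probe C=O and its ring (the
#'   canonical exclusion set)
#' @param backend ESP backend function or name (see [esp_backend()])
#' @param lambda gconcap contact threshold, Angstrom
#' @param offset evaluation-point offset toward the bond midpoint,
#'   Angstrom (default 0.1)
#' @param frame representative frame index; `NULL` selects it by the
#'   single-snapshot rule from the classical field series
#' @param include_ligand_gconcaps include ligand-residue two-body terms
#' @return list of class `gmfcc_field`: `total` (MV/cm), `components`
#'   (protein_qm, ligand_classical, solvent_classical), `frame`,
#'   `scheme`, `assembly` (list of two `assembled_esp`), `series` (the
#'   classical field series used for frame selection)
#' @export
gmfcc_bond_field <- function(sys, traj, probe, ring_excl, backend,
                             lambda = 4.0, offset = 0.1, frame = NULL,
                             include_ligand_gconcaps = TRUE) {
  # classical series with the canonical exclusions drives frame choice
  series <- field_series(traj, probe, excl = ring_excl, offset = offset)
  if (is.null(frame)) frame <- select_representative_frame(series)
  xyz <- frame_coords(traj, frame)
  snap <- sys
  snap$atoms$x <- xyz[, 1]; snap$atoms$y <- xyz[, 2]
  snap$atoms$z <- xyz[, 3]

  g <- probe_geometry(xyz, probe)
  if (offset >= g$length / 2)
    stop("offset must be smaller than half the probe bond length")
  pts <- rbind(g$c_xyz + offset * g$direction,
               g$o_xyz - offset * g$direction)

  scheme <- fragment_protein(snap, lambda = lambda)
  scheme <- build_gconcaps(snap, scheme,
                           include_ligand = include_ligand_gconcaps)
  asm <- assemble_esp(scheme, backend, pts, snap)
  protein_qm <- (asm$potentials[1] - asm$potentials[2]) / g$length *
    sf_constants$VA_to_MVcm

  n <- nrow(sys$atoms)
  lig_keep <- setdiff(which(sys$atoms$segment == "ligand"), ring_excl)
  lig_series <- field_series(traj, probe,
                             excl = setdiff(seq_len(n), lig_keep),
                             offset = offset, group = "ligand")
  solv_keep <- which(sys$atoms$segment %in% c("solvent", "ion"))
  solv_series <- field_series(traj, probe,
                              excl = setdiff(seq_len(n), solv_keep),
                              offset = offset, group = "solvent")
  comps <- c(protein_qm = protein_qm,
             ligand_classical = lig_series$mean_field,
             solvent_classical = solv_series$mean_field)
  structure(list(total = sum(comps), components = comps, frame = frame,
                 scheme = scheme, assembly = asm, series = series),
            class = "gmfcc_field")
}

#' @export
print.gmfcc_field <- function(x, ...) {
  cat("gmfcc_field: total", format(x$total, digits = 6),
      "MV/cm (frame", x$frame, ")\n")
  for (nm in names(x$components))
    cat(sprintf("  %-18s %10.4f MV/cm\n", nm, x$components[[nm]]))
  invisible(x)
}
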