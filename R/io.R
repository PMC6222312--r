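#' Read a structure file into a charged system
#'
#' Two dialects are supported. `"pqr"` is the canonical charged-structure
#' interchange: whitespace-separated ATOM/HETATM records carrying
#' `serial name resname resid x y z charge radius`. `"pdb"` reads
#' standard fixed-column PDB ATOM/HETATM records (via bio3d); charges are
#' zero until [assign_charges()] supplies them. Segments are classified
#' from residue names (see [classify_segment()]). Alternate locations:
#' only altloc A (or blank) is kept, and a note is emitted.
#'
#' @param path file path
#' @param dialect `"pqr"` or `"pdb"`
#' @param overrides optional named vector of residue-name -> segment
#' @param eps_eff effective dielectric for the returned system
#' @return a [charged_system()]
#' @export
read_structure <- function(path, dialect = c("pqr", "pdb"),
                           overrides = NULL, eps_eff = 1.0) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "pqr") {
    atoms <- .parse_pqr_lines(readLines(path), path)
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    at <- pdb$atom
    if (!is.null(at$alt)) {
      alt <- ifelse(is.na(at$alt), "", at$alt)
      if (any(!alt %in% c("", "A")))
        message("alternate locations present; keeping altloc A only")
      at <- at[alt %in% c("", "A"), , drop = FALSE]
    }
    elem <- at$elesy
    if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem))))
      elem <- .element_from_name(at$elety)
    elem <- ifelse(is.na(elem) | !nzchar(trimws(elem)),
                   .element_from_name(at$elety), trimws(elem))
    atoms <- data.frame(
      serial = at$eleno, name = trimws(at$elety), element = elem,
      resid = at$resno, resname = trimws(at$resid),
      segment = NA_character_,
      chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
      x = at$x, y = at$y, z = at$z, charge = 0,
      stringsAsFactors = FALSE)
  }
  atoms$segment <- classify_segment(atoms$resname, overrides)
  charged_system(atoms, eps_eff = eps_eff)
}

.element_from_name <- function(name) {
  nm <- trimws(name)
  two <- toupper(substr(nm, 1, 2))
  first <- toupper(substr(gsub("[^A-Za-z].*$", "", nm), 1, 1))
  ifelse(two %in% c("CL", "NA", "MG", "BR", "FE", "ZN"), two, first)
}

.parse_pqr_lines <- function(lines, path, chain = "A") {
  keep <- grepl("^(ATOM|HETATM)", lines)
  rec <- lines[keep]
  lineno <- which(keep)
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  parts <- strsplit(trimws(rec), "[[:space:]]+")
  n <- length(parts)
  out <- data.frame(serial = integer(n), name = character(n),
                    element = character(n), resid = integer(n),
                    resname = character(n), segment = NA_character_,
                    chain = chain, x = 0, y = 0, z = 0, charge = 0,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    f <- parts[[k]]
    # optional chain id column between resname and resid
    has_chain <- length(f) >= 10 && is.na(suppressWarnings(as.numeric(f[5])))
    want <- if (has_chain) 11L else 10L
    if (length(f) < want - 1L)
      stop("malformed PQR row at line ", lineno[k], " of ", path,
           " (", length(f), " fields)")
    off <- if (has_chain) 1L else 0L
    num <- suppressWarnings(as.numeric(f[(6 + off):(9 + off)]))
    if (any(is.na(num)) || is.na(suppressWarnings(as.integer(f[5 + off]))))
      stop("malformed PQR row at line ", lineno[k], " of ", path)
    out$serial[k] <- as.integer(f[2]); out$name[k] <- f[3]
    out$resname[k] <- f[4]
    if (has_chain) out$chain[k] <- f[5]
    out$resid[k] <- as.integer(f[5 + off])
    out$x[k] <- num[1]; out$y[k] <- num[2]; out$z[k] <- num[3]
    out$charge[k] <- num[4]
  }
  if (anyDuplicated(out$serial))
    stop("duplicate atom serial(s) in ", path, ": ",
         paste(unique(out$serial[duplicated(out$serial)]), collapse = ", "))
  out$element <- .element_from_name(out$name)
  out
}

#' Write a charged system as PQR
#'
#' Whitespace-separated PQR with six decimal places on coordinates and
#' charges, so a write/read round trip preserves both to well below
#' 1e-6.
#'
#' @param sys a `charged_system`
#' @param path output path
#' @param radii optional per-atom radii (Angstrom); defaults to 1.5
#' @return `path`, invisibly
#' @export
write_structure <- function(sys, path, radii = NULL) {
  a <- sys$atoms
  if (is.null(radii)) radii <- rep(1.5, nrow(a))
  lines <- sprintf("ATOM %6d %-4s %-4s %s %5d %12.6f %12.6f %12.6f %11.6f %8.4f",
                   a$serial, a$name, a$resname, a$chain, a$resid,
                   a$x, a$y, a$z, a$charge, radii)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Assign charges from a lookup table
#'
#' Replaces every protein/ligand atom's charge by the table value keyed
#' on (residue name, atom name). Solvent and ion atoms keep their
#' current charges unless the table also covers them.
#'
#' @param sys a `charged_system`
#' @param table data.frame with columns `resname`, `name`, `charge`
#' @param default optional default charge for atoms without a table
#'   entry; if `NULL` (the default policy), missing entries are an error
#' @param quiet suppress the per-residue charge-sum report
#' @return the system with charges replaced
#' @export
assign_charges <- function(sys, table, default = NULL, quiet = TRUE) {
  a <- sys$atoms
  key <- paste(a$resname, a$name, sep = "|")
  tkey <- paste(table$resname, table$name, sep = "|")
  if (anyDuplicated(tkey))
    stop("charge table has duplicate (resname, name) entries")
  hit <- match(key, tkey)
  need <- a$segment %in% c("protein", "ligand")
  miss <- need & is.na(hit)
  if (any(miss) && is.null(default)) {
    pairs <- unique(paste0("(", a$resname[miss], ", ", a$name[miss], ")"))
    stop("no charge-table entry for: ", paste(pairs, collapse = ", "))
  }
  charge <- a$charge
  charge[need] <- ifelse(is.na(hit[need]), default, table$charge[hit[need]])
  cover <- !need & !is.na(hit)     # table may also cover solvent/ions
  charge[cover] <- table$charge[hit[cover]]
  sys$atoms$charge <- charge
  if (!quiet) {
    sums <- tapply(charge, residue_keys(sys), sum)
    message("per-residue charge sums:\n",
            paste(sprintf("  %s: %+0.4f e", names(sums), sums), collapse = "\n"))
  }
  sys
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL/ENDMDL block must contain exactly one ATOM/HETATM record
#' per topology atom, in topology order. A file without MODEL records is
#' treated as a single frame.
#'
#' @param path file path
#' @param topology the `charged_system` the frames share
#' @return object of class `trajectory`: list with `topology`, `xyz`
#'   (an `n_atoms` x 3 x `n_frames` array) and `frame_times` (ps or NA)
#' @export
read_trajectory <- function(path, topology) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  n_atoms <- nrow(topology$atoms)
  if (length(model_starts) == 0) {
    blocks <- list(which(is_atom))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    blocks <- mapply(function(s, e) {
      idx <- s:e
      idx[is_atom[idx]]
    }, model_starts, model_ends, SIMPLIFY = FALSE)
  }
  n_frames <- length(blocks)
  xyz <- array(NA_real_, dim = c(n_atoms, 3, n_frames))
  for (m in seq_len(n_frames)) {
    idx <- blocks[[m]]
    if (length(idx) != n_atoms)
      stop("model ", m, " of ", path, " has ", length(idx),
           " atoms; topology has ", n_atoms)
    rec <- lines[idx]
    xyz[, 1, m] <- as.numeric(substr(rec, 31, 38))
    xyz[, 2, m] <- as.numeric(substr(rec, 39, 46))
    xyz[, 3, m] <- as.numeric(substr(rec, 47, 54))
    if (anyNA(xyz[, , m]))
      stop("malformed coordinates in model ", m, " of ", path)
  }
  trajectory(topology, xyz)
}

#' Construct a trajectory object
#'
#' @param topology a `charged_system`
#' @param xyz `n_atoms` x 3 x `n_frames` array of coordinates (Angstrom)
#' @param frame_times optional frame times in ps
#' @return object of class `trajectory`
#' @export
trajectory <- function(topology, xyz, frame_times = NULL) {
  if (length(dim(xyz)) == 2) xyz <- array(xyz, dim = c(dim(xyz), 1))
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  if (dim(xyz)[1] != nrow(topology$atoms))
    stop("frame atom count (", dim(xyz)[1], ") != topology atom count (",
         nrow(topology$atoms), ")")
  structure(list(topology = topology, xyz = xyz,
                 frame_times = frame_times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", dim(x$xyz)[3], "frames x", dim(x$xyz)[1], "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`
#' @return integer
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Coordinates of one frame
#' @param traj a `trajectory`
#' @param i frame index (1-based)
#' @return n x 3 matrix
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range: ", i)
  traj$xyz[, , i]
}

#' Write a trajectory as multi-model PDB
#'
#' Fixed-column PDB ATOM records (8.3f coordinates) inside MODEL/ENDMDL
#' blocks, one block per frame.
#'
#' @param traj a `trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  a <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, m)
    writeLines(sprintf("MODEL %8d", m), con)
    writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f",
                       a$serial, substr(a$name, 1, 4),
                       substr(a$resname, 1, 3), substr(a$chain, 1, 1),
                       a$resid, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
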