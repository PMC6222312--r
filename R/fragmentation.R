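#' Place a hydrogen link atom on a cut bond
#'
#' When a covalent bond is cut, a hydrogen atom saturates the dangling
#' valence on the kept side: it lies on the kept->removed axis at a
#' standard X-H distance from the kept atom (1.09 Angstrom from a
#' carbon, 1.01 Angstrom from a nitrogen).
#'
#' @param kept_xyz 3-vector, the atom that stays in the fragment
#' @param removed_xyz 3-vector, the atom cut away
#' @param kept_element element symbol of the kept atom (`"C"` or `"N"`)
#' @return 3-vector, link hydrogen coordinates
#' @export
place_link_atom <- function(kept_xyz, removed_xyz, kept_element) {
  axis <- removed_xyz - kept_xyz
  len <- sqrt(sum(axis^2))
  if (len <= 0) stop("cut bond has zero length; cannot place link atom")
  d <- switch(toupper(kept_element), C = 1.09, N = 1.01,
              stop("no link-atom distance for kept element '",
                   kept_element, "'"))
  kept_xyz + d * axis / len
}

# --- internal fragment constructor -----------------------------------------

.make_fragment <- function(id, kind, center, real_idx, cap_idx, links,
                           sign, sys) {
  idx <- c(real_idx, cap_idx)
  qsum <- sum(sys$atoms$charge[idx])
  # integer net charge for QM backends; the raw sum is kept so the QM
  # adapter can warn when the rounding is material
  list(id = id, kind = kind, center = center,
       real_idx = as.integer(real_idx), cap_idx = as.integer(cap_idx),
       links = links, sign = sign, charge = round(qsum),
       charge_raw = qsum)
}

.empty_links <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             kept_serial = integer(0), removed_serial = integer(0))
}

.link_row <- function(sys, xyz, kept_idx, removed_idx) {
  h <- place_link_atom(xyz[kept_idx, ], xyz[removed_idx, ],
                       sys$atoms$element[kept_idx])
  data.frame(x = h[1], y = h[2], z = h[3],
             kept_serial = sys$atoms$serial[kept_idx],
             removed_serial = sys$atoms$serial[removed_idx])
}

# backbone atom row of residue run position i with a given name
.bb_idx <- function(sys, res_idx, name) {
  hit <- res_idx[sys$atoms$name[res_idx] == name]
  if (length(hit) != 1)
    stop("residue lacks a unique backbone atom '", name, "'")
  hit
}

# contiguous protein residue runs: list of integer vectors of residue
# keys in chain order; breaks at chain-id changes or resid gaps
.protein_runs <- function(sys) {
  a <- sys$atoms
  prot <- which(a$segment == "protein")
  if (length(prot) == 0) stop("system has no protein segment")
  keys <- unique(residue_keys(sys)[prot])
  parts <- do.call(rbind, strsplit(keys, ":"))
  ord <- order(parts[, 2], as.integer(parts[, 3]))
  keys <- keys[ord]; parts <- parts[ord, , drop = FALSE]
  runs <- list(); cur <- keys[1]
  for (k in seq_along(keys)[-1]) {
    contiguous <- parts[k, 2] == parts[k - 1, 2] &&
      as.integer(parts[k, 3]) == as.integer(parts[k - 1, 3]) + 1L
    if (contiguous) cur <- c(cur, keys[k])
    else { runs <- c(runs, list(cur)); cur <- keys[k] }
  }
  c(runs, list(cur))
}

#' Fragment a protein into capped fragments and conjugate caps
#'
#' Cuts the chain residue by residue. For interior residues
#' i = 2..N-1 a capped fragment (sign +1) holds residue i plus caps
#' taken from residues i-1 and i+1; for i = 2..N-2 a conjugate cap
#' (concap, sign -1) holds exactly the two cap pieces shared by
#' adjacent capped fragments, so double counting cancels exactly.
#' Terminal residues 1 and N are absorbed whole into the caps of
#' fragments 2 and N-1. A cap from residue i-1 is its backbone
#' carbonyl unit \{CA, C, O\} with a link hydrogen replacing its N; a
#' cap from residue i+1 is its \{N, CA\} with a link hydrogen replacing
#' its C. Chain breaks (resid gaps or chain-id changes) split the
#' scheme into independent runs.
#'
#' @param sys a `charged_system` with a protein segment of at least 3
#'   contiguous residues per run
#' @param lambda generalized-concap contact threshold, Angstrom (stored;
#'   pairs are added by [build_gconcaps()])
#' @return object of class `fragment_scheme`: list with `fragments`,
#'   `lambda`, `runs` (residue-key runs), `gconcap_pairs`
#' @export
fragment_protein <- function(sys, lambda = 4.0) {
  xyz <- coords(sys)
  runs <- .protein_runs(sys)
  fragments <- list()
  for (r in seq_along(runs)) {
    keys <- runs[[r]]
    N <- length(keys)
    if (N < 3)
      stop("protein run ", r, " has only ", N,
           " residues; fragmentation needs N >= 3")
    res_idx <- lapply(keys, function(k) residue_atoms(sys, k))
    # cap pieces, built once so capped fragments and concaps share
    # bit-identical atoms and link positions
    ccap <- vector("list", N)  # C-side piece of residue i
    ncap <- vector("list", N)  # N-side piece of residue i
    for (i in seq_len(N)) {
      if (i == 1) {
        ccap[[i]] <- list(idx = res_idx[[i]], links = .empty_links())
      } else if (i < N) {
        ca <- .bb_idx(sys, res_idx[[i]], "CA")
        cc <- .bb_idx(sys, res_idx[[i]], "C")
        oo <- .bb_idx(sys, res_idx[[i]], "O")
        nn <- .bb_idx(sys, res_idx[[i]], "N")
        ccap[[i]] <- list(idx = c(ca, cc, oo),
                          links = .link_row(sys, xyz, ca, nn))
      }
      if (i == N) {
        ncap[[i]] <- list(idx = res_idx[[i]], links = .empty_links())
      } else if (i > 1) {
        ca <- .bb_idx(sys, res_idx[[i]], "CA")
        cc <- .bb_idx(sys, res_idx[[i]], "C")
        nn <- .bb_idx(sys, res_idx[[i]], "N")
        ncap[[i]] <- list(idx = c(nn, ca),
                          links = .link_row(sys, xyz, ca, cc))
      }
    }
    run_tag <- if (length(runs) > 1) paste0("run", r, ".") else ""
    for (i in 2:(N - 1)) {
      fragments[[length(fragments) + 1L]] <- .make_fragment(
        id = paste0(run_tag, "frag.", i), kind = "capped_fragment",
        center = i,
        real_idx = res_idx[[i]],
        cap_idx = c(ccap[[i - 1]]$idx, ncap[[i + 1]]$idx),
        links = rbind(ccap[[i - 1]]$links, ncap[[i + 1]]$links),
        sign = +1, sys = sys)
    }
    if (N >= 4) {
      for (i in 2:(N - 2)) {
        fragments[[length(fragments) + 1L]] <- .make_fragment(
          id = paste0(run_tag, "concap.", i), kind = "concap",
          center = c(i, i + 1),
          real_idx = integer(),
          cap_idx = c(ccap[[i]]$idx, ncap[[i + 1]]$idx),
          links = rbind(ccap[[i]]$links, ncap[[i + 1]]$links),
          sign = -1, sys = sys)
      }
    }
  }
  structure(list(fragments = fragments, lambda = lambda, runs = runs,
                 gconcap_pairs = data.frame(i = integer(), j = integer(),
                                            dist = numeric(),
                                            partner = character(),
                                            stringsAsFactors = FALSE)),
            class = "fragment_scheme")
}

#' @export
print.fragment_scheme <- function(x, ...) {
  kinds <- vapply(x$fragments, `[[`, "", "kind")
  cat("fragment_scheme:", sum(kinds == "capped_fragment"),
      "capped fragments,", sum(kinds == "concap"), "concaps,",
      nrow(x$gconcap_pairs), "gconcap pairs (lambda =", x$lambda, "A)\n")
  invisible(x)
}

# hydrogen-capped isolated residue (a generalized-concap "single"):
# both flanking peptide bonds are cut and saturated
.gconcap_single <- function(sys, xyz, keys, pos, run_keys) {
  idx <- residue_atoms(sys, run_keys[pos])
  links <- .empty_links()
  N <- length(run_keys)
  if (pos > 1) {
    nn <- .bb_idx(sys, idx, "N")
    prev <- residue_atoms(sys, run_keys[pos - 1])
    cprev <- .bb_idx(sys, prev, "C")
    links <- rbind(links, .link_row(sys, xyz, nn, cprev))
  }
  if (pos < N) {
    cc <- .bb_idx(sys, idx, "C")
    nxt <- residue_atoms(sys, run_keys[pos + 1])
    nnext <- .bb_idx(sys, nxt, "N")
    links <- rbind(links, .link_row(sys, xyz, cc, nnext))
  }
  list(idx = idx, links = links)
}

#' Add generalized concap (two-body) corrections to a scheme
#'
#' For every residue pair (i, j) with sequence separation j > i + 2
#' whose minimum inter-atom distance is at most `lambda`, adds a
#' hydrogen-capped pair fragment (sign +1) and the two hydrogen-capped
#' single residues (sign -1 each), implementing the two-body correction
#' V_ij - V_i - V_j literally. If ligand atoms are present (or a probe
#' exclusion set identifies them), ligand-residue pairs within `lambda`
#' are added with the whole ligand as one partner.
#'
#' @param sys a `charged_system`
#' @param scheme a `fragment_scheme` from [fragment_protein()]
#' @param include_ligand also pair the ligand segment with residues in
#'   contact
#' @param heavy_only measure contact distances over heavy atoms only
#'   (default uses all atoms)
#' @return the scheme with gconcap fragments and the pair table added
#' @export
build_gconcaps <- function(sys, scheme, include_ligand = TRUE,
                           heavy_only = FALSE) {
  xyz <- coords(sys)
  lambda <- scheme$lambda
  pairs <- scheme$gconcap_pairs
  for (r in seq_along(scheme$runs)) {
    run_keys <- scheme$runs[[r]]
    N <- length(run_keys)
    run_tag <- if (length(scheme$runs) > 1) paste0("run", r, ".") else ""
    if (N >= 4) {
      for (i in 1:(N - 3)) {
        for (j in (i + 3):N) {
          d <- residue_min_distance(sys, run_keys[i], run_keys[j],
                                    heavy_only = heavy_only)
          if (d > lambda) next
          si <- .gconcap_single(sys, xyz, run_keys, i, run_keys)
          sj <- .gconcap_single(sys, xyz, run_keys, j, run_keys)
          tag <- paste0(run_tag, "gconcap.", i, ".", j)
          scheme$fragments[[length(scheme$fragments) + 1L]] <-
            .make_fragment(paste0(tag, ".pair"), "gconcap_pair",
                           c(i, j), c(si$idx, sj$idx), integer(),
                           rbind(si$links, sj$links), +1, sys)
          scheme$fragments[[length(scheme$fragments) + 1L]] <-
            .make_fragment(paste0(tag, ".single_i"), "gconcap_single",
                           i, si$idx, integer(), si$links, -1, sys)
          scheme$fragments[[length(scheme$fragments) + 1L]] <-
            .make_fragment(paste0(tag, ".single_j"), "gconcap_single",
                           j, sj$idx, integer(), sj$links, -1, sys)
          pairs <- rbind(pairs, data.frame(i = i, j = j, dist = d,
                                           partner = "protein",
                                           stringsAsFactors = FALSE))
        }
      }
    }
    if (include_ligand && any(sys$atoms$segment == "ligand")) {
      lig_idx <- which(sys$atoms$segment == "ligand")
      for (i in seq_len(N)) {
        ri <- residue_atoms(sys, run_keys[i])
        d <- residue_min_distance(sys, ri, lig_idx,
                                  heavy_only = heavy_only)
        if (d > lambda) next
        si <- .gconcap_single(sys, xyz, run_keys, i, run_keys)
        tag <- paste0(run_tag, "gconcap.lig.", i)
        scheme$fragments[[length(scheme$fragments) + 1L]] <-
          .make_fragment(paste0(tag, ".pair"), "gconcap_pair", i,
                         c(si$idx, lig_idx), integer(), si$links, +1, sys)
        scheme$fragments[[length(scheme$fragments) + 1L]] <-
          .make_fragment(paste0(tag, ".single_i"), "gconcap_single", i,
                         si$idx, integer(), si$links, -1, sys)
        scheme$fragments[[length(scheme$fragments) + 1L]] <-
          .make_fragment(paste0(tag, ".single_lig"), "gconcap_single",
                         NA_integer_, lig_idx, integer(),
                         .empty_links(), -1, sys)
        pairs <- rbind(pairs, data.frame(i = i, j = NA_integer_,
                                         dist = d, partner = "ligand",
                                         stringsAsFactors = FALSE))
      }
    }
  }
  scheme$gconcap_pairs <- pairs
  scheme
}

#' Embedding background charges for a fragment
#'
#' Every protein (and ligand) atom of the system that is not among the
#' fragment's own real or cap atoms, with its point charge. Link atoms
#' never appear in backgrounds. Solvent is by default handled
#' classically outside the fragment machinery; set
#' `include_solvent = TRUE` to embed it too.
#'
#' @param scheme a `fragment_scheme`
#' @param fragment one element of `scheme$fragments`
#' @param sys the `charged_system` the scheme was built on
#' @param include_solvent include solvent (and ion) atoms in the
#'   background
#' @return data.frame with columns `serial`, `x`, `y`, `z`, `charge`
#' @export
embedding_charges <- function(scheme, fragment, sys,
                              include_solvent = FALSE) {
  segs <- c("protein", "ligand")
  if (include_solvent) segs <- c(segs, "solvent", "ion")
  pool <- which(sys$atoms$segment %in% segs)
  own <- c(fragment$real_idx, fragment$cap_idx)
  bg <- setdiff(pool, own)
  out <- sys$atoms[bg, c("serial", "x", "y", "z", "charge")]
  rownames(out) <- NULL
  out
}

#' Signed per-atom multiplicity of a scheme
#'
#' For every protein atom, the sum of fragment signs over the capped
#' fragments and concaps containing it (as real or cap). The telescoping
#' closure of the assembly requires this to be exactly 1 for every
#' protein atom; gconcap fragments are excluded since their net
#' multiplicity is zero by construction.
#'
#' @param scheme a `fragment_scheme`
#' @param sys the system the scheme was built on
#' @return integer vector over protein atoms (names = atom serials)
#' @export
scheme_multiplicity <- function(scheme, sys) {
  prot <- which(sys$atoms$segment == "protein")
  mult <- stats::setNames(rep(0L, length(prot)),
                          sys$atoms$serial[prot])
  for (f in scheme$fragments) {
    if (!f$kind %in% c("capped_fragment", "concap")) next
    idx <- c(f$real_idx, f$cap_idx)
    hit <- match(idx, prot)
    mult[hit] <- mult[hit] + f$sign
  }
  mult
}
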