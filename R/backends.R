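#' Build an ESP evaluation request
#'
#' The unit of work an ESP backend consumes: one fragment (its real and
#' cap atoms plus link hydrogens and net charge), the embedding
#' background charges, and the points where the potential is wanted.
#'
#' @param fragment a fragment from a `fragment_scheme`
#' @param sys the `charged_system` the fragment indexes into
#' @param background data.frame of background charges (see
#'   [embedding_charges()]); may have zero rows
#' @param points matrix (n x 3) or single 3-vector of evaluation points
#' @return object of class `esp_request` with elements `atoms`
#'   (data.frame: serial, name, element, x, y, z, charge, is_link),
#'   `charge`, `background`, `points`
#' @export
esp_request <- function(fragment, sys, background, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  idx <- c(fragment$real_idx, fragment$cap_idx)
  at <- sys$atoms[idx, c("serial", "name", "element", "x", "y", "z",
                         "charge")]
  at$is_link <- FALSE
  if (!is.null(fragment$links) && nrow(fragment$links) > 0) {
    lk <- data.frame(serial = NA_integer_, name = "HL", element = "H",
                     x = fragment$links$x, y = fragment$links$y,
                     z = fragment$links$z, charge = 0, is_link = TRUE)
    at <- rbind(at, lk)
  }
  rownames(at) <- NULL
  # evaluation points must not sit on fragment nuclei
  axyz <- as.matrix(at[, c("x", "y", "z")])
  for (p in seq_len(nrow(points))) {
    d2 <- (axyz[, 1] - points[p, 1])^2 + (axyz[, 2] - points[p, 2])^2 +
      (axyz[, 3] - points[p, 3])^2
    if (any(d2 < 1e-3^2))
      stop("evaluation point ", p, " lies on a nucleus of fragment ",
           fragment$id)
  }
  structure(list(atoms = at, charge = fragment$charge,
                 charge_raw = fragment$charge_raw,
                 fragment_id = fragment$id,
                 background = background, points = points),
            class = "esp_request")
}

#' Additive point-charge surrogate ESP backend
#'
#' Returns the Coulomb potential of the fragment's own point charges
#' (real plus cap atoms; link hydrogens carry zero charge) at the
#' requested points. The background is ignored: there is no
#' polarization, so the model is strictly additive over atoms. That
#' additivity is what makes the surrogate an exact oracle for the
#' fragment-assembly arithmetic.
#'
#' @param req an [esp_request()]
#' @return list of class `esp_result`: `potentials` (volts, one per
#'   point), `backend_id`, `metadata`
#' @export
surrogate_esp <- function(req) {
  stopifnot(inherits(req, "esp_request"))
  at <- req$atoms
  pots <- apply(req$points, 1, function(p) {
    d <- sqrt((at$x - p[1])^2 + (at$y - p[2])^2 + (at$z - p[3])^2)
    sf_constants$coulomb_VA_e * sum(at$charge / d)
  })
  structure(list(potentials = as.numeric(pots),
                 backend_id = "surrogate",
                 metadata = list()),
            class = "esp_result")
}

#' External quantum-chemistry ESP backend
#'
#' Adapter contract for an external engine that solves the fragment's
#' electronic structure in the field of the background point charges
#' and returns the total (electronic + nuclear) electrostatic potential
#' at the requested points. The engine is a function
#' `function(req, method, basis) -> numeric` registered via the
#' `engine` argument or `options(starkfield.qm_engine = ...)`. With no
#' engine registered the call fails with an explicit "backend
#' unavailable" error; there is never a silent fallback to the
#' surrogate. Results are cached on disk keyed by a content hash of the
#' request (coordinates rounded to 1e-6 Angstrom), so repeated calls
#' are bit-identical replays.
#'
#' @param req an [esp_request()]
#' @param method electronic-structure method label (production default
#'   `"M06-2X"`)
#' @param basis basis-set label (production default `"6-31G**"`)
#' @param engine optional engine function; overrides the
#'   `starkfield.qm_engine` option
#' @param cache_dir directory for the on-disk result cache (`NULL`
#'   disables caching)
#' @return an `esp_result` with `backend_id = "qm"` and
#'   method/basis/cache metadata
#' @export
external_qm_esp <- function(req, method = "M06-2X", basis = "6-31G**",
                            engine = NULL, cache_dir = NULL) {
  stopifnot(inherits(req, "esp_request"))
  if (is.null(engine)) engine <- getOption("starkfield.qm_engine")
  if (is.null(engine))
    stop("QM backend unavailable: no quantum-chemistry engine is ",
         "registered (set options(starkfield.qm_engine = ...) or pass ",
         "engine=)")
  if (!is.null(req$charge_raw) &&
      abs(req$charge_raw - req$charge) > 0.01)
    warning("fragment ", req$fragment_id, ": member charge sum ",
            format(req$charge_raw, digits = 4),
            " rounded to integer charge ", req$charge,
            " for the QM engine", call. = FALSE)
  key <- qm_request_hash(req, method, basis)
  cache_file <- if (!is.null(cache_dir))
    file.path(cache_dir, paste0(key, ".json")) else NULL
  if (!is.null(cache_file) && file.exists(cache_file)) {
    hit <- jsonlite::read_json(cache_file, simplifyVector = TRUE)
    # hex floats make the replay bit-identical to the original call
    return(structure(list(potentials = as.numeric(hit$potentials_hex),
                          backend_id = "qm",
                          metadata = list(method = method, basis = basis,
                                          cached = TRUE, key = key)),
                     class = "esp_result"))
  }
  vals <- engine(req, method, basis)
  if (length(vals) != nrow(req$points) || any(!is.finite(vals)))
    stop("QM engine returned invalid potentials for fragment ",
         req$fragment_id)
  if (!is.null(cache_file)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(potentials = vals,
                              potentials_hex = sprintf("%a", vals),
                              method = method, basis = basis),
                         cache_file, digits = NA, auto_unbox = TRUE)
  }
  structure(list(potentials = as.numeric(vals), backend_id = "qm",
                 metadata = list(method = method, basis = basis,
                                 cached = FALSE, key = key)),
            class = "esp_result")
}

#' Content hash of an ESP request
#'
#' MD5 over a canonical text rendering of the request: fragment atoms
#' and background charges with coordinates rounded to 1e-6 Angstrom,
#' the evaluation points, the fragment charge, and the method/basis
#' labels.
#'
#' @inheritParams external_qm_esp
#' @return character MD5 hex digest
#' @export
qm_request_hash <- function(req, method, basis) {
  fmt <- function(x) sprintf("%.6f", x)
  lines <- c(method, basis, as.character(req$charge),
             paste(req$atoms$element,
                   fmt(req$atoms$x), fmt(req$atoms$y), fmt(req$atoms$z),
                   fmt(req$atoms$charge), req$atoms$is_link),
             if (nrow(req$background) > 0)
               paste(fmt(req$background$x), fmt(req$background$y),
                     fmt(req$background$z), fmt(req$background$charge)),
             apply(req$points, 1, function(p) paste(fmt(p), collapse = " ")))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(lines, tf)
  unname(tools::md5sum(tf))
}

#' Select an ESP backend by name
#'
#' @param name `"surrogate"` or `"qm"`
#' @param ... passed to [external_qm_esp()] for the QM backend
#'   (`method`, `basis`, `engine`, `cache_dir`)
#' @return function `function(req) -> esp_result`
#' @export
esp_backend <- function(name = c("surrogate", "qm"), ...) {
  name <- match.arg(name)
  if (name == "surrogate") return(surrogate_esp)
  args <- list(...)
  function(req) do.call(external_qm_esp, c(list(req = req), args))
}
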