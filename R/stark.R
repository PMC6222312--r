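#' Vibrational Stark model for a probe bond
#'
#' The linear Stark relation ties a frequency shift of the probe to the
#' change of the protein field projected on the probe's difference
#' dipole: `h c dnu = -dmu . dF`. With the difference dipole along the
#' bond axis this reduces to `shift = -tuning_rate * delta_field`.
#'
#' @param tuning_rate Stark tuning rate |dmu|/(hc), in cm^-1 per
#'   (MV/cm); calibrated experimentally, so always a user input
#' @param axis unit vector of the difference dipole; defaults to the
#'   C->O bond direction and is carried for bookkeeping only
#' @return object of class `stark_model`
#' @export
stark_model <- function(tuning_rate, axis = NULL) {
  if (!is.numeric(tuning_rate) || length(tuning_rate) != 1 ||
      tuning_rate <= 0)
    stop("tuning_rate must be a single positive number")
  if (!is.null(axis)) {
    if (abs(sqrt(sum(axis^2)) - 1) > 1e-9)
      stop("axis must have unit norm")
  }
  structure(list(tuning_rate = tuning_rate, axis = axis),
            class = "stark_model")
}

#' Frequency shift from a field change
#'
#' @param delta_field field change projected on the probe axis, MV/cm
#' @param model a [stark_model()]
#' @return wavenumber shift, cm^-1 (positive shift for a field change
#'   against the difference dipole)
#' @export
stark_shift <- function(delta_field, model) {
  stopifnot(inherits(model, "stark_model"))
  -model$tuning_rate * delta_field
}

#' Field change from an observed frequency shift
#'
#' Exact inverse of [stark_shift()].
#'
#' @param shift wavenumber shift, cm^-1
#' @param model a [stark_model()]
#' @return field change, MV/cm
#' @export
field_from_shift <- function(shift, model) {
  stopifnot(inherits(model, "stark_model"))
  -shift / model$tuning_rate
}

#' Eyring parameters
#'
#' @param temperature kelvin (default 293, the VSE measurement
#'   temperature)
#' @return object of class `eyring_params` with the gas constant in
#'   kcal mol^-1 K^-1 and CODATA `k_B`, `h`
#' @export
eyring_params <- function(temperature = 293) {
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(temperature = temperature,
                 R_kcal = sf_constants$R_kcal,
                 kB_J = sf_constants$kB_J, h_Js = sf_constants$h_Js),
            class = "eyring_params")
}

#' Activation free energy from a catalytic rate constant
#'
#' Transition-state-theory inversion of the rate:
#' `dG = -R T ln(k_cat / (k_B T / h))`, in kcal/mol.
#'
#' @param k_cat unimolecular rate constant, s^-1 (> 0)
#' @param params an [eyring_params()]
#' @return activation free energy, kcal/mol
#' @export
eyring_dg <- function(k_cat, params = eyring_params()) {
  stopifnot(inherits(params, "eyring_params"))
  if (any(k_cat <= 0)) stop("k_cat must be > 0")
  Tk <- params$temperature
  -params$R_kcal * Tk * log(k_cat * params$h_Js / (params$kB_J * Tk))
}

#' Ordinary least-squares line with R-squared
#'
#' Simple linear regression `y ~ x` via [stats::lm()]; R-squared is the
#' squared Pearson correlation of observed and fitted values, which for
#' a single predictor equals the coefficient of determination.
#'
#' @param x,y numeric vectors of equal length (>= 2 distinct x values)
#' @return list with `slope`, `intercept`, `r_squared`, `stderr_slope`,
#'   `fit` (the `lm` object)
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(unique(x)) < 2)
    stop("x must contain at least two distinct values")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  # closed forms rather than summary.lm, which warns on exact fits
  se <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NaN
  r2 <- if (tss > 0) 1 - rss / tss else 1
  list(slope = slope, intercept = intercept, r_squared = r2,
       stderr_slope = se, fit = fit)
}

#' Per-group field contribution report
#'
#' Summarises a field decomposition the way active-site studies
#' tabulate it: each group's field, the sum over a set of key groups,
#' and the key groups' joint percentage of the total field (rounded
#' half away from zero to integer percent).
#'
#' @param decomposition data.frame with columns `group` and
#'   `field_MVcm` (e.g. from [decompose_field()]), or a named numeric
#'   vector of fields
#' @param key_groups group labels whose joint contribution is reported
#' @param total_group label of the total-field entry (default
#'   `"Sum of ARS"`, i.e. all residues plus solvent)
#' @return list with `table` (data.frame), `key_sum` (MV/cm),
#'   `total` (MV/cm), `percent` (integer)
#' @export
contribution_report <- function(decomposition, key_groups,
                                total_group = "Sum of ARS") {
  if (is.numeric(decomposition))
    decomposition <- data.frame(group = names(decomposition),
                                field_MVcm = as.numeric(decomposition),
                                stringsAsFactors = FALSE)
  need <- c(key_groups, total_group)
  miss <- setdiff(need, decomposition$group)
  if (length(miss) > 0)
    stop("decomposition lacks group(s): ", paste(miss, collapse = ", "))
  total <- decomposition$field_MVcm[decomposition$group == total_group]
  if (total == 0) stop("total field is zero; percentages undefined")
  key_sum <- sum(decomposition$field_MVcm[decomposition$group %in% key_groups])
  frac <- 100 * key_sum / total
  pct <- sign(frac) * floor(abs(frac) + 0.5)  # round half away from zero
  list(table = decomposition, key_sum = key_sum, total = total,
       percent = as.integer(pct))
}

#' Worked-example active-site field decomposition (KSI)
#'
#' Per-group time-average fields (MV/cm) on the carbonyl probe of
#' 19-nortestosterone bound to wild-type ketosteroid isomerase and the
#' D103N, Y16S and D103L mutants: the fields exerted by active-site
#' residues 16, 103 and 40, their sum ("Sum of 3RS"), the total over
#' all residues and solvent ("Sum of ARS"), and the solvent alone, as
#' obtained from force-field point charges over QM/MM-sampled
#' configurations. Bundled as a worked example for
#' [contribution_report()].
#'
#' @return data.frame with a `group` column and one column per variant
#' @export
ksi_decomposition <- function() {
  path <- system.file("extdata", "ksi_field_decomposition.csv",
                      package = "starkfield", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
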