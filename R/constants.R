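#' Physical constants used throughout the package
#'
#' The Coulomb constant is pinned to 14.399645 V*Angstrom/e
#' (e/(4*pi*eps0*Angstrom)) so that potentials computed from charges in
#' elementary-charge units and distances in Angstrom come out in volts.
#' Fields in V/Angstrom convert to MV/cm by a factor of 100.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{coulomb_VA_e}{Coulomb constant, 14.399645 V*A/e}
#'   \item{VA_to_MVcm}{conversion factor V/A -> MV/cm (100)}
#'   \item{R_kcal}{molar gas constant, kcal mol^-1 K^-1}
#'   \item{kB_J}{Boltzmann constant, J/K (CODATA 2018, exact)}
#'   \item{h_Js}{Planck constant, J s (CODATA 2018, exact)}
#' }
#' @export
sf_constants <- list(
  coulomb_VA_e = 14.399645,
  VA_to_MVcm   = 100,
  R_kcal       = 1.987204e-3,
  kB_J         = 1.380649e-23,
  h_Js         = 6.62607015e-34
)

# residue-name sets used for segment classification; overridable per call
.solvent_names <- c("HOH", "WAT", "TIP3", "SOL")
.ion_names     <- c("NA+", "CL-", "NA", "CL", "K", "MG", "K+", "MG2")

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HID", "HIE", "HIP", "ASH", "GLH", "CYX", "LYN",
          "TOY")
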