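#' Physical constants used throughout the package
#'
#' Internal computations run in Hartree atomic units (Bohr, electron charge,
#' Hartree). User-facing coordinates are in angstrom and energies in kcal/mol.
#' CODATA 2018 conversion factors.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{bohr_A}{Length of one Bohr radius in angstrom.}
#'   \item{hartree_kcal}{One Hartree in kcal/mol.}
#'   \item{coulomb_kcal}{Coulomb constant in kcal mol^-1 A e^-2, used for the
#'     point-charge energy mode.}
#' }
#' @export
epmm_constants <- list(
  bohr_A       = 0.529177210903,
  hartree_kcal = 627.509474,
  coulomb_kcal = 332.0637
)

# angstrom <-> bohr
.A2B <- function(x) x / epmm_constants$bohr_A
.B2A <- function(x) x * epmm_constants$bohr_A
# hartree -> kcal/mol
.H2KCAL <- function(x) x * epmm_constants$hartree_kcal

# package-level cache (density-normalization constants, angular grids, ...)
.epmm_cache <- new.env(parent = emptyenv())
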