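# Physical constants and unit conversions. All physics is done in atomic
# units (Hartree energies, Bohr lengths, a.u. dipoles/fields/potentials);
# conversions are applied only at reporting boundaries.

HARTREE_EV <- 27.211386   # 1 Hartree in eV
EV_NM <- 1239.84193       # lambda[nm] * E[eV] = 1239.84193
NM_BOHR <- 18.897259886   # 1 nm in Bohr

#' Unit conversions used at reporting boundaries
#'
#' The package works internally in atomic units (Hartree, Bohr, a.u. dipoles
#' and fields). These helpers convert energies between Hartree, eV and the
#' equivalent vacuum wavelength in nm.
#'
#' @param x Numeric vector of energies (or wavelengths for the `nm_to_*`
#'   directions).
#' @return Numeric vector of the same length.
#' @examples
#' ev_to_nm(hartree_to_ev(0.1044))  # ~436 nm
#' @name units
NULL

#' @rdname units
#' @export
hartree_to_ev <- function(x) x * HARTREE_EV

#' @rdname units
#' @export
ev_to_hartree <- function(x) x / HARTREE_EV

#' @rdname units
#' @export
ev_to_nm <- function(x) EV_NM / x

#' @rdname units
#' @export
nm_to_ev <- function(x) EV_NM / x

#' @rdname units
#' @export
hartree_to_nm <- function(x) EV_NM / (x * HARTREE_EV)

#' @rdname units
#' @export
nm_to_hartree <- function(x) EV_NM / x / HARTREE_EV
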