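# Bundled reference peak positions for lumiflavin / FAD in CvFAP. These are
# the published experimental band positions and the TD-DFT / MD-PMM peak
# tables the weighting and shift-decomposition operations are checked
# against; they are inputs to the analysis, not computed by it.

#' Reference absorption-peak tables for lumiflavin in CvFAP
#'
#' Small bundled tables of absorption-peak positions used by the worked
#' examples and the acceptance checks:
#'
#' * `reference_experimental_peaks()`: measured band positions of FAD in
#'   the photodecarboxylase (Apo and Holo forms) and of lumiflavin in
#'   water.
#' * `reference_gas_phase_conformers()`: gas-phase TD-DFT band positions of
#'   the five representative bending conformers B1-B5 (with their first
#'   essential-mode projections and d1 angles).
#' * `reference_pmm_peaks()`: MD-PMM band positions per conformational
#'   basin, their population-weighted combination, and lumiflavin in water.
#' * `reference_basin_populations()`: the planar / partially-bent / bent
#'   basin fractions sampled by the protein trajectory.
#'
#' @return Tibbles (or a named numeric vector for the populations); peak
#'   positions in nm.
#' @name reference_peaks
NULL

#' @rdname reference_peaks
#' @export
reference_experimental_peaks <- function() {
  tibble::tribble(
    ~system,      ~lambda1_nm, ~lambda2_nm, ~i_rel,
    "cvfap_apo",  466,         389,         1.01,
    "cvfap_holo", 466,         391,         0.96,
    "water",      443,         370,         0.86
  )
}

#' @rdname reference_peaks
#' @export
reference_gas_phase_conformers <- function() {
  tibble::tribble(
    ~conformer, ~proj1, ~d1_deg, ~lambda1_nm, ~lambda2_nm, ~i_rel,
    "B1",       -0.06,  0,       436.2,       342.8,       0.76,
    "B2",       -0.04,  3,       436.7,       344.0,       0.83,
    "B3",        0.00,  10,      437.2,       343.6,       0.83,
    "B4",        0.02,  18,      439.2,       345.8,       0.91,
    "B5",        0.06,  20,      441.0,       347.0,       0.97
  )
}

#' @rdname reference_peaks
#' @export
reference_pmm_peaks <- function() {
  tibble::tribble(
    ~system,                   ~lambda1_nm, ~lambda2_nm,
    "planar",                  458,         352,
    "partially_bent",          458,         351,
    "bent",                    462,         355,
    "md_weighted",             459,         352,
    "water",                   443,         346,
    "planar_gas",              436,         342,
    "md_weighted_gas",         438,         344
  )
}

#' @rdname reference_peaks
#' @export
reference_basin_populations <- function() {
  c(planar = 0.27, partially_bent = 0.44, bent = 0.29)
}
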