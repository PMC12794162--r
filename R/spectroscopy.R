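#' Bin perturbed transitions in frequency space
#'
#' Histograms the per-frame perturbed transition energies of each transition
#' into intervals of width `bin_width` (eV, on the unscaled energy axis),
#' recording per bin the frame count \eqn{\eta}, the mean squared
#' transition-dipole norm, and the dipole-weighted mean frequency used as
#' the bin's reference frequency \eqn{\nu_{ref}}. Using the dipole-weighted
#' mean (rather than the geometric bin center) makes the integrated
#' extinction exactly independent of the bin width.
#'
#' @param results Tibble from [pmm_trajectory()] (columns `frame`, `state`,
#'   `energy_ev`, `mu2`).
#' @param bin_width Bin width in eV. Default `sigma * HARTREE_EV / 5`, so
#'   binning never dominates the Gaussian broadening.
#' @param sigma Broadening standard deviation in Hartree (used only for the
#'   default bin width).
#' @param transitions Optional integer vector restricting which transitions
#'   are binned (default: all present).
#' @return An object of class `transition_bins`: a tibble (`transition`,
#'   `nu_center_ev`, `nu_ref_ev`, `eta`, `mu2_mean`) with attributes
#'   `n_frames` and `bin_width`.
#' @export
bin_transitions <- function(results, bin_width = NULL, sigma = 0.001, transitions = NULL) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0L) stop_validation("`results` is empty")
  if (is.null(bin_width)) bin_width <- sigma * HARTREE_EV / 5
  if (!is.numeric(bin_width) || bin_width <= 0) stop_config("`bin_width` must be > 0")
  if (!is.null(transitions)) results <- dplyr::filter(results, .data$state %in% transitions)
  if (nrow(results) == 0L) stop_validation("no results left after transition filter")
  n_frames <- length(unique(results$frame))

  bins <- results |>
    dplyr::mutate(bin = floor(.data$energy_ev / bin_width)) |>
    dplyr::group_by(.data$state, .data$bin) |>
    dplyr::summarise(
      eta = dplyr::n(),
      mu2_mean = mean(.data$mu2),
      nu_ref_ev = sum(.data$mu2 * .data$energy_ev) / sum(.data$mu2),
      .groups = "drop"
    ) |>
    dplyr::mutate(nu_center_ev = (.data$bin + 0.5) * bin_width) |>
    dplyr::rename(transition = "state") |>
    dplyr::select("transition", "nu_center_ev", "nu_ref_ev", "eta", "mu2_mean") |>
    dplyr::arrange(.data$transition, .data$nu_center_ev)

  structure(bins, class = c("transition_bins", class(bins)),
            n_frames = n_frames, bin_width = bin_width)
}

#' Assemble a Gaussian-broadened extinction spectrum
#'
#' Builds per-transition molar extinction coefficients on a common energy
#' grid by placing, for each occupied frequency bin, a Gaussian of standard
#' deviation `sigma` weighted by the bin's frame count and mean squared
#' transition dipole:
#' \deqn{\epsilon_{0,n}(\nu) \propto \sum_{\nu_{ref}}
#'   \overline{|\mu_{0,n}|^2}_{\nu_{ref}} \frac{\eta(\nu_{ref})}{N}\,\nu\,
#'   \frac{e^{-(\nu-\nu_{ref})^2/(2\sigma^2)}}{\sigma\sqrt{2\pi}}}
#' The empirical scaling factor (default 0.94) multiplies all energies (in
#' eV) before Gaussian placement; it shifts peak positions but leaves
#' relative intensities unchanged. Absolute extinction prefactors
#' (\eqn{1/(6\epsilon_0 c \hbar^2)} etc.) are folded into a single
#' arbitrary-units constant, since only positions and relative intensities
#' are compared.
#'
#' @param bins A [bin_transitions()] result.
#' @param sigma Gaussian broadening standard deviation, Hartree (the width
#'   produced by the neglected semiclassical vibrations). Default 0.001.
#' @param scaling Multiplicative energy scaling factor applied in eV.
#'   Default 0.94.
#' @param window_nm Wavelength window the grid must cover, nm.
#' @param grid_step_ev Energy grid step, eV. The default 0.002 eV keeps the
#'   wavelength resolution below 0.5 nm across the default window.
#' @param pad_ev Extra grid padding beyond the window, eV.
#' @param label Basin/conformer label stored in the metadata.
#' @return An object of class `pmm_spectrum`: a wide tibble (`energy_ev`,
#'   `wavelength_nm`, `eps_<n>` per transition, `eps_total`) accessible via
#'   `$data`, plus metadata. Use [tidy()] for a long table.
#' @export
build_spectrum <- function(bins, sigma = 0.001, scaling = 0.94,
                           window_nm = c(300, 550), grid_step_ev = 0.002,
                           pad_ev = 0.3, label = NULL) {
  if (!inherits(bins, "transition_bins")) stop_validation("`bins` must come from bin_transitions()")
  if (!is.numeric(sigma) || sigma <= 0) stop_config("`sigma` must be > 0")
  if (!is.numeric(scaling) || scaling <= 0) stop_config("`scaling` must be > 0")
  n_frames <- attr(bins, "n_frames")
  sigma_ev <- sigma * HARTREE_EV
  e_min <- EV_NM / max(window_nm) - pad_ev
  e_max <- EV_NM / min(window_nm) + pad_ev
  grid <- seq(e_min, e_max, by = grid_step_ev)

  trans <- sort(unique(bins$transition))
  eps <- matrix(0, length(grid), length(trans),
                dimnames = list(NULL, paste0("eps_", trans)))
  for (k in seq_along(trans)) {
    b <- bins[bins$transition == trans[k], ]
    centers <- scaling * b$nu_ref_ev
    amps <- b$eta / n_frames * b$mu2_mean
    for (i in seq_len(nrow(b))) {
      eps[, k] <- eps[, k] +
        amps[i] * grid * stats::dnorm(grid, mean = centers[i], sd = sigma_ev)
    }
  }
  data <- tibble::as_tibble(eps)
  data <- dplyr::bind_cols(
    tibble::tibble(energy_ev = grid, wavelength_nm = EV_NM / grid),
    data
  )
  data$eps_total <- rowSums(eps)
  new_pmm_spectrum(data, meta = list(
    sigma = sigma, scaling = scaling, bin_width = attr(bins, "bin_width"),
    n_frames = n_frames, grid_step_ev = grid_step_ev,
    label = label %||% "spectrum"
  ))
}

new_pmm_spectrum <- function(data, meta) {
  structure(list(data = data, meta = meta), class = "pmm_spectrum")
}

#' @export
print.pmm_spectrum <- function(x, ...) {
  cat(sprintf(
    "<pmm_spectrum> '%s': %d grid points (%.0f-%.0f nm), %d transitions, %d frames\n",
    x$meta$label, nrow(x$data),
    min(x$data$wavelength_nm), max(x$data$wavelength_nm),
    sum(startsWith(names(x$data), "eps_")) - 1L, x$meta$n_frames
  ))
  invisible(x)
}

#' @method tidy pmm_spectrum
#' @export
tidy.pmm_spectrum <- function(x, ...) {
  tidyr::pivot_longer(
    x$data,
    cols = dplyr::starts_with("eps_"),
    names_to = "transition", names_prefix = "eps_",
    values_to = "epsilon"
  )
}

#' @method glance pmm_spectrum
#' @export
glance.pmm_spectrum <- function(x, ...) {
  pk <- tryCatch(find_peaks(x), pmms_error = function(e) NULL)
  tibble::tibble(
    label = x$meta$label,
    n_frames = x$meta$n_frames,
    sigma_h = x$meta$sigma,
    scaling = x$meta$scaling,
    lambda1_nm = if (is.null(pk)) NA_real_ else pk$lambda1_nm,
    lambda2_nm = if (is.null(pk)) NA_real_ else pk$lambda2_nm,
    i_rel = if (is.null(pk)) NA_real_ else pk$i_rel
  )
}

#' Numerically integrate the total extinction over energy
#'
#' Trapezoidal integral of `eps_total` over the eV grid; used for the
#' binning-conservation checks.
#'
#' @param spec A `pmm_spectrum`.
#' @return Scalar integral (arbitrary units x eV).
#' @export
integrate_spectrum <- function(spec) {
  g <- spec$data$energy_ev
  y <- spec$data$eps_total
  sum(diff(g) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Population-weighted combination of basin spectra
#'
#' Pointwise convex combination of spectra computed on identical grids,
#' weighted by basin populations (must sum to 1 within 1e-9).
#'
#' @param spectra Named list of `pmm_spectrum` objects (names = basins or
#'   conformer labels).
#' @param populations Named numeric vector of fractions, same names.
#' @return A `pmm_spectrum` labelled `"weighted"`.
#' @export
weight_spectra <- function(spectra, populations) {
  if (length(spectra) == 0L) stop_validation("`spectra` is empty")
  if (is.null(names(spectra)) || is.null(names(populations)) ||
      !setequal(names(spectra), names(populations))) {
    stop_validation("`spectra` and `populations` must share the same names")
  }
  if (abs(sum(populations) - 1) > 1e-9) {
    stop_validation(sprintf("populations sum to %.12f, not 1", sum(populations)))
  }
  ref <- spectra[[1L]]$data
  eps_cols <- grep("^eps_", names(ref), value = TRUE)
  acc <- ref
  acc[eps_cols] <- 0
  n_frames <- 0L
  for (nm in names(spectra)) {
    d <- spectra[[nm]]$data
    if (nrow(d) != nrow(ref) || max(abs(d$energy_ev - ref$energy_ev)) > 1e-12) {
      stop_validation(sprintf("spectrum '%s' is on a different grid", nm))
    }
    cols <- intersect(eps_cols, names(d))
    if (!setequal(cols, eps_cols)) stop_validation("spectra carry different transition sets")
    acc[eps_cols] <- acc[eps_cols] + populations[[nm]] * d[eps_cols]
    n_frames <- n_frames + spectra[[nm]]$meta$n_frames
  }
  new_pmm_spectrum(acc, meta = utils::modifyList(
    spectra[[1L]]$meta, list(label = "weighted", n_frames = n_frames)
  ))
}

#' Locate the two main absorption peaks
#'
#' Finds strict local maxima of the total extinction on the raw grid inside
#' the reporting wavelength window and reports the two highest.
#' `lambda1` is the red-most (longer-wavelength) of the two;
#' `i_rel = height(lambda2) / height(lambda1)`. Ties between equal-height
#' maxima are resolved toward lower energy.
#'
#' @param spec A `pmm_spectrum`.
#' @param window Wavelength window, nm, default `c(300, 550)`.
#' @return A one-row tibble of class `peak_report`: `lambda1_nm`,
#'   `lambda2_nm`, `i_rel`, `height1`, `height2`. If fewer than two local
#'   maxima exist, a degenerate-spectrum error is raised carrying the single
#'   peak (fields `lambda_nm`, `height`) when there is one.
#' @export
find_peaks <- function(spec, window = c(300, 550)) {
  d <- spec$data
  sel <- d$wavelength_nm >= min(window) & d$wavelength_nm <= max(window)
  if (sum(sel) < 3L) stop_range("spectrum grid does not cover the peak window")
  g <- d$energy_ev[sel]
  w <- d$wavelength_nm[sel]
  y <- d$eps_total[sel]
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n], FALSE)
  idx <- which(is_max)
  if (length(idx) < 2L) {
    if (length(idx) == 1L) {
      stop_degenerate(
        sprintf("only one local maximum in %g-%g nm (at %.1f nm)", window[1L], window[2L], w[idx]),
        lambda_nm = w[idx], height = y[idx]
      )
    }
    stop_degenerate(sprintf("no local maxima in %g-%g nm window", window[1L], window[2L]))
  }
  # two highest maxima; equal heights -> lower energy (longer wavelength) first
  ord <- idx[order(-y[idx], g[idx])]
  top2 <- ord[1:2]
  red <- top2[which.max(w[top2])]
  blue <- top2[which.min(w[top2])]
  structure(
    tibble::tibble(
      lambda1_nm = w[red],
      lambda2_nm = w[blue],
      i_rel = y[blue] / y[red],
      height1 = y[red],
      height2 = y[blue]
    ),
    class = c("peak_report", class(tibble::tibble()))
  )
}

#' Shift of the first absorption peak between two spectra
#'
#' Signed difference `lambda1(a) - lambda1(b)` in nm: positive when `a` is
#' red-shifted with respect to `b`. Report values rounded to the nearest nm
#' with `round()`.
#'
#' @param a,b `peak_report` objects (or one-row data frames with a
#'   `lambda1_nm` column).
#' @return Signed shift in nm (unrounded).
#' @export
peak_shift <- function(a, b) {
  for (x in list(a, b)) {
    if (!is.data.frame(x) || !"lambda1_nm" %in% names(x)) {
      stop_validation("`a` and `b` must be peak reports with a lambda1_nm column")
    }
  }
  a$lambda1_nm[[1L]] - b$lambda1_nm[[1L]]
}

#' Population-weighted average of per-basin peak positions
#'
#' Convex combination \eqn{\sum_b p_b \lambda_b} of per-basin peak
#' wavelengths, the operation behind "MD weighted" rows of peak tables.
#' Returned unrounded; round to the nearest nm for reporting.
#'
#' @param values Named numeric vector of per-basin peak wavelengths, nm.
#' @param populations Named numeric vector of basin fractions, same names,
#'   summing to 1 within 1e-9.
#' @return The weighted wavelength, nm.
#' @export
weighted_peak_average <- function(values, populations) {
  if (is.null(names(values)) || is.null(names(populations))) {
    if (length(values) != length(populations)) {
      stop_validation("`values` and `populations` must have equal length (or matching names)")
    }
    names(values) <- names(populations) <- paste0("b", seq_along(values))
  }
  if (!setequal(names(values), names(populations))) {
    stop_validation("`values` and `populations` must have matching names")
  }
  if (abs(sum(populations) - 1) > 1e-9) {
    stop_validation(sprintf("populations sum to %.12f, not 1", sum(populations)))
  }
  sum(populations[names(values)] * values)
}

#' Write a spectrum as columnar text
#'
#' Two-column (`wavelength_nm`, `eps_total`) or multi-column (adding one
#' column per transition) plain-text output.
#'
#' @param spec A `pmm_spectrum`.
#' @param path File path.
#' @param per_transition Include per-transition columns?
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, per_transition = FALSE) {
  d <- spec$data
  cols <- if (per_transition) {
    c("wavelength_nm", grep("^eps_", names(d), value = TRUE))
  } else {
    c("wavelength_nm", "eps_total")
  }
  utils::write.table(
    d[, cols], path,
    row.names = FALSE, quote = FALSE, sep = " "
  )
  invisible(path)
}

#' Write a peak report as a small JSON file
#'
#' @param report A `peak_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_peak_report <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
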