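#' Plot a PMM spectrum
#'
#' Extinction versus wavelength: total spectrum plus (optionally) one line
#' per ground-to-excited transition.
#'
#' @param object A `pmm_spectrum`.
#' @param window Wavelength window, nm.
#' @param per_transition Overlay the per-transition contributions?
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pmm_spectrum
#' @export
autoplot.pmm_spectrum <- function(object, window = c(300, 550), per_transition = FALSE, ...) {
  d <- object$data
  d <- d[d$wavelength_nm >= min(window) & d$wavelength_nm <= max(window), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$wavelength_nm, y = .data$eps_total)) +
    ggplot2::geom_line(linewidth = 0.8)
  if (per_transition) {
    long <- tidyr::pivot_longer(
      d, dplyr::starts_with("eps_"),
      names_to = "transition", names_prefix = "eps_", values_to = "epsilon"
    )
    long <- long[long$transition != "total", ]
    p <- p + ggplot2::geom_line(
      data = long,
      ggplot2::aes(y = .data$epsilon, colour = .data$transition),
      linetype = "dashed", linewidth = 0.4
    )
  }
  p +
    ggplot2::labs(
      x = "wavelength (nm)", y = "extinction (arb. units)",
      title = object$meta$label
    ) +
    ggplot2::theme_minimal()
}

#' Compare several spectra
#'
#' @param spectra Named list of `pmm_spectrum` objects.
#' @param window Wavelength window, nm.
#' @return A ggplot with one curve per spectrum.
#' @export
plot_spectra <- function(spectra, window = c(300, 550)) {
  d <- purrr::imap_dfr(spectra, function(s, nm) {
    dd <- s$data[, c("wavelength_nm", "eps_total")]
    dd$spectrum <- nm
    dd
  })
  d <- d[d$wavelength_nm >= min(window) & d$wavelength_nm <= max(window), ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$wavelength_nm, y = .data$eps_total, colour = .data$spectrum
  )) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "wavelength (nm)", y = "extinction (arb. units)") +
    ggplot2::theme_minimal()
}

#' Plot a basin assignment
#'
#' Histogram of |d1| with the basin thresholds marked.
#'
#' @param object A `basin_assignment`.
#' @param binwidth Histogram bin width, degrees.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot basin_assignment
#' @export
autoplot.basin_assignment <- function(object, binwidth = 0.5, ...) {
  d <- object$assignments
  d$abs_d1 <- abs(d$d1)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$abs_d1, fill = .data$basin)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$thresholds, linetype = "dashed") +
    ggplot2::labs(x = "|d1| (degrees)", y = "frames", fill = "basin") +
    ggplot2::theme_minimal()
}

#' Plot essential-dynamics results
#'
#' Scree plot of the mode eigenvalues next to the distribution of the
#' mode-1 projections.
#'
#' @param object An `essential_modes` result.
#' @param n_modes How many modes to show in the scree panel.
#' @param ... Unused.
#' @return A ggplot (projection histogram with eigenvalue inset removed:
#'   two stacked facets).
#' @method autoplot essential_modes
#' @export
autoplot.essential_modes <- function(object, n_modes = 6L, ...) {
  n_modes <- min(n_modes, length(object$eigenvalues))
  scree <- tibble::tibble(
    panel = "eigenvalues (nm^2)",
    x = seq_len(n_modes),
    y = object$eigenvalues[seq_len(n_modes)]
  )
  proj <- tibble::tibble(
    panel = "mode-1 projection (nm)",
    x = object$projections[, 1L],
    y = NA_real_
  )
  ggplot2::ggplot() +
    ggplot2::geom_col(data = scree, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_histogram(
      data = proj, ggplot2::aes(x = .data$x), bins = 60
    ) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
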