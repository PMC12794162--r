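# one-frame, one-transition results table
delta_results <- function(energy_ev, mu2 = 1, n_frames = 1L) {
  tibble::tibble(
    frame = seq_len(n_frames), label = "B1", state = 1L,
    energy_h = ev_to_hartree(energy_ev), energy_ev = energy_ev,
    mu_x = sqrt(mu2), mu_y = 0, mu_z = 0, mu2 = mu2
  )
}

random_results <- function(n_frames = 400L, seed = 1L, center_ev = 2.8, spread = 0.05) {
  withr::with_seed(seed, {
    e1 <- rnorm(n_frames, center_ev, spread)
    e2 <- rnorm(n_frames, center_ev + 0.8, spread)
    tibble::tibble(
      frame = rep(seq_len(n_frames), 2L),
      label = "B1",
      state = rep(c(1L, 2L), each = n_frames),
      energy_ev = c(e1, e2),
      energy_h = ev_to_hartree(c(e1, e2)),
      mu_x = 0, mu_y = 0, mu_z = 0,
      mu2 = runif(2L * n_frames, 0.5, 2)
    )
  })
}

test_that("binning conserves frame counts and dipole-weighted energy", {
  # all frames identical -> a single occupied bin with eta = n_frames
  res <- delta_results(2.8, n_frames = 7L)
  b <- bin_transitions(res)
  expect_identical(nrow(as.data.frame(b)), 1L)
  expect_identical(b$eta, 7L)
  expect_equal(b$nu_ref_ev, 2.8, tolerance = 1e-12)

  # two well-separated populations occupy two bins with correct counts
  res2 <- dplyr::bind_rows(delta_results(2.8, n_frames = 3L),
                           dplyr::mutate(delta_results(3.4, n_frames = 5L),
                                         frame = frame + 3L))
  b2 <- bin_transitions(res2)
  expect_identical(sort(b2$eta), c(3L, 5L))
  expect_identical(sum(b2$eta), 8L)

  # conservation: sum over bins of eta * mean(mu2) equals sum over frames of mu2
  rr <- random_results(seed = 4)
  br <- bin_transitions(rr)
  expect_equal(sum(br$eta * br$mu2_mean), sum(rr$mu2), tolerance = 1e-10)

  expect_pmms_error(bin_transitions(rr[0, ]), "validation")
  expect_pmms_error(bin_transitions(rr, bin_width = -1), "config")
})

test_that("a single transition integrates to the closed-form Gaussian moment", {
  # integral over nu of mu2 * nu * G(nu - c) = mu2 * c for one frame
  res <- delta_results(2.9, mu2 = 1.7)
  sp <- build_spectrum(bin_transitions(res), scaling = 1, window_nm = c(250, 600))
  expect_equal(integrate_spectrum(sp), 1.7 * 2.9, tolerance = 1e-6)

  # the Gaussian center is the scaled transition energy
  sp94 <- build_spectrum(bin_transitions(res), scaling = 0.94, window_nm = c(250, 600))
  peak_ev <- sp94$data$energy_ev[which.max(sp94$data$eps_total)]
  expect_equal(peak_ev, 0.94 * 2.9, tolerance = 2 * sp94$meta$grid_step_ev)
})

test_that("spectrum assembly is linear in the squared transition dipoles", {
  rr <- random_results(seed = 5)
  sp1 <- build_spectrum(bin_transitions(rr))
  rr2 <- dplyr::mutate(rr, mu2 = 2 * mu2)
  sp2 <- build_spectrum(bin_transitions(rr2))
  expect_equal(sp2$data$eps_total, 2 * sp1$data$eps_total, tolerance = 1e-12)
})

test_that("integrated extinction is invariant under bin refinement", {
  rr <- random_results(seed = 6, n_frames = 500L)
  widths <- c(0.02, 0.005, 0.001, 0.0002)
  ints <- vapply(widths, function(w) {
    integrate_spectrum(build_spectrum(bin_transitions(rr, bin_width = w),
                                      window_nm = c(250, 650)))
  }, numeric(1L))
  expect_lt(max(abs(ints / ints[1L] - 1)), 1e-4)
})

test_that("energy scaling moves peaks by the ratio but keeps relative intensities", {
  rr <- random_results(seed = 7, n_frames = 800L)
  sp1 <- build_spectrum(bin_transitions(rr), scaling = 1.0, window_nm = c(250, 650))
  sp2 <- build_spectrum(bin_transitions(rr), scaling = 0.94, window_nm = c(250, 650))
  p1 <- find_peaks(sp1, window = c(260, 640))
  p2 <- find_peaks(sp2, window = c(260, 640))
  expect_equal(p2$lambda1_nm, p1$lambda1_nm / 0.94, tolerance = 2e-3)
  expect_equal(p2$lambda2_nm, p1$lambda2_nm / 0.94, tolerance = 2e-3)
  expect_equal(p2$i_rel, p1$i_rel, tolerance = 0.02)
})

test_that("population weighting is a convex pointwise combination", {
  rr <- random_results(seed = 8)
  spA <- build_spectrum(bin_transitions(rr))
  rr2 <- dplyr::mutate(rr, energy_ev = energy_ev + 0.05,
                       energy_h = ev_to_hartree(energy_ev))
  spB <- build_spectrum(bin_transitions(rr2))

  # equal spectra with any weights reproduce the spectrum
  w <- weight_spectra(list(a = spA, b = spA), c(a = 0.3, b = 0.7))
  expect_equal(w$data$eps_total, spA$data$eps_total, tolerance = 1e-12)

  # degenerate weights pick one spectrum
  w2 <- weight_spectra(list(a = spA, b = spB), c(a = 1, b = 0))
  expect_equal(w2$data$eps_total, spA$data$eps_total, tolerance = 1e-12)

  # convexity
  w3 <- weight_spectra(list(a = spA, b = spB), c(a = 0.27, b = 0.73))
  expect_equal(w3$data$eps_total,
               0.27 * spA$data$eps_total + 0.73 * spB$data$eps_total,
               tolerance = 1e-12)

  expect_pmms_error(weight_spectra(list(a = spA, b = spB), c(a = 0.6, b = 0.6)),
                    "validation")
  spC <- build_spectrum(bin_transitions(rr2), grid_step_ev = 0.003)
  expect_pmms_error(weight_spectra(list(a = spA, b = spC), c(a = 0.5, b = 0.5)),
                    "validation")
})

test_that("peak finding reports the two main bands, red-most first", {
  grid_ev <- seq(nm_to_ev(560), nm_to_ev(295), by = 0.002)
  gauss_nm <- function(center_nm, height, sd_ev = 0.05) {
    height * exp(-(grid_ev - nm_to_ev(center_nm))^2 / (2 * sd_ev^2))
  }
  mk_spec <- function(y) {
    pmmspectra:::new_pmm_spectrum(
      tibble::tibble(energy_ev = grid_ev, wavelength_nm = ev_to_nm(grid_ev),
                     eps_1 = y, eps_total = y),
      meta = list(label = "syn", n_frames = 1L, sigma = 0.001, scaling = 1,
                  bin_width = NA, grid_step_ev = 0.002)
    )
  }

  # equal heights at 443 and 370 nm
  p <- find_peaks(mk_spec(gauss_nm(443, 1) + gauss_nm(370, 1)))
  expect_equal(p$lambda1_nm, 443, tolerance = 0.5)
  expect_equal(p$lambda2_nm, 370, tolerance = 0.5)
  expect_equal(p$i_rel, 1, tolerance = 1e-3)

  # second band at 86% height mirrors the water band ratio
  p2 <- find_peaks(mk_spec(gauss_nm(443, 1) + gauss_nm(370, 0.86)))
  expect_equal(p2$i_rel, 0.86, tolerance = 1e-2)
  expect_gt(p2$lambda1_nm, p2$lambda2_nm)

  # monotone spectrum -> degenerate error
  expect_pmms_error(find_peaks(mk_spec(grid_ev)), "degenerate")
  # single peak -> degenerate error carrying the peak position
  err <- tryCatch(find_peaks(mk_spec(gauss_nm(420, 1))),
                  pmms_degenerate_error = function(e) e)
  expect_s3_class(err, "pmms_degenerate_error")
  expect_equal(err$lambda_nm, 420, tolerance = 0.5)

  # peak positions unchanged under uniform rescaling of epsilon
  p3 <- find_peaks(mk_spec(5.5 * (gauss_nm(443, 1) + gauss_nm(370, 0.86))))
  expect_equal(p3$lambda1_nm, p2$lambda1_nm)
  expect_equal(p3$lambda2_nm, p2$lambda2_nm)
})

test_that("peak shifts and weighted averages reproduce the bundled peak tables", {
  mk_report <- function(l1) tibble::tibble(lambda1_nm = l1)
  expect_equal(peak_shift(mk_report(443), mk_report(443)), 0)
  expect_equal(peak_shift(mk_report(466), mk_report(443)), 23)
  expect_equal(peak_shift(mk_report(459), mk_report(443)), 16)

  pops <- reference_basin_populations()
  gas <- reference_gas_phase_conformers()
  gas3 <- gas[gas$conformer %in% c("B1", "B3", "B5"), ]
  l1 <- stats::setNames(gas3$lambda1_nm, names(pops))
  l2 <- stats::setNames(gas3$lambda2_nm, names(pops))
  expect_identical(round(weighted_peak_average(l1, pops)), 438)
  expect_identical(round(weighted_peak_average(l2, pops)), 344)

  # uniform values average to themselves
  u <- stats::setNames(rep(441, 3L), names(pops))
  expect_equal(weighted_peak_average(u, pops), 441, tolerance = 1e-12)

  expect_pmms_error(
    weighted_peak_average(c(a = 1, b = 2), c(a = 0.5, c = 0.5)), "validation"
  )
})

test_that("spectra and peak reports write to readable text files", {
  rr <- random_results(seed = 9, n_frames = 50L)
  sp <- build_spectrum(bin_transitions(rr))
  p1 <- withr::local_tempfile(fileext = ".dat")
  write_spectrum(sp, p1, per_transition = TRUE)
  back <- utils::read.table(p1, header = TRUE)
  expect_identical(nrow(back), nrow(sp$data))
  expect_true(all(c("eps_1", "eps_2", "eps_total") %in% names(back)))

  pk <- find_peaks(sp, window = c(310, 540))
  p2 <- withr::local_tempfile(fileext = ".json")
  write_peak_report(pk, p2)
  got <- jsonlite::read_json(p2)
  expect_equal(got$lambda1_nm, pk$lambda1_nm, tolerance = 1e-9)
})
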