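#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic environment and bending generators.
#' The defaults are the package's study conditions: a fluctuating shell of
#' fictitious point charges around the chromophore, and a three-well
#' bending process whose basin weights (0.27 / 0.44 / 0.29) and thresholds
#' match the planar / partially-bent / bent populations observed for the
#' flavin in the photoenzyme's binding pocket.
#'
#' @param seed Integer RNG seed; every generator is a pure function of
#'   (config, seed).
#' @param n_frames Number of trajectory frames.
#' @param n_charges Number of fluctuating environment charges.
#' @param exclusion_radius,box_radius Radial shell (nm) the charges occupy
#'   around the QC expansion point.
#' @param charge_scale Maximum magnitude of the fluctuating partial charges,
#'   e (charges are drawn uniformly in `[-charge_scale, charge_scale]`).
#' @param jitter_sigma Frame-to-frame Gaussian positional jitter, nm.
#' @param mean_field_target Length-3 vector, a.u.: ensemble-mean field the
#'   environment must exert at the QC point (a bias dipole layer is added to
#'   hit it).
#' @param basin_centers,basin_sigmas Centers and widths (degrees) of the
#'   three Gaussian bending wells.
#' @param basin_weights Mixture weights of the three wells (sum to 1).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_frames = 1000L,
                             n_charges = 120L,
                             exclusion_radius = 0.6,
                             box_radius = 2.5,
                             charge_scale = 0.1,
                             jitter_sigma = 0.02,
                             mean_field_target = c(0, 0, 0),
                             basin_centers = c(2, 9, 16),
                             basin_sigmas = c(1.2, 1.2, 1.2),
                             basin_weights = c(0.27, 0.44, 0.29)) {
  cfg <- list(
    seed = as.integer(seed),
    n_frames = as.integer(n_frames),
    n_charges = as.integer(n_charges),
    exclusion_radius = exclusion_radius,
    box_radius = box_radius,
    charge_scale = charge_scale,
    jitter_sigma = jitter_sigma,
    mean_field_target = as.numeric(mean_field_target),
    basin_centers = as.numeric(basin_centers),
    basin_sigmas = as.numeric(basin_sigmas),
    basin_weights = as.numeric(basin_weights)
  )
  if (abs(sum(cfg$basin_weights) - 1) > 1e-9) stop_config("basin weights must sum to 1")
  if (cfg$exclusion_radius >= cfg$box_radius) {
    stop_config("exclusion_radius must be smaller than box_radius")
  }
  if (any(cfg$basin_sigmas <= 0)) stop_config("basin sigmas must be positive")
  if (length(cfg$mean_field_target) != 3L) stop_config("mean_field_target must have length 3")
  structure(cfg, class = "generator_config")
}

#' Synthetic flavin-like electronic reference
#'
#' Builds an 11-state electronic reference whose first two bright
#' transitions sit at the requested (unscaled) wavelengths, with
#' ground-to-excited transition dipoles sized so the unbroadened intensity
#' ratio of the two bands equals `i_rel` (heights scale as
#' \eqn{|\mu|^2 \nu}). The remaining eight states are dark (tiny seeded
#' transition dipoles) and lie above the second bright state. Permanent
#' dipoles are set with a fixed, conformer-independent difference
#' \eqn{\mu_{11}-\mu_{00}} of about 3 a.u. (the upper end of measured flavin
#' excited-state dipole changes), so external fields produce first-order
#' Stark shifts of the first band and the linear response dominates at the
#' field strengths typical spectral shifts require.
#'
#' @param label Conformer label (e.g. `"B1"`).
#' @param lambda1_nm,lambda2_nm First and second bright-transition
#'   wavelengths, nm (unscaled); must satisfy `lambda1 > lambda2 > 0`.
#' @param i_rel Target unbroadened height ratio of band 2 to band 1.
#' @param n_states Total state count including ground (default 11).
#' @param seed Integer seed controlling the dark-state details.
#' @return An [unperturbed_states()] object.
#' @export
make_flavin_like_states <- function(label = "B1",
                                    lambda1_nm = 436.2, lambda2_nm = 342.8,
                                    i_rel = 0.76, n_states = 11L, seed = 1L) {
  if (!(lambda1_nm > lambda2_nm && lambda2_nm > 0)) {
    stop_validation("need lambda1 > lambda2 > 0 (first band is the red-most)")
  }
  if (n_states < 3L) stop_validation("need at least ground + two bright states")
  withr::local_seed(seed)
  e1 <- nm_to_hartree(lambda1_nm)
  e2 <- nm_to_hartree(lambda2_nm)
  n_dark <- n_states - 3L
  dark <- if (n_dark > 0L) {
    e2 * seq(1.15, 1.9, length.out = n_dark) + stats::runif(n_dark, 0, 0.002)
  } else {
    numeric(0)
  }
  energies <- c(0, e1, e2, sort(dark))

  dx <- matrix(0, n_states, n_states)
  dy <- matrix(0, n_states, n_states)
  dz <- matrix(0, n_states, n_states)

  # bright transition dipoles: band heights go as |mu|^2 * nu
  m1 <- 1.9                                  # a.u., ~flavin S0->S1
  mu2_2 <- i_rel * m1^2 * e1 / e2
  m2 <- sqrt(mu2_2)
  ang <- 25 * pi / 180                       # in-plane polarization offset
  dx[1L, 2L] <- dx[2L, 1L] <- m1
  dx[1L, 3L] <- dx[3L, 1L] <- m2 * cos(ang)
  dy[1L, 3L] <- dy[3L, 1L] <- m2 * sin(ang)

  # permanent dipoles: conformer-independent difference for the bright states
  mu00 <- c(3.5, 0.5, 0)
  dmu1 <- c(3.0, 0.6, 0)                     # mu_11 - mu_00, fixed by design
  dmu2 <- c(2.4, -0.3, 0)
  diag_mu <- matrix(0, n_states, 3L)
  diag_mu[1L, ] <- mu00
  diag_mu[2L, ] <- mu00 + dmu1
  diag_mu[3L, ] <- mu00 + dmu2
  if (n_dark > 0L) {
    for (k in seq_len(n_dark)) {
      diag_mu[3L + k, ] <- mu00 + stats::runif(3L, -0.3, 0.3)
    }
    # faint ground-to-dark transition dipoles
    for (k in seq_len(n_dark)) {
      v <- stats::runif(3L, -1e-3, 1e-3)
      dx[1L, 3L + k] <- dx[3L + k, 1L] <- v[1L]
      dy[1L, 3L + k] <- dy[3L + k, 1L] <- v[2L]
      dz[1L, 3L + k] <- dz[3L + k, 1L] <- v[3L]
    }
  }
  diag(dx) <- diag_mu[, 1L]
  diag(dy) <- diag_mu[, 2L]
  diag(dz) <- diag_mu[, 3L]

  unperturbed_states(energies, list(x = dx, y = dy, z = dz), total_charge = 0L, label = label)
}

#' Permanent-dipole difference of the first bright transition
#'
#' \eqn{\mu_{11} - \mu_{00}} (a.u.), the quantity that sets the first-order
#' Stark response of the first band.
#'
#' @param states An [unperturbed_states()] object.
#' @return Numeric length-3 vector, a.u.
#' @export
stark_dipole_difference <- function(states) {
  vapply(c("x", "y", "z"), function(ax) {
    m <- states$dipoles[[ax]]
    m[2L, 2L] - m[1L, 1L]
  }, numeric(1L))
}

#' Synthetic fluctuating point-charge environment
#'
#' Generates `n_frames` frames of `n_charges` fictitious partial charges
#' placed uniformly in the radial shell `[exclusion_radius, box_radius]`
#' around the QC point (the origin), with frame-to-frame Gaussian positional
#' jitter. A fixed pair of bias charges (a dipole layer with zero potential
#' contribution at the QC point) is then added so the ensemble-mean field at
#' the QC point equals `mean_field_target` exactly: the bias is computed
#' from the directly summed sample mean of the random part, and verified by
#' re-summation. Charges are fictitious, not force-field derived - the
#' analysis only needs statistically controllable V/E ensembles.
#'
#' @param config A [generator_config()].
#' @return List of [charge_frame()] objects (length `n_frames`).
#' @export
make_environment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::local_seed(config$seed)
  nc <- config$n_charges
  nf <- config$n_frames
  r0 <- config$exclusion_radius
  r1 <- config$box_radius

  # base positions uniform in the shell
  u <- matrix(stats::rnorm(3L * nc), nc, 3L)
  u <- u / sqrt(rowSums(u^2))
  rad <- (stats::runif(nc) * (r1^3 - r0^3) + r0^3)^(1 / 3)
  base <- u * rad
  q <- stats::runif(nc, -config$charge_scale, config$charge_scale)

  frames_pos <- vector("list", nf)
  for (f in seq_len(nf)) {
    p <- base
    if (config$jitter_sigma > 0) {
      p <- p + matrix(stats::rnorm(3L * nc, 0, config$jitter_sigma), nc, 3L)
      # keep charges outside the exclusion shell so the clash cutoff is never hit
      d <- sqrt(rowSums(p^2))
      close <- d < r0
      if (any(close)) p[close, ] <- p[close, , drop = FALSE] * (r0 / d[close])
    }
    frames_pos[[f]] <- p
  }

  # sample-mean field of the random part, by direct summation (a.u.)
  e_mean <- c(0, 0, 0)
  for (f in seq_len(nf)) {
    rel <- -frames_pos[[f]] * NM_BOHR
    d <- sqrt(rowSums(rel^2))
    e_mean <- e_mean + colSums(q * rel / d^3)
  }
  e_mean <- e_mean / nf

  bias_needed <- config$mean_field_target - e_mean
  bias <- NULL
  if (sqrt(sum(bias_needed^2)) > 0) {
    d_bias <- (r0 + r1) / 2
    uhat <- bias_needed / sqrt(sum(bias_needed^2))
    q_bias <- sqrt(sum(bias_needed^2)) * (d_bias * NM_BOHR)^2 / 2
    if (q_bias > 50) {
      stop_feasibility(sprintf(
        "mean-field target needs a bias charge of %.1f e at %.2f nm; shrink the target or the shell",
        q_bias, d_bias
      ))
    }
    bias <- list(pos = rbind(-d_bias * uhat, d_bias * uhat), q = c(q_bias, -q_bias))
  }

  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    pos <- frames_pos[[f]]
    qq <- q
    rn <- rep("ENV", nc)
    if (!is.null(bias)) {
      pos <- rbind(pos, bias$pos)
      qq <- c(qq, bias$q)
      rn <- c(rn, "BIA", "BIA")
    }
    n_all <- length(qq)
    frames[[f]] <- charge_frame(
      tibble::tibble(
        atom_id = seq_len(n_all),
        residue_id = seq_len(n_all),
        residue_name = rn,
        x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
        q = qq
      ),
      qc_point = c(0, 0, 0),
      frame_index = f
    )
  }

  # internal verification: the realized ensemble-mean field hits the target
  e_check <- c(0, 0, 0)
  for (f in seq_len(nf)) {
    a <- frames[[f]]$atoms
    rel <- -cbind(a$x, a$y, a$z) * NM_BOHR
    d <- sqrt(rowSums(rel^2))
    e_check <- e_check + colSums(a$q * rel / d^3)
  }
  e_check <- e_check / nf
  tgt <- config$mean_field_target
  tol <- max(0.02 * sqrt(sum(tgt^2)), 1e-10)
  if (sqrt(sum((e_check - tgt)^2)) > tol) {
    stop_feasibility("bias layer failed to reproduce the mean-field target")
  }
  frames
}

# ---- bending ---------------------------------------------------------------

#' Idealized planar ring template
#'
#' A planar three-ring scaffold with the flavin ring-atom names, hinged at
#' the N5-N10 axis. The scaffold is an idealization: atoms are laid out so
#' that the raw C4-N5-N10-C9 torsion equals the butterfly bend angle
#' (planar = 0, matching the convention in which the bend is reported),
#' rather than reproducing the true fused-ring geometry, in which the
#' planar pseudo-torsion would be 180 degrees. Only the topology (atom
#' names for d1) matches the real chromophore.
#'
#' @return A list with `coords` (atoms x 3 matrix, nm), `atom_names`, and
#'   `wing` (logical: atoms rotated when bending).
#' @export
flavin_ring_template <- function() {
  coords <- rbind(
    N5   = c(0.00,  0.00, 0),
    N10  = c(0.23,  0.00, 0),
    C4   = c(-0.08, 0.12, 0),
    C4a  = c(-0.12, 0.00, 0),
    N3   = c(-0.20, 0.12, 0),
    C2   = c(-0.27, 0.00, 0),
    N1   = c(-0.20, -0.12, 0),
    C10a = c(-0.08, -0.12, 0),
    C9   = c(0.31,  0.12, 0),
    C9a  = c(0.35,  0.00, 0),
    C5a  = c(0.31, -0.12, 0),
    C6   = c(0.43, -0.12, 0),
    C7   = c(0.50,  0.00, 0),
    C8   = c(0.43,  0.12, 0)
  )
  atom_names <- rownames(coords)
  rownames(coords) <- NULL
  list(
    coords = coords,
    atom_names = atom_names,
    wing = atom_names %in% c("C9", "C9a", "C5a", "C6", "C7", "C8")
  )
}

#' Bend the ring template about the N5-N10 axis
#'
#' Rotates the benzene-side wing of the template about the x (N5-N10) axis
#' by `angle` degrees. By construction the C4-N5-N10-C9 torsion of the bent
#' template equals `angle`.
#'
#' @param angle Bend angle, degrees.
#' @param template A [flavin_ring_template()] (default: the built-in one).
#' @return Atoms x 3 coordinate matrix, nm.
#' @export
bend_template <- function(angle, template = flavin_ring_template()) {
  th <- angle * pi / 180
  co <- template$coords
  w <- template$wing
  y <- co[w, 2L]
  z <- co[w, 3L]
  co[w, 2L] <- y * cos(th) - z * sin(th)
  co[w, 3L] <- y * sin(th) + z * cos(th)
  co
}

#' Synthetic three-basin bending trajectory
#'
#' Draws the bending dihedral d1 from a three-component Gaussian mixture
#' (default centers 2 / 9 / 16 degrees, weights 0.27 / 0.44 / 0.29 - the
#' planar, partially-bent and bent basin populations) and builds ring
#' coordinates by bending the idealized template about the N5-N10 axis by
#' each frame's d1. Classifying the output with the default 6 / 12 degree
#' thresholds recovers the basin weights to within about +/-0.01 at 1e5
#' frames (the wells are narrow enough that basin overlap is negligible).
#'
#' @param config A [generator_config()].
#' @param ring Build the ring-coordinate trajectory too? (`FALSE` returns
#'   only the d1 series, useful for very long series.)
#' @return A list with `d1` (tibble: `frame`, `d1`, `component`) and
#'   `trajectory` (a [ring_trajectory()], or `NULL` if `ring = FALSE`).
#' @export
make_bending_series <- function(config, ring = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  withr::local_seed(config$seed + 1L)
  nf <- config$n_frames
  comp <- sample.int(3L, nf, replace = TRUE, prob = config$basin_weights)
  d1 <- stats::rnorm(nf, config$basin_centers[comp], config$basin_sigmas[comp])
  d1_tbl <- tibble::tibble(frame = seq_len(nf), d1 = d1, component = comp)
  traj <- NULL
  if (ring) {
    tmpl <- flavin_ring_template()
    n_atoms <- nrow(tmpl$coords)
    co <- array(NA_real_, c(nf, n_atoms, 3L))
    for (f in seq_len(nf)) {
      co[f, , ] <- bend_template(d1[f], tmpl)
    }
    traj <- ring_trajectory(co, tmpl$atom_names, seq_len(nf))
  }
  list(d1 = d1_tbl, trajectory = traj)
}
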