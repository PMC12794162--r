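#' Perturbed electronic Hamiltonian for one frame
#'
#' Builds the PMM Hamiltonian of the quantum center in the basis of its
#' unperturbed eigenstates:
#' \deqn{H_{jj'} = \delta_{jj'}\,(\epsilon_j + q V) - \sum_\alpha E_\alpha\,
#'       \mu_{\alpha,jj'}}
#' where \eqn{q} is the total QC charge, \eqn{V} and \eqn{E} the environment
#' potential and field at the QC expansion point (a.u.), and
#' \eqn{\mu_{\alpha}} the dipole-operator matrices. The short-range
#' correction term sometimes added to PMM Hamiltonians is deliberately
#' omitted: the model is purely electrostatic, and the type signature leaves
#' no hook for it.
#'
#' @param states An [unperturbed_states()] object.
#' @param v Scalar electrostatic potential at the expansion point, a.u.
#' @param e_field Numeric length-3 field vector at the expansion point, a.u.
#' @return A symmetric `n_states x n_states` matrix, Hartree.
#' @export
build_perturbed_hamiltonian <- function(states, v, e_field) {
  if (!inherits(states, "unperturbed_states")) {
    stop_validation("`states` must be an unperturbed_states object")
  }
  e_field <- as.numeric(e_field)
  if (length(e_field) != 3L || any(!is.finite(e_field)) || !is.finite(v) || length(v) != 1L) {
    stop_validation("`v` must be a finite scalar and `e_field` a finite length-3 vector (a.u.)")
  }
  h <- diag(states$energies + states$total_charge * v, nrow = states$n_states)
  h <- h -
    e_field[1L] * states$dipoles$x -
    e_field[2L] * states$dipoles$y -
    e_field[3L] * states$dipoles$z
  h
}

#' Diagonalize the perturbed Hamiltonian of one frame
#'
#' Constructs and diagonalizes the per-frame perturbed Hamiltonian, returning
#' perturbed state energies, eigenvectors, transition energies to the
#' perturbed ground state, and perturbed ground-to-excited transition dipoles
#' \eqn{\tilde\mu_{0n,\alpha} = c_0^T \mu_\alpha c_n}. Eigenvalues are sorted
#' ascending; each eigenvector's sign is fixed so its largest-magnitude
#' component is positive, making runs bit-reproducible even through
#' degeneracies.
#'
#' @param states An [unperturbed_states()] object.
#' @param env Either a one-row data frame with columns `V`, `Ex`, `Ey`, `Ez`
#'   (and optionally `frame`), or a list with elements `V` and `E`.
#' @return An object of class `pmm_frame` with elements `frame_index`,
#'   `eigenvalues` (Hartree, ascending), `eigenvectors` (columns = perturbed
#'   states in the unperturbed basis), `transition_energies` (Hartree),
#'   `transition_dipoles` (`n_excited x 3`, a.u.) and `conformer_label`.
#' @export
diagonalize_frame <- function(states, env) {
  pe <- parse_env(env)
  h <- build_perturbed_hamiltonian(states, pe$v, pe$e)
  eg <- tryCatch(
    eigen(h, symmetric = TRUE),
    error = function(e) {
      stop_numeric(sprintf("eigen-decomposition failed at frame %d: %s", pe$frame, conditionMessage(e)))
    }
  )
  ord <- order(eg$values)
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  # deterministic sign convention
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  n_exc <- states$n_states - 1L
  c0 <- vecs[, 1L]
  td <- matrix(NA_real_, n_exc, 3L, dimnames = list(NULL, c("x", "y", "z")))
  for (ax in 1:3) {
    m <- states$dipoles[[c("x", "y", "z")[ax]]]
    td[, ax] <- drop(crossprod(c0, m %*% vecs[, -1L, drop = FALSE]))
  }
  structure(
    list(
      frame_index = pe$frame,
      eigenvalues = vals,
      eigenvectors = vecs,
      transition_energies = vals[-1L] - vals[1L],
      transition_dipoles = td,
      conformer_label = states$label
    ),
    class = "pmm_frame"
  )
}

parse_env <- function(env) {
  if (is.data.frame(env)) {
    if (nrow(env) != 1L) stop_validation("`env` data frame must have exactly one row")
    list(
      v = env$V[[1L]],
      e = c(env$Ex[[1L]], env$Ey[[1L]], env$Ez[[1L]]),
      frame = if ("frame" %in% names(env)) as.integer(env$frame[[1L]]) else 1L
    )
  } else if (is.list(env)) {
    list(
      v = env$V,
      e = as.numeric(env$E),
      frame = if (!is.null(env$frame_index)) as.integer(env$frame_index) else 1L
    )
  } else {
    stop_validation("`env` must be a one-row data frame (V, Ex, Ey, Ez) or a list(V, E)")
  }
}

#' @export
print.pmm_frame <- function(x, ...) {
  cat(sprintf(
    "<pmm_frame> frame %d ('%s'): first transitions %s nm\n",
    x$frame_index, x$conformer_label,
    paste(sprintf("%.1f", hartree_to_nm(utils::head(x$transition_energies, 3L))), collapse = ", ")
  ))
  invisible(x)
}

#' @method tidy pmm_frame
#' @export
tidy.pmm_frame <- function(x, ...) {
  n_exc <- length(x$transition_energies)
  tibble::tibble(
    frame = x$frame_index,
    label = x$conformer_label,
    state = seq_len(n_exc),
    energy_h = x$transition_energies,
    energy_ev = hartree_to_ev(x$transition_energies),
    mu_x = x$transition_dipoles[, 1L],
    mu_y = x$transition_dipoles[, 2L],
    mu_z = x$transition_dipoles[, 3L],
    mu2 = rowSums(x$transition_dipoles^2)
  )
}

#' PMM along a trajectory
#'
#' Maps [diagonalize_frame()] over a trajectory of frame environments, using
#' for every frame the electronic reference selected by its conformer label
#' (the Born-Oppenheimer bookkeeping of MD-PMM: one fixed electronic
#' reference per conformational basin, never interpolated).
#'
#' @param envs Tibble of frame environments (`frame`, `V`, `Ex`, `Ey`, `Ez`),
#'   e.g. from [environment_trajectory()] or [read_field_trajectory()].
#' @param states_by_label Named list of [unperturbed_states()], keyed by
#'   conformer label.
#' @param labels Character vector of per-frame conformer labels, recycled if
#'   length 1. Defaults to an `envs$label` column if present, else to the
#'   single entry of `states_by_label`.
#' @return A tibble with one row per frame and excited state: `frame`,
#'   `label`, `state`, `energy_h`, `energy_ev` (both unscaled), `mu_x`,
#'   `mu_y`, `mu_z`, `mu2` (a.u.).
#' @export
pmm_trajectory <- function(envs, states_by_label, labels = NULL) {
  envs <- tibble::as_tibble(envs)
  if (nrow(envs) == 0L) stop_validation("`envs` must contain at least one frame")
  if (inherits(states_by_label, "unperturbed_states")) {
    states_by_label <- stats::setNames(list(states_by_label), states_by_label$label)
  }
  if (is.null(labels)) {
    labels <- if ("label" %in% names(envs)) {
      envs$label
    } else if (length(states_by_label) == 1L) {
      names(states_by_label)
    } else {
      stop_config("per-frame `labels` are required when several electronic references are supplied")
    }
  }
  if (length(labels) == 1L) labels <- rep(labels, nrow(envs))
  if (length(labels) != nrow(envs)) {
    stop_validation(sprintf(
      "`labels` has length %d but there are %d frames", length(labels), nrow(envs)
    ))
  }
  missing_labels <- setdiff(unique(labels), names(states_by_label))
  if (length(missing_labels)) {
    stop_config(sprintf(
      "no electronic reference for conformer label(s): %s",
      paste(missing_labels, collapse = ", ")
    ))
  }
  frames <- if ("frame" %in% names(envs)) as.integer(envs$frame) else seq_len(nrow(envs))

  # precompute per-label pieces once; the per-frame work is one 11x11 eigen
  refs <- lapply(states_by_label, function(s) {
    list(
      diag_e = s$energies, q = s$total_charge,
      dx = s$dipoles$x, dy = s$dipoles$y, dz = s$dipoles$z,
      n = s$n_states, label = s$label
    )
  })
  n_frames <- nrow(envs)
  out <- vector("list", n_frames)
  V <- envs$V; Ex <- envs$Ex; Ey <- envs$Ey; Ez <- envs$Ez
  for (i in seq_len(n_frames)) {
    r <- refs[[labels[[i]]]]
    h <- diag(r$diag_e + r$q * V[i], nrow = r$n) - Ex[i] * r$dx - Ey[i] * r$dy - Ez[i] * r$dz
    eg <- eigen(h, symmetric = TRUE)
    ord <- order(eg$values)
    vals <- eg$values[ord]
    vecs <- eg$vectors[, ord, drop = FALSE]
    for (k in seq_len(r$n)) {
      j <- which.max(abs(vecs[, k]))
      if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
    }
    c0 <- vecs[, 1L]
    cexc <- vecs[, -1L, drop = FALSE]
    mx <- drop(crossprod(c0, r$dx %*% cexc))
    my <- drop(crossprod(c0, r$dy %*% cexc))
    mz <- drop(crossprod(c0, r$dz %*% cexc))
    out[[i]] <- list(
      frame = frames[i], label = labels[[i]],
      energy_h = vals[-1L] - vals[1L], mu_x = mx, mu_y = my, mu_z = mz
    )
  }
  n_exc <- vapply(out, function(o) length(o$energy_h), integer(1L))
  res <- tibble::tibble(
    frame = rep(vapply(out, `[[`, integer(1L), "frame"), n_exc),
    label = rep(vapply(out, `[[`, character(1L), "label"), n_exc),
    state = unlist(lapply(n_exc, seq_len)),
    energy_h = unlist(lapply(out, `[[`, "energy_h")),
    mu_x = unlist(lapply(out, `[[`, "mu_x")),
    mu_y = unlist(lapply(out, `[[`, "mu_y")),
    mu_z = unlist(lapply(out, `[[`, "mu_z"))
  )
  res$energy_ev <- hartree_to_ev(res$energy_h)
  res$mu2 <- res$mu_x^2 + res$mu_y^2 + res$mu_z^2
  res[, c("frame", "label", "state", "energy_h", "energy_ev", "mu_x", "mu_y", "mu_z", "mu2")]
}

#' Write perturbed-frame results to a columnar text file
#'
#' One row per frame and transition: `frame label state nu_ev mu2` with
#' unscaled transition energies in eV and squared transition-dipole norms in
#' a.u.
#'
#' @param results Tibble from [pmm_trajectory()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pmm_results <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pmmspectra-results v1", con)
  writeLines("# frame label state nu_ev mu2", con)
  writeLines(sprintf(
    "%d %s %d %.17g %.17g",
    results$frame, results$label, results$state, results$energy_ev, results$mu2
  ), con)
  invisible(path)
}
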