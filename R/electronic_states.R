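#' Unperturbed electronic states of the quantum center
#'
#' Container for the gas-phase electronic reference of the quantum center
#' (QC): state energies and the full dipole-operator matrix in the basis of
#' the unperturbed eigenstates. This is the information a TD-DFT calculation
#' supplies (ground-state energy, vertical excitation energies,
#' ground-to-excited transition dipoles and state permanent dipoles); here it
#' can equally come from a fixture file or the synthetic generator.
#'
#' Conventions enforced at construction:
#' * energies are in Hartree, ground state first, sorted non-decreasing;
#' * each Cartesian dipole matrix is symmetric (real wavefunctions);
#' * dipole matrix elements between two different excited states are zero --
#'   only row/column 0 (ground) and the diagonal (permanent dipoles) may be
#'   nonzero. Excited-to-excited transition dipoles are deliberately excluded
#'   from the model; fixtures carrying them fail validation loudly rather
#'   than being silently zeroed.
#' * dipole matrix elements are assumed to be computed with origin at the QC
#'   center of mass, the same expansion point at which the environment's
#'   potential and field are evaluated.
#'
#' @param energies Numeric vector of state energies in Hartree, ground first.
#'   Only differences enter the physics, so `energies[1]` may be 0.
#' @param dipoles Named list of three `n x n` numeric matrices (`x`, `y`,
#'   `z`): dipole-operator matrix elements in atomic units.
#' @param total_charge Integer total charge of the QC in elementary charges.
#' @param label Free-text conformer id (e.g. `"B1"`, `"B3"`, `"B5"`).
#'
#' @return An object of class `unperturbed_states`.
#' @seealso [read_states()], [write_states()], [make_flavin_like_states()]
#' @export
unperturbed_states <- function(energies, dipoles, total_charge = 0L, label = "QC") {
  energies <- as.numeric(energies)
  n <- length(energies)
  if (n < 2L) {
    stop_validation("need at least a ground and one excited state")
  }
  if (!is.list(dipoles) || !all(c("x", "y", "z") %in% names(dipoles))) {
    stop_validation("`dipoles` must be a named list with matrices `x`, `y`, `z`")
  }
  dipoles <- dipoles[c("x", "y", "z")]
  for (ax in c("x", "y", "z")) {
    m <- dipoles[[ax]]
    if (!is.matrix(m) || !all(dim(m) == c(n, n))) {
      stop_validation(sprintf(
        "dipole matrix '%s' must be %d x %d to match the %d state energies",
        ax, n, n, n
      ))
    }
    storage.mode(dipoles[[ax]]) <- "double"
  }
  x <- structure(
    list(
      n_states = n,
      energies = energies,
      dipoles = dipoles,
      total_charge = as.integer(total_charge),
      label = as.character(label)
    ),
    class = "unperturbed_states"
  )
  validate_states(x)
}

#' Validate an `unperturbed_states` object
#'
#' Checks the class invariants: energy ordering, dipole-matrix symmetry
#' (absolute tolerance `1e-10` a.u.) and the excited-to-excited zero
#' structure. Called by the constructor and the reader; exported so edited
#' objects can be re-checked.
#'
#' @param x An `unperturbed_states` object.
#' @param sym_tol Absolute tolerance for dipole-matrix symmetry, a.u.
#' @return `x`, invisibly unchanged, if valid; otherwise a validation error
#'   naming the violated invariant.
#' @export
validate_states <- function(x, sym_tol = 1e-10) {
  e <- x$energies
  if (is.unsorted(e)) {
    stop_validation("invariant violated: energies must be sorted non-decreasing (ground state first)")
  }
  n <- x$n_states
  for (ax in c("x", "y", "z")) {
    m <- x$dipoles[[ax]]
    if (any(!is.finite(m))) {
      stop_validation(sprintf("invariant violated: non-finite dipole element in axis '%s'", ax))
    }
    if (max(abs(m - t(m))) > sym_tol) {
      stop_validation(sprintf(
        "invariant violated: dipole matrix '%s' is asymmetric beyond %g a.u.", ax, sym_tol
      ))
    }
    if (n > 2L) {
      ex <- m[-1L, -1L, drop = FALSE]
      off <- ex - diag(diag(ex), nrow = n - 1L)
      if (max(abs(off)) > sym_tol) {
        bad <- which(abs(off) == max(abs(off)), arr.ind = TRUE)[1L, ]
        stop_validation(sprintf(
          paste0(
            "invariant violated: nonzero excited-to-excited dipole element ",
            "(axis '%s', states %d-%d); excited-to-excited transition dipoles are not part of the model"
          ),
          ax, bad[[1L]], bad[[2L]]
        ))
      }
    }
  }
  invisible(x)
}

#' @export
print.unperturbed_states <- function(x, ...) {
  cat(sprintf(
    "<unperturbed_states> conformer '%s': %d states, charge %+d\n",
    x$label, x$n_states, x$total_charge
  ))
  exc <- (x$energies - x$energies[1L])[-1L]
  cat(sprintf(
    "  first excitations: %s nm\n",
    paste(sprintf("%.1f", hartree_to_nm(utils::head(exc, 3L))), collapse = ", ")
  ))
  invisible(x)
}

#' Excitation table of an electronic reference
#'
#' @param x An `unperturbed_states` object.
#' @param ... Unused.
#' @return A tibble with one row per excited state: excitation energy
#'   (Hartree and eV), equivalent wavelength (nm), ground-to-excited
#'   transition-dipole components and squared norm (a.u.).
#' @method tidy unperturbed_states
#' @export
tidy.unperturbed_states <- function(x, ...) {
  exc <- (x$energies - x$energies[1L])[-1L]
  mu <- vapply(
    c("x", "y", "z"),
    function(ax) x$dipoles[[ax]][1L, -1L],
    numeric(x$n_states - 1L)
  )
  mu <- matrix(mu, ncol = 3L)
  tibble::tibble(
    label = x$label,
    state = seq_len(x$n_states - 1L),
    energy_h = exc,
    energy_ev = hartree_to_ev(exc),
    wavelength_nm = hartree_to_nm(exc),
    mu_x = mu[, 1L],
    mu_y = mu[, 2L],
    mu_z = mu[, 3L],
    mu2 = rowSums(mu^2)
  )
}

#' @method glance unperturbed_states
#' @export
glance.unperturbed_states <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    label = x$label,
    n_states = x$n_states,
    total_charge = x$total_charge,
    lambda1_nm = td$wavelength_nm[1L],
    lambda2_nm = if (nrow(td) >= 2L) td$wavelength_nm[2L] else NA_real_
  )
}

# ---- fixture file format ---------------------------------------------------
# Plain-text, self-describing, versioned:
#   # pmmspectra-states v1
#   N_STATES <n>
#   CHARGE <q>
#   LABEL <text>
#   ENERGY <state 0-based> <Hartree>
#   DIPOLE <axis x|y|z> <i 0-based> <j 0-based> <a.u.>
# Only i <= j dipole elements are stored; symmetry fills the rest.

STATES_HEADER <- "# pmmspectra-states v1"

#' Read an electronic-reference fixture file
#'
#' Parses the package's plain-text fixture format for unperturbed electronic
#' states (the stand-in for TD-DFT output) and returns a validated
#' [unperturbed_states()] object.
#'
#' @param path Path to a fixture file.
#' @return An `unperturbed_states` object.
#' @export
read_states <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such states file: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[[1L]]) != STATES_HEADER) {
    stop_parse(sprintf("'%s' is not a pmmspectra-states v1 file (bad header)", path))
  }
  lines <- lines[-1L]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]

  n_states <- NA_integer_
  charge <- 0L
  label <- "QC"
  energies <- NULL
  dip_rows <- list()

  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    key <- tok[[1L]]
    if (key == "N_STATES") {
      n_states <- as.integer(tok[[2L]])
      energies <- rep(NA_real_, n_states)
    } else if (key == "CHARGE") {
      charge <- as.integer(tok[[2L]])
    } else if (key == "LABEL") {
      label <- paste(tok[-1L], collapse = " ")
    } else if (key == "ENERGY") {
      if (length(tok) != 3L) stop_parse(sprintf("malformed ENERGY record: '%s'", ln))
      i <- as.integer(tok[[2L]])
      if (is.na(n_states)) stop_parse("ENERGY record before N_STATES")
      if (is.na(i) || i < 0L || i >= n_states) {
        stop_parse(sprintf("ENERGY record with out-of-range state index: '%s'", ln))
      }
      energies[i + 1L] <- as.numeric(tok[[3L]])
    } else if (key == "DIPOLE") {
      if (length(tok) != 5L) stop_parse(sprintf("malformed DIPOLE record: '%s'", ln))
      dip_rows[[length(dip_rows) + 1L]] <- tok
    } else {
      stop_parse(sprintf("unknown record '%s' in '%s'", key, path))
    }
  }
  if (is.na(n_states)) stop_parse(sprintf("missing N_STATES record in '%s'", path))
  if (anyNA(energies)) {
    stop_parse(sprintf(
      "missing ENERGY record for state(s) %s",
      paste(which(is.na(energies)) - 1L, collapse = ", ")
    ))
  }
  dip <- lapply(
    stats::setNames(c("x", "y", "z"), c("x", "y", "z")),
    function(ax) matrix(0, n_states, n_states)
  )
  for (tok in dip_rows) {
    ax <- tok[[2L]]
    if (!ax %in% c("x", "y", "z")) stop_parse(sprintf("DIPOLE record with bad axis '%s'", ax))
    i <- as.integer(tok[[3L]])
    j <- as.integer(tok[[4L]])
    v <- as.numeric(tok[[5L]])
    if (anyNA(c(i, j)) || i < 0L || j < 0L || i >= n_states || j >= n_states || is.na(v)) {
      stop_parse(sprintf("malformed DIPOLE record: '%s'", paste(tok, collapse = " ")))
    }
    dip[[ax]][i + 1L, j + 1L] <- v
    dip[[ax]][j + 1L, i + 1L] <- v
  }
  unperturbed_states(energies, dip, charge, label)
}

#' Write an electronic-reference fixture file
#'
#' Inverse of [read_states()]: serializes all numeric fields at full double
#' precision (17 significant digits), so a write/read round trip is the
#' identity bit-for-bit.
#'
#' @param states An `unperturbed_states` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_states <- function(states, path) {
  validate_states(states)
  n <- states$n_states
  out <- c(
    STATES_HEADER,
    sprintf("N_STATES %d", n),
    sprintf("CHARGE %d", states$total_charge),
    sprintf("LABEL %s", states$label),
    sprintf("ENERGY %d %.17g", seq_len(n) - 1L, states$energies)
  )
  for (ax in c("x", "y", "z")) {
    m <- states$dipoles[[ax]]
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (m[i, j] != 0) {
          out <- c(out, sprintf("DIPOLE %s %d %d %.17g", ax, i - 1L, j - 1L, m[i, j]))
        }
      }
    }
  }
  ok <- tryCatch(
    {
      writeLines(out, path)
      TRUE
    },
    error = function(e) FALSE,
    warning = function(w) FALSE
  )
  if (!ok) stop_io(sprintf("cannot write states file '%s'", path))
  invisible(path)
}
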