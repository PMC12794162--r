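# Shared fixtures, all built in code.

# minimal two-state reference: energies (0, omega), mu_01 = m on x,
# permanent dipoles (p0, p1) on x
two_state_states <- function(omega = 0.105, m = 0.5, p0 = 0, p1 = 0, charge = 0L) {
  dx <- matrix(c(p0, m, m, p1), 2L, 2L)
  z <- matrix(0, 2L, 2L)
  unperturbed_states(c(0, omega), list(x = dx, y = z, z = z),
                     total_charge = charge, label = "two")
}

# random valid n-state reference (ground-to-excited + diagonal structure)
random_states <- function(n_states = 11L, seed = 1L, label = "rand") {
  withr::with_seed(seed, {
    energies <- c(0, 0.08 + cumsum(runif(n_states - 1L, 0.02, 0.05)))
    dip <- lapply(1:3, function(ax) {
      m <- matrix(0, n_states, n_states)
      v <- runif(n_states - 1L, -1, 1)
      m[1L, -1L] <- v
      m[-1L, 1L] <- v
      diag(m) <- runif(n_states, -2, 2)
      m
    })
    names(dip) <- c("x", "y", "z")
    unperturbed_states(energies, dip, 0L, label)
  })
}

# single point charge q at position pos (nm), expansion point at origin
point_charge_frame <- function(pos, q, frame_index = 1L, qc = c(0, 0, 0),
                               residue_name = "ION") {
  pos <- matrix(pos, ncol = 3L)
  charge_frame(
    tibble::tibble(
      atom_id = seq_len(nrow(pos)),
      residue_id = seq_len(nrow(pos)),
      residue_name = rep_len(residue_name, nrow(pos)),
      x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
      q = q
    ),
    qc_point = qc, frame_index = frame_index
  )
}

# brute-force Coulomb oracle: scalar double loop, independent of the
# vectorized implementation path
brute_force_vE <- function(frame) {
  a <- frame$atoms
  v <- 0
  e <- c(0, 0, 0)
  for (i in seq_len(nrow(a))) {
    rel <- (frame$qc_point - c(a$x[i], a$y[i], a$z[i])) * pmmspectra:::NM_BOHR
    d <- sqrt(sum(rel^2))
    v <- v + a$q[i] / d
    e <- e + a$q[i] * rel / d^3
  }
  list(V = v, E = e)
}

random_charge_frame <- function(n = 50L, seed = 1L, frame_index = 1L) {
  withr::with_seed(seed, {
    u <- matrix(rnorm(3L * n), n, 3L)
    u <- u / sqrt(rowSums(u^2))
    r <- runif(n, 0.3, 2.5)
    point_charge_frame(u * r, runif(n, -1, 1), frame_index = frame_index)
  })
}

expect_pmms_error <- function(expr, type) {
  expect_error(expr, class = paste0("pmms_", type, "_error"))
}
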