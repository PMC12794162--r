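test_that("unit Coulomb cases match closed forms", {
  # +1 e at 1 Bohr: V = 1, |E| = 1 a.u.
  d_nm <- 1 / pmmspectra:::NM_BOHR
  fr <- point_charge_frame(c(d_nm, 0, 0), 1)
  env <- site_potential_field(fr, clash_cutoff = 0.01)
  expect_equal(env$V, 1, tolerance = 1e-12)
  expect_equal(sqrt(env$Ex^2 + env$Ey^2 + env$Ez^2), 1, tolerance = 1e-12)
  expect_equal(env$Ex, -1, tolerance = 1e-12)  # field points away from + charge

  # symmetric pair +q/-q at (+d,0,0)/(-d,0,0): V = 0, E = (-2q/d^2, 0, 0)
  q <- 0.7
  d <- 0.5
  fr2 <- point_charge_frame(rbind(c(d, 0, 0), c(-d, 0, 0)), c(q, -q))
  env2 <- site_potential_field(fr2)
  d_b <- d * pmmspectra:::NM_BOHR
  expect_equal(env2$V, 0, tolerance = 1e-14)
  expect_equal(env2$Ex, -2 * q / d_b^2, tolerance = 1e-12)
  expect_equal(abs(env2$Ey) + abs(env2$Ez), 0, tolerance = 1e-14)
})

test_that("potential and field match an independent brute-force sum", {
  for (seed in 1:25) {
    fr <- random_charge_frame(n = 50L, seed = seed)
    env <- site_potential_field(fr)
    bf <- brute_force_vE(fr)
    expect_equal(env$V, bf$V, tolerance = 1e-12)
    expect_equal(c(env$Ex, env$Ey, env$Ez), bf$E, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("Coulomb sums are linear, scale with charge and are translation invariant", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      fr <- random_charge_frame(n = 40L, seed = rep + 100L)
      env <- site_potential_field(fr)
      # additivity over a random partition
      part <- sample(c(TRUE, FALSE), 40L, replace = TRUE)
      part[1L] <- TRUE; part[2L] <- FALSE  # both halves non-empty
      fa <- charge_frame(fr$atoms[part, ], fr$qc_point)
      fb <- charge_frame(fr$atoms[!part, ], fr$qc_point)
      ea <- site_potential_field(fa)
      eb <- site_potential_field(fb)
      expect_equal(env$V, ea$V + eb$V, tolerance = 1e-12)
      expect_equal(env$Ex, ea$Ex + eb$Ex, tolerance = 1e-12)

      # charge scaling
      at <- fr$atoms; at$q <- 3.5 * at$q
      es <- site_potential_field(charge_frame(at, fr$qc_point))
      expect_equal(es$V, 3.5 * env$V, tolerance = 1e-12)
      expect_equal(c(es$Ex, es$Ey, es$Ez), 3.5 * c(env$Ex, env$Ey, env$Ez),
                   tolerance = 1e-12)

      # rigid translation of everything leaves V and |E| unchanged
      shift <- rnorm(3)
      at2 <- fr$atoms
      at2$x <- at2$x + shift[1L]; at2$y <- at2$y + shift[2L]; at2$z <- at2$z + shift[3L]
      et <- site_potential_field(charge_frame(at2, fr$qc_point + shift))
      expect_equal(et$V, env$V, tolerance = 1e-12)
      expect_equal(sqrt(et$Ex^2 + et$Ey^2 + et$Ez^2),
                   sqrt(env$Ex^2 + env$Ey^2 + env$Ez^2), tolerance = 1e-12)
    }
  })
})

test_that("clash cutoff and degenerate geometry are rejected", {
  fr <- point_charge_frame(c(0.01, 0, 0), 1)
  expect_pmms_error(site_potential_field(fr), "geometry")          # default 0.05 nm
  expect_silent(site_potential_field(fr, clash_cutoff = 0.005))
  expect_pmms_error(point_charge_frame(c(0, 0, 0), 1), "validation")
})

test_that("charge edits change only the selected residue by an integer", {
  # arginine-like +1 side chain spread over 4 atoms, plus spectators
  pos <- rbind(
    c(1, 0, 0), c(1.1, 0, 0), c(1, 0.1, 0), c(1.1, 0.1, 0),  # ARG, +1 total
    c(-1, 0, 0), c(0, 1.5, 0)                                # others
  )
  atoms <- tibble::tibble(
    atom_id = 1:6,
    residue_id = c(451L, 451L, 451L, 451L, 432L, 1L),
    residue_name = c(rep("ARG", 4L), "CYS", "WAT"),
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    q = c(0.4, 0.3, 0.2, 0.1, 0.0, -0.8)
  )
  fr <- charge_frame(atoms, c(0, 0, 0))

  # neutralize ARG451: net change exactly -1
  ed <- charge_edit("ARG", 451L, new_charges = c(0, 0, 0, 0))
  fr2 <- apply_charge_edit(fr, ed)
  expect_equal(sum(fr2$atoms$q) - sum(fr$atoms$q), -1, tolerance = 1e-12)
  expect_identical(fr2$atoms[5:6, ], fr$atoms[5:6, ])
  expect_identical(fr2$atoms[c("x", "y", "z")], fr$atoms[c("x", "y", "z")])

  # deprotonate CYS432: 0 -> -1
  ed2 <- charge_edit("CYS", 432L, new_charges = -1)
  fr3 <- apply_charge_edit(fr, ed2)
  expect_equal(sum(fr3$atoms$q) - sum(fr$atoms$q), -1, tolerance = 1e-12)

  # identity edit leaves the fields untouched
  ed3 <- charge_edit("ARG", 451L, new_charges = c(0.4, 0.3, 0.2, 0.1))
  expect_equal(site_potential_field(apply_charge_edit(fr, ed3)),
               site_potential_field(fr))

  # empty selection and non-integer change are rejected
  expect_pmms_error(apply_charge_edit(fr, charge_edit("LYS", new_charges = 0)), "selection")
  expect_pmms_error(
    apply_charge_edit(fr, charge_edit("ARG", 451L, new_charges = c(0.1, 0, 0, 0))),
    "validation"
  )
})

test_that("environment_trajectory preserves order and isolates edit effects", {
  fr <- random_charge_frame(n = 30L, seed = 9)
  frames <- lapply(1:3, function(i) charge_frame(fr$atoms, fr$qc_point, i))
  envs <- environment_trajectory(frames)
  expect_identical(envs$frame, 1:3)
  expect_equal(envs$V, rep(envs$V[1L], 3L))
  expect_equal(envs$Ex, rep(envs$Ex[1L], 3L))

  expect_pmms_error(environment_trajectory(list()), "validation")

  # edited vs unedited: difference equals the edited atoms' own contribution
  at <- fr$atoms
  at$residue_name[5L] <- "TRG"
  at$q[5L] <- 0.25
  base <- charge_frame(at, fr$qc_point)
  ed <- charge_edit("TRG", new_charges = -0.75)
  edited <- apply_charge_edit(base, ed)
  dV <- site_potential_field(edited)$V - site_potential_field(base)$V
  only_target_old <- charge_frame(at[5L, ], fr$qc_point)
  at_new <- at[5L, ]; at_new$q <- -0.75
  only_target_new <- charge_frame(at_new, fr$qc_point)
  expect_equal(
    dV,
    site_potential_field(only_target_new)$V - site_potential_field(only_target_old)$V,
    tolerance = 1e-12
  )
})

test_that("charge-frame and field-trajectory files round trip", {
  frames <- lapply(1:2, function(i) random_charge_frame(n = 10L, seed = i, frame_index = i))
  p1 <- withr::local_tempfile(fileext = ".chg")
  write_charge_frames(frames, p1)
  back <- read_charge_frames(p1)
  expect_length(back, 2L)
  expect_equal(back[[1L]]$atoms, frames[[1L]]$atoms)
  expect_identical(back[[2L]]$frame_index, 2L)

  envs <- environment_trajectory(frames)
  envs$d1 <- c(3.2, NA)
  p2 <- withr::local_tempfile(fileext = ".vef")
  write_field_trajectory(envs, p2)
  back2 <- read_field_trajectory(p2)
  expect_equal(back2$V, envs$V)
  expect_equal(back2$d1, envs$d1)
})
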