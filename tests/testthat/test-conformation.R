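test_that("dihedral handles planar and degenerate arrangements", {
  # cis planar -> 0
  expect_equal(
    dihedral(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0)), 0, tolerance = 1e-12
  )
  # trans planar -> 180
  expect_equal(
    dihedral(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0)), 180, tolerance = 1e-12
  )
  # +/- 90
  expect_equal(
    abs(dihedral(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 0, 1))), 90, tolerance = 1e-12
  )
  # collinear chain is degenerate
  expect_pmms_error(
    dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)), "geometry"
  )
})

test_that("dihedral matches the bio3d torsion oracle on random quadruples", {
  withr::with_seed(123, {
    for (i in 1:200) {
      p <- matrix(rnorm(12), 4L, 3L)
      # reject near-degenerate draws the oracle also can't handle
      b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
      n1 <- pmmspectra:::cross3(b1, b2); n2 <- pmmspectra:::cross3(b2, b3)
      if (sqrt(sum(n1^2)) < 1e-3 || sqrt(sum(n2^2)) < 1e-3) next
      ref <- bio3d::torsion.xyz(as.numeric(t(p)), atm.inc = 4L)
      got <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
      delta <- (got - ref + 180) %% 360 - 180
      expect_lt(abs(delta), 1e-9)
    }
  })
})

test_that("dihedral is invariant under rigid motions", {
  withr::with_seed(5, {
    p <- matrix(rnorm(12), 4L, 3L)
    base <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    for (i in 1:20) {
      # random rotation via QR of a random matrix
      qr_ <- qr(matrix(rnorm(9), 3L, 3L))
      rot <- qr.Q(qr_)
      if (det(rot) < 0) rot[, 1L] <- -rot[, 1L]
      shift <- rnorm(3)
      p2 <- p %*% rot + matrix(shift, 4L, 3L, byrow = TRUE)
      expect_equal(dihedral(p2[1, ], p2[2, ], p2[3, ], p2[4, ]), base,
                   tolerance = 1e-9)
    }
  })
})

test_that("basin classification follows the |d1| thresholds and boundary rule", {
  ba <- classify_basins(c(3, 8, 15))
  expect_identical(ba$assignments$basin, c("planar", "partially_bent", "bent"))
  expect_equal(basin_populations(ba), c(planar = 1, partially_bent = 1, bent = 1) / 3)

  # boundary values 6 and 12 fall in the partially-bent (closed) interval
  bb <- classify_basins(c(6, 12, -6, -12))
  expect_identical(unique(bb$assignments$basin), "partially_bent")

  # all-planar series gives populations (1, 0, 0); sum is always 1
  bz <- classify_basins(rep(0, 5L))
  expect_equal(unname(basin_populations(bz)), c(1, 0, 0))
  expect_equal(sum(basin_populations(bz)), 1, tolerance = 1e-12)

  # conformer mapping defaults
  expect_identical(bz$assignments$conformer[1L], "B1")
  expect_identical(ba$populations$conformer, c("B1", "B3", "B5"))

  # populations are permutation invariant
  withr::with_seed(77, {
    d <- runif(500, 0, 20)
    p1 <- basin_populations(classify_basins(d))
    p2 <- basin_populations(classify_basins(sample(d)))
    expect_equal(p1, p2)
  })

  expect_pmms_error(classify_basins(numeric(0)), "validation")
  expect_pmms_error(classify_basins(c(1, 2), thresholds = c(12, 6)), "config")
})

test_that("generated three-well series recovers the target populations", {
  cfg <- generator_config(seed = 202, n_frames = 100000L)
  bs <- make_bending_series(cfg, ring = FALSE)
  pops <- basin_populations(classify_basins(bs$d1))
  expect_lt(max(abs(unname(pops) - c(0.27, 0.44, 0.29))), 0.01)
})

test_that("essential dynamics recovers a planted rank-1 displacement", {
  tmpl <- flavin_ring_template()
  n_atoms <- nrow(tmpl$coords)
  withr::with_seed(8, {
    v <- matrix(rnorm(3L * n_atoms, 0, 0.01), n_atoms, 3L)
  })
  co <- array(NA_real_, c(2L, n_atoms, 3L))
  co[1L, , ] <- tmpl$coords - v / 2
  co[2L, , ] <- tmpl$coords + v / 2
  traj <- ring_trajectory(co, tmpl$atom_names)
  em <- essential_dynamics(traj)
  expect_gt(em$eigenvalues[1L], 0)
  expect_lt(em$eigenvalues[2L] / em$eigenvalues[1L], 1e-10)
  # variance of each projection equals its eigenvalue
  nz <- em$eigenvalues > 1e-20
  expect_equal(apply(em$projections, 2L, stats::var)[nz], em$eigenvalues[nz],
               tolerance = 1e-8)
  # trace identity: eigenvalue sum equals total positional variance
  expect_equal(sum(em$eigenvalues), sum(apply(em$projections, 2L, stats::var)),
               tolerance = 1e-10)
})

test_that("all-identical frames give zero eigenvalues without error", {
  tmpl <- flavin_ring_template()
  co <- array(rep(tmpl$coords, each = 3L), c(3L, nrow(tmpl$coords), 3L))
  em <- essential_dynamics(ring_trajectory(co, tmpl$atom_names))
  expect_true(all(em$eigenvalues < 1e-20))
})

test_that("mode 1 of a bending trajectory is the bending mode", {
  cfg <- generator_config(seed = 31, n_frames = 3000L)
  bs <- make_bending_series(cfg)
  em <- essential_dynamics(bs$trajectory, n_modes = 4L)
  r <- stats::cor(em$projections[, 1L], bs$d1$d1)
  expect_gt(abs(r), 0.99)
  # eigenvalues descend and dominate in mode 1
  expect_true(all(diff(em$eigenvalues) <= 1e-15))
  expect_gt(em$eigenvalues[1L] / sum(em$eigenvalues), 0.9)
})

test_that("eigenvalues are invariant under rigid translation of all frames", {
  cfg <- generator_config(seed = 32, n_frames = 200L)
  bs <- make_bending_series(cfg)
  em1 <- essential_dynamics(bs$trajectory, n_modes = 3L)
  co <- bs$trajectory$coordinates
  co2 <- co
  co2[, , 1L] <- co2[, , 1L] + 5
  co2[, , 3L] <- co2[, , 3L] - 2
  em2 <- essential_dynamics(ring_trajectory(co2, bs$trajectory$atom_names), n_modes = 3L)
  expect_equal(em1$eigenvalues, em2$eigenvalues, tolerance = 1e-10)
})

test_that("representative extraction picks nearest frames, earliest on ties", {
  cfg <- generator_config(seed = 33, n_frames = 2000L)
  bs <- make_bending_series(cfg)
  em <- essential_dynamics(bs$trajectory, n_modes = 2L)
  p1 <- em$projections[, 1L]
  rng <- range(p1)

  reps <- extract_representatives(em, bs$trajectory, c(rng[1L], rng[2L]))
  expect_identical(reps$row, c(which.min(p1), which.max(p1)))

  # five targets spanning the range hit five distinct frames nearby
  targets <- seq(rng[1L] * 0.9, rng[2L] * 0.9, length.out = 5L)
  r5 <- extract_representatives(em, bs$trajectory, targets)
  expect_identical(length(unique(r5$frame)), 5L)
  expect_lt(max(abs(r5$projection - r5$target)), diff(rng) / 50)

  # duplicate targets return the same frame twice
  rd <- extract_representatives(em, bs$trajectory, c(0, 0))
  expect_identical(rd$frame[1L], rd$frame[2L])

  expect_pmms_error(
    extract_representatives(em, bs$trajectory, rng[2L] + 1), "range"
  )
})

test_that("the bent template reproduces its bend angle exactly", {
  tmpl <- flavin_ring_template()
  idx <- match(c("C4", "N5", "N10", "C9"), tmpl$atom_names)
  for (ang in c(-20, 0, 6, 12, 20)) {
    co <- bend_template(ang)
    got <- dihedral(co[idx[1L], ], co[idx[2L], ], co[idx[3L], ], co[idx[4L], ])
    expect_equal(got, ang, tolerance = 1e-6)
  }
  # dihedral_series agrees frame by frame with the drawn d1
  cfg <- generator_config(seed = 34, n_frames = 50L)
  bs <- make_bending_series(cfg)
  ds <- dihedral_series(bs$trajectory)
  expect_equal(ds$d1, bs$d1$d1, tolerance = 1e-9)
})
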