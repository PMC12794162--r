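#' Ring-atom trajectory
#'
#' Coordinates of the chromophore's C/N ring atoms along a trajectory, the
#' input for the bending dihedral and the essential-dynamics PCA.
#'
#' @param coordinates Numeric array `frames x atoms x 3`, nm.
#' @param atom_names Character vector, one name per atom. Must contain each
#'   of `C4`, `N5`, `N10`, `C9` exactly once for the bending dihedral.
#' @param frame_indices Optional integer frame ids (default `1:n_frames`).
#' @return An object of class `ring_trajectory`.
#' @export
ring_trajectory <- function(coordinates, atom_names, frame_indices = NULL) {
  if (length(dim(coordinates)) != 3L || dim(coordinates)[3L] != 3L) {
    stop_validation("`coordinates` must be a frames x atoms x 3 array")
  }
  n_atoms <- dim(coordinates)[2L]
  if (length(atom_names) != n_atoms) {
    stop_validation("`atom_names` length must match the number of atoms")
  }
  for (nm in c("C4", "N5", "N10", "C9")) {
    if (sum(atom_names == nm) != 1L) {
      stop_validation(sprintf("atom '%s' must be present exactly once", nm))
    }
  }
  if (is.null(frame_indices)) frame_indices <- seq_len(dim(coordinates)[1L])
  if (length(frame_indices) != dim(coordinates)[1L]) {
    stop_validation("`frame_indices` length must match the number of frames")
  }
  structure(
    list(
      coordinates = coordinates,
      atom_names = as.character(atom_names),
      frame_indices = as.integer(frame_indices)
    ),
    class = "ring_trajectory"
  )
}

#' @export
print.ring_trajectory <- function(x, ...) {
  d <- dim(x$coordinates)
  cat(sprintf("<ring_trajectory> %d frames, %d atoms (%s...)\n",
              d[1L], d[2L], paste(utils::head(x$atom_names, 4L), collapse = " ")))
  invisible(x)
}

#' Signed dihedral (torsion) angle
#'
#' Standard signed torsion of four points about the `p2`-`p3` axis, in
#' degrees in `(-180, 180]`. The sign follows the usual convention:
#' positive when, looking from `p2` to `p3`, the far bond rotates clockwise
#' relative to the near bond.
#'
#' @param p1,p2,p3,p4 Numeric length-3 vectors.
#' @return Angle in degrees, in `(-180, 180]`.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- as.numeric(p2) - as.numeric(p1)
  b2 <- as.numeric(p3) - as.numeric(p2)
  b3 <- as.numeric(p4) - as.numeric(p3)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sum(n1^2) < 1e-24 || sum(n2^2) < 1e-24 || nb2 < 1e-12) {
    stop_geometry("degenerate dihedral: three consecutive points are (near-)collinear")
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(
    a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L]
  )
}

#' Bending dihedral series along a ring trajectory
#'
#' Computes the butterfly-bending coordinate d1 (the C4-N5-N10-C9 dihedral)
#' for every frame.
#'
#' @param traj A [ring_trajectory()].
#' @param atoms Character vector of four atom names defining the dihedral.
#' @return A tibble with columns `frame` and `d1` (degrees).
#' @export
dihedral_series <- function(traj, atoms = c("C4", "N5", "N10", "C9")) {
  if (!inherits(traj, "ring_trajectory")) stop_validation("`traj` must be a ring_trajectory")
  idx <- match(atoms, traj$atom_names)
  if (anyNA(idx)) {
    stop_validation(sprintf(
      "atom(s) %s not found in trajectory",
      paste(atoms[is.na(idx)], collapse = ", ")
    ))
  }
  co <- traj$coordinates
  d1 <- vapply(seq_len(dim(co)[1L]), function(f) {
    dihedral(co[f, idx[1L], ], co[f, idx[2L], ], co[f, idx[3L], ], co[f, idx[4L], ])
  }, numeric(1L))
  tibble::tibble(frame = traj$frame_indices, d1 = d1)
}

#' Write a d1 series as two-column text
#'
#' @param d1_series Tibble with `frame` and `d1` columns.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dihedral_series <- function(d1_series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# frame d1_degrees", con)
  writeLines(sprintf("%d %.17g", d1_series$frame, d1_series$d1), con)
  invisible(path)
}

#' Classify frames into bending basins
#'
#' Partitions frames into the three conformational basins of flavin
#' butterfly bending using the magnitude of the d1 dihedral: planar
#' (`|d1| < low`), partially bent (`low <= |d1| <= high`) and bent
#' (`|d1| > high`). The default thresholds are 6 and 12 degrees; boundary
#' values fall in the partially-bent basin (closed interval). The magnitude
#' is used because the basins are defined on the bending amplitude; the sign
#' of d1 only encodes the pucker direction.
#'
#' @param d1_series Numeric vector of d1 values (degrees), or a data frame
#'   with columns `d1` and optionally `frame`.
#' @param thresholds Numeric length-2 `(low, high)`, degrees.
#' @param reference_map Named character vector mapping basin to the conformer
#'   label whose electronic reference represents it.
#' @return An object of class `basin_assignment` with per-frame labels,
#'   basin populations and the basin-to-conformer map. Use [tidy()] for the
#'   per-frame table and [glance()] for populations.
#' @export
classify_basins <- function(d1_series,
                            thresholds = c(6, 12),
                            reference_map = c(planar = "B1", partially_bent = "B3", bent = "B5")) {
  if (is.data.frame(d1_series)) {
    if (!"d1" %in% names(d1_series)) stop_validation("data-frame input must have a `d1` column")
    frames <- if ("frame" %in% names(d1_series)) as.integer(d1_series$frame) else seq_len(nrow(d1_series))
    d1 <- as.numeric(d1_series$d1)
  } else {
    d1 <- as.numeric(d1_series)
    frames <- seq_along(d1)
  }
  if (length(d1) == 0L) stop_validation("empty d1 series")
  if (length(thresholds) != 2L || thresholds[1L] >= thresholds[2L]) {
    stop_config("`thresholds` must be (low, high) with low < high")
  }
  basins <- c("planar", "partially_bent", "bent")
  if (!all(basins %in% names(reference_map))) {
    stop_config("`reference_map` must name all of planar, partially_bent, bent")
  }
  a <- abs(d1)
  lab <- ifelse(a < thresholds[1L], "planar",
                ifelse(a <= thresholds[2L], "partially_bent", "bent"))
  lab <- factor(lab, levels = basins)
  pops <- tibble::tibble(
    basin = basins,
    n = as.integer(table(lab)),
    fraction = as.integer(table(lab)) / length(d1),
    conformer = unname(reference_map[basins])
  )
  structure(
    list(
      assignments = tibble::tibble(
        frame = frames, d1 = d1, basin = as.character(lab),
        conformer = unname(reference_map[as.character(lab)])
      ),
      populations = pops,
      thresholds = as.numeric(thresholds),
      reference_map = reference_map
    ),
    class = "basin_assignment"
  )
}

#' @export
print.basin_assignment <- function(x, ...) {
  cat(sprintf(
    "<basin_assignment> %d frames, thresholds (%g, %g) deg\n",
    nrow(x$assignments), x$thresholds[1L], x$thresholds[2L]
  ))
  p <- x$populations
  cat(paste(sprintf("  %-14s %5.1f%%  -> %s", p$basin, 100 * p$fraction, p$conformer),
            collapse = "\n"), "\n")
  invisible(x)
}

#' @method tidy basin_assignment
#' @export
tidy.basin_assignment <- function(x, ...) x$assignments

#' @method glance basin_assignment
#' @export
glance.basin_assignment <- function(x, ...) {
  tidyr::pivot_wider(
    x$populations[, c("basin", "fraction")],
    names_from = "basin", values_from = "fraction"
  )
}

#' Basin populations as a named vector
#'
#' @param x A `basin_assignment`.
#' @return Named numeric vector of basin fractions (sums to 1).
#' @export
basin_populations <- function(x) {
  stats::setNames(x$populations$fraction, x$populations$basin)
}

# ---- essential dynamics ----------------------------------------------------

# Kabsch rotation aligning P onto Q (both already centered): returns rotated P
kabsch_fit <- function(p, q) {
  s <- svd(crossprod(p, q))
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  p %*% t(r)
}

#' Essential dynamics (positional-covariance PCA)
#'
#' Principal component analysis of the covariance matrix of positional
#' fluctuations: frames are least-squares superposed on the mean structure
#' (translation + Kabsch rotation, iterated to self-consistency), the
#' `3N x 3N` covariance matrix of the fitted coordinates is diagonalized,
#' and each frame is projected onto the eigenvectors. The leading
#' eigenvectors are the large-amplitude collective modes (for the flavin
#' ring system, mode 1 is the butterfly bending). Coordinates are
#' unweighted (no mass weighting); projections are in the coordinate units
#' (nm).
#'
#' @param traj A [ring_trajectory()] with at least 2 frames.
#' @param n_modes Number of modes to retain (default: all `3N`).
#' @param max_iter,tol Superposition self-consistency controls.
#' @return An object of class `essential_modes` with `mean_structure`
#'   (atoms x 3), `eigenvalues` (nm^2, descending), `eigenvectors`
#'   (`3N x n_modes`, orthonormal), `projections` (frames x n_modes, nm)
#'   and bookkeeping fields.
#' @export
essential_dynamics <- function(traj, n_modes = NULL, max_iter = 10L, tol = 1e-12) {
  if (!inherits(traj, "ring_trajectory")) stop_validation("`traj` must be a ring_trajectory")
  co <- traj$coordinates
  n_frames <- dim(co)[1L]
  n_atoms <- dim(co)[2L]
  if (n_frames < 2L) stop_validation("essential dynamics needs at least 2 frames")
  if (is.null(n_modes)) n_modes <- 3L * n_atoms
  n_modes <- min(n_modes, 3L * n_atoms)

  # frames as a list of centered atoms x 3 matrices
  frames <- lapply(seq_len(n_frames), function(f) {
    m <- co[f, , ]
    sweep(m, 2L, colMeans(m))
  })
  ref <- frames[[1L]]
  for (it in seq_len(max_iter)) {
    fitted <- lapply(frames, kabsch_fit, q = ref)
    new_ref <- Reduce(`+`, fitted) / n_frames
    delta <- max(abs(new_ref - ref))
    ref <- new_ref
    if (delta < tol) break
  }
  fitted <- lapply(frames, kabsch_fit, q = ref)
  x <- t(vapply(fitted, function(m) as.numeric(t(m)), numeric(3L * n_atoms)))
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  cv <- crossprod(xc) / (n_frames - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  vals <- vals[seq_len(n_modes)]
  vecs <- vecs[, seq_len(n_modes), drop = FALSE]
  proj <- xc %*% vecs
  structure(
    list(
      mean_structure = matrix(mu, n_atoms, 3L, byrow = TRUE),
      eigenvalues = vals,
      eigenvectors = vecs,
      projections = proj,
      atom_names = traj$atom_names,
      frame_indices = traj$frame_indices
    ),
    class = "essential_modes"
  )
}

#' @export
print.essential_modes <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  frac <- if (tot > 0) x$eigenvalues[1L] / tot else NA_real_
  cat(sprintf(
    "<essential_modes> %d frames, %d modes; mode 1 carries %.1f%% of the positional variance\n",
    nrow(x$projections), length(x$eigenvalues), 100 * frac
  ))
  invisible(x)
}

#' @method tidy essential_modes
#' @export
tidy.essential_modes <- function(x, ...) {
  proj <- x$projections
  colnames(proj) <- paste0("proj_", seq_len(ncol(proj)))
  dplyr::bind_cols(tibble::tibble(frame = x$frame_indices), tibble::as_tibble(proj))
}

#' @method glance essential_modes
#' @export
glance.essential_modes <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  tibble::tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue_nm2 = x$eigenvalues,
    variance_fraction = if (tot > 0) x$eigenvalues / tot else NA_real_
  )
}

#' Representative frames along the first essential mode
#'
#' For each target projection value, returns the frame whose mode-1
#' projection is nearest (ties resolved to the earliest frame). This is how
#' representative conformers spanning the bending range are picked for
#' gas-phase reference calculations.
#'
#' @param modes An [essential_dynamics()] result.
#' @param traj The [ring_trajectory()] the modes came from.
#' @param targets Numeric projection values; must lie within the observed
#'   mode-1 projection range.
#' @return A tibble with columns `target`, `frame` (frame index), `row`
#'   (position in the trajectory) and `projection`.
#' @export
extract_representatives <- function(modes, traj, targets) {
  if (!inherits(modes, "essential_modes")) stop_validation("`modes` must be essential_modes")
  p1 <- modes$projections[, 1L]
  rng <- range(p1)
  out <- purrr::map(as.numeric(targets), function(tg) {
    if (tg < rng[1L] || tg > rng[2L]) {
      stop_range(sprintf(
        "target projection %.4g outside the observed range [%.4g, %.4g]", tg, rng[1L], rng[2L]
      ))
    }
    i <- which.min(abs(p1 - tg))  # which.min takes the earliest tie
    tibble::tibble(target = tg, frame = modes$frame_indices[i], row = i, projection = p1[i])
  })
  dplyr::bind_rows(out)
}

#' Read a ring trajectory from a multi-model PDB file
#'
#' Uses bio3d to parse the PDB; each MODEL becomes one frame. Coordinates
#' are converted from Angstrom to nm.
#'
#' @param path PDB file path.
#' @param atom_names Optional subset of atom names to keep (default: all C/N
#'   atoms in the file).
#' @return A [ring_trajectory()].
#' @export
read_ring_pdb <- function(path, atom_names = NULL) {
  rlang::check_installed("bio3d", reason = "to read PDB files")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  names_all <- pdb$atom$elety
  keep <- if (is.null(atom_names)) {
    grepl("^[CN]", names_all)
  } else {
    names_all %in% atom_names
  }
  xyz <- pdb$xyz
  n_frames <- nrow(xyz)
  idx <- which(keep)
  co <- array(NA_real_, c(n_frames, length(idx), 3L))
  for (f in seq_len(n_frames)) {
    m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    co[f, , ] <- m[idx, , drop = FALSE] / 10  # Angstrom -> nm
  }
  ring_trajectory(co, names_all[idx])
}
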