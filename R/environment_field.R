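#' Point-charge environment of a single trajectory frame
#'
#' A frame of the perturbing environment: partial point charges with
#' coordinates, plus the expansion point at which the potential and field are
#' evaluated (the quantum-center center of mass, supplied explicitly so the
#' module never needs QC atomic masses).
#'
#' @param atoms A data frame with columns `atom_id` (integer), `residue_id`
#'   (integer), `residue_name` (character), `x`, `y`, `z` (nm) and `q`
#'   (partial charge, elementary charge units).
#' @param qc_point Numeric length-3 vector, nm: the QC expansion point.
#' @param frame_index Integer frame identifier.
#' @return An object of class `charge_frame`.
#' @seealso [site_potential_field()], [apply_charge_edit()]
#' @export
charge_frame <- function(atoms, qc_point, frame_index = 1L) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("atom_id", "residue_id", "residue_name", "x", "y", "z", "q")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop_validation(sprintf("`atoms` is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  qc_point <- as.numeric(qc_point)
  if (length(qc_point) != 3L || any(!is.finite(qc_point))) {
    stop_validation("`qc_point` must be a finite length-3 vector (nm)")
  }
  if (nrow(atoms) == 0L) stop_validation("a charge frame must contain at least one atom")
  d2 <- (atoms$x - qc_point[1L])^2 + (atoms$y - qc_point[2L])^2 + (atoms$z - qc_point[3L])^2
  if (any(d2 == 0)) {
    stop_validation("an environment atom coincides with the QC expansion point")
  }
  structure(
    list(atoms = atoms, qc_point = qc_point, frame_index = as.integer(frame_index)),
    class = "charge_frame"
  )
}

#' @export
print.charge_frame <- function(x, ...) {
  cat(sprintf(
    "<charge_frame> frame %d: %d charges (net %+.3f e), qc_point = (%.3f, %.3f, %.3f) nm\n",
    x$frame_index, nrow(x$atoms), sum(x$atoms$q),
    x$qc_point[1L], x$qc_point[2L], x$qc_point[3L]
  ))
  invisible(x)
}

#' Electrostatic potential and field at the QC expansion point
#'
#' Direct Coulomb sum over the frame's point charges, in atomic units:
#' \deqn{V = \sum_i q_i / |r_i - r_{qc}|, \qquad
#'       E = \sum_i q_i (r_{qc} - r_i) / |r_{qc} - r_i|^3.}
#' Positions are converted from nm to Bohr internally. No periodic-boundary
#' or Ewald treatment is applied: the PMM perturbation uses the direct sum
#' over the environment atoms provided, optionally restricted by an
#' inclusion cutoff.
#'
#' @param frame A [charge_frame()].
#' @param clash_cutoff Minimum allowed charge-to-expansion-point distance,
#'   nm; closer charges raise a degenerate-geometry error. Default 0.05 nm.
#' @param inclusion_cutoff Optional distance cutoff, nm: charges farther than
#'   this are excluded from the sums. Default `NULL` (all charges included).
#' @return A one-row tibble with columns `frame`, `V` (a.u.), `Ex`, `Ey`,
#'   `Ez` (a.u.).
#' @export
site_potential_field <- function(frame, clash_cutoff = 0.05, inclusion_cutoff = NULL) {
  if (!inherits(frame, "charge_frame")) stop_validation("`frame` must be a charge_frame")
  a <- frame$atoms
  rel <- cbind(
    frame$qc_point[1L] - a$x,
    frame$qc_point[2L] - a$y,
    frame$qc_point[3L] - a$z
  ) * NM_BOHR
  q <- a$q
  d <- sqrt(rowSums(rel^2))
  if (any(d < clash_cutoff * NM_BOHR)) {
    stop_geometry(sprintf(
      "frame %d: environment charge within the clash cutoff (%.3g nm) of the QC expansion point",
      frame$frame_index, clash_cutoff
    ))
  }
  if (!is.null(inclusion_cutoff)) {
    keep <- d <= inclusion_cutoff * NM_BOHR
    rel <- rel[keep, , drop = FALSE]
    q <- q[keep]
    d <- d[keep]
  }
  v <- sum(q / d)
  e <- colSums(q * rel / d^3)
  if (any(!is.finite(c(v, e)))) {
    stop_numeric(sprintf("frame %d: non-finite potential or field", frame$frame_index))
  }
  tibble::tibble(frame = frame$frame_index, V = v, Ex = e[1L], Ey = e[2L], Ez = e[3L])
}

#' Residue charge edit (protonation-state counterfactual)
#'
#' Describes a counterfactual change of the partial charges of one residue's
#' atoms, e.g. neutralizing an arginine-like side chain (+1 to 0) or
#' deprotonating a cysteine-like one (0 to -1). The net charge change must be
#' an integer: the edit models a protonation-state change, not arbitrary
#' charge scaling.
#'
#' @param residue_name Residue name to select.
#' @param residue_id Integer residue id, or `NA` to match every residue with
#'   that name.
#' @param atom_ids Optional integer vector of atom ids within the selection
#'   (e.g. side-chain atoms only); `NULL` selects all atoms of the residue.
#' @param new_charges Numeric vector of replacement charges, one per selected
#'   atom (in selection order), or a single value recycled.
#' @return An object of class `charge_edit`.
#' @export
charge_edit <- function(residue_name, residue_id = NA_integer_, atom_ids = NULL, new_charges) {
  structure(
    list(
      residue_name = as.character(residue_name),
      residue_id = as.integer(residue_id),
      atom_ids = if (is.null(atom_ids)) NULL else as.integer(atom_ids),
      new_charges = as.numeric(new_charges)
    ),
    class = "charge_edit"
  )
}

edit_selection <- function(frame, edit) {
  a <- frame$atoms
  sel <- a$residue_name == edit$residue_name
  if (!is.na(edit$residue_id)) sel <- sel & a$residue_id == edit$residue_id
  if (!is.null(edit$atom_ids)) sel <- sel & a$atom_id %in% edit$atom_ids
  which(sel)
}

#' Apply a charge edit to one frame
#'
#' Replaces the selected atoms' partial charges; positions and every other
#' atom are untouched. Validates that the net charge change is an integer
#' (within `1e-6` e).
#'
#' @param frame A [charge_frame()].
#' @param edit A [charge_edit()].
#' @return A new `charge_frame` with edited charges.
#' @export
apply_charge_edit <- function(frame, edit) {
  if (!inherits(edit, "charge_edit")) stop_validation("`edit` must be a charge_edit")
  idx <- edit_selection(frame, edit)
  if (length(idx) == 0L) {
    stop_selection(sprintf(
      "charge edit selects no atoms (residue '%s', id %s)",
      edit$residue_name,
      if (is.na(edit$residue_id)) "*" else as.character(edit$residue_id)
    ))
  }
  newq <- edit$new_charges
  if (length(newq) == 1L) newq <- rep(newq, length(idx))
  if (length(newq) != length(idx)) {
    stop_validation(sprintf(
      "edit supplies %d charges but the selection has %d atoms",
      length(edit$new_charges), length(idx)
    ))
  }
  dq <- sum(newq) - sum(frame$atoms$q[idx])
  if (abs(dq - round(dq)) > 1e-6) {
    stop_validation(sprintf(
      "net charge change %.8f e is not an integer; protonation-state edits must change the charge by a whole number",
      dq
    ))
  }
  atoms <- frame$atoms
  atoms$q[idx] <- newq
  charge_frame(atoms, frame$qc_point, frame$frame_index)
}

#' Potential and field along a trajectory of charge frames
#'
#' Order- and length-preserving map of [site_potential_field()] over a list
#' of frames; per-frame errors are re-signalled with the frame index.
#'
#' @param frames Non-empty list of [charge_frame()] objects.
#' @inheritParams site_potential_field
#' @return A tibble with one row per frame: `frame`, `V`, `Ex`, `Ey`, `Ez`
#'   (all a.u.).
#' @export
environment_trajectory <- function(frames, clash_cutoff = 0.05, inclusion_cutoff = NULL) {
  if (length(frames) == 0L) stop_validation("`frames` must be a non-empty list of charge frames")
  rows <- purrr::imap(frames, function(fr, i) {
    tryCatch(
      site_potential_field(fr, clash_cutoff = clash_cutoff, inclusion_cutoff = inclusion_cutoff),
      pmms_error = function(e) {
        rlang::abort(
          sprintf("frame %d of %d: %s", i, length(frames), conditionMessage(e)),
          class = class(e)[1:2], parent = e
        )
      }
    )
  })
  dplyr::bind_rows(rows)
}

# ---- I/O -------------------------------------------------------------------

CHARGES_HEADER <- "# pmmspectra-charges v1"
FIELDS_HEADER <- "# pmmspectra-fields v1"

#' Write / read point-charge trajectories
#'
#' Plain-text columnar trajectory format: per frame a `FRAME <index> <qc_x>
#' <qc_y> <qc_z>` line followed by one `atom_id residue_id residue_name x y z
#' q` line per atom (positions nm, charges e).
#'
#' @param frames List of [charge_frame()] objects.
#' @param path File path.
#' @return `write_charge_frames()` returns `path` invisibly;
#'   `read_charge_frames()` returns a list of `charge_frame` objects.
#' @name charge_frame_io
NULL

#' @rdname charge_frame_io
#' @export
write_charge_frames <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(CHARGES_HEADER, con)
  for (fr in frames) {
    writeLines(sprintf(
      "FRAME %d %.17g %.17g %.17g",
      fr$frame_index, fr$qc_point[1L], fr$qc_point[2L], fr$qc_point[3L]
    ), con)
    a <- fr$atoms
    writeLines(sprintf(
      "%d %d %s %.17g %.17g %.17g %.17g",
      a$atom_id, a$residue_id, a$residue_name, a$x, a$y, a$z, a$q
    ), con)
  }
  invisible(path)
}

#' @rdname charge_frame_io
#' @export
read_charge_frames <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such charge-frame file: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[[1L]]) != CHARGES_HEADER) {
    stop_parse(sprintf("'%s' is not a pmmspectra-charges v1 file", path))
  }
  lines <- lines[-1L]
  starts <- which(startsWith(lines, "FRAME"))
  if (length(starts) == 0L) stop_parse(sprintf("no FRAME records in '%s'", path))
  ends <- c(starts[-1L] - 1L, length(lines))
  purrr::map2(starts, ends, function(s, e) {
    hdr <- strsplit(trimws(lines[[s]]), "[[:space:]]+")[[1L]]
    if (length(hdr) != 5L) stop_parse(sprintf("malformed FRAME record: '%s'", lines[[s]]))
    body <- lines[(s + 1L):e]
    body <- body[nzchar(trimws(body))]
    tok <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(tok) != 7L)
    if (length(bad)) stop_parse(sprintf("malformed atom record: '%s'", body[[bad[1L]]]))
    m <- do.call(rbind, tok)
    atoms <- tibble::tibble(
      atom_id = as.integer(m[, 1L]),
      residue_id = as.integer(m[, 2L]),
      residue_name = m[, 3L],
      x = as.numeric(m[, 4L]),
      y = as.numeric(m[, 5L]),
      z = as.numeric(m[, 6L]),
      q = as.numeric(m[, 7L])
    )
    charge_frame(atoms, as.numeric(hdr[3:5]), as.integer(hdr[[2L]]))
  })
}

#' Write / read precomputed (V, E, d1) trajectories
#'
#' Columnar text file with one row per frame: `frame V Ex Ey Ez d1` (a.u.
#' for V/E, degrees for the optional bending dihedral `d1`, `NA` when
#' absent).
#'
#' @param envs Tibble with columns `frame`, `V`, `Ex`, `Ey`, `Ez` and
#'   optionally `d1`.
#' @param path File path.
#' @return `write_field_trajectory()` returns `path` invisibly;
#'   `read_field_trajectory()` returns the tibble.
#' @name field_trajectory_io
NULL

#' @rdname field_trajectory_io
#' @export
write_field_trajectory <- function(envs, path) {
  envs <- tibble::as_tibble(envs)
  need <- c("frame", "V", "Ex", "Ey", "Ez")
  if (!all(need %in% names(envs))) {
    stop_validation(sprintf("`envs` must have columns %s", paste(need, collapse = ", ")))
  }
  d1 <- if ("d1" %in% names(envs)) envs$d1 else rep(NA_real_, nrow(envs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(FIELDS_HEADER, con)
  writeLines("# frame V Ex Ey Ez d1", con)
  writeLines(sprintf(
    "%d %.17g %.17g %.17g %.17g %s",
    envs$frame, envs$V, envs$Ex, envs$Ey, envs$Ez,
    ifelse(is.na(d1), "NA", sprintf("%.17g", d1))
  ), con)
  invisible(path)
}

#' @rdname field_trajectory_io
#' @export
read_field_trajectory <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such field-trajectory file: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[[1L]]) != FIELDS_HEADER) {
    stop_parse(sprintf("'%s' is not a pmmspectra-fields v1 file", path))
  }
  lines <- trimws(lines[-1L])
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tok <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(tok) != 6L)
  if (length(bad)) stop_parse(sprintf("malformed field record: '%s'", lines[[bad[1L]]]))
  m <- do.call(rbind, tok)
  out <- tibble::tibble(
    frame = as.integer(m[, 1L]),
    V = as.numeric(m[, 2L]),
    Ex = as.numeric(m[, 3L]),
    Ey = as.numeric(m[, 4L]),
    Ez = as.numeric(m[, 5L]),
    d1 = suppressWarnings(as.numeric(m[, 6L]))
  )
  if (anyDuplicated(out$frame)) stop_validation("duplicate frame indices in field trajectory")
  out
}
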