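#' CG configuration container
#'
#' A single frame of bead coordinates in an orthorhombic box. The bead table
#' is a tibble so every analysis verb composes with dplyr; the box rides
#' along as a field.
#'
#' @param beads Tibble with columns `bead` (type name), `molecule` (integer
#'   id), `template` (template name or `"W"` for water), `x`, `y`, `z`
#'   (Angstrom).
#' @param box Numeric length-3 edge vector, Angstrom.
#' @param templates Named list of `cg_template` objects keyed by the values
#'   appearing in `beads$template` (water needs no entry).
#' @return A `cg_config` object.
#' @export
cg_configuration <- function(beads, box, templates = list()) {
  beads <- as_tibble(beads)
  req <- c("bead", "molecule", "template", "x", "y", "z")
  stopifnot(all(req %in% names(beads)))
  if (!all(is.finite(as.matrix(beads[, c("x", "y", "z")])))) {
    abort("coordinates must be finite", class = "cgm_invalid_parameter")
  }
  stopifnot(length(box) == 3, all(box > 0))
  # molecule bead counts must match their template
  for (tn in names(templates)) {
    cnt <- dplyr::count(dplyr::filter(beads, .data$template == tn), .data$molecule)
    nb <- length(templates[[tn]]$beads)
    if (nrow(cnt) && any(cnt$n != nb)) {
      abort(paste0("molecules of template ", tn, " must have ", nb, " beads"),
            class = "cgm_invalid_parameter")
    }
  }
  structure(list(beads = beads, box = as.numeric(box), templates = templates),
            class = "cg_config")
}

#' @export
print.cg_config <- function(x, ...) {
  cat("<cg_config> ", nrow(x$beads), " beads, ",
      dplyr::n_distinct(x$beads$molecule), " molecules, box ",
      paste(signif(x$box, 5), collapse = " x "), " A\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.cg_config <- function(x, ...) x$beads

#' CG trajectory container
#'
#' An ordered set of configurations with constant particle identity. Frames
#' are stored as one long tibble with a `frame` column; per-frame boxes and
#' times live in the `frames` index tibble.
#'
#' @param configs List of `cg_config` objects (identical bead labelling).
#' @param times_ns Frame times in ns (defaults to 0-based index).
#' @param temperature Temperature in K carried as metadata.
#' @param metadata Free-form provenance list.
#' @return A `cg_trajectory`.
#' @export
cg_trajectory <- function(configs, times_ns = NULL, temperature = NA_real_,
                          metadata = list()) {
  stopifnot(length(configs) >= 1)
  n0 <- nrow(configs[[1]]$beads)
  lab0 <- configs[[1]]$beads$bead
  for (cf in configs) {
    if (nrow(cf$beads) != n0 || !identical(cf$beads$bead, lab0)) {
      abort("all frames must share particle count and bead labelling",
            class = "cgm_format_error")
    }
  }
  if (is.null(times_ns)) times_ns <- seq_along(configs) - 1
  beads <- dplyr::bind_rows(
    lapply(seq_along(configs), function(i) {
      dplyr::mutate(configs[[i]]$beads, frame = i, .before = 1)
    })
  )
  frames <- tibble(
    frame = seq_along(configs),
    time_ns = times_ns,
    lx = vapply(configs, function(cf) cf$box[1], 1.0),
    ly = vapply(configs, function(cf) cf$box[2], 1.0),
    lz = vapply(configs, function(cf) cf$box[3], 1.0)
  )
  structure(list(beads = beads, frames = frames,
                 templates = configs[[1]]$templates,
                 temperature = temperature, metadata = metadata),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", nrow(x$frames), " frames, ",
      nrow(x$beads) / nrow(x$frames), " beads/frame",
      if (!is.na(x$temperature)) paste0(", T = ", x$temperature, " K"), "\n",
      sep = "")
  invisible(x)
}

#' @export
as_tibble.cg_trajectory <- function(x, ...) x$beads

#' Number of frames in a trajectory
#' @param traj A `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$frames)

#' Extract one frame of a trajectory as a configuration
#' @param traj A `cg_trajectory`.
#' @param i Frame index (1-based).
#' @return A `cg_config`.
#' @export
get_frame <- function(traj, i) {
  fr <- dplyr::filter(traj$beads, .data$frame == i)
  bx <- unlist(traj$frames[traj$frames$frame == i, c("lx", "ly", "lz")])
  cg_configuration(dplyr::select(fr, -"frame"), bx, traj$templates)
}

# Assemble the C++ system list for a configuration + force field.
# Per-molecule template topologies are instantiated to absolute indices.
build_system <- function(config, ff) {
  beads <- config$beads
  tabs <- lj_tables(ff)
  type_id <- match(beads$bead, tabs$types)
  if (anyNA(type_id)) {
    abort(paste0("bead types absent from force field: ",
                 paste(unique(beads$bead[is.na(type_id)]), collapse = ", ")),
          class = "cgm_missing_parameter")
  }
  bonds <- list(); angles <- list(); excl <- list()
  for (mol in split(seq_len(nrow(beads)), beads$molecule)) {
    tn <- beads$template[mol[1]]
    tpl <- config$templates[[tn]]
    if (is.null(tpl)) next   # water or monatomic molecule
    b <- tpl$bonds; a <- tpl$angles
    names_b <- tpl$beads
    if (nrow(b)) {
      bp <- lookup_bond(ff, names_b[b[, 1]], names_b[b[, 2]])
      bonds[[length(bonds) + 1L]] <- cbind(mol[b[, 1]], mol[b[, 2]],
                                           bp$kb, bp$b0)
    }
    if (!is.null(a) && nrow(a)) {
      ap <- lookup_angle(ff, names_b[a[, 1]], names_b[a[, 2]], names_b[a[, 3]])
      angles[[length(angles) + 1L]] <- cbind(mol[a[, 1]], mol[a[, 2]], mol[a[, 3]],
                                             ap$ktheta, ap$theta0 * pi / 180)
    }
    ex <- build_exclusions(b, ff$exclusion_policy)
    if (nrow(ex)) excl[[length(excl) + 1L]] <- cbind(mol[ex$i], mol[ex$j])
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else matrix(0, 0, 4)
  angles <- if (length(angles)) do.call(rbind, angles) else matrix(0, 0, 5)
  excl <- if (length(excl)) do.call(rbind, excl) else matrix(0L, 0, 2)
  mass <- ff$bead_types$mass[type_id]
  list(
    coords = as.matrix(beads[, c("x", "y", "z")]),
    box = config$box,
    type = type_id - 1L,
    eps = tabs$eps, sig = tabs$sigma,
    bonds = matrix(as.integer(bonds[, 1:2, drop = FALSE] - 1L), ncol = 2),
    bond_kb = as.numeric(bonds[, 3]), bond_b0 = as.numeric(bonds[, 4]),
    angles = matrix(as.integer(angles[, 1:3, drop = FALSE] - 1L), ncol = 3),
    ang_kt = as.numeric(angles[, 4]), ang_t0 = as.numeric(angles[, 5]),
    excl = matrix(as.integer(excl - 1L), ncol = 2),
    cutoff = ff$cutoff, shift = ff$lj_shift, mass = mass
  )
}

#' Potential energy of a configuration
#'
#' Evaluates the CG potential: harmonic bonds `Kb (b - b0)^2`, harmonic
#' angles `Ktheta (theta - theta0)^2` (theta in radians internally) and
#' truncated 12-6 Lennard-Jones over non-excluded pairs under the
#' minimum-image convention.
#'
#' @param config A `cg_config`.
#' @param ff A `cg_forcefield`; every bond/angle type present in the
#'   configuration's templates must resolve (LJ pairs resolve via mixing).
#' @return One-row tibble with columns `bond`, `angle`, `lj`, `total`
#'   (kcal/mol).
#' @export
total_energy <- function(config, ff) {
  res <- cpp_energy_forces(build_system(config, ff))
  tibble(bond = res$bond, angle = res$angle, lj = res$lj, total = res$total)
}

#' Forces on every bead
#'
#' Negative gradient of [total_energy()] with respect to bead coordinates.
#'
#' @inheritParams total_energy
#' @return Tibble with columns `fx`, `fy`, `fz` (kcal/mol/Angstrom), one row
#'   per bead in configuration order.
#' @export
forces <- function(config, ff) {
  res <- cpp_energy_forces(build_system(config, ff))
  f <- res$forces
  tibble(fx = f[, 1], fy = f[, 2], fz = f[, 3])
}
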