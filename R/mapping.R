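#' All-atom frame container
#'
#' @param atoms Tibble with columns `name`, `mass` (amu), `residue` (integer
#'   id), `resname`, `x`, `y`, `z` (Angstrom).
#' @param box Numeric length-3 edge vector.
#' @return An `atom_frame`.
#' @export
atom_frame <- function(atoms, box) {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("name", "mass", "residue", "resname", "x", "y", "z") %in% names(atoms)))
  if (any(atoms$mass <= 0)) abort("atom masses must be positive",
                                  class = "cgm_invalid_parameter")
  structure(list(atoms = atoms, box = as.numeric(box)), class = "atom_frame")
}

#' @export
print.atom_frame <- function(x, ...) {
  cat("<atom_frame> ", nrow(x$atoms), " atoms, ",
      dplyr::n_distinct(x$atoms$residue), " residues\n", sep = "")
  invisible(x)
}

# Make a residue whole across periodic boundaries before taking centroids:
# every atom is shifted by box multiples to the image nearest the first atom.
unwrap_residue <- function(xyz, box) {
  ref <- xyz[1, ]
  for (a in 1:3) {
    if (box[a] > 0) {
      d <- xyz[, a] - ref[a]
      xyz[, a] <- xyz[, a] - box[a] * round(d / box[a])
    }
  }
  xyz
}

#' Map an all-atom structure to its CG representation
#'
#' Places every CG bead at the mass-weighted center of its atom group
#' (hydrogens included). Residues are made whole across periodic boundaries
#' before centroid computation.
#'
#' @param frame An [atom_frame()].
#' @param templates Named list of `cg_template` objects; names are matched
#'   against residue names through `resname_map`.
#' @param resname_map Optional named character vector translating PDB
#'   residue-name dialects to template names (e.g. `c(DMP = "DMPC")`).
#' @return A `cg_config`; beads carry the originating residue as molecule id.
#' @export
map_structure <- function(frame, templates, resname_map = NULL) {
  stopifnot(inherits(frame, "atom_frame"))
  if (inherits(templates, "cg_template")) {
    templates <- setNames(list(templates), templates$name)
  }
  rows <- list()
  for (res in split(frame$atoms, frame$atoms$residue)) {
    rn <- res$resname[1]
    tn <- if (!is.null(resname_map) && rn %in% names(resname_map)) resname_map[[rn]] else rn
    tpl <- templates[[tn]]
    if (is.null(tpl)) {
      abort(paste0("no template for residue name ", rn), class = "cgm_mapping_error")
    }
    xyz <- unwrap_residue(as.matrix(res[, c("x", "y", "z")]), frame$box)
    nb <- length(tpl$beads)
    bead_xyz <- matrix(NA_real_, nb, 3)
    for (b in seq_len(nb)) {
      grp <- tpl$atom_groups[[b]]
      idx <- match(grp, res$name)
      if (anyNA(idx)) {
        abort(paste0("residue ", res$residue[1], " (", rn, "): bead ",
                     tpl$beads[b], " is missing atom(s) ",
                     paste(grp[is.na(idx)], collapse = ", ")),
              class = "cgm_mapping_error")
      }
      m <- res$mass[idx]
      bead_xyz[b, ] <- colSums(xyz[idx, , drop = FALSE] * m) / sum(m)
    }
    rows[[length(rows) + 1L]] <- tibble(
      bead = tpl$beads, molecule = res$residue[1], template = tpl$name,
      x = bead_xyz[, 1], y = bead_xyz[, 2], z = bead_xyz[, 3]
    )
  }
  cg_configuration(dplyr::bind_rows(rows), frame$box, templates)
}

#' Map an all-atom trajectory frame-by-frame
#'
#' @param frames List of [atom_frame()] objects with consistent topology.
#' @param templates,resname_map As in [map_structure()].
#' @param times_ns,temperature Passed to [cg_trajectory()].
#' @return A `cg_trajectory` with the same frame count.
#' @export
map_trajectory <- function(frames, templates, resname_map = NULL,
                           times_ns = NULL, temperature = NA_real_) {
  n_at <- vapply(frames, function(f) nrow(f$atoms), 1L)
  if (length(unique(n_at)) != 1) {
    abort("inconsistent atom count across frames", class = "cgm_format_error")
  }
  cfgs <- lapply(frames, map_structure, templates = templates,
                 resname_map = resname_map)
  cg_trajectory(cfgs, times_ns = times_ns, temperature = temperature,
                metadata = list(source = "map_trajectory"))
}

#' Pair water molecules into 2:1 W beads
#'
#' Greedy closest-pair matching under the minimum-image convention: all
#' candidate pairs are sorted by distance and accepted in order while both
#' members are unused. Each W bead sits at the centroid of its pair. An odd
#' molecule count leaves one molecule unpaired, with a warning.
#'
#' @param water_xyz Matrix/data frame of water molecule centroids (n x 3).
#' @param box Length-3 box vector.
#' @return List with `beads` (tibble `x`, `y`, `z`), `pairs` (index matrix)
#'   and `unpaired` (index vector, length 0 or 1).
#' @export
pair_waters <- function(water_xyz, box) {
  water_xyz <- as.matrix(water_xyz)
  n <- nrow(water_xyz)
  if (n == 0) {
    return(list(beads = tibble(x = numeric(), y = numeric(), z = numeric()),
                pairs = matrix(integer(), 0, 2), unpaired = integer()))
  }
  if (n == 1) {
    warn("odd water count: one molecule left unpaired")
    return(list(beads = tibble(x = numeric(), y = numeric(), z = numeric()),
                pairs = matrix(integer(), 0, 2), unpaired = 1L))
  }
  cmb <- utils::combn(n, 2)
  d <- water_xyz[cmb[1, ], , drop = FALSE] - water_xyz[cmb[2, ], , drop = FALSE]
  for (a in 1:3) if (box[a] > 0) d[, a] <- d[, a] - box[a] * round(d[, a] / box[a])
  dist2 <- rowSums(d^2)
  ord <- order(dist2)
  used <- logical(n)
  pairs <- matrix(integer(), 0, 2)
  for (k in ord) {
    i <- cmb[1, k]; j <- cmb[2, k]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
      if (sum(!used) < 2) break
    }
  }
  if (any(!used)) warn("odd water count: one molecule left unpaired")
  # centroid of each pair with the partner shifted to the nearest image
  bead <- matrix(NA_real_, nrow(pairs), 3)
  for (r in seq_len(nrow(pairs))) {
    p1 <- water_xyz[pairs[r, 1], ]
    p2 <- water_xyz[pairs[r, 2], ]
    for (a in 1:3) if (box[a] > 0) p2[a] <- p2[a] - box[a] * round((p2[a] - p1[a]) / box[a])
    bead[r, ] <- (p1 + p2) / 2
  }
  list(beads = tibble(x = bead[, 1], y = bead[, 2], z = bead[, 3]),
       pairs = pairs, unpaired = which(!used))
}
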