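# Bilayer structural observables: leaflet assignment, area per lipid,
# phosphate-to-phosphate and hydrophobic thickness, block aggregation with
# target-error accounting, and vesicle radial profiles.

#' Property estimate container
#'
#' @param value Aggregated value.
#' @param std Spread (sd across blocks or frames).
#' @param blocks Tibble of per-block values (may be per-frame).
#' @param property Property name.
#' @param units Unit label.
#' @return A `prop_estimate`.
#' @export
prop_estimate <- function(value, std, blocks, property, units) {
  structure(list(value = value, std = std, blocks = blocks,
                 property = property, units = units),
            class = "prop_estimate")
}

#' @export
print.prop_estimate <- function(x, ...) {
  cat("<prop_estimate> ", x$property, " = ", signif(x$value, 6), " +/- ",
      signif(x$std, 3), " ", x$units, " (", nrow(x$blocks), " blocks)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.prop_estimate <- function(x, ...) {
  tibble(property = x$property, estimate = x$value, std = x$std,
         units = x$units, n_blocks = nrow(x$blocks))
}

#' Assign lipids to bilayer leaflets
#'
#' A lipid belongs to the upper leaflet when its PO2 bead lies above the
#' instantaneous midplane (the mean PO2 z); labels are therefore invariant
#' to global translation. Assumes a planar bilayer roughly normal to z.
#'
#' @param config A `cg_config` containing lipid molecules with PO2 beads.
#' @return Tibble with `molecule`, `leaflet` (`"upper"`/`"lower"`), `z_po2`.
#' @export
assign_leaflets <- function(config) {
  po2 <- dplyr::filter(config$beads, .data$bead == "PO2")
  if (!nrow(po2)) abort("no PO2 beads present", class = "cgm_missing_bead")
  mid <- mean(po2$z)
  out <- dplyr::transmute(po2, molecule = .data$molecule, z_po2 = .data$z,
                          leaflet = ifelse(.data$z >= mid, "upper", "lower"))
  if (length(unique(out$leaflet)) < 2) {
    warn("degenerate bilayer: all lipids fall in one leaflet")
  }
  out
}

per_frame_apply <- function(traj, fun) {
  purrr::map_dfr(traj$frames$frame, function(fi) {
    tibble(frame = fi, time_ns = traj$frames$time_ns[fi],
           value = fun(get_frame(traj, fi)))
  })
}

aggregate_frames <- function(pf, property, units) {
  prop_estimate(mean(pf$value), if (nrow(pf) > 1) sd(pf$value) else 0,
                dplyr::rename(pf, block = "frame"), property, units)
}

#' Area per lipid
#'
#' Per frame, the lateral box cross-section divided by the number of lipids
#' per leaflet (mean of the two leaflets when unequal), averaged over frames.
#'
#' @param traj A `cg_trajectory` of a planar bilayer.
#' @return A `prop_estimate` in Angstrom^2.
#' @export
area_per_lipid <- function(traj) {
  pf <- per_frame_apply(traj, function(cfg) {
    lf <- assign_leaflets(cfg)
    n_up <- sum(lf$leaflet == "upper"); n_lo <- sum(lf$leaflet == "lower")
    if (n_up + n_lo == 0) abort("no lipids", class = "cgm_empty_system")
    area <- cfg$box[1] * cfg$box[2]
    mean(area / c(max(n_up, 1), max(n_lo, 1)))
  })
  aggregate_frames(pf, "A_L", "A^2")
}

#' Phosphate-to-phosphate thickness
#'
#' Per frame, the separation along z between the mean PO2 position of the
#' upper and lower leaflets.
#'
#' @param traj A `cg_trajectory` of a planar bilayer.
#' @return A `prop_estimate` in Angstrom.
#' @export
d_pp <- function(traj) {
  pf <- per_frame_apply(traj, function(cfg) {
    lf <- assign_leaflets(cfg)
    if (length(unique(lf$leaflet)) < 2) {
      abort("both leaflets must contain PO2 beads", class = "cgm_missing_bead")
    }
    abs(mean(lf$z_po2[lf$leaflet == "upper"]) -
          mean(lf$z_po2[lf$leaflet == "lower"]))
  })
  aggregate_frames(pf, "D_PP", "A")
}

#' Hydrophobic thickness (2 D_C)
#'
#' Separation between the mean z of the first chain beads (the beads bonded
#' to the ester region) of the two leaflets — the boundary of the
#' hydrocarbon core. On any bilayer built with headgroups outside the
#' chains, `2 D_C < D_PP`.
#'
#' @param traj A `cg_trajectory`; leaflets follow the PO2 assignment.
#' @param chain_bead_names Bead types defining the hydrocarbon boundary;
#'   default uses each template's first tail bead.
#' @return A `prop_estimate` in Angstrom.
#' @export
hydrophobic_thickness <- function(traj, chain_bead_names = NULL) {
  pf <- per_frame_apply(traj, function(cfg) {
    lf <- assign_leaflets(cfg)
    up <- lf$molecule[lf$leaflet == "upper"]
    z <- c(upper = numeric(0), lower = numeric(0))
    zs <- list(upper = numeric(0), lower = numeric(0))
    for (mol in split(seq_len(nrow(cfg$beads)), cfg$beads$molecule)) {
      tpl <- cfg$templates[[cfg$beads$template[mol[1]]]]
      if (is.null(tpl)) next
      idx <- if (is.null(chain_bead_names)) {
        vapply(tpl$tails, function(t) t[["first"]], 1L)
      } else {
        which(tpl$beads %in% chain_bead_names)
      }
      if (!length(idx)) abort("chain beads absent", class = "cgm_missing_bead")
      side <- if (cfg$beads$molecule[mol[1]] %in% up) "upper" else "lower"
      zs[[side]] <- c(zs[[side]], cfg$beads$z[mol[idx]])
    }
    if (!length(zs$upper) || !length(zs$lower)) {
      abort("chain beads missing from a leaflet", class = "cgm_missing_bead")
    }
    abs(mean(zs$upper) - mean(zs$lower))
  })
  aggregate_frames(pf, "2D_C", "A")
}

#' Block-average a property series
#'
#' Averages the series inside each requested time window to form block
#' values; the reported value is the unweighted mean of the block values and
#' the spread is their standard deviation. Invariant to window ordering.
#'
#' @param series Tibble with `time_ns` and `value` (e.g. per-frame values
#'   from an estimator's `blocks` field).
#' @param windows List of `c(start, end)` time windows in ns (inclusive).
#' @return A `prop_estimate` whose `blocks` are the window means.
#' @export
block_aggregate <- function(series, windows, property = "property", units = "") {
  blocks <- purrr::map_dfr(seq_along(windows), function(w) {
    win <- windows[[w]]
    inw <- series$time_ns >= win[1] & series$time_ns <= win[2]
    if (!any(inw)) {
      abort(paste0("window [", win[1], ", ", win[2], "] ns contains no samples"),
            class = "cgm_window_error")
    }
    tibble(block = w, start_ns = win[1], end_ns = win[2],
           value = mean(series$value[inw]))
  })
  prop_estimate(mean(blocks$value),
                if (nrow(blocks) > 1) sd(blocks$value) else 0,
                blocks, property, units)
}

#' Relative error against a target
#'
#' `100 |sim - target| / target`, the error accounting used when comparing
#' simulated membrane properties with experimental targets.
#'
#' @param sim Simulated value(s).
#' @param target Nonzero target value(s).
#' @param digits Optional rounding for display (`NULL` keeps full
#'   precision).
#' @return Percent error, vectorized.
#' @export
relative_error <- function(sim, target, digits = NULL) {
  if (any(target == 0)) abort("target must be nonzero", class = "cgm_division_error")
  err <- 100 * abs(sim - target) / abs(target)
  if (!is.null(digits)) err <- round(err, digits)
  err
}

#' Radial bead profiles of a vesicle
#'
#' Normalized distributions of bead radial distance from the vesicle center
#' (the centroid of all lipid beads), one density per requested bead type.
#'
#' @param traj A `cg_trajectory` of a single vesicular aggregate.
#' @param bead_names Bead types to profile; `"W"` includes water.
#' @param bin_width Radial bin width, Angstrom.
#' @return Tibble with `bead`, `r`, `density`; each bead's density
#'   integrates to 1.
#' @export
radial_profiles <- function(traj, bead_names, bin_width = 1) {
  res <- list()
  rmax <- 0
  samples <- list()
  for (fi in traj$frames$frame) {
    cfg <- get_frame(traj, fi)
    lip <- dplyr::filter(cfg$beads, .data$template != "W")
    if (!nrow(lip)) abort("no lipid beads", class = "cgm_empty_selection")
    ctr <- colMeans(as.matrix(lip[, c("x", "y", "z")]))
    for (bn in bead_names) {
      sel <- dplyr::filter(cfg$beads, .data$bead == bn)
      if (!nrow(sel)) next
      r <- sqrt((sel$x - ctr[1])^2 + (sel$y - ctr[2])^2 + (sel$z - ctr[3])^2)
      samples[[bn]] <- c(samples[[bn]], r)
      rmax <- max(rmax, r)
    }
  }
  if (!length(samples)) abort("selected beads match nothing", class = "cgm_empty_selection")
  purrr::map_dfr(names(samples), function(bn) {
    h <- histogram_pdf(samples[[bn]], bin_width, range = c(0, rmax + bin_width),
                       units = "angstrom")
    tibble(bead = bn, r = h$mid, density = h$density)
  })
}
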