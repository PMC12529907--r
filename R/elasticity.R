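# Bending modulus via the real-space fluctuation (RSF) splay method and
# area-compressibility estimators.
#
# Splay Boltzmann density (shared by the synthetic sampler and the fitter so
# that the round-trip exercises the fit, not a unit convention):
#
#   P(S) = C * exp(-kappa * S^2 * a_L / (2 kB T)),  S in [0, pi/2]
#
# with kappa expressed in kB T and the area per lipid entering in nm^2
# (Angstrom^2 inputs are converted internally). In these reduced units the
# exponent is -kappa * S^2 * a_L / 2 with a_L = A_L / 100. Under this
# convention a fluid bilayer with kappa ~ 20 kB T shows splay fluctuations
# of sd ~ 15 degrees, which is what 2-degree histogram bins and fit windows
# of +/- 1..2 sigma about the mean presuppose.

AA_PER_NM2 <- 100

splay_exponent_coef <- function(kappa, area_A2) kappa * (area_A2 / AA_PER_NM2) / 2

#' Splay Boltzmann density
#'
#' The normalized probability density of splay angles implied by a quadratic
#' splay free energy, truncated to `[0, pi/2]`.
#'
#' @param s Splay angles, radians.
#' @param kappa Bending modulus, kB T units (> 0).
#' @param area_A2 Area per lipid, Angstrom^2.
#' @return Density values at `s`.
#' @export
splay_density <- function(s, kappa, area_A2) {
  if (kappa <= 0) abort("kappa must be positive", class = "cgm_invalid_parameter")
  a <- splay_exponent_coef(kappa, area_A2)
  # normalization over [0, pi/2]: erf-based closed form
  zmax <- pi / 2 * sqrt(a)
  norm <- sqrt(pi / a) / 2 * (2 * stats::pnorm(zmax * sqrt(2)) - 1)
  ifelse(s < 0 | s > pi / 2, 0, exp(-a * s^2) / norm)
}

#' Splay sample container
#'
#' @param samples Splay angles, radians.
#' @param area_A2 Area per lipid used by the Boltzmann transform, Angstrom^2.
#' @param temperature Temperature, K.
#' @param per_frame Optional tibble of per-frame sample counts.
#' @return A `splay_samples` object.
#' @export
splay_sample_set <- function(samples, area_A2, temperature, per_frame = NULL) {
  if (!all(is.finite(samples))) abort("samples must be finite",
                                      class = "cgm_invalid_parameter")
  if (area_A2 <= 0) abort("area per lipid must be positive",
                          class = "cgm_invalid_parameter")
  structure(list(samples = as.numeric(samples), area_A2 = area_A2,
                 temperature = temperature, per_frame = per_frame),
            class = "splay_samples")
}

#' @export
print.splay_samples <- function(x, ...) {
  cat("<splay_samples> ", length(x$samples), " angles, A_L = ", x$area_A2,
      " A^2, T = ", x$temperature, " K\n", sep = "")
  invisible(x)
}

#' Lipid tail vectors
#'
#' Unit vectors from each tail's first chain bead to its terminal bead,
#' oriented so that a tail pointing toward the bilayer midplane has positive
#' projection on the leaflet's inward normal (upper-leaflet tails point
#' toward -z).
#'
#' @param config A `cg_config` with lipid templates defining `tails`.
#' @return Tibble with `molecule`, `tail`, `leaflet`, `ux`, `uy`, `uz`.
#' @export
tail_vectors <- function(config) {
  lf <- assign_leaflets(config)
  out <- list()
  for (mol in split(seq_len(nrow(config$beads)), config$beads$molecule)) {
    tpl <- config$templates[[config$beads$template[mol[1]]]]
    if (is.null(tpl) || is.null(tpl$tails)) next
    mid <- config$beads$molecule[mol[1]]
    side <- lf$leaflet[match(mid, lf$molecule)]
    for (t in seq_along(tpl$tails)) {
      a <- mol[tpl$tails[[t]][["first"]]]
      b <- mol[tpl$tails[[t]][["last"]]]
      v <- c(config$beads$x[b] - config$beads$x[a],
             config$beads$y[b] - config$beads$y[a],
             config$beads$z[b] - config$beads$z[a])
      nv <- sqrt(sum(v^2))
      if (nv == 0) abort("degenerate zero-length tail vector",
                         class = "cgm_geometry_error")
      v <- v / nv
      out[[length(out) + 1L]] <- tibble(molecule = mid, tail = t,
                                        leaflet = side,
                                        ux = v[1], uy = v[2], uz = v[3])
    }
  }
  dplyr::bind_rows(out)
}

#' Local bilayer normal at a lipid
#'
#' Least-squares plane fit through the PO2 positions of same-leaflet
#' neighbors within a cutoff (minimum-image in xy), oriented along +z for
#' the upper leaflet and -z for the lower. Falls back to the global z axis
#' when fewer than 3 neighbors are available.
#'
#' @param config A `cg_config`.
#' @param molecule Lipid molecule id.
#' @param neighbor_cutoff Lateral neighbor cutoff, Angstrom.
#' @return List with `normal` (unit length-3) and `fallback` flag.
#' @export
local_normal <- function(config, molecule, neighbor_cutoff = 15) {
  lf <- assign_leaflets(config)
  side <- lf$leaflet[match(molecule, lf$molecule)]
  po2 <- dplyr::filter(config$beads, .data$bead == "PO2")
  po2$leaflet <- lf$leaflet[match(po2$molecule, lf$molecule)]
  me <- dplyr::filter(po2, .data$molecule == !!molecule)
  nb <- dplyr::filter(po2, .data$leaflet == side)
  dx <- nb$x - me$x; dy <- nb$y - me$y
  dx <- dx - config$box[1] * round(dx / config$box[1])
  dy <- dy - config$box[2] * round(dy / config$box[2])
  keep <- sqrt(dx^2 + dy^2) <= neighbor_cutoff
  sgn <- if (side == "upper") 1 else -1
  if (sum(keep) < 3) {
    return(list(normal = c(0, 0, sgn), fallback = TRUE))
  }
  # plane z = a x + b y + c fitted to neighbor PO2 positions
  X <- cbind(dx[keep], dy[keep], 1)
  zz <- nb$z[keep]
  ab <- tryCatch(qr.solve(crossprod(X), crossprod(X, zz)),
                 error = function(e) NULL)
  if (is.null(ab)) return(list(normal = c(0, 0, sgn), fallback = TRUE))
  nvec <- c(-ab[1], -ab[2], 1)
  nvec <- nvec / sqrt(sum(nvec^2)) * sgn
  list(normal = nvec, fallback = FALSE)
}

#' Pool splay angles from bilayer frames
#'
#' The splay angle of each tail is the angle between the tail vector and
#' the local bilayer normal of its lipid (normal flipped to the leaflet's
#' inward direction so an untilted tail has S = 0). Samples are pooled from
#' all lipids and tails across all frames.
#'
#' @param traj A `cg_trajectory` of a planar bilayer.
#' @param neighbor_cutoff Passed to [local_normal()].
#' @return A `splay_samples`; its `area_A2` is taken from
#'   [area_per_lipid()] on the same trajectory.
#' @export
splay_samples <- function(traj, neighbor_cutoff = 15) {
  if (!n_frames(traj)) abort("no frames", class = "cgm_empty_input")
  al <- area_per_lipid(traj)$value
  angs <- list()
  counts <- list()
  for (fi in traj$frames$frame) {
    cfg <- get_frame(traj, fi)
    tv <- tail_vectors(cfg)
    s <- vapply(seq_len(nrow(tv)), function(r) {
      ln <- local_normal(cfg, tv$molecule[r], neighbor_cutoff)
      inward <- -ln$normal   # points from headgroup plane toward midplane
      cth <- sum(c(tv$ux[r], tv$uy[r], tv$uz[r]) * inward)
      acos(max(-1, min(1, cth)))
    }, 1.0)
    angs[[fi]] <- s
    counts[[fi]] <- tibble(frame = fi, n = length(s))
  }
  splay_sample_set(unlist(angs), al, traj$temperature %||% NA_real_,
                   per_frame = dplyr::bind_rows(counts))
}

#' Fit the bending modulus from splay statistics
#'
#' Transforms the splay histogram through the potential of mean force,
#' `y = -(2 kB T / A_L) ln P(S)`, and fits `y = kappa S^2 + C'` by weighted
#' least squares (weights = bin counts) over five windows centered on the
#' distribution mean with half-widths 1.0, 1.25, 1.5, 1.75 and 2 sigma.
#' kappa is reported from the +/- 1 sigma window; its uncertainty is the
#' standard deviation of the five window fits. Empty bins are dropped (no
#' pseudo-counts); a window retaining fewer than 3 populated bins is a fit
#' error. With kappa in kB T and `A_L` in nm^2 the transform reduces to
#' `y = -(2 / a_L) ln P(S)`.
#'
#' @param x A `splay_samples`, or a `histogram_pdf` of splay angles in
#'   radians (noise-free densities fit exactly).
#' @param bin_width Histogram bin width, radians (default 2 degrees).
#' @param area_A2 Area per lipid; required when `x` is a histogram.
#' @param windows_sigma Window half-widths in units of sigma.
#' @return A `kappa_fit` with `kappa` (kB T), `kappa_std`, per-window tibble
#'   `windows`, and the histogram used.
#' @export
fit_kappa <- function(x, bin_width = 2 * pi / 180, area_A2 = NULL,
                      windows_sigma = c(1, 1.25, 1.5, 1.75, 2)) {
  if (inherits(x, "splay_samples")) {
    area_A2 <- x$area_A2
    h <- histogram_pdf(x$samples, bin_width, range = c(0, pi / 2),
                       units = "radian")
    mu <- mean(x$samples); sg <- sd(x$samples)
  } else if (inherits(x, "histogram_pdf")) {
    if (is.null(area_A2)) abort("area_A2 required with histogram input",
                                class = "cgm_invalid_parameter")
    h <- x
    bw <- diff(attr(h, "edges")[1:2])
    mu <- sum(h$mid * h$density) * bw
    sg <- sqrt(sum((h$mid - mu)^2 * h$density) * bw)
  } else {
    abort("x must be splay_samples or histogram_pdf", class = "cgm_invalid_parameter")
  }
  a_nm <- area_A2 / AA_PER_NM2
  keep <- h$density > 0
  y_all <- -(2 / a_nm) * log(h$density)
  fits <- purrr::map_dfr(windows_sigma, function(hw) {
    inw <- keep & h$mid >= mu - hw * sg & h$mid <= mu + hw * sg
    if (sum(inw) < 3) {
      abort(sprintf("fewer than 3 populated bins in the +/-%.2f sigma window", hw),
            class = "cgm_fit_error")
    }
    fit <- lm(y ~ s2, data = tibble(y = y_all[inw], s2 = h$mid[inw]^2),
              weights = h$count[inw])
    tibble(half_width_sigma = hw, kappa = coef(fit)[["s2"]],
           intercept = coef(fit)[["(Intercept)"]], n_bins = sum(inw))
  })
  structure(list(kappa = fits$kappa[fits$half_width_sigma == windows_sigma[1]],
                 kappa_std = sd(fits$kappa), windows = fits, histogram = h,
                 area_A2 = area_A2, mu = mu, sigma = sg),
            class = "kappa_fit")
}

#' @export
print.kappa_fit <- function(x, ...) {
  cat("<kappa_fit> kappa = ", signif(x$kappa, 4), " +/- ",
      signif(x$kappa_std, 3), " kBT (", nrow(x$windows),
      " fit windows, +/-1 sigma reported)\n", sep = "")
  invisible(x)
}

#' @export
tidy.kappa_fit <- function(x, ...) {
  dplyr::mutate(x$windows, reported = .data$half_width_sigma ==
                  min(.data$half_width_sigma))
}

#' @export
glance.kappa_fit <- function(x, ...) {
  tibble(kappa = x$kappa, kappa_std = x$kappa_std, area_A2 = x$area_A2,
         mu = x$mu, sigma = x$sigma, n_samples = attr(x$histogram, "n_samples"))
}

#' Area compressibility from projected-area fluctuations
#'
#' `K_A = kB T <A> / var(A)` with `A` the total projected box area, the
#' standard fluctuation formula. With A in Angstrom^2 the result in mN/m is
#' `1.380649 * T * <A> / var(A)`.
#'
#' @param area_series Projected box areas per frame, Angstrom^2 (>= 100
#'   frames advised).
#' @param temperature Temperature, K.
#' @return K_A in mN/m.
#' @export
area_compressibility <- function(area_series, temperature) {
  if (length(area_series) < 2 || var(area_series) == 0) {
    abort("area series has no fluctuations", class = "cgm_degenerate_series")
  }
  # kB[J/K] * T * <A>[A^2 -> m^2] / var[A^4 -> m^4] * 1e3 (N/m -> mN/m)
  kB_J * temperature * mean(area_series) / var(area_series) * 1e23
}

#' Area compressibility from local thickness fluctuations
#'
#' Maps each frame's PO2 leaflet surfaces onto an `nx x ny` lateral grid,
#' measures the local phosphate-to-phosphate thickness per cell, and
#' converts thickness fluctuations to K_A through the constant-volume
#' relation `dA/A = -dt/t`, giving per-cell
#' `K_A = kB T <t>^2 / (a_cell var(t))` with `a_cell` the cell area;
#' the reported value averages over cells. Empty cells are dropped with a
#' warning; a fluctuation-free input is a degenerate-series error.
#'
#' @param traj A `cg_trajectory` of a planar bilayer.
#' @param grid `c(nx, ny)` lateral grid resolution (each >= 2).
#' @param temperature Temperature, K (defaults to the trajectory's).
#' @return K_A in mN/m.
#' @export
thickness_compressibility <- function(traj, grid = c(4, 4), temperature = NULL) {
  stopifnot(all(grid >= 2))
  temperature <- temperature %||% traj$temperature
  tmap <- list()
  for (fi in traj$frames$frame) {
    cfg <- get_frame(traj, fi)
    lf <- assign_leaflets(cfg)
    po2 <- dplyr::filter(cfg$beads, .data$bead == "PO2")
    po2$leaflet <- lf$leaflet[match(po2$molecule, lf$molecule)]
    ix <- pmin(grid[1], 1 + floor((po2$x %% cfg$box[1]) / cfg$box[1] * grid[1]))
    iy <- pmin(grid[2], 1 + floor((po2$y %% cfg$box[2]) / cfg$box[2] * grid[2]))
    cell <- paste(ix, iy)
    for (cl in unique(cell)) {
      zu <- po2$z[cell == cl & po2$leaflet == "upper"]
      zl <- po2$z[cell == cl & po2$leaflet == "lower"]
      if (!length(zu) || !length(zl)) next
      tmap[[length(tmap) + 1L]] <- tibble(frame = fi, cell = cl,
                                          thickness = mean(zu) - mean(zl),
                                          a_cell = prod(cfg$box[1:2]) / prod(grid))
    }
  }
  tmap <- dplyr::bind_rows(tmap)
  if (!nrow(tmap)) abort("no populated grid cells", class = "cgm_empty_selection")
  dropped <- prod(grid) * n_frames(traj) - nrow(tmap)
  if (dropped > 0) warn(paste0(dropped, " empty grid cells dropped"))
  stats_cell <- dplyr::summarise(
    dplyr::group_by(tmap, .data$cell),
    tbar = mean(.data$thickness), v = var(.data$thickness),
    a_cell = .data$a_cell[1], n = dplyr::n(), .groups = "drop"
  )
  stats_cell <- dplyr::filter(stats_cell, .data$n >= 2, .data$v > 0)
  if (!nrow(stats_cell)) {
    abort("thickness field has no fluctuations", class = "cgm_degenerate_series")
  }
  ka_cell <- kB_J * temperature * stats_cell$tbar^2 /
    (stats_cell$a_cell * stats_cell$v) * 1e23
  mean(ka_cell)
}
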