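#' Histogram probability density
#'
#' A normalized histogram with explicit bin edges; the common currency of
#' bond/angle distributions, splay histograms and overlap coefficients.
#'
#' @param samples Numeric sample vector.
#' @param bin_width Bin width in the sample's units.
#' @param range Optional c(lo, hi); defaults to the sample range padded by
#'   one bin.
#' @param units Unit label (`"angstrom"`, `"degree"`, `"radian"`, ...), used
#'   to refuse meaningless overlap comparisons.
#' @return A `histogram_pdf`: tibble of `mid`, `density`, `count` plus
#'   attributes `edges`, `n_samples`, `units`.
#' @export
histogram_pdf <- function(samples, bin_width, range = NULL, units = "angstrom") {
  stopifnot(bin_width > 0, length(samples) >= 1)
  if (is.null(range)) {
    range <- c(min(samples) - bin_width, max(samples) + bin_width)
  }
  edges <- seq(floor(range[1] / bin_width) * bin_width,
               ceiling(range[2] / bin_width) * bin_width, by = bin_width)
  cnt <- graphics::hist(samples, breaks = edges, plot = FALSE)$counts
  dens <- cnt / (sum(cnt) * bin_width)
  out <- tibble(mid = (edges[-1] + edges[-length(edges)]) / 2,
                density = dens, count = cnt)
  structure(out, edges = edges, n_samples = length(samples), units = units,
            class = c("histogram_pdf", class(out)))
}

# Wrap a precomputed density curve (already normalized) as a histogram_pdf.
density_as_pdf <- function(mid, density, units = "radian", counts = NULL) {
  bw <- diff(mid[1:2])
  out <- tibble(mid = mid, density = density,
                count = counts %||% rep(1, length(mid)))
  structure(out, edges = c(mid - bw / 2, mid[length(mid)] + bw / 2),
            n_samples = sum(out$count), units = units,
            class = c("histogram_pdf", class(out)))
}

#' Bond or angle probability density from a trajectory
#'
#' Pools every instance of the selected bond pair (or angle triple) across
#' all molecules and frames and returns the normalized density. Angles are
#' reported in degrees, bonds in Angstrom.
#'
#' @param traj A `cg_trajectory` whose templates define the topology.
#' @param selector Character vector of 2 bead type names (bond) or 3 (angle).
#' @param bin_width Bin width; defaults to 0.02 A for bonds, 1 degree for
#'   angles.
#' @return A `histogram_pdf`.
#' @export
bonded_pdf <- function(traj, selector, bin_width = NULL) {
  stopifnot(length(selector) %in% 2:3)
  is_bond <- length(selector) == 2
  if (is.null(bin_width)) bin_width <- if (is_bond) 0.02 else 1
  vals <- numeric(0)
  for (fi in traj$frames$frame) {
    cfg <- get_frame(traj, fi)
    xyz <- as.matrix(cfg$beads[, c("x", "y", "z")])
    for (mol in split(seq_len(nrow(cfg$beads)), cfg$beads$molecule)) {
      tpl <- cfg$templates[[cfg$beads$template[mol[1]]]]
      if (is.null(tpl)) next
      nm <- tpl$beads
      if (is_bond) {
        hit <- which(pair_key(nm[tpl$bonds[, 1]], nm[tpl$bonds[, 2]]) ==
                       pair_key(selector[1], selector[2]))
        for (r in hit) {
          d <- xyz[mol[tpl$bonds[r, 1]], ] - xyz[mol[tpl$bonds[r, 2]], ]
          d <- d - cfg$box * round(d / cfg$box)
          vals <- c(vals, sqrt(sum(d^2)))
        }
      } else {
        a <- tpl$angles
        if (is.null(a) || !nrow(a)) next
        key  <- paste(pmin(nm[a[, 1]], nm[a[, 3]]), nm[a[, 2]],
                      pmax(nm[a[, 1]], nm[a[, 3]]), sep = "|")
        want <- paste(pmin(selector[1], selector[3]), selector[2],
                      pmax(selector[1], selector[3]), sep = "|")
        for (r in which(key == want)) {
          v1 <- xyz[mol[a[r, 1]], ] - xyz[mol[a[r, 2]], ]
          v2 <- xyz[mol[a[r, 3]], ] - xyz[mol[a[r, 2]], ]
          v1 <- v1 - cfg$box * round(v1 / cfg$box)
          v2 <- v2 - cfg$box * round(v2 / cfg$box)
          cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          vals <- c(vals, acos(max(-1, min(1, cth))) * 180 / pi)
        }
      }
    }
  }
  if (!length(vals)) {
    abort(paste0("selector ", paste(selector, collapse = "-"),
                 " matches nothing in the trajectory templates"),
          class = "cgm_empty_selection")
  }
  histogram_pdf(vals, bin_width, units = if (is_bond) "angstrom" else "degree")
}

#' Harmonic parameters from a bonded distribution
#'
#' Boltzmann inversion of the `K (x - x0)^2` form: for a harmonic degree of
#' freedom in thermal equilibrium the distribution is Gaussian with variance
#' `kB T / (2 K)`, so `x0` is the distribution mean and
#' `K = kB T / (2 var)`. Multimodal mapped distributions are summarized by
#' their overall mean and variance (no mixture fitting).
#'
#' @param pdf A `histogram_pdf` (from [bonded_pdf()] or samples).
#' @param temperature Temperature in K.
#' @return One-row tibble with `x0`, `k`, `units`: `k` in kcal/mol/A^2 for
#'   bonds, kcal/mol/rad^2 for angle input in degrees (x0 stays in degrees).
#' @export
init_harmonic <- function(pdf, temperature) {
  stopifnot(inherits(pdf, "histogram_pdf"))
  bw <- diff(attr(pdf, "edges")[1:2])
  m <- sum(pdf$mid * pdf$density) * bw
  v <- sum((pdf$mid - m)^2 * pdf$density) * bw
  if (v <= 0 || sum(pdf$density > 0) < 2) {
    abort("degenerate (zero-variance) distribution",
          class = "cgm_degenerate_distribution")
  }
  units <- attr(pdf, "units")
  v_int <- if (units == "degree") v * (pi / 180)^2 else v  # K in rad^-2
  tibble(x0 = m, k = kB_KCAL * temperature / (2 * v_int), units = units)
}

#' Overlap coefficient of two probability densities
#'
#' Shared area between two normalized densities,
#' `OC = integral of min(p, q)`, from 0 (disjoint) to 1 (identical). The two
#' histograms are re-binned onto a common fine grid by linear interpolation
#' before integration.
#'
#' @param p,q `histogram_pdf` objects in the same units.
#' @param n_grid Number of points of the common integration grid.
#' @return A number in `[0, 1]`.
#' @export
overlap_coefficient <- function(p, q, n_grid = 4001) {
  if (!identical(attr(p, "units"), attr(q, "units"))) {
    abort("cannot overlap densities with different units",
          class = "cgm_unit_error")
  }
  lo <- min(attr(p, "edges")[1], attr(q, "edges")[1])
  hi <- max(max(attr(p, "edges")), max(attr(q, "edges")))
  g <- seq(lo, hi, length.out = n_grid)
  pi_ <- approx(p$mid, p$density, g, yleft = 0, yright = 0, rule = 2)$y
  qi_ <- approx(q$mid, q$density, g, yleft = 0, yright = 0, rule = 2)$y
  pi_[g < attr(p, "edges")[1] | g > max(attr(p, "edges"))] <- 0
  qi_[g < attr(q, "edges")[1] | g > max(attr(q, "edges"))] <- 0
  h <- diff(g[1:2])
  mn <- pmin(pi_, qi_)
  sum((mn[-1] + mn[-n_grid]) / 2) * h
}

#' Radial distribution function
#'
#' Shell-normalized pair correlation `g(r)` between two bead selections
#' under the minimum-image convention, averaged over frames. Pairs within
#' the same molecule are excluded by default, so first peaks reflect packing
#' rather than bonded structure (the convention used when deriving `r_min`
#' ranges for nonbonded optimization).
#'
#' @param traj A `cg_trajectory`.
#' @param sel_a,sel_b Bead type names (may be equal).
#' @param dr Bin width, Angstrom.
#' @param rmax Maximum distance; must not exceed half the smallest box edge.
#' @param exclude_intramolecular Drop same-molecule pairs (default TRUE).
#' @return Tibble with `r`, `g`, plus attribute `first_peak` (position of
#'   the first maximum).
#' @export
rdf <- function(traj, sel_a, sel_b = sel_a, dr = 0.1, rmax = NULL,
                exclude_intramolecular = TRUE) {
  box0 <- unlist(traj$frames[1, c("lx", "ly", "lz")])
  if (is.null(rmax)) rmax <- min(box0) / 2
  if (rmax > min(box0) / 2 + 1e-9) {
    abort("rmax exceeds half the smallest box edge", class = "cgm_geometry_error")
  }
  edges <- seq(0, rmax, by = dr)
  nbin <- length(edges) - 1
  acc <- numeric(nbin)
  norm <- 0
  for (fi in traj$frames$frame) {
    cfg <- get_frame(traj, fi)
    A <- cfg$beads$bead == sel_a
    B <- cfg$beads$bead == sel_b
    if (!any(A) || !any(B)) next
    xyz <- as.matrix(cfg$beads[, c("x", "y", "z")])
    ia <- which(A); ib <- which(B)
    # all A-B pairs (unordered, distinct particles)
    pr <- expand.grid(i = ia, j = ib)
    pr <- pr[pr$i != pr$j, ]
    if (sel_a == sel_b) pr <- pr[pr$i < pr$j, ]
    if (exclude_intramolecular) {
      same <- cfg$beads$molecule[pr$i] == cfg$beads$molecule[pr$j]
      pr <- pr[!same, ]
    }
    if (!nrow(pr)) next
    d <- xyz[pr$i, , drop = FALSE] - xyz[pr$j, , drop = FALSE]
    for (a in 1:3) d[, a] <- d[, a] - cfg$box[a] * round(d[, a] / cfg$box[a])
    r <- sqrt(rowSums(d^2))
    # left-closed binning: a distance exactly on an edge counts upward
    cnt <- tabulate(findInterval(r[r < rmax], edges), nbins = nbin)
    if (sel_a == sel_b) cnt <- 2 * cnt      # count ordered pairs
    V <- prod(cfg$box)
    nA <- length(ia); nB <- length(ib)
    shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbin + 1)]^3)
    ideal <- nA * (if (sel_a == sel_b) nB - 1 else nB) / V * shell
    acc <- acc + cnt / ideal
    norm <- norm + 1
  }
  if (norm == 0) abort("selections match nothing", class = "cgm_empty_selection")
  g <- acc / norm
  mids <- (edges[-1] + edges[-(nbin + 1)]) / 2
  pk <- if (any(g > 0)) {
    n <- length(g)
    loc <- which(g >= c(-Inf, g[-n]) & g > c(g[-1], -Inf) & g >= max(g) * 0.5)
    if (length(loc)) mids[loc[1]] else mids[which.max(g)]
  } else NA_real_
  structure(tibble(r = mids, g = g), first_peak = pk)
}
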