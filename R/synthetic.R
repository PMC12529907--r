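# Synthetic fixture generators. Each generator is deterministic per seed,
# echoes its spec as metadata, and produces data with exactly the
# statistical structure the corresponding estimator assumes — the backbone
# of generator/estimator round-trip testing.

# Idealized straight-lipid geometry of a template: per-bead z offsets below
# the PO2 plane, chains extended toward the midplane.
template_geometry <- function(template, spacing = 2.6) {
  n <- length(template$beads)
  depth <- numeric(n)
  depth[template$head_beads[["CHO"]]] <- -2.5    # choline above the phosphate
  depth[template$head_beads[["PO2"]]] <- 0
  glyc <- 3L
  depth[glyc] <- 2.5
  for (t in template$tails) {
    idx <- (t[["first"]] - 1L):t[["last"]]      # MTF then chain beads
    depth[idx] <- 2.5 + spacing * seq_along(idx)
  }
  depth
}

#' Build a synthetic planar bilayer
#'
#' Lipids on a square lattice with prescribed area per lipid and PO2-plane
#' separation; chains extend inward, optional Gaussian positional jitter,
#' optional water slab. By construction `area_per_lipid()` returns
#' `a_l` exactly and, at zero jitter, `d_pp()` returns `d_pp` exactly.
#'
#' @param n_per_leaflet Lipids per leaflet (a perfect square packs evenly).
#' @param a_l Target area per lipid, Angstrom^2.
#' @param d_pp Target phosphate-plane separation, Angstrom.
#' @param template A `cg_template` (default DOPC).
#' @param jitter_sd Positional jitter sd, Angstrom.
#' @param n_waters Water beads to scatter outside the membrane slab.
#' @param lz Box height; default fits the bilayer plus 30 A of water space.
#' @param seed RNG seed.
#' @return A `cg_config` with metadata attribute `spec`.
#' @export
build_bilayer <- function(n_per_leaflet = 64, a_l = 66.3, d_pp = 34,
                          template = cg_lipid_template("DOPC"),
                          jitter_sd = 0, n_waters = 0, lz = NULL, seed = 1) {
  set.seed(seed)
  L <- sqrt(n_per_leaflet * a_l)
  side <- ceiling(sqrt(n_per_leaflet))
  pitch <- L / side
  lz <- lz %||% (d_pp + 60)
  depth <- template_geometry(template)
  if (max(depth) * 2 >= d_pp + 18) {
    abort("template chains too long for the requested d_pp: beads would interdigitate beyond tolerance",
          class = "cgm_packing_error")
  }
  rows <- list()
  mol <- 0L
  for (leaf in c(1, -1)) {
    placed <- 0L
    for (gx in seq_len(side)) {
      for (gy in seq_len(side)) {
        if (placed >= n_per_leaflet) break
        placed <- placed + 1L
        mol <- mol + 1L
        nb <- length(template$beads)
        z0 <- leaf * d_pp / 2
        rows[[mol]] <- tibble(
          bead = template$beads, molecule = mol, template = template$name,
          x = (gx - 0.5) * pitch + rnorm(nb, 0, jitter_sd),
          y = (gy - 0.5) * pitch + rnorm(nb, 0, jitter_sd),
          z = z0 - leaf * depth + rnorm(nb, 0, jitter_sd)
        )
      }
    }
  }
  beads <- dplyr::bind_rows(rows)
  if (n_waters > 0) {
    half_slab <- max(abs(beads$z)) + 2
    zw <- runif(n_waters, half_slab, lz / 2)
    zw <- zw * sample(c(-1, 1), n_waters, replace = TRUE)
    beads <- dplyr::bind_rows(beads, tibble(
      bead = "W", molecule = mol + seq_len(n_waters), template = "W",
      x = runif(n_waters, 0, L), y = runif(n_waters, 0, L), z = zw
    ))
  }
  beads$z <- beads$z + lz / 2   # box origin at 0
  cfg <- cg_configuration(beads, c(L, L, lz),
                          setNames(list(template), template$name))
  attr(cfg, "spec") <- list(n_per_leaflet = n_per_leaflet, a_l = a_l,
                            d_pp = d_pp, jitter_sd = jitter_sd, seed = seed)
  cfg
}

#' Repeat a configuration into a static or jittered trajectory
#'
#' @param build_fun Zero-argument function returning a `cg_config` (called
#'   once per frame; vary its seed inside for independent frames).
#' @param n_frames Number of frames.
#' @param times_ns Frame times.
#' @param temperature Metadata temperature.
#' @return A `cg_trajectory`.
#' @export
synthetic_trajectory <- function(build_fun, n_frames = 10, times_ns = NULL,
                                 temperature = 298) {
  cfgs <- lapply(seq_len(n_frames), function(i) build_fun(i))
  cg_trajectory(cfgs, times_ns = times_ns, temperature = temperature,
                metadata = list(source = "synthetic"))
}

#' Sample splay angles from the Boltzmann density
#'
#' Inverse-CDF sampling of [splay_density()] truncated to `[0, pi/2]`:
#' the generator and [fit_kappa()] share one density definition, so their
#' round-trip exercises the fit itself.
#'
#' @param kappa Generating bending modulus, kB T (> 0).
#' @param area_A2 Area per lipid, Angstrom^2.
#' @param temperature Temperature, K (metadata; the reduced-unit density
#'   does not depend on it).
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return A `splay_samples`.
#' @export
sample_splay <- function(kappa, area_A2, temperature, n, seed = 1) {
  if (kappa <= 0) abort("kappa must be positive", class = "cgm_invalid_parameter")
  set.seed(seed)
  a <- splay_exponent_coef(kappa, area_A2)
  # F(s) = erf(s sqrt(a)) / erf(smax sqrt(a)); invert via the probit
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  erfinv <- function(y) stats::qnorm((y + 1) / 2) / sqrt(2)
  u <- runif(n)
  smax <- pi / 2
  s <- erfinv(u * erf(smax * sqrt(a))) / sqrt(a)
  splay_sample_set(s, area_A2, temperature)
}

#' Gaussian projected-area series with prescribed compressibility
#'
#' Series with mean `a0` and variance `kB T a0 / K_A` (the fluctuation
#' formula inverted), so [area_compressibility()] recovers `k_a` up to
#' sampling error. `K_A -> Inf` gives a constant series.
#'
#' @param k_a Target area compressibility, mN/m.
#' @param a0 Mean projected area, Angstrom^2.
#' @param temperature Temperature, K.
#' @param n_frames Series length.
#' @param seed RNG seed.
#' @return Numeric vector of areas.
#' @export
area_series <- function(k_a, a0, temperature, n_frames, seed = 1) {
  if (k_a <= 0) abort("k_a must be positive", class = "cgm_invalid_parameter")
  set.seed(seed)
  v <- kB_J * temperature * a0 / k_a * 1e23   # A^4 (mN/m and A^2 inputs)
  a0 + rnorm(n_frames, 0, sqrt(v))
}

#' Build a synthetic vesicle
#'
#' Two concentric spherical lipid shells: the inner leaflet's headgroups
#' face the core, the outer leaflet's face the bulk. Bead radial offsets
#' follow the template geometry, so PO2 radial profile peaks sit exactly at
#' the constructed phosphate radii when jitter is zero.
#'
#' @param n_lipids Total lipids (split between leaflets by shell area).
#' @param inner_radius Inner PO2 shell radius, Angstrom.
#' @param thickness Separation between the PO2 shells, Angstrom.
#' @param template A `cg_template`.
#' @param jitter_sd Radial jitter sd.
#' @param box Cubic box edge (default fits the vesicle plus margin).
#' @param seed RNG seed.
#' @return A `cg_config`.
#' @export
build_vesicle <- function(n_lipids = 256, inner_radius = 28, thickness = 36,
                          template = cg_lipid_template("DOPC"),
                          jitter_sd = 0, box = NULL, seed = 1) {
  set.seed(seed)
  r_in <- inner_radius
  r_out <- inner_radius + thickness
  if (r_in <= max(template_geometry(template)) + 2) {
    abort("inner radius too small to pack the template's chains",
          class = "cgm_packing_error")
  }
  n_out <- round(n_lipids * r_out^2 / (r_in^2 + r_out^2))
  n_in <- n_lipids - n_out
  box <- box %||% (2 * r_out + 60)
  depth <- template_geometry(template)
  fib_sphere <- function(n) {
    # Fibonacci lattice: near-uniform points on the unit sphere
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    theta <- pi * (1 + sqrt(5)) * i
    cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  }
  rows <- list(); mol <- 0L
  for (leaf in list(list(n = n_in, r = r_in, dir = -1),
                    list(n = n_out, r = r_out, dir = 1))) {
    dirs <- fib_sphere(leaf$n)
    for (i in seq_len(leaf$n)) {
      mol <- mol + 1L
      u <- dirs[i, ]
      # heads at the PO2 shell, chains toward the interleaflet midplane
      r_bead <- leaf$r - leaf$dir * depth + rnorm(length(depth), 0, jitter_sd)
      rows[[mol]] <- tibble(
        bead = template$beads, molecule = mol, template = template$name,
        x = box / 2 + u[1] * r_bead,
        y = box / 2 + u[2] * r_bead,
        z = box / 2 + u[3] * r_bead
      )
    }
  }
  cfg <- cg_configuration(dplyr::bind_rows(rows), rep(box, 3),
                          setNames(list(template), template$name))
  attr(cfg, "spec") <- list(n_lipids = n_lipids, inner_radius = inner_radius,
                            thickness = thickness, seed = seed)
  cfg
}

#' Random lipid-water mixture
#'
#' Uniformly random placement of whole lipids and water beads respecting a
#' minimum bead separation — the starting point of self-assembly demos.
#'
#' @param n_lipids Number of lipid molecules.
#' @param n_waters Number of W beads.
#' @param box Length-3 box vector, Angstrom.
#' @param template A `cg_template`.
#' @param min_sep Minimum inter-molecular bead separation, Angstrom.
#' @param max_tries Placement attempts per molecule before a packing error.
#' @param seed RNG seed.
#' @return A `cg_config`.
#' @export
random_mixture <- function(n_lipids = 16, n_waters = 200,
                           box = c(40, 40, 40),
                           template = cg_lipid_template("DMPC"),
                           min_sep = 3.5, max_tries = 200, seed = 1) {
  set.seed(seed)
  depth <- template_geometry(template)
  placed <- matrix(numeric(0), 0, 3)
  rows <- list(); mol <- 0L
  rand_rot <- function() {
    # uniform random rotation from a normalized quaternion
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y),
             2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x),
             2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)), 3, 3)
  }
  too_close <- function(xyz) {
    if (!nrow(placed)) return(FALSE)
    for (r in seq_len(nrow(xyz))) {
      d <- sweep(placed, 2, xyz[r, ])
      for (a in 1:3) d[, a] <- d[, a] - box[a] * round(d[, a] / box[a])
      if (min(rowSums(d^2)) < min_sep^2) return(TRUE)
    }
    FALSE
  }
  place <- function(local) {
    for (try in seq_len(max_tries)) {
      ctr <- runif(3) * box
      xyz <- sweep(local %*% t(rand_rot()), 2, ctr, "+")
      if (!too_close(xyz)) return(xyz)
    }
    abort("packing failed: box too dense for min_sep", class = "cgm_packing_error")
  }
  lipid_local <- cbind(0, 0, depth - mean(depth))
  for (i in seq_len(n_lipids)) {
    mol <- mol + 1L
    xyz <- place(lipid_local)
    placed <- rbind(placed, xyz)
    rows[[length(rows) + 1L]] <- tibble(
      bead = template$beads, molecule = mol, template = template$name,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }
  for (i in seq_len(n_waters)) {
    mol <- mol + 1L
    xyz <- place(matrix(0, 1, 3))
    placed <- rbind(placed, xyz)
    rows[[length(rows) + 1L]] <- tibble(
      bead = "W", molecule = mol, template = "W",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }
  cfg <- cg_configuration(dplyr::bind_rows(rows), box,
                          setNames(list(template), template$name))
  attr(cfg, "spec") <- list(n_lipids = n_lipids, n_waters = n_waters,
                            min_sep = min_sep, seed = seed)
  cfg
}

#' Build a synthetic all-atom residue set matching a template
#'
#' Emits an [atom_frame()] whose residues carry exactly the atom names of
#' the template's atom groups, each group clustered around its bead site —
#' the reference input for mapping tests.
#'
#' @param config A `cg_config` produced by a generator (bead positions
#'   become group centroids).
#' @param bead_types Bead table for masses.
#' @param spread Within-group atom scatter, Angstrom.
#' @param seed RNG seed.
#' @return An `atom_frame`.
#' @export
explode_to_atoms <- function(config, bead_types = cg_bead_types(),
                             spread = 0.6, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (mol in split(seq_len(nrow(config$beads)), config$beads$molecule)) {
    tn <- config$beads$template[mol[1]]
    tpl <- config$templates[[tn]]
    if (is.null(tpl)) next
    for (b in seq_along(tpl$beads)) {
      grp <- tpl$atom_groups[[b]]
      na <- length(grp)
      # hydrogens 1.008 amu; heavy atoms share the rest of the bead mass,
      # so per-residue atom masses sum exactly to the template bead masses
      bead_mass <- bead_types$mass[match(tpl$beads[b], bead_types$name)]
      is_h <- grepl("^H", grp)
      m <- rep(1.008, na)
      m[!is_h] <- (bead_mass - sum(is_h) * 1.008) / sum(!is_h)
      delta <- matrix(rnorm(3 * na, 0, spread), na, 3)
      delta <- sweep(delta, 2, colSums(delta * m) / sum(m))  # zero weighted mean
      ctr <- c(config$beads$x[mol[b]], config$beads$y[mol[b]],
               config$beads$z[mol[b]])
      rows[[length(rows) + 1L]] <- tibble(
        name = grp, mass = m, residue = config$beads$molecule[mol[1]],
        resname = tn,
        x = ctr[1] + delta[, 1], y = ctr[2] + delta[, 2], z = ctr[3] + delta[, 3]
      )
    }
  }
  atom_frame(dplyr::bind_rows(rows), config$box)
}
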