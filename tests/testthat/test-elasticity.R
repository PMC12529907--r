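# Real-space fluctuation bending modulus and area compressibility.

test_that("tail vectors are unit length and match the endpoint difference", {
  cfg <- build_bilayer(16, 64, 34, cg_lipid_template("DMPC"), seed = 1)
  tv <- tail_vectors(cfg)
  expect_equal(sqrt(tv$ux^2 + tv$uy^2 + tv$uz^2), rep(1, nrow(tv)))
  # straight builder tails point along -z in the upper leaflet
  up <- tv[tv$leaflet == "upper", ]
  expect_equal(up$uz, rep(-1, nrow(up)))
  # endpoint-difference oracle for one lipid
  tpl <- cg_lipid_template("DMPC")
  mol1 <- cfg$beads[cfg$beads$molecule == 1, ]
  t1 <- tpl$tails[[1]]
  v <- unlist(mol1[t1[["last"]], c("x", "y", "z")] -
                mol1[t1[["first"]], c("x", "y", "z")])
  v <- v / sqrt(sum(v^2))
  got <- unlist(tv[tv$molecule == 1 & tv$tail == 1, c("ux", "uy", "uz")])
  expect_equal(unname(got), unname(v), tolerance = 1e-12)
})

test_that("local normals recover flat and tilted planes, with fallback", {
  cfg <- build_bilayer(25, 64, 34, cg_lipid_template("DMPC"), seed = 2)
  ln <- local_normal(cfg, 1, neighbor_cutoff = 20)
  expect_false(ln$fallback)
  expect_equal(abs(ln$normal[3]), 1, tolerance = 1e-6)
  # tilt the whole upper leaflet plane by alpha around y
  alpha <- 0.15
  b <- cfg$beads
  x0 <- mean(b$x)
  b$z <- b$z + tan(alpha) * (b$x - x0)     # shear: plane normal tilts by alpha
  cfg2 <- cg_configuration(b, cfg$box * c(1, 1, 2), cfg$templates)
  ln2 <- local_normal(cfg2, 13, neighbor_cutoff = 12)
  want <- c(-sin(alpha), 0, cos(alpha))
  expect_equal(abs(sum(ln2$normal * want)), 1, tolerance = 1e-3)
  # a lone lipid falls back to the global axis
  solo <- cfg$beads[cfg$beads$molecule == 1, ]
  cfg3 <- cg_configuration(solo, cfg$box, cfg$templates)
  expect_warning(ln3 <- local_normal(cfg3, 1))
  expect_true(ln3$fallback)
  expect_equal(ln3$normal, c(0, 0, 1))
})

test_that("splay samples count tails x frames and vanish for untilted tails", {
  traj <- synthetic_trajectory(function(i) {
    build_bilayer(16, 64, 34, cg_lipid_template("DMPC"), seed = i)
  }, n_frames = 2)
  ss <- splay_samples(traj)
  expect_length(ss$samples, 2 * 16 * 2 * 2)   # frames x lipids x leaflets x tails
  expect_equal(max(abs(ss$samples)), 0, tolerance = 1e-6)
})

test_that("kappa fit is exact on noise-free Boltzmann input", {
  mid <- seq(0.25, 60, by = 2) * pi / 180
  for (kap in c(15, 25, 35)) {
    dens <- splay_density(mid, kap, 66.3)
    h <- cgmembrane:::density_as_pdf(mid, dens)
    fit <- fit_kappa(h, area_A2 = 66.3)
    expect_equal(fit$kappa, kap, tolerance = 1e-6 * kap)
    expect_lt(fit$kappa_std, 1e-6 * kap)
  }
})

test_that("kappa recovery stays within 5% across the physiological range", {
  errs <- vapply(c(15, 20.4, 25, 28.1, 35), function(kap) {
    ss <- sample_splay(kap, 66.3, 298, 2e5, seed = round(kap * 7))
    abs(fit_kappa(ss)$kappa - kap) / kap
  }, 1.0)
  expect_lt(median(errs), 0.05)
  expect_lt(max(errs), 0.10)
})

test_that("kappa uncertainty shrinks with sample size", {
  sds <- vapply(c(2e3, 2e4, 2e5), function(n) {
    mean(vapply(1:4, function(s) {
      fit_kappa(sample_splay(22, 66.3, 298, n, seed = s))$kappa_std
    }, 1.0))
  }, 1.0)
  expect_true(all(diff(sds) < 0))
})

test_that("doubling the area at fixed kappa regenerates consistently", {
  # kappa is invariant when samples are regenerated at the new area
  f1 <- fit_kappa(sample_splay(24, 60, 298, 2e5, seed = 5))
  f2 <- fit_kappa(sample_splay(24, 120, 298, 2e5, seed = 6))
  expect_equal(f1$kappa, 24, tolerance = 0.05 * 24)
  expect_equal(f2$kappa, 24, tolerance = 0.05 * 24)
  # while the raw PMF slope scale doubles with A_L: the distribution narrows
  expect_gt(sd(sample_splay(24, 60, 298, 1e5, 7)$samples),
            sd(sample_splay(24, 120, 298, 1e5, 7)$samples))
})

test_that("area compressibility round-trips its generator within 10%", {
  a <- area_series(300, 4000, 298, 1e4, seed = 11)
  ka <- area_compressibility(a, 298)
  expect_equal(ka, 300, tolerance = 0.10 * 300)
  # doubling the variance halves K_A
  a2 <- 4000 + (a - 4000) * sqrt(2)
  expect_equal(area_compressibility(a2, 298) / ka, 0.5, tolerance = 0.02)
  expect_error(area_compressibility(rep(4000, 100), 298),
               class = "cgm_degenerate_series")
})

test_that("K_A estimator is unbiased over a seed ensemble", {
  kas <- vapply(1:50, function(s) {
    area_compressibility(area_series(300, 4000, 298, 2000, seed = s), 298)
  }, 1.0)
  se <- sd(kas) / sqrt(50)
  expect_lt(abs(mean(kas) - 300), 2 * se + 0.02 * 300)
})

test_that("thickness-fluctuation K_A matches its closed form and is translation-invariant", {
  # synthetic thickness field: per-cell independent Gaussian thickness
  set.seed(13)
  tpl <- cg_lipid_template("DMPC")
  n <- 64; a_l <- 64
  v_t <- 0.35^2
  mk <- function(i) {
    cfg <- build_bilayer(n, a_l, 34, tpl, seed = 99)
    b <- cfg$beads
    lf <- assign_leaflets(cfg)
    up <- lf$molecule[lf$leaflet == "upper"]
    # one common thickness perturbation per frame cell; with an 8x8 lattice
    # of lipids and a 2x2 grid, each cell holds 16 lipids per leaflet
    gx <- 1 + floor((b$x %% cfg$box[1]) / cfg$box[1] * 2)
    gy <- 1 + floor((b$y %% cfg$box[2]) / cfg$box[2] * 2)
    set.seed(7000 + i)   # the builder reseeds the RNG internally
    dz <- matrix(rnorm(4, 0, sqrt(v_t)), 2, 2)
    sgn <- ifelse(b$molecule %in% up, 0.5, -0.5)
    b$z <- b$z + sgn * dz[cbind(gx, gy)]
    cg_configuration(b, cfg$box, cfg$templates)
  }
  traj <- synthetic_trajectory(mk, n_frames = 120)
  ka <- thickness_compressibility(traj, grid = c(2, 2), temperature = 298)
  a_cell <- n * a_l / 4
  want <- 1.380649e-23 * 298 * 34^2 / (a_cell * v_t) * 1e23
  expect_equal(ka, want, tolerance = 0.35 * want)
  # translation invariance
  shifted <- synthetic_trajectory(function(i) {
    cfg <- get_frame(traj, i)
    b <- cfg$beads; b$z <- b$z + 5
    cg_configuration(b, cfg$box, cfg$templates)
  }, n_frames = 20)
  ka2 <- thickness_compressibility(shifted, grid = c(2, 2), temperature = 298)
  ka2_ref <- thickness_compressibility(
    synthetic_trajectory(function(i) get_frame(traj, i), n_frames = 20),
    grid = c(2, 2), temperature = 298)
  expect_equal(ka2, ka2_ref, tolerance = 1e-9)
  # a jitter-free bilayer has no fluctuations to invert
  flat <- synthetic_trajectory(function(i) {
    build_bilayer(16, 64, 34, tpl, seed = 1)
  }, n_frames = 5)
  expect_error(thickness_compressibility(flat, temperature = 298),
               class = "cgm_degenerate_series")
})
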