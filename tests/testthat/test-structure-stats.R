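# Bonded distributions, Boltzmann-inversion initialization, overlap
# coefficients and radial distribution functions.

rigid_bond_traj <- function(b = 3, n_frames = 2) {
  tpl <- toy_template(2)
  beads <- tibble(bead = c("C3M", "C3M"), molecule = 1L, template = "TOY",
                  x = c(10, 10 + b), y = 10, z = 10)
  cfgs <- replicate(n_frames,
                    cg_configuration(beads, c(40, 40, 40),
                                     list(TOY = tpl)), simplify = FALSE)
  cg_trajectory(cfgs)
}

test_that("bonded PDFs integrate to one and localize rigid geometry", {
  traj <- rigid_bond_traj(3)
  pdf <- bonded_pdf(traj, c("C3M", "C3M"))
  bw <- diff(attr(pdf, "edges")[1:2])
  expect_equal(sum(pdf$density) * bw, 1, tolerance = 1e-9)
  expect_equal(pdf$mid[which.max(pdf$density)], 3, tolerance = bw)
  # collinear triple shows a 180 degree angle
  tpl <- toy_template(3)
  beads <- tibble(bead = rep("C3M", 3), molecule = 1L, template = "TOY",
                  x = c(5, 8, 11), y = 10, z = 10)
  traj3 <- cg_trajectory(list(cg_configuration(beads, c(40, 40, 40),
                                               list(TOY = tpl))))
  apdf <- bonded_pdf(traj3, c("C3M", "C3M", "C3M"))
  expect_equal(apdf$mid[which.max(apdf$density)], 180, tolerance = 1)
  expect_error(bonded_pdf(traj, c("PO2", "W")), class = "cgm_empty_selection")
})

test_that("histogram mean of Gaussian samples is close to the true mean", {
  set.seed(31)
  s <- rnorm(4000, 3, 0.1)
  pdf <- histogram_pdf(s, 0.02)
  bw <- diff(attr(pdf, "edges")[1:2])
  m <- sum(pdf$mid * pdf$density) * bw
  expect_lt(abs(m - 3), 3 * 0.1 / sqrt(4000))
})

test_that("Boltzmann inversion recovers harmonic force constants", {
  set.seed(32)
  s <- rnorm(2e5, 3, 0.1)
  pdf <- histogram_pdf(s, 0.005)
  p <- init_harmonic(pdf, 298)
  expect_equal(p$x0, 3, tolerance = 0.01)
  expect_equal(p$k, kB() * 298 / (2 * 0.01), tolerance = 0.02 * p$k)
  expect_equal(p$k, 29.61, tolerance = 0.6)
  # doubling the variance halves K
  s2 <- rnorm(2e5, 3, 0.1 * sqrt(2))
  p2 <- init_harmonic(histogram_pdf(s2, 0.005), 298)
  expect_equal(p2$k / p$k, 0.5, tolerance = 0.05)
  # zero variance is degenerate
  expect_error(init_harmonic(histogram_pdf(rep(3, 10), 0.02), 298),
               class = "cgm_degenerate_distribution")
})

test_that("harmonic parameters fitted from toy-simulator samples recover Kb", {
  # NVT sampling of a single bond, then inversion at the run temperature
  tpl <- toy_template(2)
  ff <- toy_ff(eps = 0.01, kb = 10, b0 = 3)
  beads <- tibble(bead = c("C3M", "C3M"), molecule = 1L, template = "TOY",
                  x = c(20, 23), y = 20, z = 20)
  cfg <- cg_configuration(beads, c(40, 40, 40), list(TOY = tpl))
  res <- run_cg_md(cfg, ff, sim_spec(timestep_fs = 5, n_steps = 40000,
                                     temperature = 298, friction_ps = 2,
                                     seed = 9, stride = 10))
  pdf <- bonded_pdf(res$trajectory, c("C3M", "C3M"), bin_width = 0.01)
  p <- init_harmonic(pdf, 298)
  expect_equal(p$x0, 3, tolerance = 0.05)
  expect_equal(p$k, 10, tolerance = 1)     # within 10%
})

test_that("overlap coefficient obeys its closed forms and symmetry", {
  set.seed(33)
  p <- histogram_pdf(rnorm(2e5, 0, 1), 0.05, range = c(-6, 6), units = "x")
  expect_equal(overlap_coefficient(p, p), 1, tolerance = 1e-6)
  q_far <- histogram_pdf(rnorm(2e5, 100, 1), 0.05, range = c(94, 106), units = "x")
  expect_equal(overlap_coefficient(p, q_far), 0)
  # two unit-sd Gaussians 2 sd apart: OC = 2*Phi(-1)
  q <- histogram_pdf(rnorm(2e5, 2, 1), 0.05, range = c(-4, 8), units = "x")
  oc <- overlap_coefficient(p, q)
  expect_equal(oc, 2 * pnorm(-1), tolerance = 0.01)
  expect_equal(overlap_coefficient(q, p), oc, tolerance = 1e-9)
  expect_gte(oc, 0); expect_lte(oc, 1)
  # unit mismatch refuses to integrate
  r <- histogram_pdf(rnorm(100), 0.5, units = "degree")
  expect_error(overlap_coefficient(p, r), class = "cgm_unit_error")
})

test_that("round-trip: simulating at fitted parameters reproduces the input PDF", {
  set.seed(34)
  target <- histogram_pdf(rnorm(1e5, 3, 0.12), 0.01, units = "angstrom")
  p <- init_harmonic(target, 298)
  # regenerate from the fitted Gaussian (the stationary distribution of the
  # harmonic bond at T) and compare by overlap
  sd_fit <- sqrt(kB() * 298 / (2 * p$k))
  regen <- histogram_pdf(rnorm(1e5, p$x0, sd_fit), 0.01, units = "angstrom")
  expect_gt(overlap_coefficient(target, regen), 0.9)
})

test_that("RDF is flat for an ideal gas and matches the brute-force oracle", {
  set.seed(35)
  n <- 150; L <- 30
  beads <- tibble(bead = "W", molecule = seq_len(n), template = "W",
                  x = runif(n, 0, L), y = runif(n, 0, L), z = runif(n, 0, L))
  cfgs <- lapply(1:8, function(i) {
    b <- beads
    b$x <- runif(n, 0, L); b$y <- runif(n, 0, L); b$z <- runif(n, 0, L)
    cg_configuration(b, c(L, L, L))
  })
  traj <- cg_trajectory(cfgs)
  g <- rdf(traj, "W", dr = 1, rmax = 14)
  expect_equal(mean(g$g[g$r > 2]), 1, tolerance = 0.05)

  # oracle equivalence on a 64-particle lattice, bin for bin
  gl <- expand.grid(x = 1:4, y = 1:4, z = 1:4)
  lat <- tibble(bead = "W", molecule = 1:64, template = "W",
                x = gl$x * 5 - 2.5, y = gl$y * 5 - 2.5, z = gl$z * 5 - 2.5)
  cfg <- cg_configuration(lat, c(20, 20, 20))
  tl <- cg_trajectory(list(cfg))
  got <- rdf(tl, "W", dr = 0.25, rmax = 9)
  want <- oracle_rdf(cfg, "W", 0.25, 9)
  expect_equal(got$g, want, tolerance = 1e-10)
})

test_that("two fixed particles give a single RDF peak at their distance", {
  beads <- tibble(bead = "W", molecule = 1:2, template = "W",
                  x = c(10, 16.4), y = 10, z = 10)
  traj <- cg_trajectory(list(cg_configuration(beads, c(40, 40, 40))))
  g <- rdf(traj, "W", dr = 0.2, rmax = 19)
  expect_equal(g$r[g$g > 0], 6.5, tolerance = 0.11)
  expect_equal(attr(g, "first_peak"), 6.5, tolerance = 0.11)
  expect_error(rdf(traj, "W", rmax = 100), class = "cgm_geometry_error")
})

test_that("RDF number integral recovers the coordination count", {
  # closed system: integral of rho g(r) 4 pi r^2 dr over all r = N - 1
  set.seed(36)
  n <- 40; L <- 16
  beads <- tibble(bead = "W", molecule = seq_len(n), template = "W",
                  x = runif(n, 0, L), y = runif(n, 0, L), z = runif(n, 0, L))
  cfg <- cg_configuration(beads, c(L, L, L))
  g <- rdf(cg_trajectory(list(cfg)), "W", dr = 0.05, rmax = L / 2)
  rho <- n / L^3
  integral <- sum(rho * g$g * 4 * pi * g$r^2 * 0.05)
  # rmax = L/2 misses the corner shells, so expect somewhat below N - 1
  expect_gt(integral, 0.4 * (n - 1))
  expect_lte(integral, n - 1 + 1)
})
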