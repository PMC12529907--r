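# Toy MD engine: integrator physics, thermostat, reproducibility, and the
# force/energy consistency contract.

dimer_config <- function(sep = 3.4, L = 50) {
  tpl <- toy_template(2)
  beads <- tibble(bead = c("C3M", "C3M"), molecule = 1L, template = "TOY",
                  x = c(L / 2, L / 2 + sep), y = L / 2, z = L / 2)
  cg_configuration(beads, c(L, L, L), list(TOY = tpl))
}

lattice_fluid <- function(n_side = 4, L = 20) {
  g <- expand.grid(x = 1:n_side, y = 1:n_side, z = 1:n_side)
  beads <- tibble(bead = "W", molecule = seq_len(n_side^3), template = "W",
                  x = (g$x - 0.5) * L / n_side, y = (g$y - 0.5) * L / n_side,
                  z = (g$z - 0.5) * L / n_side)
  cg_configuration(beads, c(L, L, L))
}

test_that("a harmonic dimer oscillates at its analytic period", {
  ff <- toy_ff(eps = 0, kb = 5, b0 = 3)
  cfg <- dimer_config(3.4)
  res <- run_cg_md(cfg, ff, sim_spec(timestep_fs = 1, n_steps = 3000,
                                     ensemble = "nve", seed = 1, stride = 1),
                   velocities = matrix(0, 2, 3))
  b <- res$trajectory$beads
  d <- abs(matrix(b$x, ncol = 2, byrow = TRUE) %*% c(1, -1))
  minima <- which(diff(sign(diff(d))) == 2)
  mu <- 42.0798 / 2
  period <- 2 * pi * sqrt(mu / (2 * 5 * 4.184e-4))   # fs
  expect_equal(mean(diff(minima)), period, tolerance = 0.01 * period)
})

test_that("an overdamped LJ dimer settles at the potential minimum", {
  bt <- cg_bead_types(epsilon = 0.5, sigma = 3.5)
  ff <- force_field(bt, cutoff = 20)
  beads <- tibble(bead = c("W", "W"), molecule = 1:2, template = "W",
                  x = c(25, 25 + 4.5), y = 25, z = 25)
  cfg <- cg_configuration(beads, c(50, 50, 50))
  res <- run_cg_md(cfg, ff, sim_spec(timestep_fs = 5, n_steps = 4000,
                                     temperature = 1, friction_ps = 50,
                                     seed = 2, stride = 10))
  last <- get_frame(res$trajectory, n_frames(res$trajectory))
  sep <- abs(diff(last$beads$x))
  expect_equal(sep, 2^(1 / 6) * 3.5, tolerance = 0.02)
})

test_that("NVT sampling satisfies equipartition within 3 percent", {
  cfg <- lattice_fluid()
  ff <- force_field(cg_bead_types(epsilon = 0.3, sigma = 3.5), cutoff = 8)
  res <- run_cg_md(cfg, ff, sim_spec(timestep_fs = 10, n_steps = 5000,
                                     temperature = 298, friction_ps = 5,
                                     seed = 3, stride = 10))
  ke <- res$energies$kinetic
  ke <- ke[-seq_len(length(ke) %/% 5)]       # discard equilibration
  expect_equal(mean(ke), 1.5 * 64 * kB() * 298, tolerance = 0.03)
})

test_that("NVE energy drift stays below 1e-4 relative over 1e4 steps", {
  # 32-bead bonded chains + shifted LJ (continuous at the cutoff), dt 1 fs
  tpl <- toy_template(4)
  cfg <- random_chain_config(n_mol = 8, n_beads = 4, L = 30, seed = 6, tpl = tpl)
  ff <- toy_ff(eps = 0.2, sigma = 3.5, cutoff = 10, shift = TRUE)
  cfg <- minimize_energy(cfg, ff, max_steps = 300)$config  # relieve overlaps
  warm <- run_cg_md(cfg, ff, sim_spec(timestep_fs = 2, n_steps = 500,
                                      temperature = 150, friction_ps = 10,
                                      seed = 6, stride = 500))
  start <- get_frame(warm$trajectory, n_frames(warm$trajectory))
  res <- run_cg_md(start, ff, sim_spec(timestep_fs = 1, n_steps = 10000,
                                       ensemble = "nve", seed = 7, stride = 20),
                   velocities = warm$final_velocities)
  etot <- res$energies$total
  scale <- max(abs(mean(etot)), sd(res$energies$kinetic))
  drift <- abs(coef(lm(etot ~ seq_along(etot)))[[2]]) * length(etot)
  expect_lt(drift / max(abs(mean(etot)), 1), 1e-4)
})

test_that("forces equal the negative numerical gradient of the energy", {
  cfg <- random_chain_config(n_mol = 4, seed = 8)
  ff <- toy_ff(shift = TRUE)  # continuous energy across the cutoff
  f <- as.matrix(forces(cfg, ff))
  h <- 1e-5
  num <- f * 0
  for (i in seq_len(nrow(f))) {
    for (a in 1:3) {
      col <- c("x", "y", "z")[a]
      bp <- cfg$beads; bm <- cfg$beads
      bp[[col]][i] <- bp[[col]][i] + h
      bm[[col]][i] <- bm[[col]][i] - h
      num[i, a] <- -(total_energy(cg_configuration(bp, cfg$box, cfg$templates), ff)$total -
                       total_energy(cg_configuration(bm, cfg$box, cfg$templates), ff)$total) / (2 * h)
    }
  }
  expect_lt(max(abs(f - num)) / max(abs(f)), 1e-4)
})

test_that("trajectories are bit-reproducible for a fixed seed", {
  cfg <- lattice_fluid()
  ff <- force_field(cg_bead_types(epsilon = 0.3, sigma = 3.5), cutoff = 8)
  spec <- sim_spec(timestep_fs = 10, n_steps = 200, temperature = 298, seed = 42)
  r1 <- run_cg_md(cfg, ff, spec)
  r2 <- run_cg_md(cfg, ff, spec)
  expect_identical(r1$trajectory$beads$x, r2$trajectory$beads$x)
  expect_identical(r1$energies$total, r2$energies$total)
  r3 <- run_cg_md(cfg, ff, sim_spec(timestep_fs = 10, n_steps = 200,
                                    temperature = 298, seed = 43))
  expect_false(identical(r1$trajectory$beads$x, r3$trajectory$beads$x))
})

test_that("minimization is monotone and finds known minima", {
  ff <- toy_ff(eps = 0, kb = 5, b0 = 3)
  stretched <- dimer_config(5.5)
  mn <- minimize_energy(stretched, ff)
  expect_equal(abs(diff(mn$config$beads$x)), 3, tolerance = 1e-3)
  expect_true(all(diff(mn$trace) <= 1e-12))
  bt <- cg_bead_types(epsilon = 0.5, sigma = 3.5)
  lj <- force_field(bt, cutoff = 25)
  beads <- tibble(bead = c("W", "W"), molecule = 1:2, template = "W",
                  x = c(20, 20 + 3 * 3.5), y = 25, z = 25)
  mn2 <- minimize_energy(cg_configuration(beads, c(50, 50, 50)), lj,
                         max_steps = 2000)
  expect_equal(abs(diff(mn2$config$beads$x)), 2^(1 / 6) * 3.5, tolerance = 0.01)
})

test_that("NPT cell scaling responds to pressure and stays finite", {
  cfg <- lattice_fluid(4, 18)
  ff <- force_field(cg_bead_types(epsilon = 0.4, sigma = 3.8), cutoff = 8)
  res <- run_cg_md(cfg, ff, sim_spec(timestep_fs = 5, n_steps = 2000,
                                     temperature = 298, friction_ps = 5,
                                     ensemble = "npt", pressure_atm = 1,
                                     seed = 9, stride = 50))
  boxes <- res$trajectory$frames
  expect_true(all(is.finite(c(boxes$lx, boxes$lz))))
  expect_false(isTRUE(all.equal(boxes$lx[1], tail(boxes$lx, 1))))
})

test_that("instability reports an actionable error", {
  # two non-bonded beads in deep LJ overlap blow past the energy guard
  bt <- cg_bead_types(epsilon = 5, sigma = 4)
  ff <- force_field(bt, cutoff = 12)
  beads <- tibble(bead = c("W", "W"), molecule = 1:2, template = "W",
                  x = c(25, 25.3), y = 25, z = 25)
  cfg <- cg_configuration(beads, c(50, 50, 50))
  expect_error(
    run_cg_md(cfg, ff, sim_spec(timestep_fs = 100, n_steps = 500,
                                ensemble = "nve", seed = 1)),
    "timestep")
})
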