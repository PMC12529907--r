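# Force-field primitives: mixing rules, LJ form, exclusions, total energy.

test_that("Lorentz-Berthelot mixing follows its closed forms and is symmetric", {
  expect_equal(unlist(lb_mix(0.5, 4.0, 0.5, 4.0)), c(epsilon = 0.5, sigma = 4.0))
  expect_equal(unlist(lb_mix(1.0, 3.0, 4.0, 5.0)), c(epsilon = 2.0, sigma = 4.0))
  m <- lb_mix(1.1, 4.63, 0.5, 4.95)
  expect_equal(m$epsilon, sqrt(0.55))
  expect_equal(m$sigma, 4.79)
  # symmetry
  m2 <- lb_mix(0.5, 4.95, 1.1, 4.63)
  expect_equal(m, m2[, names(m)])
  # sign convention preserved on magnitudes
  expect_equal(lb_mix(-1, 4, -4, 4)$epsilon, -2)
  expect_error(lb_mix(1, -1, 1, 1), class = "cgm_invalid_parameter")
})

test_that("r_min <-> sigma conversion inverts exactly", {
  expect_equal(rmin_to_sigma(2^(1 / 6)), 1)
  expect_equal(sigma_to_rmin(4.95), 5.556, tolerance = 1e-4)
  expect_equal(sigma_to_rmin(4.63), 5.197, tolerance = 1e-4)
  x <- c(0.3, 1, 4.63, 12)
  expect_equal(rmin_to_sigma(sigma_to_rmin(x)), x)
  expect_error(rmin_to_sigma(0), class = "cgm_invalid_parameter")
})

test_that("LJ pair energy has its zero, minimum and tail where it should", {
  expect_equal(pair_lj_energy(4, 1.3, 4), 0)
  expect_equal(pair_lj_energy(2^(1 / 6) * 4, 1.3, 4), -1.3)
  expect_equal(pair_lj_energy(2, 1, 1), 4 * (2^-12 - 2^-6))
  expect_equal(pair_lj_energy(13, 1, 4, cutoff = 12), 0)
  # shifted potential is continuous at the cutoff
  expect_equal(pair_lj_energy(12 - 1e-9, 1, 4, cutoff = 12, shift = TRUE), 0,
               tolerance = 1e-6)
  expect_error(pair_lj_energy(0, 1, 1), class = "cgm_singular_geometry")
})

test_that("exclusion construction distinguishes the 1-2 and 1-3 policies", {
  chain <- cbind(1:2, 2:3)  # A-B-C
  e12 <- build_exclusions(chain, "exclude-1-2")
  expect_setequal(paste(e12$i, e12$j), c("1 2", "2 3"))
  e13 <- build_exclusions(chain, "exclude-1-3")
  expect_setequal(paste(e13$i, e13$j), c("1 2", "2 3", "1 3"))
  expect_equal(nrow(build_exclusions(matrix(integer(), 0, 2))), 0)
})

test_that("total energy matches the brute-force oracle under both policies", {
  for (policy in c("exclude-1-2", "exclude-1-3")) {
    for (seed in 1:3) {
      cfg <- random_chain_config(n_mol = 6, seed = seed)
      ff <- toy_ff(policy = policy)
      got <- total_energy(cfg, ff)
      want <- oracle_energy(cfg, ff)
      expect_equal(got$total, unname(want["total"]), tolerance = 1e-10)
      expect_equal(got$bond, unname(want["bond"]), tolerance = 1e-10)
      expect_equal(got$angle, unname(want["angle"]), tolerance = 1e-10)
      expect_equal(got$lj, unname(want["lj"]), tolerance = 1e-10)
    }
  }
})

test_that("energy is invariant under rigid translations and rotations", {
  cfg <- random_chain_config(n_mol = 3, L = 200, seed = 4)
  ff <- toy_ff()
  e0 <- total_energy(cfg, ff)$total
  set.seed(11)
  for (k in 1:3) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
                  2 * (q[2] * q[4] + q[1] * q[3]),
                  2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
                  2 * (q[3] * q[4] - q[1] * q[2]),
                  2 * (q[2] * q[4] - q[1] * q[3]),
                  2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
                3, 3)
    b <- cfg$beads
    xyz <- as.matrix(b[, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    xyz2 <- sweep(sweep(xyz, 2, ctr) %*% R, 2, ctr + rnorm(3, 0, 5), "+")
    b$x <- xyz2[, 1]; b$y <- xyz2[, 2]; b$z <- xyz2[, 3]
    # huge box so the molecule never straddles the boundary after moving
    e1 <- total_energy(cg_configuration(b, cfg$box, cfg$templates), ff)$total
    expect_equal(e1, e0, tolerance = 1e-9)
  }
})

test_that("missing bonded parameters raise a named missing-parameter error", {
  cfg <- random_chain_config(n_mol = 1, seed = 1)
  ff_nobond <- force_field(cg_bead_types(0.5, 4),
                           angles = tibble(i = "C3M", j = "C3M", k = "C3M",
                                           ktheta = 2, theta0 = 150))
  expect_error(total_energy(cfg, ff_nobond), "C3M-C3M",
               class = "cgm_missing_parameter")
})

test_that("force field refuses charged beads and bad sigma", {
  bt <- cg_bead_types()
  bt$charge[1] <- 0.5
  expect_error(force_field(bt), class = "cgm_invalid_parameter")
  bt <- cg_bead_types(); bt$sigma[2] <- -1
  expect_error(force_field(bt), class = "cgm_invalid_parameter")
})

test_that("LB mixing expands pair tables and explicit overrides win", {
  bt <- cg_bead_types(epsilon = 0.4, sigma = 4)
  bt$epsilon[bt$name == "W"] <- 0.9
  ff <- force_field(bt, lj_pairs = tibble(i = "PO2", j = "W",
                                          epsilon = 1.23, sigma = 5.5))
  tabs <- lj_tables(ff)
  expect_equal(tabs$eps["CHO", "W"], sqrt(0.4 * 0.9))
  expect_equal(tabs$eps["PO2", "W"], 1.23)
  expect_equal(tabs$sigma["W", "PO2"], 5.5)
})
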