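# Toy CG molecular-dynamics engine: velocity-Verlet core with a BAOAB
# Langevin thermostat and a Berendsen-style toy barostat, compiled in C++.
# Built for correctness plumbing and small demos (dimer oscillations,
# 64-bead fluids, micelle-scale aggregates), not production membranes.

#' Simulation specification
#'
#' @param timestep_fs Integration step, fs (default 10, the CG convention).
#' @param n_steps Number of steps.
#' @param temperature Target temperature, K.
#' @param ensemble `"nve"`, `"nvt"`, `"npt"` (isotropic) or
#'   `"npt-semiiso"` (xy coupled, z free — the membrane option).
#' @param friction_ps Langevin friction, 1/ps (ignored for NVE).
#' @param pressure_atm Target pressure for NPT, atm.
#' @param tau_p_fs Barostat relaxation time, fs.
#' @param seed RNG seed; a fixed seed gives a bit-reproducible trajectory.
#' @param stride Output stride in steps.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(timestep_fs = 10, n_steps = 1000, temperature = 298,
                     ensemble = c("nvt", "nve", "npt", "npt-semiiso"),
                     friction_ps = 5, pressure_atm = 1, tau_p_fs = 1000,
                     seed = 1, stride = 10) {
  ensemble <- match.arg(ensemble)
  if (timestep_fs <= 0) abort("timestep must be positive",
                              class = "cgm_invalid_parameter")
  structure(list(timestep_fs = timestep_fs, n_steps = n_steps,
                 temperature = temperature, ensemble = ensemble,
                 friction_ps = friction_ps, pressure_atm = pressure_atm,
                 tau_p_fs = tau_p_fs, seed = seed, stride = stride),
            class = "sim_spec")
}

# Maxwell-Boltzmann velocities in A/fs
draw_velocities <- function(n, mass, temperature) {
  sv <- sqrt(kB_KCAL * temperature * ACC_CONV / mass)
  matrix(rnorm(3 * n), n, 3) * sv
}

#' Run a toy CG MD simulation
#'
#' Velocity-Verlet integration of the CG potential with a BAOAB Langevin
#' thermostat (NVT/NPT) or plain NVE, minimum-image periodic boundaries,
#' exclusions honored, and optional Berendsen-style cell scaling. Energy
#' divergence aborts with advice to reduce the timestep. Trajectories are
#' bit-reproducible for a fixed seed.
#'
#' @param config Starting `cg_config`.
#' @param ff A `cg_forcefield`.
#' @param spec A [sim_spec()].
#' @param velocities Optional starting velocity matrix (n x 3, A/fs);
#'   defaults to a Maxwell-Boltzmann draw at `spec$temperature`.
#' @return List with `trajectory` (a `cg_trajectory`), `energies` (tibble
#'   of time, kinetic, potential, total, temperature) and
#'   `final_velocities`.
#' @export
run_cg_md <- function(config, ff, spec, velocities = NULL) {
  sys <- build_system(config, ff)
  n <- nrow(sys$coords)
  set.seed(spec$seed)
  if (is.null(velocities)) {
    velocities <- if (spec$ensemble == "nve") {
      draw_velocities(n, sys$mass, spec$temperature)
    } else {
      draw_velocities(n, sys$mass, spec$temperature)
    }
  }
  gamma <- if (spec$ensemble == "nve") 0 else spec$friction_ps
  res <- cpp_run_md(sys, spec$timestep_fs, spec$n_steps, spec$temperature,
                    gamma, spec$ensemble, spec$pressure_atm, spec$tau_p_fs,
                    spec$stride, velocities)
  cfgs <- lapply(seq_along(res$frames), function(i) {
    b <- config$beads
    b$x <- res$frames[[i]][, 1]
    b$y <- res$frames[[i]][, 2]
    b$z <- res$frames[[i]][, 3]
    cg_configuration(b, res$boxes[i, ], config$templates)
  })
  traj <- cg_trajectory(cfgs, times_ns = res$time_fs * 1e-6,
                        temperature = spec$temperature,
                        metadata = list(engine = "cgmembrane-toy",
                                        spec = unclass(spec)))
  energies <- tibble(time_fs = res$time_fs, kinetic = res$kinetic,
                     potential = res$potential,
                     total = res$kinetic + res$potential,
                     temperature = res$temperature)
  list(trajectory = traj, energies = energies,
       final_velocities = res$final_velocities)
}

#' Energy minimization
#'
#' Steepest descent with a backtracking line search; the energy trace is
#' monotone non-increasing and the best configuration found is returned.
#'
#' @param config A `cg_config`.
#' @param ff A `cg_forcefield`.
#' @param max_steps Iteration budget (default 1000).
#' @param step0 Initial maximum per-coordinate displacement, Angstrom.
#' @param ftol Convergence threshold on the max force component.
#' @return List with `config`, `energy`, `trace`.
#' @export
minimize_energy <- function(config, ff, max_steps = 1000, step0 = 0.1,
                            ftol = 1e-4) {
  sys <- build_system(config, ff)
  res <- cpp_minimize(sys, max_steps, step0, ftol)
  b <- config$beads
  b$x <- res$coords[, 1]; b$y <- res$coords[, 2]; b$z <- res$coords[, 3]
  list(config = cg_configuration(b, config$box, config$templates),
       energy = res$energy, trace = res$trace)
}
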