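# Integration: energy minimization, Langevin (NVTE) dynamics via BAOAB
# splitting, and NPHT-style runs with a z-direction piston barostat at fixed
# lateral area.

#' Run settings
#'
#' @param n_steps number of timesteps
#' @param dt timestep, fs
#' @param temperature thermostat target, K
#' @param friction Langevin friction rate per bead, 1/fs (0 gives plain
#'   velocity-Verlet NVE)
#' @param pressure_z target normal pressure for the z barostat, bar, or NULL
#' @param seed RNG seed for the thermostat
#' @param frame_every trajectory frame cadence, steps
#' @param thermo_every thermodynamic log cadence, steps
#' @param zero_momentum subtract the net momentum injected by the noise
#' @param piston_mass z-barostat piston mass, amu
#' @param piston_friction piston damping rate, 1/fs
#' @param tabulated use the tabulated nonbonded fast path (exact analytic
#'   kernels when FALSE)
#' @param use_cell cell-list neighbor search (brute-force O(N^2) when FALSE;
#'   for verification)
#' @return list of class \code{run_settings}
#' @export
run_settings <- function(n_steps, dt = 10, temperature = 300,
                         friction = 1e-3, pressure_z = NULL, seed = 1,
                         frame_every = 100, thermo_every = 100,
                         zero_momentum = FALSE, piston_mass = 2e5,
                         piston_friction = 2e-5, tabulated = TRUE,
                         use_cell = TRUE) {
  stopifnot(dt > 0, n_steps >= 1, temperature >= 0)
  out <- list(n_steps = as.integer(n_steps), dt = dt,
              temperature = temperature, friction = friction,
              pressure_z = pressure_z, seed = as.integer(seed),
              frame_every = as.integer(frame_every),
              thermo_every = as.integer(thermo_every),
              zero_momentum = zero_momentum, piston_mass = piston_mass,
              piston_friction = piston_friction, tabulated = tabulated,
              use_cell = use_cell)
  class(out) <- "run_settings"
  out
}

settings_to_cpp <- function(s, barostat, time0 = 0) {
  list(dt = s$dt, n_steps = s$n_steps, temperature = s$temperature,
       friction = s$friction, seed = s$seed, frame_every = s$frame_every,
       thermo_every = s$thermo_every, zero_momentum = s$zero_momentum,
       barostat = barostat,
       pressure_z = if (is.null(s$pressure_z)) 0 else s$pressure_z,
       piston_mass = s$piston_mass, piston_friction = s$piston_friction,
       time0 = time0, tabulated = isTRUE(s$tabulated),
       use_cell = isTRUE(s$use_cell))
}

thermo_df <- function(m) {
  df <- as.data.frame(m)
  names(df) <- c("time", "E_lj", "E_coul", "E_bond", "E_angle", "E_dihedral",
                 "KE", "T", "P_zz", "Lz")
  df
}

make_traj <- function(res, config, settings, ensemble) {
  out <- list(frames = res$frames, time = res$frame_time,
              frame_lz = res$frame_lz, box = res$box,
              thermo = thermo_df(res$thermo), config = config,
              final = list(x = res$x, v = res$v, box = res$box),
              settings = settings, ensemble = ensemble)
  class(out) <- "cg_traj"
  out
}

#' @export
print.cg_traj <- function(x, ...) {
  cat(sprintf("cg_traj (%s): %d beads, %d frames, %.2f ns\n", x$ensemble,
              nrow(x$config$x), length(x$time),
              if (length(x$time)) diff(range(x$time)) / 1e6 else 0))
  invisible(x)
}

#' Energy minimization
#'
#' Adaptive steepest descent: coordinates move along the force with a step
#' that grows while the energy decreases and shrinks on uphill trials;
#' terminates when the largest force component falls below \code{ftol} or at
#' the iteration cap. Energy never increases across accepted iterations.
#'
#' @param config a \code{cg_config}
#' @param ff a \code{cg_ff}
#' @param max_iters iteration cap
#' @param ftol force tolerance, kcal/mol/A
#' @param max_step largest per-coordinate move per iteration, A
#' @return the relaxed \code{cg_config}, with minimization diagnostics in
#'   \code{meta$minimize}
#' @export
minimize <- function(config, ff, max_iters = 2000, ftol = 1.0,
                     max_step = 0.2) {
  res <- cpp_minimize(config_to_cpp(config), ff_to_cpp(ff),
                      as.integer(max_iters), ftol, max_step)
  out <- config
  out$x <- res$x
  out$meta$minimize <- list(energy = res$energy, fmax = res$fmax,
                            iterations = res$iterations)
  out
}

run_md <- function(config, ff, settings, barostat, time0 = 0) {
  if (barostat && is.null(settings$pressure_z))
    stop("pressure_z must be set for an NPHT run")
  res <- cpp_run(config_to_cpp(config), ff_to_cpp(ff),
                 settings_to_cpp(settings, barostat, time0))
  make_traj(res, config, settings, if (barostat) "npht" else "nvte")
}

#' Langevin (NVTE) dynamics
#'
#' Fixed-box run coupling BAOAB Langevin noise (the implicit background
#' solvent) to velocity-Verlet integration. With \code{friction = 0} this is
#' a plain NVE run.
#'
#' @param config a \code{cg_config} (velocities drawn from the
#'   Maxwell-Boltzmann distribution when absent)
#' @param ff a \code{cg_ff}
#' @param settings a [run_settings()]
#' @return a \code{cg_traj}
#' @export
run_nvte <- function(config, ff, settings) run_md(config, ff, settings, FALSE)

#' NPHT dynamics with a z barostat
#'
#' Langevin-thermostatted run in which the box height is a damped piston
#' degree of freedom driven by the difference between the instantaneous
#' normal pressure (virial estimator) and \code{settings$pressure_z}. The
#' lateral area stays fixed at the builder's area per lipid.
#'
#' @inheritParams run_nvte
#' @return a \code{cg_traj}; per-frame box heights are in \code{frame_lz}
#' @export
run_npht <- function(config, ff, settings) run_md(config, ff, settings, TRUE)

#' Single integration steps
#'
#' Convenience wrappers advancing one (or a few) velocity-Verlet or Langevin
#' steps, mainly for integrator verification. \code{velocity_verlet_step}
#' runs with the thermostat off.
#'
#' @param config a \code{cg_config} carrying velocities in \code{$v}
#' @param ff a \code{cg_ff}
#' @param dt timestep, fs
#' @param n_steps number of steps
#' @param settings optional [run_settings()] for \code{langevin_step}
#' @return the advanced \code{cg_config}
#' @export
velocity_verlet_step <- function(config, ff, dt = 10, n_steps = 1) {
  s <- run_settings(n_steps = n_steps, dt = dt, temperature = 0, friction = 0,
                    frame_every = n_steps + 1, thermo_every = n_steps + 1)
  tr <- run_nvte(config, ff, s)
  config$x <- tr$final$x
  config$v <- tr$final$v
  config
}

#' @rdname velocity_verlet_step
#' @export
langevin_step <- function(config, ff, settings) {
  tr <- run_nvte(config, ff, settings)
  config$x <- tr$final$x
  config$v <- tr$final$v
  config
}

#' Continue a run from a trajectory's final state
#'
#' @param traj a \code{cg_traj}
#' @return a \code{cg_config} with final positions, velocities and box
#' @export
final_config <- function(traj) {
  cfg <- traj$config
  cfg$x <- traj$final$x
  cfg$v <- traj$final$v
  cfg$box <- traj$final$box
  cfg
}
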