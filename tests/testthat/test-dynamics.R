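# Integrators: minimization, NVE conservation/reversibility, Langevin
# sampling, determinism, neighbor-search equivalence, barostat behavior.

FF <- martini_ff("explicit")

test_that("minimization relaxes a stretched bond to its analytic minimum", {
  cfg <- two_bead_config(r = 4.3, K = 20.3, r0 = 3.3)
  out <- minimize(cfg, FF, max_iters = 5000, ftol = 1e-4)
  r <- sqrt(sum((out$x[1, ] - out$x[2, ])^2))
  # the nonbonded term is excluded for the bonded pair, so minimum is r0
  expect_lt(abs(r - 3.3), 1e-3)
  expect_lte(out$meta$minimize$energy, total_energy_forces(cfg, FF)$energy$total)
  # an already-minimal bond stays put
  cfg0 <- two_bead_config(r = 3.3, K = 20.3, r0 = 3.3)
  out0 <- minimize(cfg0, FF, max_iters = 100, ftol = 1e-6)
  expect_lt(max(abs(out0$x - cfg0$x)), 1e-6)
})

test_that("zero force gives exact linear drift", {
  cfg <- grid_gas_config(2, spacing = 30)
  cfg$v <- rbind(c(1e-3, 2e-3, -1e-3), c(0, 0, 1e-3))
  tr <- run_nvte(cfg, FF, run_settings(n_steps = 100, dt = 10, temperature = 0,
                                       friction = 0, frame_every = 100))
  expect_equal(tr$final$x, cfg$x + cfg$v * 1000, tolerance = 1e-12)
})

test_that("NVE: bounded energy oscillation, no drift, time reversibility", {
  cfg <- two_bead_config(r = 4.0, K = 24, r0 = 4.7,
                         v = rbind(c(1e-3, 0, 0), c(-1e-3, 0, 0)))
  s <- run_settings(n_steps = 10000, dt = 10, temperature = 0, friction = 0,
                    frame_every = 20000, thermo_every = 100, tabulated = FALSE)
  tr <- run_nvte(cfg, FF, s)
  E <- tr$thermo$E_bond + tr$thermo$KE
  drift <- abs(mean(tail(E, 20)) - mean(head(E, 20))) / abs(mean(E))
  expect_lt(drift, 1e-4)
  # forward, velocity flip, backward returns to the start
  s2 <- run_settings(n_steps = 500, dt = 10, temperature = 0, friction = 0,
                     frame_every = 1000, tabulated = FALSE)
  tr1 <- run_nvte(cfg, FF, s2)
  back <- final_config(tr1)
  back$v <- -back$v
  tr2 <- run_nvte(back, FF, s2)
  expect_lt(max(abs(tr2$final$x - cfg$x)), 1e-8)
})

test_that("vanishing friction reduces the Langevin step to velocity Verlet", {
  cfg <- two_bead_config(r = 4.2, K = 24, r0 = 4.7,
                         v = rbind(c(1e-3, 0, 0), c(-1e-3, 0, 0)))
  a <- velocity_verlet_step(cfg, FF, dt = 10, n_steps = 50)
  b_settings <- run_settings(n_steps = 50, dt = 10, temperature = 300,
                             friction = 1e-14, seed = 3, frame_every = 100)
  b <- langevin_step(cfg, FF, b_settings)
  expect_lt(max(abs(a$x - b$x)), 1e-4)
})

test_that("Langevin thermostat satisfies equipartition within 2%", {
  n <- 216
  cfg <- grid_gas_config(n, box = c(80, 80, 80), spacing = 13, type = 6L,
                         mass = 44)
  # sample velocities over many beads and steps (> 1e5 samples)
  tr <- run_nvte(cfg, FF, run_settings(n_steps = 3000, dt = 10,
                                       temperature = 300, friction = 2e-3,
                                       seed = 11, frame_every = 5000,
                                       thermo_every = 4))
  Tm <- mean(tr$thermo$T[tr$thermo$time > 5000])
  expect_lt(abs(Tm - 300) / 300, 0.02)
})

test_that("bond length distribution is Boltzmann (KS test)", {
  cfg <- two_bead_config(r = 4.7, K = 24, r0 = 4.7)
  tr <- run_nvte(cfg, FF, run_settings(n_steps = 150000, dt = 10,
                                       temperature = 300, friction = 2e-3,
                                       seed = 5, frame_every = 50,
                                       thermo_every = 50000))
  r <- vapply(seq_along(tr$time), function(f) {
    x <- matrix(tr$frames[, f], ncol = 3, byrow = TRUE)
    sqrt(sum((x[1, ] - x[2, ])^2))
  }, 0)
  r <- r[500:length(r)]
  rg <- seq(3.2, 6.4, length.out = 4000)
  w <- rg^2 * exp(-24 * (rg - 4.7)^2 / KT300)  # radial Jacobian included
  set.seed(2)
  ref <- sample(rg, 20000, replace = TRUE, prob = w) +
    runif(20000, -4e-4, 4e-4)
  ks <- suppressWarnings(stats::ks.test(r, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("same seed reproduces the trajectory; different seed does not", {
  cfg <- grid_gas_config(27, box = c(40, 40, 40), spacing = 12, type = 6L)
  s <- run_settings(n_steps = 200, dt = 10, temperature = 300,
                    friction = 1e-3, seed = 7, frame_every = 50)
  tr1 <- run_nvte(cfg, FF, s)
  tr2 <- run_nvte(cfg, FF, s)
  expect_identical(tr1$frames, tr2$frames)
  s$seed <- 8L
  tr3 <- run_nvte(cfg, FF, s)
  expect_false(identical(tr1$final$x, tr3$final$x))
})

test_that("momentum-conserving noise keeps total momentum at zero", {
  cfg <- grid_gas_config(27, box = c(40, 40, 40), spacing = 12, type = 6L,
                         mass = 44)
  cfg$v <- matrix(0, 27, 3)
  s <- run_settings(n_steps = 500, dt = 10, temperature = 300,
                    friction = 2e-3, seed = 9, frame_every = 1000,
                    zero_momentum = TRUE)
  tr <- run_nvte(cfg, FF, s)
  p <- colSums(tr$final$v * cfg$mass)
  expect_lt(max(abs(p)), 1e-9)
})

test_that("cell-list and brute-force dynamics agree over 100 steps", {
  cfg <- random_safe_config(n = 50, box = c(26, 26, 26), seed = 21,
                            chain = FALSE, charged = TRUE)
  mk <- function(use_cell) run_settings(n_steps = 100, dt = 10,
                                        temperature = 0, friction = 0,
                                        frame_every = 200,
                                        use_cell = use_cell)
  cfg$v <- matrix(0, 50, 3)
  # box slightly above 2x cutoff: cell path must fall back gracefully
  tr_cell <- run_nvte(cfg, FF, mk(TRUE))
  tr_brut <- run_nvte(cfg, FF, mk(FALSE))
  expect_lt(max(abs(tr_cell$final$x - tr_brut$final$x)), 1e-8)
})

test_that("a diverging configuration aborts with a blow-up diagnostic", {
  x <- rbind(c(10, 10, 10), c(10.8, 10, 10))  # deep LJ overlap
  cfg <- cg_config(x = x, box = c(40, 40, 40), type = c(4L, 4L),
                   type_names = TN, charge = c(0, 0), mass = c(72, 72),
                   mol = 1:2, group = rep("lipid", 2))
  expect_error(run_nvte(cfg, FF, run_settings(n_steps = 100, dt = 10,
                                              temperature = 0, friction = 0)),
               "blew up")
})

test_that("z barostat equilibrates a small membrane and stays stationary", {
  spec <- build_spec(n_x = 6, n_y = 6, X_p = 0.1, n_p = 10,
                     geometry = "double", gap = 50, seed = 13)
  ff <- martini_ff("implicit")
  cfg <- suppressWarnings(graft_lipopolymers(
    suppressWarnings(build_double_membrane(spec, ff)), spec, ff))
  cfg <- minimize(cfg, ff, max_iters = 1500, ftol = 5)
  tr <- run_npht(cfg, ff, run_settings(n_steps = 16000, pressure_z = 1,
                                       seed = 3, frame_every = 2000,
                                       thermo_every = 100))
  lz <- tr$thermo$Lz
  n <- length(lz)
  expect_gt(max(abs(diff(lz))), 0)  # the box height actually moves
  # z extent comfortably larger than membranes + polymer at all times
  expect_gt(min(lz), 2 * 40)
  # stationarity: third-quarter vs last-quarter means within 2%
  q3 <- mean(lz[(n / 2 + 1):(3 * n / 4)])
  q4 <- mean(lz[(3 * n / 4 + 1):n])
  expect_lt(abs(q4 - q3) / q3, 0.02)
  # normal pressure fluctuates around the 1 bar target at small N
  expect_lt(abs(mean(tr$thermo$P_zz[(n / 2):n]) - 1), 50)
})
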