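# Interaction model: pair terms, bonded terms, parameter file, total energy.

test_that("pair table is complete, symmetric, and matches the bead model", {
  ff <- martini_ff("explicit")
  expect_equal(ff$bead_types$charge, c(1, -1, 0, 0, 0, 0))
  expect_true(all(ff$bead_types$mass > 0))
  expect_equal(length(ff$pair_rows), 12)
  expect_false(anyNA(ff$sigma))
  expect_equal(ff$sigma, t(ff$sigma))
  expect_equal(ff$epsilon, t(ff$epsilon))
  expect_equal(ff$sigma["EG", "EG"], 4.3)
  expect_equal(ff$epsilon["Q0", "C1"], 0.478012)
  expect_equal(ff$sigma["Q0", "C1"], 6.2)
})

test_that("shifted LJ vanishes at the cutoff and integrates its own force", {
  p <- list(sigma = 4.3, epsilon = 0.806644, cutoff = 12, shift_onset = 9)
  at_cut <- lj_shifted(c(12, 13, 20), p)
  expect_equal(at_cut$energy, rep(0, 3))
  expect_equal(at_cut$force, rep(0, 3))
  # energy at r equals the quadrature of the force from r to the cutoff
  for (r in c(4.0, 4.826, 7.5, 9.5, 11.0)) {
    quad <- integrate(function(s) lj_shifted(s, p)$force, r, 12,
                      rel.tol = 1e-10)$value
    expect_equal(lj_shifted(r, p)$energy, quad, tolerance = 1e-7)
  }
  # unshifted reference at the minimum: E = -eps before shift corrections
  rmin <- 2^(1 / 6) * 4.3
  unshifted <- 4 * 0.806644 * ((4.3 / rmin)^12 - (4.3 / rmin)^6)
  expect_equal(unshifted, -0.806644, tolerance = 1e-12)
  # the shifted well is shallower but still attractive near the minimum
  expect_lt(lj_shifted(rmin, p)$energy, 0)
  expect_equal(abs(lj_shifted(rmin, p)$force), 0, tolerance = 1e-6)
})

test_that("Q0-C1 pair at r = sigma differs from zero only by the shift term", {
  p <- list(sigma = 6.2, epsilon = 0.478012, cutoff = 12, shift_onset = 9)
  # unshifted LJ is exactly zero at r = sigma
  expect_equal(4 * p$epsilon * ((p$sigma / 6.2)^12 - (p$sigma / 6.2)^6), 0)
  shifted <- lj_shifted(6.2, p)$energy
  quad <- integrate(function(s) lj_shifted(s, p)$force, 6.2, 12,
                    rel.tol = 1e-10)$value
  expect_equal(shifted, quad, tolerance = 1e-7)
  expect_true(shifted != 0)  # the shift correction is what remains
})

test_that("shifted Coulomb: arithmetic, symmetry, neutrality, quadrature", {
  z <- coulomb_shifted(4.7, 0, 1)
  expect_equal(z$energy, 0)
  expect_equal(z$force, 0)
  # unshifted reference: 332.0637 q_i q_j / (eps_r r)
  expect_equal(332.06371 * (1) * (-1) / (15 * 4.7), -4.7101, tolerance = 1e-4)
  for (r in c(3, 4.7, 8)) {
    quad <- integrate(function(s) coulomb_shifted(s, 1, -1)$force, r, 12,
                      rel.tol = 1e-10)$value
    expect_equal(coulomb_shifted(r, 1, -1)$energy, quad, tolerance = 1e-7)
  }
  expect_equal(coulomb_shifted(5, 1, -1)$energy,
               coulomb_shifted(5, -1, 1)$energy)
  expect_lt(coulomb_shifted(5, 1, -1)$energy, 0)  # attractive
  expect_equal(coulomb_shifted(12.5, 1, -1)$energy, 0)
  expect_error(coulomb_shifted(-1, 1, 1), "positive")
})

test_that("bond, angle and dihedral terms reproduce closed-form values", {
  expect_equal(bond_energy(3.3, list(K = 20.3, r0 = 3.3))$energy, 0)
  expect_equal(bond_energy(4.3, list(K = 20.3, r0 = 3.3))$energy, 20.3)
  expect_equal(bond_energy(4.2, list(K = 24, r0 = 4.7))$energy, 6.0)
  expect_error(bond_energy(0, list(K = 1, r0 = 1)), "positive")

  p <- list(K = 3, theta0 = 120)
  expect_equal(angle_cos_sq_energy(120, p)$energy, 0)
  expect_equal(angle_cos_sq_energy(180, p)$energy, 0.75)
  expect_equal(angle_cos_sq_energy(-45, p)$energy,
               angle_cos_sq_energy(45, p)$energy)

  ph <- list(K = 20.3, theta0 = 130)
  expect_equal(angle_harmonic_energy(130, ph)$energy, 0)
  expect_equal(angle_harmonic_energy(130 + 7, ph)$energy,
               angle_harmonic_energy(130 - 7, ph)$energy)
  # generalized force matches the finite difference of the energy
  th <- 117
  h <- 1e-4
  fd <- -(angle_harmonic_energy(th + h, ph)$energy -
          angle_harmonic_energy(th - h, ph)$energy) / (2 * h * pi / 180)
  expect_equal(angle_harmonic_energy(th, ph)$force, fd, tolerance = 1e-6)

  expect_equal(dihedral_fourier_energy(0)$energy, 0.308796, tolerance = 1e-9)
  expect_equal(dihedral_fourier_energy(77)$energy,
               dihedral_fourier_energy(77 + 360)$energy)
  # dense grid scan: the minimum sits where the generalized force vanishes
  grid <- seq(-180, 180, by = 0.01)
  e <- dihedral_fourier_energy(grid)$energy
  at_min <- grid[which.min(e)]
  expect_lt(abs(dihedral_fourier_energy(at_min)$force), 2e-3)
})

test_that("parameter file round-trips all pair and dihedral rows", {
  ff <- martini_ff("explicit", eps_r = 15)
  path <- tempfile(fileext = ".yaml")
  write_ff(ff, path)
  ff2 <- read_ff(path)
  expect_equal(ff2$sigma, ff$sigma)
  expect_equal(ff2$epsilon, ff$epsilon)
  expect_equal(length(ff2$pair_rows), 12)
  expect_equal(ff2$dihedral_terms$K, c(0.46845, 0.046845, 0.078872, 0.028681))
  expect_equal(ff2$dihedral_terms$n, 1:4)
  expect_equal(ff2$dihedral_terms$phi0, c(180, 0, 0, 0))
  expect_equal(ff2$bonded$bond_eg$K, 20.3)
  # the shipped parameter file loads and is complete too
  shipped <- read_ff(system.file("extdata", "dppc_peg_cg.yaml",
                                 package = "lipobrush"))
  expect_equal(shipped$sigma, ff$sigma)
})

test_that("total energy/forces: neighbor search matches brute force exactly", {
  ff <- martini_ff("explicit")
  cfg <- random_safe_config(n = 40)
  e1 <- total_energy_forces(cfg, ff, "cell")
  e2 <- total_energy_forces(cfg, ff, "brute")
  expect_equal(e1$energy$total, e2$energy$total, tolerance = 1e-10)
  expect_lt(max(abs(e1$forces - e2$forces)), 1e-9)
})

test_that("beyond-cutoff beads have zero interaction energy", {
  ff <- martini_ff("explicit")
  cfg <- grid_gas_config(2, box = c(60, 60, 60), spacing = 20, type = 4L)
  e <- total_energy_forces(cfg, ff, "brute")
  expect_equal(e$energy$total, 0)
  expect_equal(max(abs(e$forces)), 0)
})

test_that("forces are the exact gradient (finite differences)", {
  ff <- martini_ff("explicit")
  cfg <- random_safe_config(n = 30)
  expect_lt(fd_force_error(cfg, ff, n_checks = 30), 1e-5)
})

test_that("net force vanishes; energy invariant to translation and wrap", {
  ff <- martini_ff("explicit")
  cfg <- random_safe_config(n = 35, seed = 11)
  e0 <- total_energy_forces(cfg, ff, "cell")
  expect_lt(max(abs(colSums(e0$forces))), 1e-8)
  shifted <- cfg
  shifted$x <- cfg$x + matrix(c(3.1, -2.2, 7.9), nrow(cfg$x), 3, byrow = TRUE)
  expect_equal(total_energy_forces(shifted, ff, "cell")$energy$total,
               e0$energy$total, tolerance = 1e-10)
  wrapped <- cfg
  wrapped$x[5, ] <- wrapped$x[5, ] + cfg$box   # periodic image of one bead
  expect_equal(total_energy_forces(wrapped, ff, "cell")$energy$total,
               e0$energy$total, tolerance = 1e-10)
})

test_that("a box smaller than twice the cutoff is rejected", {
  ff <- martini_ff("explicit")
  cfg <- grid_gas_config(4, box = c(20, 100, 100), spacing = 15)
  expect_error(total_energy_forces(cfg, ff), "cutoff")
})
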