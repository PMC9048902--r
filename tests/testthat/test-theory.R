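# Closed-form polymer physics: Flory statistics, overlap threshold, brush
# heights, regime labels, Rouse dynamics.

test_that("Flory free energy is minimized at the Flory radius", {
  spec <- polymer_spec(n_p = 45, a = 4.3)
  R <- seq(0.5, 15, by = 0.001)
  F <- flory_free_energy(R, spec)
  expect_equal(R[which.min(F)], flory_radius(spec), tolerance = 2e-3)
  # stretching term alone at the ideal-chain size is O(1) kT
  a_nm <- 0.43
  stretch <- 1.5 * (a_nm * sqrt(45))^2 / (45 * a_nm^2)
  expect_equal(stretch, 1.5)
  # excluded-volume divergence at small R
  expect_gt(flory_free_energy(0.01, spec), flory_free_energy(1, spec))
  expect_error(flory_free_energy(-1, spec))
})

test_that("Flory radius: limits and scaling", {
  expect_equal(flory_radius(polymer_spec(n_p = 1, a = 4.3)), 0.43)
  expect_equal(flory_radius(polymer_spec(n_p = 45, a = 4.3)), 4.2208,
               tolerance = 1e-4)
  r1 <- flory_radius(polymer_spec(n_p = 50, a = 4.3))
  r2 <- flory_radius(polymer_spec(n_p = 100, a = 4.3))
  expect_equal(r2 / r1, 2^0.6, tolerance = 1e-12)
})

test_that("overlap fraction: value, chain-length and area scaling", {
  spec <- polymer_spec(n_p = 45, a = 4.3)
  expect_lt(abs(transition_fraction(spec) - 0.014), 5e-4)
  xs <- vapply(c(30, 45, 60, 90), function(np)
    transition_fraction(polymer_spec(np, 4.3)), 0)
  expect_true(all(diff(xs) < 0))
  expect_equal(transition_fraction(spec, A_l = 1.4) /
               transition_fraction(spec, A_l = 0.7), 2)
})

test_that("mean-field brush height: scaling laws and numeric minimum", {
  spec <- polymer_spec(n_p = 45, a = 4.3)
  g <- graft_spec(X_p = 0.1, A_l = 0.7)
  L <- brush_length_mf(spec, g)
  expect_equal(brush_length_mf(polymer_spec(90, 4.3), g) / L, 2,
               tolerance = 1e-12)
  expect_equal(brush_length_mf(spec, graft_spec(0.1, 0.7)) /
               brush_length_mf(spec, graft_spec(0.0125, 0.7), warn = FALSE),
               2, tolerance = 1e-12)
  # grid minimization of the brush free energy
  Lg <- seq(1, 15, by = 0.001)
  Fg <- brush_free_energy(Lg, spec, g)
  expect_equal(Lg[which.min(Fg)], L, tolerance = 2e-3)
  expect_warning(brush_length_mf(spec, graft_spec(0.005, 0.7)), "overlap")
})

test_that("scaling-theory height equals the mean-field height exactly", {
  for (np in c(20, 45, 120)) for (xp in c(0.02, 0.1, 0.5)) {
    spec <- polymer_spec(n_p = np, a = 4.3)
    g <- graft_spec(X_p = xp, A_l = 0.7)
    sc <- brush_length_scaling(spec, g)
    expect_equal(sc$L, brush_length_mf(spec, g, warn = FALSE),
                 tolerance = 1e-12)
    expect_equal(sc$m_L, 2 / 3)
  }
  # blob limit: grafting distance equal to R_F returns R_F
  spec <- polymer_spec(n_p = 45, a = 4.3)
  rf <- flory_radius(spec)
  g_rf <- graft_spec(X_p = 0.7 / rf^2, A_l = 0.7)
  expect_equal(brush_length_scaling(spec, g_rf)$L, rf, tolerance = 1e-10)
})

test_that("regime classification matches the reference compositions", {
  spec <- polymer_spec(n_p = 45, a = 4.3)
  expect_equal(classify_regime(spec, graft_spec(0.005)), "mushroom")
  expect_equal(classify_regime(spec, graft_spec(0.014)), "critic")
  expect_equal(classify_regime(spec, graft_spec(0.1)), "brush")
  # boundary coincides with the overlap fraction
  xs <- transition_fraction(spec)
  expect_equal(classify_regime(spec, graft_spec(xs * 1.2)), "brush")
  expect_equal(classify_regime(spec, graft_spec(xs * 0.8)), "mushroom")
  th <- brush_theory(45, 4.3, 0.1, 0.7)
  expect_equal(th$L_MF, th$L_TE)
  expect_equal(th$regime, "brush")
})

test_that("Rouse prediction: limits, slope, continuity at the crossover", {
  rs <- rouse_spec(n_p = 45, a = 3.3, friction = 1e-3, mass = 44)
  expect_equal(rouse_msd_prediction(0, rs), 0)
  t <- 10^seq(2, log10(rs$tau) - 0.3, length.out = 20)
  slope <- coef(lm(log10(rouse_msd_prediction(t, rs)) ~ log10(t)))[2]
  expect_equal(unname(slope), 0.5, tolerance = 1e-10)
  eps <- 1e-6
  expect_equal(rouse_msd_prediction(rs$tau * (1 - eps), rs),
               rouse_msd_prediction(rs$tau * (1 + eps), rs),
               tolerance = 1e-4)
})

test_that("Rouse prediction matches a simulated ideal bead-spring chain", {
  # ideal chain: entropic springs only, no excluded volume
  n_b <- 32
  n_ch <- 12
  a <- 3.3
  kT <- KT300
  K_spring <- 3 * kT / a^2 / 2   # V = K r^2 with K = k/2
  ff <- martini_ff("implicit")
  ff$epsilon[] <- 0   # switch off all nonbonded terms
  xs <- c(); bonds <- NULL
  X <- NULL; mol <- integer(0)
  set.seed(31)
  for (c in seq_len(n_ch)) {
    base <- c((c - 1) %% 6, (c - 1) %/% 6, 0) * 50 + 25
    pos <- matrix(rnorm(n_b * 3, sd = a / sqrt(3)), n_b, 3)
    pos <- apply(pos, 2, cumsum) + matrix(base, n_b, 3, byrow = TRUE)
    o <- if (is.null(X)) 0 else nrow(X)
    X <- rbind(X, pos)
    bonds <- rbind(bonds, cbind(o + 1:(n_b - 1), o + 2:n_b))
    mol <- c(mol, rep(c, n_b))
  }
  cfg <- cg_config(x = X, box = c(300, 200, 300), type = rep(6L, nrow(X)),
                   type_names = TN, charge = rep(0, nrow(X)),
                   mass = rep(44, nrow(X)), mol = mol,
                   group = rep("peg", nrow(X)),
                   bonds = bonds, bond_k = rep(K_spring, nrow(bonds)),
                   bond_r0 = rep(0, nrow(bonds)) + 1e-9,
                   exclusions = bonds)
  gam <- 0.01
  tr <- run_nvte(cfg, ff, run_settings(n_steps = 150000, dt = 10,
                                       temperature = 300, friction = gam,
                                       seed = 17, frame_every = 100,
                                       thermo_every = 50000))
  ms <- msd(tr, "peg", dims = "xyz", reference = "monomer")
  rs <- rouse_spec(n_p = n_b, a = a, friction = gam, mass = 44)
  # 1.5 decades inside the subdiffusive branch: above the fastest-mode time
  # (~ xi/4k, where single-bead motion crosses over to collective modes)
  # and below tau_R/3 where the diffusive term intrudes
  t_lo <- 3.5 * rs$tau_R * (pi / n_b)^2 / 4
  sel <- ms$t > t_lo & ms$t < rs$tau_R / 5
  expect_gt(log10(max(ms$t[sel]) / min(ms$t[sel])), 1.2)
  pred <- rouse_msd_prediction(ms$t[sel], rs)
  rel <- ms$msd[sel] / pred
  expect_lt(abs(mean(rel) - 1), 0.1)
  expect_true(all(abs(rel - 1) < 0.2))
})
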