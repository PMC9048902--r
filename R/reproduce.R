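# Scaled-down reproduction protocols for the headline observables: polymer
# layer thickness and membrane thickness from double-membrane runs, and
# anomalous-diffusion exponents for grafted PEG and membrane lipids. These
# are the exact procedures the acceptance checks execute; problem sizes are
# desk-scale (see the methods vignette).

# dilute lipopolymer system for the polymer-dynamics study: n_chains free
# DPPC-PEG molecules (one lipid + one grafted chain each) far apart in a
# large periodic box, implicit solvent
build_lipopolymer_gas <- function(n_chains = 20, n_p = 45, spacing = 100,
                                  seed = 1, ff = martini_ff("implicit")) {
  ncol_g <- ceiling(sqrt(n_chains))
  nrow_g <- ceiling(n_chains / ncol_g)
  box <- c(ncol_g * spacing, nrow_g * spacing, 60 + n_p * 2.4)
  heads <- matrix(0, n_chains, 3)
  k <- 1
  for (iy in seq_len(nrow_g)) for (ix in seq_len(ncol_g)) {
    if (k > n_chains) break
    heads[k, ] <- c((ix - 0.5) * spacing, (iy - 0.5) * spacing, 25)
    k <- k + 1
  }
  cfg <- with_seed(seed, {
    cc <- assemble_lipids(heads, rep(1, n_chains),
                          runif(n_chains, 0, 2 * pi), box, ff$bonded)
    cc$meta <- list(lipid_info = data.frame(
      mol = seq_len(n_chains), leaflet = "upper", bilayer = 1L,
      head_index = (seq_len(n_chains) - 1L) * 12L + 1L))
    cc
  })
  spec <- build_spec(n_x = 2, n_y = 2, X_p = 1, n_p = n_p,
                     geometry = "single", solvent = "implicit", seed = seed)
  graft_lipopolymers(cfg, spec, ff)
}

# segmenter-driven fit window selection: the segment whose log-time span
# contains `center` (geometric position within the available lag range)
segment_window <- function(ms, t_min, center_frac = 0.5) {
  ok <- ms$t >= t_min & ms$msd > 0
  tr <- range(ms$t[ok])
  sub <- ms
  keep <- ms$t == 0 | ok
  sub$t <- ms$t[keep]; sub$msd <- ms$msd[keep]
  seg <- segment_msd(sub)
  edges <- c(tr[1], seg$breakpoints, tr[2])
  center <- 10^(log10(tr[1]) + center_frac * (log10(tr[2]) - log10(tr[1])))
  i <- findInterval(center, edges, rightmost.closed = TRUE)
  i <- min(max(i, 1), length(edges) - 1)
  c(edges[i], edges[i + 1])
}

#' Scaled-down membrane layer study
#'
#' Runs the full protocol behind the layer-thickness and lipid-dynamics
#' measurements at one composition: build a double membrane with grafted
#' facing leaflets, minimize, equilibrate the inter-membrane distance with
#' the z barostat at 1 bar / 300 K, then a fixed-box Langevin production
#' run. Returns the polymer-layer thickness \code{L = d/2}, the lipid
#' z-profile FWHM \code{h}, and the in-plane lipid center-of-mass
#' subdiffusion exponent.
#'
#' @param X_p lipopolymer molar fraction
#' @param seed integer seed
#' @param n_x,n_y lipids per leaflet edge
#' @param equil_steps NPHT step count (10 fs timestep); the layer structure
#'   is measured over the second half, after the box height is stationary
#' @param prod_steps NVTE step count for the dynamics measurement; 0 skips
#'   the production stage (structure only)
#' @return list with fields \code{L}, \code{h}, \code{d} (nm),
#'   \code{alpha_lipid}, \code{window} and the trajectories
#' @export
membrane_layer_study <- function(X_p, seed = 1, n_x = 8, n_y = 8,
                                 equil_steps = 25000, prod_steps = 22000) {
  rf_A <- flory_radius(polymer_spec(45, 4.3)) * 10
  lmf_A <- brush_length_mf(polymer_spec(45, 4.3),
                           graft_spec(max(X_p, 0.02), 0.7), warn = FALSE) * 10
  gap <- max(2.05 * rf_A, 2.1 * lmf_A)
  bs <- build_spec(n_x = n_x, n_y = n_y, A_l = 0.7, X_p = X_p, n_p = 45,
                   geometry = "double", gap = gap, solvent = "implicit",
                   seed = seed)
  ff <- martini_ff("implicit")
  cfg <- suppressWarnings(build_double_membrane(bs, ff))
  cfg <- suppressWarnings(graft_lipopolymers(cfg, bs, ff))
  cfg <- minimize(cfg, ff, max_iters = 3000, ftol = 5)
  eq <- run_npht(cfg, ff, run_settings(n_steps = equil_steps, pressure_z = 1,
                                       seed = seed * 100L + 1L,
                                       frame_every = 500, thermo_every = 500))
  pr <- NULL
  if (prod_steps > 0)
    pr <- run_nvte(final_config(eq), ff,
                   run_settings(n_steps = prod_steps, seed = seed * 100L + 2L,
                                frame_every = 100, thermo_every = 500))
  # structure: equilibrated NPHT frames (second half) plus any production
  nfr <- length(eq$time)
  prof <- density_profile(eq, "lipid", frames = seq(ceiling(nfr / 2), nfr))
  if (!is.null(pr)) {
    prof2 <- density_profile(pr, "lipid")
    if (length(prof2$counts) == length(prof$counts)) {
      prof$counts <- prof$counts + prof2$counts
      prof$n_frames <- prof$n_frames + prof2$n_frames
    } else prof <- prof2
  }
  thick <- extract_thickness(prof, "double")
  alpha <- NA_real_; D_alpha <- NA_real_; win <- c(NA, NA); ms <- NULL
  if (!is.null(pr)) {
    ms <- msd(pr, "lipid", dims = "xy", reference = "com")
    win <- segment_window(ms, t_min = 2e3)
    fit <- fit_anomalous(ms, win)
    alpha <- fit$fits$alpha[1]
    D_alpha <- fit$fits$D_alpha_cm2[1]
  }
  list(L = thick$L, h = thick$h, d = thick$d,
       alpha_lipid = alpha, D_alpha_lipid = D_alpha,
       window = win, profile = prof, msd = ms, traj = pr, equil = eq)
}

#' Scaled-down grafted-PEG dynamics study
#'
#' Langevin dynamics of ~20 dilute DPPC-PEG lipopolymers (45-mer chains on
#' their host lipids) in implicit solvent at 300 K. The 3-D monomer MSD is
#' segmented to locate the Rouse crossover; exponents are fitted on the
#' subdiffusive window below it and the diffusive window above it.
#'
#' The bead friction (default 1/(2 ps)) keeps the chain overdamped while
#' placing the Rouse crossover early enough that the diffusive regime is
#' well sampled within the run; the exponents themselves do not depend on
#' the friction.
#'
#' Below the crossover the chain and monomer displacements coincide, so the
#' subdiffusive exponent is fitted on the 3-D monomer MSD; beyond it the
#' molecule diffuses as a whole and the asymptotic exponent is fitted on the
#' molecule center-of-mass MSD (the displacement entering the model's
#' long-time law). The monomer curve's long-window slope is also reported:
#' on desk-scale spans it still sits below 1 because the internal-mode
#' plateau (about twice the squared gyration radius) has not yet been
#' outrun.
#'
#' @param seed integer seed
#' @param n_chains number of lipopolymers
#' @param n_steps production steps (10 fs timestep)
#' @param friction Langevin friction rate per bead, 1/fs
#' @return list with \code{alpha_short}, \code{alpha_long},
#'   \code{alpha_long_monomer}, \code{tau} (detected crossover, fs),
#'   \code{D_short}, \code{D_long} and both MSD curves
#' @export
peg_dynamics_study <- function(seed = 1, n_chains = 20, n_steps = 800000,
                               friction = 1e-3) {
  ff <- martini_ff("implicit")
  # the host lipid serves only as the chain's mobile anchor here; purely
  # repulsive nonbonded interactions keep the dilute molecules from
  # aggregating through their (amphiphilic) anchors during the run
  ff$style[] <- 1L
  cfg <- build_lipopolymer_gas(n_chains = n_chains, seed = seed, ff = ff)
  cfg <- minimize(cfg, ff, max_iters = 1500, ftol = 5)
  tr <- run_nvte(cfg, ff, run_settings(n_steps = n_steps, friction = friction,
                                       seed = seed * 100L + 3L,
                                       frame_every = 200, thermo_every = 5000))
  ms <- msd(tr, "peg", dims = "xyz", reference = "monomer", n_lags = 80)
  ms_com <- msd(tr, "peg", dims = "xyz", reference = "com", n_lags = 80)
  # crossover from a two-segment fit above the inertial regime; velocity
  # memory biases the local slope up to ~20/friction
  t_min <- max(3e3, 20 / friction)
  ok <- ms$t >= t_min & ms$msd > 0
  sub <- ms; keep <- ms$t == 0 | ok
  sub$t <- ms$t[keep]; sub$msd <- ms$msd[keep]
  seg <- segment_msd(sub, max_segments = 2)
  tau <- if (length(seg$breakpoints)) seg$breakpoints[1] else
    rouse_spec(n_p = 45, a = 3.3, friction = friction)$tau
  tmax <- max(ms$t)
  tau <- min(max(tau, 4 * t_min), tmax / 6)
  # short: within the subdiffusive branch, clear of inertia and crossover
  # (the ideal-chain mode relaxation time bounds it when the detected
  # crossover sits late); long: from the detected crossover out, capped so
  # every lag keeps many time origins (center-of-mass statistics)
  rsp <- rouse_spec(n_p = 45, a = 3.3, friction = friction)
  short_hi <- max(2.5 * t_min, min(tau / 4, rsp$tau_R / 2))
  short_win <- c(t_min, short_hi)
  # lower edge from the theoretical crossover (robust to noisy detection);
  # upper edge capped for time-origin statistics
  long_win <- c(max(1.5 * rsp$tau, 0.075 * tmax), 0.25 * tmax)
  fit <- fit_anomalous(ms, list(short_win, long_win))
  fit_com <- fit_anomalous(ms_com, long_win)
  list(alpha_short = fit$fits$alpha[1],
       alpha_long = fit_com$fits$alpha[1],
       alpha_long_monomer = fit$fits$alpha[2],
       D_short = fit$fits$D_alpha_cm2[1],
       D_long = fit_com$fits$D_alpha_cm2[1],
       tau = tau, windows = list(short = short_win, long = long_win),
       msd = ms, msd_com = ms_com)
}
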