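# Profiles, thickness extraction, RDF / potential of mean force, MSD and
# anomalous-diffusion fits.

# a minimal hand-made trajectory object
fake_traj <- function(frames_list, box, group, mol = NULL, mass = NULL,
                      dt = 1000) {
  n <- nrow(frames_list[[1]])
  fr <- vapply(frames_list, function(x) as.numeric(t(x)),
               numeric(3 * n))
  structure(list(
    frames = matrix(fr, nrow = 3 * n),
    time = seq_along(frames_list) * dt,
    frame_lz = rep(box[3], length(frames_list)), box = box,
    thermo = data.frame(), settings = list(dt = 10),
    config = list(x = frames_list[[1]], box = box, group = group,
                  mol = if (is.null(mol)) seq_len(n) else mol,
                  mass = if (is.null(mass)) rep(72, n) else mass,
                  type = rep(4L, n), type_names = TN),
    ensemble = "nvte"), class = "cg_traj")
}

test_that("density profile: exact counts on a hand-built fixture", {
  x <- cbind(rep(5, 6), rep(5, 6), c(1.2, 1.8, 5.5, 5.1, 8.9, 9.7))
  tr <- fake_traj(list(x), box = c(10, 10, 10), group = rep("lipid", 6))
  p <- density_profile(tr, "lipid", bin_width = 2)
  expect_equal(p$counts[1:5], c(2, 0, 2, 0, 2))
  expect_equal(sum(p$counts), 6)
  expect_error(density_profile(tr, "water"), "no beads")
})

test_that("density profile of uniform beads is flat within Poisson noise", {
  set.seed(3)
  n <- 4000
  x <- cbind(runif(n, 0, 40), runif(n, 0, 40), runif(n, 0, 80))
  tr <- fake_traj(list(x), box = c(40, 40, 80), group = rep("peg", n))
  p <- density_profile(tr, "peg", bin_width = 4)
  counts <- p$counts[p$z < 80]
  expected <- n / length(counts)
  chi2 <- sum((counts - expected)^2 / expected)
  # chi-square with ~19 dof should not be extreme
  expect_lt(chi2, qchisq(0.999, length(counts) - 1))
  expect_equal(sum(p$counts), n)
})

test_that("thickness extraction reproduces constructed slab widths", {
  # single rectangular slab, 40 A wide
  counts <- rep(0, 120)
  counts[41:80] <- 100
  t1 <- extract_thickness(fake_profile(counts), "single")
  expect_equal(t1$h, 4.0, tolerance = 0.05)
  # two slabs whose facing half-max edges are 72 A apart
  counts <- rep(0, 200)
  counts[21:60] <- 100     # slab 1: edge at 60
  counts[133:172] <- 100   # slab 2: edge at 132; separation 72
  t2 <- extract_thickness(fake_profile(counts), "double")
  expect_equal(t2$d, 7.2, tolerance = 0.05)
  expect_equal(t2$L, 3.6, tolerance = 0.03)
  expect_equal(t2$h, 4.0, tolerance = 0.1)
  # independent of bin phase (shift the whole pattern)
  counts3 <- c(rep(0, 7), counts)[1:200]
  t3 <- extract_thickness(fake_profile(counts3), "double")
  expect_equal(t3$d, t2$d, tolerance = 0.02)
  # slab straddling the periodic boundary is handled
  counts4 <- counts[c(101:200, 1:100)]
  t4 <- extract_thickness(fake_profile(counts4), "double")
  expect_equal(t4$d, t2$d, tolerance = 0.02)
  expect_error(extract_thickness(fake_profile(rep(0, 50)), "single"), "empty")
})

test_that("RDF: ideal gas is flat, discrete distances land in one bin", {
  set.seed(4)
  n <- 400
  x <- cbind(runif(n, 0, 50), runif(n, 0, 50), runif(n, 0, 50))
  frames <- lapply(1:5, function(i)
    cbind(runif(n, 0, 50), runif(n, 0, 50), runif(n, 0, 50)))
  tr <- fake_traj(frames, box = c(50, 50, 50), group = rep("peg", n))
  g <- rdf(tr, "peg", r_max = 24, n_bins = 24)
  mid <- g$g[g$r > 5]
  expect_true(all(abs(mid - 1) < 3 * sqrt(1 / (g$rho * 4 * pi * g$r[g$r > 5]^2 * 1 * n / 2 * 5))))
  # two beads at fixed distance: single nonzero bin
  x2 <- rbind(c(10, 10, 10), c(10, 10, 17.3))
  tr2 <- fake_traj(list(x2), box = c(40, 40, 40), group = rep("lipid", 2))
  g2 <- rdf(tr2, "lipid", r_max = 20, n_bins = 40)
  expect_equal(which(g2$g > 0), 15)   # bin [7.0, 7.5)
  expect_error(rdf(tr2, "lipid", r_max = 30), "half")
})

test_that("RDF histogram equals a brute-force all-pairs count", {
  set.seed(9)
  n <- 20
  frames <- lapply(1:3, function(i)
    cbind(runif(n, 0, 30), runif(n, 0, 30), runif(n, 0, 30)))
  box <- c(30, 30, 30)
  tr <- fake_traj(frames, box = box, group = rep("lipid", n))
  g <- rdf(tr, "lipid", r_max = 14, n_bins = 28)
  # independent R implementation
  hist_ref <- rep(0, 28)
  for (f in frames) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- f[i, ] - f[j, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      if (r < 14) {
        b <- floor(r / 0.5) + 1
        hist_ref[b] <- hist_ref[b] + 2
      }
    }
  }
  ideal <- 3 * n * (n - 1) / prod(box) * 4 * pi * g$r^2 * 0.5
  expect_equal(g$g, hist_ref / ideal, tolerance = 1e-12)
})

test_that("potential of mean force: values, masking, order preservation", {
  r <- list(r = 1:5, g = c(1, exp(-1), 0, 2, 0.5), rho = 0.01)
  class(r) <- "rdf_result"
  u <- effective_potential(r)
  expect_equal(u$U_eff[1], 0)
  expect_equal(u$U_eff[2], 1)
  expect_true(is.na(u$U_eff[3]))
  # deeper g peak -> lower U_eff minimum
  expect_lt(u$U_eff[4], u$U_eff[5])
})

test_that("MSD: static, ballistic, and hand-computed multi-origin cases", {
  x0 <- cbind(1:3, c(0, 5, 2), c(4, 4, 4))
  tr_static <- fake_traj(rep(list(x0), 6), box = c(50, 50, 50),
                         group = rep("peg", 3))
  m <- msd(tr_static, "peg")
  expect_true(all(m$msd == 0))
  # ballistic: x = v t exactly
  v <- c(0.3, -0.2, 0.1)
  frames <- lapply(0:5, function(k) sweep(x0, 2, v * k * 1000, "+"))
  trb <- fake_traj(frames, box = c(50, 50, 50), group = rep("peg", 3))
  mb <- msd(trb, "peg", dims = "xyz")
  ok <- mb$t > 0
  expect_equal(mb$msd[ok], sum(v^2) * mb$t[ok]^2, tolerance = 1e-12)
  # 5-frame 3-bead fixture vs direct all-origin average
  set.seed(5)
  frames <- lapply(1:5, function(i) matrix(rnorm(9, sd = 2), 3, 3))
  trh <- fake_traj(frames, box = c(50, 50, 50), group = rep("peg", 3))
  mh <- msd(trh, "peg", dims = "xyz")
  for (lag in 1:4) {
    acc <- 0; cnt <- 0
    for (t0 in 1:(5 - lag)) for (b in 1:3) {
      acc <- acc + sum((frames[[t0 + lag]][b, ] - frames[[t0]][b, ])^2)
      cnt <- cnt + 1
    }
    expect_equal(mh$msd[mh$t == lag * 1000], acc / cnt, tolerance = 1e-12)
  }
})

test_that("center-of-mass MSD uses mass-weighted molecule positions", {
  x0 <- rbind(c(0, 0, 0), c(2, 0, 0), c(10, 10, 10))
  frames <- list(x0, x0 + 1, x0 + 2)
  tr <- fake_traj(frames, box = c(50, 50, 50), group = rep("lipid", 3),
                  mol = c(1L, 1L, 2L), mass = c(72, 36, 72))
  m <- msd(tr, "lipid", dims = "xy", reference = "com")
  expect_equal(m$d, 2)
  expect_equal(m$msd[m$t == 1000], 2)  # both COMs move (1,1) in-plane
})

test_that("anomalous fit inverts a noiseless power law exactly", {
  # alpha = 0.63, D = 1.2e-4 cm^2/s^alpha, d = 2
  alpha <- 0.63
  D_cm2 <- 1.2e-4
  D <- d_alpha_to_A2fs(D_cm2, alpha)
  t <- 10^seq(3, 6.5, length.out = 40)
  m <- fake_msd(c(0, t), c(0, 2 * 2 * D * t^alpha), d = 2)
  fit <- fit_anomalous(m, c(1e3, 10^6.5))
  expect_equal(fit$fits$alpha, alpha, tolerance = 1e-6)
  expect_equal(fit$fits$D_alpha_cm2, D_cm2, tolerance = 1e-6)
  # pure normal diffusion gives alpha = 1 exactly
  m1 <- fake_msd(c(0, t), c(0, 6 * 0.005 * t), d = 3)
  expect_equal(fit_anomalous(m1, c(1e3, 1e6))$fits$alpha, 1, tolerance = 1e-9)
  # errors: non-positive MSD in window; too few points
  mbad <- fake_msd(c(0, t[1:9]), c(0, rep(0, 9)), d = 2)
  expect_error(fit_anomalous(mbad, c(1e3, 1e5)), "non-positive")
  expect_error(fit_anomalous(m, c(1e3, 1.3e3)), "fewer than 5")
})

test_that("generalized diffusion unit conversion round-trips", {
  for (alpha in c(0.3, 0.63, 1)) {
    D <- 2.8e-4
    expect_equal(d_alpha_to_cm2(d_alpha_to_A2fs(D, alpha), alpha), D)
  }
  # 1 A^2/fs^alpha = 10^(15 alpha - 16) cm^2/s^alpha at alpha = 1: 0.1 cm^2/s
  expect_equal(d_alpha_to_cm2(1, 1), 0.1)
})

test_that("MSD segmentation: pure power law vs constructed crossover", {
  t <- 10^seq(3, 7, length.out = 60)
  m1 <- fake_msd(c(0, t), c(0, 5 * t^0.8), d = 3)
  s1 <- segment_msd(m1)
  expect_equal(s1$n_segments, 1)
  expect_equal(s1$slopes[1], 0.8, tolerance = 1e-6)
  # sqrt(t) -> t crossover at tau = 10^5.2
  tau <- 10^5.2
  msd_x <- ifelse(t < tau, sqrt(tau * t), t) * 1e-3
  m2 <- fake_msd(c(0, t), c(0, msd_x), d = 3)
  s2 <- segment_msd(m2)
  expect_gte(s2$n_segments, 2)
  expect_lt(abs(log10(s2$breakpoints[1]) - 5.2), 0.2)
  # breakpoints covariant under uniform time rescaling
  m3 <- fake_msd(c(0, t * 10), c(0, msd_x), d = 3)
  s3 <- segment_msd(m3)
  expect_equal(log10(s3$breakpoints[1]), log10(s2$breakpoints[1]) + 1,
               tolerance = 0.05)
})
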