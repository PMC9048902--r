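# Shared fixtures: small configurations built in code.

TN <- c("Q0", "Qa", "Na", "C1", "MW", "EG")
KT300 <- 0.0019872041 * 300

# two bonded beads at separation r
two_bead_config <- function(r = 4.7, K = 24, r0 = 4.7, mass = 72,
                            type = 4L, box = c(100, 100, 100), v = NULL) {
  cg_config(x = rbind(c(50, 50, 50), c(50 + r, 50, 50)), box = box,
            type = rep(type, 2), type_names = TN, charge = c(0, 0),
            mass = rep(mass, 2), mol = c(1L, 1L), group = rep("lipid", 2),
            bonds = matrix(c(1, 2), 1), bond_k = K, bond_r0 = r0,
            exclusions = matrix(c(1, 2), 1), v = v)
}

# n beads on a cubic grid with no bonded terms (mixed types optional)
grid_gas_config <- function(n, box = c(100, 100, 100), spacing = 12,
                            type = 5L, charge = 0, mass = 72) {
  g <- as.matrix(expand.grid(seq(2, box[1] - 2, by = spacing),
                             seq(2, box[2] - 2, by = spacing),
                             seq(2, box[3] - 2, by = spacing)))
  stopifnot(nrow(g) >= n)
  g <- g[seq_len(n), , drop = FALSE]
  cg_config(x = g, box = box, type = rep(type, n), type_names = TN,
            charge = rep(charge, n), mass = rep(mass, n), mol = seq_len(n),
            group = rep("water", n))
}

# random beads with a minimum separation, optional bonded chain over 1..8
random_safe_config <- function(n = 40, box = c(30, 30, 30), min_sep = 3.8,
                               seed = 7, charged = TRUE, chain = TRUE) {
  set.seed(seed)
  X <- matrix(NA_real_, 0, 3)
  while (nrow(X) < n) {
    p <- runif(3, 0, box[1])
    ok <- TRUE
    if (nrow(X) > 0) {
      d <- sweep(X, 2, p)
      d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
      ok <- min(sqrt(rowSums(d^2))) > min_sep
    }
    if (ok) X <- rbind(X, p)
  }
  type <- sample(1:6, n, replace = TRUE)
  chg <- if (charged) c(1, -1, 0, 0, 0, 0)[type] else rep(0, n)
  args <- list(x = X, box = box, type = type, type_names = TN, charge = chg,
               mass = rep(50, n), mol = rep(1L, n), group = rep("lipid", n))
  if (chain) {
    dterms <- cbind(K = c(0.46845, 0.046845, 0.078872, 0.028681),
                    n = 1:4, phi0 = c(pi, 0, 0, 0))
    args <- c(args, list(
      bonds = cbind(1:7, 2:8), bond_k = rep(20.3, 7), bond_r0 = rep(3.3, 7),
      angles = cbind(1:6, 2:7, 3:8), angle_type = rep(c(0L, 1L), 3),
      angle_k = rep(5, 6), angle_theta0 = rep(c(120, 130) * pi / 180, 3),
      dihedrals = cbind(1:5, 2:6, 3:7, 4:8), dihedral_terms = dterms,
      exclusions = cbind(1:7, 2:8)))
  }
  do.call(cg_config, args)
}

# central finite-difference force check; returns worst relative error
fd_force_error <- function(cfg, ff, n_checks = 25, h = 1e-5, seed = 1) {
  e0 <- total_energy_forces(cfg, ff, "brute")
  set.seed(seed)
  err <- 0
  for (k in seq_len(n_checks)) {
    i <- sample(nrow(cfg$x), 1)
    d <- sample(3, 1)
    cp <- cfg; cp$x[i, d] <- cp$x[i, d] + h
    cm <- cfg; cm$x[i, d] <- cm$x[i, d] - h
    fd <- -(total_energy_forces(cp, ff, "brute")$energy$total -
            total_energy_forces(cm, ff, "brute")$energy$total) / (2 * h)
    err <- max(err, abs(fd - e0$forces[i, d]) / max(1, abs(fd)))
  }
  err
}

# synthetic density_profile object (for thickness-extraction tests)
fake_profile <- function(counts, bin_width = 1) {
  structure(list(z = (seq_along(counts) - 0.5) * bin_width,
                 counts = counts, n_frames = 1, bin_width = bin_width,
                 group = "lipid", Lz = length(counts) * bin_width),
            class = "density_profile")
}

# synthetic msd_result object
fake_msd <- function(t, msd, d = 2) {
  structure(list(t = t, msd = msd, d = d, group = "lipid",
                 reference = "com", dims = if (d == 2) "xy" else "xyz"),
            class = "msd_result")
}
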