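# Coarse-grained interaction model: typed beads with shifted Lennard-Jones and
# Coulomb pair terms, harmonic bonds, cosine-squared / harmonic angles and a
# Fourier dihedral for the PEG backbone torsion.

.bead_types <- data.frame(
  name   = c("Q0", "Qa", "Na", "C1", "MW", "EG"),
  mass   = c(72, 72, 72, 72, 72, 44),   # amu; 4:1 heavy-atom mapping, one EG monomer per bead
  charge = c(+1, -1, 0, 0, 0, 0),       # e; choline +, phosphate -
  stringsAsFactors = FALSE
)

# Nonbonded pair parameters; each row may cover several type pairs.
.pair_rows <- list(
  list(types = list(c("Q0","Q0"), c("C1","C1")),                         sigma = 4.7, epsilon = 0.836521),
  list(types = list(c("Qa","Qa"), c("Qa","EG"), c("MW","MW")),           sigma = 4.7, epsilon = 1.195030),
  list(types = list(c("Na","Na"), c("Q0","Na"), c("Qa","Na"), c("Q0","EG")), sigma = 4.7, epsilon = 0.956024),
  list(types = list(c("EG","EG")),                                       sigma = 4.3, epsilon = 0.806644),
  list(types = list(c("Q0","Qa")),                                       sigma = 4.7, epsilon = 1.075527),
  list(types = list(c("Q0","C1"), c("Qa","C1")),                         sigma = 6.2, epsilon = 0.478012),
  list(types = list(c("MW","C1")),                                       sigma = 4.7, epsilon = 0.478012),
  list(types = list(c("Na","C1"), c("EG","C1")),                         sigma = 4.7, epsilon = 0.645316),
  list(types = list(c("Q0","MW"), c("Qa","MW")),                         sigma = 4.7, epsilon = 1.338434),
  list(types = list(c("Na","MW")),                                       sigma = 4.7, epsilon = 0.956024),
  list(types = list(c("EG","Na")),                                       sigma = 4.7, epsilon = 1.075527),
  list(types = list(c("EG","MW")),                                       sigma = 4.7, epsilon = 1.075527)
)

# Fourier dihedral terms for the PEG backbone: K_i (kcal/mol), multiplicity
# n_i, phase phi_0 (degrees).
.dihedral_terms <- data.frame(
  phi0 = c(180, 0, 0, 0),
  K    = c(0.46845, 0.046845, 0.078872, 0.028681),
  n    = c(1, 2, 3, 4)
)

.bonded_defaults <- list(
  bond_dppc  = list(K = 24,   r0 = 4.7),  # kcal/mol/A^2, A
  bond_eg    = list(K = 20.3, r0 = 3.3),
  bond_graft = list(K = 203,  r0 = 3.3),  # stiff harmonic stand-in for the rigid DPPC-PEG link
  angle_dppc = list(K = 3, theta0_qana = 120, theta0_other = 180),  # cosine-squared
  angle_eg   = list(K = 20.3, theta0 = 130)                          # harmonic, K per rad^2
)

#' Coarse-grained force field for DPPC/PEG membranes
#'
#' Builds the full interaction parameter set: the six bead types (charged
#' choline Q0 and phosphate Qa, glycerol Na, apolar tail C1, 4:1-mapped water
#' MW, and one-monomer-per-bead EG), the nonbonded pair table, bonded terms
#' and the global nonbonded settings.
#'
#' Pair interactions use force-shifted forms: the Lennard-Jones force is
#' smoothly taken to zero between \code{shift_onset} and \code{cutoff} and the
#' Coulomb force between 0 and \code{cutoff}, with a uniform relative
#' dielectric \code{eps_r} screening the head-group charges.
#'
#' With \code{solvent = "implicit"} every pair involving an EG bead is
#' replaced by its purely repulsive Weeks-Chandler-Andersen part, so the
#' polymer behaves as an athermal good-solvent chain without explicit water;
#' lipid-lipid attractions are kept so the bilayer remains condensed. With
#' \code{solvent = "explicit"} all pairs keep the full attractive form and MW
#' water beads supply the solvent environment.
#'
#' @param solvent "implicit" or "explicit" solvent convention
#' @param eps_r relative dielectric (dimensionless)
#' @param cutoff nonbonded cutoff, A
#' @param shift_onset radius where the LJ force shift begins, A
#' @return an object of class \code{cg_ff}
#' @export
martini_ff <- function(solvent = c("implicit", "explicit"), eps_r = 15,
                       cutoff = 12, shift_onset = 9) {
  solvent <- match.arg(solvent)
  stopifnot(eps_r > 0, cutoff > 0, shift_onset < cutoff)
  tn <- .bead_types$name
  nt <- length(tn)
  sig <- matrix(NA_real_, nt, nt, dimnames = list(tn, tn))
  eps <- matrix(NA_real_, nt, nt, dimnames = list(tn, tn))
  for (row in .pair_rows) {
    for (pr in row$types) {
      sig[pr[1], pr[2]] <- sig[pr[2], pr[1]] <- row$sigma
      eps[pr[1], pr[2]] <- eps[pr[2], pr[1]] <- row$epsilon
    }
  }
  if (anyNA(sig)) stop("incomplete pair table")
  style <- matrix(0L, nt, nt, dimnames = list(tn, tn))
  if (solvent == "implicit") {
    style["EG", ] <- 1L
    style[, "EG"] <- 1L
  }
  ff <- list(
    bead_types = .bead_types,
    pair_rows = .pair_rows,
    sigma = sig, epsilon = eps, style = style,
    cutoff = cutoff, shift_onset = shift_onset,
    eps_r = eps_r, coul_cutoff = cutoff,
    bonded = .bonded_defaults,
    dihedral_terms = .dihedral_terms,
    solvent = solvent
  )
  class(ff) <- "cg_ff"
  ff
}

#' @export
print.cg_ff <- function(x, ...) {
  cat("Coarse-grained DPPC/PEG force field\n")
  cat(sprintf("  bead types : %s\n", paste(x$bead_types$name, collapse = " ")))
  cat(sprintf("  pair rows  : %d (LJ force-shifted %.1f-%.1f A)\n",
              length(x$pair_rows), x$shift_onset, x$cutoff))
  cat(sprintf("  Coulomb    : eps_r = %g, shifted 0-%.1f A\n", x$eps_r, x$coul_cutoff))
  cat(sprintf("  solvent    : %s\n", x$solvent))
  invisible(x)
}

# matrices + scalars in the layout the compiled kernels expect
ff_to_cpp <- function(ff) {
  list(sigma = unname(ff$sigma), epsilon = unname(ff$epsilon),
       style = unname(ff$style), cutoff = ff$cutoff,
       shift_onset = ff$shift_onset, eps_r = ff$eps_r,
       coul_cutoff = ff$coul_cutoff)
}

# ---- force-shift helpers (R reference implementation of the pair kernels) ----

# coefficients for the shifted r^-p kernel with F(rc)=F'(rc)=0, V(rc)=0
shift_coefs <- function(p, r1, rc) {
  d <- rc - r1
  A <- -p * ((p + 4) * rc - (p + 1) * r1) / (rc^(p + 2) * d^2)
  B <-  p * ((p + 3) * rc - (p + 1) * r1) / (rc^(p + 2) * d^3)
  C <- rc^(-p) - A / 3 * d^3 - B / 4 * d^4
  list(A = A, B = B, C = C)
}

shift_kernel <- function(r, p, r1, rc) {
  cf <- shift_coefs(p, r1, rc)
  phi <- numeric(length(r))
  f <- numeric(length(r))
  inside <- r < rc
  core <- inside & r < r1
  tail <- inside & r >= r1
  phi[core] <- r[core]^(-p) - cf$C
  f[core] <- p * r[core]^(-p - 1)
  dr <- r[tail] - r1
  phi[tail] <- r[tail]^(-p) - cf$A / 3 * dr^3 - cf$B / 4 * dr^4 - cf$C
  f[tail] <- p * r[tail]^(-p - 1) + cf$A * dr^2 + cf$B * dr^3
  list(phi = phi, f = f)
}

#' Shifted Lennard-Jones pair interaction
#'
#' Energy and radial force magnitude of the force-shifted 12-6 interaction:
#' each \eqn{r^{-p}} term is modified between \code{shift_onset} and
#' \code{cutoff} so force and energy go continuously to zero at the cutoff.
#' A positive force means repulsion.
#'
#' @param r pair distance(s), A (> 0)
#' @param params list with \code{sigma}, \code{epsilon}, and optionally
#'   \code{cutoff} (default 12) and \code{shift_onset} (default 9)
#' @return list with vectors \code{energy} (kcal/mol) and \code{force}
#'   (kcal/mol/A)
#' @export
lj_shifted <- function(r, params) {
  if (any(r <= 0)) stop("pair distance must be positive")
  rc <- params$cutoff %||% 12
  r1 <- params$shift_onset %||% 9
  s6 <- params$sigma^6
  k12 <- shift_kernel(r, 12, r1, rc)
  k6 <- shift_kernel(r, 6, r1, rc)
  list(energy = 4 * params$epsilon * (s6^2 * k12$phi - s6 * k6$phi),
       force = 4 * params$epsilon * (s6^2 * k12$f - s6 * k6$f))
}

#' Shifted Coulomb pair interaction
#'
#' Screened point-charge interaction with the force shifted from 0 to the
#' cutoff so both energy and force vanish continuously there.
#'
#' @param r pair distance(s), A (> 0)
#' @param q_i,q_j charges, e
#' @param eps_r relative dielectric
#' @param cutoff cutoff, A
#' @return list with \code{energy} (kcal/mol) and \code{force} (kcal/mol/A)
#' @export
coulomb_shifted <- function(r, q_i, q_j, eps_r = 15, cutoff = 12) {
  if (any(r <= 0)) stop("pair distance must be positive")
  if (eps_r <= 0) stop("eps_r must be positive")
  if (q_i == 0 || q_j == 0)
    return(list(energy = numeric(length(r)), force = numeric(length(r))))
  k1 <- shift_kernel(r, 1, 0, cutoff)
  pref <- .qqr2e * q_i * q_j / eps_r
  list(energy = pref * k1$phi, force = pref * k1$f)
}

#' Harmonic bond potential
#'
#' \eqn{V_b = K_b (r - r_0)^2}.
#'
#' @param r bond length(s), A (> 0)
#' @param params list with \code{K} (kcal/mol/A^2) and \code{r0} (A)
#' @return list with \code{energy} and \code{force} (radial, positive =
#'   repulsive)
#' @export
bond_energy <- function(r, params) {
  if (any(r <= 0)) stop("bond length must be positive")
  dr <- r - params$r0
  list(energy = params$K * dr^2, force = -2 * params$K * dr)
}

#' Cosine-squared angle potential
#'
#' \eqn{V_{a1} = K_{a1} (\cos\theta - \cos\theta_0)^2}, used for the DPPC
#' backbone and tail angles.
#'
#' @param theta angle(s), degrees
#' @param params list with \code{K} (kcal/mol) and \code{theta0} (degrees)
#' @return list with \code{energy} (kcal/mol) and \code{force}
#'   (\eqn{-dV/d\theta}, kcal/mol/rad)
#' @export
angle_cos_sq_energy <- function(theta, params) {
  th <- theta * pi / 180
  c0 <- cos(params$theta0 * pi / 180)
  d <- cos(th) - c0
  list(energy = params$K * d^2,
       force = 2 * params$K * d * sin(th))
}

#' Harmonic angle potential
#'
#' \eqn{V_{a2} = K_{a2} (\theta - \theta_0)^2} with \eqn{\theta} in radians,
#' used for the PEG backbone angle.
#'
#' @param theta angle(s), degrees
#' @param params list with \code{K} (kcal/mol/rad^2) and \code{theta0}
#'   (degrees)
#' @return list with \code{energy} (kcal/mol) and \code{force}
#'   (\eqn{-dV/d\theta}, kcal/mol/rad)
#' @export
angle_harmonic_energy <- function(theta, params) {
  th <- theta * pi / 180
  th0 <- params$theta0 * pi / 180
  list(energy = params$K * (th - th0)^2,
       force = -2 * params$K * (th - th0))
}

#' Fourier dihedral potential
#'
#' \eqn{V_d = \sum_i K_i [1 + \cos(n_i \phi - \phi_{0i})]}, representing the
#' PEG backbone torsion.
#'
#' @param phi dihedral angle(s), degrees
#' @param params data frame with columns \code{K} (kcal/mol), \code{n}
#'   (multiplicity) and \code{phi0} (degrees); defaults to the PEG table
#' @return list with \code{energy} (kcal/mol) and \code{force}
#'   (\eqn{-dV/d\phi}, kcal/mol/rad)
#' @export
dihedral_fourier_energy <- function(phi, params = .dihedral_terms) {
  ph <- phi * pi / 180
  e <- numeric(length(ph))
  f <- numeric(length(ph))
  for (i in seq_len(nrow(params))) {
    arg <- params$n[i] * ph - params$phi0[i] * pi / 180
    e <- e + params$K[i] * (1 + cos(arg))
    f <- f + params$K[i] * params$n[i] * sin(arg)
  }
  list(energy = e, force = f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- parameter file round trip -------------------------------------------

#' Write / read the force-field parameter file
#'
#' Serializes the complete parameterization (bead types, the nonbonded pair
#' rows, bonded terms, dihedral table and global settings) as YAML. The
#' reader validates completeness: all pair rows present exactly once and all
#' dihedral rows intact.
#'
#' @param ff a \code{cg_ff} object
#' @param path file path
#' @return \code{read_ff} returns a \code{cg_ff} object
#' @export
write_ff <- function(ff, path) {
  obj <- list(
    bead_types = ff$bead_types,
    pairs = lapply(ff$pair_rows, function(r)
      list(types = vapply(r$types, paste, "", collapse = "-"),
           sigma = r$sigma, epsilon = r$epsilon)),
    dihedral = ff$dihedral_terms,
    bonded = ff$bonded,
    settings = list(cutoff = ff$cutoff, shift_onset = ff$shift_onset,
                    eps_r = ff$eps_r, solvent = ff$solvent)
  )
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' @rdname write_ff
#' @export
read_ff <- function(path) {
  obj <- yaml::read_yaml(path)
  if (length(obj$pairs) != length(.pair_rows))
    stop("parameter file does not contain the complete pair table")
  if (length(obj$dihedral$K) != 4)
    stop("parameter file does not contain the complete dihedral table")
  ff <- martini_ff(solvent = obj$settings$solvent,
                   eps_r = obj$settings$eps_r,
                   cutoff = obj$settings$cutoff,
                   shift_onset = obj$settings$shift_onset)
  # rebuild the pair table from the file rather than the built-ins
  tn <- ff$bead_types$name
  sig <- matrix(NA_real_, length(tn), length(tn), dimnames = list(tn, tn))
  eps <- sig
  rows <- lapply(obj$pairs, function(p) {
    types <- lapply(strsplit(unlist(p$types), "-", fixed = TRUE), identity)
    list(types = types, sigma = p$sigma, epsilon = p$epsilon)
  })
  for (row in rows) {
    for (pr in row$types) {
      if (!all(pr %in% tn)) stop("unknown bead type in pair row: ", paste(pr, collapse = "-"))
      if (!is.na(sig[pr[1], pr[2]]))
        stop("duplicate pair row: ", paste(pr, collapse = "-"))
      sig[pr[1], pr[2]] <- sig[pr[2], pr[1]] <- row$sigma
      eps[pr[1], pr[2]] <- eps[pr[2], pr[1]] <- row$epsilon
    }
  }
  if (anyNA(sig)) stop("pair table incomplete after reading parameter file")
  ff$pair_rows <- rows
  ff$sigma <- sig
  ff$epsilon <- eps
  dt <- as.data.frame(obj$dihedral)
  ff$dihedral_terms <- dt[, c("phi0", "K", "n")]
  ff$bonded <- obj$bonded
  ff
}
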