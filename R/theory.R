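# Closed-form polymer-physics layer: Flory statistics for isolated grafted
# chains (mushroom regime), the overlap threshold where grafted chains begin
# to interact, mean-field and blob-scaling brush heights, and Rouse-model
# monomer dynamics.

# Overlap criterion prefactor: chains are taken to overlap when the area per
# grafted chain A_l/X_p drops below pi R_F^2 / C_OVERLAP. The O(1) geometric
# constant is pinned by the reference transition value for 45-mer PEG
# (X_p* = 0.014 at a = 4.3 A, fluid-phase A_l = 0.7 nm^2).
.C_OVERLAP <- 1.12

# Default fluid-phase area per lipid (nm^2) used for the transition estimate.
.A_L_FLUID <- 0.7

#' Polymer chain specification
#'
#' @param n_p degree of polymerization (>= 1)
#' @param a monomer radius, A
#' @param chi Flory-Huggins parameter; the excluded volume per monomer is
#'   \eqn{\nu = a^3 (1 - 2\chi)} (athermal default \eqn{\nu = a^3})
#' @return object of class \code{polymer_spec}
#' @export
polymer_spec <- function(n_p = 45, a = 4.3, chi = 0) {
  stopifnot(n_p >= 1, a > 0, chi < 0.5)
  out <- list(n_p = n_p, a = a, chi = chi, nu = a^3 * (1 - 2 * chi))
  class(out) <- "polymer_spec"
  out
}

#' Grafting specification
#'
#' @param X_p lipopolymer molar fraction (0 < X_p <= 1)
#' @param A_l area per lipid, nm^2
#' @return object of class \code{graft_spec}; field \code{D} is the grafting
#'   distance \eqn{D = \sqrt{A_l/X_p}} in nm
#' @export
graft_spec <- function(X_p, A_l = 0.7) {
  stopifnot(X_p > 0, X_p <= 1, A_l > 0)
  out <- list(X_p = X_p, A_l = A_l, D = sqrt(A_l / X_p))
  class(out) <- "graft_spec"
  out
}

#' Flory free energy of a real chain
#'
#' Two-term free energy of an isolated excluded-volume chain of end-to-end
#' size \eqn{R}: a mean-field excluded-volume repulsion
#' \eqn{\nu n_p^2 / R^3} plus the Gaussian stretching entropy
#' \eqn{(3/2) R^2 / (n_p a^2)}, in units of \eqn{k_B T}. Its minimum is at
#' the Flory radius.
#'
#' @param R end-to-end distance, nm
#' @param spec a [polymer_spec()]
#' @return free energy, k_B T
#' @export
flory_free_energy <- function(R, spec) {
  stopifnot(all(R > 0))
  a_nm <- spec$a / 10
  nu_nm <- spec$nu / 1000
  nu_nm * spec$n_p^2 / R^3 + 1.5 * R^2 / (spec$n_p * a_nm^2)
}

#' Flory radius
#'
#' \eqn{R_F = (\nu/a^3)^{1/5} a\, n_p^{3/5}}, reducing to
#' \eqn{a\, n_p^{3/5}} for an athermal solvent. This is the argmin of
#' [flory_free_energy()].
#'
#' @param spec a [polymer_spec()]
#' @return Flory radius, nm
#' @export
flory_radius <- function(spec) {
  (spec$nu / spec$a^3)^(1 / 5) * (spec$a / 10) * spec$n_p^(3 / 5)
}

#' Mushroom-to-brush transition molar fraction
#'
#' Grafted chains begin to overlap when the area per grafted chain
#' \eqn{A_l / X_p} falls below the mushroom footprint
#' \eqn{\pi R_F^2 / C}: \deqn{X_p^* = C\, A_l / (\pi R_F^2)}
#' with the O(1) constant \eqn{C = 1.12} (see Details).
#'
#' @details The transition scales linearly with the area per lipid and
#' decreases with chain length as \eqn{n_p^{-6/5}}. For a 45-mer with 4.3 A
#' monomers and a fluid-phase membrane this evaluates to 0.014.
#'
#' @param spec a [polymer_spec()]
#' @param A_l area per lipid, nm^2 (fluid-phase default 0.7)
#' @return overlap molar fraction (dimensionless)
#' @export
transition_fraction <- function(spec, A_l = .A_L_FLUID) {
  rf <- flory_radius(spec)
  .C_OVERLAP * A_l / (pi * rf^2)
}

#' Brush free energy per chain (mean-field)
#'
#' One-dimensional mean-field free energy of a chain in a brush of thickness
#' \eqn{L} at grafting distance \eqn{D}:
#' \deqn{F/k_BT = 3 \nu n_p^2 / (L D^2) + (3/2) L^2/(n_p a^2)}
#' Its minimum is the mean-field brush height.
#'
#' @param L brush thickness, nm
#' @param spec a [polymer_spec()]
#' @param graft a [graft_spec()]
#' @return free energy, k_B T
#' @export
brush_free_energy <- function(L, spec, graft) {
  stopifnot(all(L > 0))
  a_nm <- spec$a / 10
  nu_nm <- spec$nu / 1000
  3 * nu_nm * spec$n_p^2 / (L * graft$D^2) + 1.5 * L^2 / (spec$n_p * a_nm^2)
}

#' Mean-field brush height
#'
#' Minimizing [brush_free_energy()] over \eqn{L} gives
#' \deqn{L^{MF} = n_p (\nu a^2 / D^2)^{1/3}}
#' linear in \eqn{n_p} and growing as \eqn{X_p^{1/3}} at fixed \eqn{A_l}.
#'
#' @param spec a [polymer_spec()]
#' @param graft a [graft_spec()]
#' @param warn warn when the grafting is below the overlap threshold
#' @return brush height, nm
#' @export
brush_length_mf <- function(spec, graft, warn = TRUE) {
  if (warn && graft$X_p < transition_fraction(spec, graft$A_l))
    warning("X_p below the overlap threshold: brush formulas extrapolated into the mushroom regime")
  a_nm <- spec$a / 10
  nu_nm <- spec$nu / 1000
  spec$n_p * (nu_nm * a_nm^2 / graft$D^2)^(1 / 3)
}

#' Scaling-theory brush height
#'
#' Blob construction: blobs of size \eqn{D} each hold
#' \eqn{g = (D/a)^{5/3}} monomers (athermal), so
#' \deqn{L^{TE} = (n_p / g) D = n_p a (a/D)^{2/3}}
#' The height exponent with respect to the grafting distance is
#' \eqn{m_L = 2/3}, fixed by requiring \eqn{L \propto n_p}. The result
#' coincides with the mean-field height.
#'
#' @inheritParams brush_length_mf
#' @return list with \code{L} (nm) and the exponent \code{m_L}
#' @export
brush_length_scaling <- function(spec, graft) {
  a_nm <- spec$a / 10
  swell <- (spec$nu / spec$a^3)^(1 / 3)  # athermal: 1
  list(L = swell * spec$n_p * a_nm * (a_nm / graft$D)^(2 / 3), m_L = 2 / 3)
}

#' Classify the grafting regime
#'
#' "mushroom" below the overlap fraction, "brush" above, with a "critic"
#' band within \code{tol_band} (relative) of the transition.
#'
#' @inheritParams brush_length_mf
#' @param tol_band relative width of the critic band
#' @return one of "mushroom", "critic", "brush"
#' @export
classify_regime <- function(spec, graft, tol_band = 0.15) {
  xs <- transition_fraction(spec, graft$A_l)
  if (abs(graft$X_p - xs) / xs < tol_band) "critic"
  else if (graft$X_p < xs) "mushroom"
  else "brush"
}

#' Theory summary for a grafted membrane
#'
#' Evaluates the closed-form layer at one composition: Flory radius, overlap
#' fraction, mean-field and scaling brush heights and the regime label.
#'
#' @param n_p degree of polymerization
#' @param a monomer radius, A
#' @param X_p lipopolymer molar fraction
#' @param A_l area per lipid, nm^2
#' @return object of class \code{brush_theory}
#' @export
brush_theory <- function(n_p = 45, a = 4.3, X_p = 0.005, A_l = 0.7) {
  spec <- polymer_spec(n_p = n_p, a = a)
  graft <- graft_spec(X_p = X_p, A_l = A_l)
  sc <- brush_length_scaling(spec, graft)
  out <- list(
    spec = spec, graft = graft,
    R_F = flory_radius(spec),
    X_p_star = transition_fraction(spec, A_l),
    L_MF = brush_length_mf(spec, graft, warn = FALSE),
    L_TE = sc$L, m_L = sc$m_L,
    regime = classify_regime(spec, graft)
  )
  class(out) <- "brush_theory"
  out
}

#' @export
print.brush_theory <- function(x, ...) {
  cat("Grafted-polymer theory summary\n")
  cat(sprintf("  n_p = %d, a = %.2f A, X_p = %g, A_l = %.2f nm^2\n",
              x$spec$n_p, x$spec$a, x$graft$X_p, x$graft$A_l))
  cat(sprintf("  Flory radius R_F        : %.2f nm\n", x$R_F))
  cat(sprintf("  overlap fraction X_p*   : %.4f\n", x$X_p_star))
  cat(sprintf("  grafting distance D     : %.2f nm\n", x$graft$D))
  cat(sprintf("  brush height L (MF=TE)  : %.2f nm (exponent m_L = %.3f)\n",
              x$L_MF, x$m_L))
  cat(sprintf("  regime                  : %s\n", x$regime))
  invisible(x)
}

#' Rouse-chain dynamical specification
#'
#' Collects the parameters of the overdamped bead-spring picture: per-bead
#' friction, entropic spring constant \eqn{k = 3 k_B T / a^2}, bead and
#' chain diffusion coefficients, the mode relaxation time
#' \eqn{\tau_R = \xi n_p^2 a^2 / (3 \pi^2 k_B T)}, and the crossover time
#' \eqn{\tau = \pi \tau_R} at which the exact subdiffusive monomer
#' asymptote \eqn{(12 k_B T a^2 t / \pi \xi)^{1/2}} meets the
#' free-diffusion line \eqn{2 d D t} (so the piecewise prediction is
#' continuous and carries the exact short-time amplitude of the ideal
#' Rouse chain).
#'
#' @param n_p chain length
#' @param a monomer (spring) size, A
#' @param friction per-bead friction rate, 1/fs (velocity damping rate)
#' @param mass bead mass, amu
#' @param temperature K
#' @return object of class \code{rouse_spec}
#' @export
rouse_spec <- function(n_p = 45, a = 3.3, friction = 1e-3, mass = 44,
                       temperature = 300) {
  stopifnot(n_p >= 1, a > 0, friction > 0, mass > 0, temperature > 0)
  kT <- .kB * temperature
  xi <- mass * friction / .ftm2v          # kcal/mol fs / A^2
  out <- list(n_p = n_p, a = a, friction = friction, mass = mass,
              temperature = temperature,
              k_spring = 3 * kT / a^2,
              D_bead = kT / xi,            # A^2/fs
              D_chain = kT / (n_p * xi),
              tau_R = xi * n_p^2 * a^2 / (3 * pi^2 * kT),
              tau = xi * n_p^2 * a^2 / (3 * pi * kT))
  class(out) <- "rouse_spec"
  out
}

#' Rouse-model monomer mean square displacement
#'
#' Piecewise prediction, continuous at the crossover time \eqn{\tau}:
#' subdiffusive \eqn{2 d D \sqrt{\tau t}} for \eqn{t < \tau} (slope 1/2 in
#' log-log), diffusive \eqn{2 d D t} beyond, with \eqn{D} the chain
#' center-of-mass diffusion coefficient.
#'
#' @param t time(s), fs (>= 0)
#' @param spec a [rouse_spec()]
#' @param d spatial dimension
#' @return MSD, A^2
#' @export
rouse_msd_prediction <- function(t, spec, d = 3) {
  stopifnot(all(t >= 0))
  ifelse(t < spec$tau,
         2 * d * spec$D_chain * sqrt(spec$tau * t),
         2 * d * spec$D_chain * t)
}
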