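# Configuration container: positions + periodic box + full bonded topology.

#' Create a configuration object
#'
#' Bundles bead coordinates, the periodic box and the bonded topology into
#' the container the integrator and observables operate on. Most users build
#' configurations with [build_bilayer_patch()], [build_double_membrane()] or
#' [graft_lipopolymers()] rather than calling this directly.
#'
#' @param x N x 3 coordinate matrix, A
#' @param box length-3 box edge vector, A (orthorhombic, fully periodic)
#' @param type integer bead type index into \code{type_names}
#' @param type_names character vector of type labels
#' @param charge,mass per-bead charge (e) and mass (amu)
#' @param mol integer molecule id per bead
#' @param group per-bead group label: "lipid", "peg" or "water"
#' @param bonds,bond_k,bond_r0 bond index pairs (1-based) and parameters
#' @param angles,angle_type,angle_k,angle_theta0 angle triplets, functional
#'   form tag (0 = cosine-squared, 1 = harmonic), constants and equilibrium
#'   angles (radians)
#' @param dihedrals dihedral quadruplets
#' @param dihedral_terms matrix with columns K, n, phi0 (radians)
#' @param exclusions nonbonded exclusion pairs (1-based); bonded 1-2 pairs
#'   must appear here
#' @param v optional N x 3 velocity matrix, A/fs
#' @param meta free-form list (build spec etc.)
#' @return an object of class \code{cg_config}
#' @export
cg_config <- function(x, box, type, type_names, charge, mass, mol, group,
                      bonds = NULL, bond_k = NULL, bond_r0 = NULL,
                      angles = NULL, angle_type = NULL, angle_k = NULL,
                      angle_theta0 = NULL, dihedrals = NULL,
                      dihedral_terms = NULL, exclusions = NULL, v = NULL,
                      meta = list()) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3, length(box) == 3, all(box > 0),
            length(type) == nrow(x), length(charge) == nrow(x),
            length(mass) == nrow(x), all(mass > 0),
            length(mol) == nrow(x), length(group) == nrow(x))
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1L) || any(bonds > nrow(x))) stop("bond index out of range")
  }
  if (!is.null(angles)) {
    angles <- matrix(as.integer(angles), ncol = 3)
    if (any(angles < 1L) || any(angles > nrow(x))) stop("angle index out of range")
  }
  if (!is.null(dihedrals)) {
    dihedrals <- matrix(as.integer(dihedrals), ncol = 4)
    if (any(dihedrals < 1L) || any(dihedrals > nrow(x))) stop("dihedral index out of range")
  }
  if (!is.null(exclusions)) exclusions <- matrix(as.integer(exclusions), ncol = 2)
  cfg <- list(x = unname(x), v = v, box = as.numeric(box),
              type = as.integer(type), type_names = type_names,
              charge = as.numeric(charge), mass = as.numeric(mass),
              mol = as.integer(mol), group = as.character(group),
              bonds = bonds, bond_k = as.numeric(bond_k),
              bond_r0 = as.numeric(bond_r0),
              angles = angles, angle_type = as.integer(angle_type),
              angle_k = as.numeric(angle_k),
              angle_theta0 = as.numeric(angle_theta0),
              dihedrals = dihedrals, dihedral_terms = dihedral_terms,
              exclusions = exclusions, meta = meta)
  class(cfg) <- "cg_config"
  cfg
}

#' @export
print.cg_config <- function(x, ...) {
  cat(sprintf("cg_config: %d beads (%d lipid, %d peg, %d water)\n",
              nrow(x$x), sum(x$group == "lipid"), sum(x$group == "peg"),
              sum(x$group == "water")))
  cat(sprintf("  box  : %.1f x %.1f x %.1f A\n", x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  topo : %d bonds, %d angles, %d dihedrals\n",
              NROW(x$bonds), NROW(x$angles), NROW(x$dihedrals)))
  cat(sprintf("  charge: total %+.1f e\n", sum(x$charge)))
  invisible(x)
}

# layout expected by the compiled kernels
config_to_cpp <- function(cfg) {
  list(x = cfg$x, v = cfg$v, box = cfg$box, type = cfg$type,
       charge = cfg$charge, mass = cfg$mass,
       bonds = cfg$bonds, bond_k = cfg$bond_k, bond_r0 = cfg$bond_r0,
       angles = cfg$angles, angle_type = cfg$angle_type,
       angle_k = cfg$angle_k, angle_theta0 = cfg$angle_theta0,
       dihedrals = cfg$dihedrals, dihedral_terms = cfg$dihedral_terms,
       exclusions = cfg$exclusions)
}

#' Total potential energy and per-bead forces
#'
#' Evaluates every force-field term for a configuration under periodic
#' boundary conditions and minimum-image convention. The default neighbor
#' search uses a cell list; \code{method = "brute"} runs the O(N^2) double
#' loop, useful as a cross-check.
#'
#' @param config a \code{cg_config}
#' @param ff a \code{cg_ff}
#' @param method "cell" or "brute"
#' @return list with \code{energy} (per-term and total, kcal/mol),
#'   \code{forces} (N x 3, kcal/mol/A) and \code{virial_zz}
#' @export
total_energy_forces <- function(config, ff, method = c("cell", "brute")) {
  method <- match.arg(method)
  cpp_compute(config_to_cpp(config), ff_to_cpp(ff), method)
}
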