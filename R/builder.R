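# Deterministic, seeded construction of membrane + lipopolymer configurations.

# 12-bead DPPC template, head bead at the origin, tail extending to z = -20.1:
# zig-zag placement keeps every bond at its equilibrium length while giving a
# ~20 A monolayer so the unrelaxed bilayer is ~4 nm head-to-head.
dppc_template <- function() {
  zz <- 3.35                      # z drop per backbone bond
  xo <- sqrt(4.7^2 - zz^2)        # lateral zig-zag offset (bond length 4.7)
  x <- rbind(
    c(0,  0, 0),                  # 1  Q0 choline (+e)
    c(xo, 0, -zz),                # 2  Qa phosphate (-e)
    c(0,  0, -2 * zz),            # 3  Na glycerol 1
    c(0,  4.7, -2 * zz),          # 4  Na glycerol 2
    c(xo, 0, -3 * zz),            # 5  C1 tail A
    c(0,  0, -4 * zz),            # 6
    c(xo, 0, -5 * zz),            # 7
    c(0,  0, -6 * zz),            # 8
    c(xo, 4.7, -3 * zz),          # 9  C1 tail B
    c(0,  4.7, -4 * zz),          # 10
    c(xo, 4.7, -5 * zz),          # 11
    c(0,  4.7, -6 * zz)           # 12
  )
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5), c(5, 6), c(6, 7),
                 c(7, 8), c(4, 9), c(9, 10), c(10, 11), c(11, 12))
  angles <- rbind(c(2, 3, 4), c(2, 3, 5), c(3, 5, 6), c(5, 6, 7), c(6, 7, 8),
                  c(3, 4, 9), c(4, 9, 10), c(9, 10, 11), c(10, 11, 12))
  theta0 <- c(120, rep(180, 8)) * pi / 180   # Qa-Na-Na bent, others straight
  list(x = x, types = c("Q0", "Qa", "Na", "Na", rep("C1", 8)),
       bonds = bonds, angles = angles, angle_theta0 = theta0,
       span = 6 * zz)
}

#' Build specification for membrane systems
#'
#' Collects the composition and geometry parameters of a membrane build. The
#' defaults encode the reference study conditions: 45-mer PEG with 4.3 A
#' monomers, 0.7 nm^2 per lipid, 16x16 lipids per leaflet.
#'
#' @param n_x,n_y lipids per leaflet edge
#' @param A_l area per lipid, nm^2 (plausibility range 0.4-0.8)
#' @param X_p lipopolymer molar fraction (0-1)
#' @param n_p PEG degree of polymerization
#' @param a PEG monomer radius, A
#' @param geometry "single" or "double" membrane
#' @param gap inner head-to-head distance between the facing leaflets of a
#'   double membrane, A
#' @param solvent "implicit" or "explicit"
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   configuration
#' @return an object of class \code{build_spec}
#' @export
build_spec <- function(n_x = 16, n_y = 16, A_l = 0.7, X_p = 0, n_p = 45,
                       a = 4.3, geometry = c("single", "double"), gap = 90,
                       solvent = c("implicit", "explicit"), seed = 1) {
  geometry <- match.arg(geometry)
  solvent <- match.arg(solvent)
  stopifnot(X_p >= 0, X_p <= 1, n_p >= 1, a > 0, gap > 0,
            n_x >= 2, n_y >= 2)
  if (A_l < 0.4 || A_l > 0.8)
    stop("area per lipid ", A_l, " nm^2 outside the plausible range [0.4, 0.8]")
  out <- list(n_x = n_x, n_y = n_y, A_l = A_l, X_p = X_p, n_p = n_p, a = a,
              geometry = geometry, gap = gap, solvent = solvent,
              seed = as.integer(seed))
  class(out) <- "build_spec"
  out
}

#' Place a single DPPC lipid
#'
#' Returns the 12-bead template translated so its choline head sits at
#' \code{position}, pointing head-up (\code{orientation = +1}) or head-down
#' (\code{-1}), rotated by \code{rot} about the membrane normal.
#'
#' @param position head-bead coordinates, A
#' @param orientation +1 or -1
#' @param rot rotation angle about z, radians
#' @return list with \code{x}, \code{types}, \code{bonds}, \code{angles},
#'   \code{angle_theta0}
#' @export
build_dppc <- function(position = c(0, 0, 0), orientation = 1, rot = 0) {
  tpl <- dppc_template()
  x <- tpl$x
  if (rot != 0) {
    cs <- cos(rot); sn <- sin(rot)
    xy <- x[, 1:2] %*% rbind(c(cs, sn), c(-sn, cs))
    x[, 1:2] <- xy
  }
  if (orientation < 0) x[, 3] <- -x[, 3]
  x <- sweep(x, 2, position, "+")
  tpl$x <- x
  tpl
}

# assemble many lipid fragments into one configuration
assemble_lipids <- function(heads, orientations, rots, box, ff_bonded) {
  tpl <- dppc_template()
  nl <- nrow(heads)
  nb <- 12L
  X <- matrix(0, nl * nb, 3)
  types <- character(nl * nb)
  bonds <- matrix(0L, nl * 11, 2)
  angles <- matrix(0L, nl * 9, 3)
  theta0 <- numeric(nl * 9)
  mol <- integer(nl * nb)
  for (i in seq_len(nl)) {
    frag <- build_dppc(heads[i, ], orientations[i], rots[i])
    o <- (i - 1) * nb
    X[o + 1:nb, ] <- frag$x
    types[o + 1:nb] <- frag$types
    bonds[(i - 1) * 11 + 1:11, ] <- frag$bonds + o
    angles[(i - 1) * 9 + 1:9, ] <- frag$angles + o
    theta0[(i - 1) * 9 + 1:9] <- frag$angle_theta0
    mol[o + 1:nb] <- i
  }
  tn <- .bead_types$name
  type_i <- match(types, tn)
  cg_config(
    x = X, box = box, type = type_i, type_names = tn,
    charge = .bead_types$charge[type_i], mass = .bead_types$mass[type_i],
    mol = mol, group = rep("lipid", nl * nb),
    bonds = bonds, bond_k = rep(ff_bonded$bond_dppc$K, nrow(bonds)),
    bond_r0 = rep(ff_bonded$bond_dppc$r0, nrow(bonds)),
    angles = angles, angle_type = rep(0L, nrow(angles)),
    angle_k = rep(ff_bonded$angle_dppc$K, nrow(angles)),
    angle_theta0 = theta0,
    dihedrals = NULL, dihedral_terms = NULL,
    exclusions = bonds
  )
}

# head positions for one bilayer centered at zc; returns heads, orientations,
# and bookkeeping (leaflet label per lipid)
bilayer_sites <- function(spec, zc, bilayer_id) {
  sp <- sqrt(spec$A_l * 100)              # grid spacing, A
  span <- dppc_template()$span
  gx <- (seq_len(spec$n_x) - 1) * sp
  gy <- (seq_len(spec$n_y) - 1) * sp
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  nl <- nrow(grid)
  up <- cbind(grid, zc + span)
  lo <- cbind(grid[, 1] + sp / 2, grid[, 2] + sp / 2, zc - span)
  heads <- rbind(up, lo)
  heads[, 1:2] <- heads[, 1:2] + matrix(runif(2 * 2 * nl, -0.5, 0.5), ncol = 2)
  heads[, 3] <- heads[, 3] + runif(2 * nl, -0.3, 0.3)
  list(heads = heads,
       orientations = c(rep(1, nl), rep(-1, nl)),
       rots = runif(2 * nl, 0, 2 * pi),
       leaflet = c(rep("upper", nl), rep("lower", nl)),
       bilayer = rep(bilayer_id, 2 * nl))
}

#' Build a flat bilayer patch
#'
#' Two leaflets of DPPC on a jittered square lattice, tails inward, with the
#' lateral box area fixed at \code{n_x * n_y * A_l} per leaflet. The
#' unrelaxed head-to-head thickness is about 4 nm.
#'
#' @param spec a [build_spec()]
#' @param ff a \code{cg_ff} (supplies bonded parameters)
#' @param z_margin vacuum margin above and below the membrane, A
#' @return a \code{cg_config}
#' @export
build_bilayer_patch <- function(spec, ff = martini_ff(spec$solvent),
                                z_margin = 60) {
  if (spec$n_x * spec$n_y < 4) stop("patch too small: need n_x*n_y >= 4")
  sp <- sqrt(spec$A_l * 100)
  if (sp < 7)  # template footprint is ~5 A wide plus bead radii
    stop("area per lipid too small to place the lipid template without overlap")
  span <- dppc_template()$span
  Lz <- 2 * span + 2 * z_margin
  zc <- Lz / 2
  cfg <- with_seed(spec$seed, {
    s <- bilayer_sites(spec, zc, 1L)
    cc <- assemble_lipids(s$heads, s$orientations, s$rots,
                          box = c(spec$n_x * sp, spec$n_y * sp, Lz),
                          ff_bonded = ff$bonded)
    cc$meta <- list(spec = spec, membrane_span = span,
                    lipid_info = data.frame(mol = seq_len(nrow(s$heads)),
                                            leaflet = s$leaflet,
                                            bilayer = s$bilayer,
                                            head_index = (seq_len(nrow(s$heads)) - 1) * 12 + 1))
    cc
  })
  cfg
}

#' Build two parallel bilayers
#'
#' Stacks two bilayer patches separated by \code{spec$gap} (inner head-plane
#' to head-plane distance). The outer surfaces face each other across the
#' periodic z boundary at a fixed small spacing. Use
#' [graft_lipopolymers()] afterwards to decorate the facing leaflets.
#'
#' @inheritParams build_bilayer_patch
#' @return a \code{cg_config}
#' @export
build_double_membrane <- function(spec, ff = martini_ff(spec$solvent)) {
  if (spec$geometry != "double") stop("spec$geometry must be 'double'")
  if (spec$gap <= 0) stop("gap must be positive")
  rf <- flory_radius(polymer_spec(n_p = spec$n_p, a = spec$a)) * 10
  if (spec$X_p > 0 && spec$gap < 2 * rf)
    warning(sprintf("gap %.0f A is below twice the Flory radius (%.0f A): brushes start compressed",
                    spec$gap, rf))
  sp <- sqrt(spec$A_l * 100)
  span <- dppc_template()$span
  t_mem <- 2 * span
  outer <- 12
  Lz <- 2 * t_mem + spec$gap + outer
  zc1 <- outer / 2 + span
  zc2 <- zc1 + t_mem + spec$gap
  box <- c(spec$n_x * sp, spec$n_y * sp, Lz)
  cfg <- with_seed(spec$seed, {
    s1 <- bilayer_sites(spec, zc1, 1L)
    s2 <- bilayer_sites(spec, zc2, 2L)
    heads <- rbind(s1$heads, s2$heads)
    cc <- assemble_lipids(heads, c(s1$orientations, s2$orientations),
                          c(s1$rots, s2$rots), box, ff$bonded)
    nl <- nrow(heads)
    cc$meta <- list(spec = spec, membrane_span = span,
                    lipid_info = data.frame(mol = seq_len(nl),
                                            leaflet = c(s1$leaflet, s2$leaflet),
                                            bilayer = c(s1$bilayer, s2$bilayer),
                                            head_index = (seq_len(nl) - 1) * 12 + 1))
    cc
  })
  cfg
}

#' Graft PEG chains onto membrane lipids
#'
#' Converts a seeded uniform choice of lipids into DPPC-PEG lipopolymers:
#' each selected lipid gains an \code{n_p}-bead EG chain bonded to its
#' choline head by a stiff harmonic link, with harmonic backbone angles and
#' Fourier dihedrals along the chain. The initial conformation is a gentle
#' helix extending away from the membrane. For a single membrane the upper
#' (outer) leaflet is decorated; for a double membrane the two facing inner
#' leaflets are, each receiving \code{round(X_p * n_leaflet)} chains (at
#' least one when \code{X_p > 0}).
#'
#' @param config a membrane \code{cg_config} from the builders
#' @param spec the [build_spec()] used to build it
#' @param ff a \code{cg_ff}
#' @return a new \code{cg_config} including the polymer beads
#' @export
graft_lipopolymers <- function(config, spec, ff = martini_ff(spec$solvent)) {
  if (spec$X_p == 0) return(config)
  info <- config$meta$lipid_info
  if (is.null(info)) stop("configuration lacks lipid bookkeeping; build it with the patch builders")
  if (spec$geometry == "double") {
    targets <- list(info[info$bilayer == 1 & info$leaflet == "upper", ],
                    info[info$bilayer == 2 & info$leaflet == "lower", ])
    dirs <- c(1, -1)
  } else {
    targets <- list(info[info$leaflet == "upper", ])
    dirs <- 1
  }
  b <- 3.3
  dz <- if (spec$geometry == "double")
    min(2.2, max(1.0, 0.55 * spec$gap / spec$n_p)) else 2.2
  lat <- sqrt(b^2 - dz^2)
  golden <- pi * (3 - sqrt(5))

  X <- config$x
  type <- config$type
  charge <- config$charge
  mass <- config$mass
  mol <- config$mol
  group <- config$group
  bonds <- config$bonds; bond_k <- config$bond_k; bond_r0 <- config$bond_r0
  angles <- config$angles; angle_type <- config$angle_type
  angle_k <- config$angle_k; angle_theta0 <- config$angle_theta0
  dihedrals <- config$dihedrals
  eg_id <- match("EG", config$type_names)
  grafted <- integer(0)

  with_seed(spec$seed + 1000L, {
    for (tt in seq_along(targets)) {
      leaf <- targets[[tt]]
      nch <- round(spec$X_p * nrow(leaf))
      if (nch == 0) {
        warning("X_p * leaflet size < 0.5; grafting a single chain")
        nch <- 1L
      }
      sel <- leaf[sample.int(nrow(leaf), nch), , drop = FALSE]
      for (s in seq_len(nch)) {
        anchor_i <- sel$head_index[s]
        anchor <- X[anchor_i, ]
        phase <- runif(1, 0, 2 * pi)
        pos <- matrix(0, spec$n_p, 3)
        pos[1, ] <- anchor + c(0, 0, dirs[tt] * b)
        for (k in 2:spec$n_p) {
          ang <- phase + k * golden
          pos[k, ] <- pos[k - 1, ] + c(lat * cos(ang), lat * sin(ang), dirs[tt] * dz)
        }
        o <- nrow(X)
        idx <- o + seq_len(spec$n_p)
        X <- rbind(X, pos)
        type <- c(type, rep(eg_id, spec$n_p))
        charge <- c(charge, rep(0, spec$n_p))
        mass <- c(mass, rep(.bead_types$mass[eg_id], spec$n_p))
        mol <- c(mol, rep(sel$mol[s], spec$n_p))
        group <- c(group, rep("peg", spec$n_p))
        newb <- rbind(c(anchor_i, idx[1]),
                      cbind(idx[-spec$n_p], idx[-1]))
        bonds <- rbind(bonds, newb)
        bond_k <- c(bond_k, ff$bonded$bond_graft$K,
                    rep(ff$bonded$bond_eg$K, spec$n_p - 1))
        bond_r0 <- c(bond_r0, ff$bonded$bond_graft$r0,
                     rep(ff$bonded$bond_eg$r0, spec$n_p - 1))
        if (spec$n_p >= 3) {
          na <- spec$n_p - 2
          angles <- rbind(angles, cbind(idx[1:na], idx[2:(na + 1)], idx[3:(na + 2)]))
          angle_type <- c(angle_type, rep(1L, na))
          angle_k <- c(angle_k, rep(ff$bonded$angle_eg$K, na))
          angle_theta0 <- c(angle_theta0,
                            rep(ff$bonded$angle_eg$theta0 * pi / 180, na))
        }
        if (spec$n_p >= 4) {
          nd <- spec$n_p - 3
          dihedrals <- rbind(dihedrals,
                             cbind(idx[1:nd], idx[2:(nd + 1)],
                                   idx[3:(nd + 2)], idx[4:(nd + 3)]))
        }
        grafted <- c(grafted, sel$mol[s])
      }
    }
  })
  dterms <- cbind(K = .dihedral_terms$K, n = .dihedral_terms$n,
                  phi0 = .dihedral_terms$phi0 * pi / 180)
  out <- cg_config(
    x = X, box = config$box, type = type, type_names = config$type_names,
    charge = charge, mass = mass, mol = mol, group = group,
    bonds = bonds, bond_k = bond_k, bond_r0 = bond_r0,
    angles = angles, angle_type = angle_type, angle_k = angle_k,
    angle_theta0 = angle_theta0,
    dihedrals = dihedrals, dihedral_terms = dterms,
    exclusions = bonds, meta = config$meta
  )
  out$meta$grafted_mols <- grafted
  out
}

#' Add explicit coarse-grained water
#'
#' Fills the non-membrane volume with MW beads on a jittered cubic lattice at
#' the requested density (the 4:1 water mapping corresponds to about 8.35
#' beads/nm^3). Sites within the exclusion distance of any solute bead are
#' rejected; solute coordinates are untouched.
#'
#' @param config a \code{cg_config}
#' @param density target bead density, beads/nm^3
#' @param exclusion solute exclusion distance, A
#' @param seed jitter seed
#' @return a new \code{cg_config} including water beads
#' @export
solvate <- function(config, density = 8.35, exclusion = 4.0, seed = 1) {
  rho <- density / 1000            # beads per A^3
  spacing <- rho^(-1 / 3)
  box <- config$box
  # mark 2 A voxels within `exclusion` of any solute bead
  res <- 2
  dims <- pmax(ceiling(box / res), 1L)
  occ <- array(FALSE, dim = dims)
  rr <- ceiling(exclusion / res)
  offs <- as.matrix(expand.grid(-rr:rr, -rr:rr, -rr:rr))
  offs <- offs[sqrt(rowSums((offs * res)^2)) <= exclusion + res, , drop = FALSE]
  cellof <- function(p, d) pmin(pmax(floor(p / res) + 1, 1), dims[d])
  for (i in seq_len(nrow(config$x))) {
    p <- config$x[i, ] %% box
    c0 <- floor(p / res) + 1
    cells <- sweep(offs, 2, c0, "+")
    for (d in 1:3) cells[, d] <- ((cells[, d] - 1) %% dims[d]) + 1
    occ[cells] <- TRUE
  }
  nfree <- sum(!occ)
  free_vol <- nfree * res^3
  n_target <- round(rho * free_vol)
  # exact lattice tiling so the site density matches the request
  g <- lapply(1:3, function(d) {
    nd <- max(1, round(box[d] / spacing))
    sp <- box[d] / nd
    seq(sp / 2, box[d] - sp / 4, by = sp)
  })
  sites <- unname(as.matrix(expand.grid(g[[1]], g[[2]], g[[3]])))
  keep <- with_seed(seed, {
    jit <- matrix(runif(length(sites), -0.3, 0.3), ncol = 3)
    sites <<- sites + jit
    cells <- cbind(cellof(sites[, 1], 1), cellof(sites[, 2], 2),
                   cellof(sites[, 3], 3))
    !occ[cells]
  })
  sites <- sites[keep, , drop = FALSE]
  mw <- match("MW", config$type_names)
  n_new <- nrow(sites)
  out <- config
  out$x <- rbind(config$x, sites)
  out$type <- c(config$type, rep(mw, n_new))
  out$charge <- c(config$charge, rep(0, n_new))
  out$mass <- c(config$mass, rep(.bead_types$mass[mw], n_new))
  out$mol <- c(config$mol, max(config$mol) + seq_len(n_new))
  out$group <- c(config$group, rep("water", n_new))
  out$meta$solvent_free_volume <- free_vol
  out$meta$solvent_target <- n_target
  out
}
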