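Package: lipobrush
Title: Coarse-Grained Simulation and Analysis of PEG-Grafted Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale coarse-grained molecular dynamics of DPPC bilayers
    decorated with DPPC-PEG lipopolymers, in the spirit of the MARTINI model:
    a typed bead force field (shifted Lennard-Jones and Coulomb pair terms,
    harmonic bonds, cosine-squared and harmonic angles, Fourier dihedrals),
    Langevin/velocity-Verlet integration with an optional z-direction
    barostat, deterministic seeded builders for single and double membrane
    patches with grafted polyethylene-glycol chains, and trajectory
    observables (z-density profiles and layer thicknesses, radial
    distribution functions and potentials of mean force, multi-origin mean
    square displacements with anomalous-diffusion exponent fits). A
    closed-form polymer-physics layer provides Flory radii, the
    mushroom-to-brush transition, mean-field and scaling brush heights, and
    Rouse-model predictions for comparison with the simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
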