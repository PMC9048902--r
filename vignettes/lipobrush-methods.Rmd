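---
title: "Coarse-grained membranes with grafted PEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained membranes with grafted PEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

lipobrush simulates and analyses DPPC bilayers decorated with DPPC-PEG
lipopolymers at coarse-grained resolution, and provides the polymer-physics
theory needed to interpret the measurements. This vignette records the
models, the numerical choices, and what the desk-scale runs do and do not
demonstrate.

## The interaction model

Beads follow the 4:1 MARTINI-style mapping: choline `Q0` (+e), phosphate
`Qa` (-e), two glycerol `Na` beads and two four-bead `C1` tails make a
12-bead DPPC; `MW` is four-to-one water; one `EG` bead is one ethylene
glycol monomer. Nonbonded interactions are 12-6 Lennard-Jones with the pair
table built into `martini_ff()`, plus Coulomb interactions between the head
charges screened by a uniform relative dielectric (default 15).

Both pair terms use *force-shifted* forms: each $r^{-p}$ term is modified
so force and potential go continuously to zero at the 12 A cutoff (the LJ
force from 9 A, the Coulomb force from 0). The shift polynomials follow the
standard form used by CG membrane force fields,

$$F_p(r) = \frac{p}{r^{p+1}} + A (r-r_1)^2 + B (r-r_1)^3,
  \qquad F_p(r_c) = F_p'(r_c) = 0,$$

with the potential obtained by integration and zeroed at the cutoff. Tests
verify $E(r) = \int_r^{r_c} F\,\mathrm{d}r$ by quadrature.

Bonded terms: harmonic bonds $V_b = K_b (r-r_0)^2$
($K_b = 24\,\mathrm{kcal\,mol^{-1}\,\text{\AA}^{-2}}, r_0=4.7$ A for DPPC;
$20.3, 3.3$ A for EG-EG); cosine-squared angles
$V_{a1} = K_{a1}(\cos\theta - \cos\theta_0)^2$ with $K_{a1}=3$ and
$\theta_0 = 120^\circ$ for the phosphate-glycerol-glycerol angle,
$180^\circ$ otherwise; a harmonic PEG backbone angle
$V_{a2} = K_{a2}(\theta-\theta_0)^2$ with $K_{a2}=20.3$ per rad$^2$ and
$\theta_0 = 130^\circ$ (we take the angle in radians, the common MD
convention); and a four-term Fourier dihedral
$V_d = \sum_i K_i [1 + \cos(n_i\phi - \phi_{0i})]$ for the PEG torsion
($\phi_0 = 180^\circ$ for $n=1$, $0$ otherwise). The rigid DPPC-PEG link is
a stiff harmonic bond ($10\times$ the EG-EG constant) so a single
integrator path serves the whole system; at coarse-grained masses a 10 fs
step tolerates it.

Bead masses are 72 amu for the 4:1-mapped beads and 44 amu for EG (one
monomer); only first bonded neighbours are excluded from nonbonded
interactions (1-3 and 1-4 handling is configurable).

### Implicit solvent

The production analyses run without explicit water, with a Langevin bath
standing in for the solvent. Dispersion attractions between PEG monomers
would then act in vacuum rather than in water, turning a good solvent into
a poor one and collapsing the chains, so in implicit mode every pair
involving `EG` keeps only its repulsive Weeks-Chandler-Andersen part. The
polymer is then an athermal self-avoiding chain — exactly the
$\nu = a^3$ assumption of the Flory treatment used to interpret it — while
lipid-lipid attractions are retained so the bilayer stays condensed.
Explicit `MW` solvation (`solvate()`) is available for comparison work.

## Integration

`run_nvte()` integrates the Langevin equations with the BAOAB splitting,
which reduces exactly to velocity Verlet as the friction goes to zero and
samples configurations accurately at the 10 fs step used throughout. The
default bead friction is $1/\mathrm{ps}$. Nonbonded forces in the dynamics
hot path come from per-type-pair tables linearly interpolated in $r^2$
(1024 nodes); the analytic kernels remain the reference path
(`total_energy_forces()`, minimization) and the finite-difference force
tests run against them. Neighbour search uses a cell-sorted Verlet list
with a 2 A skin, per-type list radii (WCA pairs carry short cutoffs), and
half-skin displacement rebuilds; a brute-force $O(N^2)$ path is kept for
verification and both paths agree to round-off.

`run_npht()` adds a z-direction barostat: the box height is a damped
piston driven by the virial normal pressure against the 1 bar target,
with the lateral area held at the builder's area per lipid. The piston
mass ($2\times10^5$ amu) and damping ($1/50\,\mathrm{ps}$) give smooth,
overdamped approach at desk scale; only the stationary state matters for
the measurements, and stationarity is what the tests assert.

`minimize()` is adaptive steepest descent with a step cap, used only to
remove builder contacts before dynamics.

## Builders

`build_bilayer_patch()` places 12-bead lipids on a jittered square lattice
at the requested area per lipid (default $A_l = 0.7\,\mathrm{nm^2}$, the
ambient-condition value for this system), tails inward, about 4 nm
head-to-head before relaxation. `build_double_membrane()` stacks two such
bilayers with a chosen inner gap; the outer surfaces face each other
across the periodic boundary at close spacing, which mimics a stack and
lets the piston act on the inner, polymer-filled gap.
`graft_lipopolymers()` converts a seeded uniform choice of lipids in the
relevant leaflets (outer leaflet for a single membrane, the two facing
leaflets for a double membrane) into lipopolymers, each receiving
`round(X_p * n_leaflet)` chains and at least one when $X_p > 0$. Initial
chain conformations are gentle helices extending away from the membrane,
spaced to avoid trapped starts. Identical build specification and seed
give bit-identical configurations.

## Observables

- `density_profile()` histograms wrapped z coordinates per group, averaged
  over frames.
- `extract_thickness()` treats the profile as periodic. For a double
  membrane the widest low-density region is the polymer gap; the distance
  between the two facing half-maximum edges of the lipid slabs is the
  inter-membrane distance $d$, and the polymer layer is reported as
  $L = d/2$. Membrane thickness $h$ is the full width at half maximum
  (implemented as half the total width above half maximum, since the outer
  surfaces may touch across the boundary). FWHM was chosen because the
  source data define no edge criterion and it is robust to profile tails.
- `rdf()` computes the shell-normalized pair histogram with minimum-image
  distances (3-D normalization by default; the quasi-2D lipid geometry can
  optionally be analysed laterally), and `effective_potential()` returns
  $U_{\mathrm{eff}}/k_BT = -\ln g(r)$ with empty bins masked rather than
  clipped, to avoid fabricating barrier heights.
- `msd()` is a multi-time-origin mean square displacement on unwrapped
  coordinates; lipids conventionally use molecule centres of mass and
  in-plane displacements ($d=2$), polymers use monomer positions in 3-D
  ($d=3$).
- `fit_anomalous()` fits $\log_{10}$MSD against $\log_{10}t$ on chosen
  windows: the slope is the anomalous exponent $\alpha$ and the intercept
  gives $D_\alpha$ through $\mathrm{MSD} = 2 d D_\alpha t^\alpha$, with
  $1\,\mathrm{\text{\AA}^2/fs^\alpha} = 10^{15\alpha-16}\,
  \mathrm{cm^2/s^\alpha}$.
- `segment_msd()` fits continuous piecewise-linear models (1-3 segments)
  in log-log space and picks the count by BIC, with a small residual floor
  so noiseless synthetic curves do not over-segment.

## Theory layer

For an athermal chain ($\nu = a^3$) the Flory balance of excluded volume
against Gaussian stretching,
$F/k_BT = \nu n_p^2/R^3 + \tfrac32 R^2/(n_p a^2)$, is minimized at
$R_F = a\,n_p^{3/5}$ (4.22 nm for the 45-mer with $a = 4.3$ A). Grafted
chains overlap when the area per chain $A_l/X_p$ falls below the mushroom
footprint; we write the threshold as

$$X_p^* = C\,\frac{A_l}{\pi R_F^2}, \qquad C = 1.12,$$

i.e. an effective footprint radius of $0.94\,R_F$. The $O(1)$ constant is
pinned by the reference transition composition for PEG-2000 on a
fluid-phase membrane ($X_p^* = 0.014$ at $A_l = 0.7\,\mathrm{nm^2}$); the
scaling in $A_l$ and $n_p^{-6/5}$ is what the criterion itself fixes.
Compositions within 15% of $X_p^*$ are labelled "critic", matching the
three-way classification of the reference compositions (0.005 mushroom,
0.014 critic, 0.1 brush).

Above the threshold, the one-dimensional mean-field free energy
$F/k_BT = 3\nu n_p^2/(L D^2) + \tfrac32 L^2/(n_p a^2)$ with grafting
distance $D = \sqrt{A_l/X_p}$ is minimized at
$L^{MF} = n_p (\nu a^2/D^2)^{1/3}$ — linear in $n_p$, growing as
$X_p^{1/3}$. The blob construction gives the same height,
$L^{TE} = n_p a (a/D)^{2/3}$ with exponent $m_L = 2/3$ fixed by requiring
linearity in $n_p$, and the two expressions agree identically (a property
the tests assert exactly). The free-energy prefactors are chosen so the
minima reproduce these standard closed forms.

For dynamics, `rouse_spec()` collects the overdamped bead-spring
parameters: spring $k = 3k_BT/a^2$, bead diffusion $D = k_BT/\xi$, mode
relaxation time $\tau_R = \xi n_p^2 a^2/(3\pi^2 k_BT)$. The monomer MSD
prediction is the exact ideal-chain short-time asymptote
$(12 k_BT a^2 t/\pi\xi)^{1/2}$ switching to $2 d D_{chain} t$ at the
crossover $\tau = \pi\tau_R$ where the two asymptotes meet; a simulated
ideal discrete chain matches it within 10% across the subdiffusive
window. Near $\tau$ the true curve lies above both branches (the internal
modes saturate at $2 R_g^2$ while centre-of-mass diffusion takes over), so
the approach of the monomer exponent to 1 is slow — a point that matters
when reading long-time exponents from finite trajectories.

## Desk-scale study protocols

The packaged reproduction protocols (`membrane_layer_study()`,
`peg_dynamics_study()`) run the full pipeline at sizes a workstation
handles in minutes; the vignette states them as the package's choices.

*Membrane layers.* Double membranes with 8x8 lipids per leaflet (256
lipids, ~3100-3600 beads with polymer), implicit solvent, grafted facing
leaflets at $X_p = 0.005$ (one chain per facing leaflet — the round-up
rule) or $X_p = 0.1$ (six per leaflet). After minimization, 0.25 ns of
NPHT dynamics let the piston settle the inter-membrane distance against
the polymer layers; the structure is averaged over the second half, plus
a 0.2 ns fixed-box NVTE stage for the mushroom runs that also supplies
the lipid mean-square displacements. Initial gaps come from the theory
layer ($2.05 R_F$, resp. $2.1 L^{MF}$) so the piston only has to find
the contact point. Three seeds are averaged. The 8x8 patch is the
smallest that keeps the lateral box (6.7 nm) larger than the grafting
distance in the brush and comparable to the mushroom footprint; mushroom
self-images across the boundary are the main finite-size caveat.

Two systematic offsets of this desk-scale setup are worth naming. The
brush layer equilibrates slowly and with hysteresis (opposing brushes
interdigitate and are slow to re-expand); initializing from the extended
side and equilibrating for 0.25 ns yields $L \approx 5.3$-$5.6$ nm,
below the ~6.4 nm of fully hydrated reference brushes — the
implicit-solvent WCA chain lacks the solvent swelling of PEG in water.
And the CG PEG chain is locally stiff: the fixed $130^\circ$ backbone
angle gives a freely-rotating-chain characteristic ratio near 4.6
(measured end-to-end distance 6.2 nm versus the Flory 4.2 nm), so a
45-mer holds only about ten Kuhn segments and no clean Rouse $t^{1/2}$
window exists between inertia and the chain relaxation time; the
measured short-time monomer exponent is ~0.6-0.7 rather than the ideal
1/2. Both are properties of the model at this scale, and the package
reports the measured values as they come.

*PEG dynamics.* Twenty isolated DPPC-PEG molecules (45-mer chains on
their host lipids) in implicit solvent, 8 ns at the default
$1/\mathrm{ps}$ bead friction — at mushroom grafting densities chains
are dynamically equivalent to isolated ones, and the mobile host lipid
supplies the long-time diffusion the grafted chains actually have. All
nonbonded interactions are purely repulsive in this study: the anchor
lipid acts only as a drag-carrying attachment, and keeping its
amphiphilic attractions would let the dilute molecules aggregate over
nanoseconds. The subdiffusive exponent is fitted on the monomer MSD
between the end of velocity memory ($\approx 20/\xi$) and half the mode
relaxation time; the asymptotic exponent is fitted on the
whole-molecule center-of-mass MSD beyond the theoretical crossover,
with the window capped so every lag retains many time origins.

*What these runs show.* The generator emulates composition, geometry, and
thermodynamic state; it does not emulate explicit hydration water,
membrane undulations of large patches, electrostatics beyond the screened
cutoff form, or liposome curvature. Passing the desk-scale checks shows
the implementation reproduces the model's own physics at reduced size, not
that the model reproduces every property of real PEGylated bilayers.

## Numerical choices and limitations

- 10 fs timestep; blow-up guard aborts when any bead moves over 2 A in a
  step; tabulated pair forces introduce relative errors ~1e-5, well below
  thermal noise, and are bypassed wherever gradients are verified.
- The Berendsen-flavoured piston is the simplest stable semi-isotropic
  control at this scale; its mass and damping affect only the approach.
- Minimization is not a global optimizer; builders are responsible for
  overlap-free starts.
- The BIC segmenter assumes log-spaced, roughly homoscedastic MSD points;
  with fewer than three decades of lag time breakpoints are flagged as
  poorly constrained.
- Single-CPU design; systems beyond ~10^4 beads are out of the intended
  envelope.
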