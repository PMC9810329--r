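---
title: "Active chromatin polymer simulation: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active chromatin polymer simulation: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the model and its assumptions, the parameters that matter,
the numerical choices, and what the test-scale simulations do and do
not demonstrate.

## The physical model

Interphase chromatin is represented as a single bead–spring copolymer
of `N` beads in a spherical cavity whose diameter is fixed at 12
length units.  Working in reduced units — length `l` (117.6 nm when
the cavity models a 50.807 Mbp territory at typical genomic density),
energy `e = kBT` at 310 K (4.28 pN nm), time `tau = eta l^3 / e`
(0.57 ms at nucleoplasmic viscosity 1.5 cP) — each bead represents
about 2.42 kbp of chromatin, sized by close nucleosome packing:
`d = 22 nm * (bp per bead / 200)^(1/3)`, giving 50.5086 nm for the
equal-size (monodisperse) model.  A beads stand for euchromatin, B
beads for heterochromatin; the species appear in random blocks of
`b = 4` beads.

Four potentials act (all pair terms truncated at the 1 l interaction
cutoff):

* **FENE springs** between consecutive beads, spring constant
  `k = 22 e/l^2` and maximum extension `r0` equal to the sum of the two
  bead diameters.
* **Soft Gaussian excluded volume** `eps_vex exp(-alpha_vex r^2)`.
  The width `alpha_vex` is not free: it is the larger root of the
  potential-matching constraint that places the minimum of
  `h_spring + h_vex` exactly at the mean bead diameter, so the bead
  size is dynamically meaningful.  `solve_alpha_vex()` solves this
  transcendental equation by bracketed root finding on the two
  monotone branches around the maximizer `1/rm^2`; the larger root
  (narrower Gaussian) reproduces the tabulated `7.9585 1/l^2`.  For the
  bidisperse preset the three pair-type constants are stored as the
  model's printed values rather than re-derived, because a fresh
  solution of the constraint reproduces them only to about 1–2%; the
  solver is validated on the monodisperse row.
* **Heterochromatin affinity** between B pairs,
  `-eps_HC r^2 exp[-alpha_HC (c - r)^2]` with
  `c = d_B - 1/(alpha_HC d_B)`, whose minimum falls exactly at `d_B` so
  the affinity does not interfere with the bead-sizing criterion.
* **Wall confinement**, the star-polymer/wall potential with
  functionality 2 and corona radius `0.65 d/2`.  The closed form of the
  matching constant is `gamma = sqrt(pi) erfc(kRs) exp(k^2 Rs^2) /
  [kRs (1 + 2 k^2 Rs^2)]`; this is the unique choice that makes the
  potential C1 at the corona radius, which the tests verify to 1e-9.

**Topoisomerase II** acts on proximal A–A pairs (separation at most
1 l, not adjacent along the chain) as a three-state kinetic scheme:
repulsion → attraction (catch, rate `lambda_ra`) → no interaction
(rate `lambda_an = 16.7/tau`) → repulsion (release, rate
`lambda_nr = 500/tau`).  The attraction state mimics the enzyme's
closed clamp pulling two segments together; the no-interaction state
lets them pass through one another — a transient, local phantomness.
The activity `Lambda = lambda_ra (1/lambda_an + 1/lambda_nr)` is the
catch rate times the mean bound duration.

### Independent pair kinetics (a deliberate design choice)

The kinetic scheme is defined per bead pair, with uniform rates and no
budget on simultaneous enzyme events, so this package treats every
eligible pair as an *independent* kinetic process: one bead may be
bound in several pairs at once.  At stationarity a fraction
`(1/lambda_an + 1/lambda_nr) / (1/lambda_ra + 1/lambda_an +
1/lambda_nr)` of the in-range AA pairs is bound, which is what makes
`Lambda` the experimentally meaningful duty-cycle parameter.  The
alternative convention — a bead belongs to at most one bound pair —
is retained as `exclusive_binding = TRUE` for sensitivity studies.  We
do not use it as the default because it caps the bound-pair density at
one partner per bead regardless of `Lambda`: in test-scale runs the
single attracting partner is swamped by the ~50 simultaneous repulsive
neighbours of a dense cavity and the active phase separation signal
vanishes, while the independent-pair reading reproduces it.

### Variants

* `RANR` — the full three-state scheme.
* `RAR` / `RNR` — two-state schemes (catch directly into attraction or
  into no-interaction); with `lambda_nr -> infinity` (or `lambda_an ->
  infinity`) the three-state scheme reduces to them, which the tests
  check distributionally.
* `PHANTOM` — A beads never repel one another (the equilibrium
  self-avoiding-phantom polymer).
* `NONTRANSIENT` — the kinetics is replaced by a permanent AA Gaussian
  whose amplitude is the dwell-time-weighted average of the three
  states, `[(1/l_ra)(+eps) + (1/l_an)(-eps)] / (1/l_ra + 1/l_an +
  1/l_nr)`.  This is one concrete reading of a "non-transient
  attraction comparable to" a given activity; at `Lambda = 0.0309` the
  average is still net repulsive, consistent with that model showing
  no phase separation.
* `PASSIVE` — no enzyme.

## Integration and engine numerics

Positions follow overdamped Langevin dynamics with bead-size-dependent
mobility `1/(3 pi eta d_i)`, integrated by Euler–Maruyama at
`dt = 1e-4 tau`.  The compiled engine uses:

* a linked-cell Verlet list (cutoff + 0.3 l skin) rebuilt when any
  bead has moved half the skin; in slab geometry the x/y axes are
  periodic with minimum-image displacement, falling back to an
  all-pairs scan when the box is too small for a 3-cell stencil;
* cubic-Hermite tables (4096 intervals in `r^2`) for the Gaussian and
  affinity kernels.  Both the energy and its analytic derivative come
  from the same interpolant, so forces are *exactly* the gradient of
  the tabulated energy; the tables deviate from the closed forms by
  ~1e-11, far below thermal noise;
* thermal noise from a Marsaglia polar Gaussian generator driven by
  R's uniform stream (seeded via `set.seed`, hence fully
  reproducible);
* enzyme transitions sampled exactly: per step, the number of firing
  pairs in each kinetic state is Binomial(n, 1 - exp(-lambda dt)) and
  the firing pairs are uniform draws; events on pairs that are
  currently beyond the capture radius (paused) or vetoed by
  exclusivity are discarded.  Because the waiting times are
  memoryless, this thinning reproduces the per-pair Bernoulli process
  exactly at a cost proportional to the number of events.
* A bound pair that separates beyond the capture radius is paused (its
  clock stops) while it remains inside the Verlet list radius
  (1.3 l); a pair that drifts beyond that is dropped from the registry
  and must be re-caught on re-approach.  True indefinite pausing is
  retained in the R-level `kinetics_step()` reference implementation.

Initial conformations are equilibrated *ideal* chains: bond lengths
drawn from the FENE Boltzmann weight by inverse-CDF sampling, uniform
random directions, with resampling of steps that would leave the
cavity.  This is exact for a non-interacting chain and cheaper and
better defined than pre-running a phantom simulation.  Annealing then
relaxes the overlaps; the engine logs a warning when the annealing
mean-square displacement has not exceeded the cavity radius.

A step that would place a bead at or through the wall, or stretch a
bond to its FENE divergence, is a hard error naming the bead and step
— not a silent reflection — so integration failures are loud.

## Analysis definitions

* **Order parameter.**  The cavity is partitioned into cubic cells of
  1 l; each cell's accessible volume fraction `v` is estimated on a
  deterministic midpoint sub-grid (12^3 per cell by default; the total
  accessible volume reproduces the sphere volume to ~0.2%).  Per cell,
  `delta_phi = (nA VA - nB VB)/(nA VA + nB VB)`; the distribution
  `P(delta_phi)` weights cells by `v`, renormalized per snapshot over
  occupied cells (empty cells are 0/0 and are excluded — a documented
  choice), then averages over snapshots.  The Binder cumulant and
  skewness are computed from the raw weighted samples, never from the
  binned histogram, so the 41-bin default is cosmetic.  For spheres
  the grid uses an odd cell count per axis so that one cell sits at
  the cavity center.
* **Nematic order.**  Bonds between consecutive same-species beads,
  assigned to cells by bond midpoint (symmetric and unambiguous),
  accumulated over snapshots; per cell `Q = (3 <u u'> - I)/2` and `S`
  is the eigenvalue of largest magnitude (+1 aligned, -1/2 planar
  isotropic).  The scalar mean excludes the surface shell (cells whose
  center lies within 1 l of the wall) and weights cells by bond count.
* **Foci.**  Single-linkage clustering of B beads at the bead-diameter
  cutoff, implemented as union-find over cell-list neighbor pairs
  (exact); clusters below 2 b members are noise.  Shape metrics come
  from the gyration-tensor eigenvalues; the focus position is the mean
  radial coordinate of its members.
* **Cross-correlation.**  Pearson correlation of per-cell densities at
  matched snapshot indices, normalized by both fields' standard
  deviations (the symmetric form).

## Test-scale simulations: what they show

The full-scale production setting (N = 20992 beads, 2 × 2010 tau) is
available through the presets but is a cluster-scale computation.  The
package's own phenomenology checks run a reduced setting chosen to
keep the complete suite within a desk-scale compute budget: N = 512
beads at the preset's bead density, b = 4, phi_A = 0.5, annealing and
production of 8 tau each at dt = 1e-4, snapshots every 0.25 tau.  The
reduced runs use the slab geometry (periodic x/y, closed z walls, box
2.349 × 2.349 × 4 l): in a 512-bead sphere the wall-free interior
needed for the nematic mean shrinks to a single grid cell and a
passive control shows spurious non-zero order there, whereas the
slab's periodic interior carries ~18 analysis cells at the same bead
count, and the characteristic active features (wall-like A domains
with negative AA bond order near closed walls) are established
features of the slab setting as well.  At this scale the tests assert
*signs and shapes*, not published values: affinity-driven separation
(eps_HC = 4, Lambda = 0) gives a bimodal `P(delta_phi)` with positive
Binder cumulant and near-zero skewness; activity-driven separation
(eps_HC = 0, Lambda = 0.6188) gives a bimodal, clearly skewed
distribution with negative AA nematic order; the phantom variant
separates without negative AA order; and the RNR variant (no
attraction state) shows no negative AA order while RANR and RAR do.
Quantitative magnitudes at this size are not comparable to full-scale
runs — domain sizes are bounded by the box.  What the passing tests
demonstrate is that the implemented mechanism produces the
distinguishing phenomenology of each variant, not that the reduced
system reproduces full-scale magnitudes.

The synthetic-data generators (`make_fixture()`) produce
configurations with *known* analysis limits — two-point fields,
planar or shell-tangent bond sets, collinear and spherical clusters,
Gaussian order-parameter samples — and anchor each analysis operation
to a closed form.  They emulate geometry, not chromatin: passing them
says the estimators are correct, not that real nuclei look like the
fixtures.

## Mean-field module

The lattice model fills `M` sites with self-avoiding B and phantom A'
beads; two A' may overlap into a doublet D, freeing an empty site E,
with doublet fraction `alpha <= 1/2`.  The free energy per site is
mixing entropy plus `f_int = eps [c(a) Phi^2 - 2 c(a) Phi + c(a) +
1/2]`, `c(a) = -a^2 + a - 1/2`.  The package also builds `f_int` from
the underlying pair-energy table (`eps_BB = eps_A'B = eps_A'D = eps`,
`eps_DB = eps_DD = 2 eps`, like pairs half-counted); the algebraic
identity of the two forms to 1e-12 is the module's anchor — the
half-count convention is the unique one under which the stated pair
energies reproduce the closed form.  Minimizing over `alpha` (interior
stationarity `2 log(a/(1-2a)) + eps (1-2a)(1-Phi) = 0`, solved by
bracketed root finding with a grid fallback) yields `alpha* = 1/3` at
`eps = 0` and the reduced curve `f*(Phi)`; its second derivative is
estimated by central differences on the composition grid.  Scanning
`eps` locates the convex-to-concave transition by bisection — the
mean-field statement that phantomness-induced effective attraction
among B beads drives phase separation.  The transition value itself
has no published reference; the tests assert convexity at `eps = 0`
and concavity at the top of a [0, 20] scan.

## Known limitations

* The engine's pause semantics beyond the Verlet radius approximates
  indefinite pausing (see above); at the simulated densities bound
  pairs essentially never separate that far before transitioning.
* Truncating (not shifting) the Gaussian and affinity potentials at
  1 l leaves a force step of at most `2 eps alpha exp(-alpha)` there
  (~0.02 e/l for the monodisperse parameters); the tests document it.
* No hydrodynamic interactions, bending stiffness, or explicit enzyme
  particles; rates are uniform in space.
* The composition-from-imaging helper (`composition_from_rdf()`)
  implements the stated integral estimator and is exercised on
  synthetic curves only; re-deriving the bidisperse composition from
  microscopy data is out of scope.
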