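# chromactive

Brownian-dynamics simulation of interphase chromatin as a confined
random multiblock copolymer driven out of equilibrium by
Topoisomerase-II activity, with the analysis suite and mean-field
theory needed to characterize the resulting microphase separation.

## The model

A chromatin territory is coarse-grained into `N` beads — euchromatic
(A) and heterochromatic (B) — appearing in random blocks of `b` beads
along one chain, confined to a spherical cavity of diameter 12 ℓ
(ℓ = 117.6 nm; energies in e = k\_BT at 310 K; time in
τ = ηℓ³/e = 0.57 ms at nucleoplasmic viscosity 1.5 cP).  Each bead obeys
the overdamped Langevin equation

    dx_i/dt = -∇H_i / (3πη d_i) + sqrt(2 k_BT / (3πη d_i)) ζ(t)

integrated by Euler–Maruyama at dt = 10⁻⁴ τ, with

    H = H_spring + H_vex + H_HC + H_confinement

* `H_spring` — FENE bonds, `-½ k r₀² ln(1-(r/r₀)²)`, `k = 22 e/ℓ²`,
  `r₀` the sum of the bonded bead diameters;
* `H_vex` — a soft Gaussian `± ε_vex exp(-α_vex r²)` truncated at 1 ℓ,
  whose width is fixed by requiring the minimum of `h_spring + h_vex`
  at the mean bead diameter (`α_vex = 7.9585 ℓ⁻²` for the monodisperse
  model);
* `H_HC` — a short-range B–B affinity with its minimum exactly at the B
  bead diameter, amplitude `ε_HC`;
* `H_confinement` — a star-polymer/wall potential, C¹-matched at the
  corona radius.

Topoisomerase II is modelled as a catch-and-release kinetic scheme on
proximal A–A pairs: each pair within 1 ℓ is caught at Poisson rate
λ_ra, whereupon its steric repulsion flips to attraction
(`h_vex < 0`), decays to a no-interaction state at rate λ_an
(`h_vex = 0`, letting the chains pass through each other), and is
released at rate λ_nr.  The dimensionless activity is
`Λ = λ_ra (1/λ_an + 1/λ_nr)`; with the fixed λ_an = 16.7 τ⁻¹ and
λ_nr = 500 τ⁻¹, catch rates 10 and 0.5 τ⁻¹ give Λ = 0.6188 and
0.0309.  Model variants: two-state schemes (RAR, RNR), a
self-avoiding-phantom polymer (A beads never repel each other), a
non-transient cycle-averaged attraction, a passive model, and a slab
geometry (periodic x/y, closed z walls).

Analyses implemented: the per-cell composition order parameter
`Δφ = (n_A V_A - n_B V_B)/(n_A V_A + n_B V_B)` on a cubic grid with
accessible-volume weights, its distribution `P(Δφ)` with Binder
cumulant `1 - ⟨Δφ⁴⟩/3⟨Δφ²⟩²` and skewness; local nematic order of AA
or BB bonds (largest-magnitude eigenvalue of `Q = (3ûû - I)/2`);
heterochromatin-focus segmentation by single-linkage clustering with
gyration-tensor radius and shape anisotropy κ²; surface localization;
radial densities; density cross-correlations between runs.  A lattice
mean-field model of phantom/self-avoiding mixtures (doublet fraction
α, free energy per site, critical α\*, convex→concave transition of
f\*) explains why transient phantomness alone drives phase separation.

## Worked example

```r
library(chromactive)

params <- monodisperse_params(N = 512, phi_A = 0.5, eps_HC = 0,
                              lambda_ra = 10)      # Lambda = 0.6188
seq    <- generate_sequence(512, b = 4, phi_A = 0.5, seed = 1)
state  <- init_conformation(seq, params, seed = 2)
traj   <- run_bd(state, params,
                 bd_protocol(dt = 1e-4, anneal_duration = 10,
                             production_duration = 10,
                             snapshot_interval = 0.25, seed = 3))

grid <- build_grid(params$geometry)
ops  <- order_param_stats(traj, grid)
ops
#> <order_param_stats> 40 snapshot(s): Binder = 0.4915, skewness = 0.3939
glance(traj)
#> # A tibble: 1 x 7
#>   n_frames n_beads variant activity eps_HC anneal_msd mean_bound_pairs
#>      <int>   <int> <chr>      <dbl>  <dbl>      <dbl>            <dbl>
#> 1       40     512 RANR       0.619      0       1.46            6012.
```

The strongly bimodal, asymmetric `P(Δφ)` — positive Binder cumulant
with clearly non-zero skewness — is the scaled-down signature of
Topoisomerase-driven microphase separation; a passive run
(`lambda_ra = 0`) at `eps_HC = 0` shows a near-Gaussian distribution
with Binder cumulant near zero.  (At this short annealing span the
engine also warns that the annealing mean-square displacement is
below the cavity radius — full-scale runs anneal for 2010 τ.)
`autoplot(ops)` draws the distribution; `tidy()`/`glance()` return
results as tibbles.

A command-line interface wrapping the same functions ships at
`inst/cli/chromactive` (subcommands `derive-params`, `simulate`,
`analyze {delta-phi|nematic|foci|surface|radial|xcorr}`, `meanfield`,
`make-fixture`), reading and writing extended-XYZ trajectories with
JSON sidecars.

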