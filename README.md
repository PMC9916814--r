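# dendromicelle

Scheutjens–Fleer self-consistent field (SF-SCF) modelling of the
self-assembly of hybrid amphiphiles built from one charged polylysine
dendron head (generation *G*, with 2^(G+1) terminal NH3+ groups) and *t*
linear hydrophobic tails of *Nt* CH2 segments, in salt solution.  The
package is for polymer/colloid scientists who want a tested, scriptable
lattice mean-field pipeline for dendron-based micelles: thermodynamics
(grand potential, chemical potential, aggregation number, critical
micelle concentration, sphere/cylinder/lamella comparisons), structure
(core radius, corona thickness, area per dendron), and corona
electrostatics (cumulative charge, effective radius and charge, zeta
potential, two-population stratification diagnostics).

## The method in brief

Molecules are trees of united-atom segments (seven kinds: W, C, NH3+,
NH, O, Na, Cl) with Flory–Huggins contact interactions χ_XY, fixed
valencies and permittivities.  On a 1D lattice of concentric layers
(planar / cylindrical / spherical; layer volumes L(r), simple-cubic step
probabilities λ±(r) with curvature corrections) the chain statistics are
computed by first-order Markov propagators over the molecular tree,

    G(r, s) = G_X(r) ⟨G(·, s−1)⟩(r),   ⟨f⟩(r) = λ−f(r−1) + λ0 f(r) + λ+f(r+1),

combined at branch points by the composition law.  Segment potentials

    u_X(r) = α(r) + Σ_Y χ_XY (⟨φ_Y⟩(r) − φ_Y^b) + ν_X ψ(r)

couple contacts, incompressibility (α) and electrostatics (ψ from the
flux-form discrete Poisson–Boltzmann equation with ε(r) = Σ φ_X ε_X),
and are iterated to self-consistency (residual ≤ 1e−7) with Anderson
acceleration and a χ-ramp nucleation protocol for micellar states.
Micelle thermodynamics follows the small-systems route: the excess
grand potential Ω(n_agg) of a single aggregate in a canonical cell
rises to a maximum (the cmc) and decays through Ω = 0, which defines
the most probable micelle; morphologies are compared through the
chemical potential at Ω = 0.

## Worked example

A two-tailed generation-1 surfactant (the package default molecule) in
0.1 M salt, scanned over the surfactant amount in a spherical cell:

```r
library(dendromicelle)
mol <- build_molecule(G = 1, t = 2, Nt = 15)
print(mol)
#> <chain_graph> dendron G=1 with 2 tail(s) of Nt=15
#>   55 segments (25 dendron + 30 tail), 4 charged terminals

lat <- make_lattice("spherical", 40)
cv <- scan_micelles(mol, lat, thetas = c(10, 20, 28, 35) * n_segments(mol),
                    keep_states = TRUE, max_iter = 8000)
round(cv[, c("theta", "n_agg", "Omega", "mu")], 4)
#>   theta n_agg   Omega     mu
#> 1   550    10 20.7502 3.5139
#> 2  1100    20 28.2333 3.4120
#> 3  1540    28 -8.8025 5.1407
#> 4  1925    35 -1.1569 4.8269

(mic <- find_micelle(cv))
#> <micelle_thermo> n_agg = 26.099, mu_surf = 4.7299 kT,
#>                  phi_b = 3.065e-10, phi_cmc = 6.762e-11
```

Ω(n_agg) rises (pre-micellar work of formation), peaks near n ≈ 20 (the
critical micelle concentration is the bulk fraction there) and decays
through zero: the equilibrium micelle holds ~26 molecules.  Structure
and electrostatics of the state nearest the crossing:

```r
st <- attr(cv, "states")[[which.min(abs(cv$n_agg - mic$n_agg))]]
core_metrics(st)
#> <micelle_metrics> n_agg 28.00 | Rcore 4.74 (1.42 nm) |
#>                   Hshell 3.24 (0.97 nm) | s 10.10 | Nterm 112.0
charge_analysis(st)
#> <charge_analysis> 1 maximum(a) of Q | Reff 8.50 |
#>                   Qeff 13.52 / Qbare 112.00 | zeta 27.4 mV
```

A 1.4 nm hydrophobic core carries a ~1 nm corona; the cumulative charge
Q(r) has a single maximum (a classical double layer: of the 112 bare
terminal charges only ~14 remain uncompensated at the effective radius,
giving a zeta potential of ~27 mV).  Repeating this at G = 4 with long
tails (`build_molecule(4, 2, 60)`) produces *two* maxima of Q(r) and a
two-population (stratified) corona — see
`stratification_report()` and the vignette.

## Command line

```sh
Rscript inst/cli/dendromicelle.R --config study.cfg --out results/
```

with a plain-text sectioned key–value configuration (see
`?read_config`); modes: `single`, `scan`, `morphology`, `diagram`,
`stratification`.  Outputs are fixed-format CSV profiles/scan tables
plus machine-readable JSON summaries.

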