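---
title: "Lattice self-consistent field modelling of dendron-tail micelles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice self-consistent field modelling of dendron-tail micelles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Hybrid amphiphiles made of one charged polylysine dendron (generation $G$,
$2^{G+1}$ terminal $\mathrm{NH_3^+}$ groups) and $t$ linear hydrophobic
tails of $N_t$ CH$_2$ units self-assemble in salt solution into micelles
whose morphology, size and corona electrostatics depend on $(G, t, N_t)$.
`dendromicelle` implements the numerical Scheutjens--Fleer self-consistent
field (SF-SCF) machinery needed to study this self-assembly on a
one-dimensional curved lattice: chain propagators on the branched
molecular graph, Flory--Huggins contact interactions, Poisson--Boltzmann
electrostatics with a composition-dependent dielectric, and the
small-systems thermodynamics that turns converged field solutions into
aggregation numbers, critical micelle concentrations and morphology
diagrams.

# Model

## United-atom molecule

Seven segment kinds are distinguished: water `W`, hydrophobic carbon `C`
(CH/CH$_2$/CH$_3$), the charged terminal amino group `NH3+`, the neutral
polar groups `NH` and `O`, and monovalent ions `Na` (co-ion) and `Cl`
(counterion).  Each carries a valency and a relative permittivity; a
symmetric Flory--Huggins matrix $\chi_{XY}$ (zero diagonal) holds the
contact energies.  The defaults (`default_interactions()`) are the
parameter set the package is calibrated to: the driving force is
$\chi_{C,W} = 1.2$; NH and O are hydrated ($\chi_{,W} = -0.6$); all head
groups and ions are expelled from hydrocarbon ($\chi_{C,X} = 2$ or 3).

The lysine dendron is a binary tree of repeat units with deliberately
*unequal* arms: a short arm on the alpha-amino side (`NH`, `C`, `O`
between branch points) and a long arm on the epsilon-amino side (four
extra `C` before the amide), ending at generation $G$ in `NH3+` (the long
terminal arm keeps its four CH$_2$ spacers).  The exact per-residue
counts are not uniquely fixed by a united-atom picture, so
`build_molecule()` takes the template as an argument
(`lysine_repeat_unit()` is the documented default); what the analysis
relies on is only the *contour-length asymmetry*, which gives $G+2$
distinct root-to-terminal contour classes.

## Lattice and fields

The lattice is a stack of $M$ concentric layers (planar, cylindrical or
spherical), layer volumes $L(r)$ and simple-cubic step probabilities
$\lambda_\pm(r) = \tfrac16 A(r_\pm)/L(r)$ with curvature corrections from
the contact areas, so that $\lambda_- + \lambda_0 + \lambda_+ = 1$ and
the detailed flux balance $L(r)\lambda_+(r) = L(r{+}1)\lambda_-(r{+}1)$
holds exactly.  Chain statistics follow from first-order Markov
propagators over the molecular tree (leafward and rootward passes
combined at branch points by the composition law), implemented in C++
with per-node rescaling so that molecules of hundreds of segments in
strong fields cannot under- or overflow.  The propagators are validated
against exhaustive conformation enumeration on small trees.

The electrostatic potential $\psi$ (units $kT/e$) solves the flux-form
discrete Poisson equation with interface permittivities averaged
arithmetically, $\varepsilon(r) = \sum_X \phi_X(r)\,\varepsilon_{rX}$
linearly mixed, a zero-field inner boundary and $\psi(M)=0$ outside.
The dimensionless prefactor is $e^2/(\varepsilon_0 k T b)$ with
$b = 3\times10^{-10}$ m, which reproduces the Bjerrum length of water
(0.70 nm) on the lattice.

## Water as a cluster

Water is modelled as a compact cluster of `solvent_size = 5` sites (a
short `W` chain), not a single site.  This follows the united-atom
membrane parameterisation the interaction table originates from, and it
is load-bearing: with monomeric water and $\chi_{C,W}=1.2$ the model
fails qualitatively (an SDS-like reference surfactant refuses to
micellise even five-fold above its experimental cmc, and the dendron
systems aggregate as dimers).  With cluster water the same reference
surfactant gives $n_{agg}\approx 60$ at a bulk fraction of
$9\times10^{-4}$ ($\approx 9$ mM with the $[\mathrm{M}] = 10\,\phi$
calibration), the experimental scale.  `solvent_size` is a field of
`system_spec()` for sensitivity studies.

## Solving the SCF equations

`solve_scf()` iterates the segment potentials in exchange/pressure form
$u_X = w_X + \xi$: the bounded exchange fields relax damped towards
$\sum_Y \chi_{XY}(\langle\phi_Y\rangle - \phi_Y^b) + \nu_X\psi$, while
the pressure field $\xi$ is driven strongly by $\ln\sum_X\phi_X$
(incompressibility).  Solvent responds explicitly, and the ions respond
*inside* a nonlinear Poisson--Boltzmann Newton solve each sweep, which
removes the stiffest electrostatic feedback.  Anderson (DIIS)
acceleration with a trust region handles the terminal convergence;
default tolerance $10^{-7}$ on the maximum residual.

Micelles are metastable objects in a canonical cell, so plain iteration
from a cold start finds only the homogeneous solution.  Nucleation is
done by continuation: the solver first converges with $\chi_{C,W}$
raised by 0.6 (and a weak pinning well for the tails), then walks
$\chi_{C,W}$ back down in three steps.  Scans over the surfactant amount
(`scan_micelles()`) warm-start consecutive points and re-nucleate once
if a warm start falls off the micellar branch.

## Thermodynamics

With the surfactant amount $\theta$ fixed (canonical cell), the
aggregation number is the excess $n_{agg} = (\theta - V\phi^b)/N$.  The
excess grand potential $\Omega$ (work of micelle formation, no
translational term) is computed two ways: a layer-resolved field
expression, and the bookkeeping route $F - \sum_c \mu_c n_c$.  Two
chemical-potential conventions are provided: the textbook multicomponent
Flory--Huggins form (used for reporting and for morphology
comparisons), and the exact derivative of the free-energy functional,
which differs by the species constant $1 - \tfrac{N_c}{2}f_c^T\chi f_c$
and under which the bulk lattice pressure vanishes identically.  Only
the second makes $\Omega$ exact; the test-suite verifies the small-systems
identity $d\Omega/d\mu = -n_{agg}$ along micellar branches to a few
percent, which ties $\Omega$, $\mu$ and $n_{agg}$ together without
reference to the implementation.

The most probable micelle is the $\Omega = 0$ crossing on the decaying
side of $\Omega(n_{agg})$; the bulk fraction at the $\Omega$ maximum is
the critical micelle concentration.  Morphologies (sphere; cylinder per
unit length; lamella per unit area) are compared through the intensive
$\mu$ at $\Omega = 0$; transitions are bracketed on the tail-length grid
and interpolated linearly.

## Observables

`core_metrics()` defines the core radius as the volume-weighted
second-moment radius $[\int w(r) r^2 \mathrm{d}V / \int w
\mathrm{d}V]^{1/2}$ of the *excess tail-segment* distribution (for a
sharp sphere of radius $R$ this gives $\sqrt{3/5}\,R$), $R_m$ likewise
over the charged terminals, $H_{shell} = R_m - R_{core}$, and the area
per dendron $s = 4\pi R_{core}^2/n_{agg}$.  `charge_analysis()` forms
the lattice version of the shell charge $q(r)$ (excess charge per
layer, bulk composition subtracted so the cumulative charge $Q(r)$
closes at zero), locates the right-most maximum of $Q$ as the effective
radius, and reports $Q_{eff}$, $Q_{eff}/Q_{bare}$ and the zeta potential
$\psi(R_{eff})\,kT/e$.  Maxima are counted on raw lattice profiles with
plateau handling, a $10^{-8}$ noise floor and a 1% prominence cut.
`stratification_report()` splits the corona distributions by terminal
contour class, by branch-point sub-generation and by segment
sub-generation, flagging two-population (bimodal) profiles.

# What the synthetic systems do and do not establish

All tests run on molecules built in code; there is no external data.
The toy fixtures (`make_fixture()`) exercise every code path in seconds:
linear diblocks, symmetric dendrons (single contour class), the
enumeration tree set for the propagator oracle, and hand-built charge
profiles with known maxima.  A green suite establishes internal
correctness (propagator exactness, Gauss-law and Debye--Hueckel limits,
thermodynamic identities, invariants on converged states) and the
paper-level qualitative structure (single vs double cumulative-charge
maxima, trend directions with $N_t$, $t$, $N_t\,t$).  It does *not*
establish quantitative agreement with any particular experiment: the
absolute aggregation numbers here are smaller than those reported for
comparable systems in the literature, because the exact united-atom
segment counts and lattice conventions behind published SF-SCF results
are not recoverable from print (see the README and the package's test
tolerances for what is actually asserted).

# Numerical choices

* Convergence: max residual $10^{-7}$; iteration cap 50 000; Picard
  damping 0.1 on the exchange fields, gain 0.7 on the pressure field;
  Anderson depth 8 from iteration 50; trust region 1 kT per component.
* Nucleation ramp: $\Delta\chi_{C,W} = 0.6, 0.3, 0.15, 0$ with a
  $-1\,kT$ tail well (radius from the tail amount, capped at $0.35 M$)
  during the first stage only.
* Scan grids: geometric in $\theta$, `theta_grid()` defaults to 12
  points per decade; the test-suite uses deliberately reduced 3-6 point
  grids and documents that choice inline.
* Boundaries: mirror at the centre, bulk (Dirichlet $\psi = 0$, bulk
  composition) at $M$; profiles at the outer layers are checked against
  the bulk fractions at $10^{-7}$.
* Degenerate inputs: hydrophilic-only molecules converge to the
  homogeneous solution and are reported as "no micelle"; $\Omega$
  crossings with $n_{agg} \le 0.5$ or barrier $\le 10^{-6}\,kT$ are
  treated as numerical noise, not micelles.

# Known limitations

* One-dimensional lattices only: no bicontinuous or faceted aggregates,
  no inter-micelle interactions (dilute limit).
* Fixed charges (low-pH limit): no annealed protonation equilibria.
* The corona stratification at $G = 4$ reproduces the two-population
  structure, but with smaller aggregation numbers than the published
  figures; the two shortest terminal contour classes are not
  individually bimodal at the equilibrium micelle.
* Spherical micelles do not form at every composition for which the
  published diagrams report them (e.g. $G = 3$, $t = 2$, $N_t = 15$
  dissolves here); the morphology boundary *directions* are reproduced
  where they exceed the numerical resolution of the
  chemical-potential comparison.
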