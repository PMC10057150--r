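---
title: "Parameterizing boronate covalent warheads: model, fitting, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameterizing boronate covalent warheads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boronfit)
```

## The problem

Boronic-acid warheads bind serine hydrolases covalently: the boron
center accepts the catalytic serine Oγ and switches from trigonal sp²
to tetrahedral sp³. Standard small-molecule force fields (GAFF) and
protein force fields (ff14SB) describe each side of that bond but not
the bond itself, so a classical simulation of the covalent complex has
no parameters for the boron-centered bonds, angles and — most
importantly — torsions. The practical workflow is: take bond and angle
constants for the boron center from the boronic-acid force-field
literature, and fit the torsion (dihedral) Fourier terms to quantum
single-point energies computed over a set of conformers of the small
covalent adduct. `boronfit` implements that workflow end to end,
together with the analyses used to validate the result.

## Energy model

The bonded energy is the AMBER functional form: harmonic bonds
$K_r(r-r_\mathrm{eq})^2$ (kcal mol⁻¹ Å⁻², Å), harmonic angles
$K_\theta(\theta-\theta_\mathrm{eq})^2$ with $K_\theta$ per radian²
while $\theta_\mathrm{eq}$ is stored in degrees (the unit convention of
the printed parameter tables; conversion happens at evaluation), and
torsions

$$E_\phi = \frac{V_n}{\mathrm{divider}}\bigl(1 + \cos(n\phi - \gamma)\bigr)$$

with $\phi$ and $\gamma$ in degrees, converted together to radians
inside the cosine. Improper torsions use the same form with the central
atom third in the atom-type key and are instantiated only where an
explicit improper key matches an atom with exactly three neighbors —
there is no automatic planarity detection. Optional nonbonded terms are
point-charge Coulomb (332.0522173 kcal Å mol⁻¹ e⁻²) plus 12-6
Lennard-Jones with Lorentz–Berthelot combination, 1-2/1-3 exclusion and
1-4 scaling (1/1.2 electrostatic, 1/2.0 van der Waals), with no cutoff:
the intended systems are single gas-phase molecules of a few dozen
atoms.

### Literal real-valued periodicities

The fitted boronate library prints periodicities like $n = -1.001$,
$0.129$ or $1.5$. `boronfit` stores and evaluates these literally. Two
consequences are worth understanding:

* the sign matters: $\cos(-a\phi-\gamma) = \cos(a\phi+\gamma)$, which
  differs from $\cos(a\phi-\gamma)$ unless $\gamma \in \{0, 180\}$, so
  folding the sign away would change the energy;
* for non-integer $|n|$ the term is not 360°-periodic in $\phi$, so the
  energy has a branch cut at $\phi = \pm 180°$ (we report torsions on
  $(-180°, 180°]$). A torsion sitting exactly on the cut is numerically
  unstable under rigid-body motion; the toy fixtures therefore place
  rotatable substituents whose torsions resolve to non-integer-$n$ keys
  at 160° rather than the exact anti orientation.

The standard frcmod convention, in which a negative periodicity is a
continuation flag for multi-term series, is confined to the `"strict"`
export dialect of `write_frcmod()`; the default `"literal"` dialect
writes periodicities as stored (4 decimals for barrier and phase, 3 for
periodicity) and round-trips the library bit-exactly at that precision.
Strict export rounds $|n|$ to the nearest nonzero integer and warns
when the rounding error exceeds 0.5.

### Parameter store conventions

Lookups are symmetric under key reversal. Duplicate identical rows
collapse to one; rows sharing a key with different coefficients are
kept as additive Fourier terms — the AMBER norm for multi-term torsion
series, and the documented interpretation of the two printed
`oh-b-c3-h1` rows (silent overwrite would discard printed data).
Wildcards `X` are supported in the first and fourth positions only,
and resolve only when no exact or reversed entry matches, so shipping
generic ring/single-bond fallbacks can never shadow a fitted term.

## The fitting objective

Given $N$ conformers with quantum energies $E_{QM,i}$ and
molecular-mechanics energies $E_{MM,i}(\boldsymbol\theta)$ under the
floating torsion parameters $\boldsymbol\theta$, the objective is

$$f = \sum_{i=1}^{N}\bigl(E_{MM,i} - E_{QM,i} + K\bigr)^2 .$$

The constant $K$ aligns the two absolute energy scales and depends only
on molecule and structure set; for fixed $E_{MM}$ its unique minimizer
is $K = \overline{E_{QM}} - \overline{E_{MM}}$ (set the derivative to
zero). `boronfit` profiles $K$ out analytically — the residual vector
is centered at every evaluation — rather than exposing it to the
optimizer. This removes an exactly flat direction and improves
conditioning, and it guarantees the reported $K$ is optimal for the
returned parameters (a property the test suite checks against a grid
search). $R^2$ is computed between $E_{MM}+K$ and $E_{QM}$.

### Optimizer choices

* engine: Levenberg–Marquardt (`minpack.lm::nls.lm`) with box bounds,
  relative-$f$ convergence tolerance $10^{-10}$, at most 500
  iterations; the accepted-step objective trace is monotone
  non-increasing and is kept in the diagnostics;
* floating parameters: per term, any of $V_n$, $\gamma$, $n$. $n$
  floats by default (`fit_n_continuous = TRUE`, matching the
  non-integer printed values) with default bound $|n| \le 6$; $V_n$ is
  bounded to ±100 kcal/mol; $\gamma$ is effectively unconstrained
  during optimization and reported wrapped to $[0°, 360°)$;
* multistart: 8 starts by default — the stored parameter values seed
  the first, the rest are drawn uniformly inside the bounds from the
  recorded seed. The lowest $f$ wins; exact ties break toward the
  smallest total $|V_n|$ (parsimony);
* identifiability: a single Fourier term has exactly equivalent
  representations — $(v,\gamma,n) \equiv (v,-\gamma,-n)$, and
  $(-v,\gamma+180°,n)$ differs only by a constant that $K$ absorbs.
  `canonical_dihedral_term()` maps a term to the representative with
  $v \ge 0$, $n \ge 0$, $\gamma \in [0, 360°)$; recovery tests compare
  canonical forms, not raw coordinates;
* degenerate inputs: an empty floating set, a key matching no stored
  row, or a key matching no torsion path in the topology are errors; a
  structure count below the floating-parameter count produces a
  rank-deficiency warning and a best-effort fit.

## Structure-set generation and quality

`scan_torsion()` generates conformers systematically: it splits the
bond graph on the torsion's central bond (ring bonds are rejected as
non-rotatable) and rigidly rotates the far component in fixed steps, so
frame $m$ has the starting torsion plus $m\cdot\mathrm{step}$ and every
other internal coordinate is preserved to machine precision.
`coverage_check()` bins each fitted torsion into twelve 30° bins on
$(-180°, 180°]$ and flags the set when any torsion populates less than
half of them — fitting a periodic function to a sliver of the circle is
the classic way to get a wrong barrier.

### Toy fixtures and what they do (and do not) show

`toy_boronate_fixture()` builds five small (≤ 24 atom), deterministic
analogs of the boronate–serine adducts: `phenyl`, `benzyl`,
`benzylamino`, `methylamino`, and an `ester` diol-ester analog added so
that the ester-oxygen torsions and the `b-ha-c2-ha` improper — which no
small fragment of the four named warheads can realize under the
available angle inventory — are exercised too. Together the five
fixtures realize all 29 distinct dihedral keys of the built-in library
(`audit_fixture_coverage()` verifies this, and reports any key that
ever became unrealizable rather than skipping it silently).

Geometries are built by internal-coordinate (NeRF) placement using the
library's equilibrium bond lengths and angles, so tree bonds carry
exactly zero strain and angle strain is limited to sibling terms at
multi-substituted centers (the printed angle equilibria at sp² centers
are not jointly realizable — e.g. around `b-c2` they sum to 353.77°
instead of 360° — so a fraction of a kcal/mol of residual angle strain
is inherent, and where a single dihedral separation can absorb it the
builder solves for that separation exactly). Partial charges are
type-based round values with boron absorbing the residual so each
fixture is exactly neutral; they are placeholders for RESP charges, not
fitted quantities.

`synthetic_qm_energies()` emulates a quantum energy file: the MM energy
under a chosen "true" parameter set, plus a constant offset (the
absolute-scale difference between QM and MM energies, typically
hundreds to thousands of kcal/mol), plus i.i.d. Gaussian noise.
Because the generator lives inside the model class being fitted,
recovery tests demonstrate the *fitter's* correctness —
identifiability, offset profiling, convergence — and nothing about how
well the AMBER functional form approximates real DFT energies; real
quantum torsion profiles contain coupling and anharmonicity this
generator deliberately lacks. Reproducing the published per-compound
parameters themselves would require the original DFT structure sets,
which are inputs to (not outputs of) this toolkit.

## Validation analytics

**Boltzmann populations.** `boltzmann_populations()` converts relative
conformer energies to equilibrium percentages,
$p_i \propto e^{-\Delta E_i/RT}$, at $T = 298$ K exactly with
$R = 1.987204\times10^{-3}$ kcal mol⁻¹ K⁻¹, re-referencing energies to
their minimum. The test suite recomputes a published 25-conformer
population table from its printed energy columns: every cell lands
within 0.1 percentage points, and 19 of 25 match the printed 1-decimal
value exactly. The six near-misses are a rounding artifact of the
2-decimal printed energies — two printed conformers even share an
energy value (1.12 kcal/mol) while printing different percentages
(10.6/10.5), which no single computation from the printed inputs can
reproduce.

**Torsion basins.** `detect_basins()` segments a circular histogram
(default 10° bins) into maximal runs of contiguous occupied bins,
merged across ±180°, and discards basins below a 10% occupancy floor —
only torsion regions genuinely visited by a trajectory are reported.
Segmentation by empty-bin separation rather than clustering keeps the
procedure deterministic with two interpretable parameters. The basin
center is the circular mean (atan2 of mean sine and cosine), which is
the exact minimizer of the summed $1-\cos$ circular dispersion; the
test suite checks it against a brute-force grid minimizer of that
dispersion. Note that the mean that minimizes *squared arc length*
differs from the circular mean by order 0.1° at realistic spreads; the
circular mean is the standard directional-statistics choice and the
one used here.

**Reference comparison.** `compare_to_reference()` matches each
reference conformer's torsion angles (e.g. DFT minima) to the nearest
detected basin center by minimal circular distance, flagging matches
at a configurable threshold (default 30°, roughly half the width
separating gauche/anti wells). Reference values that fall between two
basins simply report their nearest center and distance — the report
does not average basins on the user's behalf.

## Problem sizes and reproducibility

The shipped tests and acceptance analyses run at desk scale: 36-frame
10° scans for recovery (one Fourier term, noiseless and at
$\sigma = 0.1$ kcal/mol over 50 seeds, where the noisy study uses the
full 8-start multistart), 1000 random quadruples for the torsion
oracle, $10^4$-point grids for offset optimality, and ≤ 24-atom
fixtures throughout — chosen so the whole suite completes in about a
minute while still exercising every code path. All stochastic steps
(multistart draws, synthetic noise) consume explicit integer seeds
recorded in their results; identical configuration and seed reproduce
outputs byte for byte.

## Known limitations

* Energies only: no forces/gradients, so no force-matching branch and
  no geometry optimization.
* Bond, angle and charge parameters are taken as fixed inputs; only
  dihedral terms are fitted.
* No solvent model, periodic boundary or cutoff — single gas-phase
  adducts only.
* Binary trajectory formats (DCD/NetCDF) are out of scope; multi-frame
  XYZ and PDB cover the supported interchange.
* Whether nonbonded terms belong inside $E_{MM}$ during fitting is
  genuinely ambiguous in practice; both modes are exposed (supply
  `nonbonded_params()` or not) and the choice is recorded in the fit
  diagnostics.
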