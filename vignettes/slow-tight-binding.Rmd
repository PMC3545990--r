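---
title: "Slow tight-binding inhibition kinetics and interface geometry with slowtight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow tight-binding inhibition kinetics and interface geometry with slowtight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowtight)
```

# The scientific problem

Kunitz/BPTI-type inhibitors are ~60-residue disulfide-stabilised
proteins that block serine proteases by inserting a "canonical loop"
substrate-like across the active site.  Textilinin-1, a snake-venom
Kunitz inhibitor of human plasmin, is of pharmacological interest as a
more selective, more rapidly reversible alternative to aprotinin for
limiting surgical blood loss: its value hinges on quantitative
differences in `k_on`, `k_off` and `Ki = k_off/k_on` against plasmin,
plasma kallikrein and trypsin, and on the structural chemistry of its
complexes — a serine O-gamma trapped at sub-van-der-Waals distance from
the P1 carbonyl carbon, a displaced catalytic histidine, and a docking
orientation that varies by a few degrees between crystallographically
independent copies.

`slowtight` implements both analytical engines needed for such a study:

* a **kinetics engine** — deterministic simulation of chromogenic
  progress curves under competing binding schemes, a seeded synthetic
  data generator, simultaneous (global) regression of curve families,
  model discrimination, and derived inhibition constants with
  propagated uncertainty; and
* a **geometry engine** — superposition/RMSD, docking angles, chi1
  dihedrals, contact classification, Lee–Richards solvent-accessible
  surface area (SASA) and buried interface area on PDB coordinates.

# The kinetic model

## Schemes

Three nested mechanisms are supported (`scheme_ids()`):

* `one_step`:  E + I ⇌ EI with rate constants `k_on` (M⁻¹s⁻¹) and
  `k_off` (s⁻¹);
* `two_step`:  E + I ⇌ EI ⇌ EI*, adding first-order isomerisation
  rates `k_isom_f`, `k_isom_r` for a tightened complex;
* `irreversible`: the one-step scheme with `k_off` fixed at 0.

Slow, tight binding means the inhibitor concentration is comparable to
the enzyme concentration (free-inhibitor depletion matters) and
equilibration is on the assay timescale (the progress curve is
biphasic).  Neither classical steady-state algebra nor the
excess-inhibitor exponential applies exactly, which is why the engine
integrates the mass-action ODEs numerically and fits them directly.

## Dynamics

The reporter reaction (hydrolysis of a p-nitroanilide substrate) is
treated as a quasi-steady-state Michaelis–Menten flux competing with
inhibitor binding.  With `E` the enzyme bound to neither inhibitor nor
committed substrate, the one-step dynamics are

```
dP/dt  =  k_cat * E * S / (K_m + S)          dS/dt = -dP/dt
dEI/dt =  k_on * E * I * K_m/(K_m + S)  -  k_off * EI
```

plus the isomerisation exchange terms for the two-step scheme.  The
factor `K_m/(K_m + S)` is the competitive *substrate protection* of the
free enzyme under rapid substrate equilibration; with it, the
excess-inhibitor approach rate is the classical

```
k_obs = k_off + k_on * I / (1 + S/K_m)
```

(`kobs_one_step()`), and the simulated curves converge on the
closed-form slow-binding curve `P(t) = vs*t + (v0-vs)(1-exp(-k_obs
t))/k_obs` (`morrison_walsh_curve()`) whenever inhibitor depletion is
negligible.  This pair of independent routes — stiff ODE integration
versus closed form — is the engine's principal correctness oracle and
agrees to well under 1% in that limit.

Deliberately *not* modelled: an explicit ES species (the QSS flux
replaces it), enzyme autolysis, product inhibition, pre-incubation
protocols, and optical path effects.  The signal model is simply
`signal = baseline + signal_coeff * P`, with `signal_coeff = 1` by
default so product concentration is reported directly.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `K_m` | Michaelis constant of the chromogenic substrate | 200 µM | representative of p-nitroanilide substrates; required configuration since assay-specific values are rarely reported |
| `k_cat` | turnover number | 10 s⁻¹ | same; enters fits only through the product `k_cat·E_total`, fitted as one shared scale |
| `S_0` | substrate concentration | 500 µM | excess-substrate design; <2% depletion over 1800 s at 0.5–1 nM enzyme |
| duration / dt | sampling grid | 1800 s / 1 s | half-lives of interest span ~0.4 s (association at µM inhibitor) to tens of minutes (dissociation), so both transient and steady state are sampled |
| noise sd | additive Gaussian signal noise | 5×10⁻⁹ | see below |
| `reference_I` | half-life reference inhibitor concentration | 1 µM | conventional reporting point for `t½(on) = ln2/(k_on·I)` |

The derived constants are exact algebra: `Ki = k_off/k_on`,
`cv(Ki) = sqrt(cv(k_on)² + cv(k_off)²)` (`ki_with_error()`),
`t½(on) = ln2/(k_on·I_ref)` in seconds and `t½(off) = ln2/k_off`
reported in minutes (`half_lives()`).

## What the synthetic generator does and does not emulate

`generate_family()` reproduces the *statistical design* of the classic
chromogenic experiments: the three built-in designs
(`builtin_designs()`) use plasmin at 0.5 nM against 0, 2, 5, 10, 15,
20, 40, 50 nM inhibitor; plasma kallikrein at 1.0 nM against 0, 3, 6,
12, 24 nM; and trypsin at 0.5 nM against 0, 2, 3, 4, 6, 11, 19, 21 nM.
Noise is additive, homoscedastic and Gaussian, seeded for exact
reproducibility.

Real instrument noise is neither white nor homoscedastic: drift and
correlated fluctuations inflate parameter uncertainties far above what
independent Gaussian errors imply at 1800 points per curve.  The two
published calibration anchors therefore cannot be matched
simultaneously by any single sd — rate-constant CVs of roughly 1–15%
suggest sd ≈ 2×10⁻⁷, while keeping every observed-versus-fitted
correlation above 0.99 (including the strongly inhibited, small-
amplitude curves) requires sd ≤ ~6×10⁻⁹.  The default (5×10⁻⁹, about
0.1% of the full-scale signal, i.e. a clean continuous read) follows
the correlation anchor, which is the one the package's acceptance
checks assert; consequently fitted CVs on the well-identified plasmin
design are of order 0.1–0.3%, smaller than those of real data.  Passing
tests on synthetic families therefore demonstrate correctness of the
estimator under the stated noise model, not instrument-realistic error
bars.

A second deliberate asymmetry: with the tabulated kallikrein rates
(`Ki ≈ 1.9 µM`), nanomolar inhibitor ladders barely inhibit, so that
design is intrinsically weakly identifying — fitted CVs there are tens
of percent, bracketing the large printed uncertainties for that enzyme.
Similarly, the tabulated aprotinin–trypsin association rate
(4.13×10² M⁻¹s⁻¹) produces no measurable curvature at nanomolar
concentrations within 1800 s; synthetic irreversible-scheme studies in
the tests therefore use faster constructed rates.

# Global fitting and model discrimination

`fit_family()` fits all curves of a family simultaneously: `k_on`,
`k_off` (and isomerisation rates) are shared across curves; the
uninhibited velocity enters through `k_cat` as one shared nuisance
scale unless fixed.  Numerical choices, in order of importance:

* **log-parameterisation** — tight-binding objectives are
  ill-conditioned and rates are positive; optimising `log k` both
  conditions the problem and makes negative excursions impossible;
* **Levenberg–Marquardt** (`minpack.lm::nls.lm`) with a **multi-start**
  (3 by default) from decade-spaced initial rate guesses, keeping the
  best final residual sum of squares;
* a **parameter box** (rates confined to 10⁻¹⁰–10¹⁰) applied as a
  growing penalty so line-search excursions cannot drive the integrator
  into overflow;
* **integration** with a stiff-capable solver (`deSolve::lsoda`,
  rtol 10⁻⁸, atol 10⁻¹² M) — nanomolar species with second-order terms
  make the system stiff; simulations conserve enzyme, inhibitor and
  substrate totals to ~10⁻¹⁵ relative;
* **standard errors** from the Gauss–Newton covariance
  `(JᵀJ)⁻¹·rss/(n-p)` with `J` evaluated by central differences at the
  solution, mapped to the natural scale by the delta method; a singular
  `JᵀJ` flags the fit non-identifiable rather than silently reporting
  numbers;
* the `converged` flag is honest: an iteration-cap exit reports
  `FALSE`.

`akaike_compare()` implements small-sample corrected AICc
(`n·ln(rss/n) + 2p + 2p(p+1)/(n-p-1)`) and Akaike weights; AICc rather
than AIC because the correction matters when parameters are many
relative to the information content of a design, and it converges to
AIC as `n` grows.  `variance_ratio_test()` is the nested F test
`F = ((rss₁-rss₂)/(p₂-p₁))/(rss₂/(n-p₂))`; a complex fit that lands
above the nested optimum is clamped at `F = 0` with a warning.  The
selection rule is conservative: the simpler scheme is kept unless the
complex one both carries Akaike weight > 0.5 *and* rejects at
`p < 0.05`.  `discriminate_schemes()` adds the irreversible-refit rule:
when the selected reversible fit leaves `k_off` with a coefficient of
variation above 100% — the signature of apparently irreversible
inhibition — the family is refit with `k_off = 0` and the one-step
versus irreversible pair re-compared.

```{r, eval = FALSE}
fam <- generate_family(builtin_designs()$plasmin, "one_step",
                       rate_parameters(k_on = 1.72e6, k_off = 7.5e-4),
                       noise_model(seed = 101))
sel <- discriminate_schemes(fam)
summary_from_fit(sel$fits[[sel$selected]])
```

# The geometry engine

* **Superposition** (`superpose()`) is the Kabsch SVD construction with
  the determinant correction that excludes reflections; `rmsd` is the
  minimised value and `rotation_angle()` extracts the axis–angle
  magnitude `acos((tr R - 1)/2)`.  C-alpha pairing
  is by residue number within a chain-equivalence map; unpaired
  residues are dropped with a logged count, since deposited chains
  differ at disordered termini.
* The **docking angle** between two copies of a complex
  (`docking_angle()`) superposes protease 1 onto protease 2 over shared
  C-alpha atoms, applies that transform to inhibitor 1, and reports the
  axis–angle magnitude of the residual best-fit rotation onto
  inhibitor 2.  It is symmetric in argument order and exactly recovers
  constructed rotations.
* **chi1** (`chi1()`) is the signed IUPAC N–CA–CB–gamma torsion, with
  the gamma atom selected by residue type; the sign convention is
  cross-checked in the tests against an independent torsion routine
  (`bio3d::torsion.xyz`).  Differences between structures are reported
  signed, so a rotation "in the opposite direction" appears with
  opposite sign.
* **Contacts** (`contacts()`) are heavy-atom and distance-only (at
  typical crystallographic resolutions hydrogens are not observed);
  donor/acceptor and charged-group typing come from fixed per-residue
  tables.  Classification precedence and defaults: ionic (opposite
  charged groups, ≤ 4.0 Å) > hydrogen bond (donor/acceptor ≤ 3.2 Å) >
  close approach (< 3.0 Å, e.g. the trapped tetrahedral-intermediate
  Ser-OG⋯C contact at 1.6 Å) > van der Waals (≤ 4.0 Å).
* **SASA** (`sasa()`) is the Lee–Richards construction: each
  solvent-expanded sphere (`r + probe`, probe 1.4 Å) is cut into
  z-slices; per slice, the arc of its circle not occluded by
  neighbouring expanded circles contributes `accessible_angle · R · h`.
  Slices are centred per atom with thickness adapted down from the
  nominal spacing (0.1 Å) so an isolated sphere is *exact*
  (a spherical zone has area `2πRh` regardless of latitude).  Radii are
  Chothia-style united heavy atoms — C 1.87, N 1.65, O 1.40, S 1.85 Å —
  kept as explicit configuration because buried-area figures are
  radii-set dependent at the several-percent level.  Hydrogens are
  implicit; waters are excluded unless requested; an element without a
  radius is an error naming the atoms.  Slicing is mildly anisotropic:
  totals vary by ≲0.5% under rigid rotation, and agree with a
  brute-force spherical-quadrature oracle within 1% on overlapping
  clusters.  **Buried area** is `sasa(A) + sasa(B) − sasa(AB)`,
  symmetric, and zero for parts beyond probe contact.

Crystallographic symmetry-mate generation is out of scope: packing
analyses run on the deposited asymmetric-unit contents only.

## Reproducing deposited-structure measurements

`deposited_structure_report()` runs the full measurement battery for
the two textilinin-1 complexes — catalytic Ser-OG to P1 carbonyl-carbon
distances (≈1.6 Å in the microplasmin complex, ≈2.6 Å in the trypsin
complex), the mean bond angle at that carbon, the protease/inhibitor
buried interface, the inter-complex buried area, and the inter-complex
docking angle — given locally supplied PDB files of the deposited
asymmetric units.  Nothing is ever downloaded: the package's tests and
acceptance script are fully self-contained on constructed fixtures, and
the deposited-structure check runs (and its test passes) only where the
user has placed the coordinate files, e.g. under
`tests/testthat/structures/`.  Protease and inhibitor chains are
auto-detected by size (>150 ordered residues = protease) with explicit
overrides.  Residue numbering is taken verbatim from the file
(plasminogen numbering S741/H603/D646; chymotrypsinogen numbering
S195/H57/D102); there is no renumbering layer.

# Problem sizes used by the tests and acceptance script

Single-family demonstrations use the full default grid (1800 s at 1 s;
8 curves × 1801 points for the plasmin design).  Repeated-seed studies
— estimator bias/SE calibration (20 seeds) and model-selection
calibration (10–20 seeds) — run the same designs at 10–30 s sampling,
which preserves the transient/steady-state structure while keeping each
study to tens of seconds.  The SASA quadrature oracle uses 2×10⁴
Fibonacci points per sphere.

# Known limitations

* The noise model is white and homoscedastic; reported SEs are correct
  for that model, optimistic for drifting instruments.
* The QSS substrate flux omits an explicit ES species; `k_on` is the
  true association constant only under rapid substrate equilibration.
* SASA is O(n²) pure R; a few thousand atoms per call is comfortable,
  whole ribosomes are not the target.
* Alternate locations are collapsed to the highest-occupancy conformer
  before geometry; occupancy-weighted measurements are not supported.
* Fits assume every curve of a family shares `E_total`, `S_0` and the
  signal calibration of its design.
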