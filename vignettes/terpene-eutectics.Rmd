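---
title: "Modeling terpene eutectic solvent systems: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling terpene eutectic solvent systems: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eutectr)
```

Deep eutectic solvents (DES) are binary mixtures of a hydrogen-bond donor
and acceptor whose eutectic temperature lies well below the ideal-solution
prediction. Terpene pairs — here menthol:borneol, menthol:camphor,
thymol:borneol and thymol:camphor — are candidate natural DES. `eutectr`
implements the computational half of their characterization: physical-property
correlations with error analysis, ideal and UNIFAC solid–liquid-equilibrium
(SLE) phase diagrams with eutectic-point location, the deep-eutectic
classification, and NMR temperature-coefficient analysis of hydrogen bonding.

## The SLE model

Each liquidus branch follows the simplified Schröder–van Laar relation with
the heat-capacity change on melting neglected:

$$\ln(x_i^L\gamma_i^L) \;=\; \frac{\Delta H_{fus,i}}{R}
  \left(\frac{1}{T_{fus,i}} - \frac{1}{T}\right),$$

parameterized per component by the melting temperature $T_{fus}$ and fusion
enthalpy $\Delta H_{fus}$. The eutectic $(x_E, T_E)$ is the intersection of
the two branches, i.e. the temperature at which the branch mole fractions sum
to one. A $\Delta C_p$ correction is deliberately absent — the model is used
here exactly in its truncated form; extending it would change the
parameterization, not the solver.

**Units of $\Delta H_{fus}$.** The shipped melting-data table stores
enthalpies in kJ/mol (menthol 13.62, thymol 18.54, borneol 7.23, camphor
6.32). The magnitudes make physical sense only on that scale, and only that
reading reproduces the published ideal eutectic points; the liquidus
arithmetic verifying this is part of the test suite. All consumers multiply
by 1000 at the point of use.

**Numerics.** `find_eutectic()` brackets $T$ on
$[T_{floor}, \min T_{fus})$ and solves by Brent's method (`uniroot`,
tolerance $10^{-8}$ K). At each temperature the branch composition comes from
the closed form for the ideal model, and for non-ideal models from damped
successive substitution $x \leftarrow (1-d)\,x + d\,e^{rhs}/\gamma(x)$ with
$d = 0.5$, at most 200 iterations, residual below $10^{-10}$, and a bracketed
fallback. Both liquidus residuals at the returned point are checked against
$10^{-8}$ and recorded on the result object. The default temperature floor is
150 K: strongly non-ideal pairs can have sub-200 K eutectics, so the floor is
a search bound, not a physical claim; it is configurable.

```{r eutectic-example}
pair <- system_pair(terpene_compounds(), "menthol", "borneol")
find_eutectic(pair)
find_eutectic(pair, activity_unifac())
```

**Known inconsistencies in the published comparison values.** Two printed
reference values are not self-consistent with the printed melting data: the
thymol:borneol ideal point (309.6 K, x 0.722) lies on the thymol liquidus
alone — simultaneous solution of both branches gives 305.1 K at x 0.648 —
and the thymol:camphor ideal composition (0.457) disagrees with the
self-consistent 0.574 although its temperature (300.1 K) is reproduced. The
package does not force agreement; the tests assert the inconsistency rather
than hide it, and both values are reported.

## Activity models

Three models implement one contract (`activity_model`): mapping
(composition, temperature, compound pair) to $\gamma^L > 0$ with
$\gamma_i \to 1$ as $x_i \to 1$.

* `activity_ideal()` returns exactly 1.
* `activity_unifac()` is a from-scratch original-form UNIFAC:
  Flory–Huggins size term with the Staverman–Guggenheim shape correction
  ($z = 10$) plus the solution-of-groups residual with
  $\psi_{mn} = e^{-a_{mn}/T}$. The subgroup $R_k, Q_k$ and main-group
  $a_{mn}$ tables are the Hansen-1991 VLE revision, shipped as versioned CSV
  data files; every pipeline result records the table version. Compositions
  are clamped at $10^{-12}$ inside logarithms so the pure and
  infinite-dilution limits evaluate cleanly; reported values use the exact
  input composition.
* `activity_margules(a12, a21)` is the two-parameter Margules model. It has
  closed-form coefficients and a tunable deviation sign, which makes it the
  analytic oracle for the SLE solver tests; it carries no scientific claim
  about the terpene systems.

Correctness of the UNIFAC implementation rests on three independent legs:
a second, loop-based transliteration of the textbook equations kept in the
test helpers (agreement to $10^{-6}$ in $\ln\gamma$ across the fixture
binaries), frozen reference values from a separately written implementation,
and property tests — pure-component limits, boundedness near the composition
edges, and Gibbs–Duhem consistency
$x_1 \partial_x \ln\gamma_1 + x_2 \partial_x \ln\gamma_2 \approx 0$ by
central differences. The consistency check evaluates on a 0.01 composition
grid but uses a $10^{-4}$ difference step: the $O(h^2)$ discretization error
of a 0.01 step (about $10^{-3}$) would otherwise swamp the $10^{-6}$
tolerance being verified.

**Group assignments.** The source study never lists its UNIFAC
decompositions, so the package ships atom-balanced choices as editable data:
menthol 3·CH3 + 3·CH2 + 4·CH + OH; borneol 3·CH3 + 3·CH2 + 2·CH + 2·C + OH;
camphor 3·CH3 + 2·CH2 + CH + 2·C + CH2CO; thymol
3·ACH + ACCH3 + ACCH + 2·CH3 + ACOH. A validation report
(`validate_group_assignment()`) checks every decomposition against the
molecular formula. With these assignments the menthol:borneol UNIFAC
eutectic lands within 0.05 K of the published 290.0 K and the activity
coefficients stay below 1.01 across the diagram, as reported. The thymol
systems do not reproduce: both the ACOH decomposition (269.1 / 274.8 K) and
the alternative aromatic-C + alcohol-OH decomposition (306.6 / 303.0 K)
miss the published 300.8 / 281.7 K. The study's supporting-information
parameter revisions are not public; with the public Hansen-1991 table no
atom-balanced assignment matches both thymol systems, so the package reports
the sign of the deviation (negative, DES-like) faithfully and the
corresponding acceptance expectation is left failing rather than tuned.

## Critical properties and the property correlations

Densities, surface tensions and refractive indices of the liquid mixtures
are estimated from *mixture critical properties*, obtained in three steps:

1. **Pure components** — Modified Lydersen–Joback–Reid group contributions:
   $T_b = 198.2 + \sum n_k\Delta T_{bM}$,
   $T_c = T_b/(0.5703 + 1.0121\sum n_k\Delta T_M - (\sum n_k\Delta T_M)^2)$,
   $P_c = M/(0.2573 + \sum n_k\Delta P_M)^2$ bar,
   $V_c = 6.75 + \sum n_k\Delta V_M$ cm³/mol, with the contribution table as
   a CSV data file. A cross-check against a classic Joback evaluation for
   cyclohexanol agrees within 1%.
2. **Acentric factor** — the study does not state its method. The default is
   the modified Rudkin/Lydersen-type correlation in $T_b$, $T_c$, $P_c$
   that accompanies this group-contribution method in the DES density
   literature; Edmister's form is available as an alternative strategy.
3. **Mixtures** — Lee–Kesler combining rules by default
   ($V_{c,m}$ and $T_{c,m}$ from cube-root volume averages,
   $\omega_m$ mole-fraction linear,
   $P_{c,m} = (0.2905 - 0.085\,\omega_m)RT_{c,m}/V_{c,m}$), with plain
   mole-fraction weighting as the alternative. Note the Lee–Kesler mixture
   $P_c$ is a corresponding-states estimate: it does not return the pure
   component's input $P_c$ at $x = 1$ (the linear rule does); $T_c$, $V_c$
   and $\omega$ reduce exactly at the endpoints under both rules.

The study's own appendix of critical-property values is referenced but not
reproduced in the text available to this package, so the chain above defines
the inputs. Its end-to-end accuracy is visible in the correlation outputs:
the predicted densities land within 1% of all four published theoretical
values (e.g. menthol:borneol 1.1009 vs 1.1116 g/mL at 298 K) and the
refractive indices within about 0.2%.

**Term grouping of the correlations.** The published equations are typeset
with flattened grouping, so the algebraic reading had to be fixed here:

* *Density*: unambiguous;
  $\rho_L = -1.13\!\times\!10^{-6}T_c^2 + 2.566\!\times\!10^{-3}T_c +
  0.2376\,\omega^{0.2211} - 4.67\!\times\!10^{-4}V_c -
  4.64\!\times\!10^{-4}T$, exactly linear in $T$ and $V_c$.
* *Refractive index*: the constants' published units force
  $n = A_5\omega^3 + A_6\omega^2/M_w + A_7P_c + A_8 + A_9\omega/T$
  ($A_6$ carries mol/g, $A_9$ carries K). This reading reproduces the
  published values and is adopted.
* *Surface tension*: no reading could be arbitrated. The implementation's
  primary form is the one that makes every logarithm argument and ratio
  dimensionless under the published units of the conversion constants
  $A_1$–$A_4$; one further plausible reading is exposed via the
  `grouping` argument, and `property_report()` tabulates both. Neither —
  nor an exhaustive search over several hundred grouping/unit variants —
  reproduces the published surface-tension magnitudes or even their ordering
  across the four systems from group-contribution critical properties, so
  those printed values are treated as not reproducible from the available
  information and are not asserted anywhere. The relative-error table is
  still fully reproduced, because it is defined on the published property
  values themselves.

Relative errors use $e_r = 100(\text{theo} - \text{exp})/\text{exp}$.
Recomputing the published error table from the published property values
matches 9 of 12 cells at rounded equality; three differ by one unit in the
last printed digit (the study evidently used unrounded theoretical values),
so "agreement at printed precision" is implemented as one unit in the last
place. Mixture molar masses follow
$M_w = (x_iM_{w,i} + x_jM_{w,j})/(x_i + x_j)$ from formula-derived pure
masses; the published table matches to 0.01 g/mol (its pure masses were
vendor-catalog values rounded to 2 d.p. before mixing).

## NMR temperature coefficients

`fit_tcoeff()` fits $\delta(T)$ by ordinary least squares and reports the
slope (ppm/K), intercept, $r^2$ and a hydrogen-bond classification:
slopes more negative than $-0.005$ ppm/K indicate intermolecular
hydrogen bonding, slopes less negative than $-0.003$ ppm/K intramolecular.
The published thresholds are strict inequalities, so both boundary values
map to "indeterminate"; this closed-boundary convention is documented and
tested exactly at $-0.005$ and $-0.003$. The per-system shift series of the
study exist only as figures, so the shipped series are synthetic
reconstructions (generator below) with slopes inside the reported
$-0.0212$ to $-0.012$ ppm/K range, labelled as such.

## The synthetic-data generator and what passing tests mean

`synthetic_system()` draws binary pairs with melting temperatures uniform on
280–490 K and fusion enthalpies on 5–20 kJ/mol — the envelope of the four
real fixtures — so seeded systems exercise the same numerical regime
(eutectics between the 150 K floor and the lower melting point, branch
curvatures of the same order). `synthetic_nmr_series()` produces straight
lines with Gaussian noise at the instrumentally realistic scale
(σ ≈ 0.005 ppm over six temperatures). Both are pure functions of their
seed. What the generator does *not* emulate: solid solutions or co-crystals,
glass formation and crystallization kinetics (the DSC thermal records are
stored but never simulated), peak picking, or any correlation structure in
NMR noise. Passing the synthetic suites therefore demonstrates solver and
estimator correctness under the stated models, not the models' adequacy for
any particular real mixture.

`brute_force_eutectic()` is the independent oracle for the eutectic solver:
a pure grid scan (coarse 1 K pass over the full bracket, fine pass at the
requested step within ±2 K) that shares no machinery with the solver. Grid
accuracy is bounded by the steps; the composition step propagates into the
temperature argmin through the branch slopes, which is why the recovery
tests use a composition step of $5\times10^{-5}$–$10^{-4}$. The standard
test sizes — 20 seeded systems for ideal and Margules recovery, 0.01
composition grids for the consistency checks, 100–200 seeds for the NMR
slope Monte Carlo — keep the whole suite in the tens of seconds on one core
while leaving the quantization noise an order of magnitude below the
asserted tolerances.

## Conventions and limitations

* Mole fraction $x$ always refers to the first-listed component of a system
  (menthol or thymol), matching the published composition ordering.
* Config files carry units in field names (`t_fus_K`, `dh_fus_kJ_per_mol`);
  registries round-trip bit-identically through YAML.
* The gas constant is 8.314 J/(mol·K); the reference pressure 1 bar.
* COSMO-RS is out of scope (it needs proprietary software and
  quantum-chemical conformer generation); its published eutectic values are
  kept only as comparison fixtures in the documentation.
* Ternary systems, solid solutions, viscosity models and digitized
  experimental liquidus points are out of scope.
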