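---
title: "Models and methods: enzyme kinetics, activation thermodynamics and thermal inactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: enzyme kinetics, activation thermodynamics and thermal inactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzytherm)
```

enzytherm implements the standard quantitative workflow for
characterizing a biocatalyst — here motivated by a thermotolerant GH10
endo-xylanase acting on oat spelt xylan — from three plain tabular assay
shapes: initial rates across substrate concentrations, maximal rates
across temperatures, and residual-activity decay curves across a
temperature panel. This vignette records the models, the unit and
rounding conventions, the numerical choices, and the limits of what the
package's own validation shows.

## Michaelis–Menten kinetics

Initial rates are fitted to $v = v_{max} S / (K_M + S)$ by nonlinear
least squares, minimizing $\sum_i (v_i - v_{max}S_i/(K_M+S_i))^2$.
Because the substrate is a heterogeneous polymer, $K_M$ is expressed in
g·L⁻¹ rather than molar units; no molar conversion is attempted (and
substrate-inhibition and Hill extensions are out of scope).

Numerical choices:

* **Log-parameterization.** The optimizer works on $(\log v_{max},
  \log K_M)$, which enforces positivity without constrained optimization
  and makes the Levenberg–Marquardt steps scale-free.
* **Analytic starting values.** $v_{max,0} = 1.1 \max v$;
  $K_{M,0}$ is the substrate level at half of $v_{max,0}$, linearly
  interpolated from the sorted data (falling back to the median substrate
  level if the half-maximal rate is outside the observed range). On
  hyperbolic data these start close enough that convergence is routine.
* **Residual treatment.** Replicates at the same substrate level enter as
  separate residuals. Residuals are unweighted by default; a `1/v`
  weighting flag is available for assays whose error grows with signal.
* **Identifiability guards.** At least four distinct substrate levels are
  required, and a flat rate response is rejected outright ($K_M$ is then
  unidentifiable) rather than returned with a huge uncertainty.

The turnover number is pure unit arithmetic,
$k_{cat} = v_{max} \cdot M \cdot 10^{-3}/60$ s⁻¹ (1 µmol·min⁻¹·mg⁻¹ =
1 mmol·min⁻¹·g⁻¹; multiplying by $M$ in g·mol⁻¹ gives mmol·min⁻¹ per mol
of enzyme). It is computed only when a molecular mass is supplied —
published $k_{cat}$ values are sometimes rounded from undisclosed
conversions, so the computed value and any reported one are kept
distinct. The catalytic efficiency is defined as $k_{cat}/K_M$ exactly,
so `efficiency * KM == kcat` to machine precision by construction.

## Activation thermodynamics

The activation energy comes from ordinary least squares of $\ln(rate)$
on $1/T$, $E_a = -\text{slope} \cdot R$. Two points determine the line
exactly; with more, $R^2$ reports the linearity. Rates measured above the
temperature optimum reflect progressive denaturation, not activation, so
the fit should be restricted to the ascending limb — `arrhenius_fit()`
takes a `t_max` cutoff for exactly this (the package does not guess the
optimum itself).

From $E_a$ and a rate constant at a reference temperature:

* $\Delta H^* = E_a - RT$;
* $\Delta G^* = -RT\ln(k h/(k_B T))$, the Eyring relation inverted.
  The rate entering it **must be a frequency in s⁻¹**; rate constants
  tagged min⁻¹ are divided by 60 first. This convention is load-bearing:
  the deactivation free energies of the reference system reproduce their
  published values only under it.
* $\Delta S^* = (\Delta H^* - \Delta G^*)/T$, i.e. the Gibbs identity
  $\Delta G^* = \Delta H^* - T\Delta S^*$ holds by construction (asserted
  to 1 J·mol⁻¹ in the tests, not independently recomputed);
* $Q_{10} = \exp(10 E_a/(R T^2))$. A form of this relation sometimes
  quoted as "antilog($E_a \cdot 10 / RT$)" overflows absurdly for
  ordinary enzyme parameters (the exponent is ~140); the $T^2$ form with
  the natural exponential is the one consistent with differentiating the
  Arrhenius law, and is what reproduces tabulated $Q_{10}$ values near
  1–2. It is implemented as written here.
* $\Delta G^*_{E-S} = RT\ln K_M$ (association constant taken as $1/K_M$)
  and $\Delta G^*_{E-T} = -RT\ln(k_{cat}/K_M)$. With $K_M$ in g·L⁻¹ both
  are unit-convention-dependent; they are reported as conventionally
  tabulated, and users should not compare them across studies that use
  different substrate units. For the reference system's printed kinetic
  constants, these two formulas do **not** reproduce the corresponding
  published values under any unit convention we could identify, so the
  package treats those two published numbers as non-reproducible metadata
  rather than targets; the formulas themselves are implemented exactly as
  defined.

Physical constants are pinned to the three-significant-figure values
universally used in this literature ($R$ = 8.314, $k_B$ = 1.38×10⁻²³,
$h$ = 6.626×10⁻³⁴) rather than CODATA precision: reproducing published
tables to their printed decimal requires computing with the same rounded
constants. Celsius-to-Kelvin conversion defaults to +273 (not 273.15),
matching thermostability tables that list 40 °C as 313 K; both choices
are exposed (`physical_constants()`, `celsius_to_kelvin(offset = )`).

## Thermal inactivation

Residual activity is modelled as first-order decay,
$\ln(A_t/A_0) = -k_d t$. Because the model has no intercept (the fraction
is 1 at $t = 0$ by definition), the default regression is forced through
the origin; the least-squares slope then has the closed form
$\sum_i t_i \ln f_i / \sum_i t_i^2$, which the implementation matches to
machine precision (a free-intercept variant is available behind a flag
for diagnosing systematic offsets such as a burst phase). Samples with
residual fraction ≤ 0 — complete inactivation below the assay floor,
typical for late samples at 70–80 °C — cannot enter a log fit; they are
excluded rather than clamped, and the exclusion count is reported.
Residual fractions slightly above 1 are tolerated (assay noise) and the
CSV reader warns rather than errors on values just above 100%.

Derived quantities per temperature: half-life $t_{1/2} = \ln 2/k_d$ and
decimal-reduction time $D = \ln 10/k_d$ (their ratio is always
$\ln 10/\ln 2 \approx 3.32$, a useful invariant check). Across the panel,
OLS of $\ln k_d$ on $1/T$ gives the deactivation energy $E_{(a)d}$, and
the Eyring relations with $k_d$ in place of $k_{cat}$ give
$\Delta H^*_D$, $\Delta G^*_D$, $\Delta S^*_D$ per temperature. $k_d$ is
stored throughout in its native assay unit (min⁻¹) and converted to s⁻¹
only inside the Eyring expression. The average number of non-covalent
bonds disrupted in forming the inactivation transition state is estimated
as $\Delta H^*_D / 5.4\ \text{kJ·mol}^{-1}$, the canonical energy for
removing one –CH₂– moiety from a hydrophobic contact.

Report rendering rounds only at the edge: energies to 0.1 kJ·mol⁻¹,
entropies to 0.1 J·mol⁻¹·K⁻¹, half-life and D to integer minutes (the
precision of published tables); all internal computation is
double-precision J·mol⁻¹. JSON reports round-trip losslessly through
`parse_report()`.

## Hydrolysis product profiles

`dp_distribution()` expresses each xylooligosaccharide species (X1–X6) as
a percentage of total product at a chosen time. Percentages are defined
on mass concentration, matching chromatographic mass quantification; a
molar option reweights by $1/(132\,\mathrm{DP}+18)$. `xylose_equivalents()`
sums conc/DP over species — the mass carried by reducing ends — which is
monotone non-decreasing under pure depolymerization (every cleavage
creates one new reducing end) and so serves as a mass-balance audit; an
optional 150/132 anhydro correction converts to free-xylose mass units.

## The synthetic-data generator

The generator exists so that every fitting stage can be validated by
recovering known parameters, without any external data. Its defaults are
the reference system's values and are treated as fixed study conditions:
$K_M$ = 1.96 g·L⁻¹, $v_{max}$ = 58.6 µmol·min⁻¹·mg⁻¹, $E_a$ = 39.8
kJ·mol⁻¹, $E_{(a)d}$ = 195.4 kJ·mol⁻¹ with the Arrhenius intercept
anchored so $k_d(313\,\mathrm{K}) = 2.0\times10^{-4}$ min⁻¹, and 5%
multiplicative Gaussian noise — the coefficient-of-variation style of
scatter that triplicate colorimetric assays show (an additive-noise
option was considered and rejected as unrepresentative). Residual
fractions are clipped at zero to emulate the assay floor, which
deliberately exercises the fitters' exclusion logic. Decay sampling
defaults to eight times spanning 0.25–2 half-lives *per temperature*,
mirroring practice (hot incubations sampled over minutes, cool ones over
days); a fixed grid can be forced. All outputs are deterministic under
the ground truth's seed, to the byte when written as CSV.

The XO generator solves a consecutive first-order cascade — each
oligomer X$n$ cleaved into X$(n{-}1)$ + X1 (X2 into two X1) — exactly,
via the matrix exponential of the 6×6 molar rate matrix, so total xylan
mass is conserved to machine precision. Default cleavage rates rise
steeply with chain length (X6 0.6 h⁻¹ down to X2 0.01 h⁻¹), the
signature of an endo-acting enzyme that leaves xylobiose nearly
untouched.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real data: substrate heterogeneity (side-chain
decorations that stall the enzyme), product inhibition, biphasic or
reversible (Lumry–Eyring) inactivation, temperature-dependent noise, and
a true polymeric substrate pool (the cascade starts from X6, so its
xylose fraction at late times is necessarily higher than a polymer
hydrolysate's; the published DP percentages are qualitative shapes the
generator approximates, not quantities it reproduces).

## Validation problem sizes

The shipped test-suite and acceptance script use: 8-point
Michaelis–Menten curves with 200 seeded replicates for the noisy-recovery
study (median $K_M$ error under 10% at 5% noise); 5-temperature decay
panels of 8 points each, with 100 seeded replicates for the single-course
$k_d$ recovery study (median error under 5% at 2% noise); the
5-temperature printed $k_d$ panel for all table-reproduction checks; and
a brute-force SSE grid of ~9×10⁵ $(K_M, v_{max})$ points as the
independent oracle for the nonlinear fitter. These sizes were chosen as
the smallest that make the statistical assertions stable across seeds.

## Known limitations

* Single-phase first-order inactivation only; no multi-domain or
  reversible-unfolding models.
* No uncertainty propagation into derived thermodynamic quantities
  (published ± values come from assay replication, which the package does
  not model).
* The Arrhenius ascending-limb cutoff is the user's responsibility
  (`t_max`); no automatic optimum detection.
* $\Delta G^*_{E-S}$ and $\Delta G^*_{E-T}$ inherit the g·L⁻¹ unit
  convention of $K_M$ and are not comparable across substrate-unit
  conventions.
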