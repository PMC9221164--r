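# enzytherm

Kinetic and thermodynamic characterization of enzymes from plain tabular
assay data, built around the workflow used to profile thermotolerant
glycoside hydrolases (the motivating system is a GH10 endo-xylanase
hydrolysing oat spelt xylan, but nothing in the package is specific to it).

It covers four connected analyses:

1. **Michaelis–Menten kinetics.** Nonlinear least-squares fit of
   `v = vmax·S/(KM + S)` to initial-rate data, with the turnover number
   `kcat = vmax·M·10⁻³/60` (vmax in µmol·min⁻¹·mg⁻¹, M in g·mol⁻¹) and the
   catalytic efficiency `kcat/KM`. For polymeric substrates KM is kept in
   g·L⁻¹. Relative-activity tables (substrate specificity, modulators) are
   normalized to a reference condition.
2. **Activation thermodynamics of catalysis.** Arrhenius regression of
   `ln(rate)` on `1/T` gives the activation energy `Ea = −slope·R`; the
   Eyring relation `k = (kB·T/h)·e^(−ΔG*/RT)` gives
   `ΔG* = −R·T·ln(k·h/(kB·T))`, with `ΔH* = Ea − R·T`,
   `ΔS* = (ΔH* − ΔG*)/T`, the temperature quotient
   `Q10 = exp(10·Ea/(R·T²))`, and the binding / transition-state free
   energies `ΔG*E−S = R·T·ln(KM)` and `ΔG*E−T = −R·T·ln(kcat/KM)`.
3. **Thermal-inactivation kinetics and deactivation thermodynamics.**
   First-order decay `ln(At/A0) = −kd·t` fitted through the origin per
   temperature; half-life `t½ = ln2/kd`, decimal-reduction time
   `D = ln10/kd`; an Arrhenius fit of `ln(kd)` on `1/T` gives the
   deactivation energy `E(a)d`, and the Eyring relations (with kd in place
   of kcat, converted to s⁻¹) give `ΔH*_D`, `ΔG*_D`, `ΔS*_D` per
   temperature, plus an estimate of the non-covalent bonds disrupted
   (`ΔH*_D / 5.4 kJ·mol⁻¹`).
4. **Hydrolysis product profiling.** Degree-of-polymerization
   distributions of xylooligosaccharide (X1–X6) time courses and a
   reducing-end (xylose-equivalent) mass-balance audit.

A synthetic-data generator (`ground_truth()`, `gen_mm_curve()`,
`gen_decay_panel()`, `gen_xo_timecourse()`) produces all three assay
shapes with known parameters and seeded multiplicative noise, so every
stage of the pipeline is validated by parameter recovery.

All functions take a data frame first and return tibbles, so analyses
chain with the pipe; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(enzytherm)

# Michaelis-Menten fit of a (synthetic, seeded) initial-rate assay
mm <- read_mm_csv(system.file("extdata", "synthetic_mm.csv", package = "enzytherm"))
fit_michaelis_menten(mm, molecular_mass = 47890)
#> Michaelis-Menten fit (8 points)
#>   KM   = 1.936 g/L
#>   vmax = 58.08 umol/min/mg
#>   kcat = 46.36 1/s
#>   kcat/KM = 23.95 L/s/g
#>   SSE = 7.237, converged: TRUE

# thermostability table from a panel of inactivation rate constants (1/min)
kd_tbl <- tibble::tibble(temp_K = c(313, 323, 333, 343, 353),
                         kd = c(2.0e-4, 2.2e-3, 2.8e-2, 2.7e-1, 7.2e-1))
cat(render_report(deactivation_params(kd_tbl)))
#> Thermal-inactivation kinetic and thermodynamic parameters
#> temp_K (K)  kd (1/min)  half_life (min)  D_value (min)  Ea_d (kJ/mol)  dG_D (kJ/mol)  dS_D (J/mol/K)  dH_D (kJ/mol)
#>        313    2.00e-04             3466          11513          195.3          109.6           265.6          192.7
#>        323    2.20e-03              315           1047          195.3          106.7           265.9          192.6
#>        333    2.80e-02               25             82          195.3          103.1           268.7          192.6
#>        343    2.70e-01                3              9          195.3           99.8           270.2          192.5
#>        353    7.20e-01                1              3          195.3           99.9           262.0          192.4
```

The generated data were seeded from a true KM of 1.96 g·L⁻¹ and vmax of
58.6 µmol·min⁻¹·mg⁻¹, recovered here to about 1% under 5% assay noise.
In the stability table, kd rises ~3600-fold between 313 and 353 K: the
half-life drops from 3466 min (2.4 days) to about a minute, the
deactivation energy of ~195 kJ·mol⁻¹ is recovered by the Arrhenius fit,
and ΔG*_D falls from 109.6 to ~100 kJ·mol⁻¹ (the enzyme denatures more
readily as temperature rises, while ΔH*_D stays nearly constant).

See `vignette` source in `vignettes/enzyme-thermo-methods.Rmd` for the
models, conventions and design choices in full.

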