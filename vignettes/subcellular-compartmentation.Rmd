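---
title: "From leaf measurements to subcellular sugar concentrations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From leaf measurements to subcellular sugar concentrations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subcellsugars)
```

## The problem

Plant carbohydrate metabolism is compartmentalized: sucrose synthesis is
cytosolic, starch lives in the plastid, and the vacuole is the main sugar
store by volume. A bulk leaf extract therefore answers "how much sugar per
gram dry weight" but not "at what concentration, where" — yet it is the
local millimolar concentration that drives enzyme kinetics and transport.
`subcellsugars` implements the full quantitative chain needed to close
that gap from bench-level measurements:

1. an electrolyte-leakage **index of injury** to quantify membrane heat
   damage,
2. **deconvolution** of non-aqueous fractionation (NAF) density-gradient
   profiles into plastidial, cytosolic and vacuolar metabolite shares,
3. **volumetrics** converting leaf morphometry and 3D electron-microscopy
   segmentation summaries into absolute compartment volumes per gram dry
   weight,
4. conversion of bulk amounts into per-compartment **amounts and
   millimolar concentrations**, and
5. **kinetic simulation** of invertase-driven sucrose cleavage at those
   concentrations, after Arrhenius adjustment of assayed activities.

A seeded synthetic-data generator produces every input with retrievable
ground truth, so the entire chain is testable without laboratory data.

## Index of injury

Leaf discs are heated for increasing durations, and electrical
conductivity of the bathing water is read after overnight shaking
(EC~initial~) and again after boiling (EC~total~). The fractional release
is $R = EC_{initial}/EC_{total}$, and the index of injury of a heated
sample relative to its unheated reference is

$$I_d = 100\,\frac{R_t - R_0}{1 - R_0}.$$

Each replicate's own $t = 0$ measurement supplies $R_0$ (a group-mean
fallback exists via `injury_curve(..., r0 = "group_mean")`), because the
identity is defined with the sample's own unheated fraction. Negative
$I_d$ values are reported, not clamped: they typically flag swapped
measurements, and clamping would hide that. The assay's dilution factor
cancels in the ratio, and $I_d$ is invariant under any common rescaling of
the two conductivities — both are tested properties. Bath temperature is
treated as metadata only.

## NAF deconvolution

Lyophilized tissue is fractionated on a density gradient (default six
fractions, 1.35–1.60 g cm^-3^ in 0.05 steps) in which compartment
membership is encoded statistically: the plastid marker
(pyrophosphatase) peaks in the lightest fraction, the vacuolar marker
(acid phosphatase) in the densest, and the cytosolic marker (UGPase) is
nearly flat. Each metabolite's normalized fraction profile $m$ is modelled
as a convex combination of the normalized marker profiles (columns of
$M$), and the compartment shares $s$ are estimated as

$$\hat{s} = \arg\min_{s \ge 0,\ \sum s = 1} \lVert M s - m \rVert_2.$$

The published workflow names an app for this correlation step but not its
algorithm; constrained least squares is this package's reading of
"correlate to estimate", and it is stated as a design choice, not as the
original tool's algorithm.

**Numerical choice.** With three compartments the constrained problem is
solved *exactly* by enumerating the $2^3 - 1$ faces of the simplex and
solving each equality-constrained least-squares subproblem through its KKT
system, keeping the feasible candidate with the smallest residual
(minimum-norm on ties, which also covers degenerate optima). This is
preferred over iterative NNLS-plus-projection because exact convex
combinations are then recovered to machine precision, and over a general
QP solver because none is needed for a 3-dimensional simplex. The test
suite checks the solver against an independent exhaustive grid search
over the simplex (step 10^-3^) on random problems.

Identifiability guards: the marker matrix must have full column rank,
there must be at least as many fractions as compartments, and the
synthetic generator refuses configurations in which two marker profiles
coincide. Replicates are deconvolved individually and aggregated by the
renormalized median — matching per-sample gradients rather than pooled
fractions — and `bootstrap_shares()` resamples replicates with
replacement for seeded quantile intervals. Only the three NAF-resolved
compartments are modelled; mitochondria, peroxisomes and the apoplast are
out of scope, as is any cross-contamination correction beyond the linear
mixing model.

## Volumetrics

The unit policy is mm/mg/mm^3^ internally, with mL gDW^-1^ appearing only
at the reporting boundary, to avoid silent 10^3^ errors. The chain per
sample is:

* disc volume $V = \pi r^2 h$ (punch radius $r$, leaf height $h$);
* volume per gram dry weight $V / (DW/1000)$;
* cell-material volume = total volume − gas space (equivalently
  $\times (1 - \text{porosity})$; the gas-space estimate may come from 3D
  SBF-SEM segmentation or 2D section areas through the same argument);
* compartment volume = cell material × segmentation proportion, /1000 to
  mL gDW^-1^.

Computation runs per sample and is then averaged, which reproduces the
slight discrepancies between recomputed and printed condition means in
published summary tables. The compartment volumes are additive by
construction (their mL sum × 1000 returns the cell-material input to
1e-9) and strictly monotone in both cell material and proportion. The
nucleus and unsegmented small organelles are folded into the cytosol
class by the segmentation upstream; whether the original analysis did
exactly this is not documented, so it is the package's default
convention, recorded here. `tissue_fractions()` handles the companion
2D cell-type percentages. The proportion-sum tolerance in
`compartment_volumes()` is 10^-3^ so that percentages printed to two
decimals (summing to 99.99 or 100.01) pass.

## Amounts to concentrations

`partition_amounts()` multiplies bulk amounts (µmol gDW^-1^) by the
shares; mass conservation is exact. Starch is excluded from partitioning
— it is plastidial by biology, not resolved by the three-compartment
gradient — and passes through as a bulk amount. Dividing by compartment
volume gives µmol mL^-1^, i.e. mM. Because shares and amounts come from
different sample sets in practice, condition-level share medians are
combined with per-replicate amounts, and that propagation choice is
recorded in the output's metadata attribute. With equal amounts,
concentration ordering is the reverse of volume ordering — which is why
amounts can peak in the vacuole while concentrations peak in the cytosol;
this volume effect is a tested property.

## Kinetics

Activities assayed at the temperature optimum (298.15 K for SPS,
303.15 K for invertases) are rescaled to growth temperature with the
Arrhenius equation $V_{max,adj} = C e^{-E_a/RT}$, where
$C = V_{max,opt}\,e^{E_a/(R\,T_{opt})}$ so the round trip at $T_{opt}$
is exact ($R = 8.314$ J mol^-1^ K^-1^, fixed). Temperatures are Kelvin
internally; sub-200 values are rejected as likely Celsius, and
`celsius_to_kelvin()` is the boundary converter. Volume normalization
(activity per gDW ÷ mL cell volume per gDW) makes rates commensurable
with mM substrate.

Sucrose cleavage is simulated with fructose as a competitive inhibitor
(scaling $K_m$) and glucose as a noncompetitive inhibitor (scaling
$V_{max}$):

$$v = \frac{V_{max,adj}}{1 + g/K_{i,Glc}}\cdot
      \frac{s}{K_m\,(1 + f/K_{i,Frc}) + s}.$$

Whether the glucose effect is pure noncompetitive or mixed is not settled
in the main-text sources, so an $\alpha$ parameter generalizes the
glucose term (uncompetitive component with constant $\alpha K_{i,Glc}$);
$\alpha = 1$, the default, reduces exactly to the classical form above,
anchored by the identity $v = V_{max}/6$ at $s = K_m$, $f = K_{i,Frc}$,
$g = K_{i,Glc}$. The numeric $K_m$, $K_i$ and $E_a$ values used in the
original study live in its supplementary material; the defaults shipped
in `kinetic_parameters()` are therefore a clearly labelled example set,
and every constant is overridable. `in_vivo_flux()` feeds cytosolic
pools to the neutral invertase and vacuolar pools to the acidic
invertase; the cell-wall invertase is adjusted and reportable but
excluded from flux, since no apoplastic concentrations are resolved.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions: six fractions over 1.35–1.60 g cm^-3^, four replicate
gradients, marker shapes matching the qualitative gradient behaviour
(plastid peak at fraction 1, vacuole at the last fraction, cytosol flat
with a small bump near fractions 2–3), and leakage timepoints 0/30/45/60
min. Noise is multiplicative mean-one lognormal per cell of the fraction
matrix — enzyme activities and sugar assays are positive and
heteroscedastic — with `noise_cv = 0.05` as the default magnitude. The
replicate-level noise of the original gradients is not published, so
this is a free parameter chosen once as a realistic assay CV, not an
estimate of the study's error. Morphometry samples are Gaussian around
condition means, truncated at zero, with proportions renormalized to the
simplex.

The leakage generator's expected injury is a logistic in exposure time
**rescaled to be exactly zero at t = 0**: the injury identity forces
$I_d(0) = 0$ because the $t = 0$ sample defines $R_0$, so an unanchored
logistic could never round-trip exactly. With zero noise, recomputing
$I_d$ from the generated conductivity pairs returns the configured curve
to floating precision.

One global seed drives everything through fixed per-generator substream
offsets, so partial reruns are reproducible and bit-identical; the
caller's RNG state is saved and restored around every generator. Ground
truth (shares, volumes derived from the configured morphometry means
through the volumetric chain, injury parameters, seed) travels with every
dataset, as an attribute in memory and as `ground_truth.yaml` on disk.

What the generator does *not* emulate: raw photometric traces,
fraction-to-fraction carry-over, marker promiscuity beyond the linear
mixing model, or correlated noise across fractions. Passing tests
therefore demonstrate correctness of the computational chain under the
stated generative model, not robustness to every failure mode of a real
gradient.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains ingestion (synthetic or TSV), injury, shares,
volumes, concentrations and kinetics, writing one TSV per stage plus a
manifest (seed, package version, md5 checksums keyed by file basename —
no timestamps), so reruns with the same configuration are byte-identical
even across output directories. `validate_inputs()` reports schema,
positivity and simplex violations with row indices instead of raising.

The test suite exercises the solver against the grid oracle on 50 random
6-fraction problems and recovers shares on 100 seeded noisy datasets
(4 replicates each, noise CV 0.05); both complete in seconds, and the
full suite runs in well under a minute — sizes chosen to make the checks
statistically meaningful while keeping the suite fast to iterate on.

## Known limitations

* Three compartments only; metabolites with substantial mitochondrial or
  apoplastic pools violate the mixing model silently (watch the
  reconstruction R² from `fit_diagnostics()`).
* Share uncertainty enters downstream only through bootstrap intervals;
  no full variance propagation into concentrations.
* Kinetic defaults are illustrative; quantitative flux conclusions
  require assay-derived constants.
* The volumetric chain treats the leaf disc as a cylinder of uniform
  height; strongly undulating leaves bias disc volume.
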