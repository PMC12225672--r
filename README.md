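# subcellsugars

Where is the sugar, and at what concentration? Bulk leaf extracts give
amounts per gram dry weight, but enzyme kinetics and transport are driven
by the *local* millimolar concentration in the plastid, cytosol or
vacuole. `subcellsugars` implements the quantitative chain that closes
this gap for leaf tissue, aimed at plant physiologists working with
non-aqueous fractionation (NAF), electrolyte-leakage assays and
3D electron-microscopy volumetrics:

- **Index of injury** from paired conductivity measurements:
  `I_d = 100 (R_t − R_0)/(1 − R_0)` with `R = EC_initial / EC_total`,
  each replicate referenced to its own unheated sample.
- **NAF deconvolution**: each metabolite's density-fraction profile `m`
  is decomposed against the marker-enzyme profiles `M` (plastid
  pyrophosphatase, cytosolic UGPase, vacuolar acid phosphatase) by exact
  simplex-constrained least squares,
  `argmin ||M s − m||₂ s.t. s ≥ 0, Σs = 1`,
  with replicate-wise fits, median aggregation and bootstrap intervals.
- **Volumetrics**: disc volume `πr²h` → volume per gDW → gas-space
  (porosity) correction → compartment volumes in mL gDW⁻¹ from 3D
  segmentation proportions; 2D tissue-type fractions alongside.
- **Concentrations**: bulk amount × share ÷ compartment volume
  (µmol gDW⁻¹ ÷ mL gDW⁻¹ = mM), with exact mass conservation and starch
  passed through unpartitioned.
- **Kinetics**: Arrhenius adjustment `V = C·exp(−Ea/RT)` of assayed
  activities to growth temperature, volume normalization, and
  Michaelis–Menten sucrose cleavage with competitive (fructose) and
  noncompetitive (glucose) inhibition for the cytosolic and vacuolar
  invertases.
- **Synthetic data** with retrievable ground truth for every stage, and
  an end-to-end `run_pipeline()` with a reproducibility manifest.

## Worked example

Deconvolve a synthetic replicate set (noise CV 5 %), derive compartment
volumes from condition-level measurements, and convert bulk sugar
amounts to subcellular concentrations:

```r
library(subcellsugars)

cfg    <- synthetic_config(noise_cv = 0.05, seed = 2026)
shares <- deconvolve_profiles(gen_naf_samples(cfg))
shares
#>   metabolite share_plastid share_cytosol share_vacuole residual_norm
#> 1    sucrose        0.2010         0.141         0.658        0.0189
#> 2    glucose        0.0964         0.215         0.688        0.0176
#> 3   fructose        0.1535         0.248         0.599        0.0213
```

The generating truth was (0.20, 0.15, 0.65) for sucrose, (0.10, 0.20,
0.70) for glucose and (0.15, 0.25, 0.60) for fructose — recovered to
about ±0.01 at this noise level. Volumes from measured condition means
(volume per gDW 15,131 mm³ g⁻¹, gas space 4,199.5 mm³ gDW⁻¹,
segmentation proportions 13.89 / 3.51 / 82.6 %):

```r
vols <- summary_volumes(15131, 4199.5,
  c(plastid = 0.1389, cytosol = 0.0351, vacuole = 0.8260))
vols$cell_material   # 10931.5 mm^3/gDW of cell material
vols$volumes
#>  plastid  cytosol  vacuole
#>     1.52     0.38     9.03   (mL/gDW, rounded)

bulk <- data.frame(metabolite = c("sucrose", "glucose", "fructose"),
                   amount = c(5, 2, 1.5))     # umol/gDW
sc <- subcellular_concentrations(bulk, shares, vols$volumes)
sc[sc$metabolite == "sucrose", ]
#>   metabolite compartment amount_umol_per_gdw concentration_mM
#> 1    sucrose     plastid               1.005           0.6620
#> 2    sucrose     cytosol               0.707           1.8414
#> 3    sucrose     vacuole               3.288           0.3642
```

Note the signature volume effect: the vacuole holds most of the sucrose
*amount* (3.29 of 5 µmol gDW⁻¹), but the cytosol — 24× smaller — has the
highest *concentration* (1.84 mM vs 0.36 mM). Feeding the cytosolic
pools into the inhibited invertase rate law shows hexose feedback at
work:

```r
p <- kinetic_parameters(v_max = 1, k_m = 10, k_i_frc = 5, k_i_glc = 5)
mixed_inhibition_rate(s = 1.84, f = 0.97, g = 1.12, p)  # 0.1091
mixed_inhibition_rate(s = 1.84, f = 0,    g = 0,    p)  # 0.1555
```

(The kinetic defaults are a labelled example set; supply assay-derived
`k_m`/`k_i` values for real inference.) The whole chain, from synthetic
generation to invertase fluxes with a checksum manifest, is one call:

```r
res <- run_pipeline(pipeline_config(outdir = "demo", seed = 1))
res$rates
```

A thin shell wrapper lives at `inst/scripts/sspipe.R`
(`Rscript sspipe.R run --outdir demo --seed 1`).

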