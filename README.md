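# hifmri

Quantitative-MRI correlates of tumor hypoxia: an R pipeline linking
**IVIM** diffusion parameters and **R2\* relaxometry** to grid-wise
**HIF-1alpha immunohistochemistry scores**, built around a digital
glioma phantom so the entire analysis is reproducible and testable
without animal data.

## Who this is for

Researchers in quantitative MRI and MR-histology correlation who want a
tested, end-to-end reference implementation of the "grid the slide,
score the stain, pair with the parameter maps, run the rank statistics"
workflow used in small-animal hypoxia imaging studies - plus a
configurable synthetic-data generator for validating such pipelines.

## The models

* **IVIM biexponential** over 11 b-values (0-2000 s/mm^2):
  `S(b)/S0 = (1 - f) exp(-b D) + f exp(-b D*)`, with true diffusion
  coefficient `D`, pseudo-diffusion `D*`, perfusion fraction `f`, and
  perfusion `f * D*`. Segmented (S0 pinned to the measured b = 0 signal)
  and full (S0 free) bounded Levenberg-Marquardt fitters, with
  per-voxel identifiability flags for the pseudo-diffusion compartment.
* **Mono-exponential gradient-echo decay** over 16 echoes
  (3.4-92.1 ms): `S(TE) = S0 exp(-TE R2*)`, `R2* = 1/T2*`; iteratively
  reweighted log-linear estimation refined by nonlinear least squares,
  with a Rician noise-floor guard.
* **HALO-style HIF scoring**: per 1 mm^2 ROI,
  `score = percent positive x mean intensity (0-3)`, range 0-300,
  `> 150` = high expression.
* **ROI grid rules**: 1 mm^2 half-open cells; ROIs excluded for air,
  mixed tissue, or >= 25% vessel/necrosis/calcification; tumor ROIs
  classed central/peripheral by a strict 1 mm distance to the tumor
  boundary.
* **Statistics**: Mann-Whitney U (exact by enumeration where feasible,
  tie-corrected normal approximation otherwise), Spearman (mid-ranks),
  Pearson, and simple linear regression, assembled into a
  tumor-vs-normal / central-vs-peripheral / high-vs-low-HIF /
  correlation report.

The phantom generator produces tissue labels (brain, lateralized
458 mm^3 tumor, intratumoral vessels/necrosis/calcification),
ground-truth parameter fields with configurable rank-correlation
coupling between the HIF field and R2* (+) / D* (-), Rician-noise DWI
and multi-echo magnitude series, and synthetic stained-cell tables.

## Worked example

```r
library(hifmri)
study <- run_study(n_animals = 8, seed = 1)
print(study$report)
```

```
<hif_report>
  analyzed ROIs: 493 (299 tumor [182 central / 117 peripheral / 108 high-HIF / 191 low-HIF], 194 normal)

-- tumor_vs_normal --
 parameter                         g1                         g2        p  sig
    R2star     37.57 +/- 6.37 (n=299)     35.58 +/- 6.90 (n=194) 2.19e-03 TRUE
 ...
 perfusion 1502.59 +/- 357.89 (n=299) 1257.41 +/- 163.47 (n=194) 8.97e-19 TRUE
 hif_score   131.85 +/- 51.03 (n=299)    21.26 +/- 14.03 (n=194) 8.32e-76 TRUE

-- central_vs_peripheral --
 parameter                         g1                         g2        p   sig
 hif_score   142.83 +/- 50.49 (n=182)   114.77 +/- 47.20 (n=117) 3.85e-06  TRUE
 ...

-- correlations with HIF score (tumor ROIs) --
 parameter    rho        p pearson_r    slope    R2
    R2star  0.356 2.32e-10     0.388  3.11000 0.151
     Dstar -0.170 3.14e-03    -0.126 -0.00754 0.016
 ...
```

Reading the output: the pooled synthetic study (8 animals, 493 analyzed
1 mm^2 ROIs) shows markedly higher HIF scores in tumor than in
contralateral normal brain, higher scores in the tumor core than at its
rim, a positive rank correlation between R2\* and the HIF score (higher
relaxation rate where deoxyhemoglobin, hence hypoxia, is higher) and a
negative correlation for the pseudo-diffusion coefficient D\* (poorer
microcirculation where hypoxia is worse). Diffusivities are displayed in
10^-6 mm^2/s, f in percent, R2\* in Hz.

Single stages are available directly:

```r
cfg <- phantom_config(seed = 7)      # geometry, couplings, noise, protocol
ph  <- simulate_phantom(cfg)         # labels, truth, DWI, MEGE, cells
fit <- fit_ivim_segmented(ph$dwi$data[48, 48, 1, ], cfg$protocol$bvalues)
an  <- analyze_phantom(ph)           # per-ROI record table
rep <- build_report(transform(an$roi, animal = 1))
```

A thin command-line wrapper (`inst/cli/hifmri.R`) exposes `simulate`,
`fit-ivim`, `fit-r2star`, `stats` and `run-all` subcommands over the
same functions; `run_pipeline()` writes every intermediate (NIfTI + JSON
sidecars, CSV tables, a JSON/Markdown report and a run manifest) and
supports `resume`.

## Layout

- `R/phantom-*.R` - configuration, label volumes, ground-truth fields,
  signal synthesis, cell tables
- `R/ivim.R`, `R/r2star.R` - voxelwise parameter estimation
- `R/hif-score.R`, `R/roi-grid.R` - scoring and the 1 mm^2 grid rules
- `R/stats.R` - tests, correlations, report assembly
- `R/pipeline.R`, `R/io.R` - orchestration and on-disk formats
- `vignettes/hypoxia-mri-methods.Rmd` - the methods vignette (models,
  calibration choices, numerical decisions, limitations)
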