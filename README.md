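# adcstar

Does an infused tracer spread through brain tissue faster than diffusion
alone can explain? `adcstar` answers that question the way it is asked in
glymphatic-transport studies: by comparing two independent estimates of a
high-molecular-weight tracer's apparent diffusion coefficient in the same
region of interest.

- **ADC\*** (pseudo-ADC) is measured from serial contrast-enhanced T1
  volumes. Within a manual ROI, each volume is split by Otsu's threshold,
  the tracer boundary is extracted as a physical point set, and each point
  of an earlier surface contributes its nearest-point travel distance to
  the next surface:

  ADC\* = dist² / (2 · d · t),  d = 3,

  pooled over all surface points of all consecutive scan pairs. ADC\*
  reflects *all* transport — diffusion **plus** convective bulk flow.

- **DTI-scaled ADC** is the purely diffusive prediction. A diffusion
  tensor is fitted voxelwise from a DW acquisition (log-linear least
  squares; FA = √½·√(Σᵢⱼ(λᵢ−λⱼ)²)/√(Σλᵢ²), ADC = (λ₁+λ₂+λ₃)/3,
  D_axi = λ₁, D_rad = (λ₂+λ₃)/2), and the region's water ADC is converted
  through tortuosity λ² = D_free/ADC: with D_free,water = 3×10⁻⁶ mm²/ms
  and D_free,albumin = 8.29×10⁻⁸ mm²/ms the prediction is
  ADC_tracer = ADC_water × D_free,albumin/D_free,water.

Per region, per-subject values of the two estimates are compared with a
pooled-variance two-sample t-test and the symmetric percent difference
100·(a−b)/((a+b)/2). ADC\* significantly above the prediction indicates
size-independent convective bulk flow.

Because the underlying animal MRI data are not public, the package ships a
fully tested advection–diffusion phantom (`phantom_spec()`,
`simulate_tracer()`, `simulate_dwi()`) with a brain-like geometry — an
isotropic "striatum" sphere under an anisotropic white-matter slab — so the
whole chain is validated against known ground truth, including the
detection contrast itself (bulk flow on vs off).

## Worked example

A five-subject synthetic cohort with radial bulk flow (0.05 mm/min ≈
0.8 µm/s) away from the infusion site, imaged at 4.5, 24 and 28.5 minutes
after the end of a 20-minute infusion:

```r
library(adcstar)

spec <- with_bulk_flow(phantom_spec(seed = 42), speed = 0.05)
res  <- run_pipeline(phantom_config(spec, n_subjects = 5))
tidy(res)
#> # A tibble: 4 × 8
#>   region   method              mean       se     n  t_stat p_value pct_difference
#>   <chr>    <chr>              <dbl>    <dbl> <int>   <dbl>   <dbl>          <dbl>
#> 1 callosum dti_scaled      1.93e- 8 1.66e-12     5 -776.         0         -187
#> 2 callosum surface_adcstar 6.49e-10 2.40e-11     5 -776.         0         -187
#> 3 striatum dti_scaled      1.74e- 8 1.69e-12     5    9.92       0           11.5
#> 4 striatum surface_adcstar 1.95e- 8 2.15e-10     5    9.92       0           11.5
```

Reading the striatum rows: the boundary-propagation estimate
(ADC\* = 1.95×10⁻⁸ mm²/ms) exceeds the purely diffusive DTI-scaled
prediction (1.74×10⁻⁸ mm²/ms) with p ≈ 9×10⁻⁶ — the cohort carries bulk
flow, and the pipeline detects it. The slab ("callosum") carries no flow;
its ADC\* stays far *below* its prediction, which is the expected behaviour
of a contour-propagation estimator under slow pure diffusion (the front
barely moves between late scans; see the vignette for the quantitative
bias analysis). `autoplot(res)` draws the region-by-method bar chart with
standard-error bars; `write_report(res, "out/")` emits `report.tsv` and
`summary.json`.

On the published region means, the symmetric percent difference reproduces
the printed contrasts:

```r
percent_difference(3.64e-8, 1.75e-8)   # striatum:        70.1 -> "70"
percent_difference(2.67e-8, 1.97e-8)   # corpus callosum: 30.2 -> "30"
```

Real data enter through sidecar manifests instead of the simulator: a CSV
`path,time_min` for the T1 series, NIfTI ROI masks, and a CSV
`path,bval,gx,gy,gz` for the DWI (see `data_config()`).

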