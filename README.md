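# surfquant

Quantification of yeast surface-displayed enzymes from fluorescence
micrographs, GFP calibration to molecules/cell, and whole-cell
Michaelis–Menten kinetics — with a synthetic-data module that makes the
whole chain testable against known ground truth.

## The problem

Yeast whole-cell biocatalysts carry an enzyme fused to a cell-wall anchor.
Bulk GFP fluorescence measures *total* expression of the tagged chimera,
but only the fraction that reaches the cell surface can touch substrate.
`surfquant` measures that fraction from two-channel micrographs and
propagates it into absolute surface abundance and catalytic constants:

1. **Segmentation & ring peeling.** Cells are segmented from the wall-stain
   (conA) channel and peeled into signed one-pixel concentric rings:
   coordinate 0 is the outermost ring inside the mask, −1 … −9 lie deeper,
   the residual interior is the CORE, and +1 … +4 lie outside. The wall
   signal concentrates in rings 0 … −9, peaking near −4.
2. **Bleed-through correction.** Intracellular GFP bleeds into the wall
   rings through the PSF. From intracellular-control strains the package
   estimates `FB_i`, the fraction of core signal detected in wall ring
   *i*, then corrects each cell:

   ```
   corr1_i = int_i − background · P_i
   corr2_i = corr1_i − inner_median · FB_i · P_i
   displayed fraction = Σ_wall corr2_i / corr1_total
   ```

3. **Abundance calibration.** Bulk plate readings are normalized
   (`GFP_corr = GFP/OD600`, `GFP_norm = GFP_corr/control`) and mapped to
   molecules/cell through OLS of `log10(GFP_norm)` on `log10(abundance)`
   over reference strains; molarity follows from the cell density via
   Avogadro's number (1.5×10⁵ molecules/cell at 10⁸ cells/mL ≈ 25 nM).
4. **Whole-cell kinetics.** Endpoint A405 readings minus an autohydrolysis
   control convert to product via Beer–Lambert with a pH-dependent
   extinction coefficient `ε(pH) = ε_max/(1+10^(pKa−pH))`; rates are fitted
   to `v = Vmax·S/(Km+S)`, and `k_cat = Vmax/[E]` uses the displayed enzyme
   concentration with recorded provenance.

## Worked example

```r
library(surfquant)

# render a strain displaying 22% of its GFP, plus intracellular controls
ctrl <- lapply(1:2, function(i) generate_micrograph(
  scene_spec(n_cells = 25, surface_fraction_true = 0, seed = i)))
strain <- generate_micrograph(
  scene_spec(n_cells = 25, surface_fraction_true = 0.22, seed = 10))

res <- run_display_pipeline(
  list(control = ctrl, strain = strain), control_strains = "control",
  config = list(min_cells_per_strain = 20))
res$fb_model
#> bleedthrough_model (mean of 50 cells):
#>  ring        fb          sd  n
#>     0 0.5932697 0.008032406 50
#>    -1 0.8002267 0.005585154 50
#>    -2 0.9257914 0.005731950 50
#>    -3 0.9773961 0.004906900 50
#>    -4 0.9949377 0.004696532 50
#>    ...
res$per_strain
#>   strain_id n_cells mean_fraction sd_fraction
#> 1    strain      25     0.2139218 0.002627502
```

The FB column is the fraction of intracellular signal still detected in
each wall ring (rising toward 1 deep inside the cell); the recovered mean
displayed fraction 0.214 sits within 0.006 of the generating truth 0.22.

Continuing down the chain:

```r
tab <- generate_calibration_table(noise_sd = 0.05, seed = 3)
dat <- calibration_gfp_norm(tab)
cal <- fit_calibration(dat$gfp_norm, dat$molecules_per_cell_true)
pred <- predict_abundance(cal, 36.9)     # a strain's mean GFP_norm
pred$molecules_per_cell
#> [1] 119889.4
displayed_abundance(pred$molecules_per_cell, 0.214, cell_density = 1e8)
#> $molecules_per_cell
#> [1] 25656.34
#> $concentration_nM
#> [1] 4.260336
```

The numbered scripts under `analysis/` run the same chain as a narrative
study — `01_simulate.R` renders all synthetic inputs, `02` quantifies
display, `03` fits calibration/fitness, `04` fits kinetics — writing
tables under `results/`.

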