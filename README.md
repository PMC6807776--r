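# alderfix

Nitrogen fixation by alder (*Alnus viridis* ssp. *fruticosa*) is a major
— and expanding — nitrogen input to upland tundra. **alderfix** implements
the full analysis chain for quantifying it: from ^15^N₂ nodule
incubations and soil-core nodule surveys to annual landscape N-fixation
fluxes, and from a classified shrubland map to a fitted distance-decay
model of soil inorganic N. It is written for ecosystem ecologists and
biogeochemists who need these calculations reproducible, tested, and
runnable end to end on synthetic data before (or instead of) a field
campaign.

## What it computes

**Per-nodule fixation rate** from a ^15^N₂ tracer incubation:

    Nfix = (APE_nodule × N_nodule) / (t × ¹⁵N_headspace)      [µmol N g⁻¹ h⁻¹]

with APE and headspace enrichment as atom fractions, N_nodule in µmol N
per g dry nodule, and t in hours.

**Nodule biomass density** (g m⁻² ground) from gridded plots (mean of
per-core densities) or bullseye plots (area-weighted inner/outer zone
means), and community means with standard errors over plots and over
cores.

**Annual area flux** by integrating the peak-season flux (biomass ×
rate) through a seasonal step function — half-maximal May 20–31, maximal
Jun 1–Aug 15, half-maximal Aug 16–31, quarter-maximal Sep 1–14; 93.5
effective full-rate days:

    annual = peak_flux × 24 × 93.5 × 14.0067 × 10⁻⁶          [g N m⁻² yr⁻¹]

**Shrubland cover** from a fused, standardized multi-band raster stack
via k-means (Lloyd + k-means++, fixed seed, k = 50 by default), with
cluster selection by ground-truth purity, map validation, and area
measurement; plain-text ASCII-grid raster I/O.

**Distance decay of soil inorganic N**: cell-edge distances from resin
plots to the nearest mapped shrubland, and the seasonal negative
exponential

    TIN = A · e^(−b·d)

fit by nonlinear least squares in three variants (shared, seasonal-A /
shared-b, fully seasonal), compared by likelihood-ratio test / AIC, with
1000-iteration season-stratified bootstrap percentile CIs.

**Leaf traits**: area-basis N and P, litter SLA under a 7% senescence
mass loss, resorption efficiencies, and covariance-matrix PCA with
bootstrapped eigenvector significance.

**Synthetic field campaign**: `scenario_config()` plus `gen_*()`
generators emulate every input stream (zero-inflated lognormal nodule
cores, invertible isotope enrichments, seasonal exponential resin
transects, two-class Gaussian spectral scenes, community trait tables),
each carrying its generating truth for recovery tests.
`run_pipeline()` ties all stages together with CSV/JSON/ASCII-grid
outputs and a seed-recording manifest.

## Worked example

```r
library(alderfix)

# 1. A 10-minute incubation in 20 atom% headspace, nodule 2 %N,
#    enrichment 0.05 atom% above natural abundance:
rec <- data.frame(shrub_id = "shr_01", community = "shrubland",
                  incubated_atm_pct = 0.4163, control_atm_pct = 0.3663,
                  nodule_pct_n = 2, incubation_time = 1/6,
                  headspace_atm_pct = 20)
nodule_fixation_rate(rec)
#>   shrub_id community  ape     rate below_detection
#> 1   shr_01 shrubland 0.05 21.41832           FALSE

# 2. Annual fluxes from the two community peak-season fluxes:
round(annual_n_fixation(c(62, 17)), 2)
#> [1] 1.95 0.53

# 3. Distance-decay fit with bootstrap CIs on a synthetic transect:
cfg <- scenario_config(seed = 1)
tr  <- gen_resin_transect(cfg)
bootstrap_ci(tr$records, "seasonal_A_shared_b", n_iter = 1000, seed = 1)
#> Bootstrap CIs (1000 iterations, case resampling, 0 failed)
#>          A_winter A_summer     b
#> estimate   29.041    3.055 0.151
#> lower      14.930   -2.013 0.064
#> upper      88.589    6.881 0.543
```

The rate in step 1 is µmol N per g dry nodule per hour. In step 2 the
two annual fluxes (g N m⁻² yr⁻¹) are the published community values their
peak fluxes imply under the default step calendar. In step 3 the
generating truth was A_winter = 33.84, A_summer = 1.73, b = 0.22 with
noise calibrated to the published CI widths; the point estimates scatter
around the truth at the expected sampling uncertainty and all three
intervals cover it.

## Layout

- `R/` — fixation, nodules, upscaling, raster + classification,
  distance decay, leaf traits, synthetic generators, pipeline/IO
- `tests/testthat/` — unit, property and acceptance tests (fixtures are
  generated in code)
- `vignettes/alder-nitrogen-methods.Rmd` — the model assumptions,
  parameter choices, numerical details and known limitations
- `scripts/acceptance.R` — headline-quantity reproduction
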