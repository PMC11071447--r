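# capflow

Computational pipeline for **flow-rate particle immunoagglutination assays on
paper microfluidic chips**, aimed at point-of-care quantification of protein
biomarkers (the motivating application is eNAMPT, an inflammatory-disease
marker measured in diluted blood and plasma).

The assay works without capturing or immobilising anything: antibody-coated
particles are pre-dried in wax-printed nitrocellulose channels, the sample is
loaded, and a ~1 min video of the advancing wetting front is recorded.
Antigen cross-links the particles into aggregates, which changes the
interfacial tension at the front and therefore the capillary flow rate; the
flow distance at a fixed early frame is the assay signal. `capflow` provides
every computational stage of that chain, for people developing or analysing
such assays:

* **Wetting-front tracking** (`track_front`) — per-channel front position
  from a frame stack, by baseline subtraction along the channel's central
  axis.
* **Flow modelling** (`fit_lw`, `pointwise_diffusion`, `compare_windows`,
  `select_detection_frame`) — the Lucas–Washburn law
  `L = sqrt(D t)`, `D = R γ_LG cos θ / (2 μ)`, fitted per window; per-frame
  `D = L²/t` series; and selection of the optimal detection frame (half the
  crossover frame of the fast initial regime).
* **Immunoagglutination kinetics** (`simulate_kinetics`, `dose_curve`,
  `find_hook_peak`, `find_crossing`) — the five-species mass-action system

  ```
  Abp + Ag      <->  Abp·Ag        (kon1, koff1)
  Abp + Abp·Ag  <->  Abp2·Ag       (kon2, koff2)
  Ag  + Abp·Ag   ->  Abp·Ag2       (kon3)
  ```

  integrated with an adaptive Runge–Kutta 5(4) scheme (Rcpp); the
  agglutination readout is `Abp2·Ag / Abp0`. The model reproduces the hook
  (prozone) effect and the curve shift/crossing when the particle amount is
  halved.
* **Calibration statistics** (`welch_t_test`, `find_lod`, `fit_sigmoid`,
  `linear_range`, `classify_tier`, `convert_dilution`,
  `group_comparison`) — Welch t-tests against the negative control, LOD,
  4-parameter logistic calibration on log10 concentration, linear-range
  search, low/middle/high tier calls, and diluted/undiluted conversions.
* **Synthetic data** (`synth_config`, `gen_profile`, `gen_video`,
  `gen_assay`) — a ground-truth generator chaining
  antigen → agglutination → interfacial tension → diffusion coefficient →
  flow profile → signal, plus rendered channel videos, so the entire
  pipeline is testable offline.
* **Orchestration** (`run_pipeline`, `inst/cli/capflow.R`) — track → fit →
  calibrate → classify from a JSON configuration, deterministic given the
  seed, outputs keyed by a config hash.

## Worked example

```r
library(capflow)

cfg <- synth_config(seed = 1)                       # 30 fps, crossover frame 50
assay <- gen_assay(cfg, c(0, 1, 2, 5, 10, 15, 20, 30, 40), n_replicates = 8)

find_lod(assay$dose_response)
#> [1] 10                                  # pg/mL in the diluted sample
convert_dilution(10, 0.1, "to_undiluted", unit = "pg/mL")
#> 0.1 ng/mL                               # undiluted-sample equivalent

fit <- fit_sigmoid(assay$dose_response)
fit$linear_range$range; fit$linear_range$r2
#> [1]  0 30
#> [1] 0.888

p <- gen_profile(cfg)
compare_windows(p, list(c(1, 50), c(1, 1499)))
#> <lw_fit> channel ch1, frames 1..50 (n = 50): D_hat = 0.09194 cm^2/s, r2 = 0.9953
#> <lw_fit> channel ch1, frames 1..1499 (n = 1499): D_hat = 0.025425 cm^2/s, r2 = 0.9047
#> D ratio matrix (row / column):
#>         1:50 1:1499
#> 1:50   1.000  3.616
#> 1:1499 0.277  1.000

pk <- find_hook_peak(dose_curve(kinetic_params(abp0 = 10), 10^seq(-2, 3, length.out = 40)))
pk$peak_value; pk$ag_at_peak
#> [1] 0.368                               # normalised agglutination at the hook peak
#> [1] 4.92                                # antigen level (model units) of the peak
```

Reading the numbers: the 10 pg/mL LOD is the lowest concentration whose
eight replicate signals differ from the negative control at Welch p < 0.05;
at a 10% sample dilution it corresponds to 0.1 ng/mL in the undiluted
specimen. The window comparison shows the fast initial flow regime — the
early-window diffusion coefficient is 3.6× the all-frame value — which is
why the signal is read at frame 25, half the crossover frame. The dose
curve's interior maximum is the hook effect: past it, excess antigen
saturates individual particles and agglutination falls.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "capflow.R", package = "capflow"))')
Rscript $CLI synth assay --seed 3 --out synthdir
Rscript $CLI calibrate --frame 25 synthdir/signals.csv --out calib.json
Rscript $CLI simulate --abp0 5 --ag-grid log:0.01:1000:50 --out dose.csv
Rscript $CLI run --config run_config.json --out outdir
```

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline from scratch against the
installed package: it simulates the kinetics with the reference rate
constants (hook peak, particle-shift crossing, conservation drift),
generates a seeded synthetic assay, renders and re-tracks a channel video,
fits the Lucas–Washburn windows, selects the detection frame, and computes
the calibration (LOD, linear range, dilution equivalents), logging each
quantity as it goes:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
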