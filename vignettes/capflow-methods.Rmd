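---
title: "Models and methods behind capflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind capflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capflow)
```

`capflow` implements the computational chain of a flow-rate particle
immunoagglutination assay on paper microfluidic chips. This vignette explains
the models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generator does and does not establish. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The assay in one paragraph

Antibody-conjugated particles are pre-dried in nitrocellulose channels
(2.1 cm × 0.3 cm, with a 0.3 cm loading zone). A sample wicks through by
capillary action while a camera records the wetting front at 30 fps. Antigen
cross-links particles into aggregates that are retained in the paper matrix;
fewer free particles at the liquid–gas interface raise the interfacial
tension and hence the flow rate, so the front distance at a fixed early frame
increases with antigen concentration — until antigen excess saturates
individual particles and the signal hooks downward (prozone effect).

## Wetting-front tracking

The raw data give only the desired output (front distance per frame), not a
detection algorithm, so the detector is the simplest one that satisfies a
round-trip property against the package's own video renderer:

* intensities are sampled on the channel's central axis, as the median over a
  3-pixel band (robust to single-pixel noise without blurring the front);
* each frame is compared to a pre-flow baseline frame; the front is the
  farthest along-axis position whose absolute change exceeds
  `threshold_rel` × the maximum change observed in that channel across the
  stack (default `threshold_rel = 0.5`; on binary-contrast stacks any value
  in (0, 1) gives the same answer, which the suite checks for 0.2–0.8);
* a channel whose maximum change is zero is reported dry (all-zero profile
  plus a warning) rather than as a spurious front.

Coordinates are 0-based half-open pixel rectangles; ROIs start at the
downstream edge of the loading zone, so distances are in cm from that edge,
truncated at the channel length. ROIs come from configuration, not
auto-detection: chips sit in a fixed 3D-printed holder, so the geometry is
constant per setup. Colour frames are collapsed to Rec.601 luminance first.
Profiles are monotone-enforced (`enforce_monotone`, a running maximum),
because a capillary front cannot recede; apparent retreats are flicker noise.
Frame 0 is the first frame of the stack and the baseline frame defaults to 0;
callers trim any pre-loading frames before tracking.

Because no video codec reader is available in the supported dependency set,
stacks are accepted as in-memory arrays or as directories of ASCII PGM (P2)
frames (`read_frame_dir`), a deliberately minimal text format.

## Lucas–Washburn modelling

Horizontal imbibition follows `L = sqrt(D t)` with
`D = R γ_LG cos θ / (2 μ)` (`diffusion_from_physics`; a contact angle above
90° means a non-wetting liquid and returns `D = 0` with a warning). Two
estimators are provided:

* `pointwise_diffusion` computes `D_i = L_i²/t_i` per frame and smooths with
  a centred moving average (default width 10 frames, window shrinking at the
  boundaries — a centred window avoids the phase lag a trailing average would
  add to the crossover estimate). The `t = 0` sample is always excluded.
* `fit_lw` fits `L = sqrt(D t)` by least squares on `L`. With
  `s = sqrt(D)` the model is linear-through-origin in `sqrt(t)`, so the
  minimiser is closed-form: `s_hat = Σ L√t / Σ t`. The alternative
  `method = "linearized"` regresses `L²` on `t` through the origin; the two
  must (and in the tests do) agree on noiseless data.

`compare_windows` reports fits over several frame windows and their pairwise
`D` ratios; on two-regime flows the early window fits a larger `D` than the
full profile, which is the physical basis for reading the signal early.

### Choosing the detection frame

The signal frame is half the crossover frame at which the flow leaves its
fast initial regime. The crossover is estimated on the **instantaneous**
diffusion series `d(L²)/dt` (first differences, then the same moving-average
smoothing, then averaging across profiles): its midpoint between the early
level (maximum over frames 1–15) and the late level (median of the final
third) is crossed at the regime change itself, and the crossing is located by
linear interpolation. The cumulative series `L²/t` was rejected for this
purpose: after a regime change it decays like
`(D_early t_c + D_late (t − t_c))/t` and crosses the same midpoint far past
the true crossover (for a crossover at frame 50 with the default generator
levels, near frame 95), which would misplace the operating point. On
noiseless two-regime families the estimator returns exactly half the
crossover frame (25 for a crossover at 50).

A known limitation: under the default i.i.d. Gaussian distance noise
(0.01 cm), monotone enforcement turns the trace into a running-maximum
staircase whose upward offset is larger where the front moves slowly. That
regime-dependent offset delays the apparent crossover by one to two frames,
so the noisy-world answer is asserted only to within two frames of the
noiseless one. `method = "max_separation"` offers a model-free alternative:
the frame maximising the between/within variance ratio of distance across
concentration groups.

## Immunoagglutination kinetics

Five species — free particles `Abp`, free antigen `Ag`, and the complexes
`Abp·Ag`, `Abp2·Ag`, `Abp·Ag2` — evolve by mass action:

* `Abp + Ag ⇌ Abp·Ag` with `kon1`, `koff1`;
* `Abp + Abp·Ag ⇌ Abp2·Ag` with `kon2`, `koff2` — the two-particle complex
  is the agglutination readout;
* `Ag + Abp·Ag → Abp·Ag2` with `kon3` and **no dissociation**: whether a
  particle carries one or two antigens makes no difference to
  agglutination, so the reverse rate is dropped. The `Abp·Ag2` species
  carries only its production term, which is exactly what closes both mass
  balances (particle mass `Abp + Abp·Ag + 2·Abp2·Ag + Abp·Ag2` and antigen
  mass `Ag + Abp·Ag + Abp2·Ag + 2·Abp·Ag2`).

Units are dimensionless model units throughout — the simulation establishes
trends (curve shapes, shifts, crossings), not absolute values, and no mapping
to molarity is attempted. The default constants
`kon1 = 6, koff1 = 0.1, kon2 = 1, koff2 = 0.05, kon3 = 2` are the
representative set; `kinetic_restriction_ranges()` exposes the admissible
exploration box (each rate ±10×), and `sample_kinetic_params()` draws from it
log-uniformly.

The integrator is an adaptive Dormand–Prince 5(4) scheme written in Rcpp
(no ODE-solver package is assumed), with `rtol = 1e-8`, `atol = 1e-10`,
per-component error scaling, and FSAL step reuse. Non-negativity is enforced
as a *clamped check*: values below `-1e3·atol` abort the integration, values
in `[-1e3·atol, 0)` are clamped to zero — a projection scheme could hide real
solver failure. Both conservation sums are recomputed at every stored output
time and a relative drift above `1e-6` raises an integration error; this,
plus the closed-form equilibrium of the reduced bimolecular system
(`kon2 = kon3 = 0` gives `[Abp][Ag]/[Abp·Ag] = koff1/kon1`), is the solver's
independent oracle.

`dose_curve` samples the normalised agglutination `Abp2·Ag(t)/Abp0` at
`t_sample = 1`, the time by which binding has levelled off for the reference
constants (the suite checks the plateau: the final slope is under 5% of the
peak rate). Both `Abp2·Ag` and `Abp·Ag` are normalised by the initial
particle concentration. `find_hook_peak` returns the grid argmax (ties to
the lower antigen level; boundary maxima are flagged as "no interior peak"),
and `find_crossing` locates the first sign change between a low- and a
high-particle curve by linear interpolation on the antigen axis.

## Calibration statistics

* **Welch t-test** (`welch_t_test`): two-sided, unequal variances,
  Welch–Satterthwaite degrees of freedom (delegated to `stats::t.test`;
  the unit tests recompute it from the textbook formulas). Two zero-variance
  samples are resolved by their means (equal → p = 1, different → p = 0,
  flagged degenerate).
* **LOD** (`find_lod`): the smallest nonzero concentration with p < α
  (default 0.05) against the zero-concentration control. Deliberately **no
  multiple-testing correction** — that matches the assay protocol being
  modelled — so with k null concentrations the family-wise false-positive
  probability is `1 − (1 − α)^k`; the caveat is documented rather than
  silently "fixed".
* **4PL calibration** (`fit_sigmoid`): a four-parameter logistic on log10
  concentration, the control mapped one decade below the smallest nonzero
  concentration (a pseudo-log floor; zero has no logarithm but the control
  must anchor the lower asymptote). If the mean response has an interior
  maximum and at least five concentrations lie at or below it, only the
  rising limb is fitted and the excluded hook-limb concentrations are
  flagged — a sigmoid cannot represent the non-monotone hook. `nls` runs
  with `scaleOffset` so that exact (zero-residual) data converge, and a
  `SSfpl` self-start is tried before declaring non-convergence; the fallback
  is a straight line in concentration, flagged. Direction (increasing /
  decreasing) is the sign of the fitted slope; a toe-only response (no upper
  plateau within the grid) is genuinely 4PL-unidentifiable and lands on the
  linear fallback by design.
* **Linear range** (`linear_range`): exhaustive search over all contiguous
  windows of at least `min_points = 3` concentrations; the widest window —
  measured in number of grid concentrations, ties broken by higher r² — with
  OLS r² ≥ 0.75 on mean signal vs concentration wins. Counting points rather
  than concentration span keeps a sparse tail of high concentrations
  (hook limb) from outweighing the dense rising limb that calibration grids
  are designed around.
* **Tier classification** (`classify_tier`): the calibration is inverted
  analytically (the 4PL is monotone between its asymptotes) and the
  concentration compared to two cut points; a value exactly at a cut goes to
  the higher tier. Decreasing calibrations need no special casing — the
  inversion itself reverses the signal ordering. Signals outside the fitted
  span are clamped to the nearest endpoint and flagged extrapolated. The
  default cuts 14.95 and 54.95 ng/mL are the midpoints between the clinical
  group spans (low 8.6–11.9, middle 18.0–23.1, high 86.8–197 ng/mL in
  undiluted plasma equivalents); they are configurable and must be given in
  the calibration's own concentration units.
* **Dilution arithmetic** (`convert_dilution`): undiluted equivalent =
  value / dilution fraction. With units attached, undiluted equivalents of
  pg/mL values are reported in ng/mL whenever the dilution is 10× or
  stronger (and ng/mL values re-diluted at 10× or stronger come back in
  pg/mL): blood and plasma biomarker levels are conventionally quoted in
  ng/mL, and this convention reproduces all the worked diluted/undiluted
  pairs exactly. The two directions are exact inverses, including the unit.

Replicates are pooled across chips (eight measurements = two chips × four
channels); chip-level blocking is not modelled.

## The synthetic world

`synth_config` states one coherent world and the defaults are the reference
conditions, not tuning knobs:

| parameter | default | why |
|---|---|---|
| `fps` | 30 | frame/time equivalences (1,500 frames = 50 s) |
| `n_frames` | 1500 | one-minute recording, 50 s of flow |
| `crossover_frame` | 50 | end of the fast initial regime |
| `D_late` | 0.02 cm²/s | slow late-stage imbibition; concentration-independent |
| `D_early` | physics map at `gamma_max` (0.09 cm²/s) | coherent with the γ→D chain; gives an early/all fit ratio in the reported few-fold range |
| `gamma_min`, `gamma_max` | 50, 72 dyn/cm | water-like tension span |
| `R_eff`, `theta`, `mu` | 5e-5 cm, 60°, 0.01 P | effective pore radius (tortuosity-reduced), wetting angle, water viscosity — chosen once so `D` lands in the regime where a 2.1 cm channel fills in tens of seconds |
| `noise_sd_cm` | 0.01 cm | free parameter (only standard errors are reported for the real assay); sub-pixel at 40 px/cm |
| `conc_per_ag_unit` | 5 pg/mL | places the simulated hook peak in the tens-of-pg/mL region where real calibrations plateau |

`gen_profile` renders the piecewise Lucas–Washburn profile
`L = sqrt(D_early t)` for `t ≤ t_c`, then
`L = sqrt(L(t_c)² + D_late (t − t_c))` — continuous by construction — adds
i.i.d. Gaussian noise, monotone-enforces and caps at the channel length,
storing the noiseless truth alongside. `gen_assay` chains
antigen → kinetics → `gamma_from_agglutination` (a **linear** map, the
minimal assumption: the data behind the assay establish the direction and
dominance of interfacial tension, not a functional form) → physics → profile
→ signal. `gen_video` darkens pixels behind the front by a fixed contrast.
All randomness derives from the configuration seed; identical configurations
reproduce identical outputs.

What the generator does **not** emulate: spatial particle transport and
retention, evaporation, blood-matrix optics, illumination flicker,
chip-to-chip blocking, and non-Gaussian tracking noise. A green round-trip
or recovery test therefore establishes internal consistency of the pipeline
on the stated world, not performance on real videos.

## Degenerate inputs and tie rules (summary)

* dry channel → all-zero profile + warning; all-zero fit window → error;
* no diffusion crossover → configured default frame + warning;
* monotone dose curve → boundary peak flag; identical curves → degenerate
  crossing at the first grid point; no sign change → NA + flag;
* zero-variance Welch samples → p ∈ {0, 1} by mean equality, flagged;
* hook-peak ties → lower antigen level; tier cut ties → higher tier;
* non-convergent 4PL → linear fallback, flagged; flat calibration cannot be
  inverted (error).

## Design shape

The package follows the classic S3 modelling idiom per component — `fit_lw`,
`simulate_kinetics`, `fit_sigmoid` return classed objects with
`print`/`coef`/`predict`/`plot`/`residuals` methods where meaningful — rather
than a single top-level fitting function, because the artifact is a staged
pipeline, not one estimator. Internals are base R; the only compiled code is
the ODE integrator, where compiled code is the norm for this kind of
kinetics work.
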