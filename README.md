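# cochloc

Method-agreement analysis for cochlear-implant electrode localization,
with post-hoc collocation of the mid-modiolar axis.

## The problem

After cochlear implantation, each electrode contact's position is reported
in polar coordinates about the cochlea's mid-modiolar axis: the
electrode-to-modiolar-axis distance (**EMD**, mm) and the angular depth of
insertion (**aDOI**, degrees from the round window, exceeding 360° past a
full turn). Manual raters and automated image-analysis tools both measure
these parameters from CT/DVT scans — but they do not select the *same*
mid-modiolar axis. A small 2-D axis disagreement imprints an
angle-dependent, partially periodic pattern on the per-electrode
differences between two measurement series, inflating Bland–Altman limits
of agreement even when electrode localization itself is sound.

`cochloc` is for audiologists, imaging researchers and methodologists who
compare electrode-localization methods (or raters). It provides:

* the coordinate model — polar/Cartesian transforms with multi-turn angle
  unwrapping along the array;
* **axis collocation** — for each array, the translation
  $(s_x, s_y)$ of the moving method's electrode cloud minimizing

  $\mathrm{cost}(s_x,s_y)=\bigl(1-\rho(\mathrm{EMD}^t,\mathrm{EMD}^{ref})\bigr)+\bigl(1-\rho(\mathrm{aDOI}^t,\mathrm{aDOI}^{ref})\bigr)$,

  where $\rho$ is the Pearson correlation and the superscript $t$ marks
  the moving set re-measured after the shift (multi-start Nelder–Mead,
  with a brute-force grid oracle);
* the agreement battery — Bland–Altman bias and ±1.96·SD limits of
  agreement, percentage error, Pearson *r* with Fisher-z CI, two-way
  mixed-effects ICC with absolute agreement, Lilliefors normality check,
  and Wilcoxon/ANOVA confounder subgroup tests;
* a synthetic spiral-cohort generator (50 arrays × 12 electrodes by
  default, hidden axis offsets, noise calibrated so two raters reproduce
  interrater limits of ±0.2 mm / ±10°) so the whole pipeline is testable
  without patient data.

## Worked example

```r
library(cochloc)

cfg <- spiral_cohort_config(n_arrays = 10, seed = 42)
coh <- generate_cohort(cfg)
meas <- coh$measurements
auto <- meas[meas$method == "auto", ]          # axis hidden-offset method
r1   <- meas[meas$method == "manual_rater1", ] # reference method
r2   <- meas[meas$method == "manual_rater2", ]

criteria <- run_apriori(r1, r2)   # interrater criteria
report <- run_comparison(auto, r1, criteria = criteria)
report
```

```
== As measured ==
<agreement_report> EMD (120 pairs)
  bias 0.025 mm, LoA [-0.432, 0.482] mm
  percentage error 40.8%, r = 0.817 [0.748, 0.869], ICC(A,k) = 0.895
  Lilliefors D = 0.070, p = 0.161, normal: TRUE
<agreement_report> ADOI (120 pairs)
  bias -0.627 deg, LoA [-16.450, 15.196] deg
  percentage error 14.4%, r = 0.998 [0.997, 0.999], ICC(A,k) = 0.999
  ...
== After axis collocation ==
<agreement_report> EMD (120 pairs)
  bias -0.000 mm, LoA [-0.179, 0.178] mm
  percentage error 15.9%, r = 0.968 [0.954, 0.977], ICC(A,k) = 0.984
  ...
verdict: EMD bias acceptable: TRUE; aDOI bias acceptable: TRUE
```

Read: as measured, the EMD limits of agreement (±0.46 mm) are dominated by
the hidden axis offsets; the per-array collocation removes that component
and the limits shrink to ±0.18 mm — inside the interrater criterion of
±0.21 mm computed by `run_apriori()` — while the aDOI limits fall from
about ±16° to ±10°. `report$shifts` holds the recovered per-array shifts,
which estimate the generator's hidden offsets (`coh$truth`).

## Analysis workflow

The `analysis/` scripts run the study workflow end to end, writing tables,
figures and JSON reports under `results/`:

```sh
Rscript analysis/01_simulate.R     # synthetic cohort + truth sidecar
Rscript analysis/02_apriori.R      # interrater criteria
Rscript analysis/03_compare.R      # comparison as measured
Rscript analysis/04_collocate.R    # axis collocation + re-comparison
Rscript analysis/05_confounders.R  # voxel-size / image-quality checks
```

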