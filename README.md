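# deformacyte

Analysis and simulation toolkit for **combined electro-optical
deformability cytometry**: a microfluidic measurement in which single
cells, deformed by viscoelastic shear flow in a 40 × 30 µm channel, are
characterised simultaneously by

* **electrical deformability (ED)** — the ratio |ΔI₁|/|ΔI₂| of
  differential impedance amplitudes from two electrode configurations
  probing orthogonal projections of the cell, normalised so rigid
  calibration beads read 1; and
* **optical deformability (OD)** — the major/minor axis ratio of a
  moment-fit ellipse on a brightfield image captured by an
  impedance-triggered LED flash.

The impedance signal of each cell is an anti-symmetric double Gaussian;
its peak-valley separation Δt₁ over the electrode spacing D₁ gives the
velocity v = D₁/Δt₁, which predicts the arrival time at the imaging
window (Δt₂ = D₂/v) and fires the LED — so each camera frame contains
the same cell that produced the impedance event. Electrical diameter
follows the Coulter cube-root law d = 10 µm × (ΔI₁/ΔI₁,bead)^(1/3).
Cells sheared near the channel walls deform into tear-drops that inflate
OD but not ED; a lateral gate (±6.3 µm ≈ ±10 px around the midline)
removes this artefact. Dose-response experiments (e.g. graded
glutaraldehyde fixation) are summarised by a three-parameter Hill fit
y(c) = y_max + (y_min − y_max)·c/(EC₅₀ + c).

The package is aimed at instrument developers and analysts who need a
tested, ground-truth-backed implementation of this chain: a seeded
simulator of synchronized traces and frames, the event detector, the
image measurement, the correlation/gating logic, and the population
statistics.

## Worked example

Simulate one acquisition run (167 HL60-like cells + 33 beads at
10 µl/min), run the full detect–measure–correlate–gate chain, and
summarise:

```r
library(deformacyte)

cfg <- cohort_config(n_cells = 167, n_beads = 33, flow_ul_min = 10,
                     deform_mean = 1.16, event_rate_hz = 8, seed = 102)
res <- run_pipeline(list(cohort = cfg))
res$summary
#>       group  n ed_mean   ed_sd   ed_sem od_mean   od_sd   od_sem
#> 1 untreated 94   1.168 0.06452 0.006654   1.178 0.06471 0.006675
#> 2      bead 18   1.014 0.02467 0.005815   1.015 0.01119 0.002636
res$gated$report
#>       group retained total percent       summary
#> 1 untreated      100   149      67 100/149 (67%)
#> 2      bead       18    32      56   18/32 (56%)
res$coincidence$percent
#> [1] 1.7
res$calibration$optical$pixel_scale_um
#> [1] 0.6281
```

Reading this: the gated cell population reads ED 1.168 ± 0.065 and OD
1.178 ± 0.065 — the two modalities agree and recover the simulated
group mean of 1.16 — while beads sit at 1.01 in both, as rigid spheres
should. 1.7% of occupied frames contained two cells (coincidences,
excluded from the summary), and the pixel scale recovered from the
10 µm beads is 0.628 µm/px against a true 0.63. `res$cohort`,
`res$events`, `res$optics` and `res$gated$all` hold the per-stage
tables; `out_dir` in the config writes them as CSV with a YAML run
manifest.

`run_study()` repeats this over several cohorts (flow rates or doses)
and fits the between-modality line over group means; `fit_hill()`
estimates EC₅₀ from a dose series. A thin command-line wrapper with
`simulate / impedance / optics / correlate / fit-hill / report`
subcommands lives at `inst/cli/deformacyte.R`.

## Layout

| Path | Contents |
|---|---|
| `R/geometry.R` | channel/acquisition config, duct velocity profile |
| `R/cohort.R`, `R/trace.R`, `R/frames.R` | ground-truth simulator: cohorts, impedance traces, triggered frames |
| `R/impedance.R` | event detection, velocity, trigger prediction, ED, electrical diameter |
| `R/optics.R` | preprocessing, segmentation, moment ellipse, OD, calibrations |
| `R/fusion.R` | event-frame matching, coincidence, blur, Y gate |
| `R/stats.R` | group stats, linear fits, Welch tests, Hill dose-response |
| `R/pipeline.R` | end-to-end pipeline, study driver, table validation |
| `vignettes/deformacyte-methods.Rmd` | models, assumptions, design choices, limitations |
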