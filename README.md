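# t1track

Simulation and quantification toolkit for ferumoxytol-enhanced myocardial
"T1 tracking": measuring the cyclic change in intramyocardial blood volume
(iMBV) between end-systole (ES) and end-diastole (ED) with a continuous,
spoiled steady-state (SPGR) MRI sequence that alternates slab-selective (3D)
and slice-selective (2D) excitation.

## Why

iMBV — the fraction of myocardial tissue occupied by intravascular blood —
peaks at end-diastole and dips at end-systole; the size of that drop reflects
coronary microcirculatory function and falls with coronary disease, without
any pharmacological stress. With an intravascular contrast agent the drop can
be read from pre/post-contrast T1 maps at the two cardiac phases using the
fast-exchange formula

    iMBV = (1/T1_post^tissue - 1/T1_pre^tissue) / (1/T1_post^blood - 1/T1_pre^blood)

but conventional magnetization-prepared T1 mapping mixes ES and ED spin
histories, and plain 2D steady-state imaging is confounded by in-flow and
through-plane motion. The hybrid 2D/3D sequence modelled here keeps every
spin that can move into the slice at its SPGR steady state
`S = M0 sin(a) (1-E1)/(1-E1 cos(a))`, `E1 = exp(-TR/T1)`, and opens a brief
(< 100 ms) 2D imaging window with tiny golden-angle (23.63°) radial readouts
once per heartbeat. An FA 3° (proton-density-weighted) and an FA 20°
(T1-weighted) scan are combined: their ratio is inverted to T1 through a
Bloch-simulation look-up table, "instantaneously" per readout.

The package provides, for this measurement chain:

* a longitudinal Bloch engine with closed-form SPGR steady states, driven
  relaxation times, Ernst angles and hard-pulse slice-profile simulation;
* ECG-locked hybrid 2D/3D schedules, the feasible-heart-rate analysis and
  the cyclic T1-tracking experiment;
* a two-compartment water-exchange (Bloch-McConnell) signal model with the
  fast-exchange / no-exchange iMBV estimators and the SPGR
  exchange-independence condition;
* look-up-table T1 mapping with PD normalization and B1+ correction;
* digital cardiac and capillary phantoms with multi-coil golden-angle
  radial k-space simulation (exact DFT or gridding NUFFT);
* density-compensated gridding and CG-SENSE reconstruction;
* the end-to-end ES/ED iMBV pipeline, segment-wise repeatability (CoV) and
  group-comparison utilities.

## Worked example

```r
library(t1track)

# protocol with the 99 ms (22-projection) imaging window
p22 <- seq_params(projections_per_beat = 22)

# highest heart rate at which out-of-slice spins re-reach steady state
# (5% tolerance) before each imaging window, T1 = 1800 ms
max_feasible_heart_rate(fa = 20, t1 = 1800, params = p22)
#> [1] 182
max_feasible_heart_rate(fa = 3, t1 = 1800, params = p22)
#> [1] 100

# sensitivity of the fast-exchange estimate to pre-contrast blood T1 error
pair <- contrast_pair(tissue_pre = 1493, tissue_post = 985,
                      blood_pre = 1800, blood_post = 340)
imbv_sensitivity(pair, which = "blood_pre", delta = -200)
#> [1] 0.02998302
```

The first two numbers say the 20° T1-weighted drive tolerates essentially
any clinical heart rate while the 3° PD-weighted drive is the limiting scan;
the third says a 200 ms mis-measurement of an 1800 ms pre-contrast blood T1
moves the estimated blood volume fraction by only 3% (relative) when the
post-contrast blood T1 is 340 ms — the estimator is dominated by the short
post-contrast blood T1.

The full synthetic experiment — digital cardiac phantom, eight radial
acquisitions (pre/post × ES/ED × PD/T1-weighted), CG-SENSE reconstruction,
T1 maps, iMBV maps — runs as:

```r
cfg <- pipeline_config(
  phantom = phantom_spec(matrix_size = 96, snr = 30),
  total_beats = 120, seed = 1,
  out_dir = "t1track_run")
res <- run_pipeline(cfg)
round(100 * c(programmed = res$summary$programmed_rel_change,
              measured  = res$summary$measured_rel_change), 1)
#> programmed   measured
#>       19.5       18.5
```

i.e. the pipeline recovers the programmed 19.5% ES-to-ED iMBV drop from
noisy k-space to within about one percentage point (the seed-to-seed
scatter at this scan length is ~0.7 points). NIfTI maps, CSV
tables, a JSON summary and the resolved YAML config land in `out_dir`. A
thin shell wrapper is installed as `exec/t1track`
(`t1track run|figures|simulate`).

`reproduce_figures()` regenerates the simulation study tables (feasible
heart rate per flip angle, T1-tracking traces, exchange-regime bias,
slice-profile sensitivity, fast/no-exchange convergence) as tibbles/CSVs,
with `autoplot()` / `plot_*()` companions.

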