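# timerflow

Preprocessing of Fluorescent Timer flow-cytometry data: thresholding,
autofluorescence-based normalization, and the trigonometric
transformation into Timer Angle and Timer Intensity.

## The problem

Fluorescent Timer proteins (e.g. the mCherry-derived Fast-FT) emit blue
fluorescence immediately after translation and mature spontaneously and
irreversibly into a red-emitting form, with a maturation half-time of
about 4 hours for Fast-FT. The blue/red balance of a single cell
therefore encodes the time elapsed since the reporter locus was switched
on — the basis of the Tocky ("Timer of cell kinetics and activity")
approach to reading transcriptional dynamics by flow cytometry.

Quantifying that balance is fragile in practice: there is no calibration
standard for the two Timer channels, detector voltages vary between
instruments and users, and any blue/red acquisition bias skews the
apparent maturation state. `timerflow` implements the standard
preprocessing chain that makes Timer measurements comparable:

1. **Thresholding.** Gating thresholds for Timer Blue and Red are taken
   from a Timer-negative control sample, either as per-channel empirical
   quantiles (default q = 0.975, linear interpolation) or as manual
   values. Cells above either threshold are Timer-positive; the rest are
   autofluorescent background.
2. **Normalization.** With `B_log = log10(max(B, floor))` (and likewise
   `R_log`), each cell is normalized against the *gated* negative
   control (the control cells at or below both thresholds):

   ```
   B_norm = (B_log − max(B_log,gated_neg)) / s(B_log,gated_neg)
   R_norm = (R_log − max(R_log,gated_neg)) / s(R_log,gated_neg)
   ```

   where the scale `s` is the MAD (×1.4826, the default) or the SD.
   Because a gain change multiplies raw fluorescence, it only shifts the
   log values — and the shift cancels exactly against the gated-negative
   maximum, which is what makes the downstream angle instrument-invariant.
3. **Trigonometric transformation.** After clamping negative normalized
   values at 0,

   ```
   I = sqrt(B_norm² + R_norm²)         (Timer Intensity)
   θ = arccos(B_norm / I) · 180/π      (Timer Angle, degrees)
   ```

   so θ runs from 0° (pure blue, new expression) to 90° (pure red, aged
   expression); cells at the origin carry a missing angle.

The package also ships a kinetic simulator — a two-compartment linear
ODE of production, blue→red maturation and shared degradation — that
generates complete synthetic time-course datasets (CSV files plus
negative control and ground-truth sidecars), so the entire pipeline is
testable without instrument data.

## Worked example

```r
library(timerflow)

dir <- file.path(tempdir(), "tocky_demo")
manifest <- simulate_timecourse(
  kinetics_config(),                     # 4 h maturation half-time
  measurement_config(n_cells = 1000, seed = 1),
  timepoints = c(0, 8, 24), samples_per_timepoint = 1,
  output_dir = dir)

result <- timer_transform_batch(manifest, spec = threshold_spec("quantile", 0.975))
result$params
#> <normalization_params> method=MAD, log10 floor=1, n_gated_neg=952
#>   blue: location=2.4810 scale=0.2510
#>   red:  location=2.4938 scale=0.2342

summarize_batch(result, manifest)[, c("sample_id", "group",
                                      "n_timer_positive", "mean_angle")]
#>           sample_id      group n_timer_positive mean_angle
#> 1 sample_t000h_rep1         0h               52   57.97826
#> 2 sample_t008h_rep1         8h              775   26.66405
#> 3 sample_t024h_rep1        24h              801   42.98028
#> 4  negative_control unassigned               48   45.90320
```

At 0 h essentially no cell exceeds the autofluorescence thresholds (52
of 1000, matching the 2.5% false-positive rate of the q = 0.975 gate,
and carrying no real Timer signal). By 8 h most cells are
Timer-positive with a low mean angle (~27°: mostly immature, blue
protein), and by 24 h the mean angle has risen to ~43° as the blue
protein matures into red — the angle tracks time since expression
onset.

The same pipeline is available from the shell via the installed CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/timerflow.R", package="timerflow"))')" \
    simulate --out data --seed 1
# -> data/*.csv, data/manifest/, data/truth/
...  prep --dir data --pattern '*.csv' --negfile data/negative_control.csv \
         --blue Timer_Blue --red Timer_Red --out prep
...  transform --manifest prep --out out
...  qc --manifest data/manifest --out qc
...  sweep --manifest data/manifest --out sweep.csv --quantiles 0.95,0.975,0.99
```

Exit codes: 0 success, 1 configuration error, 2 data error. Every run
directory receives a `run_config.yaml` echo and a version-stamped
`run.log`.

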