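---
title: "Preprocessing Fluorescent Timer flow-cytometry data with timerflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preprocessing Fluorescent Timer flow-cytometry data with timerflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timerflow)
```

## The measurement and its model

A Fluorescent Timer protein is translated in a blue-emitting immature
form whose chromophore matures irreversibly into a red-emitting form.
In a flow cytometer each cell yields one blue and one red intensity, and
the blue/red balance encodes how long ago the reporter was switched on:
cells that just started transcribing are almost purely blue, cells that
stopped long ago are almost purely red, and continuously transcribing
cells settle at an intermediate balance set by the maturation and
degradation rates.

`timerflow` converts raw per-cell blue/red intensities into two derived
quantities:

* **Timer Angle** θ ∈ [0°, 90°]: the polar angle of the cell's
  (normalized blue, normalized red) coordinates; 0° is pure blue (new
  expression), 90° pure red (aged expression).
* **Timer Intensity** I ≥ 0: the norm of the same coordinates; overall
  Timer expression strength above background.

Three stages produce them, always in this order and always with
statistics frozen from a single Timer-negative control:

1. thresholds from the negative control (quantile or manual);
2. normalization statistics from the *gated* negative control (cells at
   or below both thresholds);
3. per-cell log-transform, normalization, positivity/quadrant
   classification, and the polar transform — applied identically to
   every sample and to the control itself.

The batch entry point `timer_transform_batch()` enforces that order; the
per-stage functions (`compute_gate_thresholds()`,
`gate_negative_cells()`, `compute_normalization_params()`,
`transform_sample()`) are exported so each stage can be inspected.

### Assumptions

* The negative control measures autofluorescence only, and the samples'
  background is distributed like the control's (same instrument
  settings within a batch).
* Acquisition bias acts multiplicatively per channel (a gain/voltage
  change scales intensities). On the log scale this is an additive
  shift, which cancels exactly in `B_norm = (B_log − max_gated_neg) /
  scale_gated_neg` because the location and every log value shift
  together and the spread of a shifted set is unchanged. This is the
  property that makes the Timer Angle instrument-invariant, and it is
  asserted to 1e−9 in the test suite for multipliers 0.1–10 applied to
  all files including the control. If a bias were applied to samples
  but *not* to the control the cancellation would not occur.
* Upstream quality control (compensation, doublet/dead-cell removal,
  target-population gating) has already been done in external software;
  the package ingests per-cell CSV exports.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `quantile_q` | 0.975 | — | Per-channel negativity gate leaving a 2.5% autofluorescence tail; a conventional choice, fully configurable, or replaced by manual thresholds. |
| `method` | `"MAD"` | — | Scale of the gated-negative log values. MAD (×1.4826, so it estimates the SD under normality) resists outliers that survive gating; `"SD"` (n−1 denominator) is the alternative and agrees with MAD within a few percent on Gaussian backgrounds. |
| `log_floor` | 1 | raw units | Values below the floor are raised to it before `log10`, making the transform total for the zero/negative values that baseline-subtracted exports contain. |
| `normalize` | `TRUE` | — | `FALSE` centers the log values (x − location) without scale division — the "non-normalized" angle used to demonstrate bias sensitivity. |
| `min_gate` | 10 | cells | Below this, the gated-negative max and MAD/SD are meaningless; the run aborts rather than emitting unstable parameters. |

## Numerical choices and degenerate inputs

* **Quantile definition**: linear interpolation between order statistics
  (R's type 7), the common statistical-software default, cross-checked
  in the tests against an independently coded interpolation.
* **Gating is inclusive (≤), positivity strict (>)**: a cell exactly at
  threshold is background. The same thresholds serve to gate the
  negative control and to select Timer-positive sample cells; both are
  derived from the same autofluorescence boundary, and nothing in the
  pipeline requires them to differ (manual mode allows any values).
* **Clamping**: normalized values below 0 are floored at 0 before the
  polar step, so the arccos argument lies in [0, 1], θ ∈ [0°, 90°]
  exactly, and I measures expression *above* background. The unclamped
  `blue_norm`/`red_norm` are still emitted for QC.
* **Origin cells**: when both clamped coordinates are 0, I = 0 and the
  direction is undefined; the angle is missing (`NA`), never an
  arbitrary 0°. Angles and intensities are reported only for
  Timer-positive cells.
* **Degenerate control**: if all gated log values coincide, or the
  chosen scale is 0 (a zero MAD can occur with heavy ties even when the
  SD is positive), the run aborts with a "degenerate negative control"
  error — never a silent division by ~0.
* **Output precision**: CSV outputs are written at 6 significant
  digits; in-memory results keep full double precision, and exactness
  claims (invariance to 1e−9, Pythagoras to 1e−12 relative) refer to
  the in-memory values.

## The synthetic-data generator

`kinetics_config()` defines the minimal kinetic model consistent with
blue→red maturation: production p (molecules/h), maturation
m = ln 2 / 4 h, shared degradation d = ln 2 / 24 h,

    dB/dt = p − (m + d) B,   dR/dt = m B − d R,   B(0) = B0, R(0) = 0.

`kinetic_amounts()` evaluates the closed-form solution (with an exact
d = 0 limit) and is verified in the tests against a numerical ODE
integration (deSolve, tolerance 1e−10) to 1e−6 relative error, against
the ODE residual on a time grid, and against the conservation law
B + R = p·t when degradation is off. The 4 h maturation half-time is
the one experimentally grounded constant for Fast-FT; the remaining
defaults (24 h protein half-life, p = 1000 molecules/h with a 0.5
lognormal CV across cells, uniform onset ages over the stimulation
interval — the continuous-stimulation picture) are documented fixture
choices for a plausible activation time course, not estimates of any
real dataset, and were fixed once before the validation suite was run.

`measurement_config()` adds the instrument: channel gains (units per
molecule; unequal gains reproduce acquisition bias), multiplicative
lognormal measurement noise (CV 0.3), and additive lognormal
autofluorescence in both channels for *every* cell (log10 mean 2.0,
log10 SD 0.25, i.e. background around 100 raw units), plus an inert FSC
channel. `simulate_timecourse()` writes one CSV per
timepoint × replicate (default 11 × 3 = 33 sample files), a negative
control, per-cell ground-truth sidecars, and a ready manifest; every
file has a seed derived deterministically from the master seed, so
reruns are byte-identical.

What the generator does **not** emulate: spectral spillover and
compensation artefacts, cell-size (FSC) dependence of fluorescence,
instrument pulse shape, doublets, or the biology of any particular
reporter locus. Passing tests therefore demonstrate the correctness and
invariances of the preprocessing arithmetic under realistic noise and
background — not robustness to every artefact of real cytometry data.

## Design decisions on genuinely open points

* **SD vs MAD**: the normalization is conventionally written with the
  SD, while robust practice prefers the MAD. Both are supported; MAD is
  the default, and the 1.4826 consistency constant makes the two
  interchangeable on Gaussian backgrounds (asserted within 3% at n =
  10⁵ in the tests).
* **"Non-normalized" angle**: defined here as the centered-only variant
  (log value minus the gated-negative maximum, no scale division,
  clamped at 0). This is one consistent reading; it keeps the two modes
  on the same log scale so their angles are directly comparable, and it
  reproduces the expected bias behaviour (the angle is non-increasing
  in a blue multiplier).
* **Bias invariance is tested with the multiplier applied to all
  files**, control included — the reading under which normalization
  cancels the bias exactly, as a change of detector gain would affect
  every tube in a batch.
* **One negative control per run**: multiple controls would require a
  pooling rule the method does not define.
* **Interactivity replaced by scripts**: manual thresholds plus the
  `sweep` subcommand (a grid over quantile × scale method × normalize
  flag, long-format output) replace interactive gating and the
  exploratory GUI, for reproducibility.
* **MFI**: arithmetic mean of raw values over all cells by default
  (geometric mean available), computed per sample alongside quadrant
  fractions and mean angle/intensity in `summarize_sample()`.
* **Plots are projections**: `plot_tocky()`'s three modes (raw log
  blue/red with threshold lines; normalized blue/red for Timer-positive
  cells; angle 0–90° vs intensity) always return — and optionally write
  — the plotted points as CSV, so correctness is asserted on data, not
  pixels.

## Validation problem sizes

The test suite generates all data in code: tiny enumerable tables for
exact oracles (≤ 20-cell tables against an independently coded
brute-force evaluation of the whole chain, 100 seeded instances),
1,000–3,000-cell samples for distributional and invariance properties
(10,000 cells total in the multiplier-invariance check), and a
33-file × 200-cell time course for the end-to-end determinism run.
These sizes were chosen to make every property measurable with
comfortable statistical margins while keeping the suite quick to run.

## Known limitations

* No FSC-based size correction of fluorescence: negative controls
  typically lack the large activated cells needed to calibrate it, and
  modern (spectral) instruments are less size-sensitive.
* Autofluorescence-based normalization extrapolates the background
  statistics to the bright end of the distribution; cells with extreme
  expression may be imperfectly corrected.
* Input is the CSV per-cell export dialect (comma, header row, "."
  decimal); FCS files are not read directly — export them to CSV with
  the acquisition software first.
* The angle is a per-cell maturation readout, not a rate estimate;
  converting angle distributions into transcriptional dynamics is
  downstream analysis outside this package's scope.
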