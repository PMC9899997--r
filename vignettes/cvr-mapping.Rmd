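---
title: "Methods: continuous CVR indices from multi-channel NIRS and niABP"
author: "cvrmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous CVR indices from multi-channel NIRS and niABP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrmap)
```

## The measurement model

Cerebrovascular reactivity (CVR) indices are moving Pearson correlations
between slow (0.005–0.05 Hz) fluctuations of a driving-pressure signal and
a cerebral blood-volume surrogate. `cvrmap` computes them from two
asynchronous device streams:

* **niABP** — finger-cuff arterial pressure, nominally 100 Hz, in mmHg.
  Its device output lags the physiology; a fixed correction (below)
  compensates.
* **NIRS channels** — for each transmitter–receiver pair, oxy- (HbO) and
  deoxyhemoglobin (HHb) at nominally 250 Hz, in arbitrary concentration
  units, for both the 30-mm *normal* channel (scalp + cerebral tissue) and
  the 10-mm *short* channel (scalp only).

The processing chain is:

1. **Delay alignment.** The NIRS timestamps are shifted forward by a fixed
   `nirs_delay` (default 3.22 s), rounded to a whole number of native
   samples — 805 at 250 Hz, 322 at 100 Hz — with the sub-sample residual
   logged in the record metadata. Whole-sample shifting preserves waveform
   morphology; at the 10-s averaging scale a sub-sample interpolation would
   buy nothing. Both streams are then trimmed to their common overlap. No
   resampling is ever performed: the two streams keep their native rates
   and are only ever combined *after* decimation onto shared wall-clock
   windows, which avoids interpolation artifacts entirely and is exactly
   equivalent for window means.
2. **Short-channel subtraction.** `pure = normal − scale × short`,
   elementwise, with `scale = 1` by default (no regression coefficient is
   fitted; the gain is configurable via `short_scale`). Since the short
   channel samples only extracerebral tissue, any scalp process common to
   both channels cancels.
3. **Derived traces.** `tHb = HbO + HHb`, `HbDiff = HbO − HHb` (exact
   identities, enforced float-exactly), and `rSO2 = 100 · HHb / tHb` as a
   percentage. Samples with non-positive tHb give missing rSO₂. The HHb
   numerator follows the acquisition software's published trace definition;
   the conventional oxygen-saturation ratio (HbO/tHb) is available via
   `rso2_numerator = "HbO"`, and a note is emitted whenever the default is
   used so no analysis silently assumes the wrong convention. COx inherits
   whichever convention is configured (with the HHb numerator its sign is
   flipped relative to HbOx).
4. **Decimation.** Every trace is reduced by non-overlapping 10-s
   arithmetic means anchored at the aligned record's start, timestamped at
   window right edges, incomplete trailing window dropped. A uniform full
   period of any sinusoid sums to zero, so the 10-s mean *analytically*
   annuls components at multiples of 0.1 Hz — cardiac pulsation and Mayer
   waves — while the 0.005–0.05 Hz vasogenic band passes nearly untouched.
5. **Sliding correlation.** For each surrogate (HbO, HHb, tHb, HbDiff,
   rSO₂), the Pearson correlation with niABP over the last 30 decimated
   means (a 300-s window), advanced every decimated sample (10 s). This is
   the standard pressure-reactivity construction: fully overlapping windows,
   not block-wise. Five indices per channel: HbOx, HHbx, tHbx, HbDiffx,
   COx, all in [−1, +1].

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `nirs_delay` | 3.22 | s | Delay added to NIRS timestamps (device-pair calibration) |
| `decim_window` | 10 | s | Non-overlapping mean length; sets confounder rejection at k/10 Hz |
| `corr_window` | 30 | means | Correlation window (300 s); shorter = noisier, more responsive |
| `update_step` | 1 | means | Hop between windows (10 s update rate) |
| `min_valid_fraction_per_mean` | 0.5 | — | Raw-sample validity needed per 10-s mean |
| `min_valid_means_per_window` | 30 | count | Joint-valid mean pairs needed per index value |
| `short_scale` | 1.0 | — | Short-channel subtraction gain |
| `rso2_numerator` | `"HHb"` | — | rSO₂ ratio numerator (`"HbO"` for the saturation convention) |
| `cadence` | 10 | s | Heat-map frame interval |

## Missing data and degenerate inputs

Missing samples are explicit markers (`NA` in memory, `NaN` cells in CSV;
empty cells mean "this stream has no sample on this tick"). Missingness is
monotone through the pipeline: a derived sample is missing whenever any
input sample is. A 10-s mean requires at least half of its raw samples; an
index value requires all 30 means jointly valid by default, so windows
spanning recording gaps are *skipped* (emitted missing), not shortened —
a shortened window would silently change the estimator's variance.
Zero-variance correlation windows (flatlined or clamped signals, which are
physiologically meaningful) yield missing values, never errors, and all
emitted values are clamped to [−1, +1] against float rounding. No
detrending is applied within the correlation window.

## The signal simulator

No public recordings exist for this device pairing, so the generator is a
first-class, tested module rather than a fixture. niABP is a sum of
sinusoids placed at physiological frequencies — cardiac (1.1 Hz, 20 mmHg),
respiratory (0.25 Hz, 3 mmHg), Mayer (0.1 Hz, 3 mmHg) and slow vasogenic
components (0.01/0.02/0.04 Hz at 3/5/2 mmHg, all constrained to the
0.005–0.05 Hz band) — around a 90-mmHg mean, plus white sensor noise. The
slow components form a unit-RMS carrier `s(t)`; each NIRS channel's
cerebral modulation is

    m(t) = coupling · s(t) + (1 − |coupling|) · u(t)

with `u(t)` an independent unit-RMS slow process (random phases per
channel and seed). The coupling in [−1, +1] is the directly recoverable
ground truth for the correlation indices: the downstream tHbx is a
nondecreasing function of it, exactly ±1 at the endpoints in the noiseless
case. The modulation enters HbO with amplitude +1.0 and HHb with −0.4
(arbitrary units — no amplitude ranges for hemoglobin slow waves are
established, and the indices are scale-invariant, so only the signs and the
rSO₂ ratio depend on these choices); a pressure rise therefore raises HbO
and tHb and lowers HHb. Both the normal and the short channel carry an
identical scalp process (scaled by `scalp_fraction`) and identical
extracerebral baselines, so unit-gain subtraction cancels them exactly; the
short channel has no cerebral component. tHb and HbDiff are formed exactly
from HbO and HHb. The ABP record is delayed by `nirs_delay_true` (default
3.24 s, a measured device lag), so the pipeline's 3.22-s correction leaves
a known 0.02-s residual — deliberately nonzero, and measurable by impulse
cross-timing via the simulator's `impulse_time` hook.

What the simulator does *not* emulate: the Lassen-curve nonlinearity
(pressure-passivity is a dichotomy, not a sigmoid), Windkessel dynamics,
motion artifacts and de-spiking, optical-density-to-hemoglobin conversion,
heart-rate variability, and nonstationary coupling. Passing parameter
recovery on this generator therefore demonstrates that the estimator
recovers a *linear slow-wave coupling under stationary conditions* — it
does not validate clinical thresholds on real data.

## Numerical and design notes

* **Merged CSV dialect.** Rows sit on the union of the two time grids; each
  stream fills only its own ticks. At 250/100 Hz the grids coincide only
  every 20 ms, so forcing ABP onto NIRS ticks would drop half its samples
  and break lossless round-tripping; the union grid keeps write–read an
  identity (cells are written with 17 significant digits). A
  one-file-per-device mode is also supported; both dialects are tested.
* **Window anchoring.** Decimation windows are anchored at the aligned
  record's common start for *both* streams, so the decimated timelines
  coincide by construction; the sliding window then intersects timestamps
  exactly (integer microsecond keys).
* **Correlation arithmetic.** Per-window two-pass (mean-centred)
  product-moment computation; constant windows are detected exactly before
  any division. The engine's sliding output is property-tested against
  independent per-window recomputation with `stats::cor` to 1e−12.
* **Mayer rejection and COx.** The analytic null of the 10-s mean makes
  every *linearly averaged* trace immune to 0.1-Hz contamination to float
  precision. rSO₂, however, is a per-sample ratio: Mayer content entering
  HbO/HHb *before* the ratio re-enters COx at second order (of the relative
  perturbation, ~1e−3 for even large perturbations). This is a property of
  the ratio definition itself, not of the implementation, and is covered by
  a dedicated test.
* **Colour map.** Linear symmetric blue–white–red: −1 → `#0000FF`,
  0 → `#FFFFFF`, +1 → `#FF0000`, missing → gray; `colour(−v)` is `colour(v)`
  with red and blue exchanged. Frames associate each channel with its most
  recent index value at or before the tick, expiring after one cadence
  interval. Channel markers are filled discs at the transmitter–receiver
  midpoint on a normalized [0,1]² template (cosmetic outline polygon, no
  anatomical registration); optional inverse-distance field interpolation
  is off by default, matching the discrete-patch display.
* **Layouts.** `lobar8`: one 30-mm channel per lobe per hemisphere, each
  with a 10-mm short reference. `grid4x4`: 8 transmitters + 8 receivers in
  a checkerboard, giving `r·(c−1) + c·(r−1) = 24` orthogonally adjacent
  channels. Layouts are declarative JSON, validated for role/separation
  consistency rather than hardcoded.

## Problem sizes used by the test suite

Simulated recordings of 330–700 s exercise the file-based pipeline
(330 s is just above the 310-s minimum for a first correlation window);
parameter recovery uses 900-s recordings over 10 seeds and three coupling
values; oracle equivalence uses 200 random decimated series. These sizes
give stable Monte-Carlo summaries while keeping the full suite around a
minute and a half.

## Known limitations

* The 3.22-s delay is a device-pair calibration constant, not estimated
  from data; a different hardware pairing needs its own measurement (the
  impulse cross-timing utility supports this).
* Short-channel subtraction is unit-gain; no per-channel regression scaling
  is fitted.
* Frames render headlessly to PNG; there is no interactive or real-time
  ("online") display, no forecasting, and no ICP-based reference index.
* Correlation windows spanning gaps are skipped; with very intermittent
  signals the index series can be mostly missing even when means exist.

```{r example, eval = FALSE}
cfg <- sim_config(duration = 600, coupling = c(ch1 = 0.9, ch2 = 0),
                  sensor_noise_sd = 0.2, seed = 42)
rec <- preprocess_record(align_streams(simulate_recording(cfg)))
idx <- compute_cvr(rec)
summary(idx)
plot(idx, index_type = "tHbx")
render_frames(idx, "lobar8", "tHbx", out_dir = tempfile())
```
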