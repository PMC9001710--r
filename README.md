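# avpipe

Analysis of primary visual cortex (V1) single-unit activity during **active
vision** — natural free viewing with self-initiated saccades — compared with
**passive vision** — a flashed image while fixation is held. The package
implements the complete analysis chain for laminar free-viewing recordings
and ships a synthetic-session generator with full ground truth, so every
stage is testable without any recorded data.

The two conditions are aligned to the moment visual input reaches the
system: the **image onset** (`img-on`, passive) and each **fixation onset**
after a saccade (`fix-on`, active). For every single-unit and condition the
pipeline asks: is there a significant firing-rate peak, at what latency,
and how sparsely is the response distributed over events?

## What it computes

- **Eye events** — saccades from Savitzky–Golay velocity/acceleration with
  the dual threshold 30 °/s and 8000 °/s², artifact screening, and
  fixations from inter-saccade intervals with gaze shift ≤ 1°.
- **Spike-train curation** — waveform up-sampling and minimum alignment,
  PCA + Gaussian-mixture re-clustering (≤ 3 clusters, BIC), rejection of
  clusters with > 0.1 % inter-spike intervals below 1.2 ms, merging of
  clusters with waveform R² > 0.95, and firing-rate change-point detection
  by sliding 30-trial Kolmogorov–Smirnov blocks under Benjamini–Hochberg
  control; only each unit's longest stationary segment is analyzed.
- **Responses** — PSTHs from a Gaussian kernel whose bandwidth minimizes an
  integrated-squared-error cost, sampled at 2 ms; the peak in [0, 300) ms
  gives the unit's latency; significance compares per-event spike counts in
  a 20-ms peak-centered bin against exclusive 20-ms baseline bins
  (passive: the second before img-on; active: from 1 s after img-on to
  image offset) by a two-sample KS test at α = 0.05. Units are classified
  doubly responsive / fixation-only / img-only / non-responsive, and split
  at 80 ms img-on latency into short/long latency classes.
- **Lifetime sparseness** — with per-event counts *rᵢ*, *i = 1..N*,

  S = (1 − a) / (1 − 1/N),  a = (Σᵢ rᵢ/N)² / (Σᵢ rᵢ²/N),

  counted in a 100-ms window centered on the PSTH peak; S = 0 for a unit
  responding equally to all events and S = 1 for a unit responding to
  exactly one. Condition comparisons use Wilcoxon signed-rank tests per
  cortical layer.
- **Image features** — the RF-windowed patch at each event (Gaussian window
  with SD = 0.25 × RF diameter) is scored for spectral contrast (radial
  power marginal weighted by a Gaussian CSF, mean 3.0 cycles/°, FWHM
  1.5 cycles/°) and orientedness (magnitude of the angle-doubled
  orientation resultant of the power spectrum, in [0, 1]); fix-on events
  can be subsampled so their contrast distribution matches img-on (decile
  histogram matching) to control contrast confounds.
- **Layers** — current source density from 1–100 Hz band-passed laminar
  LFP via the second spatial difference; the image-onset-evoked sink–source
  pair marks the layer 4c/5 boundary; depths map to supragranular /
  granular / infragranular bands (0.4-mm bands around the boundary), with
  channels > 1 mm below excluded as V2.

## Worked example

```r
library(avpipe)

session <- simulate_session(n_trials = 60, n_units = 45, seed = 11)
report  <- run_study(session, seed = 1)
report
```

```
Passive vs active vision study report
  units analyzed (V1): 45
  doubly responsive:   14 (31%)
  fixation-only:       24 (53%)
  img-only:            2 (4%)
  non-responsive:      5 (11%)
  sparseness supragranular: med img 0.582 / fix 0.692 (p = 0.01149, n = 15)
  sparseness granular:     med img 0.511 / fix 0.541 (p = 0.5137, n = 15)
  sparseness infragranular: med img 0.560 / fix 0.521 (p = 0.5895, n = 15)
  4c/5 boundary: 1.15 mm
```

Reading the output: far more units respond to fixation onset than to image
onset (fixation-only ≫ img-only) — the synthetic population injects that
asymmetry and the pipeline recovers it; supragranular units respond to only
a subset of fixations, so their fix-on sparseness exceeds their img-on
sparseness (significant in the supragranular layer only); the CSD boundary
estimate matches the generator's 1.15 mm ground truth. `report$latency`
additionally shows that units with long img-on latencies (> 80 ms) shorten
their latency under active vision, while short-latency units do not.

A sparseness calculation by hand:

```r
lifetime_sparseness(c(5, 5, 5, 5))   # 0      (equal response everywhere)
lifetime_sparseness(c(10, 0, 0, 0))  # 1      (response on a single event)
lifetime_sparseness(c(2, 0, 2, 0))   # 2/3    (a = 0.5, N = 4)
```

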