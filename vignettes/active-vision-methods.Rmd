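---
title: "Methods: passive versus active vision analysis for laminar V1 recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive versus active vision analysis for laminar V1 recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(avpipe)
```

## The problem

During natural vision, primates sample the world with several saccades per
second; each fixation onset delivers a new retinal image, much as a flashed
stimulus does during a classical fixation experiment. `avpipe` implements a
complete analysis chain for asking how V1 single-unit responses differ
between these two regimes: responses aligned to **image onset** (`img-on`,
passive vision — the animal holds fixation while an image appears) and to
**fixation onset** (`fix-on`, active vision — the animal's own saccade
brings a new patch into the receptive field). The quantities of interest
are responsiveness (does the unit have a significant rate peak?), peak
latency, and lifetime sparseness, each resolved by cortical layer.

Because real laminar free-viewing recordings are not publicly deposited,
the package pairs every analysis stage with a synthetic-session generator
that produces gaze traces, spike trains, stimulus images and laminar LFP
with exact ground truth. All claims made by the test suite are claims about
recovery of known synthetic structure, under noise models described below —
not about any particular animal dataset.

## Eye events

Velocity and acceleration are Savitzky–Golay derivatives (default window 21
samples, polynomial order 3, at 1 kHz) of the two position channels,
combined radially. Saccade candidates are maximal runs with velocity above
30 °/s; a run qualifies only if acceleration also exceeds 8000 °/s²
within it. A joint "both above threshold throughout" rule is not usable
verbatim: the acceleration magnitude of any smooth saccade passes through
zero at peak velocity, so the acceleration criterion is applied at segment
initiation, operationally anywhere within the run (with smoothed
derivatives the acceleration peak can trail the velocity crossing by a
couple of samples). Run edges are then refined outward to the flanking
velocity minima, which removes the systematic late bias a pure threshold
crossing has for onset times (the velocity of a minimum-jerk profile grows
quadratically from zero, so the 30 °/s crossing lags the true onset by a
couple of milliseconds).

Artifact screening bounds are configurable defaults, chosen from the
physiology of primate saccades rather than fitted to anything: duration
6–150 ms, amplitude 0.05–40°, peak velocity < 1200 °/s.

Inter-saccade intervals become fixations when the maximum pairwise
displacement of gaze within the interval is at most 1°. Maximum pairwise
displacement is the conservative reading of a "gaze shift" criterion — it
cannot miss a slow drift that returns near its start. Fixation onset equals
the preceding saccade offset, and duration runs to the next saccade onset,
so saccade and fixation intervals tile the trace.

## Spike-train curation

Waveforms are cut from the > 500 Hz (fourth-order Butterworth) high-passed
signal, cubic-spline up-sampled to 200 kHz, and aligned on their minima.
Re-clustering projects onto the first 3 principal components and fits
Gaussian mixtures with 1–3 components, selecting the model by BIC (the
number of clusters is otherwise unidentified). Clusters whose
inter-spike-interval refractory violations (< 1.2 ms) exceed 0.1 % are
discarded as multi-unit contamination. Cluster pairs whose mean waveforms
correlate with R² > 0.95 are merged; R² is maximized over integer lags
within ±10 samples because minimum alignment leaves residual jitter, and
merging acts on connected components so it is symmetric and transitive.

Firing-rate stationarity is enforced by change-point detection on per-trial
spike counts: a 30-trial block slides one trial at a time ("each and every
successive" block; a disjoint step-30 partition would localize change
points only to ±15 trials), the first and last 15 counts of every block
are compared by a two-sample KS test, and the resulting p-value series is
subjected to Benjamini–Hochberg control at α = 0.05. Each maximal run of
significant consecutive blocks is consolidated into a single change point
at the middle of the run's minimum-p block; without consolidation a single
rate step would generate a run of near-duplicate change points. Only the
longest segment between change points is analyzed; an exact length tie is
resolved toward the later segment, since late-session data follow
electrode stabilization. KS p-values on tied integer counts use the
asymptotic statistic, which is conservative under ties; no tie correction
is applied.

## PSTHs, latency and peak significance

The PSTH is a Gaussian-kernel rate estimate whose single bandwidth is
selected by minimizing an integrated-squared-error cost estimated from the
binned spike times (the fixed-kernel variant of kernel-bandwidth
optimization; the locally adaptive variant is deliberately not used — a
fixed bandwidth is deterministic, cheap, and sufficient for peak-latency
recovery to within ±10 ms in the regimes tested). The curve is sampled
every 2 ms and boundary-corrected so that its integral over the analysis
window equals the mean spike count per event. The peak is searched in
[0, 300) ms post-trigger; the window is a package default, wide enough for
the longest latencies considered (~120 ms) plus kernel spread.

Significance uses spike-count distributions, not the smoothed curve: counts
per trigger in a 20-ms bin centered on the peak (shifted inward when the
peak abuts the window edge) are compared by a two-sample KS test at
α = 0.05 against counts in exclusive 20-ms bins tiling the
condition-specific baseline — the second preceding each image onset for
the passive condition, and everything from 1 s after image onset to image
offset for the active condition (free viewing has no pre-stimulus period;
the first second is excluded to avoid the image-onset transient). A unit
counts as responsive only for rate *increases*: the KS test is sign-blind,
so the verdict additionally requires the mean peak count to exceed the mean
baseline count. The mean is used rather than the median deliberately: at
realistic V1 rates a 20-ms bin holds zero spikes in most events in *both*
distributions, so both medians are typically zero even for strongly
responsive units, and a median rule would destroy power without adding
specificity.

Fix-on triggers are restricted to post-saccadic fixations at least 100 ms
long (so the peak bin fits within the fixation), starting at least 200 ms
after image onset (excluding the first, image-onset-confounded fixation)
and early enough that the full analysis window fits inside the viewing
period. All three cutoffs are configurable.

Units are classified by the two significance verdicts (doubly responsive /
fixation-only / img-only / non-responsive) and split at 80 ms img-on
latency into short- and long-latency classes; paired latency differences
are reported for doubly responsive units only, since only they have a
defined latency in both conditions.

## Lifetime sparseness

With per-event counts \(r_i\), \(i = 1..N\):

\[ a = \frac{\left(\sum_i r_i / N\right)^2}{\sum_i r_i^2 / N}, \qquad
   S = \frac{1 - a}{1 - 1/N}. \]

Counts are taken in a 100-ms window centered on the condition's PSTH peak,
shifted to start at the trigger when the peak is earlier than 50 ms. S is
0 when the unit responds identically to every event and 1 when it responds
to exactly one; it is invariant to count rescaling and event permutation,
and moving a spike from a weaker to a stronger event can only increase it
(all property-tested). An all-zero count vector makes \(a\) a 0/0 form; it
is defined as S = 0 with a degenerate flag and excluded from condition
comparisons — a silent unit carries no sparseness information, and
including it under either convention (0 or 1) would bias layer medians.
Real-valued "counts" are accepted so rate-based inputs can reuse the
statistic. Note that S is also driven by the mean count: sparse Poisson
counts with small means give large S even without event structure, which
is why condition comparisons are paired within units.

Layer-resolved comparisons use Wilcoxon signed-rank tests (α = 0.05) of
fix-on versus img-on sparseness per layer, plus the contrast-matched
variant below.

## Image contrast and orientedness

For each trigger the patch at the receptive-field position (gaze plus RF
offset) is cut, luminance mean-subtracted over the inscribed circle, and
multiplied by a 2-D Gaussian with SD = 0.25 × RF diameter, so luminance
decays smoothly to the mean at the patch edge. From the 2-D power spectrum
with physical axes in cycles/°:

- **Contrast** — the radial marginal (integer-ring binning at the DFT's
  native resolution) weighted by a Gaussian contrast-sensitivity profile
  with mean 3.0 cycles/° and FWHM 1.5 cycles/° (SD = FWHM / 2√(2 ln 2) ≈
  0.637 cycles/°), summed over frequency. The DC bin is excluded: the mean
  is already subtracted, and residual DC from windowing is noise.
- **Orientedness** — the magnitude of the orientation resultant with
  **angle doubling**, \(|\sum P e^{i2\theta}| / \sum P\). Without doubling
  the resultant is identically ~0 for any real image, because the power
  spectrum obeys \(P(\theta) = P(\theta + \pi)\); doubling is the standard
  circular-statistics treatment of axial data. The magnitude (not the real
  part) of the complex resultant is taken, giving a value in [0, 1]: 0 for
  isotropic spectra, 1 for a single orientation, and ~0 again for two
  orthogonal orientations of equal power (their doubled angles are
  antipodal).

Contrast matching subsamples fix-on events so each img-on contrast decile
holds an equal share of retained events — decile histogram matching with a
seeded subsample. "Comparable contrast" has no unique definition; decile
matching was chosen over caliper nearest-neighbor matching because it is
distribution-level, needs no pairing, and its result is easy to audit with
a two-sample test. Fix-on events outside the img-on support are never
retained; disjoint supports yield an empty selection with a warning.

## Laminar layer assignment

LFP channels are band-passed 1–100 Hz (fourth-order Butterworth, applied
forward-backward for zero phase) and trigger-averaged around image onsets.
The CSD is the standard second spatial difference,
\(-[V_{k-1} - 2V_k + V_{k+1}]/h^2\) with h = 0.1 mm. More elaborate
inverse-CSD estimators exist, but locating a single sink–source pair is
robust to the estimator choice, and the second difference is fully
specified by the electrode geometry; an inverse method would be a drop-in
extension.

The layer 4c/5 boundary is the midpoint of the sink-above/source-below
channel pair maximizing |sink| + |source| at a common latency; the pair may
be adjacent or straddle one near-zero channel, because a boundary falling
exactly on a channel nulls the CSD there. Pairs must exceed 3 pre-trigger
SDs (with an absolute floor at numerical roundoff of the averaged LFP, so
an analytically flat CSD can never produce a spurious boundary); otherwise
the boundary is undetermined and units stay unassigned. A second
qualifying pair more than 1 mm deeper is reported as a putative V2
boundary. Depth bands relative to the boundary (positive above):
> 0.4 mm supragranular; (0, 0.4] granular; [−0.4, 0] infragranular (an
exactly-zero depth is infragranular, matching a "0 to 0.4 mm below" band
convention); < −1 mm excluded as V2. Depths between 0.4 and 1 mm below
carry no published band and are reported `unassigned` rather than guessed.

## The synthetic session generator

`simulate_session()` composes the generators into a full session; its
defaults are the study conditions under which the package's guarantees are
stated, chosen once from the physiology being emulated:

- **Gaze**: 1 kHz sampling (detection thresholds lose nothing relative to
  higher rates); trials of 1.2 s central fixation + 3 s free viewing;
  gamma fixation durations with mean ~168 ms giving ~15 fixations per
  trial, in the range reported for freely viewing macaques; gamma saccade
  amplitudes with mean 5° truncated to [1, 20]° (microsaccades are not
  modeled — the detector makes no saccade/microsaccade distinction, but
  sub-degree saccades sit below the velocity threshold by construction);
  minimum-jerk saccade displacement with a main-sequence duration law
  (~21 ms + 2.2 ms/°), so peak velocity grows with amplitude and exceeds
  the 30 °/s threshold for every generated saccade; fixational drift as a
  random walk with cumulative SD ~0.1° over 400 ms, safely below the 1°
  fixation criterion.
- **Stimuli**: isotropic 1/f-amplitude noise backgrounds — the canonical
  second-order stand-in for natural scenes — with five 2° Gabor objects at
  pairwise separations above 4°, on a 34.8 × 26.1° canvas.
- **Spikes**: inhomogeneous Poisson with rate = baseline + event-locked
  Gaussian kernels (amplitude-parameterized, so `gain` is the peak added
  rate in Hz); baselines log-normal around 6 Hz; response classes drawn
  with probabilities 0.52 / 0.34 / 0.02 / 0.12 (doubly, fixation-only,
  img-only, non-responsive); 20 % of units get a mid-session baseline
  step (×0.4 or ×2.5) to exercise segmentation. Simulation draws per-bin
  Poisson counts at 1 ms, which is exact in expectation at these rates.
- **Injected effects**: long-latency units (img-on latency ~N(110, 10) ms)
  respond to fix-on at ~N(70, 8) ms, short-latency units keep matched
  latencies; supragranular units respond to each fixation with probability
  0.12 (gain rescaled to conserve the mean), which raises their fix-on
  lifetime sparseness by ~0.1–0.2 over img-on while leaving other layers
  untouched. Both effects can be switched off for null studies.
- **LFP**: a dipolar potential constructed by discretely integrating the
  target CSD profile twice, so the second-difference estimator recovers the
  sink–source pair exactly; an alpha-function (τ = 40 ms) image-onset
  time course; 1/f temporal noise made spatially smooth across contacts
  (0.1-mm-spaced channels see nearly the same volume-conducted noise —
  spatially independent noise would be amplified ~h⁻² by any
  second-difference estimator and is not a realistic regime).

What the generator does **not** emulate: saliency-guided gaze (fixation
targets are random, so img-on and fix-on patch-contrast distributions are
similar rather than shifted as in real free viewing — contrast matching is
therefore exercised by dedicated shifted-distribution simulations, not by
the session), higher-order natural image statistics, burst/refractory
spike-train structure, eye-movement-locked LFP modulation, and
biophysical waveform variation beyond linear amplitude drift plus white
noise. Passing the end-to-end suite therefore demonstrates correct
recovery of the modeled structure, not robustness to everything real data
can do.

## Numerical and design choices worth knowing

- Problem sizes in the validation suite: eye detection is benchmarked on
  100 three-second trials; latency recovery on 4 × 50 simulated units;
  significance calibration on 500 null + 200 responsive units;
  change-point behavior on 200 + 500 simulated count series; the
  end-to-end study on 20 sessions of 60 trials × 45 units. These sizes
  give stable Monte-Carlo estimates while keeping a full run on one CPU
  in minutes.
- The end-to-end check of layer specificity asks that the supragranular
  paired sparseness test be significant *and* that the supragranular
  median fix−img difference be positive and the largest across layers.
  It does not additionally require the other layers to be non-significant:
  that would compound two 5 % null rejection rates into every run's
  success criterion, making the aggregate check fail ~15 % of the time by
  construction even when the package is correct.
- `run_study()` is deterministic given the session and its `seed`
  argument; the only stochastic stage is the contrast-matching subsample.
- Re-clustering and merging are exercised on waveform banks in their own
  tests; `run_study()` applies segmentation-based curation by default and
  leaves GMM re-sorting opt-in (`config$curation$recluster`), since
  simulated sessions carry known spike identities.
- Degenerate inputs are defined, not crashed: zero-spike PSTHs are flat
  and non-significant; all-zero sparseness is 0 with a flag; degenerate
  constant samples compare with p = 1 and a flag; an undetectable CSD
  boundary leaves units unassigned with a warning.

## Limitations

Latency is defined as the PSTH peak time, so it inherits kernel-bandwidth
bias for strongly skewed response profiles. The KS test on discrete counts
is conservative; exact tie-corrected alternatives would gain some power at
small event counts. The second-difference CSD assumes a homogeneous,
isotropic volume conductor. Sparseness comparisons are within-unit and
paired, but S itself conflates event-to-event selectivity with mean rate;
between-layer comparisons of absolute S should be read with that in mind.
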