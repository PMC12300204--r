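---
title: "Identifying people from saccade dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying people from saccade dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeid)
```

## The identification problem

When a point jumps to a new position on a screen, the oculomotor response it
elicits is highly stereotyped — a saccadic latency of roughly 150–200 ms, a
ballistic saccade whose peak velocity (300–500°/s over the 4–20° amplitude
range) and duration follow the *main sequence*, then a fixation with
micro-movements — yet the precise dynamics differ from person to person, and
those differences are stable enough to serve as a behavioural biometric.
`gazeid` implements an identification pipeline built on exactly this signal:
given 1000 Hz monocular recordings of a jumping-point task (100 positions
shown for 1 s each), it decides which of `l` enrolled users produced a
recording.

## From raw gaze to feature vectors

**Windowing.** Each stimulus position contributes the 303 horizontal-position
samples that immediately follow its onset. 303 is the minimal length whose
three successive point-to-point differences leave exactly 300 samples, i.e.
three segments of 100 covering latency, saccade and early fixation. Positions
whose 1000-sample block contains any `NaN` gaze (blinks, tracker dropouts)
are discarded entirely, and only positions valid in *every* trial of an
experiment are used — the first `X` of them in stimulus order — so all
subjects and sessions are represented by the same stimulus jumps.

**Dynamic channels.** Per segment, seven 100-element channels are computed
from horizontal position $x$:

* velocity $v = \partial x/\partial t$, acceleration $a = \partial v/\partial
  t$, jerk $j = \partial a/\partial t$ (point-to-point differences over
  $\Delta t = 1$ ms);
* their point-to-point percentage changes, e.g. $vc_i = (v_{i+1} -
  v_i)/v_i$, kept as fractions;
* the amplitude spectrum $A_k = \left|\sum_{m=0}^{n-1} v_m
  e^{-2\pi i m k/n}\right|$ of the segment's velocity, all $n = 100$ bins.

The velocity/acceleration/jerk series are truncated to their **last** 300
elements before segmentation so that all channels cover the same raw samples
as jerk (indices 3–302 of the window); trailing alignment keeps the channels
co-registered. Percentage-change series lose one element; they are padded
back to 100 by repeating their final value, an explicit and deliberately
boring rule. A percentage-change denominator below $10^{-12}$ in magnitude
yields 0 — fixation velocity sits near zero, and without the guard the
channel would be dominated by division artefacts.

**Statistical summary.** The 16-value vector holds (min, max, mean, std) of
$v$, $a$, $j$ and $A$, in that order, with the *population* standard
deviation (divide by $N$).

**Scaling.** Every channel is min–max scaled to $[0, 1]$. The extrema are
fitted on the training sessions only and applied to the held-out session
with clipping; fitting them on all data at once is available as
`scale_mode = "global"`, but the default avoids leaking test-session range
information into training. Because scaling is per-fold, the feature dataset
stores unscaled channels and defers scaling to evaluation time. The
statistical vector is computed from the scaled channels, so its entries also
live in $[0, 1]$.

## The two classifiers

Both networks are implemented natively in R (BLAS matrix operations,
backpropagation verified against finite differences in the test suite) and
trained with Adam (learning rate 0.001) on categorical cross-entropy for a
fixed epoch budget with **no early stopping**, so results from different
conditions remain comparable.

* **Recurrent model** (time-series features, input 100 steps × 7 channels):
  LSTM(64, full sequence) → dropout 0.5 → LSTM(64, final state) → dense 64
  (ReLU) → softmax over `l` labels. Dropout is applied only between the
  recurrent layers; the first layer passes its full hidden sequence to the
  second, which passes only its final state onward. Forget-gate biases are
  initialised to 1, all other weights Glorot-uniform.
* **Dense model** (statistical features, input 16): hidden ReLU layers of
  100, 75 and 50 neurons, then softmax.

**Batch size.** Neither architecture pins a batch size; the package default
is 16. With the moderate training sets this package typically sees (hundreds
to a few thousand segments), larger batches give the optimiser so few
updates per epoch that the dropout-regularised LSTM barely moves within a
short epoch budget; at batch 16 the same architecture trains reliably.
The batch size is a `train_config()` field, so any other choice is one
argument away.

## Evaluation protocol

Identification is evaluated with **Leave-One-Session-Out** cross-validation:
with `S` sessions the model is trained `S` times on `S − 1` sessions and
validated on the remaining one, so every fold tests on recordings acquired
at a different time from all training data — the template-aging regime that
makes eye-movement biometrics hard.

Within a fold, each of a user's `X · G` test segments is classified
independently, giving probability vectors $P_{ij}$. These are fused at score
level by the arithmetic mean,

$$P_{U_i} = \frac{\sum_j^{X\cdot G} P_{ij}}{X \cdot G},$$

and the identity is the argmax of $P_{U_i}$ (ties, which have measure zero
in practice, break toward the lowest class index). Accuracy, macro-averaged
F1 and Cohen's kappa are computed on these fused user-level decisions — one
decision per user per fold — and aggregated over folds as mean and
population standard deviation. Sample-level (pre-fusion) metrics are
available via `per_sample = TRUE` for diagnostics.

The bookkeeping follows `FVn = G × X` samples per user per session and
`T_FVn = S × FVn` per user overall; `sample_counts()` exposes the resulting
totals and split sizes, and the test suite checks them against the full
grid of published experiment designs (9 sessions × 14 users down to 3
sessions × 90 users).

## The synthetic cohort generator

Real multi-session gaze corpora are large external downloads, so the package
ships a parametric simulator that makes every stage testable. Each simulated
subject is a `subject_profile()`:

| parameter | unit | default | role |
|---|---|---|---|
| `latency_mean`, `latency_sd` | ms | 175, 15 | saccadic latency distribution |
| `vpeak_scale` | °/s | 480 | peak velocity of a 20° saccade |
| `duration_slope` | ms/° | 0.5 | extra saccade duration per degree |
| `fixation_noise_sd` | DVA | 0.05 | white micro-movement noise |
| `drift_rate` | DVA/s | 0.3 | slow fixation drift scale |
| `undershoot_frac` | — | 0.08 | fraction of the step left to correct |
| `blink_rate` | per position | 0.05 | Poisson rate of NaN runs |

Saccades follow a minimum-jerk trajectory (closed form, endpoint-smooth)
whose target peak velocity obeys a saturating main sequence
$V_p(A) = \texttt{vpeak\_scale}\,(1 - e^{-A/5})/(1 - e^{-20/5})$ — the
standard exponential form, normalised so `vpeak_scale` is the 20° peak
velocity — with `duration_slope` lengthening the movement beyond the pure
minimum-jerk duration. This keeps the main-sequence invariant exact: peak
velocity increases monotonically with amplitude for every profile. Landing
positions undershoot the target by `undershoot_frac` and are corrected by an
exponential glide (60 ms time constant) during fixation. Session-to-session
template aging is emulated by `session_effect()`: bounded multiplicative
drift of the velocity gain (|log gain| ≤ 0.2), a latency shift and noise
inflation. Blinks are Poisson-injected NaN runs of 50–150 ms.
`random_profiles()` draws cohorts uniformly over physiological ranges
(latency 150–200 ms, gain 380–560°/s, etc.), and every generator is a pure
function of its seed.

**What the simulator does not emulate** — and hence what passing tests do
*not* show about real data: microsaccades, tremor and other structured
fixational spectra (noise is white plus linear drift); vertical-channel
dynamics (targets sit on the horizontal axis; the vertical trace is noise,
present for file-format completeness only); calibration error, smooth
artefacts around blinks, and head-motion residuals; and crucially the
*true* between-subject distribution of oculomotor parameters — simulated
subjects differ exactly where the profile says they differ. Synthetic
results therefore validate the machinery (windowing, features, training,
fusion, protocol), not the field accuracy of the method on real recordings.

## Numerical choices and degenerate inputs

* Derivatives use $\Delta t$ in seconds, so units are °/s, °/s², °/s³; any
  constant factor would be absorbed by min–max scaling, making the choice
  cosmetic but documented.
* `minmax_scale` maps a constant channel to all zeros rather than NaN.
* An empty valid-position intersection, a window containing NaN, a class
  absent from a training fold, or fewer than 2 sessions each raise a typed
  error (`gazeid_validation_error`, `gazeid_insufficient_data`) rather than
  propagating silently.
* Cohen's kappa returns NaN when chance agreement is exactly 1 (both label
  sequences constant and equal) — the statistic is undefined there.
* Training is reproducible under a fixed seed in a single-threaded BLAS;
  bit-exactness across platforms or threaded BLAS builds is not promised.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run an 8-subject, 3-session cohort
with velocity gains spaced 25% apart, 20 retained stimulus positions (1440
segments in total) and a 30-epoch training budget — a size chosen so the
full LOSO × 2-classifier sweep completes in minutes on one CPU while still
being a genuinely multi-session, multi-subject identification task. Under
these conditions the LSTM's fused LOSO accuracy is expected to sit far above
the 0.125 chance level (the shipped checks require > 0.5), with the dense
model above chance. Larger cohorts, more sessions, the full 100-position
schedule and the 150-epoch budget are one configuration change away
(`default_config()`), at proportionally larger cost.

## Known limitations

* The simulator's separability is by construction; it cannot certify
  real-world accuracy.
* The LSTM is a plain non-CuDNN implementation in R: correct and adequately
  fast at desk scale, but not suited to corpus-scale training.
* Only the horizontal gaze channel drives features, matching the task's
  horizontal stimulus layout; oblique or vertical stimulus geometries would
  need a second channel.
* Identification is closed-set: the model always answers with one of the
  enrolled identities. Open-set rejection (verification, EER) is out of
  scope.
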