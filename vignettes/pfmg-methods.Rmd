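---
title: "Methods: pFMG gesture recognition and IR teleoperation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pFMG gesture recognition and IR teleoperation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfmg)
```

This vignette is the package's own account of the models, conventions and
design choices it implements. The pipeline targets pneumatic
force-myography (pFMG): an armband of five sealed air chambers whose
internal pressures deform with forearm muscle contraction, sampled at a
1.35 ms period (740 Hz), optionally with an IMU supplying absolute Euler
orientation at the same rate.

## The synthetic signal model

Participant recordings of this kind are typically not shareable, so the
package ships a generator whose output has the statistical structure the
recognition pipeline assumes, making every downstream stage testable. Each
recording of gesture $g$ on chamber $c$ is

$$ p_{g,c}(t) = \sigma_r(t)\,\mu_{g,c} + o_{j,c} + \delta t + \varepsilon_t $$

where $\mu_{g,c}$ is the gesture's held relative-pressure level,
$\sigma_r(t)$ a sigmoid onset envelope reaching the plateau after the ramp
time $r$, $o_{j,c} \sim N(0, \sigma_o^2)$ an offset drawn once per
(trial $j$, chamber) emulating how users re-form a gesture slightly
differently on each re-initiation, $\delta$ a slow common drift, and
$\varepsilon_t \sim N(0, \sigma_\varepsilon^2)$ i.i.d. sample noise.
Pressures are *relative*: the rest baseline is subtracted at generation
time, mirroring acquisition systems that reference each chamber to its
initial user pressure.

Defaults and why:

* **2000 samples per recording, 1.35 ms period, 3 trials per session** —
  the acquisition protocol itself: one recording spans 2.7 s, long enough
  to hold a static pose without fatigue.
* **Chamber-mean vectors** for the five shipped gestures (Fist, Pinch,
  Spread Fingers, Wave In, Wave Out) are honest inventions at realistic
  relative-pressure scales (1–8 units): no published numeric pressure
  values exist for this device class, so the defaults reproduce only the
  qualitative structure reported for it — Fist and Spread Fingers differ
  strongly on chamber 1, while chamber 2 (sitting over the pronator teres,
  which none of the five gestures recruits) stays near one common level
  across all gestures. `make_redundant_chamber()` reproduces that
  redundant-chamber situation exactly for robustness tests.
* **noise_sd = 0.35, trial_offset_sd = 0.25** — chosen once so that the
  smallest between-gesture separation on the most informative chamber
  (about 1.8 units) is roughly five noise standard deviations: clearly
  separable after window averaging, but not degenerate. The per-trial
  offset is smaller than any between-gesture separation yet large enough
  that leave-trial-out evaluation is a real generalisation test.
* **drift_slope = 0.02 units/s** — slow sensor/thermal drift, an order of
  magnitude below the gesture levels over a recording.
* **onset ramp = 200 ms sigmoid** — a plausible muscle-engagement
  timescale; published traces show stable plateaus but do not quantify the
  transition, so only the plateau matters downstream.
* **Euler sweeps are linear in time** over the recording (the
  quasi-dynamic instruction to users is merely to rotate "slowly");
  angles live in degrees on $[-180, 180)$.

What the generator does **not** model: chamber mechanics (hysteresis,
creep, lifetime cycling), inter-subject variability structure (exposed
only as spec parameters), armband re-donning shifts within a session, and
motion artifacts. Passing tests on generated data therefore demonstrate
the correctness of the pipeline's mechanics and its behaviour under the
stated signal model — not field performance on real forearms, which is
known to vary across individuals and sessions.

## Windowing and integrity checks

Windows of $W = 100$ samples (135 ms) advance at stride $S = 50$, i.e.
50% overlap. The general count is $\lfloor (N - W)/S \rfloor + 1$; the
textbook expression $N/S - 1$ is its special case when $W = 2S$ and $S$
divides $N$ (39 windows for $N = 2000$). Trailing partial windows are
dropped: a fragment shorter than a window would change feature scaling.

Two advisory checks mirror a real acquisition chain's fail-safes; both
only inform, and classification always consumes unfiltered data (for
steady pFMG plateaus, filtering was found unnecessary):

* **Spike alert**: flag a >20% change of the pressure value within less
  than one second. Three conventions make this well-posed on
  baseline-relative streams. The compared "pressure value" is a
  one-window (100-sample) moving average, since the rule targets genuine
  pressure transients rather than sample-to-sample sensor noise. The
  onset transient (first 10% of samples) is excluded, because the rule's
  scope is a *held* static gesture. And the relative-change denominator is
  floored at 20% of the stream's dynamic range: a barely engaged chamber
  sits near zero relative pressure, where a pointwise-relative ratio would
  flag ordinary noise; the floor anchors the rule to the pressure scale of
  an engaged chamber.
* **Band-pass validity check**: a 5th-order Butterworth band-pass copy
  (default pass band 0.5–330 Hz, i.e. inside a 10% margin of the Nyquist
  frequency) is produced for inspection, and a flag raises when the
  out-of-band fraction of spectral energy on the held, linearly detrended
  portion exceeds 25%. Detrending and the held-portion restriction keep
  the gesture's own plateau and onset — which are signal, not artifact —
  from dominating the lowest frequency bins.

## Features

Seventeen time-domain features per window and channel, the standard
myoelectric repertoire: IAV, WL, AAC, SSC, SSI, RMS, VAR, MAV, MAV1, MAV2,
ZC, TM3, TM4, TM5, WAMP, DASDV, MYOP. The four counting features (ZC, SSC,
WAMP, MYOP) take amplitude thresholds; the default is adaptive, 1% of the
window's dynamic range, since no canonical values exist for pressure
signals, and fixed numeric thresholds can be supplied where the scale is
known. Exact identities (SSI $= W \cdot$ RMS$^2$, MAV $=$ IAV$/W$, AAC
$=$ WL$/W$) and the homogeneity degrees (1 for amplitude features, 2 for
SSI/VAR, $k$ for TM$_k$) are enforced in the test suite against a
literal-loop oracle. A *featured frame* concatenates the five channels'
feature vectors in fixed channel order — $5 \times 17 = 85$ values — and
carries its gesture, session and trial labels.

## Feature selection

A filter method, independent of any classifier. For feature $f$, channel
$c$, gesture $g$ with frames $x_1 \dots x_m$:

* intra-gesture CV: $\mathrm{sd}(x)/|\bar{x}|$ — low means the feature is
  repeatable within a gesture;
* inter-gesture CV (per $f, c$): CV across gestures of the intra-gesture
  means — high means the feature separates gestures.

Scores are averaged over channels (intra additionally over gestures), the
features are ranked on each score, and the composite is
$2\,\mathrm{rank}_{\text{inter}} + 1\,\mathrm{rank}_{\text{intra}}$ (ties
alphabetical): separation is deliberately weighted above stability,
because two gestures can vary within themselves yet remain far apart.
Fixed-threshold masking (intra < 10%, inter > 20%) is available as a
diagnostic view only — a feature can pass on one chamber and fail on
another, which is why masking gives way to ranking. `select_top()` keeps
$\lfloor \text{fraction} \cdot n \rfloor$ features (at least one): halving
14 candidates keeps 7, halving the full 17-member registry keeps 8. Means
below $10^{-12}$ in absolute value fall back to that epsilon in CV
denominators and are marked unstable rather than dropped.

## Evaluation protocol

Frames from the same trial are never split: windows of one recording are
strongly dependent (50% overlap), so scattering them across train and test
would leak. All $\binom{n}{r}$ combinations of $r$ held-out trials at the
2:1 train:test ratio are enumerated in lexicographic order — 3 partitions
for a 3-trial session (inter-trial), 15 for the 6 trials of two sessions
(inter-session) — and metrics are averaged over partitions. Within each
partition, standardisation (zero mean, unit variance) is fitted on the
training fold only; zero-variance and linearly dependent columns (pivoted
QR, tolerance $10^{-7}$) are dropped there too, since exact relationships
like MAV $=$ IAV$/W$ would make discriminant covariance estimates
singular. The seven classifiers run on library defaults (RF fixed at 100
trees under a supplied seed; K-NN at $k = 5$ with full class-probability
votes for log loss). Log loss is averaged per partition, and a partition
whose training fold lacks a label present in its test fold is an error,
never a silent skip. Wall time is reported for interface parity but is
hardware-dependent and excluded from any assertion.

## Post-processing and control

Per-window predictions stream at roughly 10 per second (one per stride).
A queue of capacity 10 emits, once full, the modal label provided it fills
at least $\theta = 0.75$ of the queue; otherwise the period is too random
and the decision is `Unknown` (optionally replaced by the last confident
gesture, useful under user fatigue). The buffer then slides by one — a
latency choice over flush-and-refill, which would quantise decisions to
one per second. During warm-up the surface value is `pending`, never a
guess. Commands are debounced: a transmission happens only when the final
gesture changes state; `Unknown` never transmits.

Spatial augmentation is strictly post-prediction: orientation never enters
the features, so a held gesture under rotation (quasi-dynamic) classifies
identically to its static counterpart, and augmentation toggles without
touching recognition. At gesture onset the Euler triplet is captured as
the setpoint; while held, the controller output is
$\text{gain} \times \Delta$ with $\Delta$ the shortest-arc signed
difference on the gesture's configured axis, wrapped to $[-180, 180)$
(a 170° → −170° sweep is +20°, not −340°). Output modes: a repeat rate in
codes/second, an incrementing code index
($\lfloor \Delta/\text{step} \rfloor$), or a discrete three-state output
with ±10° default thresholds (the demonstrated lateral/medial → red/blue
behaviour prints no angles; ±10° rejects setpoint noise while remaining
comfortable to exceed).

## IR code model

NEC — the dominant consumer protocol — gets a full codec: 9000 µs leader
pulse, 4500 µs space, 32 pulse-distance bits (562.5 µs pulse, then
562.5 µs space for 0 or 1687.5 µs for 1), trailing 562.5 µs pulse, 67
ticks total. Decoding classifies each duration within a relative
tolerance, default 25% — common decoder practice, comfortably separating
the two space symbols while absorbing the ±10% jitter real receivers see.
Frames that match nothing are *recorded raw* rather than rejected; because
a scrambled recording is effectively random, an unknown-protocol code is
accepted only when at least two independent recordings agree tick-wise
within tolerance (`verify_unknown()`), in which case the agreeing
recordings' element-wise mean is stored. Sony (12/20-bit) and RC5 (14-bit)
are represented as typed payload containers that round-trip through the
raw-tick path; full codecs for the long tail of manufacturer protocols are
out of scope. Transmission is simulated on an append-only virtual bus
(JSON-lines), where the invariant *transmissions = debounced state changes
× mapped-code multiplicity (+ rate-mode repeats)* is testable; carrier
modulation and line-of-sight physics are non-goals.

## Numerical conventions and degenerate inputs

* Windows must hold ≥ 2 finite samples; empty or non-finite input errors.
* Feature identities are asserted to $10^{-9}$; proportional-control
  linearity to $10^{-9}$ of a degree.
* CV denominators floor at $10^{-12}$; spike-alert denominators at 20% of
  stream dynamic range; band edges must satisfy $0 < f_{lo} < f_{hi} <$
  Nyquist.
* The generator uses a private RNG stream (seed folded with the session
  id) and restores the caller's RNG state.
* Queue mode ties break alphabetically, making decisions deterministic.
* All-constant training folds error rather than silently degenerate.

## Problem sizes

The shipped defaults — 5 gestures × 3 trials × 2000 samples, 585 frames of
85 features, 3 or 15 partitions — run the full seven-model evaluation in a
few seconds on one core, and the test suite exercises the complete
pipeline at these sizes plus reduced variants (200–1000 samples) where
only mechanics are under test.

## Known limitations

* Synthetic validation only: the generator's i.i.d. Gaussian noise and
  per-trial offsets understate the structured artifacts of real wear
  (electrode-equivalent shifts, pressure coupling during rotation).
* The LDA-perfect regime of the defaults says nothing about the much
  harder real-data regime; directional claims (inter-session ≥
  inter-trial; removing selected features hurts) are asserted, magnitudes
  are not.
* True dynamic gestures (transient motion) are out of scope by design;
  the mode-vote queue would fragment them into discrete states.
* Only NEC is decoded; unknown protocols replay verbatim without
  understanding repeat symbols.
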