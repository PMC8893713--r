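---
title: "Methods: spatial coding analysis of astrocytic and neuronal calcium signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial coding analysis of astrocytic and neuronal calcium signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(astroplace)
```

This vignette is the package's own account of the science it implements: the
models and procedures, the parameters that matter and their defaults, what the
synthetic-session generator does and does not emulate, the numerical choices
made where conventions were open, and the known limitations.

## The problem

During navigation of a 180-cm virtual corridor, hippocampal neurons express
place fields, and astrocytes — both somata and their fine processes — show
calcium signals that may also be spatially modulated, with slower kinetics and
broader apparent fields. The analysis pipeline quantifies, per region of
interest (ROI) and per population: whether calcium activity carries
information about track position; where and how wide the spatial response
field is and how reproducible it is; whether information carried by pairs of
ROIs is redundant or synergistic; whether apparent spatial information merely
reflects the identity of the three 60-cm visual-cue zones that tile the
corridor; and how well the animal's position can be decoded from population
activity.

## From fluorescence to events

ΔF/F₀ uses a rolling-percentile baseline: F₀(t) is the 20th percentile of the
raw trace in a centered window (30 s astrocytes, 10 s neurons), truncated —
not padded — at the trace ends, so no data are fabricated; percentiles use
linear interpolation between order statistics (R's default type 7; the
convention is fixed here because it is not dictated by the procedure itself).
Neuronal traces are first neuropil-corrected with a factor of 0.7.

Transient detection estimates noise in two stages: σ₁ is the SD of the whole
ΔF/F₀ trace; samples with |x| > σ₁ are removed and σ₂ is the SD of the
remainder. σ₂ estimates baseline fluctuation amplitude robustly against large
transients — but note that for a trace dominated by noise it is intrinsically
conservative (truncating a unit Gaussian at ±1σ leaves an SD of ≈ 0.54), so
the working assumption is that real traces carry enough large-transient mass
to inflate σ₁ well above the noise floor. Astrocytic events must cross ±2σ₂
and return within ±σ₂ only after more than 0.5 s; neuronal events use ±3σ₂
and ±2σ₂. Boundary semantics, which the criteria alone do not fix: an event
is a maximal contiguous run of samples beyond the return threshold containing
at least one crossing of the entry threshold, and its duration runs from the
entry crossing to the return below the return threshold, compared strictly
against 0.5 s. Negative deflections are detected with mirrored criteria and
enter only the false-discovery-rate estimate FDR = NEn/(NEp + NEn). Noise
estimation is performed once per concatenated session trace, not per trial.
Event traces keep the ΔF/F₀ values inside positive events and zero everything
else; all downstream spatial and information analyses operate on event traces
unless stated otherwise.

A property worth stating plainly: on sparse traces whose noise is close to
white Gaussian at 3 Hz, the ±2σ₂ entry threshold sits at barely 1.5 noise SDs
(because σ₂ underestimates the noise SD), and two-frame noise excursions then
occur every few tens of seconds on each side. The detector's sub-5% FDR
operating point therefore depends on recordings being event-rich; the
package's synthetic detector fixture (8 transients per 750 frames) measures
an FDR far above 5%, and this is a property of the detector design at that
event density, not an implementation artifact.

## Response fields and their reliability

Analysis is restricted to running trials: maximal runs of frames with speed
strictly above 1 cm/s in one direction, merging same-direction runs separated
by less than 1 s. Occupancy (time per bin) and activity (mean fluorescence
per bin) maps use 80 bins of 2.25 cm, are normalized to sum 1, smoothed with
a Gaussian kernel of σ = 3 bins (6.75 cm; truncated and renormalized at the
track ends so no mass is invented), and renormalized. The response profile is
their ratio; bins with zero smoothed occupancy are flagged undefined and
excluded from fitting rather than imputed.

Field fitting follows the profile-decomposition recipe: the profile is
peak-normalized (so the amplitude bound 0 ≤ a ≤ 1 is coherent), local maxima
above its 25th percentile seed a bounded nonlinear least-squares fit
(`minpack.lm`) of a sum of Gaussians with 0 ≤ c ≤ 180 cm, 0 ≤ σ ≤ 90 cm; the
response field is the component with the largest amplitude, its width 2σ.
Plateaus of exactly equal profile values count as a single local maximum
seeded at their center (a two-bin plateau arises generically when a symmetric
peak falls on a bin edge); edge bins count as maxima when strictly greater
than their single inner neighbor. Amplitude ties between fitted components
are broken toward the smaller σ, then the smaller center, making the field
choice deterministic. The track is linear, so no distance ever wraps.

Reliability compares field centers fitted on odd versus even trials, scaled
by the more conservative (smaller) width: 1 − |Δc| / (2·min σ). Stability
requires the centers from the two session halves to differ by less than
15 cm; a missing field in either half counts as unstable. Jackknife profile
standard errors use the standard leave-one-trial-out formula. Spatial
precision bins the corridor into 40 bins, computes each trial's
center of mass of the event trace and the amplitude-weighted mean across
trials, and reports the inverse amplitude-weighted squared dispersion; as
printed, the weighted-mean formula normalizes by the sum of the centers of
mass rather than of the weights, which is dimensionally inconsistent — the
package uses the standard amplitude-weighted mean Σ AₙCOMₙ / Σ Aₙ. The
per-ROI dynamic range entering the astrocyte/neuron precision comparison is
not defined by the source procedure; max − min of the event trace is used and
is configurable. Zero dispersion across trials yields infinite precision,
returned as `Inf` with a flag rather than an arbitrary cap.

## Mutual information and its bias corrections

Position is discretized with uniform-count (equipopulated) bins, N_S = 12 by
default, ties broken by frame order; astrocytic event traces use 4 equally
spaced bins over their range and neuronal event traces are binarized. The
plug-in mutual information uses the standard Shannon definition (the
typeset forms of the single-ROI and pairwise information in the source carry
obvious typographical garbling — a p(s) in the logarithm's denominator and a
stray marginal factor — and the framework they cite makes the intent
unambiguous). Significance uses a permutation null (default 10⁴ response
permutations, significant above the 95th percentile).

Four limited-sampling corrections are implemented:

- **bootstrap** — subtract the mean of the permutation null (conservative);
- **Panzeri–Treves** — subtract [Σₛ(R̃ₛ − 1) − (R̃ − 1)] / (2N ln 2), counting
  "relevant" response bins naively as occupied bins (documented and
  swappable);
- **quadratic extrapolation** — fit I(N) = I∞ + a/N + b/N² through the full
  sample and averaged disjoint halves and quarters (default 100 random
  splits) and report I∞. Subsamples are drawn over frames: the estimator's N
  is the sample count, and frame subsampling keeps the 1/N design exact for
  arbitrary trial structure;
- **shuffled** — I − ⟨I of within-stimulus shuffled responses⟩ + I of the
  analytic conditional-independent distribution. For a single response array
  the within-stimulus shuffle leaves the joint table invariant and the
  correction degenerates to the identity; it is meaningful (and used) for
  multi-ROI response arrays, where it overcorrects slightly and brackets the
  quadratic-extrapolation estimate from below.

On independent stimulus–response data at N = 1000 frames all four corrections
are unbiased to within 0.02 bits (the plug-in bias alone at N_S = 12,
N_R = 4 is ≈ 0.024 bits there).

## Pairwise breakdown and synergy

For a pair of ROIs with joint response R = (R₁, R₂), the information
decomposes exactly (plug-in) as I = I_LIN + I_SS + I_CI + I_CD, where I_LIN
is the sum of single-ROI informations, I_SS ≤ 0 measures redundancy from
signal similarity, I_CI is the stimulus-independent correlational term, and
I_CD ≥ 0 is the stimulus-dependent correlational (synergy-bearing) term,
computed from the conditional-independent reference P_ind(r|s) = Πc P(r_c|s).
With quadratic-extrapolation correction all five quantities are extrapolated,
which preserves the identity exactly because the extrapolation is linear;
with the shuffled correction only I is corrected and the identity holds up to
correction noise. The identity, the sign constraints, and the vanishing of
I_CD under exact conditional independence are enforced by tests.

A pair is classified as correlation-enhanced when its joint information
exceeds the 95th percentile of the within-stimulus trial-shuffle
distribution. The shuffle permutes, independently per ROI, the response
values among frames of the same stimulus bin — this preserves every ROI's
per-bin response histogram exactly while destroying within-trial coupling;
the trial-identity wording of the original procedure maps onto frames here
because responses enter the analysis frame-wise. Under conditional
independence the test is exact by exchangeability (≈5% false flags).

## Genuine spatial information versus cue identity

The corridor carries three distinct 60-cm visual textures. If a response were
driven purely by the displayed cue, positions within one zone would be
indistinguishable from it. The cue-constrained shuffle permutes position
labels only within each zone — preserving the response's cue-identity
information, destroying within-zone positional structure — and compares the
observed (Panzeri–Treves-corrected, uniform-width position bins with N_S
divisible by 3 so bins nest in zones) information against the 95th percentile
of the shuffled distribution I_V; at population level the same permutation
wraps the full SVM decode cycle and reports the genuine fraction
(I − I_V)/I.

One consequence the package makes explicit: a response that repeats
*periodically* with the 60-cm cue period (locked to the repeating texture
elements rather than to the texture's identity) identifies position within
every zone, and the within-zone shuffle therefore flags it as genuinely
spatial — correctly so, by the operational definition. The generator
accordingly distinguishes `cue-periodic` tuning (rate a function of position
modulo 60 cm) from `cue-zone` tuning (response a function of zone identity
only); the latter is the pure visual-cue hypothesis and the proper negative
control for this test, and it is generated as an instantaneous function of
the current zone so that indicator kinetics do not imprint position-locked
transients at zone boundaries.

## Population decoding

Decoding uses an RBF-kernel SVM (`e1071`) on per-frame population vectors of
event-trace values, restricted to running frames, with position classes of
equal width at granularity G (defaults 4–24 monodirectional; at least three
observations per class are required). Outer 10-fold cross-validation is
stratified by position class — stratification is a design choice here,
guaranteeing every class appears in each training fold — and hyperparameters
are selected per outer fold by inner 5-fold cross-validation over cost ∈
{0.1, 1, 10, 100} and kernel width ∈ scale-heuristic × {0.1, 1, 10}; the grid
is recorded with the results. Frames, not trials, are the cross-validation
units, matching the observation-wise setup of the original analysis; the
temporal autocorrelation leakage this admits across folds is a faithful
reproduction, and is the main reason decoded information on real-like data
should be read comparatively rather than absolutely. Pooled test predictions
form one confusion matrix; decoded information is its plug-in MI with the
conservative bootstrap correction, and accuracy the diagonal fraction. The
chance null permutes position labels frame-wise (the blockwise-by-trial
alternative is not what the procedure describes, a choice flagged here); the
trial-shuffle null applies the within-class per-ROI permutation above. Error
profiles fit a Gaussian to the histogram of signed prediction errors over
misclassified frames; note the histogram has a structural hole at zero, so
the fit's R² should be read with that in mind. Null repetition counts
(10³ chance, 500 trial shuffles) are scalable; tests and the acceptance
properties run with reduced counts and single-combination grids, stated where
used.

## The synthetic-session generator

The generator exists so that every stage has ground truth. It emulates: a
180-cm corridor with three 60-cm cue zones and reward at 115 cm; ~30 running
trials per session at ~3 Hz with frame-wise speeds drawn from a Gaussian
(mean 15 cm/s, SD 4 — a typical steady running pace), brief sub-1 cm/s pauses
injected at 1.5% of frames so trial segmentation is non-trivial, and 5-s
intertrial timeouts with teleport to the track start; Gaussian place tuning
with astrocytic fields wider than neuronal (σ 14–22 cm versus 7–12 cm,
centers drawn over the interior 20–90% of the track so fields are not
truncated by the ends); double-exponential indicator kinetics (astrocytes
τ_rise 1 s / τ_decay 3 s, neurons 0.1 s / 1 s — stand-ins chosen to reproduce
the broader, slower astrocytic responses, since no numeric kinetics are
reported for astrocytic events); ΔF/F₀ response amplitude 1.0 against
independent Gaussian noise of SD 0.15 (a realistic single-ROI SNR for
two-photon data); optional shared noise whose pairwise weight decays
exponentially with centroid distance (default length scale 50 µm); and
optional extra common noise for tagged ROI pairs gated by occupancy of the
astrocytic partner's field, planting position-dependent noise correlations.

Three design choices deserve justification:

- **Kernel normalization and alignment.** The indicator kernel is normalized
  to unit sum, and the per-ROI signal is rescaled so its session peak equals
  the nominal amplitude — `amplitude` thus means the observed response peak
  in ΔF/F₀ units, not a latent rate scale the kernel would silently dilute.
  The kernel is applied with center-of-mass lag alignment, so nominal field
  centers coincide with observable response centers rather than being
  displaced downstream by the indicator lag (4 s × 15 cm/s = 60 cm for the
  astrocytic kernel — uncompensated, "ground-truth center" would be
  meaningless).
- **Per-trial convolution with steady-state extensions.** Each trial's rate
  is extended backwards and forwards at the trial's entry/exit speed before
  convolution, so neither trial onsets nor the alignment read zero-padded
  rate. Without this, onset and end-of-track transients imprint
  position-locked artifacts that masquerade as genuine within-zone spatial
  information.
- **Observable ground truth.** Indicator kinetics shift and broaden the
  observable field relative to the latent tuning parameters (the astrocytic
  kernel alone adds ≈ 47 cm of spatial smear at 15 cm/s), so latent
  parameters are not the estimand of field fitting. The generator therefore
  exports `expected_center` and `expected_sigma`: the single-Gaussian summary
  of the noiseless signal on the realized trajectory, passed through the same
  binning and smoothing as the pipeline. Parameter-recovery tests compare
  fits against this observable ground truth — and, for the event-based
  pipeline, against the same detector-plus-fitter applied to the noiseless
  signal gated at the noisy trace's estimated thresholds, so the comparison
  isolates noise robustness from the (documented, systematic) narrowing that
  event-gating imposes on apparent field widths.

What the generator does not emulate, and what passing tests therefore do not
establish about real recordings: non-Gaussian and nonstationary noise,
drifting baselines, motion artifacts, overlapping ROIs with signal
contamination, astrocytic events not locked to position (spontaneous waves),
reward- and lick-related activity, and trial-to-trial remapping. Tests on
synthetic data validate the estimators' correctness and calibration, not the
biological claims one might make with them.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; derived streams are produced
with a fixed integer recurrence so per-ROI noise is stable under population
changes, and identical configurations reproduce sessions bit-exactly. The
session container is a directory of full-precision CSV tables plus a YAML
metadata file, chosen so containers are plain text and round-trip exactly; R
HDF5 bindings are not part of this package's dependency set.

The packaged verification experiments use desk-scale problem sizes chosen to
make their statistical assertions decisive: 50 traces × 750 frames for the
detector fixture; 1000 random joint tables for the estimator oracle; 100
seeds × 1000 frames for bias calibration; 100 tuned ROIs × 30 trials for
field recovery; 60 cue-locked plus 30 place-tuned ROIs (and populations of
40 at G = 18 with 12 cue-constrained permutations) for the genuine-information
checks; and 20 synergistic plus 40 independent pairs for the synergy
calibration. Full-study null counts (10⁴ MI permutations, 10³ chance decodes,
500 trial shuffles) remain the documented defaults of the corresponding
functions.

## Known limitations

- The spatial-precision and dynamic-range conventions fix two
  underspecified details (weighted-mean normalization; event-trace max − min)
  and are configurable where they matter.
- The event detector's FDR operating point presumes event-rich traces; see
  the events section above.
- The shuffled information correction is a no-op for single-ROI responses by
  construction.
- Decoding treats frames as exchangeable units; temporal autocorrelation
  inflates absolute performance estimates, faithfully to the original design.
- The response-time summary of event-triggered averages is deliberately
  omitted: its definition is not given in the source methods, and guessing it
  would produce an unverifiable number.
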