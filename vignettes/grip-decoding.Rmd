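---
title: "Continuous grip-type decoding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous grip-type decoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science behind its pipeline:
the model of the data, what each tunable parameter means and why its default
is what it is, what the synthetic-data generator does and does not emulate,
and the choices made where the underlying protocol left the design open.

## The task and the data model

A monkey seated before a six-sector turntable fixates one object, presses
and then releases a key (key release = t = 0, movement start), reaches,
grasps, pulls and holds the object.  Objects are presented in random order,
8 repetitions each.  Two six-object sets exist; in each, the first three
objects are grasped with closely related grips and are merged into one
class for 4-grip analyses, while objects 4–6 keep distinct grips.

The recorded unit of data is a spike train of one neuron in one trial,
aligned to key release and restricted to the analysis epoch
[−1800, +200] ms.  Neurons were recorded one at a time, so population
vectors must be assembled across sessions: for every object, the package
pairs the r-th (randomly permuted, seeded) repetition of each neuron into
pseudo-trial r.  Random pairing is the conservative choice — it creates no
artifactual trial-to-trial correlations between neurons, which matches the
physical situation of separately recorded sessions.

## Features: sliding-window normalized firing rates

For window width `bin_width` (25–200 ms) and step 10 ms, windows are
half-open intervals `[start, end)` — a spike on a shared boundary is
counted once, in the later window.  The windowed rate is the spike count
divided by the window length; each neuron's rates are then divided by that
neuron's maximum windowed rate over **all** of its trials and windows *at
that bin width*, so the normalized firing rate (nFR) lies in [0, 1] with
the maximizer at exactly 1.  Normalization is per bin width because the
maximum of windowed rates depends on the window length; normalizing with a
25 ms maximum would leave 200 ms values far below 1 and make "normalized"
a misnomer.  A neuron with no spikes anywhere has no defined normalization
and is dropped with a warning.

A window is timestamped by its **end**: a prospective prosthesis can only
use spikes that have already occurred, so the feature available at time t
summarizes `[t − bin_width, t)`.

## Onset detection

The population nFR of an object (mean over neurons and that object's
pseudo-trials) is compared against a threshold
`baseline mean + 2.5 × baseline SD`, with baseline statistics over the
analysis windows lying fully inside the first 400 ms of object
presentation ([−1800, −1400] ms).  t_onset is the end of the first window
opening a run of at least `persistence` consecutive strictly
supra-threshold windows.

The persistence default is `ceiling(bin_width / step) + 1`, i.e. the run
must outlast one full window length.  With a 10 ms step, adjacent windows
share up to 95% of their spikes, so a single spike burst elevates up to
`bin_width / step` consecutive windows at once; a run criterion of 2 would
fire on such flukes (in simulation it produced onsets up to a second early).
Requiring the run to outlast the window-overlap scale suppresses
single-burst flukes while leaving genuine steps detected at their first
supra-threshold window.  The run requirement is exposed as a parameter; at
the fixed 2.5 SD multiplier, occasional pre-onset noise runs remain (on
stationary series their rate is roughly independent of population size,
because the threshold scales with the measured SD), which is why onset
summaries over objects use the median.

Degenerate baselines (SD = 0) keep the threshold at the baseline mean with
a strict inequality, so a flat series never yields an onset.

## Labeling windows

Windows ending after key release are grip execution and carry the trial's
grip.  Before key release, *sub-threshold activity is baseline*: a window
is labeled with the trial's grip only if it ends after the trial's onset
boundary **and** its own population nFR exceeds the trial's threshold.
The alternative — labeling every window past a single onset boundary as
grip — labels "diluted" windows that overlap the response onset only
fractionally; their number grows with the window width, which would make
wide windows *worse* than narrow ones, the opposite of what window
averaging should do.  Threshold-following labels keep the baseline/grip
distinction aligned with what the features can express at every width.

The per-trial boundary is resolved in order of preference: the trial's own
threshold crossing; else the object-level onset; else key release, so that
movement-phase windows still carry grip labels in unmodulated data (where
a recognition ratio at chance level is the meaningful outcome, not an
undefined one).

## Classification

Both schemes use ν-SVMs with radial-basis kernels (LIBSVM via `e1071`),
one-vs-one multiclass decomposition, on the nFR vectors:

* **direct**: one machine over k + 1 classes (baseline + 4 or 6 grips);
* **hierarchical**: a binary baseline-vs-active machine, then a k-grip
  machine invoked only on windows called active.

Defaults and their rationale:

* `nu = 0.1`.  ν upper-bounds the fraction of margin violations and
  lower-bounds the fraction of support vectors.  The library default 0.5
  forces at least half of the training windows inside the margin, which on
  near-separable nFR clusters costs ~4–5 RR points at 100 ms; 0.1 fits
  tightly while retaining regularization.  ν is additionally capped just
  below the LIBSVM feasibility bound `2·min(n_i, n_j)/(n_i + n_j)` implied
  by the realized class counts, and designs in which identical feature
  vectors occur in several classes (empty windows labeled both baseline
  and grip in sparse data) fall back to the equivalent C-parameterization,
  which tolerates inseparable duplicates.
* `gamma = 1/n_neurons`, the library convention for the RBF width; on
  [0, 1]-bounded features its influence was minor.
* **Class balance.**  Baseline windows outnumber grip windows several-fold,
  and in 4-grip mode the merged class carries three objects' windows, so
  training subsamples every class (seeded) to the median grip-class count.
  Balancing only the baseline class would leave merged-class imbalances
  that violate the ν feasibility bound at moderate ν.
* **Splits.**  25% of pseudo-trials train, 75% test, stratified by object
  (with 8 repetitions: 2 train / 6 test per object), repeated over 50
  seeded splits; splitting is by trial, never by window, so no trial
  contributes to both partitions.

The recognition ratio is reported over windows whose *true* label is a
grip (`scope = "grip"`): the proportion of grips correctly identified; a
grip window predicted as baseline counts as an error.  `scope = "all"`
includes baseline windows for the alternative reading.

## The synthetic-data generator

Each neuron is an inhomogeneous-Poisson (optionally doubly stochastic)
unit with a ramp-and-hold profile: baseline rate until its onset latency,
linear ramp of duration `rise_time` to an object-dependent plateau, hold
until the trial's movement end (drawn per trial from a normal truncated at
50 ms; 334 ± 113 ms for the original set, 407 ± 192 ms for the special
set).  Spikes are drawn by thinning with the rate held piecewise-constant
over 1 ms.  A neuron has one preferred object at full modulation; objects
in the same merged grip group receive correlated, higher shares of the
modulation depth than objects outside it, so confusions concentrate within
the merged triplet, as they do in real premotor populations.

Two optional noise processes make the rates doubly stochastic:

* a slow multiplicative excitability drift (log-normal Ornstein–Uhlenbeck
  gain), reproducing the overdispersion (Fano factor > 1) of cortical
  counts;
* a phase-locked rate rhythm `exp(κ·cos(2πt/P + φ))/I₀(κ)` with a random
  phase per trial — motor and premotor firing is entrained to
  low-frequency population rhythms, and because the phase is not locked to
  task events, windows shorter than one cycle see the rhythm as
  irreducible rate noise while windows spanning whole cycles integrate it
  away exactly.

The rhythm is the ingredient that reproduces the characteristic bin-width
profile of real grasp decoding — excellent at 75–150 ms, strongly degraded
at 25 ms.  Independent-Poisson noise alone cannot produce that profile:
count noise scales as 1/√window, which ties accuracy at 25 ms to accuracy
at 100 ms far too tightly (near-perfect 100 ms decoding would imply far
better 25 ms decoding than real recordings show).  A super-Poisson noise
source that cancels over full cycles breaks exactly that link.

### Frozen scenarios

Scenario definitions are versioned data (`inst/extdata/scenarios.yaml`),
not code paths:

* **paperlike** — 36 original-set neurons, 8 repetitions.  Tuning
  dispersion was calibrated, once, on the frozen generation seed so the
  pipeline reproduces the qualitative and quantitative behavior expected
  of the real population: mean RR above 96% for direct 6-grip decoding at
  100 ms, a ≥ 30-point drop at 25 ms, direct-vs-hierarchical differences
  within 2% at wide windows, and per-object onsets preceding movement
  start.  The calibrated values: baseline 12 Hz (gamma-distributed,
  shape 4), plateau 65 Hz at the preferred object (shape 10), merged-group
  shares 0.15–0.45 and across-group shares 0–0.2 of the modulation depth,
  onset latencies −550 ± 40 ms, rise times 30–50 ms, 10 Hz rhythm with
  locking κ = 3.5.
* **paperlike_special** — 10 special-set neurons; later onset latencies
  (−150 ± 120 ms, straddling movement start) and the longer movement
  durations of that set.
* **separable** — a high-rate, sharply tuned population (no rhythm, no
  drift, identical latencies) on which decoding is nearly perfect; used to
  verify that both schemes approach ceiling and agree.
* **null** — untuned neurons (modulation 0): rates never depart from
  baseline, so decoding can only reach chance.

What the generator does **not** emulate: spike-sorting artifacts and unit
contamination, session non-stationarities, correlated noise between
simultaneously recorded neurons (the real pseudo-population has none
either, by construction), visuomotor object responses during fixation,
and the true (unpublished) tuning statistics of the recorded neurons.
Passing tests on synthetic data therefore demonstrate that the pipeline
is correct and behaves as the protocol describes on data with the stated
structure — not that any particular RR would be attained on new
recordings.

## Statistics

Scheme and object-set comparisons use the Friedman test with the window
widths as the paired blocks (the only pairing structure shared by all
conditions); bin-width influence uses the Kruskal–Wallis test; both at
p ≤ 0.01, with average ranks and tie corrections (`stats::friedman.test`,
`stats::kruskal.test`).  Fully tied designs (no variation anywhere) are
reported as statistic 0, p = 1 rather than NaN.  The chi-square
approximations are accurate near the decision threshold; in the middle of
the null distribution the exact Friedman distribution is lumpy and the
approximation can deviate from permutation p-values by several hundredths,
which is immaterial for calls at p ≤ 0.01.

Chance level for an untrained/untuned decoder is defined by label
permutation (retraining with grip labels permuted across training trials),
not by the uniform-guess constant 100/(k + 1): a trained machine does not
guess uniformly — the baseline class draws training windows from every
training trial while each grip class draws from its own few, so baseline
captures a larger share of feature space even on exchangeable data, and
observed chance RR sits somewhat below the uniform constant.

## Problem sizes

The shipped tests and the acceptance script run the full-scale protocol
population (36 neurons × 6 objects × 8 repetitions) with 50 splits for the
headline quantities, 30 splits plus 100 label permutations for the chance
property, 100 seeded populations for onset recovery, and brute-force or
Monte-Carlo oracles (200 window-counting instances; 3000-draw permutation
references) for the numeric properties — sizes chosen so the entire suite
completes in a few minutes on one CPU while keeping Monte-Carlo error well
below the asserted tolerances.

## Known limitations

* The acceptance-style bounds hold on the frozen scenarios; real
  recordings differ in tuning statistics and noise structure.
* Onset detection at the fixed 2.5 SD multiplier retains a residual
  pre-onset false-run rate on stationary baselines; per-object medians are
  the recommended population summary.
* The ν-SVM is refit per split; no hyperparameter search is performed
  (none is described in the protocol), so reported RRs are not optimized
  upper bounds.
* No online/causal filtering, feature selection, or neuron-dropping
  analyses; the window end timestamp is the only causality device.
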