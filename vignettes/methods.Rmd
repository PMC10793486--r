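---
title: "Methods: trajectory encoding, functional networks and context groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory encoding, functional networks and context groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the estimators, the tunable parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where several defensible options existed. It states no empirical
result that the test suite does not itself compute.

## 1. The encoding model

Spiking is modeled at the resolution of 10 ms bins. A *kinematic sample*
centered at time `t0` pairs the spike count of a unit in the bin
containing `t0` with the hand velocity trajectory over a window
`[t0 − τlead, t0 + τlag]`, down-sampled to a 40 Hz grid (25 ms spacing),
and the mean hand position over the same grid. Velocities and positions
are shoulder-referenced: the shoulder marker is subtracted from the hand
marker before differentiation so postural drift does not masquerade as
hand movement. The grid is left-aligned and excludes the right endpoint of
the window; this is the only layout in which a 400 ms window at 40 Hz
yields exactly 16 time points and hence 48 x-y-z velocity terms, the
canonical count for the `[−100, +300]` ms model. Samples are extracted
every 30 ms wherever the full window fits inside a reach segment, so every
emitted sample's window lies within exactly one segment.

Model families, in increasing order of richness:

| family            | columns                          | window            |
|-------------------|----------------------------------|-------------------|
| `velocity`        | 6 velocity terms                 | `[+100, +150]` ms |
| `short_kinematics`| 6 velocity + 3 position          | `[+100, +150]` ms |
| `trajectory`      | 48 velocity terms                | `[−100, +300]` ms |
| `full_kinematics` | 48 velocity + 3 position         | `[−100, +300]` ms |
| `kin_plus_FN`     | 51 kinematic + 2 network features| `[−100, +300]` ms |

The conditional intensity is log-linear,
`exp(γ + k⃗·v̂ + c⃗·p̄ + β0 F0 + β1 F1)`. We fit a Poisson likelihood on
the 10 ms counts (the exponential link makes Poisson the natural choice;
a Bernoulli/logit variant is available via `family = "bernoulli"` in
`fit_glm_ridge()` since single 10 ms bins rarely hold more than one
spike). The ridge penalty `α‖β‖²` is on the absolute scale, the intercept
is unpenalized, and the optimizer is a damped Newton iteration converging
to tolerance 1e-8; the defaults are `α = 0.05` for the kinematics families
and `α = 1e-6` for network models. Prediction quality is the area under
the ROC curve (Mann–Whitney formulation, ties counted 1/2) of the
predicted intensity against the binarized response on held-out data, with
the 80/20 train/test partition independently redrawn for each of
`n_splits` splits (default 500). We read "sampled randomly with
replacement" as redrawing the partition itself — train and test must be
disjoint within a split for the held-out AUC to be honest.

*A note on matched penalties.* The two printed penalty weights differ by
several orders of magnitude. At a few thousand samples, fitting 51
kinematic columns at `α = 1e-6` costs roughly 0.02–0.04 held-out AUC in
pure overfitting relative to `α = 0.05`. Any comparison meant to isolate
the contribution of the two network features must therefore hold `α`
fixed across the two models being compared; the ground-truth validation
in the test suite compares `full_kinematics` and `kin_plus_FN` both at
`α = 1e-6`. Comparing across the per-family defaults confounds feature
content with regularization strength at this sample size.

## 2. Kinematic preprocessing

Marker tracking is cleaned by three rules applied in order: frames with
reprojection error above 20 px (35 px suits noisier rigs) or fewer than 2
cameras are invalidated; surviving valid runs strictly shorter than 50 ms
are invalidated (brief islands of "good" tracking inside bad stretches
are untrustworthy); interior invalid gaps strictly shorter than 200 ms
are filled by linear interpolation and flagged. Both duration rules are
strict inequalities — exactly-50 ms runs survive, exactly-200 ms gaps stay
open. Positions are then smoothed with a 3rd-order Savitzky–Golay filter
over 70 ms (window forced to an odd frame count, rounding up), applied
per valid run with no wrap-around; an order-3 filter passes cubic
trajectories untouched. Velocity is computed by central differences
within valid runs, one-sided at run boundaries.

Reaches are segmented by finding local maxima of the shoulder-referenced
hand y-position with topographic prominence of at least 0.02 m (the y
axis is the extension direction), then attaching each peak to its
surrounding movement bout: frames with hand speed ≥ 0.05 m/s, after
closing still gaps shorter than 0.4 s (a reach decelerates through the
speed threshold around the y-peak, and multi-attempt reaches contain
brief holds). A prominent peak with no movement bout around it is not a
reach. The speed threshold and prominence are configuration parameters;
the values are package defaults, not published constants.

## 3. The functional network

Spike trains are binarized (1 if the 10 ms bin holds at least one spike;
bins are half-open, boundary spikes belong to the later bin). The directed
edge weight from source *j* to target *i* is the confluent mutual
information: the plug-in mutual information between `j(t)` and the
confluent target state `i(t) OR i(t+1)`. We use the maximum-likelihood
(plug-in) estimator with no bias correction; its bias is
`≈ 1/(2 N ln 2)` bits at N bins, which the minimum-bin floor
(`min_bins = 1000`) keeps an order of magnitude below typical coupled-pair
weights. A bin contributes only when both `t` and `t+1` lie inside the
analyzed context, so no statistic straddles a context boundary. The
diagonal is stored as zero and excluded from every average. Three networks
are computed per session: `reachFN1` and `reachFN2` from the two random
halves of the reach segments, and `spontaneousFN` from all non-reach bins
(we do not attempt to distinguish in-apparatus from home-enclosure
spontaneous behavior).

Network features are cross-paired: samples from `reachSet1` use
`reachFN2` in-weights and vice versa, so a sample is never evaluated with
a network estimated from its own data.

## 4. Pathlets

A unit's preferred path is obtained by treating the fitted velocity
coefficients as instantaneous velocities on the sample grid and
integrating with the rectangle rule — forward from `t0` for lag-side
points, backward for lead-side points — so the path passes through the
origin at `t0`. Position coefficients are not integrated. Pairwise
pathlet similarity is the Pearson correlation of the flattened position
sequences (the anchor excluded); correlating integrated positions rather
than the raw coefficient vectors matches what the path display shows, and
the raw-coefficient variant remains available
(`pathlet_correlation(..., on = "coefficients")`).

## 5. Perturbation analyses

Functional groups of the strongest N% of off-diagonal edges (ties broken
lexicographically for determinism) are manipulated in two ways: *permuted
weights* (the weight multiset shuffled over the same source–target pairs)
and *permuted targets*. For permuted targets each (source, weight) pair
is reassigned to a uniformly drawn new target; since the conMI matrix is
dense, every destination already holds a weight, so the reassignment is
realized as a within-column swap — the displaced weight takes the vacated
slot. This conserves the global weight multiset and every source's
out-weight multiset exactly, and in the minimal two-edge configuration it
forces the unique valid derangement. Manipulated features are substituted
into the fitted model *without retraining* (retraining would re-optimize
the coefficients and mask the manipulation) and the AUC loss is measured
on the training samples, normalized by the above-chance headroom:
`100·(AUC_intact − AUC_perm)/(AUC_intact − 0.5)`, so 100% means all
predictive power above chance is gone (the raw difference is also
reported). Units whose intact training AUC does not exceed 0.5 are
excluded with a warning. Strong-group losses are compared per shuffle
against random matched-size groups (drawn uniformly, overlap allowed) and
against full removal of the network terms, by one-sided sign tests.

## 6. Context groups

The cross-context generalization test trains the network model with
spontaneous-network features on reach samples and tests it with
reach-network features, against the reference model trained and tested
with (cross-paired) reach features; both use identical split sequences.
The per-unit difference in mean held-out AUC (`delta`) is sorted in
descending order, first-differenced, median-filtered (window 5 by
default; the window is exposed and recorded in output metadata), and the
threshold is the first index at which the filtered derivative falls below
7.5% of its maximum. Units ranked before the threshold are
context-specific. We difference first and then filter; the rule depends
only on the derivative, so adding a constant to every delta cannot change
the labels. Flat inputs yield zero context-specific units and a
degeneracy flag.

Group comparisons (edge-weight changes between contexts, kinematic-model
AUC, within-group pathlet correlations, modulation and firing-rate-ratio
controls) use Mood's median test, two-sided, without continuity
correction (a correction flag exists). Within-group edge sets require
both endpoints in the group; cross-group edges count only toward the full
network. The modulation metric — which the source analyses display but
never define — is our stand-in: |mean rate over [0, +250] ms − mean rate
over [−250, 0] ms| around reach onset, rates averaged over reaches first,
normalized by their sum. The AUC-matched control keeps only
context-invariant units whose kinematic-model AUC strictly exceeds the
lowest AUC in the context-specific group.

## 7. The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed and are not tuned per analysis.

**Kinematics.** Each reach event is one to three minimum-jerk extension
cycles along a per-event direction dominated by +y (direction jitter sd
0.45 on x and z, amplitudes 5–12 cm, brief holds, partial retractions
between cycles, full retraction at the end), giving events of roughly
1.5–3.5 s — long, multi-attempt prey-pursuit-like movements. Events ride
on a low-pass Gaussian wander (position sd 2.5 mm, corner below 1 Hz —
position *and* velocity smooth, which an Ornstein–Uhlenbeck position
would violate) and are separated by spontaneous stretches (mean gap 12 s;
34 s in the `paperlike` profile, which reaches roughly an hour of
session). Spontaneous behavior is movement-rich: out-and-back
minimum-jerk bouts confined to the x–z plane (2–6 s apart, 3–8 cm) give
the spontaneous context genuine kinematic drive without ever producing a
y-extension that could be mistaken for a reach. Marker noise (0.2 mm
white) and injected dropout bursts (binomial total count laid out in
geometric-length bursts of high reprojection error or single-camera
frames) populate the quality fields. The spike simulator is driven by the
noise-free kinematics; the analysis pipeline only ever sees the noisy
series.

**Population.** Baseline rates are drawn in 2–10 spikes/s and then
clamped per unit so the worst-case expected count per bin —
`exp(γ + drive_cap + min(Σb, coup_cap))` — stays below 0.90, just under
the simulator's hard stability cap of 0.95 expected spikes per bin
(log-linear models with strong gain must budget their operating point or
diverge). Preferred trajectories are smooth curves (four Gaussian bumps,
sd 150 ms, per axis) calibrated so the velocity log-drive has a target
per-unit standard deviation; the calibration includes a factor 2.8 for
the coherent summation of temporally correlated velocity terms. The
kinematic drive is clipped at 2.5 per-unit standard deviations, a mild
rate-map saturation that bounds the worst case.

The population has three planted classes mirroring the empirical
structure the pipeline is meant to detect:

* a **context-specific subgroup** (20%): tuned above the invariant pool
  (drive sd 0.75–0.80 — a deliberately narrow range, because under the
  stability budget tuning sets the group's firing rates, and a
  homogeneous group lets the planted coupling ladder dominate the
  cross-context deficits) with preferred trajectories dominated by the y
  axis — the movement dimension exercised only during reaching — and
  densely interconnected (in-degree 4) by directed couplings that exist
  *only* during reach epochs. Coupling totals are stratified across the
  group on a log scale from 2.25 to 2.55, which spaces the planted
  generalization deficits roughly evenly and keeps the weakest planted
  deficit above the background spread of unplanted units.
* **context-invariant coupled units**: weakly tuned (0.4–0.6), coupled
  (in-degree 2, totals 1.8–2.4) within their own weakly tuned pool with
  identical coupling in both contexts, so the same edges carry comparable
  activity and conMI in either context.
* **uncoupled units**: moderately-to-strongly tuned (0.6–0.9) to x/z
  velocity components present in both contexts, with the highest stable
  firing rates.

This axis structure is not incidental: tuning to the reach-only movement
dimension is itself a context-specific property (reach co-modulation has
no spontaneous counterpart), so the generator's planted subgroup is
context-specific through *both* its couplings and its tuning — matching
the empirical association between context specificity, strong kinematic
tuning and extension preference. Couplings act multiplicatively on the
next 10 ms bin through the binarized previous-bin state (strictly causal;
coincident-bin dependence arises from shared drive only), saturate at a
summed drive of `coup_cap` (default 1.0, a stand-in for synaptic
saturation), and counts are Poisson with event times uniform within their
bin.

**What passing tests do and do not show.** The generator produces
idealized tracking (sub-millimeter noise, quiet wander), exactly
log-linear rate maps, exactly Poisson counts and a hard separation
between planted classes. Real recordings have none of these guarantees —
sorting errors, non-Poisson variability, continuous rather than discrete
coupling structure, richer and larger spontaneous movements. Recovery at
the tested scale demonstrates the pipeline's correctness and power under
its own model class, not performance guarantees on real data.

## 8. Problem sizes and numerical choices

The ground-truth validation session uses 100 units and 60 reach events
(about 3,500 samples, 9–14k reach bins and 70k+ spontaneous bins), with
25–30 train/test splits per model and 50 permutation shuffles; these
sizes give every test statistic comfortable resolution (conMI noise floor
below 1e-4 bits, AUC standard errors a few thousandths) while keeping the
full suite fast. Degenerate inputs are handled explicitly throughout:
zero-entropy marginals give exactly 0 bits; single-class AUC is a flagged
missing value; all-zero responses abort the GLM with a message; flat
delta vectors yield zero context-specific units; zero-variance pathlets
are flagged undefined. Ties are resolved deterministically wherever an
ordering matters (strong-edge cuts lexicographically, AUC by midrank).
Every stochastic step takes an explicit seed, and one master seed expands
into fixed child seeds (truth +1, kinematics +2, spikes +3) in
`make_default_session()`.

## 9. Known limitations

* The plug-in conMI estimator is biased upward at small bin counts; reach
  networks estimated from split halves of a session sit closer to the
  estimator's noise floor than spontaneous networks, and weak couplings
  (log-lift below ~0.5 per edge) are not reliably separated from the
  shared-drive background at a few thousand reach bins.
* The all-pairs rank correlation between an estimated network and a
  sparse ground-truth coupling matrix is bounded well below 1 even for
  perfect edge recovery, because the overwhelmingly many zero-coupling
  pairs are tied in the truth; edge-recovery quality is therefore
  assessed by ranking statistics (ROC AUC of weights against the true
  edge indicator), not by an all-pairs correlation.
* The kink classifier is sensitive to the top of the sorted-delta curve:
  an isolated extreme unit can dominate the derivative maximum. The
  median filter absorbs single outliers, but curves whose leading several
  steps are all large will threshold early. This is a property of the
  rule, preserved deliberately.
* Spontaneous behavior is stipulated, not fitted: no public quantitative
  description of spontaneous marmoset kinematics exists to calibrate
  against.
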