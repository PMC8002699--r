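---
title: "Reject options for particle-filter pose tracking in depth images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reject options for particle-filter pose tracking in depth images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfreject)
```

## The problem

Marker-less tracking of a rigid target in a depth-image stream — for
example a bone surface tracked during computer-assisted surgery so that
cutting guides can be projected onto it — must not silently go wrong. A
particle filter reports a pose every frame whether or not that pose is
still anywhere near the truth; occlusion by instruments or personnel and
sudden repositioning of the patient are the two classic ways the track is
lost. `pfreject` implements a 6-DoF depth-image particle filter together
with three *reject options*: procedures that monitor quantities the filter
computes anyway and raise an alarm when the track is likely to be off by
more than a chosen tolerance.

Because no public depth recording of this kind exists, the package ships a
simulator that generates the study conditions synthetically, and every
claim the package makes is evaluated on that simulator.

## The tracking model

The state is a 14-component pose $\rho = (p, q, \nu^{trans}, \nu^{rot})$:
position $p \in \mathbb{R}^3$ (m), unit orientation quaternion $q$,
translational velocity $\nu^{trans} \in \mathbb{R}^3$ and a rotational
velocity stored as a full quaternion increment $\nu^{rot} \in
\mathbb{R}^4$. Storing the rotational velocity with four components makes
the 14-dimensional state exact; its noise perturbs all four components and
is deliberately *not* renormalized — it is a velocity, not an orientation.

Each frame, $K$ particles are proposed around the current track:
velocities decay by a factor $v_f$ and receive Gaussian noise
($\sigma = n_{trans}$ per translational axis, $n_{rot}$ per rotational
component), and the pose is integrated backward-Euler style with the *new*
velocities; the orientation update $q \leftarrow \mathrm{normalize}(q +
\tfrac{1}{2}(q \otimes \nu^{rot})\,dt)$ is the normalized-linear
(Nlerp-style) increment. Time is measured in frames ($dt = 1$): the noise
magnitudes of the standard configuration lattice only produce per-frame
motion of a trackable magnitude under that unit, so the package adopts it
throughout and keeps the camera frame period (1/30 s) purely as metadata.

Each particle is scored by rendering the expected depth image of the
target at the particle's pose and summing a per-pixel mixture
log-likelihood over the image:

* expected pixel invalid (background): contributes 0 — anything fits;
* observed pixel invalid (dropout): $\ln(w_{uni}/(\hat d - \check d))$;
* observation at or nearer than expected: uniform + Gaussian + truncated
  exponential $\lambda e^{-\lambda x_o} / (1 - e^{-\lambda x_e})$, the
  occlusion term;
* observation farther than expected: uniform + Gaussian only.

The Gaussian has mean $x_e$ and depth-dependent variance $d_f x_e^2 +
b_n$. The mixture weights $(w_{uni}, w_{gaus}, w_{exp})$ are not forced to
sum to one; the likelihood is an unnormalized score, which is harmless for
the argmax and for thresholding. All arithmetic stays in the log domain;
the effective sample size is computed as $2\,\mathrm{LSE}(w) -
\mathrm{LSE}(2w) \in [0, \ln K]$ with log-sum-exp normalization, so no
weight is ever exponentiated on its raw scale.

The new track is the argmax-weight particle (ties: lowest index), and all
$K$ particles of the next frame are proposed from it — a deliberate,
literal reading of the one-reference prediction/argmax selection scheme
rather than a classical resampling genealogy; this is the scheme whose
diagnostics the reject models consume, and it is flagged here because
other particle-filter implementations propagate particles individually.

## Error labels and tolerance pairs

Per frame the package records the position error $\delta = \lVert \hat p -
\tilde p \rVert_2$ (m) and the angular error $\alpha = 2\arccos\lvert
(\hat q \otimes \tilde q^{-1})_w \rvert$ (rad). Two conventions are worth
stating. First, $\delta$ is the Euclidean norm — the tolerances it is
compared against (0.05–0.2) are lengths in meters, so a squared distance
would be dimensionally inconsistent. Second, the absolute value inside the
$\arccos$ applies the quaternion double cover: $q$ and $-q$ are the same
physical rotation, and without the absolute value an estimator that lands
on the antipodal representative would be charged a spurious near-$2\pi$
error.

"Lost" is defined relative to a tolerance pair $\sigma_i = (d_i, a_i)$;
twenty equidistant pairs span $d \in [0.05, 0.2]$ m and $a \in [0.13,
0.26]$ rad, from strict $\sigma_1 = (0.05, 0.13)$ to tolerant
$\sigma_{20} = (0.2, 0.26)$. A 20-frame window (stride 10) is labeled lost
under $\sigma_i$ when any frame in it *strictly* exceeds either tolerance;
values exactly at the tolerance are kept. The window features are the 7
configuration values concatenated with the 4 filter outputs (max
log-likelihood, log-ESS, mean and variance of the raw log-weights)
averaged over the window — an 11-vector. The window-maximum $\delta$ and
$\alpha$ serve as the regression targets, which makes the regression
decision rule consistent with the existential exceedance in the labels.
The 10-frame overlap is applied uniformly to all three strategies.

## The three reject strategies

**Likelihood threshold (Chow-style baseline).** Reject when the
window-mean maximum log-likelihood falls below $\tau$. $\tau$ is selected
from the 401 integer candidates in $[-200, 200]$ by maximizing training
F1 (the selection objective is a package choice; ties resolve to the
smallest candidate). The strategy thresholds the same windowed feature the
learned models see, so all three strategies are compared on identical
samples.

**Regression.** Two regressors (one for $\delta_{max}$, one for
$\alpha_{max}$) fitted once per fold; a window is kept under $\sigma_i$
iff both predictions are at or below the pair's tolerances. Families:
ordinary least squares, random forest (100 trees), RBF support-vector
regression, and optionally Gaussian-process regression. No resampling is
applied to regression training data.

**Per-pair classification and the sparse ensemble.** One binary classifier
per tolerance pair (linear-kernel SVM with the signed margin as score, or
random forest with the lost-vote fraction as score), trained after SMOTE
balancing of the training partition only. Because each classifier exposes
a continuous score, its decision threshold $\phi$ can be shifted to serve
*neighbouring* tolerance pairs: the coverage range of a classifier at
goals $(g_p, g_r)$ is the set of pairs for which some cutpoint of the
training scores attains precision $\ge g_p$ and recall $\ge g_r$. The
sparse ensemble is the minimum-cardinality subset of the 20 candidates
whose ranges cover all pairs — found by exhaustive search in increasing
cardinality (exact for the 20-candidate pool; a brute-force subset
enumeration verifies it in the tests) — with each pair assigned to the
covering member with the highest precision + recall, "highest combined
precision and recall" being read literally as the sum.

SMOTE is implemented in the package (interpolation between minority
samples and their 5 nearest minority neighbours, oversampling to parity):
it is a ~30-line algorithm and keeping it internal makes the
training-partition-only discipline easy to enforce and to instrument in
tests.

## Evaluation protocol

Walk-forward 10-fold cross-validation, built *within each run*: every
run's time-ordered windows are cut into 11 equal consecutive blocks
(remainder spread over the earliest blocks); fold $k$ trains on blocks
$1..k$ of every run and tests on every run's block $k+1$. Training
windows always precede test windows within each run, every sample is
tested at most once, and every filter configuration is represented in
training — the deployment setting of a reject monitor, which watches the
*future* of runs whose past it has seen, and which generalizes over time
rather than over unseen configurations. (The alternative — concatenating
all runs and cutting folds across the pooled ordering — makes every test
block consist of configurations absent from training; since 7 of the 11
features are the configuration vector, that evaluates config-space
extrapolation instead, a different and much harder question that the
per-pair classifiers are not designed for.) Precision and recall use "lost" as the
positive class; cells with an undefined metric (no positive predictions,
or no positives present) are excluded from averages rather than zeroed —
zeroing would bias the comparison against conservative strategies — and
the number of excluded cells is reported alongside.

## What the simulator emulates — and what it does not

The simulator renders analytic primitives (sphere, box) through an ideal
pinhole camera at 64×48 px and corrupts depths with zero-mean Gaussian
noise of variance $d_f x^2 + b_n$ plus independent dropout, the same
variance law the likelihood assumes. The default noise ($d_f = 10^{-5}$,
$b_n = 4\cdot10^{-6}$ m², 2% dropout) gives a ~2.5 mm standard deviation
at 0.5 m — the close-range accuracy class of structured-light and
stereo depth cameras, and fine enough that the orientation of a
several-centimetre target is genuinely constrained by the data. With it,
nominal tracking keeps errors well inside the strictest tolerance pair,
so lost windows are a minority driven by the scripted events and by
adverse filter configurations — the imbalanced regime the classification
strategies (and SMOTE) are designed for. Ground-truth motion is an AR(1)
velocity random walk (decay 0.9, translational diffusion 0.5 mm/frame,
rotational 0.001/frame), i.e. smooth millimetre-scale drift that stays
far from the tolerances on its own. The two packaged failure scenarios are an
occlusion covering 60% of the target's rendered pixels for ~18% of the
sequence (a slab at intermediate depth, placed each frame by projected
pixel counting to hit the configured coverage within ±10%) and an
instantaneous 0.151 m pose jump at the 75% mark, aimed so the target
stays inside the frame. Sequences are 220 frames — 21 windows each — so a
single disturbance punctuates an otherwise nominal track, and the
packaged benchmark tracks 2 scenarios × 60 lattice-sampled configurations
with particle counts capped at 300. These sizes are the package's chosen
desk-scale study conditions (about half the sequence length, and a
fraction of the configuration count, of a full-scale study), stated here
so that results are read at that scale; the event-to-nominal proportion
per sequence is kept at full-scale levels because the label base rates —
and with them the behavior of every reject strategy — follow that
proportion directly.

The benchmark target is a 6×4×3 cm box at 0.5 m (a ~24×16 px footprint),
not a sphere: a sphere's orientation is invisible to a depth camera, so
angular errors would be pure unobservable drift and the angular half of
every label would be noise. The box's asymmetric silhouette makes
orientation genuinely estimable, which is what the real system's
asymmetric bone-graft template provides.

What the simulator does *not* emulate: textured or deformable anatomy,
correlated (non-i.i.d.) sensor noise, multi-path and edge artifacts,
clutter objects that resemble the target, and re-detection after loss.
Passing tests therefore demonstrate the machinery — likelihood, filter,
labeling, strategy training, covering algorithm — under controlled
conditions, not clinical performance; on real recordings the quantitative
precision/recall levels would differ even though the qualitative ordering
of the strategies is expected to be stable.

## Numerical choices and degenerate inputs

* The $\arccos$ argument of the angular error is clamped to $[-1, 1]$.
* Nlerp flips the sign of its second argument when the dot product is
  negative (shortest arc); interpolants that cancel raise an error rather
  than returning garbage.
* A zero quaternion cannot be normalized or inverted (error); the
  rotational integration guards against a pathological velocity cancelling
  the orientation.
* The occlusion exponential's normalizer $1 - e^{-\lambda x_e}$ is read as
  truncating the exponential to $[0, x_e]$; $\lambda$ defaults to 1 m⁻¹
  and is exposed in the configuration.
* Particle weights of a hypothesis rendering entirely outside the sensor
  range sum to zero (the expected image is all-invalid); such hypotheses
  compete at weight 0, which matching hypotheses beat easily because a
  well-matched pixel contributes a large positive log-density.
* The filter's argmax resolves ties to the lowest particle index; all
  stochastic stages consume the R RNG so a seed fixes the entire pipeline
  bit-for-bit.
* Single-class training labels make a threshold or classifier fit
  degenerate; such fits raise an error that the evaluation layer logs and
  skips, and candidates that cannot be trained simply drop out of the
  ensemble's candidate pool.

## Worked example

A miniature end-to-end run (2 scenarios, 6 configurations — a few minutes
of CPU; the packaged benchmark uses 60):

```{r example, eval = FALSE}
library(pfreject)
ds <- benchmark_dataset(n_configs = 6, seed = 1)
rep_chow <- evaluate_strategy(ds, "chow")
rep_reg <- evaluate_strategy(ds, "regression", kind = "rf")
rep_cls <- evaluate_strategy(ds, "classification", kind = "rf")
compare_strategies(list(rep_chow, rep_reg, rep_cls))
ens <- train_sparse_ensemble(ds, kind = "rf", goal_p = 0.9, goal_r = 0.9)
ens
```

## Known limitations

* The one-reference argmax proposal scheme has no particle diversity
  across frames beyond the current proposal cloud; after a large
  displacement, recovery depends entirely on the translational noise
  reach.
* The sparse-ensemble search is exhaustive and exact up to ~20 candidates;
  larger pools would need the greedy variant.
* The Gaussian-process regression family is practical only for a few
  thousand windows.
* Walk-forward folds evaluate pooled windows; per-scenario folds (one
  model per operating room, say) are a straightforward but unimplemented
  variant.
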