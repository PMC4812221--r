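---
title: "Key-pose activity recognition: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Key-pose activity recognition: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keypose)
```

## The recognition problem

RGBD sensors ship with joint-tracking software that reduces each video
frame to a small set of 3D joint positions — a skeleton. Recognizing which
activity of daily living (drinking, sitting down, answering the phone, ...)
a skeleton sequence shows is a core capability for ambient assisted-living
systems, where activity logs feed health monitoring for people living
independently. `keypose` implements a deliberately simple, fast and
training-light pipeline for this task, in four stages.

### 1. Posture features

Each frame with $P$ joints becomes a dimensionless posture vector. With
$\mathbf{J}_0$ the torso and $\mathbf{J}_2$ the neck,

$$\mathbf{d}_i = \frac{\mathbf{J}_i - \mathbf{J}_0}
  {\lVert \mathbf{J}_2 - \mathbf{J}_0 \rVert}, \qquad i = 1,\dots,P-1,$$

and the frame feature is $\mathbf{f} = [\mathbf{d}_1, \dots,
\mathbf{d}_{P-1}]$, of length $3(P-1)$. Centering on the torso removes
where the person stands; dividing by the neck–torso distance removes body
size. The feature deliberately **keeps** orientation: facing direction
carries information about the action, so no rotation normalization is
applied (`test` coverage asserts a rotated frame changes the feature).
Nothing temporal enters the descriptor, which is what eventually makes the
pipeline insensitive to execution speed.

Degenerate frames (neck–torso distance below $10^{-9}$ m, i.e. corrupt
tracking) raise an error naming the frame index rather than being dropped:
silently removing frames would change the sequence length and hence the
clustering input, so the caller must decide.

### 2. Key-pose extraction

The $N$ posture vectors of one sequence are clustered into $K$ groups by
k-means under the squared-Euclidean objective

$$\arg\min_{S} \sum_{j=1}^{K} \sum_{\mathbf{f}_i \in S_j}
  \lVert \mathbf{f}_i - \mathbf{C}_j \rVert^2 .$$

The $K$ centroids are the sequence's *key poses*. Clustering is run per
sequence — no shared dictionary is learned across sequences — so encoding a
new sequence requires no training data at all.

Numerical choices (the clustering literature leaves them open, so they are
fixed here and exposed as arguments):

* k-means++ seeding, `n_init = 10` restarts (best objective kept),
  at most 300 Lloyd iterations, relative improvement tolerance $10^{-6}$;
* after Lloyd converges, single-point improvement passes (Hartigan-style
  moves with exact size-weighted objective deltas) run until no move
  lowers the objective — this escapes the partition-level local optima
  that plain Lloyd is stuck in, and on tiny instances makes the solver
  agree with exhaustive enumeration;
* ties (a frame equidistant from two centroids) go to the lower-indexed
  centroid, making runs bit-reproducible;
* an emptied cluster is repaired by donating the point farthest from its
  centroid, so the result always has exactly $K$ non-empty clusters and
  the activity vector below always has exactly $K$ blocks;
* $K > N$ is an error by default (`clamp_k = TRUE` sets $K \leftarrow N$),
  mirroring the practice of capping $K$ at the shortest sequence length in
  a dataset;
* every sequence's seed is derived by hashing (master seed, sequence id,
  repetition), so experiments are reproducible while sequences stay
  independent.

### 3. Activity feature vector

Centroids carry no time information, so they are sorted by the frame index
at which their cluster first occurs; e.g. cluster IDs
`2,2,2,3,3,1,1,4,4,4` give the order `2, 3, 1, 4`. The sorted centroids
are concatenated into the activity vector of fixed length $3K(P-1)$ — with
$K = 5$ and $P = 7$, just 90 elements. Because the descriptor ignores how
long each pose was held, playing the same motion faster or slower (any
monotone resampling preserving the pose visit order) leaves it unchanged
on well-separated data.

### 4. Classification

Activity vectors are classified by a one-vs-one multiclass soft-margin SVM
with RBF kernel $K(\mathbf{x}, \mathbf{y}) = e^{-\gamma \lVert \mathbf{x} -
\mathbf{y} \rVert^2}$: one binary machine per class pair
($M(M-1)/2$ for $M$ classes), majority voting at prediction, LIBSVM (via
the `e1071` package) as the solver. Three conventions are fixed in-package:

* features are standardized per dimension (mean 0, variance 1), with the
  statistics fitted **on the training split only** and frozen — test
  vectors are transformed, never refitted (a leakage guard that the test
  suite asserts);
* $(C, \gamma)$ are chosen by stratified cross-validated grid search on
  the training split, default grid $C \in \{2^{-5}, 2^{-3}, \dots,
  2^{15}\}$, $\gamma \in \{2^{-15}, \dots, 2^{3}\}$, 5 folds; CV-accuracy
  ties break toward smaller $C$, then smaller $\gamma$ (the smoother
  model). The original experimental work on this pipeline did not report
  its selection procedure or values, so this conventional protocol is the
  package's own choice;
* predictions are closed-world: a novel activity is still mapped to the
  most similar training class. Rejecting unknown activities (e.g. via
  probability outputs) is explicitly out of scope.

## Evaluation protocols

`protocol_spec()` covers the standard settings: class-stratified random
splits (presets A/B/C at training fractions 1/3, 2/3, 1/2), leave-one-
actor-out ("new-person"), and leave-one-sequence-out. Stratification of
the random splits is a deliberate choice — plain random splits at a 1/3
training fraction can lose a class entirely, which both crashes the SVM
and distorts the metrics. Repetitions rerun the protocol with fresh
derived seeds (clustering is randomized) and results are averaged
arithmetically; per-repetition detail is retained in the report.

Metrics follow the usual confusion-matrix definitions (rows = truth,
columns = prediction): per-class precision and recall, pooled accuracy,
and unweighted macro averages. A class never predicted (or absent from a
test fold) yields an undefined marker (`NA`) that is excluded from the
macro average by default; `undefined_as_zero = TRUE` switches to the
pessimistic zero convention.

### Mirroring augmentation

Datasets with left-handed actors benefit from adding the "other-handed"
version of each training sequence. `mirror_sequence()` reflects every
frame across the body's sagittal plane and swaps left/right joint labels.
The sagittal plane is defined **per frame, body-relative**: through the
torso joint, normal along the left→right shoulder direction. A
camera-fixed plane would break for rotated subjects; the body-relative
definition makes mirroring an exact involution and an isometry, both of
which are property-tested. In `run_experiment()`, mirrored copies are
added to training folds only (under the same actor ID, so actor-disjoint
folds stay leak-free); the test fold is always the natural recording,
which keeps augmented and unaugmented runs comparable.

## The synthetic generator: what it emulates, and what not

`synthetic_config()` / `simulate_sequences()` produce labelled datasets
with exactly the structure the pipeline assumes: each class is an ordered
tour of latent key poses (offsets from a fixed ~1.75 m rest skeleton);
each actor has a body scale and stands somewhere on a floor area; frames
dwell on each pose (60% of its allocation) and linearly interpolate toward
the next (40%); i.i.d. Gaussian noise is added per coordinate; actors may
be left-handed (their sequences are mirrored). Defaults — 3 classes,
5 actors, 3 repetitions each, 30–60 frames, 5 mm noise, scales 0.9–1.1, a
3 m floor square, 0.3 m minimum pose separation — are meant as a small
but plausible laboratory capture campaign: the repetition structure
mirrors common public datasets, 5 mm is typical RGBD joint jitter, and
0.3 m separation is the scale of a clearly distinct arm/leg posture.

The generator supports two analysis regimes used throughout the tests:

* **dwell-only, noiseless** (`interpolate = FALSE, noise_sigma = 0`, unit
  scale, no translation): every frame sits exactly on a key pose, so
  clustering at the true $K$ must return inertia 0 and centroids that
  equal the template pose features exactly, in template order — an exact
  invertibility check of the whole encoding;
* **dwell-only with noise**: pose clusters are tight, well-separated
  blobs, the regime in which duplication- and speed-invariance of the
  activity vector hold provably and are asserted at $10^{-6}$.

What the generator does **not** emulate: biomechanics (bone lengths are
not preserved under noise), realistic inter-class confusability (templates
are drawn independently, so classes are easier to separate than e.g.
*drink* vs *phone call*), tracking dropouts and occlusions, and any
specific public dataset's statistics. A pipeline that is perfect on these
synthetic campaigns is therefore validated for *correctness of its
mechanics and invariances*, not for field accuracy; on public benchmark
recordings, accuracy also depends on unreported solver hyperparameters, so
published figures can be approached but not matched exactly.

Problem sizes in the shipped tests and acceptance script (45-sequence
campaigns, 200 oracle instances capped at $N \le 8$, 5 generator seeds for
the end-to-end run) were chosen so the full suite completes in minutes on
one CPU while still exercising every stage; all scale linearly if larger
studies are wanted.

## Known limitations

* Dwell weights make pose *durations* part of the generative model, but
  the encoder discards them by design; activities distinguished only by
  timing are outside this representation's reach.
* First-occurrence ordering is brittle when a clustering run relabels
  poses inconsistently across very noisy sequences; the restarts mitigate
  but cannot eliminate this.
* The closed-world SVM never abstains.
* `clamp_k` changes the feature length per sequence when it fires, so it
  must be used uniformly (the experiment runner refuses mixed lengths).

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 42)
sim <- simulate_sequences(cfg)
spec <- protocol_spec("new_person", k_values = 4, scheme = "J7", seed = 42)
report <- run_experiment(sim$manifest, spec, sequences = sim$sequences)[["4"]]
report$accuracy
report$confusion
```
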