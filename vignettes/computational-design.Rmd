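---
title: "Computationally informed design and analysis of object-recognition experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computationally informed design and analysis of object-recognition experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`objstrat` implements, end to end and on purely synthetic data, the workflow
of a visual discrimination study in which a hierarchical feature model is
used twice: first as an analysis tool (which stages of processing explain an
observer's per-pair performance?) and second as a design tool (which
stimulus pairs *dissociate* early from late processing?). This vignette
explains the model choices, the tunable parameters, and what the synthetic
pipeline does and does not establish about real behavioural data.

## The stimulus family

Stimuli are 100 x 100 grayscale renderings of an object made of a body
("base") with three spheres attached on top. Two shape dimensions define
the task:

* **concavity** — 11 levels mapping linearly to a signed bulge of the
  base's silhouette (level 0 maximally concave, 5 flat, 10 maximally
  convex);
* **alignment** — 4 levels displacing the left sphere upward and the right
  sphere downward, from horizontally aligned (0) to misaligned along an
  upper-left to lower-right diagonal (3).

The renderer is a deterministic signed-distance-function ray marcher with
orthographic projection and single-light Lambert shading. Geometry
constants live in `render_config()`: the base is a profiled slab whose
half-width varies quadratically in height (the concavity parameter is the
mid-height bulge, at most 0.18 world units where the frame spans
[-1, 1]); spheres have radius 0.16 and the alignment step is one third of
a radius, so level 3 displaces by a full radius. The background is black
and the object is lit, which makes the convex distractor brighter than the
concave target — a deliberate property of the design, since brightness is
one of the low-level cues whose explanatory power the analysis later
quantifies. Rendering is pure arithmetic: identical specifications produce
bit-identical pixels, and for left-right symmetric shapes, left versus
right lighting produces exact mirror images (a unit test).

Identity-preserving transformations are rotations about the three axes (0
to 180 degrees in 30 degree steps), five light locations, three sizes
(100/80/60 %) and five screen positions. Excluding size and position, the
enumerated space is 4 x 11 x 7^3 x 5 = 75,460 stimuli.

### The 4 x 4 sub-grid and roles

The experiment uses a 4 x 4 sub-grid of the 4 x 11 shape grid.
`select_subgrid()` chooses the four concavity columns by exhaustive search
(all 330 subsets) with a lexicographic objective: maximal end-to-end pixel
dissimilarity (the trained pair must stay maximally different), then
minimal variance of adjacent-column dissimilarities, then symmetric
spacing. On a space whose dissimilarity is exactly linear in the concavity
index this returns columns {0, 3, 7, 10}; on the rendered stimuli it
returns {0, 4, 7, 10}. The packaged default, used wherever no data-driven
selection is supplied, is {0, 3, 7, 10}.

Roles follow the anti-diagonal rule: the four cells on the anti-diagonal
are ambiguous, the six cells on the concave/aligned side are targets, the
six on the convex/misaligned side distractors.

### Protocols

`protocol_pairs()` reproduces the design's pair lists exactly: three
training protocols (the base pair; dimension learning with one
concavity-only and one alignment-only pair; 5 x 5 transformations) and
nine test protocols — three rotation protocols of 6 x 6 = 36 pairs each,
light location 16, size 4, position 25, combination rotation 36, and the
two model-informed protocols of 7 x 7 = 49 pairs each: 287 test pairs in
total.

The canonical labelled training set (`training_stimuli()`) contains the 16
unique stimuli of the three training protocols: the base pair, the two
one-dimension pairs (chosen with stimuli disjoint from the base pair, at
the unambiguous grid cells nearest the trained corners), and the five
singly-transformed variants of each base-pair member.

## The decoder

`fit_decoder()` is the package's central fitting function. For each of the
13 named sublayers of the backbone (conv1, norm1, pool1, conv2, norm2,
pool2, conv3, conv4, conv5, pool5, fc6, fc7, fc8) it:

1. extracts activations of the training images **before rectification**;
2. reduces them by PCA, retaining at most `n_components` (default 23,
   never more than n - 1) components, and standardises each retained
   component to zero mean and unit variance;
3. fits a linear soft-margin SVM (libsvm via **e1071**, `cost = 1`,
   deterministic) in the standardised space.

The **classification score** of a pair is the signed geometric distance of
the target to the layer's hyperplane minus that of the distractor,
`(w'x + b)/||w||` each; positive means the layer favours the correct
choice. Scores are antisymmetric under swapping the pair and invariant to
rescaling the hyperplane (both property-tested).

A technical point worth knowing: standardising all n - 1 principal
components whitens the training configuration into a regular simplex, so
the *training* geometry (and noiseless training accuracy, which is 100 %
at every layer) is identical across sublayers. All layer specificity lives
in how *new* images project — which is exactly what every downstream
analysis uses.

### The default backbone

The default backbone is a compact convolutional hierarchy with frozen,
seeded Gaussian weights at its native 32 x 32 resolution: three
convolution / cross-channel-normalisation / max-pool blocks, three further
convolutions, and three fully connected stages, all bias-free (so an
all-zero image produces all-zero activations). It is a structural stand-in
exposing the 13-sublayer readout contract; any backbone with the same
contract (for instance a pretrained one) can be plugged in via a `forward`
function. Random fully connected features generalise far less than
pretrained ones — a limitation discussed below.

### Noise calibration

Without noise the readouts separate the 16 training stimuli perfectly at
every layer, which would put the model's training performance far above a
biological observer's. `calibrate_noise()` adds zero-mean iid Gaussian
pixel noise to the inputs and bisects its standard deviation on [0, 1]
(luminance units) until the mean training accuracy — averaged over all
sublayers, stimuli and (by default) 100 fresh noise draws — is within
`tol = 0.02` of the 0.75 target. The evaluation draws are a fixed seeded
schedule scaled by the candidate sd, which keeps accuracy monotone along
the bisection path. Typical calibrated values are sd ~ 0.7.

## Model-informed pair selection

`sample_candidates()` draws target/distractor pairs uniformly with
replacement (default 10,000 iterations) from a pool of 5145 target and
5145 distractor stimuli (three shape cells per side — configurable, since
the exact pool membership is a free design choice — crossed with all
rotation and light transformations; 5145^2 = 26,471,025 ordered pairs).
Each candidate is summarised by its mean classification score over the
early (1-3) and late (11-13) sublayers, standardised by the *population*
standard deviation of those means across candidates.

`filter_select()` keeps the `zero_vs_high` profile (|early z| <= 0.5 and
late z >= 1.5) or its mirror image, then ranks survivors by the **profile
contrast** — the high-side z minus the magnitude of the near-zero side —
and greedily picks k = 7 pairs with pairwise-distinct targets and
distractors. Ranking by the high side alone is tempting but subtly wrong:
the z-scores are not centred (the candidate population's mean score is
positive), so the near-zero side of a high-side-ranked selection stays
biased toward the population bulk, and the assembled protocol remains
solvable by the layers that are meant to be at chance. The contrast
ranking removes that bias; with it, the re-scored 49-pair protocols show
chance-level decisions on their "zero" side across selection seeds (a
dedicated acceptance-style test).

The protocol is assembled as the 7 x 7 cross of the selected stimuli,
which is what yields 49 pairs from 7 + 7 stimuli. The cross construction
has a second, convenient consequence: for off-diagonal pairs the "zero"
side's score is a difference of two per-stimulus distances of similar
magnitude, so positive and negative signs balance and the chance-level
property is stable.

Thresholds (`tau_zero = 0.5`, `tau_high = 1.5` SD units) are exposed in
`selection_criteria()` and reported in the selection object, since the
original cut-offs are not published to this precision.

## Synthetic observers

`observer_model()` is the generative model the statistics stage assumes —
a probit choice rule with lapse:

p(correct) = lambda / 2 + (1 - lambda) * Phi( sum_l w_l s_l / sigma )

with w a simplex of layer weights, s the pair's 13 classification scores,
sigma the decision noise and lambda the lapse rate. This trial-level model
is the package's own assumption (the study design it emulates fits no such
model); it exists so that every statistic downstream has a ground truth to
recover.

`species_presets()` provides two illustrative observers:

* **rat-like** — weights on the convolutional sublayers 4-10 with a
  triangular profile decaying toward depth, lapse 0.30, relative decision
  noise 2.0. The triangular profile matters: per-layer score dispersion
  grows roughly six-fold from conv2 to fc8, so a flat profile would be
  dominated by the deep, late-correlated stages and the preset would stop
  behaving like a mid-level observer.
* **human-like** — uniform weights on the fully connected sublayers
  11-13, lapse 0.05, relative decision noise 0.5.

Decision noise is *relative*: `simulate_study()` rescales it by the
across-pair spread of the observer's weighted score
(`normalize_decision_noise()`), so the presets transfer across backbones
and calibrations. With the calibrated decoder the rat-like observer sits
near 63 % overall with high-vs-zero > zero-vs-high, and the human-like
observer solves zero-vs-high near ceiling (~96 %) while staying near
chance on high-vs-zero — the dissociation signature, with the paired
orderings opposite between the two presets.

A deliberate limitation: the human-like preset does **not** reproduce a
~94 % overall accuracy across all nine protocols. A pure fc-layer reader
of a random-weight backbone generalises poorly on several transformation
protocols because untrained fully connected features are far less
transformation-tolerant than pretrained ones. The preset reproduces the
direction of every dissociation, not the absolute human performance
level.

`simulate_sessions()` reproduces the session structure: training sessions
of 100 trials with veridical reward and correction trials (the incorrect
pair repeats until answered correctly; correction trials are excluded from
every analysis); test sessions of 120 trials with one third old
(base-pair) trials, correction trials only after old errors, and random
reward in 80 % of new trials (affecting only the `rewarded` flag, never
correctness). Correction-run lengths are drawn as geometric variables,
which is distributionally identical to simulating the repeats one at a
time. Session time limits and inter-trial intervals are not simulated, as
timing never enters any analysis.

## Statistics

* `accuracy_table()` — per-pair accuracies after dropping correction
  trials and any test session whose base-pair accuracy falls below 65 %;
  old trials are reported separately and never enter per-pair accuracies.
* `binomial_chance_test()` — exact two-sided binomial test with
  Clopper-Pearson interval (`stats::binom.test`).
* `layer_correlation_profile()` — per-sublayer Pearson correlation between
  per-pair accuracy and classification score, with a one-sided permutation
  test (default 1000 permutations). The p-value uses the add-one
  estimator (b + 1)/(m + 1), which is never exactly zero.
* `split_half_reliability()` — per split, each pair's trials are halved at
  random and the two per-pair accuracy vectors correlated; the mean over
  (default) 100 splits is Spearman-Brown corrected to a full-set
  reliability. Whether the original analyses split by session or by trial
  is unknowable from the description; random trial halves are the default
  here.
* `combined_reliability()` — geometric mean of two full-set reliabilities,
  the ceiling for a cross-dataset correlation.
* `layer_regression()` — OLS of the 287 per-pair accuracies on the 13
  scores, reporting R^2, the overall F test, per-coefficient t tests and
  sqrt(R^2) as the correlation-scale equivalent.
* `brightness_predictor()` / `pixel_similarity_predictor()` — the
  low-level image covariates: the base pair's brightness difference minus
  each test pair's, and the (A + D)/2 - (C + B)/2 contrast of similarities
  to the trained stimuli. Pixel similarity defaults to Pearson correlation
  of flattened pixels (negative Euclidean distance is available), as the
  original measure is not specified.
* `species_comparison()` — per-subject training-normalised test
  performance, the within-species protocol contrast, and the
  species-by-protocol interaction (unpaired t on per-subject
  zero-vs-high minus high-vs-zero). The function is symmetric in its two
  arguments; pass the human-like table first to read the interaction as
  human minus rat.

Pooled accuracies are trial-level (sum correct / sum trials), not means of
subject means; both conventions are computable from the trial table.

## Problem sizes and numerical choices

The package's own test battery runs the full chain at reduced but
statistically adequate sizes, chosen once: noise calibration at the full
100 iterations; pair search with 1,200-3,000 candidate draws (the
dissociation profiles are stable from a few hundred draws onward);
simulated studies of 11 subjects x 20 sessions per protocol, which puts
split-half reliability above 0.9 and makes the profile-peak and
regression-recovery checks sharp; 1000 permutations for profile tests.
Degenerate inputs (zero-variance sublayers, empty candidate pools,
zero-spread standardisation, all-correction trial tables) raise immediate
errors rather than propagating NaNs; ties in binary decisions (score
exactly 0) count as incorrect.

## What passing the synthetic battery does and does not show

The synthetic generator emulates the session structure, the exclusion
rules, and choice behaviour driven by known layers. Recovery of the
planted structure (profile peaks, regression weights, orderings,
interaction sign) validates the *analysis chain* — it shows the pipeline
measures what it claims to measure at realistic trial counts. It does not
validate the substantive claims about any real species: real observers are
not probit readers of a fixed hierarchy, real reliabilities are far lower
(0.40-0.46 split-half, against > 0.9 here), and the pretrained features
of the original network differ from the synthetic backbone's. Those
questions need the real behavioural data, which this package deliberately
does not depend on.
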