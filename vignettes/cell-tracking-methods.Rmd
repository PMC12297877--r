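---
title: "Tracking mitotically active cells: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking mitotically active cells: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotrack)
library(dplyr)
```

## The problem

Long-term grayscale microscopy of adherent cell cultures produces image
series in which a detector (typically a fine-tuned convolutional network)
emits per-frame bounding boxes for two object classes: moving cells, and
cells in the early mitotic phases whose boxes are larger and rounder.
Detectors miss objects intermittently, and detections carry no identity, so
turning per-frame boxes into cell trajectories requires (a) a motion model
that can predict where a known cell should be, (b) an appearance model that
can tell visually similar cells apart, and (c) an association step that
combines both. `mitotrack` implements this tracking-by-detection loop, the
evaluation metrics suited to incompletely annotated data, and a synthetic
data generator so every stage can be tested end to end without any imaging
data.

## Motion model

Each track carries an 8-dimensional state
$x = (c_x, c_y, a, h, v_{c_x}, v_{c_y}, v_a, v_h)$: box centre, aspect
ratio $w/h$, height, and their per-frame velocities. Dynamics are constant
velocity, $x_{t+1} = F x_t$ with $F = \begin{pmatrix} I_4 & \Delta t I_4
\\ 0 & I_4 \end{pmatrix}$, and the detector observes $z = H x$ with
$H = (I_4 \mid 0)$. Noise is isotropic: initial covariance
$P_0 = 500\,I_8$, process noise $Q = 0.1\,I_8$, observation noise
$R = 2\,I_4$ — pixel-scale values that assume a detector with roughly
1–2 px of localisation noise and say almost nothing about initial
velocities, which are initialised to zero on the first detection.

States are estimated with an unscented Kalman filter. The scaled unscented
transform propagates $2n + 1$ sigma points through the transition function
and reconstructs mean and covariance from weighted sample moments; the
hyperparameters are the Merwe defaults $\alpha = 10^{-3}$, $\beta = 2$,
$\kappa = 0$, all configurable via `ukf_params()`. With the shipped
*linear* $F$ and $H$ the UKF is mathematically identical to the linear
Kalman filter, and the test suite exploits exactly that: an independently
written linear filter serves as the oracle, and predict/update must agree
with it to $10^{-6}$ relative error across random states. The unscented
machinery earns its keep as an extension point — a non-linear transition
(e.g. coordinated-turn dynamics closer to how cells actually crawl) can be
plugged in without touching any other part of the tracker.

Numerical choices: covariances are re-symmetrised as $(P + P^\top)/2$
after every step; Cholesky factorisation retries with diagonal jitter
escalating from $10^{-9}$ to $10^{-3}$ before raising an error; and the
aspect-ratio and height components of the mean are clamped to a floor of
$10^{-3}$ after predict/update, because the linear model happily predicts
negative sizes that the box geometry cannot represent.

## Appearance model

A detection's appearance is summarised by pooling feature maps from three
scales of a convolutional backbone: each $H_i \times W_i \times C_i$ map
is global-average-pooled to a length-$C_i$ vector
$e_i = \tfrac{1}{H_i W_i}\sum_{u,v} F_i(u, v, :)$, the three vectors are
concatenated, and the result is $\ell_2$-normalised to a unit embedding
$\hat e$. Embeddings are compared by cosine distance
$d_{\cos} = 1 - \hat e_i \cdot \hat e_j / (\lVert\hat e_i\rVert
\lVert\hat e_j\rVert)$; the norms are kept in the formula even though
fused embeddings are already unit norm, so the function is robust to
unnormalised inputs.

The backbone is a *contract*, not a dependency: any function mapping a
crop to three feature maps at strictly decreasing resolution fits.
The package ships `toy_backbone()`, a deterministic, training-free
implementation (fixed seeded sinusoidal functionals of the intensity image
mixed with gradient magnitude, at resolutions 32/16/8 for a 128 px input
and 8/16/32 channels) whose purpose is reproducibility: identical crops
give bit-identical embeddings, and visually distinct crops separate in
cosine distance. It is *not* a discriminative learned descriptor, and
tests using it only verify the pooling/fusion/distance pipeline — not
re-identification power on real imagery. An adapter for a pretrained
network (e.g. ResNet50 tapped at its three intermediate stages) can be
supplied through the same contract; it is deliberately not bundled because
trained weights are a download and contribute nothing to verifying the
pipeline algebra. Crops are clipped to the frame, resized bilinearly to
the backbone input size, and grayscale values are used directly.

## Association

The cost of assigning detection $j$ to track $i$ blends both cues:
$C_{ij} = \lambda\, d^2_{\text{motion}}(i,j) + (1 - \lambda)\,
d_{\cos}(i,j)$, where $d^2_{\text{motion}}$ is the squared Mahalanobis
distance of the detection's measurement under the track's predicted
measurement distribution (innovation covariance $S$), and $d_{\cos}$ is
the minimum cosine distance to the track's gallery of recent embeddings.
$\lambda$ defaults to 0.5 — no principled value exists without a learned
appearance model, so equal weighting is the neutral choice; when no
embeddings are supplied the cost reduces to the pure motion distance.
Pairs with $d^2_{\text{motion}}$ above the 95% $\chi^2_4$ quantile
(9.4877) are gated out, and optionally pairs with cosine distance above
0.4 (applied only when embeddings are in use). Gated entries enter the
solver as a large finite sentinel ($10^5$) and are stripped from the
result, so the Hungarian solver never sees infinities.

The one-to-one assignment is solved exactly by a shortest-augmenting-path
Hungarian implementation (tested against an exhaustive-permutation oracle
on every run of the suite); ties between equal-cost optima fall to the
solver's ascending scan order, which deterministically favours low
indices. Association is class-agnostic — a `Cell` detection may match a
track whose last detection was `Division` and vice versa — because
mitosis *is* a transition between the classes; a track reports the class
of its most recent matched detection.

Confirmed tracks are matched in an age-prioritised cascade: age-1 tracks
(matched last frame) get first claim on detections, then age-2, and so on
to `max_age`. Tentative tracks and confirmed tracks that just missed one
frame then get an IoU fallback round (cost $1 - \text{IoU}$, feasible
above 0.3 overlap), which is more forgiving than the Mahalanobis gate
while a track's velocity estimate is still poor.

## Track lifecycle and gap-filling

New tracks start `tentative` and confirm after `n_init = 3` consecutive
hits; a tentative track that misses a single frame is deleted (it was
probably clutter). Confirmed tracks survive `max_age = 30` consecutive
misses before deletion, and while unmatched they *coast*: for up to
`max_coast = 5` consecutive frames the tracker emits their UKF-predicted
box, flagged `source = "predicted"`. This gap-filling is the mechanism by
which tracking lifts recall above the raw detection stream — a transient
detector dropout no longer costs the frames it spans. The coasting budget
is bounded because indefinitely emitted predictions degenerate into false
boxes as uncertainty grows; five frames covers transient dropouts while
staying well inside the motion model's useful prediction horizon.
Evaluation can include or exclude coasted boxes (`include_predicted`);
the default includes them, since recovering missed objects is precisely
what they are for. Each track keeps a bounded gallery of its last 100
embeddings (oldest evicted) for the appearance term. Track identifiers
are handed out sequentially from 1 and never reused.

Division events are not modelled in the tracker: a daughter cell is simply
a new track. Lineage reconstruction is out of scope.

## Evaluation metrics

On incompletely annotated data, precision-style metrics mislead: a correct
detection of an unannotated object counts as a false positive. The package
therefore implements completeness-oriented metrics. Ground truth and
predictions are matched per frame, greedily by descending IoU with a 0.5
threshold (ties to lowest indices); unmatched *predictions* are ignored.
**Modified Recall** is $100 \cdot \sum TP / \sum (TP + FN)$ over all
frames; **Average IoU** is the mean IoU over matched pairs only. The
greedy rule and the 0.5 threshold are this package's choices — reasonable
defaults where no canonical rule exists, and both configurable. An
identity-switch counter (a ground-truth identity's matched predicted
identity changing between its consecutive matches) supports
tracking-continuity checks; it is invariant to renaming predicted
identities by a bijection.

## The synthetic generator

`simulate_cells()` emulates the statistical structure of a sparse adherent
culture: 1600 × 1200 frames, an initial population drawn uniformly from
10–22 cells, per-cell box heights around 40 px, aspect ratios around 1.3.
Motion is a heading-noise random walk — constant per-cell speed of 1–4
px/frame along a heading diffusing with σ = 0.3 rad/frame, reflecting at
the borders. This is deliberately *not* the tracker's constant-velocity
model: testing a filter on its exactly matched dynamics proves little, so
the simulator stresses it with curved, non-linear paths. Divisions are
rare (default rate 0.002 per cell per frame, keeping the strong class
imbalance of real mitosis annotations): a dividing cell's box inflates by
1.4× and rounds to aspect 1 for 5 frames, then the parent identity
disappears and two fresh daughter identities appear in the same frame.
`degrade_detections()` models the detector: independent per-box dropout,
Gaussian box jitter (σ = 1 px default), uniform confidences in [0.5, 1],
and optional Poisson clutter. `render_frames()` draws Gaussian blobs on a
noisy background for exercising the image pipeline, with no pretence of
optical realism; `invert_intensity()` provides the grayscale-inversion
augmentation used on such imagery. The `well_separated` mode confines
each cell to its own tile of the frame — the regime where a correct
tracker must produce exactly one track per cell and zero identity
switches.

Because no quantitative motion statistics are published for this kind of
culture, the motion defaults are plausible rather than calibrated. What
passing tests on this generator shows is that the tracking loop is
correct: gaps are bridged, identities are conserved when separation makes
that unambiguous, and recall improves over raw detections under dropout.
What they do not show is performance on real microscopy, which depends on
detector quality and a discriminative appearance model.

Appearance in simulation is handled by `signature_embeddings()`: each
simulated cell owns a fixed random unit vector, and each detection gets a
noisy re-normalised copy of its cell's vector. In 16 dimensions distinct
signatures are nearly orthogonal (cosine distance ≈ 1) while same-cell
embeddings stay within ≈ 0.1, which gives the association stage an
appearance channel with realistic *structure* at zero rendering cost.

## Problem sizes and verification

The shipped tests and the acceptance script run on deliberately modest
problem sizes — sequences of 50–100 frames with 10–15 cells, 10 random
seeds for the stochastic properties, 100 random states for the
filter-equivalence oracle and 200 random instances for the assignment
oracle — chosen so the whole suite verifies the pipeline's properties in
a few minutes on one core. The properties checked are scale-free
(optimality, equivalence, determinism, strict recall improvement), so
larger instances add runtime, not information.

## Known limitations

* The shipped motion model is linear; the UKF's advantage is only realised
  if a non-linear transition is plugged in.
* The toy backbone is a reproducibility device, not a re-identification
  model; real deployments should adapt a pretrained network through the
  backbone contract.
* Evaluation requires a matching rule the data's original annotation
  process never specified; results are sensitive to the IoU threshold in
  crowded scenes.
* Divisions are handled as track death plus two births; lineage is not
  reconstructed.
* The simulator does not model occlusion, deformation, cell contact, or
  imaging artefacts — dropout is independent per box, which is kinder than
  the spatially correlated failures of real detectors.
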