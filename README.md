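# mitotrack

Multi-object tracking-by-detection for time-lapse microscopy of
mitotically active cell cultures.

Modern cell-culture imaging pipelines pair a convolutional detector with a
tracker: the detector emits per-frame bounding boxes for two classes
(`Cell`, and the larger, rounder `Division` objects preceding cytokinesis),
and the tracker links those boxes into persistent cell identities. The
detector misses objects intermittently, so a good tracker does two jobs:
it keeps identities stable across frames, and it *fills the gaps* —
emitting motion-predicted boxes through transient dropouts so downstream
analyses (migration, proliferation, division timing) see continuous
trajectories. `mitotrack` implements that loop for R users, along with the
evaluation metrics appropriate for incompletely annotated microscopy data
and a synthetic cell-motion simulator that makes every stage testable
without any imaging data.

## What is inside

* **Motion**: an unscented Kalman filter over the 8-D box state
  `(cx, cy, a, h, v_cx, v_cy, v_a, v_h)` with constant-velocity dynamics
  `x[t+1] = F x[t]`, observation `z = H x`, and isotropic covariances
  `P0 = 500 I8`, `Q = 0.1 I8`, `R = 2 I4`.
* **Appearance**: multi-scale embeddings — three convolutional feature
  maps, global-average-pooled (`e_i = mean over (u,v) of F_i(u,v,:)`),
  concatenated and L2-normalised — compared by cosine distance
  `1 − ê_i·ê_j / (‖ê_i‖‖ê_j‖)`; the backbone is a pluggable contract with
  a deterministic training-free implementation included.
* **Association**: blended cost
  `C_ij = λ d²_motion(i,j) + (1−λ) d_cos(i,j)` with chi-squared
  Mahalanobis gating (χ²₀.₉₅, 4 df ≈ 9.4877), solved one-to-one by a
  Hungarian algorithm inside an age-prioritised matching cascade, with an
  IoU fallback stage for young tracks.
* **Lifecycle**: tentative → confirmed after 3 hits, deletion after 30
  misses, and gap-filling: unmatched confirmed tracks emit their
  filter-predicted box for up to 5 consecutive frames.
* **Evaluation**: Modified Recall `100·ΣTP / Σ(TP+FN)` (false positives
  not penalised — appropriate when annotations are incomplete), Average
  IoU over matched pairs, and an identity-switch counter.
* **Simulation**: curved-random-walk cell motion with division events,
  detector dropout/jitter degradation, optional frame rendering, and
  per-cell appearance signatures.
* **I/O and CLI**: MOT-challenge and YOLO-style text files, and a
  `mitotrack` command (`inst/cli/mitotrack`) with `simulate`, `track`,
  `evaluate` and `ablate` subcommands.

## Worked example

Simulate a 60-frame culture of 12 cells, degrade it with 30% detector
dropout, track it, and compare raw detections with tracker output:

```r
library(mitotrack)

gt  <- simulate_cells(sim_config(frames = 60, n_cells = c(12, 12), seed = 11))
det <- degrade_detections(gt, dropout_p = 0.3, seed = 12)
emb <- signature_embeddings(det, gt, seed = 13)
tr  <- track_cells(det, embeddings = emb, n_frames = 60)

glance(tr)
#> # A tibble: 1 × 5
#>   n_frames n_tracks n_boxes n_detected n_coasted
#>      <dbl>    <int>   <int>      <int>     <int>
#> 1       60       18     668        456       212

tidy(tr)
#> # A tibble: 668 × 8
#>   frame track_id     x     y     w     h class source
#>   <int>    <int> <dbl> <dbl> <dbl> <dbl> <chr> <chr>
#> 1     3        5 1250.  282.  39.0  26.4 Cell  detected
#> 2     4        5 1248.  282.  37.2  26.4 Cell  predicted
#> ...

evaluate_tracking(gt, det)       # the raw detector stream
#> <track_eval> Modified Recall 69.23%, Average IoU 91.35% (TP 522, FN 232, pairs 522)
evaluate_tracking(gt, tidy(tr))  # the tracker output
#> <track_eval> Modified Recall 86.47%, Average IoU 90.19% (TP 652, FN 102, pairs 652)
count_id_switches(gt, tidy(tr))
#> [1] 2
```

Reading the numbers: the detector alone recovers 69% of the annotated
boxes; the tracker re-emits every matched detection *plus* 212 coasted
(filter-predicted) boxes across dropout gaps — rows with
`source = "predicted"`, like frame 4 of track 5 above — lifting Modified
Recall to 86% at essentially unchanged localisation quality (Average IoU
90%). The 18 track identities for 12 cells reflect restarts where a cell's
confirmation window was interrupted; identities are never merged.
`autoplot(tr)` draws the trajectories, with coasted boxes as open points.

The same comparison is available from the shell:

```sh
inst/cli/mitotrack ablate --seed 3 --frames 40 --cells 10 --dropout 0.3
#> configuration,modified_recall,average_iou
#> raw_detections,72.70,92.79
#> tracked,92.06,91.71
```

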