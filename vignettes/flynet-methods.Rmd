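---
title: "Tracking flies and quantifying their social networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking flies and quantifying their social networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flynet)
```

flynet turns overhead grayscale video of a group of walking fruit flies into
a directed, weighted social interaction network, and provides the tools to
compare and average such networks across experimental repeats. This vignette
explains the models behind each stage, the tunable parameters and their
defaults, the numerical choices, and what the built-in synthetic arena does
and does not establish about real recordings.

## The constant-count tracker

The tracker rests on one structural assumption: **the number of flies N is
constant throughout the video**. A closed arena filmed in full guarantees
this, and the assumption converts the hardest tracking failure — losing or
inventing animals during occlusions — into a solvable assignment problem.

### Detection

Frames are segmented by background subtraction. The background is the
per-pixel temporal median over up to nine frames sampled evenly across the
video (`build_background()`); with bright flies on a dark static arena the
median removes every fly. The median is computed by a vectorised
compare-exchange network rather than a per-pixel `median()` call, which
would otherwise dominate the whole run. Foreground pixels are those whose
absolute difference from the background exceeds a threshold; by default the
threshold comes from Otsu's criterion on the difference-image histogram,
computed once per video (static lighting; a per-frame threshold would let an
empty frame segment its own noise). Foreground pixels are grouped into
8-connected components — 4-connectivity breaks thin, ~20 px fly bodies —
and components under `min_area = 4` px are dropped as sensor noise. Both
parameters are engineering defaults, exposed in `flynet_config()` and
logged with every run.

Each blob carries its centroid, area, pixel list and principal axis. For a
uniform ellipse the variance along the major axis is $a^2/4$, so the body
half-length is estimated as $2\sqrt{\lambda_1}$ from the leading eigenvalue
of the pixel covariance.

### Keeping N identities through occlusions

When two or more flies interact their bodies merge into a single connected
component, so a frame may show fewer blobs than flies. The typical
single-fly area is the median blob area over frames whose blob count equals
N (`estimate_fly_area()`). If a frame shows $N - n$ blobs, $n$ duplicate
nodes are created and the assignment between the previous frame's N flies
and the current blobs is kept square (`build_assignment_graph()`). Blobs
whose area exceeds `merge_factor` (default 1.5) times the typical area are
flagged as merge candidates; the $n$ duplicates are then allocated
greedily, each to the blob whose area most exceeds its current
multiplicity's worth of typical fly area. The greedy rule matters when
several pairs merge in the same frame: a two-fly component can sit just
under the flag threshold, and count conservation — not the area test — must
decide where the missing flies are.

The square assignment is solved exactly by the Hungarian algorithm
(`solve_assignment()`, a shortest-augmenting-path implementation with dual
potentials, $O(N^3)$) on Euclidean centre-to-centroid distances. Distance is
the entire cost — no velocity extrapolation — because at arena frame rates
a fly moves a small fraction of the inter-fly spacing per frame. The number
of flies matched into copies of a blob is that blob's final fly count.

Multi-fly blobs are then split with a k-component Gaussian mixture fitted
to the blob's pixel coordinates by EM (`split_merged_blob()`): means are
initialised at the previous centres of the flies assigned to the blob, full
covariances are floored at 0.25 px² (eigenvalue floor) so a thin body cannot
collapse a component, at most 100 iterations with a $10^{-4}$ log-likelihood
tolerance. An emptied component triggers one k-means re-initialisation; a
second failure is an error. Identities are finally re-assigned by a second
Hungarian pass between the previous centres and all current (split)
centres.

### Orientation

A walking fly keeps its head pointing along its direction of motion. The
head is the major-axis endpoint agreeing in sign with the velocity smoothed
over `orient_window = 5` frames; below `speed_floor = 0.2` px/frame the
previous head choice is retained (axis sign is propagated through flips).
Frames before the first informative motion are back-filled once the first
choice is made. The orientation sweep runs in forward time after all
positions are fixed, so backward-tracked prefixes (used when a video starts
mid-occlusion and the tracker anchors on the first fully separated frame)
get the same treatment.

## Touch classification

A *touch* is a single-frame event in which one fly (the interactor)
contacts another (the interacted) head to tail. Frames are classified by a
support vector machine over **22 temporal features** per ordered pair and
frame $t$: the Euclidean distances from the interactor's head to the
interacted's tail at the 11 frames $t-5 \dots t+5$, and the magnitudes of
the interactor's displacement from its window-centre position, expressed in
a coordinate frame translated to the interacted fly's concurrent position,
at the same 11 frames (the $t+0$ entry is 0 by construction). The window
means the classifier sees approach dynamics, not just instantaneous
proximity.

The classifier (`train_touch_classifier()`) is an RBF-kernel SVM with
per-feature z-scoring learned from the training set; cost and kernel width
are chosen by 5-fold cross-validation over a small grid. Training data are
balanced touch/no-touch frames; negatives mix gated near-misses with random
far pairs, mirroring the prediction-time distribution.

At prediction time (`classify_frames()`) only ordered pairs whose head-tail
distance is within `candidate_radius` (default three body lengths) are
scored. The gate is purely computational — at N = 16 there are 240 ordered
pairs per frame — and the suite checks that no positive classification sits
anywhere near the gate boundary on the synthetic fixtures.

*Touch interactions* are extracted from the per-frame labels by run-length
rules (`extract_interactions()`): gaps shorter than `min_gap = 15` frames
are merged first — a flickering classifier output is one sustained touch —
and merged runs shorter than `min_run = 15` frames (~0.5 s at 30 fps) are
dropped. Merging before thresholding is a deliberate order; the reverse
would split a sustained touch interrupted by single misclassified frames.

## The social network and its nine parameters

Interactions are tallied into an N×N adjacency matrix of counts — row =
interactor, column = interacted, zero diagonal (no self-interaction is
defined) — and normalised by the maximum entry before any parameter is
computed (`build_adjacency()`, `social_network()`). The parameters:

* **In/Out/Total degree** — directed edge counts per node; degree =
  in-degree + out-degree. **Weighted** versions (strengths) sum normalised
  weights. Both the normalised total and the raw count total are exported,
  since figures comparing absolute activity plausibly use counts.
* **Clustering coefficient** — the weighted directed form: with
  $\hat W = W^{1/3}$ element-wise,
  $C_i = [(\hat W + \hat W^T)^3]_{ii} \, / \, 2[d^{tot}_i(d^{tot}_i - 1) -
  2 d^{\leftrightarrow}_i]$, zero when the denominator vanishes.
* **Betweenness centrality** — fraction of all-pairs shortest paths through
  a node (endpoints excluded, equal splitting among ties), with edge
  lengths $1/w$ — the convention of connectivity toolboxes. Computed via
  igraph; the tests check it against exhaustive path enumeration.
* **Global efficiency** — mean inverse shortest-path length over ordered
  node pairs (disconnected pairs contribute 0).
* **Transitivity** — closed over total directed triplets on the binarised
  graph (three distinct nodes; a reciprocal pair is not a triplet).
* **Density** — realised directed edges over $N(N-1)$.
* **Assortativity** — Pearson correlation of total binary degrees across
  directed edges, reported as `NA` (not 0) when degree variance is zero,
  e.g. on a complete graph. A weighted out/out variant is deliberately not
  the default: the definition follows the unweighted-network lineage of the
  parameter.
* **Weighted total interaction** — the sum of normalised weights.

`relabel_by_outgoing()` renumbers flies in ascending weighted out-degree
(ties by weighted in-degree, then original index), so that similarly ranked
flies occupy similar positions across repeats — useful before matching and
for presentation.

## Averaging node-unaligned networks

Averaging networks from different repeats entry-wise is only meaningful if
node k is "the same fly" in every repeat. With a fresh group of flies per
repeat it is not, and the naive mean blurs structure. The package aligns
networks by minimising the Frobenius norm $\|W_1 - P W_2 P^T\|_F$ over
permutation matrices — an NP-hard quadratic assignment — with the
**graduated assignment** heuristic: a doubly stochastic relaxation updated
by softassign (exponentiated compatibility gradient, then alternating
row/column Sinkhorn normalisation) while the inverse temperature anneals
from $\beta_0 = 0.5$ by factor 1.075 up to 10, with 30 Sinkhorn sweeps per
step. The final soft assignment is projected to the nearest permutation by
maximum-weight bipartite matching. Two refinements are deliberate design
choices: a first-improvement 2-opt descent over pairwise transpositions
(lowest-index preference, making tie handling deterministic), and 20
internally seeded random 2-opt restarts. The annealed relaxation finds the
right basin on structured inputs (planted permutations are recovered
exactly), while the restarts guard against the shallow local minima typical
of small noisy instances. The identity permutation is a guaranteed
fallback: the returned objective never exceeds it.

The **average network** (`average_networks()`) is the incremental running
mean: $M \leftarrow \frac{i-1}{i} M + \frac{1}{i} W_i^\circ$ with
$W_i^\circ = P W_i P^T$ the aligned copy of the $i$-th network. Note the
update uses the *forward* conjugation $P W_i P^T$ — the orientation that
actually reduces $\|M - W_i^\circ\|$, which the suite verifies — and stores
every permutation so the final mean can be recomputed from scratch
(associativity check). The first network anchors the mean; `anchor =
"median"` instead anchors on the network with median total interaction,
since the incremental mean is mildly order-sensitive. Automorphic inputs
make the minimiser non-unique; the deterministic tie-breaking makes runs
reproducible rather than canonical.

## Group statistics

`mann_whitney()` compares one parameter between two conditions: U from rank
sums with midranks, exact two-sided p by enumeration when $n_a + n_b \le
12$ without ties, otherwise the normal approximation with tie and
continuity corrections (delegated to `stats::wilcox.test`, which implements
exactly this switch). `scheirer_ray_hare()` is the rank-based two-way
extension of Kruskal–Wallis: all observations are ranked jointly, two-way
sums of squares are computed on the ranks, and each effect's
$H = SS_{\mathrm{effect}} / MS_{\mathrm{total}}$ is referred to
$\chi^2$ with the effect's degrees of freedom; $MS_{\mathrm{total}} =
N(N+1)/12$ without ties and is tie-corrected otherwise. When one factor is
degenerate the statistic reduces exactly to Kruskal–Wallis, which the suite
asserts. `correlation_map()` computes pairwise Pearson correlations between
per-fly parameters with a significance mask at p < 0.01 (Spearman by
option); zero-variance columns yield flagged `NA`s.

## The synthetic arena

Every stage is testable without recorded data through the simulator
(`sim_config()`, `simulate_trajectories()`, `render_frames()`), which
emulates the geometry and photometry of an overhead infrared arena camera:
dark background, one bright filled ellipse per fly with a 2.5:1 aspect
ratio and a target body area of 20 px, 30 frames/s nominal rate, and
optional Gaussian pixel noise (off by default).

**Motion model.** Headings follow an Ornstein–Uhlenbeck-like angular walk:
the turn per frame is Gaussian with standard deviation
$1.2\,(1 - \text{persistence})$ rad (persistence 0.9 by default), speeds
relax towards a Gaussian target (mean 1.2, sd 0.4 px/frame), walls clamp
and reflect, and a soft collision-avoidance projection keeps free flies
two body lengths apart in capped 2.5 px steps. No published motion model
exists for this setting; any smooth bounded walk suffices for the
tracker's purposes, and the parameters were chosen once to give
plausible-looking arena traffic. The default arena (480×360 px for 16
flies) matches the areal density of a 640×480 recording of larger groups;
density is the main driver of chance multi-fly pile-ups, which are the
genuinely ambiguous events for any constant-count tracker.

**Scripted episodes.** Touch and crossing episodes are planned with
per-fly disjoint time windows and orchestrated at run time by a scheduler:
an approaching fly is steered smoothly towards a standoff slot near its
partner (detouring around the partner's body on a forward-curving arc when
it approaches from the wrong side), and the episode activates only when
the fly has genuinely arrived, up to a bounded delay — so scripted events
never teleport anyone. During a touch the interactor's head is placed
within the touch radius of the partner's tail *by construction*; during a
crossing the two bodies overlap along the axis into one connected
component while their centres stay separable. A smoothed slot axis absorbs
abrupt partner turns, episode leaders keep a wider (smoothly ramped) wall
margin and curve away from walls rather than mirror-reflecting, and
colliding episodes push each other apart through their leaders. The planted
touch window **is** the synthetic ground truth: the touch radius defaults
to half a body length (~4 px), a geometric stand-in for a behavioural
definition.

**What the simulator does not emulate** — and what passing tests therefore
do not establish about real data: appearance variation between flies,
illumination drift and shadows, reflections at arena walls or water edges,
grooming and jump/flight events, wing and leg kinematics, and real
behavioural statistics of touch. The synthetic results validate the
algorithmic machinery (count conservation, assignment optimality, feature
computation, run-length rules, matching and averaging), not biological
detection performance, which requires expert-annotated recordings.

## Numerical choices and degenerate inputs

* EM covariance floor 0.25 px²; eigenvalue flooring keeps components
  non-degenerate at the 20 px body scale.
* Assignment costs must be finite; the solver is exact, so ties between
  equal-cost matchings resolve by construction order, deterministically.
* Clustering and transitivity denominators of zero give 0 and `NA`
  respectively; assortativity with zero degree variance gives `NA`.
* Sinkhorn normalisation stops at $10^{-6}$ row/column-sum error or 30
  sweeps; non-convergence warns and projects the current state.
* Zero adjacency matrices have all-zero weights (no 0/0), zero efficiency
  and density.
* All simulation, training, matching-restart and planning randomness is
  seeded; identical configurations reproduce bit-identical results, and
  internal seeding never disturbs the caller's RNG stream.

## Problem sizes used by the test suite

The suite validates the tracker on a 50-fly, 2,000-frame, 640×480 arena
with 25 scripted crossings (constant-count property), on 16-fly 1,200-frame
videos with 20 crossings (identity continuity), and runs the full
track–classify–network pipeline on twenty 16-fly, 1,500-frame arenas with
30 planted touches each, against one classifier trained on 1,000 touch and
1,000 no-touch frames from a separate labelled arena. Exhaustive oracles
run at up to N = 7 (assignment), N = 6 (QAP, network parameters) and
N = 8 (planted-permutation recovery); the rank-test calibration uses 1,000
null simulations. These sizes were chosen so the whole suite completes on a
single CPU while still exercising every group size the methods target.

## Known limitations

* Identity through a merge is inferred, not observed: flies that remain
  merged and nearly coincident for many frames can exchange identities
  without any appearance cue to correct it. The tracker guarantees the
  *count*, not the impossibility of swaps; at the paper-scale densities the
  suite measures, swaps are confined to rare multi-fly pile-ups.
* Only head-to-tail touch is classified. The feature/classifier interface
  is generic — other interaction classes would need their own labels and
  possibly features.
* The incremental average depends mildly on input order; anchoring on the
  median-activity network reduces but does not remove this.
* Graduated assignment is a heuristic for an NP-hard problem; optimality is
  verified exhaustively only at small N, and at N = 16 the returned
  alignment is a certified-not-worse-than-identity local optimum.
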