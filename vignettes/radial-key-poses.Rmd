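---
title: "Radial silhouette features and the bag of key poses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial silhouette features and the bag of key poses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keyposes)
```

This vignette documents the model behind the package, the parameters
that matter, the numerical conventions, and the design choices that were
genuinely open — the things a maintainer would want written down.

## The pose representation

A silhouette is a binary mask; its information for action recognition
sits almost entirely in the outer contour. The package traces the
contour of the largest 4-connected foreground component with the classic
border-following algorithm (via EBImage), keeping the traversal list as
the point set `P` — on 1-pixel-wide protrusions the trace revisits
pixels, which is the standard behaviour of border following and is kept
as-is.

With the contour centroid `C = (x_c, y_c)` as origin, each point gets
its Euclidean distance `d_i` to `C` and an angle
`alpha_i ∈ (0, 360]` measured as a single clockwise sweep in image
coordinates (y grows downward), starting at the downward vertical:

```
alpha_i = arccos((y_i - y_c) / d_i) * 180 / pi        if x_i - x_c >= 0
          360 - arccos((y_i - y_c) / d_i) * 180 / pi  otherwise
```

with `alpha = 0` mapped to 360. The implementation evaluates this as
`atan2(dx, dy) mod 360`, which is identical on all inputs and avoids an
explicit clamp of the arccos argument (for callers that do evaluate the
arccos form, the argument should be clamped to `[-1, 1]`; rounding can
push it out by a few ulps). Two conventions were fixed deliberately:

* The branch condition is centroid-relative (`x_i - x_c >= 0`); an
  absolute-image-coordinate reading would be vacuous for any silhouette
  to the right of the image origin.
* The two branches must sweep in the *same* rotational direction.
  The mirror-folded alternative (`180 + arccos(...)` on the raw
  argument) parameterizes the two half-planes in opposite directions,
  which destroys the property that rotating a contour by a whole number
  of bins cyclically shifts the feature — a property the test suite
  asserts exactly. Whether the sweep starts at the upward or downward
  vertical only permutes bins globally and is immaterial.

Bins are assigned as `s_i = ceiling(S * alpha_i / 360)`: angles exactly
on a boundary join the lower-index bin, and a point coincident with the
centroid (`d_i = 0`, geometrically near-impossible on a real contour)
deterministically joins bin 1 rather than raising an error.

Each bin's distances are collapsed by one of three summaries:
`variance` — the sum of squared deviations from the bin mean, kept
exactly as defined (no division by the count; the normalization below
absorbs scale) — `max`, and `range`. An empty bin contributes 0, the
natural "no mass" value. The `S` summaries are normalized to unit sum.
If the pre-normalization sum is below `1e-9` times the contour radius
(e.g. a perfect circle under `range`, where only rounding residue
remains), the all-zero vector is returned with a `degenerate` flag
instead of dividing by (near) zero; downstream Euclidean distances
remain well defined.

Two numerical details make the stated invariances exact rather than
approximate. Contours are translated to their bounding-box origin
before the centroid computation, so integer pixel contours produce
bit-identical features under any integer mask offset (floating-point
means are not translation-equivariant otherwise). And because the
summaries are computed per bin before normalization, scaling a contour
about its centroid leaves the feature unchanged to rounding for all
three summaries.

One practical caveat, visible in the tests: under *rasterization*
(rather than exact coordinate scaling) the local-spread summaries
`range` and `variance` are noticeably noisier than `max`, because a
half-pixel staircase perturbation is large relative to a bin's spread
but small relative to its maximum distance. The 2×-rescaling stability
check is therefore asserted for `max`; users working with very
low-resolution or heavily aliased silhouettes should prefer `max`, or
use `range` at resolutions where the figure radius is tens of pixels.

## The bag of key poses

Training sequences are pooled per (view, class) combination and each of
the `M × R` groups is reduced to `K` cluster centers by K-means with
Euclidean distance; the centers are the key poses, labeled with their
group. Pooling per group (rather than globally) guarantees every class
and every view equal representation in the dictionary — this is the
model-fusion approach: one shared multiview model, not per-view
classifiers fused at decision time.

K-means choices: k-means++ seeded initialization, Lloyd iterations, 10
restarts keeping the best total within-cluster sum of squares, all
driven by a caller-supplied seed (per-group seeds are derived from it).
K-means is the one nondeterministic stage of the method, which is why
the evaluation harness repeats runs over derived seeds and reports
medians. On tiny groups the restarts reliably find the global optimum
(the suite checks equality with exhaustive-partition K-means on groups
of ≤ 12 points). A group with fewer than `K` distinct frames clamps `K`
to that count with a warning rather than failing or emitting empty
clusters. The training set is put into a canonical label order before
grouping, so the learned bag does not depend on how the caller stored
the sequences.

Each key pose then receives a weight: every training frame is matched
with its nearest key pose (lowest index on exact ties), and
`w = matches / assignments` counts the within-class fraction of those
matches. A key pose never selected keeps `w = 0` but stays in the bag —
there is no removal rule, and it can still be a nearest neighbour at
test time. Converting sequences to key-pose indices also yields, for
every training frame, its nearest-match distance; `average_distance` is
the mean of these. The phrase "average distance computed throughout the
training stage" admits a second reading — the mean pairwise distance
among the key poses themselves — which is exposed as
`compute_average_distance(method = "pairwise")`; the assignment-based
reading is the default because those are the distances the training
stage actually computes. The two differ numerically (pairwise distances
are much larger since key poses are spread out), so the choice matters
for the relevance term's scale and is stored with the model.

## Weighted DTW and best-view fusion

Sequence matching uses the classical unconstrained DTW recursion with
`dtw(0,0) = 0`, infinite first row and column, no window, no slope
constraint, and no path-length normalization — boundary conditions are
not dictated by the recursion itself, so the plain textbook choice is
used. The local cost of pairing key poses `i` and `j` is

```
d(i, j) = e(i, j) + z * rel(i, j)
rel(i, j) = |e(i, j) - average_distance| * w_i * w_j
```

where `e` is the Euclidean feature distance and `z ∈ {-1, +1}` comes
from the pairing table: two discriminative poses (`w > 0.9`) follow the
sign of the deviation (closer-than-average favored), two ambiguous
poses (`w < 0.1`) are always favored, a discriminative–ambiguous pair
is always penalized, and any other pairing follows the deviation sign.
`dev = 0` is treated as "below average" for continuity. The relevance
magnitude uses the *absolute* deviation so that `z` alone controls the
sign of the adjustment; combining the signed deviation with the table
would *increase* the cost of similar discriminative pairs — the
opposite of the table's stated intent of favoring them
(`match_params(signed_relevance = TRUE)` restores the literal signed
form for comparison). Pair costs, and hence accumulated DTW distances,
can be negative; no clamping is applied because all candidate matches
are scored under the same scheme, so only relative order matters.
Thresholds 0.1/0.9 are empirical constants carried in `match_params()`.

Since both test and training sequences are sequences of bag members,
the implementation precomputes the full key-pose pair cost matrix once
per model and params, making each DTW a table-lookup dynamic program.

A test performance may come with any subset of views. Each available
view is converted and matched against **all** stored training sequences
— not just same-view ones: the view-specific key poses make same-view
matches naturally closer, and not hard-filtering by view label means
the camera setup need not match between training and testing. The final
label is taken from the view whose best match has the globally lowest
distance (best view); ties break toward the lowest training-sequence
index, then the first view, for determinism.

## The synthetic data generator

No silhouette dataset is bundled, so the generator produces the input
regime the method assumes: multiple action classes, actors, and
synchronized views of binary masks, with controllable difficulty.
Shapes are star-shaped polygons `r(theta) = r0 * (1 + A(phase) *
cos(L * (theta - rot(phase))) + 0.06 * cos(2 * (theta - dir_c)))`:

* **Class identity** is the lobe count `L` (2, 3, 4, ... per class) plus
  a class-specific elongation direction `dir_c`. Lobe counts are kept
  below the Nyquist limit of typical bin counts (`S ~ 12`) — higher
  counts can alias onto each other after binning (e.g. 5- and 7-lobe
  patterns are indistinguishable at `S = 12`), which would make class
  separability depend on `S` in a way real actions do not.
* **Motion phase** modulates the lobe amplitude (`A` breathes by ±25%
  around 0.75 of its base) and slightly rotates the lobes (±0.05 rad).
  The rotation is kept small deliberately: radial features of a rotating
  shape shift cyclically across bins, and large rotations make one
  class's feature cloud sweep through another's.
* **Views** apply a fixed affine deformation (rotation by
  `(m-1) * pi/7`, y-squash by `1/(1 + 0.3 (m-1))`) to the same
  underlying pose — emulating cameras at different angles, not
  modelling projection.
* **Actors** perturb the shape multiplicatively (amplitude, base
  radius, orientation offset), drawn once per actor, so leave-one-actor-
  out folds genuinely face an unseen shape variant.
* **Boundary noise** flips pixels independently within a 1-pixel band
  around the true contour, mimicking segmentation errors; specks split
  off by flipping are handled by the largest-component rule.

Star-shaped regions are connected by construction, and the base radius
(0.17 of the image side, 80 px default) leaves headroom so a 2×-scaled
figure still fits the canvas. The whole dataset is a pure function of
`(config, seed)`; all randomness flows through one seeded stream.

What passing tests on this generator do **not** show: the shapes are
rigid parametric polygons, not articulated bodies; there is no
occlusion, no camera projection, no frame-to-frame segmentation
correlation, and class geometry is far cleaner than real silhouettes.
Results on the synthetic benchmark demonstrate correctness of the
pipeline and its claimed invariances, not field accuracy on video data.

## Evaluation protocols and parameter selection

Both protocols score one decision per multiview performance
(sequence-level accuracy). LOSO holds out each multiview sequence in
turn; LOAO holds out all sequences of one actor. The test suite runs the
full pipeline at 3 classes × 2 views × 3 actors × 2 sequences × 20
frames of 80 × 80 px — small enough for interactive runs, large enough
that every group clusters with `K = 3`–4 comfortably.

`parameter_sweep()` scores each `(S, K)` cell by the median accuracy
over `repetitions` runs with derived seeds (`seed + repetition`),
because K-means nondeterminism makes single runs noisy. The lower
median is used for even counts (deterministic, no interpolation), and
among cells tying at the maximum the lexicographically lowest `(S, K)`
wins — lower values are cheaper at both feature extraction and
matching.

Typical parameter guidance: `S` between 8 and 46 (12 is a good
default — low enough to filter boundary noise, high enough to separate
classes), `K` from a handful to ~130 depending on intra-class pose
variety, `summary = "range"` for clean silhouettes and `"max"` for
noisy ones.

## Known limitations

* Cross-view invariance is out of scope: a view must have been seen at
  training time to be matched well (unseen angles are matched to the
  nearest trained view implicitly, with degraded distances).
* Silhouette extraction itself (background subtraction, depth
  segmentation) is assumed done upstream.
* DTW distances are compared across views unnormalized; with highly
  unequal sequence lengths per view, path-length effects could bias the
  best-view decision. The recursion is kept as defined; a normalization
  switch was considered and rejected as a silent semantic change.
* The weight thresholds (0.1, 0.9) and the relevance form are carried
  as given; no attempt is made to learn them from data.
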