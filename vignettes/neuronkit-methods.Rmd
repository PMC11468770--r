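---
title: "Methods: neuron morphometry and collaborative-reconstruction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuron morphometry and collaborative-reconstruction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuronkit)
```

`neuronkit` models the computational layer of collaborative neuron
reconstruction: the tree representation and its metrics, the detectors that
propose somas, boutons and suspicious critical points, and the protocol
under which several annotators converge on a single validated morphology.
This vignette explains the models, the tunable parameters and the numerical
choices, and states exactly what the synthetic study conditions do and do
not demonstrate.

## The reconstruction unit

A reconstruction is a rooted tree of SWC records (`id, type, x, y, z,
radius, parent`), held as a tibble with a unit tag (`micron` or `voxel`)
and a per-axis voxel size. We adopt the *quasi-binary* convention: a
finalised tree has one root (the soma), no cycles, and at most two children
per non-soma node; only the soma may fan out further. `validate_tree()`
reports violations rather than erroring because fragment files (multiple
roots, orphan references) are legitimate intermediate states.

Two conventions are worth spelling out:

- **Pruning units.** "Terminal branches with fewer than six units" is read
  as six SWC records on the branch, excluding the branching point, which
  belongs to the retained structure. An alternative reading (six
  micrometers of cable) exists; node count was chosen because a "unit" of
  annotation work is a record, and because resampling standardises record
  spacing anyway. Pruning iterates to a fixed point — removing a branch can
  expose a newly short terminal branch — and branches attached directly to
  the root are exempt, so a small unbranched tree cannot delete itself.
- **Topological depth** counts bifurcation levels: the maximum number of
  branching points on any root-to-tip path, plus one. A bare soma or an
  unbranched cable has depth 1.

## Comparing reconstructions

`match_length()` resamples both trees to a common step — at most half the
distance threshold and no coarser than one voxel, so length ratios are not
biased by uneven sampling — and classifies each resampled edge by whether
its midpoint lies within the threshold of the other tree. This yields
R~c~ (fraction of the test reconstruction that is correct) and
R~m~ (fraction of the reference that is recovered); the accuracy is their
harmonic mean `2 Rc Rm / (Rc + Rm)`, zero when both vanish. Two empty trees
agree perfectly (accuracy 1); an empty tree against a non-empty one scores
0. R~m~ is the *recovered* ratio (one minus the missing fraction): with the
alternative sign convention a perfect reconstruction could not reach
accuracy 1.

The distance threshold defaults to two voxel lengths, the same threshold
the consistency metric uses for "nearby" nodes; no separate constant is
introduced. Matching is arc-length-based rather than node-based so that two
reconstructions of the same cable sampled differently still match.

Nearest-neighbour queries run on an exact uniform-grid spatial hash
(compiled); ties are broken by the lower point index so results are
deterministic. The test suite checks the whole machinery against an
O(n²) exhaustive search.

`consistency()` is node-based by definition: for every node of each
reconstruction, the nearest node of the other; the mean of the two
directional means is the bidirectional distance, and the fraction of pooled
nearest distances below two voxels is the consistency. It is symmetric in
its arguments.

## Topological height and stage analysis

Tips have topological height TH = 1 and a branching point is one plus the
highest TH among its children. Pass-through nodes inherit their child's TH:
TH is a branch-level quantity and must be invariant under resampling, which
inserts and removes pass-through nodes freely. The normalised topological
height divides by the per-neuron maximum TH over all recovered stages —
never per stage — so that NTH is comparable along the timeline; it is also
scale-free in the coordinates.

Stage recovery divides the edit log's wall-clock span (not its event count)
into `n` equal segments, with stage *i* the replay of all add/delete events
up to `t_min + i·span/n`; confirmations do not change geometry. The final
stage is therefore always the full replay.

`matched_unmatched_by_nth()` accumulates each resampled edge's length into
the NTH bin of its child node, split by matched/unmatched against a
reference, per stage. Lengths are conserved: matched plus unmatched per
stage equals the stage's resampled cable length. When the table is averaged
over several neurons, we average per neuron and then across neurons, so a
large neuron does not dominate the bins.

## Soma detection

For each ~256³ block: (1) discard blocks with 16-bit maximum below 250 —
an empty-field filter (8-bit input skips it with a warning); (2) z-score
normalise, clip at ±3σ and map to [0, 255] — 3σ clipping is the standard
convention where no mapping is prescribed; (3) binarise at the block's 99th
intensity percentile (linear interpolation over the full histogram; the
comparison is `>=` so the top percentile survives even when it saturates at
255); (4) Euclidean distance-transform the foreground — the "grayscale
distance transform" is read as the EDT of the just-binarised image, with a
gray-weighted geodesic variant available behind `transform = "geodesic"`;
(5) voxels with transform values in [5, 30] become candidates, scored and
sized by the transform value (the bounds are in voxels: the transform is
computed on the voxel grid); (6) greedy non-maximum suppression with a
15-voxel radius (half the upper candidate band), with score ties broken by
lexicographic coordinate order so the result is independent of input
ordering. Because the transform value *is* the blob radius, suppression
additionally removes any candidate lying inside a stronger candidate's
ball: a 25-voxel soma otherwise leaves an in-band ring of redundant
candidates outside a fixed 15-voxel radius.

`crop_block()` centres a block on a voxel with a fixed asymmetric split for
even sizes (`size - size %/% 2 - 1` voxels before the centre, `size %/% 2`
after), so integer centring is reproducible.

## Bouton detection

Varicosities appear as joint peaks in the intensity and radius profiles
along an axonal shaft. Profiles are computed per branch (peaks never span a
bifurcation) on the axon resampled at one voxel. Intensities are trilinear
samples of the 8-bit image (16-bit blocks are min-max rescaled, because the
intensity threshold is defined on 8-bit data). Radii use a surface test:
the largest integer r such that at least 85% of the sphere surface of
radius r is above a background threshold. Radii are estimated on a 3³
box-smoothed copy of the volume, and the default threshold adapts per
point — background median plus a quarter of the local centre intensity
above it — which tracks the brightness variation of unevenly labelled
axons; a fixed global threshold sits at the steepest part of the tube's
intensity fall-off and quantises radii uselessly at realistic noise levels.

Candidates are intensity peaks (moving average of width 3; a flat plateau
bounded by smaller values counts once, at its centre — integer radii
produce such plateaus constantly) with a radius peak within 3 nodes. Two
heuristics then apply: candidate radius at least 1.5× the median radius of
up to 10 surrounding nodes per side — excluding the candidate's own
contiguous radius plateau, which would otherwise inflate its baseline — and
8-bit intensity strictly above 120. Finally, candidates closer than 5
voxels (Euclidean) are deduplicated, keeping the brighter one. "1.5 times
larger than surrounding nodes" is read as larger in radius; the radius
profile is the quantity being peaked over.

## Critical-point verification

Candidates are branching points and tips of the pruned reconstruction,
scaled into the image frame. Each candidate gets a 32³ image patch
(zero-padded at volume borders) and a mask patch rasterised from the tree
(voxels within the local node radius of any edge, at least one voxel so
thin neurites stay visible). Verification is a contract — any function
`(patch_pair, kind) → probability in [0, 1]` — so trained convolutional
verifiers can plug in; network architectures and weights are deliberately
out of scope here. The shipped reference heuristic thresholds the patch at
its Otsu level floored at median + 3·MAD (Otsu alone bisects the noise when
foreground is sparse), takes the foreground component around the patch
centre, and clusters its boundary crossings: at least three disjoint exits
for a genuine branching point, at most one for a genuine terminal.
Truth for evaluation is distance-based: a candidate is positive when the
expert tree has a critical point of the same kind within 4 voxels (about
half the patch radius).

## Collaboration protocol and simulator

The protocol state is a set of segments (polylines between topological
events) with author, status and attachment. The rules enforced by
`apply_event()`: an added segment must originate from the soma, from a
segment by the same author, or from a confirmed segment; confirming,
deleting or modifying another user's segment requires the segment to
originate from the soma or a confirmed segment; nobody confirms their own
segment; the reconstruction is complete when every live segment is
confirmed. Violations raise classed conditions and leave the state
unchanged. Deleting a segment cascades to its attached subtree, preserving
the attachment invariant; a "modify" is represented as a delete plus an add
sharing a lineage reference. Agreement is the confirmed share of live cable
length — by the self-confirmation ban, every confirmed segment was touched
by at least two users.

The simulator runs round-robin agents with one action per turn: review an
eligible peer segment if any exists (confirm a correct one; delete a
spurious one with probability `confirm_diligence`, otherwise wrongly
confirm it), else trace an untraced true branch the agent may legally
extend, substituting a spurious branch with probability `error_rate`.
Timestamps are turn indices, the turn cap is 50× the number of true
branches, and the whole run is a pure function of the seed. Diligence 1 and
error 0 reproduce an error-free session exactly. The noncollaborative
counterfactual (`revoke_cross_edits()`) replays the log ignoring deletes by
non-authors (and replacement adds), which resurrects peer-deleted spurious
branches.

## Image metrics

Signal complexity divides each 20³ cube's mean foreground intensity by its
mean background intensity, with the foreground mask rasterised from the
reconstruction radii; cubes without foreground (or without background)
score 0, and the map is min-max rescaled to 8 bits. Local structural
complexity generalises Sholl analysis to every node as a centre, counting
edges whose endpoints straddle each probe sphere (an endpoint exactly on
the sphere counts with the inside, so grid-aligned fixtures are not
silently dropped). User attention counts distinct users with events inside
a 20 µm axis-aligned box per node, closed on the lower face and open on the
upper so abutting boxes partition space.

Image quality uses non-negative matrix factorisation. Every ten z-slices
are averaged and flattened into matrix *columns*; the factorisation is
rank 3 with a deterministic NNDSVD-style initialisation from the truncated
SVD followed by 200 multiplicative Frobenius updates — no random restarts,
so reports are reproducible. No pre-installed R package provides NMF, so
the factorisation (≈30 lines) is implemented here. The background is the
component whose spatial loading has the smallest coefficient of variation —
background illumination varies least across the field; the signal is the
original minus the background reconstruction, clipped at zero. Statistics
use only background below its 99th percentile and signal above its 90th, to
limit cross-talk. `contrast` is reported as the absolute difference of the
filtered medians; the literal signed convention (background minus signal,
negative for bright-signal images) is available via `literal_contrast =
TRUE`. On these phantoms `signal_rsd` decreases monotonically with added
noise σ — slab averaging suppresses the noise in the spread faster than in
the filtered median — so ranking phantoms by descending `signal_rsd` puts
the cleanest first; the tests assert exactly this ordering.

## Synthetic study conditions

The phantom generator emulates sparse fluorescence microscopy: Gaussian
cross-section tubes (σ = radius/2 — a one-parameter stand-in for the point
spread), hard soma balls, Gaussian varicosity swellings at shaft sites
(kept 5 voxels clear of tips and bifurcations, where a shaft profile is
undefined), bright blob artifacts standing in for vessel fluorescence and
dye leakage, and additive Gaussian noise, clipped to 8 or 16 bits. The
default voxel size (0.46, 0.46, 2.0) µm mirrors the anisotropic block
geometry of whole-brain datasets (256 voxels ≈ 117.76 µm laterally, 512 µm
axially). Default intensities (background 50, shaft 300, soma 500, noise σ
50 on the 16-bit scale) give a signal-to-noise ratio of 5 by the
(shaft − background)/σ convention. Artifact blobs default to radius 3
voxels — bright specks *below* the soma band, so they stress the [5, 30]
filter rather than duplicating somas; artifacts as large and bright as a
soma are indistinguishable from one by any geometry-based detector, which
is precisely why the human confirmation stage exists in the workflow.

What passing tests show: the pipelines recover what they are defined to
recover under controlled optics, and the protocol machinery is safe and
convergent. What they do not show: performance on real microscopy (uneven
labelling, crossing neurites from other cells, anisotropic PSF tails), nor
anything about trained verifier models, which are out of scope.

## Problem sizes

The test suite uses: 100 random trees for round-trip/pruning properties;
50 random pairs against the O(n²) matching oracle; 12 phantoms of 256³ for
soma recovery plus boundary fixtures; 10 rendered phantoms for bouton
recovery; 10⁵ fuzzed protocol events; 50 seeded three-annotator sessions
(10 true branches each, error 0.1, diligence 0.9) for convergence and error
confinement; and byte-level double runs of every CLI subcommand. The
acceptance script uses 20 soma phantoms and 20 collaboration runs. These
sizes keep a full run in the tens of minutes on one CPU while leaving the
statistical margins comfortable.

## Known limitations

- Radius estimation quantises to integer voxels; sub-voxel neurite radii
  (common at 0.2–0.3 µm resolution limits) are not resolved, which is why
  the bouton ratio test uses the surrounding median rather than a pointwise
  ratio.
- The matching statistic is length-based; a topologically wrong
  reconstruction overlapping the right cable can still score high. The
  critical-point machinery exists precisely to catch those errors.
- The simulator's agents are memoryless and round-robin; human annotators
  batch their work and specialise. The protocol guarantees do not depend on
  the schedule, but timing-related quantities (events per stage) should not
  be over-interpreted.
- The NMF quality metrics are comparative, not calibrated: they rank
  acquisitions of the same field, and the sign convention of `contrast`
  follows the absolute-difference default.
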