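---
title: "Stitching, alignment and read calling for in situ sequencing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitching, alignment and read calling for in situ sequencing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(issq)
```

## The problem

Barcode-based in situ sequencing reads out a short nucleotide barcode inside
intact cells through repeated cycles of sequencing-by-synthesis. Every cycle
yields a grid of partially overlapping microscope tiles in four fluorescence
channels (one per base, order G, T, A, C) plus a fiducial channel that is
constant across cycles. Two registration errors have to be corrected before
any base can be called: intra-cycle stage jitter (the microscope never
returns to exactly the commanded position) and inter-cycle rigid offsets
(the plate is removed and replaced between cycles). Because the features of
interest — rolling-circle amplicon colonies — are only 1–3 px across, a
single-cycle misalignment of even one or two pixels corrupts every read in
the affected region, so stitching and cross-cycle alignment must be near
pixel-perfect.

## The registration model

All tiles of all cycles are nodes of one *constraint graph*. An edge
(constraint) joins every unordered tile pair whose nominal stage positions
satisfy the overlap inequality `-wj <= dx <= wi` and `-hj <= dy <= hi`
(`dx = xj - xi`), within and across cycles alike. Each constraint carries an
initial offset (from the stage positions) that is then *refined*:

1. The circular cross-correlation of the two mean-subtracted fiducial
   rasters is computed with FFTs. The two strongest correlation maxima are
   each expanded into the four offsets that the circular ambiguity allows
   (`m` and `m - n` per axis), giving eight candidates.
2. Every candidate is scored by the zero-normalized cross-correlation
   (ZNCC) of the overlap it implies — the dot product of the mean-centred,
   unit-norm overlap intensities — and the best-scoring candidate becomes
   the refined offset, its ZNCC the constraint score.

Plain (mean-free) cross-correlation is the default rather than a whitened
cross-power spectrum. Whitening gives each spatial frequency equal weight,
which sharpens peaks on feature-rich natural images but drowns the true
peak in amplified high-frequency noise whenever the texture is band-limited
or an overlap is small; the ZNCC re-scoring step is indifferent to which
surface proposed the candidates, so the more conservative surface is the
safer default (`normalize = TRUE` restores classic phase correlation).
Candidates implying an overlap below 32 px are excluded: a handful of
shared pixels can reach chance ZNCC values near 1. Neither variant
estimates rotation or non-rigid distortion; the model is translation-only
by assumption.

Unreliable constraints are identified against an explicit null: 100 tile
pairs far enough apart to share no content (both offset components above
twice the largest tile dimension; when a small layout has too few such
pairs the most separated non-overlapping pairs are used, with a warning,
and a 2x2-style layout in which *every* pair overlaps disables filtering
with threshold -1). The nearest-rank 95th percentile of their scores is the
score threshold; constraints below it are *filtered*. A robust linear stage
model — RANSAC over affine maps from initial to refined offsets, exact
least-squares refit on the consensus set — then *imputes* replacement
offsets for the filtered edges, so the graph keeps its full edge set with
measured offsets wherever the data supports them and model predictions
elsewhere. Imputed edges get a fixed floor weight, `max(s_thresh, 0.05)`,
so they guide the solve without competing with measured edges; measured
weights are the ZNCC scores (floored at 0.05 so that all solver weights
stay positive even when the estimated threshold is negative). The RANSAC
inlier threshold defaults to a deliberately generous 30 px: a *global*
affine map cannot represent per-cycle-pair rigid offsets or per-tile
jitter, so true constraints deviate from it by tens of pixels, and only
catastrophically wrong refinements should be demoted.

## The global solve

Each constraint contributes two weighted equations,
`s_ij (x'_j - x'_i) = s_ij dx'_ij` and the y analogue, giving an
overdetermined linear system in the unknown global positions. The default
solver minimizes the weighted sum of *absolute* residuals — the
least-absolute-error criterion, equivalent to the linear program obtained
by adding nonnegative slack variables to each equation and minimizing
their sum. The x and y systems decouple and are each solved exactly with
the Barrodale–Roberts simplex (`quantreg::rq.fit.br` at tau = 0.5), which
is that LP specialized to L1 regression. The absolute-error criterion is
what makes the pipeline robust: a bad constraint that survived filtering
pulls a least-squares solution proportionally to its error, but contributes
only its (bounded) sign to the L1 gradient. Weighted least squares
(`method = "mse"`) and a maximum-score spanning tree
(`method = "spanning_tree"`, ties broken by the smaller tile-id pair) are
provided as the standard alternatives.

The system only determines positions up to a common translation. Rather
than leaving that gauge freedom to the solver, the first tile of the first
cycle is pinned to exactly (0, 0); disconnected graphs are solved per
component, secondary components keeping their nominal placement. On
degenerate instances the LP can have multiple optimal position sets;
solutions are therefore validated by objective value, which is unique.

Merging requires integer positions. `integerize_positions(method =
"round")` rounds each coordinate (re-anchoring so the anchor stays exactly
at 0). `method = "ilp"` refines the rounded solution by exact
per-coordinate integer descent: with all other tiles fixed, one tile's
conditional objective is a piecewise-linear convex function whose integer
optimum is the floor or ceiling of a weighted median, and sweeps are
iterated until no coordinate moves (with a time limit that falls back to
rounding). This is a local method rather than a branch-and-bound integer
program, but it starts at the rounded optimum so its objective can never be
worse than rounding, and because the constraint matrix is a signed
incidence matrix (totally unimodular), integer-valued offsets admit integer
optimal solutions that the descent typically reaches. Tiles are then
embedded in one frame shared by all cycles and merged per pixel by the mean
of contributing tiles or by the tile whose centre is nearest (ties to the
lower tile id); uncovered pixels are `NA`, tracked by a contributor-count
raster, and written as zeros with a count sidecar in TIFF export (TIFF has
no NaN for integer data).

## Alignment evaluation

`evaluate_alignment()` cuts the stitched frame into 200 px blocks (partial
edge blocks are skipped — slivers make unstable FFTs) and measures, per
block and per cycle pair, the phase-correlation offset of the fiducial
channel, unwrapped to the centred range. The block error is the maximum
over cycle pairs of the offset's L2 norm; the summary reports the median
block error — the median, not the mean, because feature-free blocks return
random offsets — and the *alignment percentage*, the share of blocks with
error below 1 px. Blocks with empty pixels or near-zero variance in any
cycle are excluded and counted; because it is a reporting choice whether
such blocks belong in the percentage's denominator, both the
evaluated-blocks and the all-blocks denominators are returned. Block
offsets are integer-resolution by default, matching the sub-1-px binning of
the summary.

## Read calling

The aligned stack is a 4-D raster `f(t, c, x, y)`. The cascade, in order,
with stage tags enforcing it:

1. **Background subtraction** (`sigma = 3`): subtract a Gaussian blur from
   every cycle/channel plane. This difference-of-Gaussians kills features
   larger than the blur scale — cells, illumination, accumulated
   fluorophore background (strongest in the C and A channels as cycles
   proceed) — while 1–2 px dots pass. Values may go negative.
2. **Z-scoring**: every plane to mean 0, sd 1 (population convention).
   This equalizes channel brightness and compensates the decay of colony
   amplitude over cycles, making all downstream calls invariant to any
   positive per-plane affine rescaling of the raw data. It assumes roughly
   balanced base usage per cycle across the library; a frequency-aware
   normalization is out of scope.
3. **Second-max suppression**: per pixel, subtract the second-largest
   channel value and clip at zero, leaving at most one nonzero channel —
   the defining property of an amplicon dot, which is bright in exactly one
   channel, while debris bright in several channels vanishes. A `sigma = 1`
   blur then tames the noise this sharpening amplifies.
4. **Temporal std projection**: per pixel, the standard deviation across
   cycles (population convention, two-pass centred formula so
   cycle-constant pixels give exactly 0), summed over channels. Colonies
   switch channels between cycles and light up; static content cancels.
5. **LoG detection**: scale-normalized Laplacian-of-Gaussian maxima over 7
   scales between sigma 1 and 3, thresholded on the response. The response
   threshold has no universal value; the default (0.1) was fixed once on
   the package's synthetic fixtures — where it keeps essentially all true
   colonies while rejecting noise maxima — and is a required review point
   for data normalized differently.
6. **Base calling**: channel values are read at the rounded colony centre
   from the *normalized* (pre-suppression) stack — suppression zeroes the
   runner-up channels, and the raw stack re-imports the background the
   cascade removed; extraction from the raw stack remains available via
   `extract_stage = "raw"`. Each cycle's base is the argmax channel; exact
   ties go to the fixed channel priority (G, T, A, C) and set a flag. A
   single centre pixel is used rather than a neighbourhood maximum; the
   detection blur has already aggregated the dot's neighbourhood.
7. **Cells and consensus**: a colony belongs to the cell whose label mask
   covers its centre pixel (label 0 = background, excluded). Per cell the
   `k = 2` most frequent reads are retained (count ties broken
   lexicographically, flagged), then matched to the barcode library by
   Levenshtein distance: a unique minimal-distance entry matches the cell,
   tied minima make it *ambiguous*, and a minimum above `max_distance`
   leaves it unmatched. Double-barcode libraries match a pair of reads to a
   pair of barcodes, trying both read-to-slot assignments and summing the
   two distances, with the same uniqueness rule; a cell with a single
   retained read fills both slots with it. Segmentation itself is an input
   (any labelled mask), not part of the package.

## The synthetic scene generator

Every stage is validated against scenes with exact ground truth, because
the quantities of interest (true tile positions, true colony barcodes) are
unobservable in real data.

* **Tiles** are crops of one latent full-field raster per cycle, so
  overlap content is *exactly* shared — the fixed point registration tests
  need. True position = nominal grid position (stride
  `floor(w * (1 - overlap))`) + per-tile integer jitter (rounded Gaussian,
  `jitter_sd`) + per-cycle rigid offset (uniform integers in [-8, 8] by
  default, cycle 1 pinned at zero). Nominal positions are reported without
  jitter or cycle offsets, as a real stage would. The scene refuses
  configurations where `overlap * min(tile) <= 2 * jitter_sd`, which could
  destroy true overlaps.
* **Texture** is speckle: white noise smoothed with a 0.8 px Gaussian,
  rescaled to mean 100, sd 30, clipped at zero. The ~1 px correlation
  length mirrors the fine nuclear and dot features that dominate real
  fiducial channels and keeps registration well-posed even for the ~2%-area
  corner overlaps of diagonal tile pairs; smoother textures leave those
  pairs unresolvable, which is precisely the regime the score filter and
  imputation exist for.
* **Sequencing content**: disk-shaped cells (non-overlapping, radius 8–14
  px) each draw a barcode from the library with replacement; colonies
  (Poisson mean 10 per cell, at least 1) sit uniformly inside their cell
  and render as Gaussian dots of sigma 1.5 px, amplitude
  `100 * decay^(t-1)` at cycle `t` in the channel of base `t`. Defaults
  emulate the difficult regime the cascade is built for: decay 0.9 per
  cycle, an additive background ramping linearly on the A and C channels to
  30% of the initial amplitude by the last cycle, and Gaussian noise at 10%
  of amplitude. The generator does not model PSF/optics, rotation,
  non-rigid distortion, or non-Gaussian camera noise — so passing tests
  demonstrate correctness of the algorithms under the stated error model,
  not performance on any particular microscope.

All generator randomness flows from explicit integer seeds; equal seeds
give bit-identical outputs.

## Numerical and reproducibility choices

* Gaussian blurs are separable convolutions with a discrete normalized
  kernel truncated at 4 sigma and replicate (nearest) boundaries, so a
  constant image is reproduced exactly; large planes are processed in
  column strips with full-kernel padding, which bounds memory without
  changing a single output value.
* The problem sizes exercised by the tests and the acceptance script — a
  4x4 grid by 3 cycles of 512 px tiles for stitching, 200 cells on a 768 px
  frame over 12 cycles for read calling, 50 random 4–6-node graphs for the
  solver-versus-enumeration check — are chosen so the whole validation
  suite runs on a laptop-class single core in minutes while still
  exercising every code path at realistic parameter values.
* Pipeline outputs are TSVs with a `#` comment header recording version and
  parameters; identical configurations produce byte-identical tables.
* Intensities are stored in 32-bit float TIFFs scaled to [0, 1] with the
  affine encoding recorded in a JSON manifest.
* Levenshtein distances come from `utils::adist` (standard unit-cost edit
  distance); the global L1 solve is delegated to `quantreg`'s exact simplex
  rather than a hand-rolled LP, with an independent exhaustive-enumeration
  oracle in the test suite.

## Known limitations

Rotation and scale are not estimated (a user-supplied per-cycle scale is
accepted); all-pair cycle alignment scales quadratically in cycles;
detection of colonies closer than ~2 px merges them — the per-cell
consensus absorbs most of the resulting read loss; the z-score
normalization assumes balanced base frequencies; the integer stage is a
descent, not a certified global integer optimum (its objective is still
never worse than rounding, and on noiseless scenes it recovers truth
exactly).

## A worked example

```{r example, eval = FALSE}
lib <- generate_barcode_library(64, length = 8, rng_seed = 1)
scene <- synthetic_scene(grid_shape = c(3, 3), tile_size = c(256, 256),
                         overlap_fraction = 0.15, n_cycles = 8,
                         jitter_sd = 2, rng_seed = 1)
sim <- generate_tile_set(scene, sequencing = list(n_cells = 20, library = lib,
                                                  n_cycles = 8))
st <- stitch_tiles(sim$tiles, seed = 1)
evaluate_alignment(st$stitched, block = 200)
sq <- stitched_sequencing(st$stitched, sim$truth, st$layout)
rc <- call_reads(sq$stack, sq$mask, lib)
table(rc$cells$status)
```
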