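# issq — stitching, alignment and read calling for in situ sequencing

Barcode-based in situ sequencing images the same well through repeated
cycles of sequencing-by-synthesis: each cycle produces a grid of partially
overlapping microscope tiles with four base channels (G, T, A, C) and a
fiducial channel shared across cycles. Rolling-circle amplicon colonies
appear as 1–3 px dots, bright in exactly one channel per cycle according to
the barcode inside the cell. Calling those barcodes requires near
pixel-perfect registration of every tile of every cycle, followed by a
filter cascade that separates dots from a background that grows over cycles
while the signal decays.

`issq` implements that computational core for analysts of optical pooled
screens and related in situ sequencing experiments:

* **Joint registration on a constraint graph.** Every overlapping tile
  pair — within and across cycles — contributes a positional constraint,
  refined by FFT cross-correlation with the circular ambiguity resolved by
  zero-normalized cross-correlation (ZNCC) scoring of all eight candidate
  offsets. Constraints scoring below the 95th percentile of a null of
  non-overlapping pairs are filtered and re-imputed from a RANSAC-fitted
  linear stage model.
* **Global positioning by least absolute error.** The weighted system
  `s_ij (x'_j − x'_i) = s_ij dx'_ij` over all constraints is solved by
  minimizing the sum of absolute residuals — the linear program obtained by
  attaching slack variables `t, u, v, w ≥ 0` to each row and minimizing
  their sum — with weighted least squares and a maximum-score spanning tree
  as alternatives, then integerized (rounding, or integer descent that is
  never worse) and merged into per-cycle mosaics.
* **Alignment evaluation.** Residual inter-cycle error measured per 200 px
  block as the maximum over cycle pairs of the phase-correlation offset
  norm, summarized by the median block error and the percentage of blocks
  below 1 px.
* **Read calling.** Difference-of-Gaussian background subtraction (σ = 3),
  per-plane z-scoring, second-maximum suppression (+ σ = 1 blur),
  std-across-cycles projection, Laplacian-of-Gaussian colony detection
  (σ = 1..3, 7 scales), per-cycle argmax base calling, cell assignment via
  a label mask, top-k consensus per cell (k = 2) and single- or
  double-barcode library matching by Levenshtein distance with a
  unique-minimum rule.
* **A synthetic scene generator** producing tile sets, sequencing stacks,
  cell masks and barcode libraries with exact ground truth, so every stage
  is testable end to end.

## Worked example

```r
library(issq)

lib   <- generate_barcode_library(64, length = 8, rng_seed = 1)
scene <- synthetic_scene(grid_shape = c(3, 3), tile_size = c(256, 256),
                         overlap_fraction = 0.15, n_cycles = 8,
                         jitter_sd = 2, rng_seed = 1)
sim   <- generate_tile_set(scene, sequencing = list(n_cells = 20,
                                                    library = lib,
                                                    n_cycles = 8))

st <- stitch_tiles(sim$tiles, seed = 1)
st$layout
#> global_layout (integer): 72 tiles, method mae, anchor 1, objective 504.674

evaluate_alignment(st$stitched, block = 200)
#> alignment_report: 9 blocks of 200 px ( 5 excluded )
#>   median error: 0 px; aligned <1 px: 100 %

sq <- stitched_sequencing(st$stitched, sim$truth, st$layout)
rc <- call_reads(sq$stack, sq$mask, lib)
table(rc$cells$status)
#> matched
#>      20
```

The layout line reports the solved integer positions of all 72 tiles (9
tiles × 8 cycles) with the anchor tile pinned at (0, 0); the objective is
the weighted sum of absolute constraint residuals at those positions. The
alignment report says every evaluable 200 px block of the stitched mosaic
has zero measured inter-cycle offset (blocks at the ragged mosaic border
are excluded). All 20 simulated cells end up `matched`, and comparing with
the generator's ground truth shows all 20 carry their true barcode.

A thin CLI wraps the same functions (`exec/issq` after installation):

```sh
issq simulate --grid 4x4 --overlap 0.15 --cycles 12 --seed 1 --out sim/
issq stitch --tiles sim/tiles --method mae --integerize round --merge mean --out stitched/
issq evaluate --stitched stitched/ --block 200
issq call-reads --stack stitched/ --mask sim/mask_latent.tif --library sim/library.tsv --k 2
issq run --seed 1 --out run/
```

## Layout

```
R/                  implementation (generator, registration, solver,
                    evaluation, read calling, I/O, pipeline)
exec/issq           command-line entry point
scripts/acceptance.R  end-to-end validation script
tests/testthat/     unit, property and acceptance tests
vignettes/methods.Rmd  the model, assumptions and design choices
```
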