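#' Assemble a run configuration
#'
#' Collects every tunable of the pipeline with defaults matching the
#' method's canonical parameter set (background sigma 3, post-suppression
#' sigma 1, LoG scales 1..3 over 7 steps, 200 px evaluation blocks, 100
#' null pairs at the 95th percentile, 2 consensus reads per cell).
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed; every random draw in the run derives from it.
#' @param grid,tile_size,overlap,cycles,jitter_sd synthetic scene geometry
#'   (used by the simulate stage).
#' @param n_cells,library_size,colonies_per_cell,amplitude,decay,noise_sd,
#'   background_max synthetic sequencing content.
#' @param solver,integerize,merge stitching choices (see
#'   [solve_positions()], [integerize_positions()], [merge_tiles()]).
#' @param n_pairs,percentile score-threshold null sampling.
#' @param block evaluation block size in px.
#' @param sigma_background,blur_sigma,min_sigma,max_sigma,num_sigma,
#'   log_threshold,k,max_distance,extract_stage read-calling parameters.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, grid = c(3, 3),
                       tile_size = c(256, 256), overlap = 0.15, cycles = 4L,
                       jitter_sd = 2, n_cells = 20L, library_size = 32L,
                       colonies_per_cell = 10, amplitude = 100, decay = 0.9,
                       noise_sd = 10, background_max = 30,
                       solver = "mae", integerize = "round", merge = "mean",
                       n_pairs = 100L, percentile = 95, block = 200L,
                       sigma_background = 3, blur_sigma = 1, min_sigma = 1,
                       max_sigma = 3, num_sigma = 7, log_threshold = 0.1,
                       k = 2L, max_distance = Inf,
                       extract_stage = "normalized") {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are rejected.
#'
#' @param path YAML file.
#' @param overrides named list of values taking precedence over the file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Stitch and align a tile collection
#'
#' Runs the full registration chain: adjacency graph, phase-correlation
#' refinement, null-based score filtering, robust stage model, imputation,
#' global solve, integerization and merging.
#'
#' @param tc a [tile_collection()].
#' @param solver,integerize,merge,n_pairs,percentile,anchor,seed see the
#'   stage functions.
#' @return list with `graph`, `layout` (integer stage), `stitched`.
#' @export
stitch_tiles <- function(tc, solver = "mae", integerize = "round",
                         merge = "mean", n_pairs = 100L, percentile = 95,
                         anchor = NULL, seed = 1L) {
  graph <- build_adjacency_graph(tc)
  graph <- refine_constraints(graph, tc)
  s_thresh <- suppressWarnings(
    estimate_score_threshold(tc, n_pairs = n_pairs, percentile = percentile,
                             rng_seed = seed))
  graph <- filter_constraints(graph, s_thresh)
  model <- fit_stage_model(graph, rng_seed = seed)
  graph <- impute_constraints(graph, model)
  layout <- solve_positions(graph, method = solver, anchor = anchor)
  layout <- integerize_positions(layout, method = integerize)
  stitched <- merge_tiles(tc, layout, mode = merge)
  list(graph = graph, layout = layout, stitched = stitched, model = model)
}

#' Extract the sequencing stack and aligned mask from pipeline artifacts
#'
#' Builds a raw [seq_stack()] from the first four channels of a stitched
#' image (empty pixels filled with 0) and re-registers the synthetic ground
#' truth mask into the stitched frame using the known true position of the
#' anchor tile.
#'
#' @param stitched a 5-channel [stitched_image][merge_tiles()] from a
#'   simulated scene.
#' @param truth the `truth` element of [generate_tile_set()].
#' @param layout the solved [global_layout][solve_positions()].
#' @return list with `stack` and `mask` in the stitched frame.
#' @export
stitched_sequencing <- function(stitched, truth, layout) {
  d <- dim(stitched$data)
  data <- stitched$data[, , 1:4, , drop = FALSE]
  data[is.na(data)] <- 0
  stack <- seq_stack(data, stage = "raw")
  pos <- truth$positions
  arow <- match(layout$anchor, pos$id)
  # stitched pixel (1,1) in ground-truth coordinates:
  gx <- stitched$origin[1] + pos$true_x[arow]
  gy <- stitched$origin[2] + pos$true_y[arow]
  # ... and in latent mask indices (mask row 1 = truth frame_origin y):
  off_c <- as.integer(round(gx - truth$frame_origin[1]))
  off_r <- as.integer(round(gy - truth$frame_origin[2]))
  mask0 <- truth$sequencing$mask
  out <- matrix(0L, d[1], d[2])
  rows <- seq_len(d[1]) + off_r
  cols <- seq_len(d[2]) + off_c
  rin <- rows >= 1 & rows <= nrow(mask0)
  cin <- cols >= 1 & cols <= ncol(mask0)
  out[rin, cin] <- mask0[rows[rin], cols[cin]]
  list(stack = stack, mask = out)
}

#' Run the full pipeline on a synthetic scene
#'
#' simulate -> stitch -> evaluate -> call-reads, writing every artifact
#' (tiles, constraint table, stitched TIFFs, alignment report, colony and
#' cell tables, summary JSON) under `cfg$out_dir`. All randomness derives
#' from `cfg$seed`; two runs with an identical configuration produce
#' byte-identical tables. Every stage writes its artifacts as soon as it
#' completes, so a failed run can be diagnosed from the directory contents.
#'
#' @param cfg a [run_config()].
#' @return invisible list with the in-memory results of every stage.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  # --- simulate -------------------------------------------------------
  lib <- generate_barcode_library(cfg$library_size, length = cfg$cycles,
                                  rng_seed = cfg$seed)
  scene <- synthetic_scene(grid_shape = cfg$grid, tile_size = cfg$tile_size,
                           overlap_fraction = cfg$overlap,
                           n_cycles = cfg$cycles, jitter_sd = cfg$jitter_sd,
                           rng_seed = cfg$seed)
  sim <- generate_tile_set(scene, sequencing = list(
    n_cells = cfg$n_cells, library = lib, n_cycles = cfg$cycles,
    amplitude = cfg$amplitude, decay = cfg$decay, noise_sd = cfg$noise_sd,
    background_max = cfg$background_max,
    colonies_per_cell = cfg$colonies_per_cell))
  tiles_dir <- file.path(out, "tiles")
  write_tiles(sim$tiles, tiles_dir)
  write_library(lib, file.path(out, "library.tsv"))
  write_mask(sim$truth$sequencing$mask, file.path(out, "mask_latent.tif"))
  write_tsv_commented(sim$truth$positions,
                      file.path(out, "true_positions.tsv"),
                      list(seed = cfg$seed))

  # --- stitch ---------------------------------------------------------
  st <- stitch_tiles(sim$tiles, solver = cfg$solver,
                     integerize = cfg$integerize, merge = cfg$merge,
                     n_pairs = cfg$n_pairs, percentile = cfg$percentile,
                     seed = cfg$seed)
  write_constraints(st$graph, file.path(out, "constraints.tsv"))
  write_stitched(st$stitched, file.path(out, "stitched"), st$layout)

  # --- evaluate -------------------------------------------------------
  report <- evaluate_alignment(st$stitched, block = min(cfg$block,
                                                        cfg$tile_size[1]))
  write_alignment_report(report, out)

  # --- call reads -----------------------------------------------------
  sq <- stitched_sequencing(st$stitched, sim$truth, st$layout)
  rc <- call_reads(sq$stack, sq$mask, lib, k = cfg$k,
                   sigma_background = cfg$sigma_background,
                   blur_sigma = cfg$blur_sigma, min_sigma = cfg$min_sigma,
                   max_sigma = cfg$max_sigma, num_sigma = cfg$num_sigma,
                   threshold = cfg$log_threshold,
                   extract_stage = cfg$extract_stage,
                   max_distance = cfg$max_distance)
  col_out <- rc$colonies
  write_tsv_commented(col_out[, c("x", "y", "sigma", "cell", "read", "tie")],
                      file.path(out, "colonies.tsv"),
                      list(seed = cfg$seed, k = cfg$k))
  write_tsv_commented(rc$consensus, file.path(out, "consensus.tsv"),
                      list(seed = cfg$seed, k = cfg$k))
  write_tsv_commented(rc$cells, file.path(out, "cells.tsv"),
                      list(seed = cfg$seed))

  truth_bc <- sim$truth$sequencing$cell_barcodes
  matched <- rc$cells[rc$cells$status == "matched", ]
  correct <- merge(matched, truth_bc, by = "cell")
  summary <- list(
    n_tiles = length(sim$tiles$tiles), n_cycles = cfg$cycles,
    median_alignment_error_px = report$median_error,
    alignment_percentage = report$alignment_percentage,
    n_colonies = nrow(rc$colonies),
    n_cells_detected = length(unique(rc$consensus$cell)),
    n_cells_matched = nrow(matched),
    pct_cells_matched = 100 * nrow(matched) /
      max(1, nrow(truth_bc)),
    pct_matched_correct = if (nrow(correct) > 0)
      100 * mean(correct$barcode.x == correct$barcode.y) else NA)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, stitch = st, report = report, reads = rc,
                 summary = summary))
}
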