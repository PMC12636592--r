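# Shared fixture builders; everything is generated in code under fixed seeds.

# Small registration scene used by several test files.
small_scene <- function(grid = c(3, 3), tile = 128L, cycles = 2L,
                        jitter = 2, seed = 7L) {
  synthetic_scene(grid_shape = grid, tile_size = c(tile, tile),
                  overlap_fraction = 0.15, n_cycles = cycles,
                  jitter_sd = jitter, rng_seed = seed)
}

# True offset (of j relative to i) looked up from generator ground truth.
true_offset <- function(truth, i, j) {
  p <- truth$positions
  c(p$true_x[match(j, p$id)] - p$true_x[match(i, p$id)],
    p$true_y[match(j, p$id)] - p$true_y[match(i, p$id)])
}

# Position errors of a layout against generator ground truth, relative to
# the anchor tile.
layout_errors <- function(layout, truth) {
  p <- layout$positions
  tr <- truth$positions
  aidx <- match(layout$anchor, tr$id)
  cbind(p$x - (tr$true_x[match(p$tile_id, tr$id)] - tr$true_x[aidx]),
        p$y - (tr$true_y[match(p$tile_id, tr$id)] - tr$true_y[aidx]))
}

# Hand-built constraint graph for solver tests: edges is a data frame with
# i, j, dx, dy (refined offsets) and w.
toy_graph <- function(edges, n_nodes) {
  nodes <- data.frame(id = seq_len(n_nodes), cycle = 1L,
                      x = 0, y = 0, w = 100, h = 100)
  cons <- data.frame(
    i = edges$i, j = edges$j, cycle_i = 1L, cycle_j = 1L,
    dx = edges$dx, dy = edges$dy, dx_ref = edges$dx, dy_ref = edges$dy,
    score = edges$w, status = "measured", weight = edges$w,
    stringsAsFactors = FALSE)
  structure(list(constraints = cons, nodes = nodes, s_thresh = NULL,
                 null_sample = NULL), class = "constraint_graph")
}

# Exhaustive minimum of the weighted L1 objective over all integer position
# assignments (anchor = node 1 at 0) inside a box guaranteed to contain an
# optimum: an optimal solution sits at a spanning-tree vertex, so the box is
# the hull of all spanning-tree accumulated positions, padded by 1.
brute_force_l1 <- function(edges, n_nodes) {
  tree_positions <- function(sel) {
    pos <- rep(NA_real_, n_nodes); pos[1] <- 0
    repeat {
      done <- TRUE
      for (e in sel) {
        i <- edges$i[e]; j <- edges$j[e]
        if (!is.na(pos[i]) && is.na(pos[j])) { pos[j] <- pos[i] + edges$d[e]; done <- FALSE }
        if (is.na(pos[i]) && !is.na(pos[j])) { pos[i] <- pos[j] - edges$d[e]; done <- FALSE }
      }
      if (done) break
    }
    if (anyNA(pos)) NULL else pos
  }
  vertex_pos <- list()
  for (sel in utils::combn(nrow(edges), n_nodes - 1, simplify = FALSE)) {
    p <- tree_positions(sel)
    if (!is.null(p)) vertex_pos[[length(vertex_pos) + 1]] <- p
  }
  stopifnot(length(vertex_pos) > 0)
  vp <- do.call(rbind, vertex_pos)
  lo <- floor(apply(vp, 2, min)) - 1; hi <- ceiling(apply(vp, 2, max)) + 1
  grids <- lapply(2:n_nodes, function(k) seq(lo[k], hi[k]))
  g <- as.matrix(expand.grid(grids))
  pos <- cbind(0, g)
  obj <- 0
  for (e in seq_len(nrow(edges)))
    obj <- obj + edges$w[e] * abs(pos[, edges$j[e]] - pos[, edges$i[e]] - edges$d[e])
  min(obj)
}

# Minimal integer-stage layout for merge tests.
manual_layout <- function(ids, x, y, cycles = rep(1L, length(ids))) {
  structure(list(positions = data.frame(tile_id = ids, cycle = cycles,
                                        x = x, y = y),
                 anchor = ids[1], method = "mae", objective = 0,
                 edges = data.frame(i = integer(), j = integer(),
                                    dx = numeric(), dy = numeric(),
                                    w = numeric()),
                 stage = "integer"),
            class = "global_layout")
}

# Minimal single-channel tile collection from a list of matrices.
manual_tiles <- function(rasters, positions, cycles = rep(1L, length(rasters))) {
  tiles <- lapply(seq_along(rasters), function(k)
    list(id = k, cycle = cycles[k], raster = rasters[[k]], channels = NULL,
         nominal = positions[k, ], size = c(ncol(rasters[[k]]), nrow(rasters[[k]]))))
  tile_collection(tiles, n_cycles = max(cycles))
}

# Stitched-image wrapper around a list of per-cycle fiducial planes.
manual_stitched <- function(planes) {
  h <- nrow(planes[[1]]); w <- ncol(planes[[1]])
  data <- array(0, c(h, w, 1, length(planes)))
  for (t in seq_along(planes)) data[, , 1, t] <- planes[[t]]
  structure(list(data = data, count = array(1L, c(h, w, length(planes))),
                 origin = c(0, 0), fiducial_channel = 1L),
            class = "stitched_image")
}
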