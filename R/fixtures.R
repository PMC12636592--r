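#' Describe a synthetic multi-cycle tile scene
#'
#' A scene fixes the acquisition geometry emulated by [generate_tile_set()]:
#' a rectangular tile grid with fractional overlap, per-tile integer stage
#' jitter (intra-cycle error) and per-cycle rigid offsets (the plate being
#' removed and replaced between sequencing cycles).
#'
#' @param grid_shape integer `(rows, cols)` of the tile grid.
#' @param tile_size integer `(w, h)` tile dimensions in pixels.
#' @param overlap_fraction nominal overlap between adjacent tiles, in (0, 1).
#' @param n_cycles number of imaging cycles.
#' @param jitter_sd standard deviation (px) of the per-tile stage jitter;
#'   jitter is rounded to integers so ground truth stays on the pixel grid.
#' @param cycle_offsets optional `n_cycles x 2` matrix of per-cycle rigid
#'   offsets `(dx, dy)`; by default cycle 1 is `(0, 0)` and later cycles draw
#'   integer offsets uniformly from `[-8, 8]`.
#' @param rng_seed integer seed governing every random draw of the scene.
#' @return object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(grid_shape = c(3, 3), tile_size = c(256, 256),
                            overlap_fraction = 0.15, n_cycles = 3,
                            jitter_sd = 2, cycle_offsets = NULL,
                            rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape); tile_size <- as.integer(tile_size)
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1),
            length(tile_size) == 2, all(tile_size >= 8),
            overlap_fraction > 0, overlap_fraction < 1,
            n_cycles >= 1, jitter_sd >= 0)
  if (overlap_fraction * min(tile_size) <= 2 * jitter_sd)
    stop("overlap_fraction * min(tile_size) must exceed 2 * jitter_sd, ",
         "otherwise true overlaps may not survive the stage jitter")
  if (is.null(cycle_offsets)) {
    set.seed(rng_seed)
    cycle_offsets <- rbind(c(0L, 0L),
                           if (n_cycles > 1)
                             matrix(sample(-8:8, 2 * (n_cycles - 1),
                                           replace = TRUE),
                                    ncol = 2))
  }
  cycle_offsets <- matrix(as.numeric(cycle_offsets), ncol = 2)
  stopifnot(nrow(cycle_offsets) == n_cycles)
  structure(list(grid_shape = grid_shape, tile_size = tile_size,
                 overlap_fraction = overlap_fraction, n_cycles = n_cycles,
                 jitter_sd = jitter_sd, cycle_offsets = cycle_offsets,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_scene")
}

# Latent full-field fiducial texture: speckle (lightly smoothed white
# noise) rescaled to mean 100, sd 30 and clipped at zero. The ~1 px
# correlation length mirrors the fine nuclear/dot features that dominate
# real fiducial channels and keeps registration well-posed even for the
# small corner overlaps of diagonal tile pairs.
speckle_field <- function(h, w, rng_seed, smooth_sigma = 0.8, mean = 100,
                          sd = 30) {
  set.seed(rng_seed)
  f <- gaussian_blur(matrix(stats::rnorm(h * w), h, w), smooth_sigma)
  f <- (f - base::mean(f)) / stats::sd(f)
  pmax(mean + sd * f, 0)
}

#' Generate a synthetic tile set with exact ground truth
#'
#' Renders one latent full-field raster (per the scene's texture) and crops
#' every tile from it at its true position (nominal grid position + stage
#' jitter + cycle offset), so overlap content is exactly shared between
#' neighbours. Nominal positions are reported without jitter or cycle
#' offsets, emulating what the microscope stage would record.
#'
#' @param scene a [synthetic_scene()].
#' @param texture `"speckle"` (default), a function `(h, w, rng_seed)`
#'   returning a matrix, or a ready-made latent matrix at least as large as
#'   the scene requires.
#' @param sequencing optional list of arguments for
#'   [generate_sequencing_stack()] (e.g. `list(n_cells = 20, library = lib)`)
#'   rendered on the latent frame; tiles then carry 5 channels
#'   (G, T, A, C, fiducial) with `fiducial_channel = 5`.
#' @param keep_latent keep the latent field (and sequencing ground truth
#'   stack) in the returned object.
#' @return list with `tiles` (a [tile_collection()]) and `truth` (a list with
#'   per-tile true positions and, when `sequencing` is given, the colony and
#'   cell ground truth, mask and library).
#' @export
generate_tile_set <- function(scene, texture = "speckle", sequencing = NULL,
                              keep_latent = FALSE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  w <- scene$tile_size[1]; h <- scene$tile_size[2]
  nr <- scene$grid_shape[1]; nc <- scene$grid_shape[2]
  stride_x <- floor(w * (1 - scene$overlap_fraction))
  stride_y <- floor(h * (1 - scene$overlap_fraction))
  n_tiles <- nr * nc
  tcyc <- scene$n_cycles

  set.seed(scene$rng_seed + 1L)
  jit <- if (scene$jitter_sd > 0) {
    matrix(round(stats::rnorm(2L * n_tiles * tcyc, sd = scene$jitter_sd)),
           ncol = 2)
  } else matrix(0, n_tiles * tcyc, 2)

  info <- expand.grid(col = seq_len(nc), row = seq_len(nr),
                      cycle = seq_len(tcyc))
  info <- info[order(info$cycle, info$row, info$col), ]
  info$tile <- rep(seq_len(n_tiles), tcyc)
  info$id <- seq_len(nrow(info))
  info$nominal_x <- (info$col - 1) * stride_x
  info$nominal_y <- (info$row - 1) * stride_y
  info$true_x <- info$nominal_x + jit[, 1] + scene$cycle_offsets[info$cycle, 1]
  info$true_y <- info$nominal_y + jit[, 2] + scene$cycle_offsets[info$cycle, 2]

  x0 <- min(info$true_x); y0 <- min(info$true_y)
  fw <- max(info$true_x) - x0 + w
  fh <- max(info$true_y) - y0 + h

  field <- if (is.matrix(texture)) {
    texture
  } else if (is.function(texture)) {
    texture(fh, fw, scene$rng_seed + 2L)
  } else if (identical(texture, "speckle")) {
    speckle_field(fh, fw, scene$rng_seed + 2L)
  } else stop("unknown texture descriptor: ", texture)
  if (nrow(field) < fh || ncol(field) < fw)
    stop("latent texture smaller than the scene frame")
  if (stats::sd(field) < 1e-8)
    stop("degenerate (constant) texture: registration would be underdetermined")

  seq_truth <- NULL; seq_stack_latent <- NULL
  if (!is.null(sequencing)) {
    sim <- do.call(generate_sequencing_stack,
                   c(list(frame = c(fh, fw),
                          rng_seed = scene$rng_seed + 3L), sequencing))
    seq_stack_latent <- sim$stack
    seq_truth <- sim$truth
    seq_truth$mask <- sim$mask
    seq_truth$library <- sim$library
    # colony/cell coordinates are in latent-frame pixels; express them in the
    # ground-truth position frame (which has its origin at (x0, y0))
    seq_truth$colonies$x <- seq_truth$colonies$x + x0
    seq_truth$colonies$y <- seq_truth$colonies$y + y0
  }

  tiles <- vector("list", nrow(info))
  for (k in seq_len(nrow(info))) {
    ry <- (info$true_y[k] - y0) + seq_len(h)
    rx <- (info$true_x[k] - x0) + seq_len(w)
    fid <- field[ry, rx]
    channels <- NULL
    if (!is.null(seq_stack_latent)) {
      cyc <- info$cycle[k]
      channels <- array(0, c(h, w, 5L))
      channels[, , 1:4] <- seq_stack_latent[ry, rx, , cyc]
      channels[, , 5L] <- fid
    }
    tiles[[k]] <- list(id = info$id[k], cycle = info$cycle[k],
                       raster = fid, channels = channels,
                       nominal = c(info$nominal_x[k], info$nominal_y[k]),
                       size = c(w, h))
  }
  tc <- tile_collection(tiles, n_cycles = tcyc,
                        n_channels = if (is.null(seq_stack_latent)) 1L else 5L,
                        fiducial_channel = if (is.null(seq_stack_latent)) 1L
                                           else 5L)
  truth <- list(positions = info[, c("id", "tile", "cycle", "row", "col",
                                     "nominal_x", "nominal_y",
                                     "true_x", "true_y")],
                frame_origin = c(x0, y0),
                sequencing = seq_truth)
  out <- list(tiles = tc, truth = truth)
  if (keep_latent) {
    out$latent <- field
    out$latent_stack <- seq_stack_latent
  }
  out
}

#' Generate a label mask of non-overlapping disk-shaped cells
#'
#' @param n_cells number of cells to place (0 allowed).
#' @param frame `(height, width)` of the mask in pixels.
#' @param radius range `(min, max)` of cell radii in pixels.
#' @param rng_seed integer seed.
#' @param max_tries placement attempts before giving up.
#' @return integer matrix with 0 = background and labels `1..n_cells`;
#'   cell centres and radii attached as attribute `"cells"`.
#' @export
generate_cell_mask <- function(n_cells, frame, radius = c(8, 14),
                               rng_seed = 1L, max_tries = 2000L * max(n_cells, 1L)) {
  stopifnot(n_cells >= 0, length(frame) == 2)
  h <- frame[1]; w <- frame[2]
  mask <- matrix(0L, h, w)
  cells <- data.frame(cell = integer(), x = numeric(), y = numeric(),
                      r = numeric())
  if (n_cells == 0) {
    attr(mask, "cells") <- cells
    return(mask)
  }
  set.seed(rng_seed)
  tries <- 0L
  while (nrow(cells) < n_cells) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n_cells, " non-overlapping cells in a ",
           h, "x", w, " frame after ", max_tries, " tries")
    r <- if (radius[1] == radius[2]) radius[1] else
      sample(seq(radius[1], radius[2]), 1L)
    x <- sample(seq(r + 1, w - r - 1), 1L)
    y <- sample(seq(r + 1, h - r - 1), 1L)
    if (nrow(cells) > 0 &&
        any((cells$x - x)^2 + (cells$y - y)^2 <= (cells$r + r + 2)^2)) next
    lab <- nrow(cells) + 1L
    cells <- rbind(cells, data.frame(cell = lab, x = x, y = y, r = r))
    xs <- max(1, x - r):min(w, x + r)
    ys <- max(1, y - r):min(h, y + r)
    dd <- outer((ys - y)^2, (xs - x)^2, "+")
    blk <- mask[ys, xs, drop = FALSE]
    blk[dd <= r^2] <- lab
    mask[ys, xs] <- blk
  }
  attr(mask, "cells") <- cells
  mask
}

#' Generate a random barcode library
#'
#' @param n number of entries.
#' @param length barcode length (= number of sequencing cycles).
#' @param mode `"single"` for one barcode per entry, `"double"` for ordered
#'   barcode pairs.
#' @param rng_seed integer seed.
#' @return character vector of unique barcodes, or for `mode = "double"` a
#'   data frame with columns `bc1`, `bc2`.
#' @export
generate_barcode_library <- function(n, length = 12L, mode = c("single", "double"),
                                     rng_seed = 1L) {
  mode <- match.arg(mode)
  set.seed(rng_seed)
  draw <- function(k) {
    out <- character(0)
    while (base::length(out) < k) {
      cand <- vapply(seq_len(k - base::length(out)), function(i)
        paste(sample(c("G", "T", "A", "C"), length, replace = TRUE),
              collapse = ""), "")
      out <- unique(c(out, cand))
    }
    out
  }
  if (mode == "single") return(draw(n))
  data.frame(bc1 = draw(n), bc2 = draw(n), stringsAsFactors = FALSE)
}

# Default per-cycle additive background: linear ramp over cycles on the A and
# C channels only (channel order G, T, A, C), reaching `max_level` at the
# final cycle. Matches the phenomenology of fluorophore buildup that is
# strongest in those two channels.
background_ramp <- function(n_cycles, max_level, channels = c(3L, 4L)) {
  bg <- matrix(0, n_cycles, 4L)
  ramp <- if (n_cycles > 1) (seq_len(n_cycles) - 1) / (n_cycles - 1) else 0
  for (ch in channels) bg[, ch] <- ramp * max_level
  bg
}

render_sequencing_channels <- function(frame, colonies, n_cycles,
                                       colony_sigma, amplitude, decay,
                                       background, noise_sd, rng_seed) {
  h <- frame[1]; w <- frame[2]
  stack <- array(0, c(h, w, 4L, n_cycles))
  base_idx <- c(G = 1L, T = 2L, A = 3L, C = 4L)
  rad <- ceiling(4 * colony_sigma)
  for (t in seq_len(n_cycles)) {
    amp <- amplitude * decay^(t - 1)
    planes <- array(0, c(h, w, 4L))
    for (ch in 1:4) planes[, , ch] <- background[t, ch]
    if (nrow(colonies) > 0) {
      for (i in seq_len(nrow(colonies))) {
        ch <- base_idx[[substr(colonies$barcode[i], t, t)]]
        x0 <- colonies$x[i]; y0 <- colonies$y[i]
        xs <- max(0, x0 - rad):min(w - 1, x0 + rad)
        ys <- max(0, y0 - rad):min(h - 1, y0 + rad)
        dot <- amp * exp(-outer((ys - y0)^2, (xs - x0)^2, "+") /
                           (2 * colony_sigma^2))
        planes[ys + 1, xs + 1, ch] <- planes[ys + 1, xs + 1, ch] + dot
      }
    }
    stack[, , , t] <- planes
  }
  if (noise_sd > 0) {
    set.seed(rng_seed + 7L)
    stack <- stack + array(stats::rnorm(length(stack), sd = noise_sd),
                           dim(stack))
  }
  stack
}

#' Generate a synthetic sequencing stack with ground truth
#'
#' Renders amplicon colonies as Gaussian dots, bright in exactly one channel
#' per cycle according to each colony's barcode. Colony amplitude decays
#' multiplicatively over cycles; an additive background (by default a linear
#' ramp on the A and C channels) builds up over cycles; Gaussian noise is
#' added last. Cells are disk-shaped with a known label mask; every colony
#' lies inside a cell.
#'
#' @param n_cells number of cells (ignored when `mask` is supplied).
#' @param library a barcode library from [generate_barcode_library()] (single
#'   mode: character vector); cells draw barcodes from it with replacement.
#' @param n_cycles number of cycles; must equal the barcode length.
#' @param frame `(height, width)` in pixels.
#' @param colony_sigma Gaussian dot sigma in pixels.
#' @param amplitude peak dot intensity at cycle 1.
#' @param decay per-cycle multiplicative brightness factor; the peak at cycle
#'   t is `amplitude * decay^(t-1)`.
#' @param background `n_cycles x 4` additive background matrix, or `NULL` for
#'   the default A/C ramp reaching `background_max` at the final cycle.
#' @param background_max final-cycle background level of the default ramp.
#' @param noise_sd additive Gaussian noise sd.
#' @param colonies_per_cell mean colonies per cell (Poisson, minimum 1).
#' @param mask optional precomputed label mask (from [generate_cell_mask()]).
#' @param cell_radius radius range passed to [generate_cell_mask()].
#' @param rng_seed integer seed.
#' @return list with `stack` (a [seq_stack()] at stage `"raw"`), `mask`,
#'   `library` and `truth` (colony table and per-cell barcodes).
#' @export
generate_sequencing_stack <- function(n_cells, library, n_cycles = 12L,
                                      frame = c(512L, 512L),
                                      colony_sigma = 1.5, amplitude = 100,
                                      decay = 0.9, background = NULL,
                                      background_max = 0.3 * amplitude,
                                      noise_sd = 0.1 * amplitude,
                                      colonies_per_cell = 10,
                                      mask = NULL, cell_radius = c(8, 14),
                                      rng_seed = 1L) {
  lib <- if (is.data.frame(library)) library$bc1 else library
  if (any(nchar(lib) != n_cycles))
    stop("barcode length (", nchar(lib[1]), ") must equal n_cycles (",
         n_cycles, ")")
  if (is.null(mask))
    mask <- generate_cell_mask(n_cells, frame, radius = cell_radius,
                               rng_seed = rng_seed)
  cells <- attr(mask, "cells")
  set.seed(rng_seed + 3L)
  colonies <- data.frame(x = integer(), y = integer(), cell = integer(),
                         barcode_index = integer(), barcode = character())
  cell_barcodes <- data.frame(cell = integer(), barcode_index = integer(),
                              barcode = character())
  if (!is.null(cells) && nrow(cells) > 0) {
    bc_idx <- sample(seq_along(lib), nrow(cells), replace = TRUE)
    cell_barcodes <- data.frame(cell = cells$cell, barcode_index = bc_idx,
                                barcode = lib[bc_idx],
                                stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cells))) {
      n_col <- max(1L, stats::rpois(1L, colonies_per_cell))
      r_in <- max(cells$r[i] - 2, 1)
      placed <- 0L
      while (placed < n_col) {
        dx <- stats::runif(1, -r_in, r_in); dy <- stats::runif(1, -r_in, r_in)
        if (dx^2 + dy^2 > r_in^2) next
        x <- as.integer(round(cells$x[i] + dx)) - 1L
        y <- as.integer(round(cells$y[i] + dy)) - 1L
        if (mask[y + 1L, x + 1L] != cells$cell[i]) next
        colonies <- rbind(colonies,
                          data.frame(x = x, y = y, cell = cells$cell[i],
                                     barcode_index = bc_idx[i],
                                     barcode = lib[bc_idx[i]],
                                     stringsAsFactors = FALSE))
        placed <- placed + 1L
      }
    }
  }
  if (is.null(background))
    background <- background_ramp(n_cycles, background_max)
  stopifnot(nrow(background) == n_cycles, ncol(background) == 4L)
  data <- render_sequencing_channels(frame, colonies, n_cycles, colony_sigma,
                                     amplitude, decay, background, noise_sd,
                                     rng_seed)
  list(stack = seq_stack(data, stage = "raw"),
       mask = mask, library = library,
       truth = list(colonies = colonies, cell_barcodes = cell_barcodes,
                    background = background, amplitude = amplitude,
                    decay = decay))
}
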