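# TSV writers/readers with a `#` comment block recording provenance, so
# every table carries the parameters that produced it.

write_tsv_commented <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# issq ",
                    as.character(utils::packageVersion("issq"))), con)
  for (nm in names(params))
    writeLines(paste0("# ", nm, " = ",
                      paste(format(params[[nm]]), collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# r-tiff stores samples in [0, 1]; arbitrary intensities are written as
# 32-bit float after an affine map recorded in the accompanying manifest.
intensity_encoding <- function(x) {
  off <- min(0, min(x, na.rm = TRUE))
  sc <- max(x - off, na.rm = TRUE)
  if (!is.finite(sc) || sc == 0) sc <- 1
  list(offset = off, scale = sc)
}

write_plane_tiff <- function(planes, path, enc) {
  pages <- lapply(planes, function(p) {
    p[is.na(p)] <- enc$offset
    (p - enc$offset) / enc$scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

read_plane_tiff <- function(path, enc) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) p * enc$scale + enc$offset)
}

#' Write a tile collection to disk
#'
#' One multi-page TIFF per tile (pages = channels) plus a `positions.tsv`
#' sidecar (tile_id, cycle, x, y) and a JSON manifest with the collection
#' geometry and the intensity encoding.
#'
#' @param tc a [tile_collection()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tiles <- function(tc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  info <- tiles_info(tc)
  all_vals <- range(unlist(lapply(tc$tiles, function(t)
    range(if (is.null(t$channels)) t$raster else t$channels))))
  enc <- list(offset = min(0, all_vals[1]),
              scale = max(all_vals[2] - min(0, all_vals[1]), 1e-12))
  for (tl in tc$tiles) {
    planes <- if (is.null(tl$channels)) list(tl$raster) else
      lapply(seq_len(dim(tl$channels)[3]), function(c) tl$channels[, , c])
    write_plane_tiff(planes, file.path(dir, sprintf("tile_%04d.tif", tl$id)),
                     enc)
  }
  write_tsv_commented(info[, c("id", "cycle", "x", "y")],
                      file.path(dir, "positions.tsv"),
                      list(units = "px"))
  jsonlite::write_json(
    list(n_cycles = tc$n_cycles, n_channels = tc$n_channels,
         fiducial_channel = tc$fiducial_channel,
         intensity_offset = enc$offset, intensity_scale = enc$scale),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a tile collection from disk
#'
#' Counterpart of [write_tiles()]. Stage positions in the sidecar may be in
#' pixels (default), microns (`units = "um"`, converted with `um_per_px`) or
#' grid indices (`units = "grid"`, converted with the pixel stride).
#'
#' @param dir directory written by [write_tiles()].
#' @param positions optional path to an alternative positions sidecar.
#' @param units units of the sidecar x/y columns.
#' @param um_per_px pixel size in microns (for `units = "um"`).
#' @param grid_stride pixel stride between grid positions (for
#'   `units = "grid"`).
#' @return a [tile_collection()].
#' @export
read_tiles <- function(dir, positions = file.path(dir, "positions.tsv"),
                       units = c("px", "um", "grid"), um_per_px = NULL,
                       grid_stride = NULL) {
  units <- match.arg(units)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  pos <- read_tsv_commented(positions)
  if (anyDuplicated(pos$id)) stop("duplicate tile id in positions sidecar")
  if (units == "um") {
    if (is.null(um_per_px)) stop("um_per_px required for micron positions")
    pos$x <- pos$x / um_per_px; pos$y <- pos$y / um_per_px
  } else if (units == "grid") {
    if (is.null(grid_stride)) stop("grid_stride required for grid positions")
    pos$x <- pos$x * grid_stride; pos$y <- pos$y * grid_stride
  }
  enc <- list(offset = man$intensity_offset, scale = man$intensity_scale)
  tiles <- vector("list", nrow(pos))
  for (k in seq_len(nrow(pos))) {
    path <- file.path(dir, sprintf("tile_%04d.tif", pos$id[k]))
    if (!file.exists(path))
      stop("missing tile image for tile ", pos$id[k], " (cycle ",
           pos$cycle[k], "): ", path)
    planes <- read_plane_tiff(path, enc)
    if (length(planes) != man$n_channels)
      stop("tile ", pos$id[k], " has ", length(planes),
           " channels, expected ", man$n_channels)
    h <- nrow(planes[[1]]); w <- ncol(planes[[1]])
    channels <- NULL
    if (man$n_channels > 1) {
      channels <- array(0, c(h, w, man$n_channels))
      for (c in seq_along(planes)) channels[, , c] <- planes[[c]]
    }
    tiles[[k]] <- list(id = as.integer(pos$id[k]),
                       cycle = as.integer(pos$cycle[k]),
                       raster = planes[[man$fiducial_channel]],
                       channels = channels,
                       nominal = c(pos$x[k], pos$y[k]), size = c(w, h))
  }
  tile_collection(tiles, n_cycles = man$n_cycles,
                  n_channels = man$n_channels,
                  fiducial_channel = man$fiducial_channel)
}

#' Export the constraint table as TSV
#'
#' @param graph a [constraint graph][build_adjacency_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_constraints <- function(graph, path) {
  cons <- graph$constraints
  nm <- match(cons$i, graph$nodes$id)
  write_tsv_commented(
    data.frame(tile_i = cons$i, cycle_i = cons$cycle_i, tile_j = cons$j,
               cycle_j = cons$cycle_j, dx = cons$dx, dy = cons$dy,
               dx_refined = cons$dx_ref, dy_refined = cons$dy_ref,
               score = cons$score, status = cons$status,
               weight = cons$weight)[!is.na(nm) | TRUE, ],
    path, list(s_thresh = graph$s_thresh %||% NA))
}

#' Write a stitched image to disk
#'
#' One multi-page TIFF per cycle (pages = channels), a contributor-count
#' TIFF per cycle (empty pixels are written as zeros in the image pages and
#' have count 0), and a JSON manifest with frame origin, intensity encoding
#' and, when given, the solved per-tile integer positions and solver
#' metadata.
#'
#' @param stitched a [stitched_image][merge_tiles()].
#' @param dir output directory.
#' @param layout optional [global_layout][solve_positions()] recorded in the
#'   manifest.
#' @return `dir`, invisibly.
#' @export
write_stitched <- function(stitched, dir, layout = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stitched$data)
  enc <- intensity_encoding(stitched$data)
  for (t in seq_len(d[4])) {
    planes <- lapply(seq_len(d[3]), function(c) stitched$data[, , c, t])
    write_plane_tiff(planes, file.path(dir, sprintf("cycle_%02d.tif", t)),
                     enc)
    cnt <- stitched$count[, , t]
    tiff::writeTIFF(cnt / max(1, max(cnt)),
                    file.path(dir, sprintf("count_%02d.tif", t)),
                    bits.per.sample = 32)
  }
  man <- list(height = d[1], width = d[2], n_channels = d[3],
              n_cycles = d[4], origin = stitched$origin,
              fiducial_channel = stitched$fiducial_channel,
              count_scale = max(1, max(stitched$count)),
              intensity_offset = enc$offset, intensity_scale = enc$scale)
  if (!is.null(layout)) {
    man$solver <- list(method = layout$method,
                       int_method = layout$int_method %||% NA,
                       anchor = layout$anchor, objective = layout$objective)
    man$positions <- layout$positions
  }
  jsonlite::write_json(man, file.path(dir, "stitched.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a stitched image from disk
#'
#' @param dir directory written by [write_stitched()].
#' @return a [stitched_image][merge_tiles()].
#' @export
read_stitched <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "stitched.json"),
                             simplifyVector = TRUE)
  enc <- list(offset = man$intensity_offset, scale = man$intensity_scale)
  data <- array(0, c(man$height, man$width, man$n_channels, man$n_cycles))
  count <- array(0L, c(man$height, man$width, man$n_cycles))
  for (t in seq_len(man$n_cycles)) {
    planes <- read_plane_tiff(file.path(dir, sprintf("cycle_%02d.tif", t)),
                              enc)
    for (c in seq_len(man$n_channels)) data[, , c, t] <- planes[[c]]
    count[, , t] <- as.integer(round(
      tiff::readTIFF(file.path(dir, sprintf("count_%02d.tif", t))) *
        man$count_scale))
    empty <- count[, , t] == 0L
    if (any(empty)) for (c in seq_len(man$n_channels)) {
      blk <- data[, , c, t]; blk[empty] <- NA_real_; data[, , c, t] <- blk
    }
  }
  structure(list(data = data, count = count, origin = man$origin,
                 fiducial_channel = man$fiducial_channel),
            class = "stitched_image")
}

#' Read/write a barcode library TSV
#'
#' Single mode: one barcode per line (column `barcode`). Double mode: two
#' tab-separated columns `bc1`, `bc2`.
#'
#' @param library character vector or `bc1`/`bc2` data frame.
#' @param path file path.
#' @return [write_library()] returns `path` invisibly; [read_library()]
#'   returns the library.
#' @export
write_library <- function(library, path) {
  df <- if (is.data.frame(library)) library else data.frame(barcode = library)
  write_tsv_commented(df, path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  df <- read_tsv_commented(path)
  if (all(c("bc1", "bc2") %in% names(df))) return(df[, c("bc1", "bc2")])
  df[[1]]
}

#' Write/read a cell label mask TIFF
#'
#' Labels are stored as 16-bit values (supports up to 65535 cells).
#'
#' @param mask integer label matrix.
#' @param path file path.
#' @return [write_mask()] returns `path` invisibly; [read_mask()] the mask.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Export an alignment report
#'
#' Writes the per-block error table as TSV and the summary as JSON.
#'
#' @param report an [alignment_report][evaluate_alignment()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_alignment_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_commented(report$blocks, file.path(dir, "alignment_blocks.tsv"),
                      list(block_size = report$block_size))
  jsonlite::write_json(
    report[c("block_size", "median_error", "alignment_percentage",
             "alignment_percentage_all", "n_blocks", "n_excluded")],
    file.path(dir, "alignment_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
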