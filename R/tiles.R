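#' Tile collection
#'
#' Container for all cycles' tiles. Each tile is a list with fields `id`
#' (integer, unique across cycles), `cycle`, `raster` (the fiducial-channel
#' matrix used for registration), optional `channels` (H x W x C array of
#' all channels), `nominal` (`(x, y)` stage position in pixels, 0-based,
#' x = column) and `size` (`(w, h)`).
#'
#' @param tiles list of tiles as described above.
#' @param n_cycles number of cycles present.
#' @param n_channels channels per tile.
#' @param fiducial_channel index of the channel constant across cycles.
#' @return object of class `tile_collection`.
#' @export
tile_collection <- function(tiles, n_cycles, n_channels = 1L,
                            fiducial_channel = 1L) {
  if (length(tiles) == 0) stop("empty tile collection")
  ids <- vapply(tiles, `[[`, 0L, "id")
  if (anyDuplicated(ids)) stop("duplicate tile ids")
  cycles <- vapply(tiles, `[[`, 0L, "cycle")
  if (!all(seq_len(n_cycles) %in% cycles))
    stop("every cycle must have at least one tile; missing cycle ",
         paste(setdiff(seq_len(n_cycles), cycles), collapse = ", "))
  for (tl in tiles) {
    stopifnot(nrow(tl$raster) == tl$size[2], ncol(tl$raster) == tl$size[1])
  }
  structure(list(tiles = tiles, n_cycles = as.integer(n_cycles),
                 n_channels = as.integer(n_channels),
                 fiducial_channel = as.integer(fiducial_channel)),
            class = "tile_collection")
}

#' Summarize tiles as a data frame
#'
#' @param tc a [tile_collection()].
#' @return data frame with one row per tile (id, cycle, x, y, w, h).
#' @export
tiles_info <- function(tc) {
  data.frame(
    id = vapply(tc$tiles, `[[`, 0L, "id"),
    cycle = vapply(tc$tiles, `[[`, 0L, "cycle"),
    x = vapply(tc$tiles, function(t) t$nominal[1], 0),
    y = vapply(tc$tiles, function(t) t$nominal[2], 0),
    w = vapply(tc$tiles, function(t) t$size[1], 0),
    h = vapply(tc$tiles, function(t) t$size[2], 0))
}

#' @export
print.tile_collection <- function(x, ...) {
  cat("tile_collection:", length(x$tiles), "tiles,", x$n_cycles, "cycles,",
      x$n_channels, "channel(s), fiducial channel", x$fiducial_channel, "\n")
  invisible(x)
}

# Look up a tile by id.
get_tile <- function(tc, id) {
  ids <- vapply(tc$tiles, `[[`, 0L, "id")
  tc$tiles[[match(id, ids)]]
}
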