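# Edges usable for the global solve: refined offsets with positive weights.
solver_edges <- function(graph) {
  cons <- graph$constraints
  use <- cons$status %in% c("measured", "imputed")
  e <- cons[use, , drop = FALSE]
  if (any(is.na(e$weight))) {
    # weights default to the ZNCC score when imputation was not run
    e$weight <- pmax(ifelse(is.na(e$score), 0.05, e$score), 0.05)
  }
  e
}

# Connected components of the node set under the given edges (ids).
graph_components <- function(node_ids, edges) {
  comp <- stats::setNames(seq_along(node_ids), as.character(node_ids))
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- as.character(edges$i[k]); b <- as.character(edges$j[k])
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

# Weighted L1 (least absolute deviations) solve of A x = b via the exact
# Barrodale-Roberts simplex in quantreg (tau = 0.5 halves the objective but
# has the same argmin). Falls back to exact solve for square systems.
solve_l1 <- function(A, b) {
  if (nrow(A) == ncol(A)) {
    qrA <- qr(A)
    if (qrA$rank == ncol(A)) return(drop(qr.coef(qrA, b)))
  }
  fit <- suppressWarnings(quantreg::rq.fit.br(A, b, tau = 0.5))
  drop(fit$coefficients)
}

# Solve one axis of the global positioning problem for one connected
# component. edges: data frame with columns i, j, d (refined offset), w
# (weight); ids: node ids in the component; anchor: id fixed at 0.
solve_axis <- function(edges, ids, anchor, method) {
  pos <- stats::setNames(numeric(length(ids)), as.character(ids))
  free <- setdiff(ids, anchor)
  if (length(free) == 0) return(pos)
  if (method == "spanning_tree") stop("handled separately")
  A <- matrix(0, nrow(edges), length(free),
              dimnames = list(NULL, as.character(free)))
  b <- numeric(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    w <- edges$w[k]
    ic <- as.character(edges$i[k]); jc <- as.character(edges$j[k])
    if (jc %in% colnames(A)) A[k, jc] <- w
    if (ic %in% colnames(A)) A[k, ic] <- -w
    b[k] <- w * edges$d[k]
  }
  sol <- if (method == "mae") solve_l1(A, b) else qr.coef(qr(A), b)
  pos[as.character(free)] <- sol
  pos
}

# Maximum-score spanning tree (Kruskal; ties broken by the smaller (i, j)
# tile-id pair), then positions accumulated from the anchor.
spanning_tree_positions <- function(edges, ids, anchor) {
  ord <- order(-edges$w, edges$i, edges$j)
  parent <- stats::setNames(seq_along(ids), as.character(ids))
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  adj <- list()
  for (k in ord) {
    a <- as.character(edges$i[k]); b <- as.character(edges$j[k])
    ra <- find(match(a, names(parent))); rb <- find(match(b, names(parent)))
    if (ra == rb) next
    parent[ra] <- rb
    adj[[a]] <- rbind(adj[[a]], c(edges$j[k], edges$dx[k], edges$dy[k]))
    adj[[b]] <- rbind(adj[[b]], c(edges$i[k], -edges$dx[k], -edges$dy[k]))
  }
  posx <- stats::setNames(rep(NA_real_, length(ids)), as.character(ids))
  posy <- posx
  posx[as.character(anchor)] <- 0; posy[as.character(anchor)] <- 0
  queue <- as.character(anchor)
  while (length(queue) > 0) {
    a <- queue[1]; queue <- queue[-1]
    nb <- adj[[a]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      b <- as.character(nb[r, 1])
      if (!is.na(posx[b])) next
      posx[b] <- posx[a] + nb[r, 2]
      posy[b] <- posy[a] + nb[r, 3]
      queue <- c(queue, b)
    }
  }
  list(x = posx, y = posy)
}

# Weighted L1 objective of a set of positions against the solver edges.
layout_objective <- function(edges, px, py) {
  rx <- px[as.character(edges$j)] - px[as.character(edges$i)] - edges$dx
  ry <- py[as.character(edges$j)] - py[as.character(edges$i)] - edges$dy
  sum(edges$w * (abs(rx) + abs(ry)))
}

#' Solve global tile positions from the constraint graph
#'
#' Solves the overconstrained pairwise system `w_ij (p_j - p_i) = w_ij d_ij`
#' for all tiles jointly. The default minimizes the weighted sum of absolute
#' residuals (the least-absolute-error criterion, robust to residual bad
#' constraints); `"mse"` solves the same weighted rows by least squares;
#' `"spanning_tree"` accumulates offsets along the maximum-score spanning
#' tree. The anchor tile is fixed at exactly (0, 0); if the graph has several
#' connected components each is solved separately (with a warning), anchored
#' at its first tile's nominal offset.
#'
#' @param graph a [constraint graph][impute_constraints()] with refined
#'   offsets and weights.
#' @param method `"mae"`, `"mse"` or `"spanning_tree"`.
#' @param anchor tile id to pin at (0, 0); default the first tile of the
#'   first cycle.
#' @return object of class `global_layout`: data frame `positions` (tile_id,
#'   cycle, x, y) plus `anchor`, `method` and `objective` (the weighted L1
#'   objective of the returned positions).
#' @export
solve_positions <- function(graph, method = c("mae", "mse", "spanning_tree"),
                            anchor = NULL) {
  method <- match.arg(method)
  edges <- solver_edges(graph)
  if (nrow(edges) == 0) stop("no usable constraints")
  nodes <- graph$nodes
  if (is.null(anchor))
    anchor <- nodes$id[nodes$cycle == min(nodes$cycle)][1]
  comp <- graph_components(nodes$id, edges)
  if (max(comp) > 1)
    warning("constraint graph has ", max(comp),
            " connected components; solving each separately")
  e <- data.frame(i = edges$i, j = edges$j, dx = edges$dx_ref,
                  dy = edges$dy_ref, w = edges$weight)
  px <- stats::setNames(rep(NA_real_, nrow(nodes)), as.character(nodes$id))
  py <- px
  for (cidx in seq_len(max(comp))) {
    ids <- nodes$id[comp == cidx]
    ce <- e[e$i %in% ids & e$j %in% ids, , drop = FALSE]
    canchor <- if (anchor %in% ids) anchor else ids[1]
    if (method == "spanning_tree") {
      st <- spanning_tree_positions(ce, ids, canchor)
      cx <- st$x; cy <- st$y
    } else {
      cx <- solve_axis(data.frame(i = ce$i, j = ce$j, d = ce$dx, w = ce$w),
                       ids, canchor, method)
      cy <- solve_axis(data.frame(i = ce$i, j = ce$j, d = ce$dy, w = ce$w),
                       ids, canchor, method)
    }
    if (!(anchor %in% ids)) {
      # secondary component: keep its rough nominal placement
      off <- nodes[match(canchor, nodes$id), c("x", "y")]
      cx <- cx + off$x; cy <- cy + off$y
    }
    px[as.character(ids)] <- cx[as.character(ids)]
    py[as.character(ids)] <- cy[as.character(ids)]
  }
  positions <- data.frame(tile_id = nodes$id, cycle = nodes$cycle,
                          x = as.numeric(px), y = as.numeric(py))
  structure(list(positions = positions, anchor = anchor, method = method,
                 objective = layout_objective(e, px, py),
                 edges = e, stage = "float"),
            class = "global_layout")
}

#' @export
print.global_layout <- function(x, ...) {
  cat("global_layout (", x$stage, "): ", nrow(x$positions), " tiles, method ",
      x$method, ", anchor ", x$anchor, ", objective ",
      signif(x$objective, 6), "\n", sep = "")
  invisible(x)
}

# Optimal integer for one coordinate given all others fixed: the 1-D
# objective sum w |x - target| is piecewise-linear convex, so the best
# integer is the floor or ceiling of the weighted median of targets.
best_integer_coord <- function(targets, weights) {
  o <- order(targets)
  targets <- targets[o]; weights <- weights[o]
  cum <- cumsum(weights)
  med <- targets[which(cum >= sum(weights) / 2)[1]]
  cand <- unique(c(floor(med), ceiling(med)))
  val <- vapply(cand, function(x) sum(weights * abs(x - targets)), 0)
  cand[which.min(val)]
}

#' Integerize a solved layout
#'
#' Tile positions must be integers before merging. `"round"` rounds each
#' coordinate to the nearest integer (re-anchored so the anchor stays at
#' exactly (0, 0)). `"ilp"` additionally refines the rounded solution by
#' exact per-coordinate integer descent on the weighted L1 objective (each
#' coordinate's conditional optimum is the floor/ceiling of a weighted
#' median), iterated to convergence; its objective is therefore never worse
#' than rounding.
#'
#' @param layout a float-stage [global_layout][solve_positions()].
#' @param method `"round"` or `"ilp"`.
#' @param max_passes maximum descent sweeps for `"ilp"`.
#' @param time_limit seconds allowed for the integer refinement before
#'   falling back to the rounded solution with a warning.
#' @return the layout with integer `x`, `y`, stage `"integer"`, and
#'   `objective` recomputed at the integer positions.
#' @export
integerize_positions <- function(layout, method = c("round", "ilp"),
                                 max_passes = 100L, time_limit = 300) {
  method <- match.arg(method)
  stopifnot(inherits(layout, "global_layout"))
  pos <- layout$positions
  aidx <- match(layout$anchor, pos$tile_id)
  px <- round(pos$x - pos$x[aidx])
  py <- round(pos$y - pos$y[aidx])
  names(px) <- names(py) <- as.character(pos$tile_id)
  e <- layout$edges
  if (method == "ilp" && nrow(e) > 0) {
    t0 <- Sys.time()
    px0 <- px; py0 <- py
    timed_out <- FALSE
    for (pass in seq_len(max_passes)) {
      changed <- FALSE
      for (idn in names(px)) {
        if (idn == as.character(layout$anchor)) next
        if (as.numeric(difftime(Sys.time(), t0, units = "secs")) >
            time_limit) { timed_out <- TRUE; break }
        as_i <- e$i == as.integer(idn); as_j <- e$j == as.integer(idn)
        tx <- c(px[as.character(e$j[as_i])] - e$dx[as_i],
                px[as.character(e$i[as_j])] + e$dx[as_j])
        ty <- c(py[as.character(e$j[as_i])] - e$dy[as_i],
                py[as.character(e$i[as_j])] + e$dy[as_j])
        wgt <- c(e$w[as_i], e$w[as_j])
        if (length(wgt) == 0) next
        nx <- best_integer_coord(tx, wgt)
        ny <- best_integer_coord(ty, wgt)
        if (nx != px[idn] || ny != py[idn]) {
          px[idn] <- nx; py[idn] <- ny; changed <- TRUE
        }
      }
      if (timed_out || !changed) break
    }
    if (timed_out) {
      warning("integer refinement hit the time limit; falling back to ",
              "rounded positions")
      px <- px0; py <- py0
    }
  }
  pos$x <- as.numeric(px); pos$y <- as.numeric(py)
  layout$positions <- pos
  layout$stage <- "integer"
  layout$int_method <- method
  layout$objective <- layout_objective(e, px, py)
  layout
}

#' Merge tiles into per-cycle stitched rasters
#'
#' Places every tile at its integer position in one common coordinate frame
#' shared by all cycles and merges overlapping areas either by the per-pixel
#' mean of all contributing tiles or by taking the value from the tile whose
#' centre is nearest the pixel. Pixels no tile covers are `NA` (tracked by a
#' per-cycle contributor-count array).
#'
#' @param tc the [tile_collection()].
#' @param layout an integer-stage [global_layout][integerize_positions()].
#' @param mode `"mean"` or `"nearest_center"`.
#' @return object of class `stitched_image`: list with `data`
#'   (H x W x channels x cycles array, `NA` where empty), `count`
#'   (H x W x cycles contributor counts), `origin` (`(x, y)` of pixel (1, 1)
#'   in layout coordinates) and `fiducial_channel`.
#' @export
merge_tiles <- function(tc, layout, mode = c("mean", "nearest_center")) {
  mode <- match.arg(mode)
  stopifnot(layout$stage == "integer")
  pos <- layout$positions
  info <- tiles_info(tc)
  m <- match(info$id, pos$tile_id)
  x <- pos$x[m]; y <- pos$y[m]
  x0 <- min(x); y0 <- min(y)
  W <- as.integer(max(x + info$w) - x0)
  H <- as.integer(max(y + info$h) - y0)
  nch <- tc$n_channels; ncy <- tc$n_cycles
  data <- array(0, c(H, W, nch, ncy))
  count <- array(0L, c(H, W, ncy))
  bestd <- if (mode == "nearest_center") array(Inf, c(H, W, ncy)) else NULL
  for (k in seq_along(tc$tiles)) {
    tl <- tc$tiles[[k]]
    cyc <- tl$cycle
    rx <- (x[k] - x0) + seq_len(info$w[k])   # columns in frame
    ry <- (y[k] - y0) + seq_len(info$h[k])
    ch <- if (is.null(tl$channels)) {
      array(tl$raster, c(info$h[k], info$w[k], 1L))
    } else tl$channels
    if (mode == "mean") {
      for (c in seq_len(nch))
        data[ry, rx, c, cyc] <- data[ry, rx, c, cyc] + ch[, , c]
      count[ry, rx, cyc] <- count[ry, rx, cyc] + 1L
    } else {
      cx <- (x[k] - x0) + (info$w[k] - 1) / 2   # 0-based centre column
      cy <- (y[k] - y0) + (info$h[k] - 1) / 2
      dd <- outer(((ry - 1) - cy)^2, ((rx - 1) - cx)^2, "+")
      cur <- bestd[ry, rx, cyc]
      take <- dd < cur
      if (any(take)) {
        for (c in seq_len(nch)) {
          blk <- data[ry, rx, c, cyc]
          src <- ch[, , c]
          blk[take] <- src[take]
          data[ry, rx, c, cyc] <- blk
        }
        cur[take] <- dd[take]
        bestd[ry, rx, cyc] <- cur
      }
      count[ry, rx, cyc] <- count[ry, rx, cyc] + 1L
    }
  }
  if (mode == "mean") {
    for (cyc in seq_len(ncy)) {
      cnt <- count[, , cyc]
      cnt[cnt == 0L] <- NA_integer_
      for (c in seq_len(nch))
        data[, , c, cyc] <- data[, , c, cyc] / cnt
    }
  } else {
    for (cyc in seq_len(ncy)) {
      empty <- count[, , cyc] == 0L
      if (any(empty))
        for (c in seq_len(nch)) {
          blk <- data[, , c, cyc]; blk[empty] <- NA_real_
          data[, , c, cyc] <- blk
        }
    }
  }
  structure(list(data = data, count = count, origin = c(x0, y0),
                 fiducial_channel = tc$fiducial_channel),
            class = "stitched_image")
}

#' @export
print.stitched_image <- function(x, ...) {
  d <- dim(x$data)
  cat("stitched_image:", d[1], "x", d[2], "px,", d[3], "channel(s),",
      d[4], "cycle(s), origin (", x$origin[1], ",", x$origin[2], ")\n")
  invisible(x)
}
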