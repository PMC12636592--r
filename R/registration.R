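#' Build the overlap constraint graph
#'
#' One constraint is created for every unordered tile pair -- within a cycle
#' or across cycles alike -- whose nominal positions satisfy the overlap
#' inequality `-wj <= dx <= wi` and `-hj <= dy <= hi`, where
#' `dx = xj - xi`, `dy = yj - yi`. Initial offsets are those nominal
#' differences.
#'
#' @param tc a [tile_collection()].
#' @return object of class `constraint_graph`: a list with `constraints`
#'   (data frame: i, j, cycle_i, cycle_j, dx, dy, dx_ref, dy_ref, score,
#'   status, weight), `nodes` (the [tiles_info()] table), `s_thresh` and
#'   `null_sample` (both `NULL` until [estimate_score_threshold()] /
#'   [filter_constraints()] run).
#' @export
build_adjacency_graph <- function(tc) {
  info <- tiles_info(tc)
  n <- nrow(info)
  if (n < 1) stop("empty tile collection")
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  a <- pairs[, 1]; b <- pairs[, 2]
  dx <- info$x[b] - info$x[a]
  dy <- info$y[b] - info$y[a]
  keep <- dx >= -info$w[b] & dx <= info$w[a] &
          dy >= -info$h[b] & dy <= info$h[a]
  nk <- sum(keep)
  cons <- data.frame(
    i = info$id[a[keep]], j = info$id[b[keep]],
    cycle_i = info$cycle[a[keep]], cycle_j = info$cycle[b[keep]],
    dx = dx[keep], dy = dy[keep],
    dx_ref = rep(NA_real_, nk), dy_ref = rep(NA_real_, nk),
    score = rep(NA_real_, nk), status = rep("unmeasured", nk),
    weight = rep(NA_real_, nk), stringsAsFactors = FALSE)
  structure(list(constraints = cons, nodes = info, s_thresh = NULL,
                 null_sample = NULL),
            class = "constraint_graph")
}

#' @export
print.constraint_graph <- function(x, ...) {
  cat("constraint_graph:", nrow(x$nodes), "tiles,", nrow(x$constraints),
      "constraints")
  if (nrow(x$constraints) > 0)
    cat(" (", paste(names(table(x$constraints$status)),
                    table(x$constraints$status),
                    sep = ": ", collapse = ", "), ")", sep = "")
  if (!is.null(x$s_thresh)) cat("; s_thresh =", signif(x$s_thresh, 4))
  cat("\n")
  invisible(x)
}

# Nearest-rank percentile: the smallest element with at least p% of the
# sample at or below it. No interpolation, so the threshold is always an
# observed score.
nearest_rank_percentile <- function(x, percentile) {
  sorted <- sort(x)
  sorted[max(1L, ceiling(percentile / 100 * length(sorted)))]
}

# Cached FFTs of every tile's fiducial raster, padded to the common size.
tile_ffts <- function(tc) {
  info <- tiles_info(tc)
  h <- max(info$h); w <- max(info$w)
  ffts <- vector("list", length(tc$tiles))
  for (k in seq_along(tc$tiles)) {
    m <- tc$tiles[[k]]$raster
    m <- m - mean(m)
    if (nrow(m) != h || ncol(m) != w) {
      p <- matrix(0, h, w); p[seq_len(nrow(m)), seq_len(ncol(m))] <- m
      m <- p
    }
    ffts[[k]] <- stats::fft(m)
  }
  names(ffts) <- as.character(info$id)
  ffts
}

#' Refine every constraint by phase cross-correlation
#'
#' Runs [phase_align()] for each constraint in the graph, reusing one cached
#' FFT per tile. Refined offsets and ZNCC scores are stored on the graph;
#' constraints whose eight candidates were all degenerate get score -1.
#'
#' @param graph a [build_adjacency_graph()] result.
#' @param tc the [tile_collection()] the graph was built from.
#' @param normalize passed to [phase_align()].
#' @return the graph with `dx_ref`, `dy_ref`, `score` filled in and status
#'   `"measured"`.
#' @export
refine_constraints <- function(graph, tc, normalize = FALSE) {
  ffts <- tile_ffts(tc)
  ids <- vapply(tc$tiles, `[[`, 0L, "id")
  cons <- graph$constraints
  for (k in seq_len(nrow(cons))) {
    ti <- tc$tiles[[match(cons$i[k], ids)]]
    tj <- tc$tiles[[match(cons$j[k], ids)]]
    r <- phase_align(ti$raster, tj$raster,
                     fa = ffts[[as.character(cons$i[k])]],
                     fb = ffts[[as.character(cons$j[k])]],
                     normalize = normalize)
    cons$dx_ref[k] <- r$dx
    cons$dy_ref[k] <- r$dy
    cons$score[k] <- r$score
    cons$status[k] <- "measured"
  }
  graph$constraints <- cons
  graph
}

#' Estimate the ZNCC score threshold from non-overlapping pairs
#'
#' Samples pairs of tiles that are far apart (both `|dx|` and `|dy|`
#' exceeding twice the maximum tile dimension), aligns each with
#' [phase_align()], and takes the given nearest-rank percentile of the
#' resulting scores as the null threshold. If too few pairs satisfy the
#' strict distance criterion, the most separated non-overlapping pairs are
#' used instead, with a warning.
#'
#' @param tc a [tile_collection()].
#' @param n_pairs number of null pairs to sample.
#' @param percentile percentile (nearest-rank) of the null scores.
#' @param rng_seed seed for the pair sampling.
#' @param normalize passed to [phase_align()].
#' @return the score threshold, with the sampled pairs and their scores
#'   attached as attribute `"null_sample"`.
#' @export
estimate_score_threshold <- function(tc, n_pairs = 100L, percentile = 95,
                                     rng_seed = 1L, normalize = FALSE) {
  info <- tiles_info(tc)
  n <- nrow(info)
  if (n < 2) stop("need at least 2 tiles to estimate a score threshold")
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  a <- pairs[, 1]; b <- pairs[, 2]
  dx <- abs(info$x[b] - info$x[a]); dy <- abs(info$y[b] - info$y[a])
  maxw <- pmax(info$w[a], info$w[b]); maxh <- pmax(info$h[a], info$h[b])
  strict <- dx > 2 * maxw & dy > 2 * maxh
  nonoverlap <- !(info$x[b] - info$x[a] >= -info$w[b] &
                  info$x[b] - info$x[a] <= info$w[a] &
                  info$y[b] - info$y[a] >= -info$h[b] &
                  info$y[b] - info$y[a] <= info$h[a])
  set.seed(rng_seed)
  if (sum(strict) >= n_pairs) {
    pick <- sample(which(strict), n_pairs)
  } else {
    pick <- which(strict)
    pool <- setdiff(which(nonoverlap), pick)
    if (length(pool) + length(pick) == 0) {
      # tiny layouts (e.g. 2x2 grids) can have every pair overlapping; with
      # no null to sample, no constraint can be declared unreliable
      warning("no non-overlapping tile pairs available for the null ",
              "sample; returning threshold -1 (no filtering)")
      return(structure(-1, null_sample = data.frame(i = integer(),
                                                    j = integer(),
                                                    score = numeric())))
    }
    need <- min(n_pairs - length(pick), length(pool))
    if (need > 0) {
      # most separated first, so the relaxed sample stays as null-like as
      # possible
      pool <- pool[order(pmin(dx[pool] / maxw[pool], dy[pool] / maxh[pool]),
                         decreasing = TRUE)]
      pick <- c(pick, pool[seq_len(need)])
    }
    warning("only ", sum(strict), " tile pairs satisfy the strict distance ",
            "criterion; relaxed to the ", length(pick),
            " most separated non-overlapping pairs")
  }
  scores <- numeric(length(pick))
  for (k in seq_along(pick)) {
    ta <- tc$tiles[[a[pick[k]]]]; tb <- tc$tiles[[b[pick[k]]]]
    scores[k] <- phase_align(ta$raster, tb$raster, normalize = normalize)$score
  }
  ns <- data.frame(i = info$id[a[pick]], j = info$id[b[pick]], score = scores)
  structure(nearest_rank_percentile(scores, percentile), null_sample = ns)
}

#' Filter constraints below the score threshold
#'
#' @param graph a scored [constraint graph][refine_constraints()].
#' @param s_thresh score threshold, typically from
#'   [estimate_score_threshold()].
#' @return the graph with sub-threshold constraints demoted to status
#'   `"filtered"` and `s_thresh` recorded.
#' @export
filter_constraints <- function(graph, s_thresh) {
  cons <- graph$constraints
  if (any(cons$status == "unmeasured"))
    stop("all constraints must be scored before filtering")
  low <- cons$score < s_thresh
  cons$status[low] <- "filtered"
  if (!any(!low))
    stop("every constraint fell below the score threshold; graph unsolvable")
  graph$constraints <- cons
  graph$s_thresh <- as.numeric(s_thresh)
  graph$null_sample <- attr(s_thresh, "null_sample")
  graph
}

#' Fit a robust linear stage model
#'
#' Fits the affine map from initial (nominal) offsets to refined offsets,
#' `[dx', dy'] = M [dx, dy] + b`, on the measured, score-passing constraints
#' using a seeded RANSAC (minimal samples of 3, least-squares refit on the
#' consensus set). The recovered map captures stage parameters such as the
#' effective travel between tiles. Constraints whose residual exceeds
#' `inlier_threshold` are recorded as outliers for demotion during
#' imputation.
#'
#' @param graph a filtered [constraint graph][filter_constraints()].
#' @param inlier_threshold residual norm (px) below which a constraint is an
#'   inlier. The default is deliberately generous: true constraints deviate
#'   from any single global affine map by the per-tile stage jitter and the
#'   per-cycle-pair rigid offsets, and only catastrophically wrong
#'   refinements should be demoted (a demoted constraint is replaced by the
#'   model prediction, which cannot represent inter-cycle offsets).
#' @param n_iter RANSAC iterations.
#' @param rng_seed seed for the RANSAC sampling.
#' @return object of class `stage_model` with `coef` (3 x 2 matrix:
#'   intercept row then the 2 x 2 linear map), `inliers`, and `outlier_rows`
#'   (row indices into the graph's constraint table).
#' @export
fit_stage_model <- function(graph, inlier_threshold = 30, n_iter = 500L,
                            rng_seed = 1L) {
  cons <- graph$constraints
  rows <- which(cons$status == "measured")
  X <- cbind(1, cons$dx[rows], cons$dy[rows])
  Y <- cbind(cons$dx_ref[rows], cons$dy_ref[rows])
  identity_model <- function(msg) {
    warning("stage model fallback to identity: ", msg)
    structure(list(coef = rbind(c(0, 0), diag(2)),
                   inliers = rows, outlier_rows = integer(0),
                   fallback = TRUE),
              class = "stage_model")
  }
  if (length(rows) < 3) return(identity_model("fewer than 3 constraints"))
  if (qr(X)$rank < 3) return(identity_model("rank-deficient design"))
  set.seed(rng_seed)
  best_in <- NULL; best_err <- Inf
  for (it in seq_len(n_iter)) {
    s <- sample(length(rows), 3L)
    A <- X[s, , drop = FALSE]
    if (abs(det(A)) < 1e-9) next
    B <- solve(A, Y[s, , drop = FALSE])
    res <- sqrt(rowSums((Y - X %*% B)^2))
    inl <- res < inlier_threshold
    err <- sum(res[inl])
    if (sum(inl) > length(best_in %||% integer(0)) ||
        (sum(inl) == length(best_in %||% integer(0)) && err < best_err)) {
      best_in <- which(inl); best_err <- err
    }
  }
  if (is.null(best_in) || length(best_in) < 3)
    return(identity_model("no consensus set found"))
  B <- qr.coef(qr(X[best_in, , drop = FALSE]), Y[best_in, , drop = FALSE])
  res <- sqrt(rowSums((Y - X %*% B)^2))
  inl <- res < inlier_threshold
  structure(list(coef = B, inliers = rows[inl],
                 outlier_rows = rows[!inl], fallback = FALSE),
            class = "stage_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict refined offsets from a stage model
#'
#' @param object a [stage_model][fit_stage_model()].
#' @param offsets two-column matrix (or length-2 vector) of initial offsets.
#' @param ... unused.
#' @return two-column matrix of predicted refined offsets.
#' @export
predict.stage_model <- function(object, offsets, ...) {
  if (is.null(dim(offsets))) offsets <- matrix(offsets, ncol = 2)
  cbind(1, offsets) %*% object$coef
}

#' Impute filtered constraints from the stage model
#'
#' Constraints demoted by the score filter (and the stage model's residual
#' outliers) receive the model-predicted refined offset, status `"imputed"`,
#' and a floor weight `max(s_thresh, 0.05)`, so repaired edges keep the
#' graph connected without dominating measured ones. Measured constraints
#' get weight equal to their ZNCC score (floored at 0.05 to keep all LP
#' weights positive). The edge set is never changed.
#'
#' @param graph a filtered [constraint graph][filter_constraints()].
#' @param model a [stage_model][fit_stage_model()].
#' @param floor_weight weight assigned to imputed edges.
#' @return the graph with refined offsets, statuses and weights finalized.
#' @export
impute_constraints <- function(graph, model,
                               floor_weight = max(graph$s_thresh %||% 0.05,
                                                  0.05)) {
  cons <- graph$constraints
  cons$status[model$outlier_rows] <- "filtered"
  fix <- which(cons$status == "filtered")
  if (length(fix) > 0) {
    pred <- predict(model, cbind(cons$dx[fix], cons$dy[fix]))
    cons$dx_ref[fix] <- pred[, 1]
    cons$dy_ref[fix] <- pred[, 2]
    cons$status[fix] <- "imputed"
    cons$weight[fix] <- floor_weight
  }
  meas <- cons$status == "measured"
  cons$weight[meas] <- pmax(cons$score[meas], 0.05)
  graph$constraints <- cons
  graph
}
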