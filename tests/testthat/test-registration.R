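test_that("adjacency graph contains exactly the overlapping pairs", {
  # single tile: no constraints
  one <- manual_tiles(list(matrix(rnorm(100), 10, 10)),
                      matrix(c(0, 0), 1, 2))
  expect_equal(nrow(build_adjacency_graph(one)$constraints), 0)

  # 2x2 grid of 100 px tiles at 10% overlap: 4 side pairs + 2 diagonal pairs
  sc <- synthetic_scene(grid_shape = c(2, 2), tile_size = c(100, 100),
                        overlap_fraction = 0.1, n_cycles = 1, jitter_sd = 0,
                        rng_seed = 1)
  sim <- generate_tile_set(sc)
  g <- build_adjacency_graph(sim$tiles)
  expect_equal(nrow(g$constraints), 6)
  # oracle: enumerate all pairs and apply the overlap inequality directly
  info <- tiles_info(sim$tiles)
  n_expected <- 0
  for (a in 1:3) for (b in (a + 1):4) {
    dx <- info$x[b] - info$x[a]; dy <- info$y[b] - info$y[a]
    if (dx >= -100 && dx <= 100 && dy >= -100 && dy <= 100)
      n_expected <- n_expected + 1
  }
  expect_equal(nrow(g$constraints), n_expected)

  # same position in two cycles: one inter-cycle constraint at offset (0,0)
  r <- matrix(rnorm(64), 8, 8)
  two <- manual_tiles(list(r, r), matrix(0, 2, 2), cycles = c(1L, 2L))
  g2 <- build_adjacency_graph(two)
  expect_equal(nrow(g2$constraints), 1)
  expect_equal(c(g2$constraints$dx, g2$constraints$dy), c(0, 0))
  expect_equal(c(g2$constraints$cycle_i, g2$constraints$cycle_j), c(1, 2))
})

test_that("constraint refinement recovers ground-truth offsets exactly", {
  sc <- small_scene(seed = 13)
  sim <- generate_tile_set(sc)
  g <- refine_constraints(build_adjacency_graph(sim$tiles), sim$tiles)
  cons <- g$constraints
  info <- tiles_info(sim$tiles)
  for (k in seq_len(nrow(cons))) {
    tru <- true_offset(sim$truth, cons$i[k], cons$j[k])
    # exactness is expected wherever the true overlap carries substantial
    # signal (here >= 2000 px of shared speckle); smaller slivers are the
    # score filter's job
    ov <- prod(pmax(0, 128 - abs(tru)))
    if (ov >= 2000) {
      expect_equal(c(cons$dx_ref[k], cons$dy_ref[k]), tru,
                   info = paste("constraint", cons$i[k], "-", cons$j[k]))
      expect_equal(cons$score[k], 1.0, tolerance = 1e-10)
    }
  }
})

test_that("nearest-rank percentile follows the stated rule", {
  expect_equal(issq:::nearest_rank_percentile(rep(0.42, 100), 95), 0.42)
  expect_equal(issq:::nearest_rank_percentile(0.01 * (1:100), 95), 0.95)
  expect_equal(issq:::nearest_rank_percentile(c(0.3, 0.1, 0.2), 50), 0.2)
})

test_that("score threshold sits below true-overlap scores on a clean scene", {
  sc <- small_scene(seed = 21)
  sim <- generate_tile_set(sc)
  g <- refine_constraints(build_adjacency_graph(sim$tiles), sim$tiles)
  s_thresh <- suppressWarnings(
    estimate_score_threshold(sim$tiles, n_pairs = 40, rng_seed = 21))
  cons <- g$constraints
  info <- tiles_info(sim$tiles)
  substantial <- vapply(seq_len(nrow(cons)), function(k) {
    tru <- true_offset(sim$truth, cons$i[k], cons$j[k])
    prod(pmax(0, 128 - abs(tru))) >= 2000
  }, TRUE)
  expect_lt(s_thresh, min(cons$score[substantial]))
  expect_error(estimate_score_threshold(
    manual_tiles(list(matrix(rnorm(64), 8, 8)), matrix(0, 1, 2))),
    "at least 2 tiles")
})

test_that("filtering demotes exactly the sub-threshold constraints", {
  g <- toy_graph(data.frame(i = c(1, 2), j = c(2, 3), dx = c(10, 10),
                            dy = c(0, 0), w = c(0.9, 0.2)), 3)
  f <- filter_constraints(g, 0.5)
  expect_equal(f$constraints$status, c("measured", "filtered"))
  # threshold -1: nothing filtered
  expect_true(all(filter_constraints(g, -1)$constraints$status == "measured"))
  # threshold above the maximum: unsolvable
  expect_error(filter_constraints(g, 0.95), "unsolvable")
})

test_that("stage model recovers a planted affine map despite gross outliers", {
  set.seed(31)
  n <- 60
  dx <- runif(n, -200, 200); dy <- runif(n, -200, 200)
  dxr <- dx * 1.02 + 3; dyr <- dy * 1.02 - 1
  out_idx <- sample(n, 6)
  dxr[out_idx] <- dxr[out_idx] + runif(6, 150, 300)
  dyr[out_idx] <- dyr[out_idx] - runif(6, 150, 300)
  g <- toy_graph(data.frame(i = rep(1, n), j = rep(2, n), dx = dx, dy = dy,
                            w = 1), 2)
  g$constraints$dx_ref <- dxr; g$constraints$dy_ref <- dyr
  m <- fit_stage_model(g, inlier_threshold = 2, rng_seed = 31)
  expect_equal(m$coef[1, ], c(3, -1), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(m$coef[2:3, ], diag(2) * 1.02, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_setequal(m$outlier_rows, out_idx)
})

test_that("identity data gives the identity stage model with no outliers", {
  set.seed(32)
  dx <- runif(20, -100, 100); dy <- runif(20, -100, 100)
  g <- toy_graph(data.frame(i = rep(1, 20), j = rep(2, 20), dx = dx, dy = dy,
                            w = 1), 2)
  m <- fit_stage_model(g, rng_seed = 32)
  expect_equal(m$coef, rbind(c(0, 0), diag(2)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_length(m$outlier_rows, 0)
})

test_that("rank-deficient designs fall back to the identity map", {
  g <- toy_graph(data.frame(i = c(1, 1), j = c(2, 3), dx = c(10, 20),
                            dy = c(0, 0), w = 1), 3)
  expect_warning(m <- fit_stage_model(g), "identity")
  expect_equal(predict(m, c(100, 0)), matrix(c(100, 0), 1), ignore_attr = TRUE)
})

test_that("imputation replaces filtered offsets with model predictions", {
  g <- toy_graph(data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                            dx = c(100, 0, 100), dy = c(0, 100, 100),
                            w = c(0.9, 0.9, 0.1)), 3)
  g <- filter_constraints(g, 0.5)
  # known linear model: refined = 1.1 * initial + (2, -5)
  m <- structure(list(coef = rbind(c(2, -5), diag(2) * 1.1),
                      inliers = 1:2, outlier_rows = integer(0),
                      fallback = FALSE), class = "stage_model")
  before <- g$constraints[, c("i", "j")]
  g2 <- impute_constraints(g, m)
  expect_equal(g2$constraints[, c("i", "j")], before)  # edge set unchanged
  imp <- g2$constraints[3, ]
  expect_equal(imp$status, "imputed")
  expect_equal(c(imp$dx_ref, imp$dy_ref), c(100 * 1.1 + 2, 100 * 1.1 - 5))
  expect_equal(imp$weight, max(g$s_thresh, 0.05))
  # identity model, no filtered constraints: graph unchanged
  gid <- toy_graph(data.frame(i = 1, j = 2, dx = 7, dy = 3, w = 0.8), 2)
  gid$s_thresh <- 0.2
  mid <- structure(list(coef = rbind(c(0, 0), diag(2)), inliers = 1,
                        outlier_rows = integer(0), fallback = FALSE),
                   class = "stage_model")
  g3 <- impute_constraints(gid, mid)
  expect_equal(g3$constraints$dx_ref, 7)
  expect_equal(g3$constraints$status, "measured")
})
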