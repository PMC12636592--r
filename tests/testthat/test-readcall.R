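random_stack <- function(h = 12, w = 12, cycles = 4, seed = 61) {
  set.seed(seed)
  seq_stack(array(rnorm(h * w * 4 * cycles), c(h, w, 4, cycles)))
}

test_that("background subtraction removes constant and large-scale content", {
  st <- seq_stack(array(5, c(31, 31, 4, 2)))
  out <- background_subtract(st)
  expect_lt(max(abs(out)), 1e-6)
  expect_equal(issq:::stack_stage(out), "background_filtered")

  # unit impulse: centre keeps 1 minus the blur kernel's central weight
  imp <- array(0, c(51, 51, 4, 2)); imp[26, 26, 1, 1] <- 1
  out <- background_subtract(seq_stack(imp), sigma = 3)
  k <- gaussian_kernel1d(3)
  centre_weight <- k[(length(k) + 1) / 2]^2
  expect_equal(out[26, 26, 1, 1], 1 - centre_weight, tolerance = 1e-12)

  # narrow dots survive, wide blobs are crushed
  xy <- outer((1:81 - 41)^2, (1:81 - 41)^2, "+")
  wide <- exp(-xy / (2 * 20^2)); narrow <- exp(-xy / (2 * 1^2))
  arr <- array(0, c(81, 81, 4, 2))
  arr[, , 1, 1] <- narrow; arr[, , 2, 1] <- wide
  out <- background_subtract(seq_stack(arr), sigma = 3)
  expect_gt(out[41, 41, 1, 1] / out[41, 41, 2, 1], 5)
})

test_that("z-scoring gives population mean 0 / sd 1 and worked values", {
  st <- random_stack()
  out <- zscore_normalize(st)
  for (t in 1:4) for (c in 1:4) {
    p <- out[, , c, t]
    expect_lt(abs(mean(p)), 1e-9)
    expect_equal(sqrt(mean((p - mean(p))^2)), 1, tolerance = 1e-9)
  }
  # worked example {0,0,10,10} -> {-1,-1,1,1} with population sd 5
  arr <- array(c(0, 0, 10, 10), c(2, 2, 1, 1))
  # (single channel/cycle plane)
  z <- zscore_normalize(seq_stack(array(rep(c(0, 0, 10, 10), 4), c(2, 2, 4, 1))))
  expect_equal(as.vector(z[, , 1, 1]), c(-1, -1, 1, 1))
  # scale invariance
  z7 <- zscore_normalize(seq_stack(unclass(st) * 7))
  expect_equal(unclass(z7), unclass(zscore_normalize(st)), tolerance = 1e-12)
  # already-normalized plane passes through
  p0 <- unclass(st)
  for (t in 1:4) for (c in 1:4) {
    q <- p0[, , c, t]
    p0[, , c, t] <- (q - mean(q)) / sqrt(mean((q - mean(q))^2))
  }
  expect_equal(unclass(zscore_normalize(seq_stack(p0))), p0,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("second-max suppression leaves at most one nonzero channel", {
  # worked pixel examples, blur disabled to see the raw rule
  px <- function(v) {
    arr <- array(rep(v, each = 1), c(1, 1, 4, 1))
    as.vector(second_max_suppress(seq_stack(arr), blur_sigma = 0))
  }
  expect_equal(px(c(5, 3, 2, 1)), c(2, 0, 0, 0))
  expect_equal(px(c(5, 5, 1, 0)), c(0, 0, 0, 0))
  expect_equal(px(c(2, 2, 2, 2)), c(0, 0, 0, 0))

  st <- random_stack(8, 8, 3, seed = 62)
  out <- second_max_suppress(st, blur_sigma = 0)
  nz <- apply(unclass(out) > 0, c(1, 2, 4), sum)
  expect_true(all(nz <= 1))
  expect_equal(issq:::stack_stage(out), "suppressed")
})

test_that("temporal std projection matches hand values and is nonnegative", {
  # cycle-constant stack projects to exactly zero
  arr <- array(3, c(4, 4, 4, 5))
  expect_true(all(temporal_std_projection(seq_stack(arr)) == 0))
  # one channel alternating {0,1,0,1}: population sd 0.5
  arr <- array(0, c(2, 2, 4, 4))
  arr[, , 2, c(2, 4)] <- 1
  expect_true(all(temporal_std_projection(seq_stack(arr)) == 0.5))
  # single cycle undefined
  expect_error(temporal_std_projection(seq_stack(array(0, c(2, 2, 4, 1)))),
               "cycles")
  st <- random_stack(seed = 63)
  expect_true(all(temporal_std_projection(st) >= 0))
})

test_that("LoG detection finds isolated Gaussian dots at their centres", {
  expect_equal(nrow(detect_colonies(matrix(0, 50, 50))), 0)
  proj <- matrix(0, 100, 100)
  centres <- cbind(x = c(20, 50, 80, 30, 70), y = c(20, 30, 40, 70, 80))
  for (k in 1:5) {
    xy <- outer((1:100 - 1 - centres[k, "y"])^2,
                (1:100 - 1 - centres[k, "x"])^2, "+")
    proj <- proj + 10 * exp(-xy / (2 * 1.5^2))
  }
  det <- detect_colonies(proj)
  expect_equal(nrow(det), 5)
  d2 <- outer(det$y, centres[, "y"], "-")^2 + outer(det$x, centres[, "x"], "-")^2
  expect_true(all(apply(d2, 2, min) <= 1))

  # two dots 20 px apart stay separate
  proj2 <- matrix(0, 60, 60)
  for (cx in c(20, 40)) {
    xy <- outer((1:60 - 31)^2, (1:60 - 1 - cx)^2, "+")
    proj2 <- proj2 + 10 * exp(-xy / (2 * 1.5^2))
  }
  expect_equal(nrow(detect_colonies(proj2)), 2)
})

test_that("base calling reads the argmax channel per cycle", {
  lib <- "GTAC"
  colonies <- data.frame(x = 10L, y = 10L, cell = 1L, barcode_index = 1L,
                         barcode = lib, stringsAsFactors = FALSE)
  data <- issq:::render_sequencing_channels(
    c(21, 21), colonies, 4, colony_sigma = 1.5, amplitude = 50, decay = 1,
    background = matrix(0, 4, 4), noise_sd = 0, rng_seed = 1)
  st <- seq_stack(data)
  out <- extract_and_call(st, data.frame(x = 10, y = 10))
  expect_equal(out$read, "GTAC")
  expect_false(out$tie)

  # independent argmax oracle on a random stack
  st <- random_stack(6, 6, 5, seed = 64)
  cols <- data.frame(x = c(0, 3, 5), y = c(5, 2, 0))
  out <- extract_and_call(st, cols)
  for (k in 1:3) {
    expected <- paste(vapply(1:5, function(t)
      c("G", "T", "A", "C")[which.max(st[cols$y[k] + 1, cols$x[k] + 1, , t])],
      ""), collapse = "")
    expect_equal(out$read[k], expected)
  }

  # an exact two-way tie uses channel priority and sets the flag
  arr <- array(0, c(3, 3, 4, 2))
  arr[2, 2, c(2, 3), 1] <- 5   # T and A tie in cycle 1
  arr[2, 2, 4, 2] <- 1
  out <- extract_and_call(seq_stack(arr), data.frame(x = 1, y = 1))
  expect_equal(out$read, "TC")
  expect_true(out$tie)
})

test_that("colonies inherit the mask label at their centre pixel", {
  mask <- matrix(0L, 10, 10)
  mask[3:6, 3:6] <- 7L
  cols <- assign_to_cells(data.frame(x = c(3, 0, 6), y = c(4, 0, 2)), mask)
  expect_equal(cols$cell, c(7L, 0L, 0L))  # boundary pixel: exact lookup
  mask[3, 7] <- 9L
  expect_equal(assign_to_cells(data.frame(x = 6, y = 2), mask)$cell, 9L)
})

test_that("consensus keeps the k most frequent reads with stated tie rule", {
  colonies <- data.frame(
    cell = rep(1L, 9),
    read = c(rep("AAA", 5), rep("CCC", 3), "GGG"))
  cons <- consensus_reads(colonies, k = 2)
  expect_equal(cons$read, c("AAA", "CCC"))
  expect_equal(cons$count, c(5L, 3L))
  # single read
  expect_equal(consensus_reads(data.frame(cell = 1L, read = "TTT"))$read,
               "TTT")
  # all tied: lexicographic, flagged
  tied <- data.frame(cell = 1L, read = rep(c("GGG", "AAA", "CCC"), 2))
  cons <- consensus_reads(tied, k = 2)
  expect_equal(cons$read, c("AAA", "CCC"))
  expect_true(all(cons$tie))
  # background colonies are dropped
  bg <- data.frame(cell = c(0L, 0L, 2L), read = "AAA")
  expect_equal(consensus_reads(bg)$cell, 2L)
})

test_that("edit distance matches classic hand-checked values", {
  expect_equal(as.integer(levenshtein("GTAC", "GTAC")), 0L)
  expect_equal(as.integer(levenshtein("GTAC", "GGAC")), 1L)
  expect_equal(as.integer(levenshtein("kitten", "sitting")), 3L)
})

test_that("edit distance is symmetric and satisfies the triangle inequality", {
  set.seed(65)
  rand_read <- function() paste(sample(c("G", "T", "A", "C"),
                                       sample(3:8, 1), TRUE), collapse = "")
  for (i in 1:30) {
    a <- rand_read(); b <- rand_read(); c <- rand_read()
    dab <- as.integer(levenshtein(a, b))
    expect_equal(dab, as.integer(levenshtein(b, a)))
    expect_lte(dab, as.integer(levenshtein(a, c)) +
                 as.integer(levenshtein(c, b)))
  }
})

test_that("library matching applies the unique-minimum rule", {
  cons <- data.frame(cell = 1L, read = "AAAT", count = 3L, rank = 1L,
                     tie = FALSE)
  lib <- c("AAAA", "TTTT")
  res <- match_barcodes(cons, lib)
  expect_equal(res$status, "matched")
  expect_equal(res$barcode, "AAAA")
  expect_equal(res$distance, 1)

  # verbatim hit at distance 0
  res0 <- match_barcodes(data.frame(cell = 1L, read = "TTTT"), lib)
  expect_equal(res0$distance, 0)
  expect_equal(res0$barcode, "TTTT")

  # tie between two entries: confirm with the brute-force distance matrix,
  # then expect ambiguity
  lib2 <- c("AAAA", "AATA")
  read <- "AATA"
  mutated <- "AAAA"   # one substitution away from both entries? verify:
  dm <- levenshtein(mutated, lib2)
  expect_equal(as.vector(dm), c(0, 1))  # not a tie -> matched
  tie_read <- "AAGA"  # distance 1 to both AAAA and AATA
  expect_equal(as.vector(levenshtein(tie_read, lib2)), c(1, 1))
  res2 <- match_barcodes(data.frame(cell = 1L, read = tie_read), lib2)
  expect_equal(res2$status, "ambiguous")

  # max_distance turns distant minima into unmatched
  res3 <- match_barcodes(data.frame(cell = 1L, read = "GGGG"), lib,
                         max_distance = 1)
  expect_equal(res3$status, "unmatched")
  expect_error(match_barcodes(cons, character(0)), "empty")
})

test_that("double-barcode matching sums distances over the best pairing", {
  lib <- data.frame(bc1 = c("AAAA", "GGGG"), bc2 = c("TTTT", "CCCC"),
                    stringsAsFactors = FALSE)
  cons <- data.frame(cell = c(1L, 1L), read = c("TTTT", "AAAA"),
                     count = c(4L, 3L), rank = 1:2, tie = FALSE)
  res <- match_barcodes(cons, lib)
  # reads arrive in slot order (bc2, bc1); the swapped assignment matches
  expect_equal(res$status, "matched")
  expect_equal(res$distance, 0)
  expect_equal(c(res$bc1, res$bc2), c("AAAA", "TTTT"))
  # one substitution away still matches uniquely with distance 1
  cons2 <- data.frame(cell = 1L, read = c("AAAT", "TTTT"),
                      count = c(2L, 2L), rank = 1:2, tie = FALSE)
  res2 <- match_barcodes(cons2, lib)
  expect_equal(res2$distance, 1)
  expect_equal(res2$status, "matched")
})

test_that("called reads are invariant to per-plane affine intensity rescales", {
  lib <- generate_barcode_library(8, length = 5, rng_seed = 66)
  sim <- generate_sequencing_stack(4, lib, n_cycles = 5, frame = c(128, 128),
                                   noise_sd = 2, rng_seed = 66)
  rc1 <- call_reads(sim$stack, sim$mask, lib)
  scaled <- unclass(sim$stack)
  set.seed(67)
  for (t in 1:5) for (c in 1:4)
    scaled[, , c, t] <- scaled[, , c, t] * runif(1, 0.5, 20) + runif(1, -5, 50)
  rc2 <- call_reads(seq_stack(scaled), sim$mask, lib)
  expect_equal(rc2$colonies$read, rc1$colonies$read)
  expect_equal(rc2$cells, rc1$cells)
})

test_that("the wrapper enforces stage order and recovers planted barcodes", {
  lib <- generate_barcode_library(16, length = 6, rng_seed = 68)
  sim <- generate_sequencing_stack(6, lib, n_cycles = 6, frame = c(192, 192),
                                   noise_sd = 0, decay = 1,
                                   background_max = 0, rng_seed = 68)
  # colony-free planes in a noiseless render are constant and warn
  rc <- suppressWarnings(call_reads(sim$stack, sim$mask, lib))
  truth <- sim$truth$cell_barcodes
  matched <- rc$cells[rc$cells$status == "matched", ]
  mm <- merge(matched, truth, by = "cell")
  expect_equal(nrow(matched), nrow(truth))
  expect_true(all(mm$barcode.x == mm$barcode.y))
})
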