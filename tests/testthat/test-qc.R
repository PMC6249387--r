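test_that("background estimation uses per-well medians", {
  vals <- rbind(matrix(100L, 4, 3), matrix(0L, 2, 3))
  m <- counts_from_matrix(vals, well_type = rep(c("cell", "empty"), c(4, 2)))
  qc <- estimate_background(m)
  expect_identical(qc$background_fraction, 0)
  expect_identical(qc$fold_separation, Inf)

  withr::with_seed(8, {
    cell_tot <- rpois(10, 3000)
    empty_tot <- rpois(6, 30)
  })
  vals2 <- matrix(0L, 16, 1)
  vals2[, 1] <- c(cell_tot, empty_tot)
  m2 <- counts_from_matrix(vals2, well_type = rep(c("cell", "empty"), c(10, 6)))
  qc2 <- estimate_background(m2)
  sorted_middle <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  expect_equal(qc2$fold_separation,
               sorted_middle(cell_tot) / sorted_middle(empty_tot))
  expect_equal(qc2$background_fraction, 1 / qc2$fold_separation)

  m3 <- counts_from_matrix(matrix(10L, 3, 2))
  expect_warning(qc3 <- estimate_background(m3), "no empty wells")
  expect_true(is.na(qc3$background_fraction))
})

test_that("cell filtering applies the threshold and guards empty results", {
  vals <- matrix(0L, 6, 2)
  vals[, 1] <- c(1000L, 900L, 5L, 800L, 2L, 3L)
  m <- counts_from_matrix(vals,
                          well_type = rep(c("cell", "empty"), c(4, 2)))
  f0 <- suppressWarnings(filter_cells(m, min_total = 0))
  expect_identical(nrow(f0$values), 4L)
  expect_true(all(f0$row_meta$well_type == "cell"))
  expect_identical(f0$state, "filtered")

  f <- suppressWarnings(filter_cells(m, min_total = 100))
  expect_identical(f$row_meta$well_id, c("W001", "W002", "W004"))
  qc <- attr(f, "qc")
  expect_identical(qc$cells_retained, 3L)
  expect_identical(qc$cells_dropped, 1L)
  expect_identical(qc$filter_threshold_used, 100)

  expect_error(suppressWarnings(filter_cells(m, min_total = 1001)),
               "1001")
})

test_that("auto filter policy drops exactly the deliberately low-count cells", {
  cfg <- fast_config(mean_depth = 3000, background_fraction = 0.01)
  truth <- simulate_truth(cfg)
  m <- sim_counts(truth)
  # depress ten cells below any plausible threshold
  low <- 3:12
  m$values[low, ] <- 0L
  m$values[low, 1] <- 7L
  m <- scid_counts(m$values, m$row_meta, m$col_meta, state = "raw")
  f <- filter_cells(m, min_total = "auto")
  qc <- attr(f, "qc")
  expect_identical(qc$cells_dropped, 10L)
  expect_identical(setdiff(m$row_meta$well_id[m$row_meta$well_type == "cell"],
                           f$row_meta$well_id),
                   m$row_meta$well_id[low])
  expect_gte(qc$filter_threshold_used, 500)
})

test_that("subsampling conserves totals exactly and is seeded", {
  withr::with_seed(12, {
    vals <- matrix(rpois(60, 50), 6, 10)
  })
  m <- counts_from_matrix(vals, state = "filtered")
  depth <- min(rowSums(vals))
  s <- subsample_counts(m, depth = "min", seed = 42)
  expect_true(all(rowSums(s$values) == depth))
  expect_true(all(s$values <= vals))
  expect_identical(s$state, "subsampled")

  # the minimum-total row passes through unchanged
  i_min <- which.min(rowSums(vals))
  expect_identical(unname(s$values[i_min, ]), as.integer(vals[i_min, ]))

  s2 <- subsample_counts(m, depth = "min", seed = 42)
  expect_identical(s$values, s2$values)
  s3 <- subsample_counts(m, depth = "min", seed = 43)
  expect_false(identical(s$values, s3$values))
  expect_true(all(rowSums(s3$values) == depth))

  expect_error(subsample_counts(m, depth = 0), "positive")
  expect_warning(subsample_counts(m, depth = max(rowSums(vals))), "dropped")
})

test_that("subsampled entries track the hypergeometric expectation", {
  m <- counts_from_matrix(matrix(c(900L, 100L), 1, 2), state = "filtered")
  draws <- vapply(1:2000, function(s) {
    subsample_counts(m, depth = 100, seed = s)$values[1, 1]
  }, integer(1))
  # X ~ Hypergeometric(N = 1000, K = 900, n = 100): mean 90
  v <- 100 * 0.9 * 0.1 * (900 / 999)
  se <- sqrt(v / length(draws))
  expect_lt(abs(mean(draws) - 90), 3 * se)
})

test_that("min-max scaling maps columns to [0, 1] and is idempotent", {
  m <- counts_from_matrix(matrix(c(0L, 5L, 10L), 3, 1), state = "subsampled")
  expect_equal(unname(scale_minmax(m)$values[, 1]), c(0, 0.5, 1))

  mc <- counts_from_matrix(matrix(7L, 3, 2), state = "subsampled")
  expect_warning(sc <- scale_minmax(mc), "zero-variance")
  expect_true(all(sc$values == 0))

  withr::with_seed(4, {
    vals <- matrix(rpois(200, 20), 20, 10)
  })
  m2 <- counts_from_matrix(vals, state = "subsampled")
  sc2 <- scale_minmax(m2)
  expect_equal(unname(apply(sc2$values, 2, min)), rep(0, 10))
  expect_equal(unname(apply(sc2$values, 2, max)), rep(1, 10))
  # re-scaling scaled data changes nothing
  sc3 <- scale_minmax(sc2)
  expect_equal(sc3$values, sc2$values)
})

test_that("phospho/total ratios divide with the pseudocount", {
  vals <- matrix(c(10L, 4L, 10L, 9L), 2, 2)
  colnames(vals) <- c("pAKT", "AKT")
  m <- counts_from_matrix(vals, state = "subsampled")
  m$col_meta$epitope_class <- c("phospho", "total")
  m$col_meta$total_partner <- c("AKT", NA)
  r <- phospho_ratio(m, pseudocount = 1)
  expect_equal(unname(r$values[, "pAKT"]), c(11 / 11, 5 / 10))

  withr::with_seed(6, {
    ph <- matrix(rpois(30, 5), 10, 3)
    tot <- matrix(rpois(30, 20), 10, 3)
  })
  vals2 <- cbind(ph, tot)
  colnames(vals2) <- c(paste0("pP", 1:3), paste0("P", 1:3))
  m2 <- counts_from_matrix(vals2, state = "subsampled")
  m2$col_meta$epitope_class <- rep(c("phospho", "total"), each = 3)
  m2$col_meta$total_partner <- c(paste0("P", 1:3), rep(NA, 3))
  r2 <- phospho_ratio(m2, pseudocount = 0.5)
  expect_equal(unname(r2$values), unname((ph + 0.5) / (tot + 0.5)))

  m3 <- counts_from_matrix(vals, state = "subsampled")
  expect_error(phospho_ratio(m3), "no phospho")
})

test_that("the full-size panel yields eleven phospho/total ratio columns", {
  truth <- simulate_truth(sim_config(n_cell_wells = 20, n_empty_wells = 4,
                                     mean_depth = 500, seed = 2))
  m <- sim_counts(truth)
  f <- suppressWarnings(filter_cells(m, min_total = 0))
  r <- phospho_ratio(subsample_counts(f, seed = 1))
  expect_identical(ncol(r$values), 11L)
})
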