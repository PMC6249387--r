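test_that("extract_segments slices exactly and flags short reads", {
  layout <- tiny_layout()
  w <- "ACGTACGT"; a <- "AAACCCGGGT"; u <- "ACGTACGTACGTACG"
  seg <- extract_segments(paste0(w, a, u), layout)
  expect_identical(seg$well_bc, w)
  expect_identical(seg$ab_bc, a)
  expect_identical(seg$umi, u)
  expect_false(seg$too_short)

  short <- extract_segments(strrep("A", layout$min_read_length - 1L), layout)
  expect_true(short$too_short)
  expect_true(is.na(short$ab_bc))

  withr::with_seed(3, {
    reads <- vapply(1:1000, function(i) {
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    }, character(1))
  })
  seg <- extract_segments(reads, layout)
  ab_oracle <- vapply(reads, function(r) {
    paste(strsplit(r, "")[[1]][(layout$ab_bc[1] + 1):(layout$ab_bc[1] + 10)],
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
  expect_identical(seg$ab_bc, ab_oracle)
})

test_that("match_barcode agrees with brute-force Hamming scan and rejects ambiguity", {
  wl <- random_whitelist(30, 10, 3, seed = 9)

  hit <- match_barcode(wl[7], wl, max_mismatch = 1)
  expect_identical(hit$barcode, wl[7])
  expect_identical(hit$distance, 0L)

  withr::with_seed(21, {
    for (i in 1:200) {
      true_bc <- sample(wl, 1)
      pos <- sample(10, 1)
      ch <- strsplit(true_bc, "")[[1]]
      ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
      obs <- paste(ch, collapse = "")
      got <- match_barcode(obs, wl, max_mismatch = 1)
      want <- match_oracle(obs, wl, 1)
      expect_identical(got$barcode, want$barcode)
      expect_identical(as.integer(got$distance), as.integer(want$distance))
    }
  })

  # observed midway between two entries differing at 2 positions -> no match
  a <- "AAAAAAAAAA"; b <- "CCAAAAAAAA"; mid <- "ACAAAAAAAA"
  got <- match_barcode(mid, c(a, b), max_mismatch = 1)
  expect_true(is.na(got$barcode))

  expect_error(match_barcode("ACGT", wl, 1), "length")
})

test_that("assign_reads tallies partition the input and flag corrections", {
  cfg <- fast_config()
  truth <- simulate_truth(cfg)
  sim <- simulate_reads(truth)

  res <- assign_reads(sim$reads, sim$layout, truth$panel, truth$plate)
  rep <- res$report
  expect_identical(rep$n_assigned, rep$n_reads_total)
  expect_identical(rep$n_ab_corrected, 0L)
  expect_identical(
    rep$n_too_short + rep$n_well_unassigned + rep$n_ab_unassigned +
      rep$n_assigned,
    rep$n_reads_total)

  # one substitution in every antibody barcode: all assigned, all corrected
  err <- simulate_reads(truth, inject_ab_errors = TRUE)
  res2 <- assign_reads(err$reads, err$layout, truth$panel, truth$plate)
  expect_identical(res2$report$n_assigned, res2$report$n_reads_total)
  expect_identical(res2$report$n_ab_corrected, res2$report$n_reads_total)

  # reads from a foreign well barcode land in n_well_unassigned
  foreign <- paste0(strrep("T", cfg$well_bc_len),
                    substr(sim$reads[1:50], cfg$well_bc_len + 1L, 33L))
  stopifnot(!strrep("T", cfg$well_bc_len) %in% truth$plate$well_barcode)
  res3 <- assign_reads(foreign, sim$layout, truth$panel, truth$plate,
                       max_mismatch_well = 0)
  expect_identical(res3$report$n_well_unassigned, 50L)

  # incompatible panel/mismatch configuration fails before streaming
  close_panel <- scid_panel(data.frame(
    antibody_name = c("X", "Y"),
    barcode = c("AAAAAAAAAA", "CAAAAAAAAA")))
  expect_error(
    assign_reads(sim$reads, sim$layout, close_panel, truth$plate,
                 max_mismatch_ab = 1),
    "min pairwise")
})

test_that("count_umis collapses duplicates and matches the distinct-set oracle", {
  panel <- tiny_panel()
  plate <- tiny_plate()

  dup <- data.frame(well_id = "W001", antibody_name = "TGM1",
                    umi = rep("AAAAAAAAAAAAAAA", 5))
  m <- count_umis(dup, panel, plate)
  expect_identical(m$values["W001", "TGM1"], 1L)
  expect_identical(dim(m$values), c(4L, 4L))

  withr::with_seed(17, {
    reads <- data.frame(
      well_id = sample(plate$well_id, 500, replace = TRUE),
      antibody_name = sample(panel$tags$antibody_name, 500, replace = TRUE),
      umi = sample(c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC",
                     "GGGGGGGGGGGGGGG", "TTTTTTTTTTTTTTT",
                     "ACGTACGTACGTACG"), 500, replace = TRUE)
    )
  })
  m <- count_umis(reads, panel, plate)
  for (w in plate$well_id) {
    for (a in panel$tags$antibody_name) {
      oracle <- length(unique(
        reads$umi[reads$well_id == w & reads$antibody_name == a]))
      expect_identical(m$values[w, a], as.integer(oracle))
    }
  }
  # order invariance
  m2 <- count_umis(reads[rev(seq_len(nrow(reads))), ], panel, plate)
  expect_identical(m$values, m2$values)
})

test_that("directional UMI collapse absorbs likely sequencing errors only", {
  panel <- tiny_panel()
  plate <- tiny_plate()
  # 10 reads of one UMI + 1 read of a single-mismatch neighbor -> 1 molecule
  umis <- c(rep("AAAAAAAAAAAAAAA", 10), "AAAAAAAAAAAAAAC")
  reads <- data.frame(well_id = "W001", antibody_name = "TGM1", umi = umis)
  m <- count_umis(reads, panel, plate, umi_collapse = "directional")
  expect_identical(m$values["W001", "TGM1"], 1L)
  # equal-abundance neighbors stay distinct molecules
  umis2 <- c(rep("AAAAAAAAAAAAAAA", 5), rep("AAAAAAAAAAAAAAC", 5))
  reads2 <- data.frame(well_id = "W001", antibody_name = "TGM1", umi = umis2)
  m2 <- count_umis(reads2, panel, plate, umi_collapse = "directional")
  expect_identical(m2$values["W001", "TGM1"], 2L)
})

test_that("replicate-barcode correlations match a direct Pearson oracle and merge conserves", {
  withr::with_seed(33, {
    n_cells <- 40
    base <- rnbinom(n_cells, size = 5, mu = 2000)
    splits <- t(vapply(base, function(x) rmultinom(1, x, rep(1 / 3, 3))[, 1],
                       integer(3)))
  })
  vals <- cbind(splits, matrix(5L, n_cells, 1))
  colnames(vals) <- c("AKT_bc1", "AKT_bc2", "AKT_bc3", "OTHER")
  m <- counts_from_matrix(vals)
  m$col_meta$replicate_group <- c("AKT", "AKT", "AKT", NA)

  res <- merge_replicate_barcodes(m)
  expect_equal(nrow(res$correlations), 3L)
  pearson_oracle <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  r12 <- res$correlations$pearson_r[
    res$correlations$antibody_a == "AKT_bc1" &
      res$correlations$antibody_b == "AKT_bc2"]
  expect_equal(r12, pearson_oracle(vals[, 1], vals[, 2]), tolerance = 1e-12)

  expect_identical(unname(res$merged$values[, "AKT"]),
                   as.integer(rowSums(vals[, 1:3])))
  expect_identical(unname(res$merged$values[, "OTHER"]),
                   as.integer(vals[, 4]))

  # identical columns correlate exactly
  v2 <- cbind(A_bc1 = base, A_bc2 = base)
  m2 <- counts_from_matrix(v2)
  m2$col_meta$replicate_group <- c("A", "A")
  expect_equal(merge_replicate_barcodes(m2, merge = FALSE)$correlations$pearson_r,
               1, tolerance = 1e-12)

  m3 <- counts_from_matrix(v2)
  m3$col_meta$replicate_group <- c("A", NA)
  expect_warning(merge_replicate_barcodes(m3, merge = FALSE),
                 "fewer than 2")
})
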