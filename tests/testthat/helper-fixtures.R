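# Shared fixtures and independent oracles. Fixtures are built in code; all
# randomness is locally seeded so tests are order-independent.

# rejection-sample a whitelist with pairwise Hamming distance >= min_dist
random_whitelist <- function(n, len, min_dist, seed = 1L) {
  withr::with_seed(seed, {
    kept <- character(0)
    while (length(kept) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
      if (!length(kept) ||
          min(hamming_pair_oracle(cand, kept)) >= min_dist) {
        kept <- c(kept, cand)
      }
    }
    kept
  })
}

# position-by-position Hamming distance of one string to many (oracle)
hamming_pair_oracle <- function(x, ys) {
  xc <- strsplit(x, "")[[1]]
  vapply(strsplit(ys, ""), function(yc) sum(xc != yc), integer(1))
}

# brute-force nearest-whitelist match (oracle for match_barcode)
match_oracle <- function(observed, whitelist, max_mismatch) {
  d <- hamming_pair_oracle(observed, whitelist)
  ok <- which(d <= max_mismatch)
  if (!length(ok)) return(NULL)
  best <- ok[d[ok] == min(d[ok])]
  if (length(best) > 1L) return(NULL)
  list(barcode = whitelist[best], distance = d[best])
}

# brute-force two-sample KS statistic over pooled points (oracle)
ks_d_oracle <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1)))
}

# ordinary least squares by explicit normal equations (oracle)
polyfit_oracle <- function(x, y, degree) {
  X <- outer(x, 0:degree, "^")
  drop(solve(t(X) %*% X, t(X) %*% y))
}

tiny_panel <- function() {
  scid_panel(data.frame(
    antibody_name = c("ITGB1", "TGM1", "pAKT", "AKT"),
    barcode = c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG", "TTTTTTTTTT"),
    epitope_class = c("receptor", "total", "phospho", "total"),
    total_partner = c(NA, NA, "AKT", NA),
    pathway_group = c("adhesion", "differentiation", "EGF", "EGF"),
    stringsAsFactors = FALSE
  ))
}

tiny_plate <- function() {
  scid_plate(data.frame(
    well_barcode = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT"),
    well_id = c("W001", "W002", "W003", "W004"),
    well_type = c("cell", "cell", "cell", "empty"),
    gate_label = c("ITGB1+", "ITGB1+", "ITGB1low", "none"),
    stringsAsFactors = FALSE
  ))
}

tiny_layout <- function() read_layout()

# small fast simulation config for unit tests
fast_config <- function(...) {
  args <- list(...)
  defaults <- list(n_cell_wells = 24L, n_empty_wells = 8L, panel_size = 12L,
                   mean_depth = 400, duplication_rate = 0.5,
                   error_rate = 0, seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# build a scid_counts from a plain matrix of cell wells
counts_from_matrix <- function(values, state = "raw",
                               gate = rep("none", nrow(values)),
                               well_type = rep("cell", nrow(values))) {
  n <- nrow(values)
  p <- ncol(values)
  ab <- colnames(values)
  if (is.null(ab)) ab <- sprintf("AB%02d", seq_len(p))
  scid_counts(
    values,
    row_meta = data.frame(well_id = sprintf("W%03d", seq_len(n)),
                          well_type = well_type, gate_label = gate,
                          stringsAsFactors = FALSE),
    col_meta = data.frame(antibody_name = ab, stringsAsFactors = FALSE),
    state = state
  )
}
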