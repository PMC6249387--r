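#' Extract barcode segments from read sequences
#'
#' Slices the well-barcode, antibody-barcode and UMI segments out of each
#' read according to the layout. Reads shorter than
#' `layout$min_read_length` are flagged `too_short` (their segments are
#' `NA`), never an error: truncated reads are an expected part of real
#' sequencing output.
#'
#' @param read_sequence Character vector of read sequences.
#' @param layout A `scid_layout`.
#' @return data.frame with columns `well_bc`, `ab_bc`, `umi`, `too_short`.
#' @export
extract_segments <- function(read_sequence, layout) {
  stopifnot(inherits(layout, "scid_layout"))
  too_short <- nchar(read_sequence) < layout$min_read_length
  seg <- function(s) {
    out <- substr(read_sequence, s[1] + 1L, s[1] + s[2])
    out[too_short] <- NA_character_
    out
  }
  data.frame(
    well_bc = seg(layout$well_bc),
    ab_bc = seg(layout$ab_bc),
    umi = seg(layout$umi),
    too_short = too_short,
    stringsAsFactors = FALSE
  )
}

# Radius-m neighborhood lookup table for a barcode whitelist: every string
# within Hamming distance <= max_mismatch of some whitelist entry, mapped to
# the index of the unique nearest entry. Strings claimed by two entries at
# the same minimal distance are dropped (ambiguous -> no-match). Exactness:
# an observed string matches some entry within max_mismatch iff it is in
# the table.
barcode_match_table <- function(whitelist, max_mismatch) {
  stopifnot(max_mismatch >= 0L, max_mismatch <= 2L)
  variant <- NULL; idx <- NULL; dist <- NULL # NSE notes for R CMD check
  dt <- data.table(variant = whitelist, idx = seq_along(whitelist),
                   dist = 0L)
  frontier <- dt
  for (m in seq_len(max_mismatch)) {
    frontier <- mutate_all_positions(frontier)
    frontier[, dist := m]
    dt <- rbind(dt, frontier)
  }
  # min distance per (variant, idx), then ambiguity removal per variant
  dt <- dt[, .(dist = min(dist)), by = .(variant, idx)]
  setorder(dt, variant, dist)
  dt <- dt[, {
    if (.N > 1L && dist[2] == dist[1]) NULL else .SD[1]
  }, by = variant]
  setkey(dt, variant)
  dt
}

# every single-substitution variant of every row's variant string
mutate_all_positions <- function(dt) {
  L <- nchar(dt$variant[1])
  bases <- c("A", "C", "G", "T")
  out <- vector("list", L * 3L)
  k <- 0L
  for (pos in seq_len(L)) {
    pre <- substr(dt$variant, 1L, pos - 1L)
    cur <- substr(dt$variant, pos, pos)
    post <- substr(dt$variant, pos + 1L, L)
    for (b in bases) {
      keep <- cur != b
      if (!any(keep)) next
      k <- k + 1L
      out[[k]] <- data.table(variant = paste0(pre[keep], b, post[keep]),
                             idx = dt$idx[keep], dist = 0L)
    }
  }
  unique(rbindlist(out[seq_len(k)]), by = c("variant", "idx"))
}

#' Error-tolerant barcode matching against a whitelist
#'
#' Finds, for each observed sequence, the unique whitelist entry within
#' Hamming distance `max_mismatch`. Ambiguity is rejected, never guessed:
#' if two entries tie at the minimal qualifying distance the observation is
#' a no-match. With a whitelist whose minimum pairwise distance is at least
#' `2 * max_mismatch + 1`, every match is provably unique.
#'
#' @param observed Character vector of observed sequences, same length as
#'   the whitelist entries.
#' @param whitelist Character vector of equal-length barcodes.
#' @param max_mismatch Maximum Hamming distance (0, 1 or 2).
#' @return data.frame with columns `barcode` (matched entry or `NA`) and
#'   `distance` (`NA` for no-match).
#' @examples
#' match_barcode("ACGTACGTAC", c("ACGTACGTAC", "TTTTGGGGCC"), 1)
#' @export
match_barcode <- function(observed, whitelist, max_mismatch = 1L) {
  wl_len <- unique(nchar(whitelist))
  if (length(wl_len) != 1L) stop("whitelist entries must have equal length")
  if (any(nchar(observed) != wl_len)) {
    stop("observed sequence length differs from whitelist length (", wl_len,
         ")")
  }
  tab <- barcode_match_table(whitelist, as.integer(max_mismatch))
  hit <- tab[data.table(variant = observed), on = "variant"]
  data.frame(
    barcode = whitelist[hit$idx],
    distance = hit$dist,
    stringsAsFactors = FALSE
  )
}

read_fastq_sequences <- function(fastq) {
  if (is.character(fastq) && length(fastq) == 1L && file.exists(fastq)) {
    as.character(readDNAStringSet(fastq, format = "fastq"))
  } else {
    as.character(fastq)
  }
}

#' Assign reads to wells and antibodies
#'
#' The demultiplexing stage: extracts the barcode segments from every read,
#' matches the well barcode against the plate layout and the antibody
#' barcode against the panel (both with Hamming-tolerant, ambiguity-
#' rejecting matching), and tallies every read into exactly one category of
#' the demux report. Error correction beyond `max_mismatch = 0` requires
#' the whitelist's minimum pairwise distance to be at least
#' `2 * max_mismatch + 1`; this is checked before any read is touched.
#'
#' @param fastq Path to a FASTQ file (plain or gzipped), or a character
#'   vector of read sequences.
#' @param layout A `scid_layout`.
#' @param panel A `scid_panel`.
#' @param plate A `scid_plate`.
#' @param max_mismatch_ab,max_mismatch_well Maximum Hamming distance for
#'   antibody / well barcode correction (defaults 1; UMIs are never
#'   corrected here).
#' @return List with `assigned` (data.table: `well_id`, `antibody_name`,
#'   `umi`, `n_mismatches_ab`, `n_mismatches_well`) and `report` (a
#'   `scid_demux_report`: total/too-short/unassigned/corrected/assigned
#'   tallies plus per-well and per-antibody assigned-read counts). The
#'   tallies `n_too_short + n_well_unassigned + n_ab_unassigned +
#'   n_assigned` partition `n_reads_total`.
#' @export
assign_reads <- function(fastq, layout, panel, plate,
                         max_mismatch_ab = 1L, max_mismatch_well = 1L) {
  stopifnot(inherits(panel, "scid_panel"), inherits(plate, "scid_plate"))
  max_mismatch_ab <- as.integer(max_mismatch_ab)
  max_mismatch_well <- as.integer(max_mismatch_well)
  if (max_mismatch_ab > 0L &&
      panel$min_pairwise_distance < 2L * max_mismatch_ab + 1L) {
    stop("panel min pairwise barcode distance (", panel$min_pairwise_distance,
         ") cannot support max_mismatch_ab = ", max_mismatch_ab,
         " (needs >= ", 2L * max_mismatch_ab + 1L,
         "); use exact matching (max_mismatch_ab = 0)")
  }
  well_min_dist <- min_pairwise_distance(plate$well_barcode)
  if (max_mismatch_well > 0L &&
      well_min_dist < 2L * max_mismatch_well + 1L) {
    stop("plate well-barcode min pairwise distance (", well_min_dist,
         ") cannot support max_mismatch_well = ", max_mismatch_well)
  }

  seqs <- read_fastq_sequences(fastq)
  segs <- extract_segments(seqs, layout)
  n_total <- length(seqs)
  ok <- !segs$too_short

  well_tab <- barcode_match_table(plate$well_barcode, max_mismatch_well)
  ab_tab <- barcode_match_table(panel$tags$barcode, max_mismatch_ab)

  well_hit <- well_tab[data.table(variant = segs$well_bc[ok]), on = "variant"]
  ab_hit <- ab_tab[data.table(variant = segs$ab_bc[ok]), on = "variant"]

  well_ok <- !is.na(well_hit$idx)
  ab_ok <- !is.na(ab_hit$idx)
  assigned_mask <- well_ok & ab_ok

  assigned <- data.table(
    well_id = plate$well_id[well_hit$idx[assigned_mask]],
    antibody_name = panel$tags$antibody_name[ab_hit$idx[assigned_mask]],
    umi = segs$umi[ok][assigned_mask],
    n_mismatches_ab = ab_hit$dist[assigned_mask],
    n_mismatches_well = well_hit$dist[assigned_mask]
  )

  report <- structure(list(
    n_reads_total = n_total,
    n_too_short = sum(!ok),
    n_well_unassigned = sum(!well_ok),
    n_ab_unassigned = sum(well_ok & !ab_ok),
    n_ab_corrected = sum(assigned$n_mismatches_ab > 0L),
    n_well_corrected = sum(assigned$n_mismatches_well > 0L),
    n_assigned = nrow(assigned),
    per_well = as.list(table(assigned$well_id)),
    per_antibody = as.list(table(assigned$antibody_name))
  ), class = "scid_demux_report")

  list(assigned = assigned, report = report)
}

#' @export
print.scid_demux_report <- function(x, ...) {
  cat("scid demux report:\n")
  for (nm in c("n_reads_total", "n_too_short", "n_well_unassigned",
               "n_ab_unassigned", "n_assigned", "n_ab_corrected",
               "n_well_corrected")) {
    cat(sprintf("  %-20s %d\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Count unique UMIs per well and antibody
#'
#' Collapses assigned reads to molecules: the count for a (well, antibody)
#' cell is the number of distinct UMIs among its reads. The default
#' `exact` mode treats UMIs as identical only when their sequences are
#' equal; `directional` additionally absorbs single-mismatch UMIs into a
#' more abundant neighbor (greedy, count-ordered, absorbing when the
#' neighbor's read count is at least `2 * count - 1`), which guards against
#' UMI sequencing errors at the cost of slight undercounting. The matrix
#' always has one row per plate well (empty wells retained for background
#' QC) and one column per panel tag, regardless of which were observed.
#'
#' @param assigned data.frame/data.table of assigned reads (`well_id`,
#'   `antibody_name`, `umi`), e.g. from [assign_reads()].
#' @param panel A `scid_panel`.
#' @param plate A `scid_plate`.
#' @param umi_collapse `"exact"` (default) or `"directional"`.
#' @return A `scid_counts` in state `raw`.
#' @export
count_umis <- function(assigned, panel, plate,
                       umi_collapse = c("exact", "directional")) {
  umi_collapse <- match.arg(umi_collapse)
  stopifnot(inherits(panel, "scid_panel"), inherits(plate, "scid_plate"))
  assigned <- as.data.table(assigned)
  unknown_well <- setdiff(assigned$well_id, plate$well_id)
  if (length(unknown_well)) {
    stop("assigned reads reference unknown well(s): ",
         paste(head(unknown_well, 5), collapse = ", "))
  }
  unknown_ab <- setdiff(assigned$antibody_name, panel$tags$antibody_name)
  if (length(unknown_ab)) {
    stop("assigned reads reference unknown antibody(s): ",
         paste(head(unknown_ab, 5), collapse = ", "))
  }

  well_id <- NULL; antibody_name <- NULL; umi <- NULL; N <- NULL
  if (umi_collapse == "exact") {
    counts <- unique(assigned[, .(well_id, antibody_name, umi)])[
      , .(N = .N), by = .(well_id, antibody_name)]
  } else {
    counts <- assigned[, .(N = collapse_directional(umi)),
                       by = .(well_id, antibody_name)]
  }

  values <- matrix(0L, nrow = nrow(plate), ncol = nrow(panel$tags))
  i <- match(counts$well_id, plate$well_id)
  j <- match(counts$antibody_name, panel$tags$antibody_name)
  values[cbind(i, j)] <- counts$N

  scid_counts(
    values,
    row_meta = as.data.frame(plate)[, c("well_id", "well_type", "gate_label")],
    col_meta = panel$tags,
    state = "raw"
  )
}

# greedy directional single-mismatch UMI collapse within one (well, antibody)
# group; returns the number of inferred molecules
collapse_directional <- function(umis) {
  tab <- sort(table(umis), decreasing = TRUE)
  useqs <- names(tab)
  n <- length(useqs)
  if (n <= 1L) return(n)
  chm <- do.call(rbind, strsplit(useqs, "", fixed = TRUE))
  reps <- integer(0)          # indices of cluster representatives
  for (k in seq_len(n)) {
    absorbed <- FALSE
    for (r in reps) {
      if (sum(chm[k, ] != chm[r, ]) <= 1L &&
          tab[r] >= 2L * tab[k] - 1L) {
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) reps <- c(reps, k)
  }
  length(reps)
}

#' Replicate-barcode concordance and merging
#'
#' When several barcodes are independently conjugated to the same antibody
#' (a `replicate_group` in the panel), each barcode is a technical
#' replicate of the same protein measurement, and their concordance across
#' cells measures the reproducibility of the assay. Computes, per
#' replicate group, the Pearson correlation across cell wells for every
#' pair of member barcodes, and optionally a merged matrix in which each
#' group's columns are summed into one.
#'
#' @param matrix A `scid_counts`.
#' @param merge Also return the summed-by-group matrix?
#' @return List with `correlations` (data.frame: `replicate_group`,
#'   `antibody_a`, `antibody_b`, `pearson_r`) and `merged` (a
#'   `scid_counts`, or `NULL` when `merge = FALSE`). Groups with fewer than
#'   two members are skipped with a warning.
#' @export
merge_replicate_barcodes <- function(matrix, merge = TRUE) {
  stopifnot(inherits(matrix, "scid_counts"))
  cm <- matrix$col_meta
  groups <- unique(cm$replicate_group[!is.na(cm$replicate_group) &
                                        nzchar(cm$replicate_group)])
  if (!length(groups)) stop("panel has no replicate_group annotations")

  use_rows <- matrix$row_meta$well_type == "cell"
  if (!any(use_rows)) use_rows <- rep(TRUE, nrow(matrix$values))
  vals <- matrix$values[use_rows, , drop = FALSE]

  cors <- list()
  for (g in groups) {
    members <- which(!is.na(cm$replicate_group) & cm$replicate_group == g)
    if (length(members) < 2L) {
      warning("replicate group '", g, "' has fewer than 2 members; skipped")
      next
    }
    pairs <- utils::combn(members, 2L)
    cors[[g]] <- data.frame(
      replicate_group = g,
      antibody_a = cm$antibody_name[pairs[1, ]],
      antibody_b = cm$antibody_name[pairs[2, ]],
      pearson_r = apply(pairs, 2L, function(p) {
        cor(vals[, p[1]], vals[, p[2]])
      }),
      stringsAsFactors = FALSE
    )
  }
  correlations <- do.call(rbind, c(cors, list(make.row.names = FALSE)))

  merged <- NULL
  if (merge) {
    group_of <- ifelse(is.na(cm$replicate_group) | !nzchar(cm$replicate_group),
                       cm$antibody_name, cm$replicate_group)
    ug <- unique(group_of)
    mvals <- vapply(ug, function(g) {
      rowSums(matrix$values[, group_of == g, drop = FALSE])
    }, numeric(nrow(matrix$values)))
    mcm <- cm[match(ug, group_of), , drop = FALSE]
    mcm$antibody_name <- ug
    mcm$barcode <- NA_character_
    mcm$replicate_group <- NA_character_
    merged <- scid_counts(mvals, matrix$row_meta, mcm, state = matrix$state)
  }
  list(correlations = correlations, merged = merged)
}
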