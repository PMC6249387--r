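#' Estimate technical background from empty wells
#'
#' Empty wells received staining and library preparation but no cell, so
#' their UMI totals measure carry-over and ambient antibody signal. The
#' report summarizes per-well totals with medians (robust to outlier
#' wells): `fold_separation` = median cell total / median empty total, and
#' `background_fraction` its reciprocal. A well-behaved scID-seq plate
#' shows roughly 100-fold separation, i.e. ~1% background.
#'
#' @param matrix A `scid_counts` in state `raw` (empty wells still
#'   present).
#' @return A `scid_qc` list: `empty_well_totals`, `cell_well_totals`,
#'   `background_fraction`, `fold_separation`, and placeholders
#'   (`cells_retained`, `cells_dropped`, `filter_threshold_used`) filled in
#'   by [filter_cells()]. With no empty wells the background fields are
#'   `NA` with a warning.
#' @export
estimate_background <- function(matrix) {
  stopifnot(inherits(matrix, "scid_counts"))
  if (matrix$state != "raw") {
    stop("background must be estimated on the raw matrix (state is '",
         matrix$state, "')")
  }
  is_empty <- matrix$row_meta$well_type == "empty"
  is_cell <- matrix$row_meta$well_type == "cell"
  if (!any(is_cell)) stop("matrix has no cell wells")
  empty_totals <- matrix$row_meta$total_umis[is_empty]
  cell_totals <- matrix$row_meta$total_umis[is_cell]

  if (!any(is_empty)) {
    warning("no empty wells present; background is unavailable")
    bf <- NA_real_
    fs <- NA_real_
  } else {
    med_empty <- median(empty_totals)
    med_cell <- median(cell_totals)
    bf <- if (med_cell > 0) med_empty / med_cell else NA_real_
    fs <- if (med_empty > 0) med_cell / med_empty else Inf
  }

  structure(list(
    empty_well_totals = setNames(empty_totals,
                                 matrix$row_meta$well_id[is_empty]),
    cell_well_totals = setNames(cell_totals,
                                matrix$row_meta$well_id[is_cell]),
    background_fraction = bf,
    fold_separation = fs,
    cells_retained = NA_integer_,
    cells_dropped = NA_integer_,
    filter_threshold_used = NA_real_
  ), class = "scid_qc")
}

#' @export
print.scid_qc <- function(x, ...) {
  cat("scid QC report:\n")
  cat(sprintf("  cell wells: %d (median total %.0f)\n",
              length(x$cell_well_totals), median(x$cell_well_totals)))
  cat(sprintf("  empty wells: %d (median total %s)\n",
              length(x$empty_well_totals),
              if (length(x$empty_well_totals))
                sprintf("%.0f", median(x$empty_well_totals)) else "-"))
  cat(sprintf("  fold separation: %.1f   background fraction: %.4f\n",
              x$fold_separation, x$background_fraction))
  if (!is.na(x$cells_retained)) {
    cat(sprintf("  filter: threshold %.0f, retained %d, dropped %d\n",
                x$filter_threshold_used, x$cells_retained, x$cells_dropped))
  }
  invisible(x)
}

#' Filter cell wells on UMI totals
#'
#' Drops empty wells and low-coverage cell wells. The default policy keeps
#' cell wells whose UMI total is at least 10x the median empty-well total,
#' with a floor of 500 UMIs — a guard band motivated by the ~100-fold
#' cell/empty separation of a well-behaved plate.
#'
#' @param matrix A `scid_counts` in state `raw`.
#' @param min_total Integer threshold, or `"auto"` for the default policy.
#' @param qc Optional `scid_qc` from [estimate_background()]; when given,
#'   a copy updated with the filter outcome is attached to the result as
#'   attribute `"qc"` (also attached when `qc` is `NULL`, computed fresh).
#' @return A `scid_counts` in state `filtered` containing only retained
#'   cell wells. Errors if no cell survives the threshold.
#' @export
filter_cells <- function(matrix, min_total = "auto", qc = NULL) {
  stopifnot(inherits(matrix, "scid_counts"))
  if (matrix$state != "raw") {
    stop("filter_cells expects a raw matrix (state is '", matrix$state, "')")
  }
  if (is.null(qc)) qc <- suppressWarnings(estimate_background(matrix))

  if (identical(min_total, "auto")) {
    med_empty <- if (length(qc$empty_well_totals)) {
      median(qc$empty_well_totals)
    } else 0
    min_total <- max(500, 10 * med_empty)
  }
  min_total <- as.numeric(min_total)

  is_cell <- matrix$row_meta$well_type == "cell"
  keep <- is_cell & matrix$row_meta$total_umis >= min_total
  if (!any(keep)) {
    stop("no cell wells have total UMIs >= ", min_total,
         "; lower min_total or check the run")
  }

  qc$filter_threshold_used <- min_total
  qc$cells_retained <- sum(keep)
  qc$cells_dropped <- sum(is_cell) - sum(keep)

  out <- scid_counts(matrix$values[keep, , drop = FALSE],
                     matrix$row_meta[keep, , drop = FALSE],
                     matrix$col_meta, state = "filtered")
  attr(out, "qc") <- qc
  out
}

#' Normalize sequencing depth by rarefaction
#'
#' Equalizes per-cell coverage by drawing, without replacement, the same
#' number of UMIs from each cell's observed UMI multiset (a multivariate
#' hypergeometric draw per cell). Without-replacement sampling matches the
#' physical semantics: UMIs are discrete molecules, and a subsample is a
#' subset of them. After subsampling every row total equals `depth`
#' exactly and every entry is bounded by its original value.
#'
#' @param matrix A `scid_counts` in state `filtered` (or `raw`).
#' @param depth Integer target depth, or `"min"` (default): the minimum
#'   retained row total, which discards no cells. With an explicit depth,
#'   cells whose total is below it are dropped with a warning.
#' @param seed Integer seed; the draw is reproducible and does not disturb
#'   the caller's RNG state.
#' @return A `scid_counts` in state `subsampled`.
#' @export
subsample_counts <- function(matrix, depth = "min", seed = 1L) {
  stopifnot(inherits(matrix, "scid_counts"))
  if (!matrix$state %in% c("raw", "filtered")) {
    stop("subsample_counts expects integer counts (state is '",
         matrix$state, "')")
  }
  totals <- rowSums(matrix$values)
  if (identical(depth, "min")) {
    depth <- min(totals)
  }
  depth <- as.integer(depth)
  if (is.na(depth) || depth <= 0L) stop("depth must be a positive integer")

  keep <- totals >= depth
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) with total < ", depth, " dropped: ",
            paste(head(matrix$row_meta$well_id[!keep], 5), collapse = ", "))
  }
  vals <- matrix$values[keep, , drop = FALSE]

  out_vals <- withr::with_seed(as.integer(seed), {
    t(apply(vals, 1L, subsample_row, depth = depth))
  })
  dimnames(out_vals) <- dimnames(vals)

  scid_counts(out_vals, matrix$row_meta[keep, , drop = FALSE],
              matrix$col_meta, state = "subsampled")
}

# multivariate hypergeometric draw: sample `depth` molecules without
# replacement from the multiset encoded by integer vector x
subsample_row <- function(x, depth) {
  total <- sum(x)
  if (total == depth) return(as.integer(x))
  pool <- rep.int(seq_along(x), x)
  tabulate(pool[sample.int(total, depth)], nbins = length(x))
}

#' Min-max scale each antibody across cells
#'
#' Rescales every antibody column to \[0, 1\] across all cells:
#' `(x - min) / (max - min)`. This equalizes the influence of abundant and
#' scarce epitopes so that downstream PCA and testing are not dominated by
#' the highest-count antibodies. Zero-variance columns become all-zero
#' with a warning.
#'
#' @param matrix A `scid_counts` in state `subsampled` (any state with at
#'   least 2 rows is accepted).
#' @return A `scid_counts` in state `scaled`.
#' @export
scale_minmax <- function(matrix) {
  stopifnot(inherits(matrix, "scid_counts"))
  if (nrow(matrix$values) < 2L) stop("scaling needs at least 2 cells")
  vals <- matrix$values
  mins <- apply(vals, 2L, min)
  maxs <- apply(vals, 2L, max)
  rng <- maxs - mins
  flat <- rng == 0
  if (any(flat)) {
    warning("zero-variance column(s) scaled to all-0: ",
            paste(colnames(vals)[flat], collapse = ", "))
    rng[flat] <- 1
  }
  scaled <- sweep(sweep(vals, 2L, mins, "-"), 2L, rng, "/")
  scaled[, flat] <- 0
  scid_counts(scaled, matrix$row_meta, matrix$col_meta, state = "scaled")
}

#' Phospho/total protein ratios per cell
#'
#' For every phospho epitope whose panel entry names a measured total-
#' protein partner, computes the per-cell ratio
#' `(phospho + pseudocount) / (total + pseudocount)`, correcting
#' phosphorylation signal for protein abundance. Computed on subsampled
#' (depth-equalized) integer counts; the pseudocount guards against
#' division by zero on sparse epitopes.
#'
#' @param matrix A `scid_counts` in state `subsampled` (or `filtered`).
#' @param pseudocount Non-negative real added to numerator and denominator
#'   (default 1).
#' @return A `scid_ratios`: list with `values` (cells x pairs matrix,
#'   columns named by the phospho antibody), `pairs` (data.frame `phospho`,
#'   `total`), `pseudocount`, `row_meta`.
#' @export
phospho_ratio <- function(matrix, pseudocount = 1) {
  stopifnot(inherits(matrix, "scid_counts"))
  cm <- matrix$col_meta
  paired <- which(cm$epitope_class == "phospho" &
                    !is.na(cm$total_partner) & nzchar(cm$total_partner))
  if (!length(paired)) {
    stop("panel has no phospho epitopes with a total_partner")
  }
  phospho <- cm$antibody_name[paired]
  total <- cm$total_partner[paired]
  j_tot <- match(total, cm$antibody_name)
  if (anyNA(j_tot)) {
    stop("total_partner not present in matrix columns: ",
         paste(total[is.na(j_tot)], collapse = ", "))
  }
  vals <- (matrix$values[, paired, drop = FALSE] + pseudocount) /
    (matrix$values[, j_tot, drop = FALSE] + pseudocount)
  colnames(vals) <- phospho
  structure(list(
    values = vals,
    pairs = data.frame(phospho = phospho, total = total,
                       stringsAsFactors = FALSE),
    pseudocount = pseudocount,
    row_meta = matrix$row_meta
  ), class = "scid_ratios")
}

#' @export
print.scid_ratios <- function(x, ...) {
  cat(sprintf("scid_ratios: %d cells x %d phospho/total pairs (pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}
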