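#' PCA on designated trajectory markers
#'
#' Runs principal-component analysis on the cells x markers sub-matrix of
#' a scaled count matrix. Columns are mean-centered but not re-standardized:
#' the prior min-max scaling already equalizes epitope ranges, so the
#' covariance PCA weighs markers by their (comparable) dynamic range.
#'
#' @param matrix A `scid_counts` in state `scaled`.
#' @param markers Character vector of marker antibody names (default
#'   [scid_markers()]).
#' @return List with `scores` (cells x components), `variance_explained`
#'   (fractions, one per component), `rotation` (loadings), `markers`.
#' @export
marker_pca <- function(matrix, markers = scid_markers()) {
  stopifnot(inherits(matrix, "scid_counts"))
  missing_markers <- setdiff(markers, colnames(matrix$values))
  if (length(missing_markers)) {
    stop("marker(s) absent from matrix: ",
         paste(missing_markers, collapse = ", "))
  }
  if (nrow(matrix$values) < length(markers) + 1L) {
    stop("need at least ", length(markers) + 1L, " cells for PCA on ",
         length(markers), " markers")
  }
  sub <- matrix$values[, markers, drop = FALSE]
  pc <- prcomp(sub, center = TRUE, scale. = FALSE)
  list(
    scores = pc$x,
    variance_explained = pc$sdev^2 / sum(pc$sdev^2),
    rotation = pc$rotation,
    markers = markers
  )
}

#' Orient and scale PC1 into a pseudo-time
#'
#' A principal component's sign is arbitrary, so the differentiation axis
#' is anchored biologically: the sign of PC1 is chosen so that pseudo-time
#' correlates positively with a late-differentiation marker (`up_marker`,
#' default TGM1); if that correlation is exactly zero the tie is broken
#' toward negative correlation with a basal marker (`down_marker`, default
#' ITGB1). The oriented scores are then min-max scaled to \[0, 1\].
#'
#' @param pc1_score Per-cell PC1 scores.
#' @param matrix The scaled `scid_counts` the scores came from.
#' @param up_marker,down_marker Marker names anchoring the orientation.
#' @return List with `pseudotime` (per-cell, in \[0, 1\]), `flipped`
#'   (was the sign inverted?), `ambiguous` (both anchor correlations zero;
#'   orientation kept as-is).
#' @export
orient_and_scale <- function(pc1_score, matrix, up_marker = "TGM1",
                             down_marker = "ITGB1") {
  stopifnot(inherits(matrix, "scid_counts"))
  for (m in c(up_marker, down_marker)) {
    if (!m %in% colnames(matrix$values)) {
      stop("orientation marker absent from matrix: ", m)
    }
  }
  cor0 <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else cor(x, y)
  }
  r_up <- cor0(pc1_score, matrix$values[, up_marker])
  r_down <- cor0(pc1_score, matrix$values[, down_marker])

  ambiguous <- FALSE
  if (r_up > 0) {
    flipped <- FALSE
  } else if (r_up < 0) {
    flipped <- TRUE
  } else if (r_down != 0) {
    flipped <- r_down > 0
  } else {
    flipped <- FALSE
    ambiguous <- TRUE
    warning("pseudo-time orientation ambiguous: PC1 uncorrelated with both ",
            up_marker, " and ", down_marker)
  }
  s <- if (flipped) -pc1_score else pc1_score
  rng <- range(s)
  pt <- if (diff(rng) == 0) rep(0, length(s)) else (s - rng[1]) / diff(rng)
  list(pseudotime = pt, flipped = flipped, ambiguous = ambiguous)
}

#' Assign cells to consecutive pseudo-time bins
#'
#' Sorts cells by pseudo-time and groups them into consecutive,
#' non-overlapping bins of `bin_size` cells in rank order (the 10-cell
#' bins used to smooth per-epitope profiles). A trailing remainder smaller
#' than `bin_size / 2` is merged into the previous bin; a larger remainder
#' stays as its own bin. Fewer cells than `bin_size` yield a single bin
#' with a warning. Ties in pseudo-time are broken by input order, and the
#' assignment depends only on ranks, so any permutation of the input rows
#' yields the same binning.
#'
#' @param pseudotime Per-cell pseudo-time values.
#' @param bin_size Cells per bin (default 10; must be >= 2).
#' @return Integer bin id per cell (1-based, aligned to the input order).
#' @export
bin_cells <- function(pseudotime, bin_size = 10L) {
  bin_size <- as.integer(bin_size)
  if (bin_size < 2L) stop("bin_size must be >= 2")
  n <- length(pseudotime)
  if (n < bin_size) {
    warning("fewer cells (", n, ") than bin_size (", bin_size,
            "); using a single bin")
    return(rep(1L, n))
  }
  rank_of <- rank(pseudotime, ties.method = "first")
  bin <- (rank_of - 1L) %/% bin_size + 1L
  n_bins <- max(bin)
  remainder <- n - (n_bins - 1L) * bin_size
  if (remainder < bin_size / 2 && n_bins > 1L) {
    bin[bin == n_bins] <- n_bins - 1L
  }
  bin
}

#' Cubic trend fit on binned means
#'
#' Ordinary least-squares polynomial fit (default third order) of per-bin
#' mean values against per-bin mean pseudo-time. Coefficients are in
#' ascending degree order (intercept first). R-squared is clipped at 0 for
#' pathological fits; a constant response gives coefficients
#' `(mean, 0, ..., 0)` and R-squared 0.
#'
#' @param bin_centers Mean pseudo-time per bin.
#' @param bin_means Mean (scaled) value per bin.
#' @param degree Polynomial degree (default 3). Needs at least
#'   `degree + 1` bins.
#' @return A `scid_trend`: list with `antibody_name` (`NA` here; filled by
#'   [trend_all()]), `bin_centers`, `bin_means`, `coefficients`
#'   (length `degree + 1`), `r_squared`.
#' @export
fit_trend <- function(bin_centers, bin_means, degree = 3L) {
  degree <- as.integer(degree)
  n <- length(bin_centers)
  if (length(bin_means) != n) stop("bin_centers and bin_means differ in length")
  if (n < degree + 1L) {
    stop("need at least ", degree + 1L, " bins for a degree-", degree,
         " fit (have ", n, "); reduce the degree")
  }
  tss <- sum((bin_means - mean(bin_means))^2)
  if (tss == 0) {
    coefs <- c(mean(bin_means), rep(0, degree))
    r2 <- 0
  } else {
    fit <- lm(bin_means ~ stats::poly(bin_centers, degree, raw = TRUE))
    coefs <- unname(coef(fit))
    coefs[is.na(coefs)] <- 0
    rss <- sum(fit$residuals^2)
    r2 <- max(0, 1 - rss / tss)
  }
  structure(list(
    antibody_name = NA_character_,
    bin_centers = bin_centers,
    bin_means = bin_means,
    coefficients = coefs,
    r_squared = r2
  ), class = "scid_trend")
}

#' Evaluate a fitted trend polynomial
#'
#' @param trend A `scid_trend`.
#' @param t Pseudo-time values to evaluate at.
#' @return Fitted values.
#' @export
eval_trend <- function(trend, t) {
  drop(outer(t, seq_along(trend$coefficients) - 1L, "^") %*%
         trend$coefficients)
}

#' Full pseudo-time ordering of a scaled matrix
#'
#' Convenience wrapper chaining [marker_pca()], [orient_and_scale()] and
#' [bin_cells()] into one result object.
#'
#' @inheritParams marker_pca
#' @inheritParams orient_and_scale
#' @inheritParams bin_cells
#' @return A `scid_pseudotime`: list with `cell_ids`, `markers`,
#'   `pc_variance_explained`, `pc1_score`, `pseudotime` (in \[0, 1\]),
#'   `rank` (1-based permutation), `bin_id`, `orientation_flipped`,
#'   `orientation_ambiguous`.
#' @export
run_pseudotime <- function(matrix, markers = scid_markers(), bin_size = 10L,
                           up_marker = "TGM1", down_marker = "ITGB1") {
  pca <- marker_pca(matrix, markers)
  ori <- orient_and_scale(pca$scores[, 1L], matrix, up_marker, down_marker)
  structure(list(
    cell_ids = matrix$row_meta$well_id,
    markers = markers,
    pc_variance_explained = pca$variance_explained,
    pc1_score = unname(pca$scores[, 1L]),
    pseudotime = ori$pseudotime,
    rank = rank(ori$pseudotime, ties.method = "first"),
    bin_id = bin_cells(ori$pseudotime, bin_size),
    orientation_flipped = ori$flipped,
    orientation_ambiguous = ori$ambiguous
  ), class = "scid_pseudotime")
}

#' @export
print.scid_pseudotime <- function(x, ...) {
  cat(sprintf("scid_pseudotime: %d cells, %d bins\n",
              length(x$pseudotime), max(x$bin_id)))
  cat(sprintf("  PC1 variance explained: %.1f%%%s\n",
              100 * x$pc_variance_explained[1],
              if (x$orientation_flipped) " (sign flipped)" else ""))
  invisible(x)
}

#' Binned means and cubic trends for every epitope
#'
#' Computes, for each antibody column (and optionally each phospho/total
#' ratio column), the per-bin mean profile over pseudo-time and its cubic
#' OLS fit. The trend direction — the sign of the fitted polynomial at
#' pseudo-time 1 minus its value at 0 — summarizes whether an epitope
#' rises or falls over differentiation.
#'
#' @param matrix A scaled `scid_counts`.
#' @param ptime A `scid_pseudotime` for the same cells.
#' @param ratios Optional `scid_ratios` for the same cells; ratio columns
#'   are appended with names `ratio:<phospho>`.
#' @param degree Polynomial degree (default 3).
#' @return A `scid_trends`: list with `fits` (named list of `scid_trend`),
#'   `table` (data.frame: `antibody_name`, `pathway_group`, `c0`..`c3`,
#'   `r_squared`, `direction`), `bin_centers`, `bin_means` (bins x
#'   columns matrix).
#' @export
trend_all <- function(matrix, ptime, ratios = NULL, degree = 3L) {
  stopifnot(inherits(matrix, "scid_counts"),
            inherits(ptime, "scid_pseudotime"))
  if (nrow(matrix$values) != length(ptime$pseudotime)) {
    stop("matrix and pseudotime describe different numbers of cells")
  }
  vals <- matrix$values
  pathways <- matrix$col_meta$pathway_group %||%
    rep(NA_character_, ncol(vals))
  if (!is.null(ratios)) {
    if (nrow(ratios$values) != nrow(vals)) {
      stop("ratios and matrix describe different numbers of cells")
    }
    rvals <- ratios$values
    colnames(rvals) <- paste0("ratio:", colnames(rvals))
    pw <- pathways[match(ratios$pairs$phospho,
                         matrix$col_meta$antibody_name)]
    vals <- cbind(vals, rvals)
    pathways <- c(pathways, pw)
  }

  bin <- ptime$bin_id
  sizes <- as.vector(table(bin))
  bin_means <- rowsum(vals, bin) / sizes
  bin_centers <- as.vector(rowsum(ptime$pseudotime, bin) / sizes)

  fits <- lapply(seq_len(ncol(vals)), function(j) {
    tr <- fit_trend(bin_centers, bin_means[, j], degree)
    tr$antibody_name <- colnames(vals)[j]
    tr
  })
  names(fits) <- colnames(vals)

  co <- t(vapply(fits, `[[`, numeric(degree + 1L), "coefficients"))
  colnames(co) <- paste0("c", 0:degree)
  direction <- vapply(fits, function(f) {
    sign(eval_trend(f, 1) - eval_trend(f, 0))
  }, numeric(1))
  tab <- data.frame(
    antibody_name = colnames(vals),
    pathway_group = pathways,
    co,
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    direction = direction,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(fits = fits, table = tab, bin_centers = bin_centers,
                 bin_means = bin_means),
            class = "scid_trends")
}

#' @export
print.scid_trends <- function(x, ...) {
  cat(sprintf("scid_trends: %d epitopes, %d bins, degree %d\n",
              length(x$fits), length(x$bin_centers),
              length(x$fits[[1]]$coefficients) - 1L))
  invisible(x)
}
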