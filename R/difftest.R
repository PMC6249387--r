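#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the two-sample K-S statistic `D = sup_x |ECDF_a(x) -
#' ECDF_b(x)|` by evaluating both empirical CDFs at the pooled sorted
#' values (which handles ties exactly), and a two-sided p-value from the
#' asymptotic Kolmogorov distribution with the standard effective-sample-
#' size correction `lambda = (sqrt(en) + 0.12 + 0.11 / sqrt(en)) * D`,
#' `en = n_a * n_b / (n_a + n_b)`.
#'
#' @param values_a,values_b Numeric samples (each of length >= 2).
#' @param exact Use the exact permutation distribution of D
#'   ([stats::psmirnov()]) instead of the asymptotic approximation;
#'   only permitted for `n_a * n_b <= 10000` (the group sizes typical
#'   here, 163 vs 57, are comfortably asymptotic).
#' @return List with `d_statistic` (in \[0, 1\]) and `p_value` (in
#'   (0, 1\]).
#' @examples
#' ks_two_sample(rnorm(50), rnorm(50, 1))
#' @export
ks_two_sample <- function(values_a, values_b, exact = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each sample needs at least 2 values (got ", length(values_a),
         " and ", length(values_b), ")")
  }
  if (anyNA(values_a) || anyNA(values_b)) stop("samples must not contain NA")
  pooled <- sort(unique(c(values_a, values_b)))
  d <- max(abs(ecdf(values_a)(pooled) - ecdf(values_b)(pooled)))
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (exact) {
    if (n_a * n_b > 10000) {
      stop("exact K-S p-values are limited to n_a * n_b <= 10000; ",
           "use the asymptotic default")
    }
    p <- stats::psmirnov(d, sizes = c(n_a, n_b), z = c(values_a, values_b),
                         two.sided = TRUE, lower.tail = FALSE)
    return(list(d_statistic = d, p_value = p))
  }
  en <- sqrt(n_a * n_b / (n_a + n_b))
  lambda <- (en + 0.12 + 0.11 / en) * d
  p <- kolmogorov_sf(lambda)
  list(d_statistic = d, p_value = p)
}

# survival function of the Kolmogorov distribution,
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(101L)
  terms <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
  min(1, max(0, 2 * sum(terms)))
}

#' Select dynamic epitopes between sorted populations
#'
#' Tests every antibody column for a distribution difference between the
#' two FACS gate groups (e.g. ITGB1+ vs ITGB1low) with the two-sample K-S
#' test and flags epitopes significant at `alpha` on the raw p-value (no
#' multiple-testing correction in the primary call, matching the
#' p < 0.001 selection rule; Benjamini-Hochberg q-values are reported as
#' an informational column). When trend fits are supplied, each result
#' carries the epitope's pseudo-time direction, and pathways are flagged
#' "concordant" when at least two of their antibodies are significant with
#' agreeing trend directions.
#'
#' @param matrix A `scid_counts` (scaled, by default the state tested).
#' @param alpha Significance threshold on the raw p-value (default 0.001).
#' @param trends Optional `scid_trends` from [trend_all()].
#' @param gate_labels Optional per-cell labels overriding
#'   `matrix$row_meta$gate_label`.
#' @return data.frame with one row per antibody: `antibody_name`,
#'   `d_statistic`, `p_value`, `q_value`, `n_a`, `n_b`, `significant`,
#'   `pathway_group`, `trend_direction`; the concordance summary is in
#'   attribute `"pathways"` (data.frame: `pathway_group`, `n_significant`,
#'   `concordant`).
#' @export
select_dynamic <- function(matrix, alpha = 0.001, trends = NULL,
                           gate_labels = NULL) {
  stopifnot(inherits(matrix, "scid_counts"))
  if (is.null(gate_labels)) gate_labels <- matrix$row_meta$gate_label
  labels <- setdiff(unique(gate_labels), "none")
  if (length(labels) != 2L) {
    stop("need exactly two gate labels among cells; found: ",
         paste(labels, collapse = ", "))
  }
  labels <- sort(labels)
  in_a <- gate_labels == labels[1]
  in_b <- gate_labels == labels[2]
  if (sum(in_a) < 2L || sum(in_b) < 2L) {
    stop("each gate group needs at least 2 cells (",
         labels[1], ": ", sum(in_a), ", ", labels[2], ": ", sum(in_b), ")")
  }

  tests <- lapply(seq_len(ncol(matrix$values)), function(j) {
    ks_two_sample(matrix$values[in_a, j], matrix$values[in_b, j])
  })
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  res <- data.frame(
    antibody_name = colnames(matrix$values),
    d_statistic = vapply(tests, `[[`, numeric(1), "d_statistic"),
    p_value = p,
    q_value = p.adjust(p, method = "BH"),
    n_a = sum(in_a),
    n_b = sum(in_b),
    significant = p < alpha,
    pathway_group = matrix$col_meta$pathway_group %||%
      rep(NA_character_, ncol(matrix$values)),
    trend_direction = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(trends)) {
    idx <- match(res$antibody_name, trends$table$antibody_name)
    res$trend_direction <- trends$table$direction[idx]
  }

  pw <- res[!is.na(res$pathway_group) & nzchar(res$pathway_group), ]
  pathways <- do.call(rbind, lapply(split(pw, pw$pathway_group), function(g) {
    sig <- g[g$significant, ]
    dirs <- sig$trend_direction[!is.na(sig$trend_direction)]
    data.frame(
      pathway_group = g$pathway_group[1],
      n_significant = nrow(sig),
      concordant = nrow(sig) >= 2L && length(dirs) >= 2L &&
        (all(dirs > 0) || all(dirs < 0)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(pathways) <- NULL
  attr(res, "pathways") <- pathways
  attr(res, "alpha") <- alpha
  attr(res, "groups") <- labels
  res
}
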