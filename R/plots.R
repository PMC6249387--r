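utils::globalVariables(c("pseudotime", "bin_mean", "fitted"))

#' Plot binned epitope dynamics with fitted trends
#'
#' Pseudo-time versus per-bin mean for each selected epitope, with the
#' fitted cubic overlaid — the per-pathway dynamics panels of a typical
#' scID-seq analysis.
#'
#' @param trends A `scid_trends` from [trend_all()].
#' @param antibodies Epitopes to show (default: all); a pathway name also
#'   works when the trend table carries pathway groups.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_trends <- function(trends, antibodies = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_trends requires the ggplot2 package")
  }
  stopifnot(inherits(trends, "scid_trends"))
  sel <- names(trends$fits)
  if (!is.null(antibodies)) {
    by_pathway <- trends$table$antibody_name[
      trends$table$pathway_group %in% antibodies]
    sel <- union(intersect(sel, antibodies), by_pathway)
    if (!length(sel)) stop("no epitope or pathway matches: ",
                           paste(antibodies, collapse = ", "))
  }
  pts <- do.call(rbind, lapply(sel, function(a) {
    data.frame(antibody = a, pseudotime = trends$bin_centers,
               bin_mean = trends$fits[[a]]$bin_means)
  }))
  grid <- seq(min(trends$bin_centers), max(trends$bin_centers),
              length.out = 100)
  curves <- do.call(rbind, lapply(sel, function(a) {
    data.frame(antibody = a, pseudotime = grid,
               fitted = eval_trend(trends$fits[[a]], grid))
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = pseudotime)) +
    ggplot2::geom_point(ggplot2::aes(y = bin_mean), size = 1) +
    ggplot2::geom_line(data = curves, ggplot2::aes(y = fitted),
                       color = "#c0392b") +
    ggplot2::facet_wrap(~antibody, scales = "free_y") +
    ggplot2::labs(x = "pseudo-time", y = "bin mean (scaled counts)") +
    ggplot2::theme_minimal(base_size = 10)
}
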