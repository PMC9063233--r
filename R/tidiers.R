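# broom-style tidiers and ggplot2 autoplot methods for the result classes.

#' Tidy an enrichment grid
#'
#' Returns the grid as a plain tibble, optionally restricted to testable
#' cells (those with at least one in-set marker).
#'
#' @param x An `enrich_grid` from [run_grid()].
#' @param tested_only Drop rows with `m_f = 0`? Default `FALSE`.
#' @param ... Unused.
#' @return A tibble with one row per (trait, set) cell.
#' @method tidy enrich_grid
#' @export
tidy.enrich_grid <- function(x, tested_only = FALSE, ...) {
  out <- tibble::as_tibble(x)
  if (tested_only) out <- out[!is.na(out$p_emp), , drop = FALSE]
  out
}

#' One-row summary of an enrichment grid
#'
#' @param x An `enrich_grid` from [run_grid()].
#' @param alpha_fdr FDR threshold for the significance count.
#' @param ... Unused.
#' @return A tibble with `n_traits, n_sets, n_tested, n_untestable,
#'   n_significant, min_q, n_exact`.
#' @method glance enrich_grid
#' @export
glance.enrich_grid <- function(x, alpha_fdr = 0.05, ...) {
  tested <- !is.na(x$p_emp)
  tibble::tibble(
    n_traits = length(unique(x$trait_id)),
    n_sets = length(unique(x$set_id)),
    n_tested = sum(tested),
    n_untestable = sum(!tested),
    n_significant = sum(x$q_fdr[tested] < alpha_fdr),
    min_q = if (any(tested)) min(x$q_fdr[tested]) else NA_real_,
    n_exact = sum(x$exact[tested])
  )
}

#' Plot an enrichment grid as a trait-by-set heat map
#'
#' Tiles are shaded by `-log10(p)`; cells passing the FDR threshold are
#' starred, the conventional display for a GWAS-signal-by-cell-type grid.
#'
#' @param object An `enrich_grid` from [run_grid()].
#' @param alpha_fdr FDR threshold for starring; default 0.05.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrich_grid
#' @export
autoplot.enrich_grid <- function(object, alpha_fdr = 0.05, ...) {
  df <- tidy.enrich_grid(object, tested_only = TRUE)
  df$neglog10_p <- -log10(df$p_emp)
  df$sig <- !is.na(df$q_fdr) & df$q_fdr < alpha_fdr
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set_id, y = .data$trait_id,
                                   fill = .data$neglog10_p)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_text(data = df[df$sig, , drop = FALSE],
                       ggplot2::aes(label = "*"), size = 6, vjust = 0.75) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = expression(-log[10](p))) +
    ggplot2::labs(x = "gene set", y = "trait",
                  caption = sprintf("* FDR < %g", alpha_fdr)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Tidy a module-score table
#'
#' @param x A `module_scores` from [module_score()].
#' @param ... Unused.
#' @return A tibble `module, group, score`.
#' @method tidy module_scores
#' @export
tidy.module_scores <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "gene_scores") <- NULL
  out
}

#' Plot module trajectories over the time course
#'
#' One line per module of scaled score against ordered group (time
#' point), the line-graph companion of a scaled-expression heat map.
#'
#' @param object A `module_scores` from [module_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot module_scores
#' @export
autoplot.module_scores <- function(object, ...) {
  df <- tidy.module_scores(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score,
                                   color = .data$module,
                                   group = .data$module)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "time point", y = "scaled module score",
                  color = "module") +
    ggplot2::theme_minimal()
}

#' Bar chart of cell-cycle indices
#'
#' @param ci A tibble from [cycle_index()].
#' @param x Name of the grouping column to place on the x axis; defaults
#'   to the first grouping column.
#' @param fill Optional second grouping column mapped to fill.
#' @return A ggplot object.
#' @export
plot_cycle_index <- function(ci, x = NULL, fill = NULL) {
  group_cols <- setdiff(names(ci),
                        c("n_cells", "n_proliferating", "cycle_index"))
  x <- x %||% group_cols[1]
  p <- if (is.null(fill)) {
    ggplot2::ggplot(ci, ggplot2::aes(x = .data[[x]], y = .data$cycle_index))
  } else {
    ggplot2::ggplot(ci, ggplot2::aes(x = .data[[x]], y = .data$cycle_index,
                                     fill = .data[[fill]]))
  }
  p + ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = x, y = "cell-cycle index") +
    ggplot2::theme_minimal()
}
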