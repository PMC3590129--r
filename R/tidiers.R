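#' Tidy a differential-expression fit
#'
#' @param x a `mirkd_de` from [run_diffexp()].
#' @param ... unused.
#' @return tibble with one row per tested miR: normalized condition means,
#'   fold change, VST log2 fold change, dispersion, raw and BH-adjusted p.
#' @export
tidy.mirkd_de <- function(x, ...) {
  x$results
}

#' One-row summary of a differential-expression fit
#'
#' @inheritParams tidy.mirkd_de
#' @return tibble: `n_tested`, `n_dropped_zero_rows`, `n_sig_raw_05`,
#'   `n_sig_adj_05`, `median_dispersion`.
#' @export
glance.mirkd_de <- function(x, ...) {
  tibble(
    n_tested = nrow(x$results),
    n_dropped_zero_rows = x$settings$n_dropped_zero_rows,
    n_sig_raw_05 = sum(x$results$p_raw < 0.05),
    n_sig_adj_05 = sum(x$results$p_adj < 0.05),
    median_dispersion = median(x$results$dispersion)
  )
}

#' MA-style plot of a differential-expression fit
#'
#' Mean normalized count (log10) against the VST log2 fold change, with
#' BH-significant miRs highlighted.
#'
#' @param object a `mirkd_de`.
#' @param alpha BH significance threshold for highlighting.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mirkd_de <- function(object, alpha = 0.05, ...) {
  d <- object$results %>%
    mutate(mean_norm = (.data$mean_norm_a + .data$mean_norm_b) / 2,
           significant = .data$p_adj < alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_norm,
                                  y = .data$vst_log2fc,
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean normalized count",
                  y = "VST log2 fold change (acute / convalescent)",
                  colour = sprintf("BH < %.02g", alpha)) +
    ggplot2::theme_minimal()
}

#' Tidy an enrichment result
#'
#' @param x a `mirkd_enrichment` from [run_enrichment()].
#' @param ... unused.
#' @return plain tibble of per-pathway results.
#' @export
tidy.mirkd_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mirkd_enrichment")
  as_tibble(out)
}

#' One-row summary of an enrichment run
#'
#' @inheritParams tidy.mirkd_enrichment
#' @return tibble: `n_pathways_tested`, `n_universe`,
#'   `n_targets_in_universe`, `top_pathway`, `top_p`.
#' @export
glance.mirkd_enrichment <- function(x, ...) {
  tibble(
    n_pathways_tested = nrow(x),
    n_universe = attr(x, "n_universe"),
    n_targets_in_universe = attr(x, "n_targets_in_universe"),
    top_pathway = if (nrow(x) > 0) x$pathway_id[1] else NA_character_,
    top_p = if (nrow(x) > 0) x$p[1] else NA_real_
  )
}

#' Bar chart of pathway enrichment
#'
#' @param object a `mirkd_enrichment`.
#' @param top number of top pathways to display.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mirkd_enrichment <- function(object, top = 15, ...) {
  d <- tidy(object) %>%
    head(top) %>%
    mutate(pathway_id = factor(.data$pathway_id,
                               levels = rev(.data$pathway_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p),
                                  y = .data$pathway_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL) +
    ggplot2::theme_minimal()
}
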