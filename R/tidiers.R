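#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a burden result table
#'
#' Broom-style view of a `rvp_burden` table: one row per (gene, test) with
#' `estimate` (the case carrier frequency), `null.value` (the control
#' carrier frequency used as the null), `statistic` (the carrier count),
#' `p.value` (raw) and `adj.p.value` (corrected).
#'
#' @param x A `rvp_burden` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rvp_burden
#' @export
tidy.rvp_burden <- function(x, ...) {
  as_tibble(x) %>%
    mutate(
      estimate = .data$k_case / .data$n_case,
      null.value = .data$p0,
      statistic = .data$k_case,
      p.value = .data$raw_p,
      adj.p.value = .data$corrected_p
    ) %>%
    select(dplyr::all_of(c("gene", "test", "estimate", "null.value",
                           "statistic", "p.value", "adj.p.value",
                           "significant")))
}

#' One-row summary of a burden analysis
#'
#' @param x A `rvp_burden` tibble.
#' @param ... Unused.
#' @return A tibble with gene counts and significant hits per test.
#' @method glance rvp_burden
#' @export
glance.rvp_burden <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$test) %>%
    summarise(
      n_genes = dplyr::n_distinct(.data$gene),
      n_significant = sum(.data$significant),
      min_corrected_p = min(.data$corrected_p),
      .groups = "drop"
    )
}

#' Plot a burden analysis
#'
#' Per-gene -log10 p-values, faceted by test, with the significance level
#' drawn as a dashed line (Bonferroni-corrected p for the carrier-burden
#' test, raw p for the overabundance test, matching how each is assessed).
#'
#' @param object A `rvp_burden` tibble.
#' @param alpha Significance level to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rvp_burden
#' @export
autoplot.rvp_burden <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object) %>%
    mutate(neglog_p = -log10(pmax(.data$corrected_p, .Machine$double.xmin)))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene, .data$neglog_p),
                                   y = .data$neglog_p,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~test, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "-log10 p (as assessed)", fill = "significant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-sample coverage QC
#'
#' Histogram of per-sample fractions of panel bases at the QC depth, with
#' the pass threshold marked.
#'
#' @param qc Output of [sample_coverage_qc()].
#' @param config A [threshold_config()] (for the threshold line).
#' @return A ggplot object.
#' @export
plot_coverage_qc <- function(qc, config = threshold_config()) {
  ggplot2::ggplot(qc, ggplot2::aes(x = .data$fraction_at_depth,
                                   fill = .data$passed)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = config$qc_fraction, linetype = "dashed") +
    ggplot2::labs(x = paste0("fraction of panel bases at >=", config$qc_depth, "x"),
                  y = "samples", fill = "passed QC") +
    ggplot2::theme_minimal()
}

#' Tidy a pipeline run
#'
#' Returns the tiered variant table of a [run_pipeline()] result.
#'
#' @param x A `pipeline_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pipeline_run
#' @export
tidy.pipeline_run <- function(x, ...) as_tibble(x$variants)

#' One-row summary of a pipeline run
#'
#' @param x A `pipeline_run`.
#' @param ... Unused.
#' @return A tibble with stage counts and the yield summary when present.
#' @method glance pipeline_run
#' @export
glance.pipeline_run <- function(x, ...) {
  base <- tibble(
    n_variants = nrow(x$variants),
    n_qc_fail = if (is.null(x$qc)) NA_integer_ else sum(!x$qc$passed),
    n_burden_genes = if (is.null(x$burden)) NA_integer_ else
      dplyr::n_distinct(x$burden$gene)
  )
  if (!is.null(x$yield)) bind_cols(base, x$yield) else base
}
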