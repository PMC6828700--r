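#' Read a per-base depth table
#'
#' The de-facto `samtools depth` layout: three tab-separated columns
#' `chrom`, `pos` (1-based), `depth`, no header, one file per sample (or a
#' 4-column variant with `sample_id` first).
#'
#' @param path Path to the depth file.
#' @param sample_id Sample identifier to attach when the file has 3 columns.
#' @return Tibble with columns `sample_id`, `chrom`, `pos`, `depth`.
#' @export
read_depth_table <- function(path, sample_id = NULL) {
  df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols())
  if (ncol(df) == 3) {
    if (is.null(sample_id)) abort("3-column depth file needs `sample_id`")
    df <- tibble(sample_id = sample_id, chrom = as.character(df[[1]]),
                 pos = as.integer(df[[2]]), depth = as.integer(df[[3]]))
  } else if (ncol(df) >= 4) {
    df <- tibble(sample_id = as.character(df[[1]]),
                 chrom = as.character(df[[2]]),
                 pos = as.integer(df[[3]]), depth = as.integer(df[[4]]))
  } else {
    abort("depth file must have 3 or 4 tab-separated columns")
  }
  if (any(df$depth < 0, na.rm = TRUE)) abort("negative depth")
  df
}

#' Sample-level coverage quality control
#'
#' Applies the study's sample QC rule: a sample fails when strictly less
#' than `qc_fraction` (default 50%) of targeted panel bases are covered by
#' at least `qc_depth` (default 20) reads. A sample at exactly the fraction
#' threshold passes, since only "< 50%" fails. Panel bases absent from the
#' depth table count as depth 0.
#'
#' @param depths Tibble of per-base depths (`sample_id`, `chrom`, `pos`,
#'   `depth`), restricted to one or more samples; positions outside the
#'   panel are an error.
#' @param panel A [panel_design()].
#' @param config An [threshold_config()].
#' @return Tibble with one row per sample: `sample_id`, `fraction_at_depth`,
#'   `passed`.
#' @export
#' @examples
#' pan <- panel_design(tibble::tibble(chrom = "1", start = 0, end = 10,
#'                                    gene = "G1"))
#' d <- tibble::tibble(sample_id = "S1", chrom = "1", pos = 1:10, depth = 25L)
#' sample_coverage_qc(d, pan)
sample_coverage_qc <- function(depths, panel, config = threshold_config()) {
  stopifnot(inherits(panel, "panel_design"))
  total <- panel_span(panel)
  if (total == 0) abort("empty panel")
  depths <- as_tibble(depths)
  if (nrow(depths) > 0) {
    inside <- in_panel(depths$chrom, depths$pos, panel)
    if (!all(inside)) {
      abort(paste0(sum(!inside), " depth position(s) outside panel intervals"))
    }
  }
  depths %>%
    group_by(.data$sample_id) %>%
    summarise(
      fraction_at_depth = sum(.data$depth >= .env$config$qc_depth) / .env$total,
      .groups = "drop"
    ) %>%
    mutate(passed = .data$fraction_at_depth >= .env$config$qc_fraction)
}

#' Cohort-level coverage summary
#'
#' Summarises per-sample fractions-at-depth across a cohort (median via the
#' midpoint-of-two rule for even n, i.e. `stats::median`), counts QC passes
#' and failures, and reports per-interval and per-gene covered fractions
#' aggregated over samples (the study does not state whether its per-region
#' statistic is per interval or per gene, so both are returned).
#'
#' @inheritParams sample_coverage_qc
#' @return A list with `samples` (per-sample QC tibble), `overall` (tibble
#'   with `median`, `min`, `max` fraction, `n_pass`, `n_fail`),
#'   `per_interval` and `per_gene` (mean covered fraction across samples).
#' @export
cohort_coverage_summary <- function(depths, panel, config = threshold_config()) {
  qc <- sample_coverage_qc(depths, panel, config)
  if (nrow(qc) == 0) abort("no samples in depth table")
  overall <- tibble(
    median = median(qc$fraction_at_depth),
    min = min(qc$fraction_at_depth),
    max = max(qc$fraction_at_depth),
    n_pass = sum(qc$passed),
    n_fail = sum(!qc$passed)
  )
  n_samp <- nrow(qc)
  iv <- panel$intervals %>%
    mutate(interval_id = paste0(.data$chrom, ":", .data$start, "-", .data$end),
           width = .data$end - .data$start)
  pos_map <- tibble(
    chrom = rep(iv$chrom, iv$width),
    pos = unlist(purrr::map2(iv$start, iv$end, ~ seq(.x + 1L, .y))),
    interval_id = rep(iv$interval_id, iv$width)
  )
  covered_counts <- depths %>%
    filter(.data$depth >= .env$config$qc_depth) %>%
    count(.data$chrom, .data$pos, name = "n_covered") %>%
    inner_join(pos_map, by = c("chrom", "pos"))
  per_interval <- iv %>%
    left_join(
      covered_counts %>%
        group_by(.data$interval_id) %>%
        summarise(n_covered = sum(.data$n_covered), .groups = "drop"),
      by = "interval_id"
    ) %>%
    mutate(
      n_covered = dplyr::coalesce(.data$n_covered, 0),
      fraction = .data$n_covered / (.data$width * n_samp)
    ) %>%
    select(dplyr::all_of(c("interval_id", "gene", "width", "fraction")))
  per_gene <- per_interval %>%
    group_by(.data$gene) %>%
    summarise(
      fraction = sum(.data$fraction * .data$width) / sum(.data$width),
      .groups = "drop"
    )
  per_interval <- per_interval %>% select(-dplyr::all_of("width"))
  list(samples = qc, overall = overall,
       per_interval = per_interval, per_gene = per_gene)
}
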