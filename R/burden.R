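#' Exact binomial upper-tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, evaluated through the survival
#' form of the binomial distribution function (numerically stable for the
#' tiny tail probabilities the burden test produces). `k <= 0` returns 1
#' exactly (the whole sample space); `k > n` returns 0 exactly (the empty
#' event).
#'
#' @param k Observed count (vectorised).
#' @param n Number of trials.
#' @param p Success probability in `[0, 1]`.
#' @return Upper-tail probabilities.
#' @export
#' @examples
#' binomial_tail(2, 10, 0.1) # 1 - P(0) - P(1)
binomial_tail <- function(k, n, p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p must be in [0, 1]")
  if (any(n < 0, na.rm = TRUE)) abort("n must be non-negative")
  out <- pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
  out[k <= 0] <- 1
  out[k > n] <- 0
  out
}

#' Count carriers of qualifying variants per gene
#'
#' A carrier is an individual with at least one qualifying variant in the
#' gene, counted once regardless of variant count or zygosity (het,
#' homozygous alternate and hemizygous all count equally - "binary"
#' carrier status).
#'
#' @param dataset A `cohort_dataset`.
#' @param purpose Qualifying rule, as in [qualifying_filter()].
#' @param config A [threshold_config()].
#' @param controls Control `cohort_dataset` supplying the control MAF for
#'   the `carrier_burden` rule (ignored for `overabundance`). When the
#'   dataset itself is the control cohort, pass it as its own `controls`.
#' @param genes Genes to count; default every panel gene. A gene off the
#'   panel is an error.
#' @return Tibble `gene`, `carriers`.
#' @export
count_carriers <- function(dataset,
                           purpose = c("carrier_burden", "overabundance"),
                           config = threshold_config(),
                           controls = NULL, genes = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  purpose <- match.arg(purpose)
  panel_genes <- dataset$panel$genes$gene
  if (is.null(genes)) genes <- panel_genes
  off <- setdiff(genes, panel_genes)
  if (length(off) > 0) {
    abort(paste0("gene(s) not in panel: ", paste(head(off, 5), collapse = ", ")))
  }
  v <- dataset$variants
  if (purpose == "carrier_burden") {
    if (is.null(controls)) {
      abort("carrier_burden counting needs the control dataset for MAF")
    }
    v <- attach_control_maf(v, controls)
  }
  v <- v[qualifying_filter(v, purpose, config), , drop = FALSE]
  counts <- v %>%
    filter(.data$gene %in% .env$genes) %>%
    group_by(.data$gene) %>%
    summarise(carriers = dplyr::n_distinct(.data$sample_id), .groups = "drop")
  tibble(gene = genes) %>%
    left_join(counts, by = "gene") %>%
    mutate(carriers = as.integer(dplyr::coalesce(.data$carriers, 0L))) %>%
    arrange(.data$gene)
}

#' Carrier-burden test with Bonferroni correction
#'
#' The significance of observing `k` carriers among `n_case` cases when the
#' control carrier frequency is `p0`: the exact binomial upper tail
#' `P(X >= k)` under `Binomial(n_case, p0)`, multiplied by the number of
#' genes on the panel (capped at 1). Genome-wide significance is declared
#' when the corrected p-value is below `alpha`. A zero `p0` with observed
#' carriers yields a raw p of 0 and is flagged `degenerate`.
#'
#' @param k Case carrier count (vectorised over genes).
#' @param n_case Number of cases.
#' @param p0 Control carrier frequency in `[0, 1]`.
#' @param G Bonferroni divisor (number of genes tested), `>= 1`.
#' @param alpha Significance level.
#' @param gene Optional gene labels.
#' @return Tibble with class `rvp_burden`: `gene`, `test`, `k_case`,
#'   `n_case`, `p0`, `raw_p`, `corrected_p`, `significant`, `degenerate`.
#' @export
#' @examples
#' carrier_burden_test(k = 3, n_case = 271, p0 = 2e-4, G = 112)
carrier_burden_test <- function(k, n_case, p0, G, alpha = 0.05, gene = NULL) {
  if (any(G < 1)) abort("Bonferroni divisor G must be >= 1")
  raw <- binomial_tail(k, n_case, p0)
  res <- tibble(
    gene = if (is.null(gene)) NA_character_ else gene,
    test = "carrier_burden",
    k_case = as.integer(k),
    n_case = as.integer(n_case),
    p0 = p0,
    raw_p = raw,
    corrected_p = pmin(1, raw * G),
    significant = pmin(1, raw * G) < alpha,
    degenerate = p0 == 0 & k > 0
  )
  class(res) <- c("rvp_burden", class(res))
  res
}

#' Exact two-tailed binomial overabundance test
#'
#' Compares the observed number of case carriers of rare, likely
#' deleterious variants with the frequency expected from controls. The
#' expected frequency is `m_ctrl / n_ctrl`; when no control carries such a
#' variant, a 0.5-count continuity fallback (`0.5 / n_ctrl`) avoids a
#' degenerate null (configurable). The two-tailed p-value uses the
#' small-p (minimum-likelihood) method: the sum of `Binomial(n_case, p)`
#' probabilities over every outcome no more likely than the observed one -
#' the same convention as [stats::binom.test()]. Significance is assessed
#' per test at `alpha` with no multiplicity correction, matching how the
#' source analysis applied it.
#'
#' @param k_case Observed case carrier count (vectorised).
#' @param n_case Number of cases.
#' @param m_ctrl Control carrier count.
#' @param n_ctrl Number of controls (`> 0`).
#' @param config A [threshold_config()] (supplies `alpha` and the
#'   pseudo-count switch).
#' @param gene Optional gene labels.
#' @return Tibble with class `rvp_burden`: `gene`, `test`, `k_case`,
#'   `n_case`, `m_ctrl`, `n_ctrl`, `p0`, `raw_p`, `corrected_p` (equal to
#'   `raw_p`; the study applied alpha per test), `significant`.
#' @export
#' @examples
#' overabundance_test(k_case = 8, n_case = 271, m_ctrl = 2, n_ctrl = 503)
overabundance_test <- function(k_case, n_case, m_ctrl, n_ctrl,
                               config = threshold_config(), gene = NULL) {
  if (any(n_ctrl == 0)) abort("n_ctrl must be positive")
  if (any(m_ctrl > n_ctrl) || any(k_case > n_case)) {
    abort("carrier counts cannot exceed cohort sizes")
  }
  if (any(c(k_case, m_ctrl) < 0)) abort("counts must be non-negative")
  n <- length(k_case)
  m_ctrl <- rep_len(m_ctrl, n)
  n_ctrl <- rep_len(n_ctrl, n)
  n_case <- rep_len(n_case, n)
  p0 <- m_ctrl / n_ctrl
  if (config$ctrl_pseudo_count) {
    p0[m_ctrl == 0] <- 0.5 / n_ctrl[m_ctrl == 0]
  }
  raw <- vapply(seq_len(n), function(i) {
    two_tailed_binom_p(k_case[i], n_case[i], p0[i])
  }, numeric(1))
  res <- tibble(
    gene = if (is.null(gene)) NA_character_ else gene,
    test = "overabundance",
    k_case = as.integer(k_case),
    n_case = as.integer(n_case),
    m_ctrl = as.integer(m_ctrl),
    n_ctrl = as.integer(n_ctrl),
    p0 = p0,
    raw_p = raw,
    corrected_p = raw,
    significant = raw < config$alpha
  )
  class(res) <- c("rvp_burden", class(res))
  res
}

# Small-p two-tailed binomial p-value: sum of pmf over outcomes with
# pmf(x) <= pmf(k) (relative tolerance guards against floating-point ties).
two_tailed_binom_p <- function(k, n, p) {
  if (p == 0) return(if (k == 0) 1 else 0)
  if (p == 1) return(if (k == n) 1 else 0)
  d <- dbinom(0:n, n, p)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

#' Run both gene-level burden analyses over a case/control pair
#'
#' For every panel gene with at least one qualifying variant in either
#' cohort, computes the Bonferroni-corrected carrier-burden test (control
#' carrier frequency taken from the control cohort itself) and the exact
#' two-tailed overabundance test. Results are sorted by corrected p-value,
#' then gene.
#'
#' @param cases,controls `cohort_dataset`s sharing the same panel genes.
#' @param config A [threshold_config()]; a `NULL` `bonferroni_genes`
#'   resolves to the panel gene count.
#' @return A `rvp_burden` tibble with one row per (gene, test).
#' @export
run_burden_analysis <- function(cases, controls, config = threshold_config()) {
  stopifnot(inherits(cases, "cohort_dataset"), inherits(controls, "cohort_dataset"))
  shared <- intersect(cases$panel$genes$gene, controls$panel$genes$gene)
  if (length(shared) == 0) abort("case and control panels share no genes")
  n_case <- sum(cases$samples$role == "case")
  n_ctrl <- nrow(controls$samples)
  G <- bonferroni_n(config, cases$panel)

  cb_case <- count_carriers(cases, "carrier_burden", config, controls = controls,
                            genes = shared)
  cb_ctrl <- count_carriers(controls, "carrier_burden", config,
                            controls = controls, genes = shared)
  ov_case <- count_carriers(cases, "overabundance", config, genes = shared)
  ov_ctrl <- count_carriers(controls, "overabundance", config, genes = shared)

  any_variant <- union(
    unique(cases$variants$gene), unique(controls$variants$gene)
  )
  keep <- intersect(shared, any_variant)
  cb <- cb_case %>%
    filter(.data$gene %in% keep) %>%
    left_join(cb_ctrl %>% rename(m_ctrl = "carriers"), by = "gene")
  cb_res <- carrier_burden_test(
    k = cb$carriers, n_case = n_case, p0 = cb$m_ctrl / n_ctrl,
    G = G, alpha = config$alpha, gene = cb$gene
  )
  ov <- ov_case %>%
    filter(.data$gene %in% keep) %>%
    left_join(ov_ctrl %>% rename(m_ctrl = "carriers"), by = "gene")
  ov_res <- overabundance_test(
    k_case = ov$carriers, n_case = n_case, m_ctrl = ov$m_ctrl,
    n_ctrl = n_ctrl, config = config, gene = ov$gene
  )
  res <- bind_rows(cb_res, ov_res) %>%
    arrange(.data$corrected_p, .data$gene, .data$test)
  class(res) <- c("rvp_burden", "tbl_df", "tbl", "data.frame")
  res
}

#' Write a burden report
#'
#' Tab-separated (full double precision) and JSON renderings of a burden
#' result table.
#'
#' @param burden A `rvp_burden` tibble.
#' @param path Output path (`.tsv`; a `.json` sibling is written too).
#' @return `path`, invisibly.
#' @export
write_burden_report <- function(burden, path) {
  readr::write_tsv(as_tibble(burden), path)
  jsonlite::write_json(as_tibble(burden),
                       sub("\\.tsv$", ".json", path),
                       digits = NA, na = "null")
  invisible(path)
}
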