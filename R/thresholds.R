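#' Analysis threshold configuration
#'
#' Collects every numeric cut-off used by the pipeline in one validated
#' object, so that a run can be described completely by its configuration.
#' Defaults follow the published panel analysis this package reimplements:
#' hard filtering at ExAC frequency < 1e-4 and 1000 Genomes frequency < 1e-3,
#' conservation GERP++ > 4, deleteriousness CADD Phred > 20 where available;
#' research-variant prioritisation at MTR centile < 25; gene intolerance when
#' at least 3 of 5 constraint criteria are met (DOMINO > 0.5, HI percentile
#' < 25, RVIS percentile < 25, pLI > 0.9, missense Z > 2); coverage QC at
#' >= 50% of panel bases covered by >= 20 reads; burden tests on qualifying
#' variants with MAF < 1e-3 at alpha = 0.05, Bonferroni-corrected over the
#' number of panel genes.
#'
#' @param exac_max ExAC allele-frequency upper bound (exclusive) for the hard
#'   filter.
#' @param kg_max 1000 Genomes allele-frequency upper bound (exclusive).
#' @param gerp_min GERP++ lower bound (exclusive); missing GERP is treated as
#'   not applicable.
#' @param cadd_min CADD Phred lower bound (exclusive).
#' @param cadd_policy `"strict"` requires the CADD criterion whenever a score
#'   is present; `"advisory"` records the outcome without letting it fail the
#'   variant (some validated variants in the source study scored just below
#'   20).
#' @param mtr_centile_max MTR centile upper bound (exclusive) for the
#'   prioritisation vote.
#' @param domino_min,hi_pct_max,rvis_pct_max,pli_min,z_missense_min Gene
#'   intolerance criterion cut-offs.
#' @param min_criteria Number of intolerance criteria (out of 5) that must be
#'   met.
#' @param qc_depth Read depth defining a "covered" base.
#' @param qc_fraction Minimum fraction of panel bases at `qc_depth` for a
#'   sample to pass QC (a sample fails only when strictly below).
#' @param burden_maf_max Control-cohort MAF upper bound (exclusive) for
#'   carrier-burden qualifying variants.
#' @param alpha Significance level for both burden tests.
#' @param bonferroni_genes Number of tests for the Bonferroni correction;
#'   `NULL` means "use the panel gene count" and is resolved at test time.
#' @param ctrl_pseudo_count Use a 0.5-count continuity fallback when the
#'   control carrier count is zero in the overabundance test.
#'
#' @return An object of class `rvp_thresholds` (a validated named list).
#' @seealso [read_threshold_config()]
#' @export
#' @examples
#' cfg <- threshold_config()
#' cfg$cadd_min
threshold_config <- function(exac_max = 1e-4,
                             kg_max = 1e-3,
                             gerp_min = 4,
                             cadd_min = 20,
                             cadd_policy = c("strict", "advisory"),
                             mtr_centile_max = 25,
                             domino_min = 0.5,
                             hi_pct_max = 25,
                             rvis_pct_max = 25,
                             pli_min = 0.9,
                             z_missense_min = 2,
                             min_criteria = 3,
                             qc_depth = 20,
                             qc_fraction = 0.5,
                             burden_maf_max = 1e-3,
                             alpha = 0.05,
                             bonferroni_genes = NULL,
                             ctrl_pseudo_count = TRUE) {
  cadd_policy <- match.arg(cadd_policy)
  cfg <- list(
    exac_max = exac_max, kg_max = kg_max, gerp_min = gerp_min,
    cadd_min = cadd_min, cadd_policy = cadd_policy,
    mtr_centile_max = mtr_centile_max,
    domino_min = domino_min, hi_pct_max = hi_pct_max,
    rvis_pct_max = rvis_pct_max, pli_min = pli_min,
    z_missense_min = z_missense_min, min_criteria = min_criteria,
    qc_depth = qc_depth, qc_fraction = qc_fraction,
    burden_maf_max = burden_maf_max, alpha = alpha,
    bonferroni_genes = bonferroni_genes,
    ctrl_pseudo_count = isTRUE(ctrl_pseudo_count)
  )
  validate_thresholds(cfg)
  structure(cfg, class = "rvp_thresholds")
}

validate_thresholds <- function(cfg) {
  num <- c("exac_max", "kg_max", "gerp_min", "cadd_min", "mtr_centile_max",
           "domino_min", "hi_pct_max", "rvis_pct_max", "pli_min",
           "z_missense_min", "min_criteria", "qc_depth", "qc_fraction",
           "burden_maf_max", "alpha")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort(paste0("threshold `", f, "` must be a single positive number"))
    }
  }
  for (f in c("exac_max", "kg_max", "burden_maf_max", "domino_min", "pli_min",
              "qc_fraction", "alpha")) {
    if (cfg[[f]] > 1) abort(paste0("threshold `", f, "` must be <= 1"))
  }
  if (!is.null(cfg$bonferroni_genes) &&
      (!is.numeric(cfg$bonferroni_genes) || cfg$bonferroni_genes < 1)) {
    abort("`bonferroni_genes` must be NULL or a number >= 1")
  }
  invisible(cfg)
}

#' Read a threshold configuration from YAML or JSON
#'
#' The file mirrors [threshold_config()] field for field; absent fields keep
#' their defaults and unknown fields are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `rvp_thresholds` object.
#' @export
read_threshold_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(threshold_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("unknown threshold field(s): ", paste(bad, collapse = ", ")))
  }
  do.call(threshold_config, vals)
}

#' @export
print.rvp_thresholds <- function(x, ...) {
  cat("<rvp_thresholds>\n")
  for (f in names(x)) {
    cat(sprintf("  %-18s %s\n", f,
                if (is.null(x[[f]])) "panel gene count" else format(x[[f]])))
  }
  invisible(x)
}

# Resolve the Bonferroni divisor against a panel.
bonferroni_n <- function(config, panel) {
  if (!is.null(config$bonferroni_genes)) return(config$bonferroni_genes)
  panel_n_genes(panel)
}
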