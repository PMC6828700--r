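crit_pass <- "pass"
crit_fail <- "fail"
crit_na <- "not_applicable"

#' Hard-filter annotated variants
#'
#' The first stage of variant prioritisation: population-frequency rarity
#' (ExAC < `exac_max`, 1000 Genomes < `kg_max`), evolutionary conservation
#' (GERP++ > `gerp_min`) and predicted deleteriousness (CADD Phred >
#' `cadd_min`, applied "where available"). Verdict semantics:
#'
#' * A missing population frequency passes the frequency criterion - an
#'   unobserved variant is novel, which is the rarest state of all.
#' * A missing GERP or CADD score makes that criterion `not_applicable`.
#' * Under `cadd_policy = "strict"` every applicable criterion must pass;
#'   under `"advisory"` the CADD outcome is recorded in the verdict but
#'   does not fail the variant.
#'
#' The per-criterion outcomes are returned alongside the overall verdict so
#' that the decision can be reconstructed exactly; `reasons` collapses the
#' failing criteria into a single string.
#'
#' @param variants Data frame with (at least) the annotation columns
#'   `exac_af`, `kg_af`, `gerp`, `cadd_phred`. All other columns pass
#'   through.
#' @param config A [threshold_config()].
#' @return The input tibble with appended columns `crit_exac`, `crit_kg`,
#'   `crit_gerp`, `crit_cadd` (each `"pass"`/`"fail"`/`"not_applicable"`),
#'   `hard_pass` (logical) and `reasons` (character).
#' @export
#' @examples
#' hard_filter(tibble::tibble(exac_af = 0, kg_af = 0, gerp = 5.67,
#'                            cadd_phred = 26.3))$hard_pass
hard_filter <- function(variants, config = threshold_config()) {
  variants <- as_tibble(variants)
  out <- variants %>%
    mutate(
      crit_exac = if_else(is.na(.data$exac_af) |
                            .data$exac_af < .env$config$exac_max,
                          crit_pass, crit_fail),
      crit_kg = if_else(is.na(.data$kg_af) | .data$kg_af < .env$config$kg_max,
                        crit_pass, crit_fail),
      crit_gerp = case_when(
        is.na(.data$gerp) ~ crit_na,
        .data$gerp > .env$config$gerp_min ~ crit_pass,
        TRUE ~ crit_fail
      ),
      crit_cadd = case_when(
        is.na(.data$cadd_phred) ~ crit_na,
        .data$cadd_phred > .env$config$cadd_min ~ crit_pass,
        TRUE ~ crit_fail
      )
    )
  required <- c("crit_exac", "crit_kg", "crit_gerp")
  if (config$cadd_policy == "strict") required <- c(required, "crit_cadd")
  fail_mat <- sapply(required, function(cc) out[[cc]] == crit_fail)
  fail_mat <- matrix(fail_mat, nrow = nrow(out),
                     dimnames = list(NULL, required))
  reason_labels <- c(
    crit_exac = "population frequency (ExAC)",
    crit_kg = "population frequency (1000G)",
    crit_gerp = "conservation (GERP)",
    crit_cadd = "deleteriousness (CADD)"
  )
  out$hard_pass <- if (nrow(out) == 0) logical(0) else rowSums(fail_mat) == 0
  out$reasons <- apply(
    cbind(fail_mat,
          if (config$cadd_policy == "advisory") {
            matrix(out$crit_cadd == crit_fail, ncol = 1,
                   dimnames = list(NULL, "crit_cadd"))
          }),
    1L,
    function(f) paste(reason_labels[names(f)[f]], collapse = "; ")
  )
  if (nrow(out) == 0) out$reasons <- character(0)
  out
}

#' Qualifying-variant rules for the burden tests
#'
#' The two burden statistics count carriers of *qualifying* variants under
#' different rules:
#'
#' * `purpose = "carrier_burden"`: protein-altering consequence (missense,
#'   stop gain, splice or other loss-of-function) and control-cohort MAF
#'   strictly below `burden_maf_max` (default 0.001). The `control_maf`
#'   column must be present (see [control_allele_frequency()]); a missing
#'   `control_maf` value counts as 0 (variant unseen in controls).
#' * `purpose = "overabundance"`: ExAC frequency < `exac_max`, 1000 Genomes
#'   frequency < `kg_max` and CADD Phred > `cadd_min`. Missing frequencies
#'   count as 0 (novel); a missing CADD score disqualifies, because this
#'   rule names no exemption.
#'
#' @param variants Data frame with the columns the chosen rule needs.
#' @param purpose `"carrier_burden"` or `"overabundance"`.
#' @param config A [threshold_config()].
#' @return Logical vector, one element per row.
#' @export
qualifying_filter <- function(variants,
                              purpose = c("carrier_burden", "overabundance"),
                              config = threshold_config()) {
  if (length(purpose) != 1 ||
      !purpose %in% c("carrier_burden", "overabundance")) {
    purpose <- tryCatch(match.arg(purpose),
                        error = function(e) abort("unknown purpose"))
  }
  variants <- as_tibble(variants)
  if (purpose == "carrier_burden") {
    if (!"control_maf" %in% names(variants)) {
      abort("carrier_burden rule needs a `control_maf` column")
    }
    maf <- dplyr::coalesce(variants$control_maf, 0)
    variants$consequence %in% c("missense", "stop_gain", "splice", "other_lof") &
      maf < config$burden_maf_max
  } else {
    exac <- dplyr::coalesce(variants$exac_af, 0)
    kg <- dplyr::coalesce(variants$kg_af, 0)
    exac < config$exac_max & kg < config$kg_max &
      !is.na(variants$cadd_phred) & variants$cadd_phred > config$cadd_min
  }
}

#' Control-cohort allele frequency per variant
#'
#' Computes the allele frequency of every distinct (chrom, pos, ref, alt)
#' key in a control dataset: allele count (het = 1, hom_alt = 2, hemi = 1)
#' over `2 * n_controls` chromosomes (a simplification that ignores the
#' haploid male X, acceptable at the rarity thresholds in play). Used as
#' the MAF in the carrier-burden qualifying rule.
#'
#' @param controls A `cohort_dataset` of controls.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `control_maf`.
#' @export
control_allele_frequency <- function(controls) {
  stopifnot(inherits(controls, "cohort_dataset"))
  n_chrom <- 2 * nrow(controls$samples)
  controls$variants %>%
    mutate(ac = c(het = 1, hom_alt = 2, hemi = 1)[.data$genotype]) %>%
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
    summarise(control_maf = sum(.data$ac) / .env$n_chrom, .groups = "drop")
}

# Attach control_maf to a variant table (0 when unseen in controls).
attach_control_maf <- function(variants, controls) {
  af <- control_allele_frequency(controls)
  variants %>%
    left_join(af, by = c("chrom", "pos", "ref", "alt")) %>%
    mutate(control_maf = dplyr::coalesce(.data$control_maf, 0))
}

#' Write a long-format filter report
#'
#' One row per (variant, criterion) with the outcome, plus the overall
#' verdict, tab-separated.
#'
#' @param verdicts Output of [hard_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(verdicts, path) {
  long <- verdicts %>%
    select(dplyr::any_of(c(variant_key_cols, "gene",
                           "crit_exac", "crit_kg", "crit_gerp", "crit_cadd",
                           "hard_pass"))) %>%
    tidyr::pivot_longer(
      dplyr::all_of(c("crit_exac", "crit_kg", "crit_gerp", "crit_cadd")),
      names_to = "criterion", values_to = "outcome"
    ) %>%
    mutate(criterion = sub("^crit_", "", .data$criterion))
  readr::write_tsv(long, path)
  invisible(path)
}
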