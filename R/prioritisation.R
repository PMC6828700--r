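truncating_consequences <- c("stop_gain", "splice", "other_lof")

#' Score the three research-variant prioritisation criteria
#'
#' For variants that survive hard filtering but carry no clinical (ACMG)
#' label, the study prioritised by three predictor votes: regional missense
#' intolerance (MTR centile < 25), PolyPhen2 HVAR "probably damaging" (D) or
#' "possibly damaging" (P), and MutationTaster "disease causing" (D or
#' automatic A). A missing score makes its criterion not applicable. A
#' truncating variant (stop gain, splice, other LOF) with missing
#' missense-specific scores is additionally flagged `lof`, since those
#' predictors are undefined for it rather than merely unmeasured.
#'
#' @param variants Data frame with columns `mtr_centile`, `polyphen2_hvar`,
#'   `mutation_taster`, `consequence`.
#' @param config A [threshold_config()].
#' @return Input with appended columns `mtr_pass`, `polyphen_pass`,
#'   `muttaster_pass` (`"pass"`/`"fail"`/`"not_applicable"`), `n_pass`,
#'   `n_applicable` (0-3) and `lof` (logical).
#' @export
#' @examples
#' score_criteria(tibble::tibble(
#'   mtr_centile = 0.79, polyphen2_hvar = "D", mutation_taster = "D",
#'   consequence = "missense"
#' ))[, c("n_pass", "n_applicable")]
score_criteria <- function(variants, config = threshold_config()) {
  variants <- as_tibble(variants)
  out <- variants %>%
    mutate(
      mtr_pass = case_when(
        is.na(.data$mtr_centile) ~ crit_na,
        .data$mtr_centile < .env$config$mtr_centile_max ~ crit_pass,
        TRUE ~ crit_fail
      ),
      polyphen_pass = case_when(
        is.na(.data$polyphen2_hvar) ~ crit_na,
        .data$polyphen2_hvar %in% c("D", "P") ~ crit_pass,
        TRUE ~ crit_fail
      ),
      muttaster_pass = case_when(
        is.na(.data$mutation_taster) ~ crit_na,
        .data$mutation_taster %in% c("D", "A") ~ crit_pass,
        TRUE ~ crit_fail
      )
    )
  crit <- cbind(out$mtr_pass, out$polyphen_pass, out$muttaster_pass)
  out$n_pass <- rowSums(crit == crit_pass)
  out$n_applicable <- rowSums(crit != crit_na)
  out$lof <- out$consequence %in% truncating_consequences & out$n_applicable < 3
  out
}

#' Classify gene intolerance to variation (3-of-5 rule)
#'
#' A gene is called intolerant when at least `min_criteria` (default 3) of
#' five constraint criteria are met: DOMINO probability of autosomal
#' dominance > 0.5, haploinsufficiency index percentile < 25, RVIS
#' percentile < 25, pLI > 0.9 and missense Z > 2. A missing metric counts
#' as "criterion not met" - the numerator threshold is fixed, the
#' denominator never shrinks.
#'
#' @param constraints Data frame with columns `gene`, `domino`,
#'   `hi_percentile`, `rvis_percentile`, `pli`, `z_missense`.
#' @param config A [threshold_config()].
#' @return Tibble `gene`, `criteria_met`, `n_available`, `intolerant`.
#' @export
#' @examples
#' classify_gene_intolerance(tibble::tibble(
#'   gene = "AGAP1", domino = NA, hi_percentile = 17.79,
#'   rvis_percentile = 10.60, pli = 1.0, z_missense = 1.41
#' ))
classify_gene_intolerance <- function(constraints, config = threshold_config()) {
  constraints <- as_tibble(constraints)
  met <- cbind(
    domino = !is.na(constraints$domino) & constraints$domino > config$domino_min,
    hi = !is.na(constraints$hi_percentile) &
      constraints$hi_percentile < config$hi_pct_max,
    rvis = !is.na(constraints$rvis_percentile) &
      constraints$rvis_percentile < config$rvis_pct_max,
    pli = !is.na(constraints$pli) & constraints$pli > config$pli_min,
    z = !is.na(constraints$z_missense) &
      constraints$z_missense > config$z_missense_min
  )
  avail <- cbind(
    !is.na(constraints$domino), !is.na(constraints$hi_percentile),
    !is.na(constraints$rvis_percentile), !is.na(constraints$pli),
    !is.na(constraints$z_missense)
  )
  tibble(
    gene = constraints$gene,
    criteria_met = as.integer(rowSums(met)),
    n_available = as.integer(rowSums(avail)),
    intolerant = rowSums(met) >= config$min_criteria
  )
}

tier_levels <- c("clinical_pathogenic", "clinical_likely_pathogenic",
                 "clinical_vus", "clinical_likely_benign",
                 "research_prioritised", "research_supported",
                 "not_prioritised")

acmg_to_tier <- c(
  pathogenic = "clinical_pathogenic",
  likely_pathogenic = "clinical_likely_pathogenic",
  VUS = "clinical_vus",
  likely_benign = "clinical_likely_benign",
  benign = "clinical_likely_benign"
)

#' Assign a report tier to each variant
#'
#' Combines the upstream evidence into the study's reporting cascade:
#'
#' 1. hard-filter failures are `not_prioritised`;
#' 2. variants in known disease genes carry their ACMG label through to the
#'    corresponding clinical tier (the label is consumed, never recomputed);
#'    a known-gene variant without a label is an error;
#' 3. candidate-gene variants passing all three prioritisation criteria -
#'    or truncating variants whose applicable criteria all pass - are
#'    `research_prioritised`;
#' 4. candidate-gene variants passing two of three are `research_supported`
#'    when the gene is intolerant to variation or the row carries an
#'    explicit `support` flag (clinical corroboration is outside software);
#' 5. everything else is `not_prioritised`.
#'
#' @param variants Output of [score_criteria()], additionally carrying
#'   `gene`, `acmg_class`, `hard_pass` (from [hard_filter()]) and optionally
#'   a logical `support` column.
#' @param panel A [panel_design()] providing the known/candidate gene split.
#' @param intolerance Output of [classify_gene_intolerance()]; genes absent
#'   from it are treated as not intolerant.
#' @return The input with an appended `tier` column (factor with the tier
#'   levels in reporting order).
#' @export
assign_tier <- function(variants, panel, intolerance = NULL) {
  variants <- as_tibble(variants)
  need <- c("gene", "acmg_class", "hard_pass", "n_pass", "n_applicable", "lof")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) {
    abort(paste0("assign_tier needs column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"support" %in% names(variants)) variants$support <- FALSE
  gene_info <- panel$genes
  v <- variants %>%
    left_join(gene_info, by = "gene") %>%
    left_join(
      if (is.null(intolerance)) {
        tibble(gene = character(), intolerant = logical())
      } else {
        intolerance %>% select(dplyr::all_of(c("gene", "intolerant")))
      },
      by = "gene"
    ) %>%
    mutate(intolerant = dplyr::coalesce(.data$intolerant, FALSE))
  bad <- v$hard_pass & v$known_disease_gene & is.na(v$acmg_class)
  if (any(bad, na.rm = TRUE)) {
    abort("clinical tier requested for known-gene variant without ACMG label")
  }
  tier <- case_when(
    !v$hard_pass ~ "not_prioritised",
    v$known_disease_gene ~ unname(acmg_to_tier[v$acmg_class]),
    v$n_pass == 3 ~ "research_prioritised",
    v$lof & v$n_applicable > 0 & v$n_pass == v$n_applicable ~
      "research_prioritised",
    v$n_pass == 2 & (v$intolerant | dplyr::coalesce(v$support, FALSE)) ~
      "research_supported",
    TRUE ~ "not_prioritised"
  )
  variants$tier <- factor(tier, levels = tier_levels)
  variants
}

#' Call inheritance from trio genotypes
#'
#' Works gene by gene within each sample. Input rows carry the child's
#' genotype plus the parents' genotypes where available (`mother_gt`,
#' `father_gt`: `"ref"`, `"het"`, `"hom_alt"`, `"hemi"`, or `NA` when that
#' parent was not genotyped). Calls, per variant:
#'
#' * `homozygous` - child is homozygous alternate;
#' * `x_linked_maternal` - hemizygous X variant carried by the mother;
#' * `de_novo` - absent from both genotyped parents (both must be
#'   available), or a hemizygous X variant absent from the genotyped mother;
#' * `maternal` / `paternal` - present in exactly that parent;
#' * `not_maternal` / `not_paternal` - absent from the single genotyped
#'   parent;
#' * `compound_het` - two or more heterozygous variants in the same gene
#'   with opposite parental origins (one maternal, one paternal) replace
#'   their individual parental calls;
#' * `unknown` otherwise.
#'
#' A heterozygous X call in a male is flagged in the `note` column as an
#' inconsistency rather than silently interpreted.
#'
#' @param variants Data frame with columns `sample_id`, `gene`, `chrom`,
#'   `genotype`, `mother_gt`, `father_gt` and the sample's `sex`.
#' @return Input with appended `inheritance` and `note` columns.
#' @export
call_inheritance <- function(variants) {
  variants <- as_tibble(variants)
  need <- c("sample_id", "gene", "chrom", "genotype", "mother_gt",
            "father_gt", "sex")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) {
    abort(paste0("call_inheritance needs column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(is.na(variants$genotype))) abort("child genotype missing")
  carries <- function(gt) !is.na(gt) & gt %in% c("het", "hom_alt", "hemi")
  on_x <- variants$chrom %in% c("X", "chrX")
  m_av <- !is.na(variants$mother_gt)
  f_av <- !is.na(variants$father_gt)
  m_car <- carries(variants$mother_gt)
  f_car <- carries(variants$father_gt)

  inh <- character(nrow(variants))
  note <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    gt <- variants$genotype[i]
    if (gt == "hom_alt") {
      inh[i] <- "homozygous"
    } else if (gt == "hemi" && on_x[i]) {
      if (m_av[i] && m_car[i]) {
        inh[i] <- "x_linked_maternal"
      } else if (m_av[i]) {
        inh[i] <- "de_novo"
        note[i] <- "hemizygous X, mother genotyped reference"
      } else {
        inh[i] <- "unknown"
        note[i] <- "hemizygous X, mother unavailable"
      }
    } else if (m_av[i] && f_av[i]) {
      inh[i] <- if (!m_car[i] && !f_car[i]) "de_novo"
      else if (m_car[i] && !f_car[i]) "maternal"
      else if (!m_car[i] && f_car[i]) "paternal"
      else "unknown"
      if (m_car[i] && f_car[i]) note[i] <- "carried by both parents"
    } else if (m_av[i]) {
      inh[i] <- if (m_car[i]) "maternal" else "not_maternal"
    } else if (f_av[i]) {
      inh[i] <- if (f_car[i]) "paternal" else "not_paternal"
    } else {
      inh[i] <- "unknown"
    }
    if (gt == "het" && on_x[i] && variants$sex[i] == "male") {
      note[i] <- "inconsistent: heterozygous X call in a male"
    }
  }
  variants$inheritance <- inh
  variants$note <- note

  # compound heterozygotes: >=2 hets in one gene with opposite origins
  variants %>%
    group_by(.data$sample_id, .data$gene) %>%
    mutate(
      comp = sum(.data$genotype == "het" & .data$inheritance == "maternal") > 0 &
        sum(.data$genotype == "het" & .data$inheritance == "paternal") > 0,
      inheritance = if_else(
        .data$comp & .data$genotype == "het" &
          .data$inheritance %in% c("maternal", "paternal"),
        "compound_het", .data$inheritance
      )
    ) %>%
    ungroup() %>%
    select(-dplyr::all_of("comp"))
}

#' Diagnostic-yield summary from the report tables
#'
#' Counts distinct individuals (never variant rows) in the study's yield
#' groupings:
#'
#' * `n_known_gene_individuals` - individuals with any variant in the known
#'   disease gene report;
#' * `n_pathogenic` - of those, carrying at least one ACMG-pathogenic
#'   variant; `n_likely_pathogenic_only` - likely pathogenic but nothing
#'   pathogenic;
#' * `n_naive_reportable` - naive individuals with a variant of potential
#'   clinical significance (pathogenic, likely pathogenic or VUS; likely
#'   benign excluded), with `pct_naive_reportable` over `n_naive`;
#' * `n_naive_path_or_lp` - naive individuals with a pathogenic or likely
#'   pathogenic variant;
#' * `n_candidate_individuals` - individuals in the candidate gene report;
#' * `n_candidate_naive_new` - naive candidate-gene carriers with no
#'   clinical-relevance variant of their own in the known-gene report;
#' * `n_combined_naive` - distinct union of naive reportable and naive
#'   candidate carriers, with `pct_combined_naive`.
#'
#' Percentages are rounded to one decimal place.
#'
#' @param known Known-gene report: columns `sample_id`, `naive`,
#'   `acmg_class`.
#' @param candidate Candidate-gene report: columns `sample_id`, `naive`.
#' @param n_naive Number of naive cases analysed (denominator; default 271).
#' @param n_total Total cases analysed (default 366).
#' @return A one-row tibble of counts and percentages.
#' @export
#' @examples
#' fx <- load_fixture_tables()
#' summarize_yield(fx$known, fx$candidate)
summarize_yield <- function(known, candidate, n_naive = 271, n_total = 366) {
  if (n_naive <= 0 || n_total <= 0) abort("denominators must be positive")
  known <- as_tibble(known)
  candidate <- as_tibble(candidate)
  reportable_classes <- c("pathogenic", "likely_pathogenic", "VUS")

  path_samples <- known %>%
    filter(.data$acmg_class == "pathogenic") %>% pull(.data$sample_id) %>% unique()
  lp_samples <- known %>%
    filter(.data$acmg_class == "likely_pathogenic") %>%
    pull(.data$sample_id) %>% unique()
  naive_reportable <- known %>%
    filter(.data$naive, .data$acmg_class %in% reportable_classes) %>%
    pull(.data$sample_id) %>% unique()
  naive_plp <- known %>%
    filter(.data$naive,
           .data$acmg_class %in% c("pathogenic", "likely_pathogenic")) %>%
    pull(.data$sample_id) %>% unique()
  cand_naive <- candidate %>%
    filter(.data$naive) %>% pull(.data$sample_id) %>% unique()

  pct1 <- function(k, n) round(100 * k / n, 1)
  tibble(
    n_known_gene_individuals = dplyr::n_distinct(known$sample_id),
    n_pathogenic = length(path_samples),
    n_likely_pathogenic_only = length(setdiff(lp_samples, path_samples)),
    n_naive_reportable = length(naive_reportable),
    pct_naive_reportable = pct1(length(naive_reportable), n_naive),
    n_naive_path_or_lp = length(naive_plp),
    n_candidate_individuals = dplyr::n_distinct(candidate$sample_id),
    n_candidate_naive = length(cand_naive),
    n_candidate_naive_new = length(setdiff(cand_naive, naive_reportable)),
    n_combined_naive = length(union(naive_reportable, cand_naive)),
    pct_combined_naive = pct1(length(union(naive_reportable, cand_naive)),
                              n_naive),
    n_naive = n_naive,
    n_total = n_total
  )
}

#' Aggregate recurrence contribution of a gene set
#'
#' Sums per-gene counts of affected individuals and expresses them as a
#' percentage of an aggregate cohort, rounded to one decimal.
#'
#' @param counts Tibble with columns `gene`, `n_individuals`.
#' @param n_aggregate Aggregate cohort size.
#' @return One-row tibble `n_genes`, `n_individuals`, `pct`.
#' @export
#' @examples
#' rc <- load_recurrence_counts()
#' recurrence_contribution(rc$counts, rc$n_aggregate)
recurrence_contribution <- function(counts, n_aggregate) {
  if (n_aggregate <= 0) abort("denominator must be positive")
  tibble(
    n_genes = nrow(counts),
    n_individuals = sum(counts$n_individuals),
    pct = round(100 * sum(counts$n_individuals) / n_aggregate, 1)
  )
}
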