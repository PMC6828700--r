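#' Run the full panel analysis pipeline
#'
#' Orchestrates the stages in study order: coverage QC (samples failing the
#' 50%-at-20x rule are excluded from every downstream stage), hard
#' filtering, prioritisation (criteria scoring, gene intolerance, tier
#' assignment, trio inheritance where parent genotypes are supplied) and
#' the two gene-level burden analyses. Stages can be switched off with
#' `stages`; a stage error aborts with the stage name.
#'
#' @param cases A `cohort_dataset` of cases.
#' @param controls Optional `cohort_dataset` of controls (required for the
#'   burden stage).
#' @param coverage Optional per-base depth tibble (`sample_id`, `chrom`,
#'   `pos`, `depth`) for the QC stage.
#' @param coverage_panel Panel the depths cover (defaults to the case
#'   panel).
#' @param parent_genotypes Optional tibble (`sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `mother_gt`, `father_gt`) for inheritance calling.
#' @param config A [threshold_config()].
#' @param stages Character subset of `c("qc", "filter", "prioritise",
#'   "burden")`.
#' @return A `pipeline_run` object: list with `config`, `stages`, `qc`,
#'   `variants` (annotated with verdicts, criteria, tiers, inheritance),
#'   `intolerance`, `burden`, `yield`, `log`.
#' @export
run_pipeline <- function(cases, controls = NULL, coverage = NULL,
                         coverage_panel = NULL, parent_genotypes = NULL,
                         config = threshold_config(),
                         stages = c("qc", "filter", "prioritise", "burden")) {
  stopifnot(inherits(cases, "cohort_dataset"))
  bad <- setdiff(stages, c("qc", "filter", "prioritise", "burden"))
  if (length(bad) > 0) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage `", name, "` failed: ", conditionMessage(e)))
    })
  }

  qc <- NULL
  if ("qc" %in% stages && !is.null(coverage)) {
    qc <- stage("qc", {
      pan <- if (is.null(coverage_panel)) cases$panel else coverage_panel
      sample_coverage_qc(coverage, pan, config)
    })
    failed <- qc$sample_id[!qc$passed]
    note("qc: ", nrow(qc), " samples, ", length(failed), " failed")
    if (length(failed) > 0) {
      cases <- cohort_dataset(
        cases$panel,
        cases$samples %>% filter(!.data$sample_id %in% failed),
        cases$variants %>% filter(!.data$sample_id %in% failed),
        cases$constraints
      )
    }
  }

  variants <- cases$variants
  intolerance <- NULL
  if ("filter" %in% stages) {
    variants <- stage("filter", hard_filter(variants, config))
    note("filter: ", sum(variants$hard_pass), "/", nrow(variants),
         " variants pass hard filters (policy ", config$cadd_policy, ")")
  }
  if ("prioritise" %in% stages) {
    if (!"filter" %in% stages) abort("stage `prioritise` needs stage `filter`")
    variants <- stage("prioritise", {
      v <- score_criteria(variants, config)
      intolerance <<- classify_gene_intolerance(cases$constraints, config)
      v <- assign_tier(v, cases$panel, intolerance)
      if (!is.null(parent_genotypes)) {
        v <- v %>%
          left_join(parent_genotypes,
                    by = c("sample_id", "chrom", "pos", "ref", "alt")) %>%
          left_join(cases$samples %>%
                      select(dplyr::all_of(c("sample_id", "sex"))),
                    by = "sample_id") %>%
          call_inheritance()
      }
      v
    })
    note("prioritise: ",
         sum(variants$tier != "not_prioritised"), " variants tiered")
  }

  burden <- NULL
  if ("burden" %in% stages) {
    if (is.null(controls)) abort("stage `burden` needs a control dataset")
    burden <- stage("burden", run_burden_analysis(cases, controls, config))
    note("burden: ", dplyr::n_distinct(burden$gene), " genes tested")
  }

  yield <- NULL
  if ("prioritise" %in% stages) {
    samp_naive <- cases$samples %>%
      select(dplyr::all_of(c("sample_id", "naive")))
    known_rep <- variants %>%
      filter(startsWith(as.character(.data$tier), "clinical")) %>%
      left_join(samp_naive, by = "sample_id")
    cand_rep <- variants %>%
      filter(startsWith(as.character(.data$tier), "research")) %>%
      left_join(samp_naive, by = "sample_id")
    yield <- stage("prioritise", summarize_yield(
      known_rep, cand_rep,
      n_naive = max(1, sum(cases$samples$naive)),
      n_total = max(1, nrow(cases$samples))
    ))
  }

  structure(list(
    config = config, stages = stages, qc = qc, variants = variants,
    intolerance = intolerance, burden = burden, yield = yield, log = log
  ), class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> stages:", paste(x$stages, collapse = " -> "), "\n")
  for (l in x$log) cat("  ", l, "\n", sep = "")
  invisible(x)
}

#' Write pipeline reports
#'
#' Emits the run's tables into a directory, in the layouts of the study's
#' published report tables: `known_gene_report.tsv` (clinically tiered
#' variants in known disease genes), `candidate_gene_report.tsv`
#' (research-tiered variants with their prioritisation scores),
#' `burden_report.tsv`/`.json`, `qc_report.tsv` and `yield_summary.tsv` +
#' `.json`. Machine outputs keep full double precision; regenerating the
#' reports from the same run is byte-identical.
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_reports <- function(run, dir) {
  stopifnot(inherits(run, "pipeline_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit_tsv <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_tsv(df, p, na = "NA")
    written <<- c(written, p)
  }
  v <- run$variants
  if (!is.null(v) && "tier" %in% names(v)) {
    report_cols <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                     "hgvs_c", "hgvs_p", "gnomad_af", "acmg_class",
                     "cadd_phred", "gerp", "mtr_centile", "polyphen2_hvar",
                     "mutation_taster", "tier", "inheritance", "note")
    sel <- function(df) df %>%
      select(dplyr::any_of(report_cols)) %>%
      arrange(.data$sample_id, .data$gene, .data$pos)
    emit_tsv(sel(v %>% filter(startsWith(as.character(.data$tier), "clinical"))),
             "known_gene_report.tsv")
    emit_tsv(sel(v %>% filter(startsWith(as.character(.data$tier), "research"))),
             "candidate_gene_report.tsv")
  }
  if (!is.null(run$qc)) emit_tsv(run$qc, "qc_report.tsv")
  if (!is.null(run$burden)) {
    p <- file.path(dir, "burden_report.tsv")
    write_burden_report(run$burden, p)
    written <- c(written, p, sub("\\.tsv$", ".json", p))
  }
  if (!is.null(run$yield)) {
    emit_tsv(run$yield, "yield_summary.tsv")
    p <- file.path(dir, "yield_summary.json")
    jsonlite::write_json(as.list(run$yield), p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
  }
  invisible(written)
}
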