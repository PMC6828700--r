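# Frozen checksums of the transcribed report tables; load_fixture_tables()
# refuses to return silently corrupted copies.
fixture_md5 <- c(
  known_gene_report.tsv = "e7e37dd4228c2265dc9381a892e670d6",
  candidate_gene_report.tsv = "07c9eb9f932fbfa7bfe73c1d78a46e6a",
  gene_burden_table.tsv = "b06d87ce1c4e723b2e20398d6232e5d9"
)

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "rvpanel")
  if (!nzchar(p)) abort(paste0("packaged fixture not found: ", name))
  p
}

#' Load the packaged study report tables
#'
#' Returns the three report tables of the cerebral-palsy panel study,
#' transcribed verbatim from the published main-text tables:
#'
#' * `known`: 24 variant rows over 23 distinct individuals carrying variants
#'   of possible clinical significance in known disease genes (one
#'   individual carries a compound-heterozygous pair, hence two rows), with
#'   trio inheritance, gnomAD frequency and the ACMG classification assigned
#'   by the study.
#' * `candidate`: 26 rows over 26 distinct individuals with prioritised
#'   variants in variation-intolerant candidate genes, with the CADD Phred,
#'   GERP++, MTR centile, PolyPhen2 HVAR and MutationTaster scores used by
#'   the prioritisation criteria.
#' * `burden`: the per-gene carrier-burden table (carriers with MAF < 0.001
#'   among 271 cases, control EUR carrier frequency, published corrected
#'   p-value, and the four constraint metrics printed alongside). The
#'   published corrected p-values are carried for reference only; they are
#'   not reproducible from the printed counts and frequencies alone.
#'
#' The `prior_case`/`prior_variant` flags transcribe the tables' footnotes
#' marking individuals and variants already reported in the authors' earlier
#' exome study; `naive = !prior_case` identifies the newly sequenced cases.
#' Dashes in the printed score columns are read as missing values.
#'
#' @return A named list of tibbles `known`, `candidate`, `burden`.
#' @export
#' @examples
#' fx <- load_fixture_tables()
#' dplyr::n_distinct(fx$known$sample_id)
load_fixture_tables <- function() {
  for (nm in names(fixture_md5)) {
    got <- unname(tools::md5sum(fixture_path(nm)))
    if (got != fixture_md5[[nm]]) {
      abort(paste0("fixture integrity check failed for ", nm))
    }
  }
  known <- readr::read_tsv(
    fixture_path("known_gene_report.tsv"),
    col_types = readr::cols(
      sample_id = readr::col_character(), gene = readr::col_character(),
      inheritance = readr::col_character(), gnomad_af = readr::col_double(),
      variant = readr::col_character(), dbsnp = readr::col_character(),
      acmg_class = readr::col_character(), prior_case = readr::col_logical(),
      prior_variant = readr::col_logical()
    ), na = c("", "NA")
  ) %>% mutate(naive = !.data$prior_case)
  candidate <- readr::read_tsv(
    fixture_path("candidate_gene_report.tsv"),
    col_types = readr::cols(
      gene = readr::col_character(), sample_id = readr::col_character(),
      inheritance = readr::col_character(), gnomad_af = readr::col_double(),
      variant = readr::col_character(), consequence = readr::col_character(),
      cadd_phred = readr::col_double(), gerp = readr::col_double(),
      mtr_centile = readr::col_double(),
      polyphen2_hvar = readr::col_character(),
      mutation_taster = readr::col_character(),
      prior_case = readr::col_logical(), prior_variant = readr::col_logical()
    ), na = c("", "NA", "-", "–")
  ) %>% mutate(naive = !.data$prior_case)
  burden <- readr::read_tsv(
    fixture_path("gene_burden_table.tsv"),
    col_types = readr::cols(
      gene = readr::col_character(),
      carriers_maf001_cases = readr::col_integer(),
      n_de_novo = readr::col_integer(),
      eur_frequency = readr::col_double(),
      corrected_p = readr::col_double(), n_lp_vus = readr::col_integer(),
      pli = readr::col_double(), hi_percentile = readr::col_double(),
      rvis_raw = readr::col_double(), rvis_percentile = readr::col_double(),
      z_missense = readr::col_double()
    ), na = c("", "NA")
  )
  list(known = known, candidate = candidate, burden = burden)
}

#' Packaged synthetic 112-gene panel
#'
#' A synthetic stand-in for the study's capture design: the gene symbols
#' reported in the study's tables (known disease genes and candidate genes)
#' padded with placeholder candidate symbols to the published panel size of
#' 112 genes, three intervals per gene, total span 388,046 bp. Coordinates
#' are invented; the real design is not publicly deposited. The published
#' analysable-bases figure (384,858 bp, printed as 99.44% target coverage)
#' is recorded in [panel_reference_sizes()].
#'
#' @return A [panel_design()] with 112 genes.
#' @export
load_synthetic_panel <- function() {
  read_panel_bed(
    fixture_path("panel_synthetic.bed"),
    genes = readr::read_tsv(fixture_path("panel_genes_synthetic.tsv"),
                            col_types = "cll")
  )
}

#' Published panel size constants
#'
#' The study prints a total target size of 388,046 bp and 384,858 bp of
#' analysable target bases, labelled "99.44% target coverage" (the printed
#' ratio of the two numbers is 99.18%; both printed values are carried
#' as-is, unreconciled).
#'
#' @return A named list with `target_bp`, `analysable_bp`,
#'   `printed_pct_analysable`, `n_genes`, `n_amplicons`.
#' @export
panel_reference_sizes <- function() {
  list(target_bp = 388046, analysable_bp = 384858,
       printed_pct_analysable = 99.44, n_genes = 112L, n_amplicons = 19989L)
}

#' Gene constraint profiles from the packaged burden table
#'
#' Extracts the five intolerance metrics (DOMINO is not printed in the table
#' and is therefore missing) in the layout [classify_gene_intolerance()]
#' consumes.
#'
#' @return A tibble with the constraint columns.
#' @export
load_fixture_constraints <- function() {
  load_fixture_tables()$burden %>%
    mutate(domino = NA_real_) %>%
    select(dplyr::all_of(constraint_cols))
}

#' Recurrently hit genes in the aggregate cohort
#'
#' The per-gene counts of individuals with variants of potential clinical
#' significance across the study's aggregate cohort of 489 clinically
#' unselected cases (this panel study plus the authors' earlier exome
#' study): six genes, 20 individuals in total.
#'
#' @return A list with `counts` (tibble `gene`, `n_individuals`) and
#'   `n_aggregate` (489).
#' @export
load_recurrence_counts <- function() {
  counts <- readr::read_tsv(fixture_path("recurrent_gene_counts.tsv"),
                            col_types = "ci")
  list(counts = counts, n_aggregate = 489L)
}
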