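#' Simulation configuration
#'
#' Describes a synthetic case/control panel cohort with known ground truth.
#' Defaults emulate the study conditions this package models: 271 naive
#' cases against 503 EUR controls on a 112-gene panel, with trio DNA
#' availability of 45 complete trios / 171 single parents / 55 none per 271
#' cases (scaled proportionally for other cohort sizes).
#'
#' Planted variants are all rare and protein-altering, so the carrier-burden
#' qualifying rate per gene equals the configured carrier rate. Annotation
#' scores come from a two-component mixture: with probability
#' `damaging_prob` a variant is "damaging-like" (CADD > 20, GERP > 4, MTR
#' centile < 25, damaging categorical predictions, zero population
#' frequency) and otherwise "benign-like" (CADD < 20, GERP <= 4, high MTR
#' centile, rare but nonzero frequencies below the hard-filter cut-offs).
#' The overabundance qualifying rate per gene is therefore
#' `carrier_rate * damaging_prob` in closed form.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param panel A [panel_design()]; default the packaged synthetic 112-gene
#'   panel.
#' @param gene_models Tibble `gene`, `control_carrier_rate`,
#'   `case_enrichment`; default rate 0.01, enrichment 1 for every panel
#'   gene. `control_carrier_rate * case_enrichment` must be `<= 1`.
#' @param trio_counts Named vector `full`, `single`, `none` per 271 cases.
#' @param de_novo_fraction Fraction of planted case variants that are de
#'   novo; the remainder are inherited from one parent.
#' @param damaging_prob Mixture weight of the damaging-like annotation
#'   component.
#' @param acmg_probs Label probabilities for variants planted in known
#'   disease genes (`pathogenic`, `likely_pathogenic`, `VUS`,
#'   `likely_benign`).
#' @param coverage List: `mean_depth` (Poisson mean at covered bases),
#'   `fail_fraction` (target fraction of samples built to fail the
#'   50%-at-20x rule), `bases_per_gene` (panel bases simulated per gene;
#'   coverage QC is a per-base proportion, so a fixed subsample of the
#'   design is simulated).
#' @param injected_variants Optional tibble of fully specified variant rows
#'   (same columns as the cohort variant table, plus optional `mother_gt`,
#'   `father_gt`, `planted_inheritance`) planted verbatim in named samples.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_cases = 271, n_controls = 503,
                              panel = NULL, gene_models = NULL,
                              trio_counts = c(full = 45, single = 171, none = 55),
                              de_novo_fraction = 0.2,
                              damaging_prob = 0.7,
                              acmg_probs = c(pathogenic = 0.1,
                                             likely_pathogenic = 0.1,
                                             VUS = 0.7, likely_benign = 0.1),
                              coverage = list(mean_depth = 100,
                                              fail_fraction = 0,
                                              bases_per_gene = 30),
                              injected_variants = NULL) {
  if (is.null(panel)) panel <- load_synthetic_panel()
  stopifnot(inherits(panel, "panel_design"))
  if (is.null(gene_models)) {
    gene_models <- tibble(gene = panel$genes$gene,
                          control_carrier_rate = 0.01,
                          case_enrichment = 1)
  }
  gene_models <- as_tibble(gene_models)
  stopifnot(all(c("gene", "control_carrier_rate", "case_enrichment") %in%
                  names(gene_models)))
  if (any(gene_models$control_carrier_rate < 0 |
            gene_models$control_carrier_rate > 1) ||
      any(gene_models$case_enrichment < 0) ||
      any(gene_models$control_carrier_rate * gene_models$case_enrichment > 1)) {
    abort("invalid gene model: rate in [0,1], enrichment >= 0, product <= 1")
  }
  if (!all(c("full", "single", "none") %in% names(trio_counts)) ||
      any(trio_counts < 0)) {
    abort("trio_counts must be a non-negative vector with full/single/none")
  }
  if (de_novo_fraction < 0 || de_novo_fraction > 1 ||
      damaging_prob < 0 || damaging_prob > 1) {
    abort("fractions must be in [0, 1]")
  }
  cov_def <- list(mean_depth = 100, fail_fraction = 0, bases_per_gene = 30)
  coverage <- modifyList(cov_def, coverage)
  if (coverage$fail_fraction < 0 || coverage$fail_fraction > 1) {
    abort("coverage fail_fraction must be in [0, 1]")
  }
  structure(list(
    n_cases = n_cases, n_controls = n_controls, panel = panel,
    gene_models = gene_models, trio_counts = trio_counts,
    de_novo_fraction = de_novo_fraction, damaging_prob = damaging_prob,
    acmg_probs = acmg_probs, coverage = coverage,
    injected_variants = injected_variants
  ), class = "sim_config")
}

# Independent substream seeds derived from one master seed, so adding one
# generation stage never perturbs another. Kept below 2^31.
substream_seeds <- function(seed, n = 6) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

with_stream <- function(stream_seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed)
  force(code)
}

#' Simulate a case/control panel cohort with ground truth
#'
#' Generates a case and a control [cohort_dataset()] under a
#' [simulation_config()]: per gene, each case carries at least one
#' qualifying variant with probability
#' `control_carrier_rate * case_enrichment` and each control with
#' probability `control_carrier_rate`; annotation scores follow the
#' two-component mixture; trio availability and parental genotypes are
#' generated consistently with each variant's planted inheritance. Output
#' is deterministic given (`config`, `seed`).
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list: `cases` and `controls` (`cohort_dataset`s),
#'   `parent_genotypes` (tibble keyed by sample and variant, `mother_gt` /
#'   `father_gt`, `NA` when unavailable) and `truth` (ledger of every
#'   planted variant: mixture component, planted inheritance, qualifying
#'   status for both burden rules).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- substream_seeds(seed, 6)
  panel <- config$panel
  gm <- config$gene_models

  samples_cases <- with_stream(seeds[1], make_case_manifest(config))
  samples_ctrl <- make_control_manifest(config)

  case_var <- with_stream(
    seeds[2],
    draw_planted_variants(samples_cases, gm, panel, config, enriched = TRUE)
  )
  ctrl_var <- with_stream(
    seeds[3],
    draw_planted_variants(samples_ctrl, gm, panel, config, enriched = FALSE)
  )
  trio <- with_stream(
    seeds[4], draw_parent_genotypes(case_var, samples_cases, config)
  )
  case_var <- trio$variants

  if (!is.null(config$injected_variants)) {
    inj <- as_tibble(config$injected_variants)
    inj_var <- inj %>% select(dplyr::any_of(variant_cols))
    for (col in setdiff(variant_cols, names(inj_var))) {
      inj_var[[col]] <- NA
    }
    inj_var$planted_inheritance <-
      if ("planted_inheritance" %in% names(inj)) inj$planted_inheritance else NA
    inj_var$damaging <- TRUE
    case_sel <- inj_var$sample_id %in% samples_cases$sample_id
    case_var <- bind_rows(case_var, inj_var[case_sel, ])
    ctrl_var <- bind_rows(ctrl_var, inj_var[!case_sel, ] %>%
                            select(-dplyr::any_of("planted_inheritance")))
    pg <- inj %>%
      select(dplyr::any_of(c(variant_key_cols, "mother_gt", "father_gt")))
    if (!"mother_gt" %in% names(pg)) pg$mother_gt <- NA_character_
    if (!"father_gt" %in% names(pg)) pg$father_gt <- NA_character_
    trio$parent_genotypes <- bind_rows(trio$parent_genotypes,
                                       pg[case_sel, , drop = FALSE])
  }

  constraints <- tibble(
    gene = panel$genes$gene, domino = NA_real_, hi_percentile = NA_real_,
    rvis_percentile = NA_real_, pli = NA_real_, z_missense = NA_real_
  )
  truth <- bind_rows(
    case_var %>% mutate(cohort = "case"),
    ctrl_var %>% mutate(cohort = "control", planted_inheritance = NA_character_)
  ) %>%
    select(dplyr::all_of(c("cohort", "sample_id", "gene", "chrom", "pos",
                           "ref", "alt", "consequence", "damaging",
                           "planted_inheritance")))
  cases <- cohort_dataset(
    panel, samples_cases,
    case_var %>% select(dplyr::all_of(variant_cols)), constraints
  )
  controls <- cohort_dataset(
    panel, samples_ctrl,
    ctrl_var %>% select(dplyr::all_of(variant_cols)), constraints
  )
  list(cases = cases, controls = controls,
       parent_genotypes = trio$parent_genotypes, truth = truth)
}

make_case_manifest <- function(config) {
  n <- config$n_cases
  if (n == 0) {
    return(tibble(sample_id = character(), role = character(),
                  naive = logical(), sex = character(),
                  mother_available = logical(), father_available = logical(),
                  mother_id = character(), father_id = character()))
  }
  tc <- config$trio_counts
  n_full <- round(n * tc[["full"]] / sum(tc))
  n_single <- round(n * tc[["single"]] / sum(tc))
  n_none <- n - n_full - n_single
  avail <- sample(rep(c("full", "single", "none"),
                      times = c(n_full, n_single, n_none)))
  ids <- sprintf("S%04d", seq_len(n))
  single_is_mother <- runif(n) < 0.5
  tibble(
    sample_id = ids, role = "case", naive = TRUE,
    sex = sample(c("male", "female"), n, replace = TRUE),
    mother_available = avail == "full" | (avail == "single" & single_is_mother),
    father_available = avail == "full" | (avail == "single" & !single_is_mother)
  ) %>%
    mutate(
      mother_id = if_else(.data$mother_available, paste0(ids, "_M"),
                          NA_character_),
      father_id = if_else(.data$father_available, paste0(ids, "_F"),
                          NA_character_)
    )
}

make_control_manifest <- function(config) {
  n <- config$n_controls
  tibble(
    sample_id = sprintf("C%04d", seq_len(n)), role = "control",
    naive = FALSE, sex = rep(c("male", "female"), length.out = max(n, 1))[seq_len(n)],
    mother_available = FALSE, father_available = FALSE,
    mother_id = NA_character_, father_id = NA_character_
  )
}

draw_planted_variants <- function(samples, gm, panel, config, enriched) {
  n <- nrow(samples)
  if (n == 0) return(empty_truth_variants())
  iv <- panel$intervals
  rows <- purrr::map_dfr(seq_len(nrow(gm)), function(gi) {
    g <- gm$gene[gi]
    rate <- gm$control_carrier_rate[gi] *
      if (enriched) gm$case_enrichment[gi] else 1
    carrier <- runif(n) < rate
    if (!any(carrier)) return(NULL)
    ividx <- which(iv$gene == g)
    giv <- iv[ividx, , drop = FALSE]
    k <- sum(carrier)
    # sample positions without replacement within the gene footprint so no
    # two carriers collide on the same site unintentionally
    offsets <- sample.int(sum(giv$end - giv$start), k, replace = FALSE)
    cum <- cumsum(giv$end - giv$start)
    which_iv <- findInterval(offsets - 1L, c(0L, cum), rightmost.closed = FALSE)
    pos <- giv$start[which_iv] + offsets -
      c(0L, cum)[which_iv] # 1-based within half-open interval
    tibble(
      sample_id = samples$sample_id[carrier],
      chrom = giv$chrom[1],
      pos = as.integer(pos),
      gene = g,
      sex = samples$sex[carrier]
    )
  })
  if (nrow(rows) == 0) return(empty_truth_variants())
  m <- nrow(rows)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  consequence <- sample(c("missense", "stop_gain", "splice", "other_lof"),
                        m, replace = TRUE, prob = c(0.85, 0.05, 0.05, 0.05))
  damaging <- runif(m) < config$damaging_prob
  on_x <- rows$chrom %in% c("X", "chrX")
  genotype <- if_else(on_x & rows$sex == "male", "hemi",
                      if_else(runif(m) < 0.01, "hom_alt", "het"))
  ann <- draw_annotations(m, damaging, consequence)
  known <- rows$gene %in% panel$genes$gene[panel$genes$known_disease_gene]
  acmg <- rep(NA_character_, m)
  if (any(known)) {
    acmg[known] <- sample(names(config$acmg_probs), sum(known), replace = TRUE,
                          prob = config$acmg_probs)
  }
  tibble(
    sample_id = rows$sample_id, chrom = rows$chrom, pos = rows$pos,
    ref = unname(ref), alt = unname(alt), genotype = genotype,
    gene = rows$gene,
    transcript = paste0("TX_", rows$gene),
    hgvs_c = paste0("c.", rows$pos, ref, ">", alt),
    hgvs_p = NA_character_,
    consequence = consequence
  ) %>%
    bind_cols(ann) %>%
    mutate(acmg_class = acmg, damaging = damaging)
}

draw_annotations <- function(m, damaging, consequence) {
  missense_like <- consequence == "missense"
  cadd <- if_else(damaging, 20 + stats::rgamma(m, shape = 2, scale = 4),
                  runif(m, 5, 20))
  gerp <- if_else(damaging, 4 + abs(rnorm(m, 1, 0.8)), runif(m, -2, 4))
  mtr <- if_else(damaging, runif(m, 0, 25), runif(m, 25, 100))
  pp <- if_else(damaging,
                sample(c("D", "P"), m, replace = TRUE, prob = c(0.7, 0.3)),
                "B")
  mt <- if_else(damaging,
                sample(c("D", "A"), m, replace = TRUE, prob = c(0.8, 0.2)),
                sample(c("N", "P"), m, replace = TRUE))
  tibble(
    exac_af = if_else(damaging, 0, runif(m, 0, 5e-5)),
    kg_af = if_else(damaging, 0, runif(m, 0, 5e-4)),
    gnomad_af = if_else(damaging, 0, runif(m, 0, 5e-5)),
    gerp = gerp,
    cadd_phred = cadd,
    mtr_centile = if_else(missense_like, mtr, NA_real_),
    polyphen2_hvar = if_else(missense_like, pp, NA_character_),
    mutation_taster = mt
  )
}

empty_truth_variants <- function() {
  empty_variant_table() %>%
    mutate(damaging = logical(0), planted_inheritance = character(0))
}

draw_parent_genotypes <- function(case_var, samples, config) {
  if (nrow(case_var) == 0) {
    case_var$planted_inheritance <- character(0)
    return(list(
      variants = case_var,
      parent_genotypes = tibble(
        sample_id = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character(),
        mother_gt = character(), father_gt = character()
      )
    ))
  }
  v <- case_var %>%
    left_join(samples %>%
                select(dplyr::all_of(c("sample_id", "mother_available",
                                       "father_available"))),
              by = "sample_id")
  m <- nrow(v)
  on_x <- v$chrom %in% c("X", "chrX")
  de_novo <- runif(m) < config$de_novo_fraction
  from_mother <- if_else(on_x & v$genotype == "hemi", TRUE, runif(m) < 0.5)
  truth <- case_when(
    v$genotype == "hom_alt" ~ "homozygous",
    de_novo ~ "de_novo",
    from_mother & on_x & v$genotype == "hemi" ~ "x_linked_maternal",
    from_mother ~ "maternal",
    TRUE ~ "paternal"
  )
  mother_gt <- case_when(
    !v$mother_available ~ NA_character_,
    truth == "homozygous" ~ "het",
    truth %in% c("maternal", "x_linked_maternal") ~ "het",
    TRUE ~ "ref"
  )
  father_gt <- case_when(
    !v$father_available ~ NA_character_,
    truth == "homozygous" ~ "het",
    truth == "paternal" ~ "het",
    TRUE ~ "ref"
  )
  case_var$planted_inheritance <- truth
  list(
    variants = case_var,
    parent_genotypes = tibble(
      sample_id = v$sample_id, chrom = v$chrom, pos = v$pos,
      ref = v$ref, alt = v$alt,
      mother_gt = mother_gt, father_gt = father_gt
    )
  )
}

#' Simulate per-base coverage profiles
#'
#' Builds one coverage profile per sample over a reduced rendering of the
#' panel (`bases_per_gene` bases from each gene's first interval; coverage
#' QC is a per-base proportion, so a fixed subsample of the design
#' exercises the rule at desk scale). A configured fraction of samples is
#' constructed to fall below the 50%-at-20x QC rule: designated failures
#' have 20-45% of bases covered, designated passes 85-99.5%; covered-base
#' depths are Poisson around `mean_depth` and uncovered bases are drawn
#' below the depth threshold.
#'
#' @param config A [simulation_config()] (uses `coverage` and the panel).
#' @param n_samples Number of profiles (default `n_cases + n_controls` is
#'   not assumed; default `n_cases`).
#' @param seed Integer seed.
#' @param qc_depth Depth threshold the construction targets (default 20).
#' @return A list: `profiles` (tibble `sample_id`, `chrom`, `pos`,
#'   `depth`), `panel` (the reduced `panel_design` the profiles cover) and
#'   `truth` (tibble `sample_id`, `planted_fail`).
#' @export
simulate_coverage <- function(config = simulation_config(),
                              n_samples = config$n_cases, seed = 1L,
                              qc_depth = 20) {
  stopifnot(inherits(config, "sim_config"))
  cov <- config$coverage
  iv <- config$panel$intervals %>%
    group_by(.data$gene) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    mutate(end = pmin(.data$end, .data$start + cov$bases_per_gene))
  small_panel <- panel_design(iv, genes = config$panel$genes)
  pp <- panel_positions(small_panel)
  B <- nrow(pp)
  n_fail <- round(cov$fail_fraction * n_samples)
  with_stream(seed, {
    fail_idx <- if (n_fail > 0) sample.int(n_samples, n_fail) else integer(0)
    profiles <- purrr::map_dfr(seq_len(n_samples), function(i) {
      fails <- i %in% fail_idx
      q <- if (fails) runif(1, 0.2, 0.45) else runif(1, 0.85, 0.995)
      n_cov <- round(q * B)
      covered <- sample.int(B, n_cov)
      depth <- sample.int(qc_depth, B, replace = TRUE) - 1L
      depth[covered] <- rpois(n_cov, cov$mean_depth)
      tibble(sample_id = sprintf("S%04d", i), chrom = pp$chrom,
             pos = pp$pos, depth = depth)
    })
    truth <- tibble(
      sample_id = sprintf("S%04d", seq_len(n_samples)),
      planted_fail = seq_len(n_samples) %in% fail_idx
    )
    list(profiles = profiles, panel = small_panel, truth = truth)
  })
}
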