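# Brute-force pmf-summation oracle for the binomial upper tail, built from
# lchoose directly so it shares no code path with pbinom/dbinom.
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  if (p == 0) return(0)
  if (p == 1) return(1)
  x <- k:n
  sum(exp(lchoose(n, x) + x * log(p) + (n - x) * log1p(-p)))
}

# Small-p two-tailed oracle by full enumeration with lchoose-based pmf.
two_tailed_oracle <- function(k, n, p) {
  x <- 0:n
  pmf <- exp(lchoose(n, x) + x * log(p) + (n - x) * log1p(-p))
  min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
}

# A tiny two-gene panel used across unit tests.
toy_panel <- function() {
  panel_design(
    tibble::tibble(
      chrom = c("1", "1", "X"),
      start = c(100L, 500L, 100L),
      end = c(200L, 600L, 300L),
      gene = c("GENEA", "GENEA", "GENEX")
    ),
    genes = tibble::tibble(
      gene = c("GENEA", "GENEX"),
      known_disease_gene = c(TRUE, FALSE),
      candidate_gene = c(FALSE, TRUE)
    )
  )
}

toy_samples <- function(ids = c("S1", "S2"), role = "case") {
  tibble::tibble(
    sample_id = ids, role = role, naive = role == "case",
    sex = "female", mother_available = FALSE, father_available = FALSE,
    mother_id = NA_character_, father_id = NA_character_
  )
}

# One fully annotated variant row, overridable field by field.
toy_variant <- function(...) {
  base <- tibble::tibble(
    sample_id = "S1", chrom = "1", pos = 150L, ref = "A", alt = "G",
    genotype = "het", gene = "GENEA", transcript = "TX1",
    hgvs_c = "c.1A>G", hgvs_p = "p.K1E", consequence = "missense",
    exac_af = 0, kg_af = 0, gnomad_af = 0, gerp = 5, cadd_phred = 25,
    mtr_centile = 10, polyphen2_hvar = "D", mutation_taster = "D",
    acmg_class = NA_character_
  )
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}

# Random annotation bundles for property-style filter tests.
random_annotations <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    exac_af = ifelse(runif(n) < 0.2, NA, runif(n) ^ 4),
    kg_af = ifelse(runif(n) < 0.2, NA, runif(n) ^ 4),
    gnomad_af = NA_real_,
    gerp = ifelse(runif(n) < 0.2, NA, runif(n, -5, 8)),
    cadd_phred = ifelse(runif(n) < 0.2, NA, runif(n, 0, 45)),
    mtr_centile = ifelse(runif(n) < 0.2, NA, runif(n, 0, 100)),
    polyphen2_hvar = sample(c("D", "P", "B", NA), n, replace = TRUE),
    mutation_taster = sample(c("D", "A", "N", "P", NA), n, replace = TRUE),
    consequence = sample(c("missense", "stop_gain", "splice", "synonymous",
                           "other_lof", "other"), n, replace = TRUE),
    control_maf = ifelse(runif(n) < 0.3, 0, runif(n) ^ 3)
  ))
}
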