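test_that("criteria scoring reproduces published predictor votes", {
  # MTR 0.79 + PolyPhen D + MutationTaster D -> 3/3
  full <- score_criteria(toy_variant(mtr_centile = 0.79,
                                     polyphen2_hvar = "D",
                                     mutation_taster = "D"))
  expect_equal(full$n_pass, 3)
  expect_equal(full$n_applicable, 3)
  expect_false(full$lof)

  # MTR 33.11 (above the 25th centile) -> 2/3
  two <- score_criteria(toy_variant(mtr_centile = 33.11,
                                    polyphen2_hvar = "D",
                                    mutation_taster = "D"))
  expect_equal(two$n_pass, 2)
  expect_equal(two$mtr_pass, "fail")

  # stop gain with missing missense-only scores: applicable set shrinks and
  # the variant is flagged LOF
  sg <- score_criteria(toy_variant(consequence = "stop_gain",
                                   mtr_centile = NA, polyphen2_hvar = NA,
                                   mutation_taster = "A"))
  expect_equal(sg$n_applicable, 1)
  expect_equal(sg$n_pass, 1)
  expect_true(sg$lof)
})

test_that("gene intolerance follows the 3-of-5 rule on published profiles", {
  cons <- load_fixture_constraints()
  calls <- classify_gene_intolerance(cons)
  get <- function(g) dplyr::filter(calls, gene == g)
  # pLI 1.00, HI 17.79, RVIS 10.60% met; Z 1.41 and missing DOMINO not
  expect_equal(get("AGAP1")$criteria_met, 3L)
  expect_true(get("AGAP1")$intolerant)
  expect_equal(get("AGAP1")$n_available, 4L)
  # pLI, RVIS, Z met; HI 50.61 not
  expect_equal(get("KIF1A")$criteria_met, 3L)
  expect_true(get("KIF1A")$intolerant)
  # only RVIS met
  expect_equal(get("PROC")$criteria_met, 1L)
  expect_false(get("PROC")$intolerant)
})

test_that("adding a passing metric never flips intolerant to tolerant", {
  base <- tibble::tibble(gene = "G", domino = NA_real_, hi_percentile = 50,
                         rvis_percentile = 10, pli = 0.99, z_missense = 3)
  with_extra <- dplyr::mutate(base, domino = 0.9)
  expect_true(classify_gene_intolerance(base)$intolerant)
  expect_true(classify_gene_intolerance(with_extra)$intolerant)
  expect_gte(classify_gene_intolerance(with_extra)$criteria_met,
             classify_gene_intolerance(base)$criteria_met)
})

make_tier_input <- function() {
  v <- dplyr::bind_rows(
    toy_variant(sample_id = "P174", gene = "GENEA",
                acmg_class = "pathogenic"),
    toy_variant(sample_id = "P443", gene = "GENEX", chrom = "X", pos = 150L,
                mtr_centile = 0.79),
    toy_variant(sample_id = "P176", gene = "GENEX", chrom = "X", pos = 200L,
                mtr_centile = 33.11),
    toy_variant(sample_id = "P999", gene = "GENEX", chrom = "X", pos = 250L,
                exac_af = 0.01, mtr_centile = 33.11)
  )
  score_criteria(hard_filter(v))
}

test_that("tier assignment follows the clinical/research cascade", {
  v <- make_tier_input()
  intol <- tibble::tibble(gene = "GENEX", intolerant = TRUE)
  tiers <- assign_tier(v, toy_panel(), intol)
  expect_equal(as.character(tiers$tier),
               c("clinical_pathogenic", "research_prioritised",
                 "research_supported", "not_prioritised"))
  # without gene intolerance the 2/3 variant is not rescued
  tiers2 <- assign_tier(v, toy_panel(),
                        tibble::tibble(gene = "GENEX", intolerant = FALSE))
  expect_equal(as.character(tiers2$tier[3]), "not_prioritised")
  # but an explicit per-variant support flag rescues it
  v3 <- dplyr::mutate(v, support = c(FALSE, FALSE, TRUE, FALSE))
  tiers3 <- assign_tier(v3, toy_panel(), NULL)
  expect_equal(as.character(tiers3$tier[3]), "research_supported")
  # truncating variant whose applicable criteria all pass is prioritised
  sg <- score_criteria(hard_filter(
    toy_variant(sample_id = "P947", gene = "GENEX", chrom = "X",
                consequence = "stop_gain", mtr_centile = NA,
                polyphen2_hvar = NA, mutation_taster = "A")
  ))
  expect_equal(as.character(assign_tier(sg, toy_panel(), NULL)$tier),
               "research_prioritised")
})

test_that("tier assignment is pure and order-invariant", {
  v <- make_tier_input()
  intol <- tibble::tibble(gene = "GENEX", intolerant = TRUE)
  t1 <- assign_tier(v, toy_panel(), intol)
  perm <- c(3, 1, 4, 2)
  t2 <- assign_tier(v[perm, ], toy_panel(), intol)
  expect_equal(as.character(t2$tier), as.character(t1$tier)[perm])
  expect_error(
    assign_tier(
      score_criteria(hard_filter(toy_variant(gene = "GENEA",
                                             acmg_class = NA_character_))),
      toy_panel(), NULL
    ),
    "ACMG"
  )
})

trio_row <- function(...) {
  base <- tibble::tibble(sample_id = "S1", gene = "G1", chrom = "1",
                         genotype = "het", mother_gt = NA_character_,
                         father_gt = NA_character_, sex = "female")
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}

test_that("inheritance calling covers trio, duo and X-linked situations", {
  # both parents reference -> de novo
  dn <- call_inheritance(trio_row(mother_gt = "ref", father_gt = "ref"))
  expect_equal(dn$inheritance, "de_novo")
  # single genotyped mother without the variant -> not_maternal
  nm <- call_inheritance(trio_row(mother_gt = "ref"))
  expect_equal(nm$inheritance, "not_maternal")
  # compound het: paternal + maternal pair in one gene
  ch <- call_inheritance(dplyr::bind_rows(
    trio_row(mother_gt = "ref", father_gt = "het"),
    trio_row(mother_gt = "het", father_gt = "ref")
  ) |> dplyr::mutate(pos = c(1L, 2L)))
  expect_equal(ch$inheritance, c("compound_het", "compound_het"))
  # two paternal variants are not compound het
  pp <- call_inheritance(dplyr::bind_rows(
    trio_row(mother_gt = "ref", father_gt = "het"),
    trio_row(mother_gt = "ref", father_gt = "het")
  ))
  expect_equal(pp$inheritance, c("paternal", "paternal"))
  # male hemizygous X variant carried by mother
  xl <- call_inheritance(trio_row(chrom = "X", genotype = "hemi",
                                  mother_gt = "het", sex = "male"))
  expect_equal(xl$inheritance, "x_linked_maternal")
  # homozygous child
  hz <- call_inheritance(trio_row(genotype = "hom_alt", mother_gt = "het",
                                  father_gt = "het"))
  expect_equal(hz$inheritance, "homozygous")
  # heterozygous X call in a male is flagged inconsistent
  bad <- call_inheritance(trio_row(chrom = "X", sex = "male",
                                   mother_gt = "ref", father_gt = "ref"))
  expect_match(bad$note, "inconsistent")
  # de novo and parental calls never co-occur for one variant
  expect_error(call_inheritance(trio_row(genotype = NA_character_)),
               "genotype missing")
})

test_that("yield counting is over distinct individuals, not rows", {
  known <- tibble::tibble(
    sample_id = c("A", "A", "B", "C"),
    naive = c(TRUE, TRUE, TRUE, FALSE),
    acmg_class = c("pathogenic", "pathogenic", "likely_benign", "VUS")
  )
  cand <- tibble::tibble(sample_id = c("A", "D"), naive = c(TRUE, TRUE))
  y <- summarize_yield(known, cand, n_naive = 10, n_total = 20)
  expect_equal(y$n_known_gene_individuals, 3)
  expect_equal(y$n_pathogenic, 1)
  expect_equal(y$n_naive_reportable, 1)      # B is likely benign, C not naive
  expect_equal(y$n_candidate_naive_new, 1)   # A already counted, D new
  expect_equal(y$n_combined_naive, 2)
  expect_equal(y$pct_naive_reportable, 10)
  expect_error(summarize_yield(known, cand, n_naive = 0), "positive")
})
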