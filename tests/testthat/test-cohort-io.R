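test_that("read_panel_bed computes span and gene count and rejects bad input", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200\tG1", "1\t300\t350\tG1"), bed)
  pan <- read_panel_bed(bed)
  expect_equal(panel_span(pan), 150)
  expect_equal(panel_n_genes(pan), 1)

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_error(read_panel_bed(empty), "no intervals")

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200\tG1", "1\t500\t400\tG2"), bad)
  expect_error(read_panel_bed(bad), "line 2")

  short <- withr::local_tempfile(fileext = ".bed")
  writeLines("1\t100\t200", short)
  expect_error(read_panel_bed(short), "4 tab-separated")
})

test_that("the packaged synthetic panel matches the published design size", {
  pan <- load_synthetic_panel()
  expect_equal(panel_n_genes(pan), 112)
  expect_equal(panel_span(pan), panel_reference_sizes()$target_bp)
  expect_equal(sum(pan$genes$known_disease_gene) +
                 sum(pan$genes$candidate_gene), 112)
})

test_that("VCF + annotation join handles biallelic, multi-allelic and orphan rows", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "calls.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t150\t.\tA\tC,T\t.\tPASS\t.\tGT\t0/1\t0/2",
    "1\t550\t.\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/0"
  ), vcf)
  ann <- file.path(dir, "ann.tsv")
  hdr <- paste(c("chrom", "pos", "ref", "alt", "gene", "transcript", "hgvs_c",
                 "hgvs_p", "consequence", "exac_af", "kg_af", "gnomad_af",
                 "gerp", "cadd_phred", "mtr_centile", "polyphen2_hvar",
                 "mutation_taster", "acmg_class"), collapse = "\t")
  row <- function(pos, ref, alt) {
    paste(c("1", pos, ref, alt, "GENEA", "TX1", "c.x", "p.x", "missense",
            "0", "0", "0", "5.0", "25", "10", "D", "D", "NA"), collapse = "\t")
  }
  writeLines(c(hdr, row(150, "A", "C"), row(150, "A", "T"),
               row(550, "G", "A"), row(999, "G", "A")), ann)
  man <- file.path(dir, "manifest.tsv")
  writeLines(c("sample_id\trole\tnaive\tsex\tmother_id\tfather_id",
               "S1\tcase\tTRUE\tfemale\tNA\tNA",
               "S2\tcase\tTRUE\tmale\tNA\tNA"), man)

  expect_message(
    ds <- read_variant_annotations(vcf, ann, man, toy_panel()),
    "1 annotation row"
  )
  expect_s3_class(ds, "cohort_dataset")
  # multi-allelic site split: S1 carries A>C, S2 carries A>T
  expect_equal(nrow(ds$variants), 3)
  site1 <- dplyr::filter(ds$variants, pos == 150)
  expect_setequal(site1$alt, c("C", "T"))
  expect_equal(dplyr::filter(ds$variants, pos == 550)$genotype, "hom_alt")

  # unknown sample is an error
  man2 <- file.path(dir, "manifest2.tsv")
  writeLines(c("sample_id\trole\tnaive\tsex\tmother_id\tfather_id",
               "S1\tcase\tTRUE\tfemale\tNA\tNA"), man2)
  expect_error(read_variant_annotations(vcf, ann, man2, toy_panel()),
               "not in manifest")
})

test_that("allele trimming normalises shared prefixes and suffixes", {
  df <- tibble::tibble(
    pos = c(100L, 100L, 100L),
    ref = c("CAT", "CTT", "A"),
    alt = c("CGT", "CT", "G")
  )
  out <- normalize_variant_alleles(df)
  expect_equal(out$pos, c(101L, 100L, 100L))
  expect_equal(out$ref, c("A", "CT", "A"))
  expect_equal(out$alt, c("G", "C", "G"))
})

test_that("a cohort dataset round-trips through disk record for record", {
  sim <- simulate_cohort(
    simulation_config(n_cases = 15, n_controls = 10), seed = 11
  )
  dir <- withr::local_tempdir()
  write_cohort(sim$cases, dir)
  back <- read_cohort(dir)
  expect_equal(back$samples, sim$cases$samples)
  expect_equal(back$panel$intervals, sim$cases$panel$intervals)
  # per-sample variant keys and annotations survive
  key <- function(v) dplyr::arrange(
    v[, c("sample_id", "chrom", "pos", "ref", "alt", "genotype", "gene",
          "exac_af", "cadd_phred", "consequence")],
    sample_id, chrom, pos, ref, alt
  )
  expect_equal(key(back$variants), key(sim$cases$variants), tolerance = 1e-12)
})

test_that("fixture tables carry the published row and individual counts", {
  fx <- load_fixture_tables()
  expect_equal(nrow(fx$known), 24)
  expect_equal(dplyr::n_distinct(fx$known$sample_id), 23)
  expect_equal(nrow(fx$candidate), 26)
  expect_equal(dplyr::n_distinct(fx$candidate$sample_id), 26)
  agap1 <- dplyr::filter(fx$burden, gene == "AGAP1")
  expect_equal(agap1$carriers_maf001_cases, 8L)
  expect_equal(agap1$eur_frequency, 0.006)
})

test_that("duplicate variant rows are deduplicated with a warning", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "calls.vcf")
  # same site listed twice
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t150\t.\tA\tC\t.\tPASS\t.\tGT\t0/1",
    "1\t150\t.\tA\tC\t.\tPASS\t.\tGT\t0/1"
  ), vcf)
  ann <- file.path(dir, "ann.tsv")
  hdr <- paste(c("chrom", "pos", "ref", "alt", "gene", "transcript", "hgvs_c",
                 "hgvs_p", "consequence", "exac_af", "kg_af", "gnomad_af",
                 "gerp", "cadd_phred", "mtr_centile", "polyphen2_hvar",
                 "mutation_taster", "acmg_class"), collapse = "\t")
  writeLines(c(hdr, paste(c("1", "150", "A", "C", "GENEA", "TX1", "c.x", "p.x",
                            "missense", "0", "0", "0", "5.0", "25", "10", "D",
                            "D", "NA"), collapse = "\t")), ann)
  man <- file.path(dir, "manifest.tsv")
  writeLines(c("sample_id\trole\tnaive\tsex\tmother_id\tfather_id",
               "S1\tcase\tTRUE\tfemale\tNA\tNA"), man)
  expect_warning(
    ds <- read_variant_annotations(vcf, ann, man, toy_panel()),
    "deduplicated"
  )
  expect_equal(nrow(ds$variants), 1)
})
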