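# Column layouts shared by the IO layer, the simulator and the tests.
variant_key_cols <- c("sample_id", "chrom", "pos", "ref", "alt")
variant_core_cols <- c(variant_key_cols, "genotype", "gene", "transcript",
                       "hgvs_c", "hgvs_p", "consequence")
annotation_cols <- c("exac_af", "kg_af", "gnomad_af", "gerp", "cadd_phred",
                     "mtr_centile", "polyphen2_hvar", "mutation_taster",
                     "acmg_class")
variant_cols <- c(variant_core_cols, annotation_cols)
sample_cols <- c("sample_id", "role", "naive", "sex",
                 "mother_available", "father_available",
                 "mother_id", "father_id")
constraint_cols <- c("gene", "domino", "hi_percentile", "rvis_percentile",
                     "pli", "z_missense")
consequence_levels <- c("missense", "stop_gain", "splice", "synonymous",
                        "other_lof", "other")
genotype_levels <- c("het", "hom_alt", "hemi")

#' Assemble a cohort dataset
#'
#' The unit every pipeline stage consumes: a panel design, a sample manifest,
#' a joined variant + annotation table and a gene-constraint table. All
#' invariants are checked on construction: every variant's sample appears in
#' the manifest, every variant's gene is on the panel, alleles differ,
#' frequencies and percentiles are bounded, hemizygous genotypes occur only
#' on sex chromosomes, and controls are never flagged naive.
#'
#' @param panel A [panel_design()].
#' @param samples Sample manifest tibble with columns `sample_id`, `role`
#'   (`"case"`/`"control"`), `naive`, `sex` (`"male"`/`"female"`/`"unknown"`),
#'   `mother_available`, `father_available`, `mother_id`, `father_id`.
#' @param variants Variant table: identification columns (`sample_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `genotype`, `gene`,
#'   `transcript`, `hgvs_c`, `hgvs_p`, `consequence`) plus annotation columns
#'   (`exac_af`, `kg_af`, `gnomad_af`, `gerp`, `cadd_phred`, `mtr_centile`,
#'   `polyphen2_hvar`, `mutation_taster`, `acmg_class`). Missing scores are
#'   `NA`, never 0.
#' @param constraints Per-gene constraint tibble with columns `gene`,
#'   `domino`, `hi_percentile`, `rvis_percentile`, `pli`, `z_missense`.
#' @return A `cohort_dataset` object.
#' @export
cohort_dataset <- function(panel, samples, variants = NULL, constraints = NULL) {
  stopifnot(inherits(panel, "panel_design"))
  samples <- as_tibble(samples)
  miss <- setdiff(sample_cols, names(samples))
  if (length(miss) > 0) {
    abort(paste0("samples missing column(s): ", paste(miss, collapse = ", ")))
  }
  samples <- samples[, sample_cols]
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in manifest")
  if (!all(samples$role %in% c("case", "control"))) {
    abort("sample role must be 'case' or 'control'")
  }
  if (any(samples$role == "control" & samples$naive)) {
    abort("controls must have naive = FALSE")
  }
  if (any(!samples$mother_available & !is.na(samples$mother_id)) ||
      any(!samples$father_available & !is.na(samples$father_id))) {
    abort("parent id present but availability FALSE")
  }

  if (is.null(variants)) {
    variants <- empty_variant_table()
  }
  variants <- as_tibble(variants)
  miss <- setdiff(variant_cols, names(variants))
  if (length(miss) > 0) {
    abort(paste0("variants missing column(s): ", paste(miss, collapse = ", ")))
  }
  variants <- variants[, variant_cols] %>%
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt)
  if (nrow(variants) > 0) {
    unknown <- setdiff(unique(variants$sample_id), samples$sample_id)
    if (length(unknown) > 0) {
      abort(paste0("variant sample(s) not in manifest: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    off <- setdiff(unique(variants$gene), panel$genes$gene)
    if (length(off) > 0) {
      abort(paste0("variant gene(s) not on panel: ",
                   paste(head(off, 5), collapse = ", ")))
    }
    if (any(variants$ref == variants$alt)) abort("ref == alt in variant table")
    if (!all(variants$genotype %in% genotype_levels)) {
      abort("genotype must be one of het/hom_alt/hemi")
    }
    if (!all(variants$consequence %in% consequence_levels)) {
      abort("unknown consequence value")
    }
    hemi_bad <- variants$genotype == "hemi" &
      !variants$chrom %in% c("X", "chrX", "Y", "chrY")
    if (any(hemi_bad)) abort("hemizygous genotype off the sex chromosomes")
    check_unit <- function(x, nm, hi = 1) {
      if (any(!is.na(x) & (x < 0 | x > hi))) {
        abort(paste0(nm, " out of range [0, ", hi, "]"))
      }
    }
    check_unit(variants$exac_af, "exac_af")
    check_unit(variants$kg_af, "kg_af")
    check_unit(variants$gnomad_af, "gnomad_af")
    check_unit(variants$mtr_centile, "mtr_centile", hi = 100)
  }

  if (is.null(constraints)) {
    constraints <- tibble(
      gene = character(), domino = double(), hi_percentile = double(),
      rvis_percentile = double(), pli = double(), z_missense = double()
    )
  }
  constraints <- as_tibble(constraints)
  miss <- setdiff(constraint_cols, names(constraints))
  if (length(miss) > 0) {
    abort(paste0("constraints missing column(s): ", paste(miss, collapse = ", ")))
  }
  constraints <- constraints[, constraint_cols] %>% arrange(.data$gene)

  structure(
    list(panel = panel, samples = samples, variants = variants,
         constraints = constraints),
    class = "cohort_dataset"
  )
}

empty_variant_table <- function() {
  tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), genotype = character(),
    gene = character(), transcript = character(), hgvs_c = character(),
    hgvs_p = character(), consequence = character(),
    exac_af = double(), kg_af = double(), gnomad_af = double(),
    gerp = double(), cadd_phred = double(), mtr_centile = double(),
    polyphen2_hvar = character(), mutation_taster = character(),
    acmg_class = character()
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "<cohort_dataset> %d samples (%d cases / %d controls), %d variants, %d panel genes\n",
    nrow(x$samples), sum(x$samples$role == "case"),
    sum(x$samples$role == "control"), nrow(x$variants), panel_n_genes(x$panel)
  ))
  invisible(x)
}

#' Normalise variant alleles by trimming shared bases
#'
#' Callers and annotation tools often represent the same indel differently.
#' This trims the longest shared allele suffix, then the shared prefix
#' (advancing `pos`), always leaving at least one base in each allele. True
#' left-alignment against the reference genome is out of scope; trim-based
#' normalisation is sufficient to reconcile pre-aligned representations of
#' the same call.
#'
#' @param df Data frame with columns `pos`, `ref`, `alt` (others untouched).
#' @return The data frame with normalised `pos`, `ref`, `alt`.
#' @export
#' @examples
#' normalize_variant_alleles(
#'   tibble::tibble(pos = 100L, ref = "CAT", alt = "CGT")
#' )
normalize_variant_alleles <- function(df) {
  norm1 <- function(pos, ref, alt) {
    r <- strsplit(ref, "")[[1]]
    a <- strsplit(alt, "")[[1]]
    # shared suffix
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # shared prefix
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos <- pos + 1L
    }
    list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
  }
  needs <- nchar(df$ref) > 1 & nchar(df$alt) > 1
  if (!any(needs)) return(df)
  fixed <- purrr::pmap(
    list(df$pos[needs], df$ref[needs], df$alt[needs]), norm1
  )
  df$pos[needs] <- vapply(fixed, `[[`, numeric(1), "pos")
  df$ref[needs] <- vapply(fixed, `[[`, character(1), "ref")
  df$alt[needs] <- vapply(fixed, `[[`, character(1), "alt")
  df
}

#' Read a sample manifest
#'
#' Tab-separated with header columns `sample_id`, `role`, `naive`, `sex`,
#' `mother_id`, `father_id` (empty/NA parent ids mean unavailable).
#'
#' @param path Path to the manifest TSV.
#' @return Tibble in the [cohort_dataset()] sample layout.
#' @export
read_manifest <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), role = readr::col_character(),
    naive = readr::col_logical(), sex = readr::col_character(),
    mother_id = readr::col_character(), father_id = readr::col_character()
  ), na = c("", "NA"))
  df %>%
    mutate(
      mother_available = !is.na(.data$mother_id),
      father_available = !is.na(.data$father_id)
    ) %>%
    select(dplyr::all_of(sample_cols))
}

write_manifest <- function(samples, path) {
  samples %>%
    select(dplyr::all_of(c("sample_id", "role", "naive", "sex",
                           "mother_id", "father_id"))) %>%
    readr::write_tsv(path, na = "NA")
  invisible(path)
}

#' Read an annotation table
#'
#' Tab-separated with header; one row per (chrom, pos, ref, alt) carrying the
#' gene/transcript/HGVS fields and every score consumed by the filters.
#' The literal `-` (as printed in report tables) and empty fields are read as
#' missing; missing is never coerced to 0 because 0 is a legal score.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with the annotation columns.
#' @export
read_annotation_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    gene = readr::col_character(), transcript = readr::col_character(),
    hgvs_c = readr::col_character(), hgvs_p = readr::col_character(),
    consequence = readr::col_character(),
    exac_af = readr::col_double(), kg_af = readr::col_double(),
    gnomad_af = readr::col_double(), gerp = readr::col_double(),
    cadd_phred = readr::col_double(), mtr_centile = readr::col_double(),
    polyphen2_hvar = readr::col_character(),
    mutation_taster = readr::col_character(),
    acmg_class = readr::col_character()
  ), na = c("", "NA", "-", "–"))
}

#' Read variant calls, join annotations, and build a cohort dataset
#'
#' Reads a VCF (via vcfR), splits multi-allelic records into one row per
#' alternate allele, trims allele representations, and inner-joins the
#' annotation table on the normalised (chrom, pos, ref, alt) key. Annotation
#' rows with no matching call are dropped and counted in a message; duplicate
#' (sample, variant) rows are deduplicated with a warning; a variant sample
#' absent from the manifest is an error.
#'
#' @param vcf_path Path to a VCF v4.x file with GT genotypes.
#' @param annotation_path Path to the annotation TSV
#'   (see [read_annotation_table()]).
#' @param manifest_path Path to the sample manifest TSV.
#' @param panel A [panel_design()].
#' @param constraints Optional gene-constraint tibble.
#' @return A [cohort_dataset()].
#' @export
read_variant_annotations <- function(vcf_path, annotation_path, manifest_path,
                                     panel, constraints = NULL) {
  for (p in c(vcf_path, annotation_path, manifest_path)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  samples <- read_manifest(manifest_path)
  calls <- read_vcf_calls(vcf_path)
  unknown <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("variant sample(s) not in manifest: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  calls <- normalize_variant_alleles(calls)
  ann <- normalize_variant_alleles(read_annotation_table(annotation_path))

  ndup <- nrow(calls) - nrow(distinct(calls, dplyr::across(dplyr::all_of(variant_key_cols))))
  if (ndup > 0) {
    warn(paste0("deduplicated ", ndup, " duplicate (sample, variant) row(s)"))
    calls <- calls %>%
      distinct(dplyr::across(dplyr::all_of(variant_key_cols)), .keep_all = TRUE)
  }

  joined <- inner_join(calls, ann, by = c("chrom", "pos", "ref", "alt"))
  n_unmatched <- nrow(anti_join(ann, calls, by = c("chrom", "pos", "ref", "alt")))
  if (n_unmatched > 0) {
    message(n_unmatched, " annotation row(s) had no matching call and were excluded")
  }
  cohort_dataset(panel, samples, joined, constraints = constraints)
}

# Long tibble of per-sample calls from a VCF, one row per alt allele carried.
read_vcf_calls <- function(vcf_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(sample_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  genotype = character()))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  sample_ids <- colnames(gt)
  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    purrr::map_dfr(seq_along(alts), function(a) {
      g <- gt[i, ]
      alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
      carried <- purrr::map_chr(alleles, function(al) {
        if (length(al) == 0 || all(is.na(al)) || all(al == ".")) return(NA_character_)
        hits <- sum(al == as.character(a))
        if (hits == 0) return(NA_character_)
        if (length(al) == 1) return("hemi")
        if (hits == length(al)) return("hom_alt")
        "het"
      })
      keep <- !is.na(carried)
      if (!any(keep)) return(NULL)
      tibble(
        sample_id = sample_ids[keep],
        chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]),
        ref = fix$REF[i],
        alt = alts[a],
        genotype = unname(carried[keep])
      )
    })
  })
  rows
}

#' Write cohort variant calls as a minimal VCF
#'
#' Emits a VCF v4.2 with GT-only genotype columns for every manifest sample,
#' sites sorted by (chrom, pos, ref, alt). Hemizygous calls are written as
#' haploid genotypes.
#'
#' @param dataset A `cohort_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(dataset, path) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  v <- dataset$variants
  samples <- dataset$samples$sample_id
  sites <- v %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  gt_code <- c(het = "0/1", hom_alt = "1/1", hemi = "1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- character(nrow(sites))
  if (nrow(sites) > 0) {
    v_key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
    for (i in seq_len(nrow(sites))) {
      key <- paste(sites$chrom[i], sites$pos[i], sites$ref[i], sites$alt[i], sep = ":")
      hit <- v[v_key == key, ]
      cells <- setNames(rep("0/0", length(samples)), samples)
      cells[hit$sample_id] <- gt_code[hit$genotype]
      body[i] <- paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i],
                         sites$alt[i], ".", "PASS", ".", "GT", cells),
                       collapse = "\t")
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write and re-read a cohort dataset
#'
#' `write_cohort()` serialises a dataset into a directory using the same
#' dialects the readers consume: `panel.bed` + `panel_genes.tsv`,
#' `manifest.tsv`, `calls.vcf`, `annotations.tsv` and `constraints.tsv`.
#' `read_cohort()` reverses it; the round trip reproduces the dataset
#' record for record.
#'
#' @param dataset A `cohort_dataset`.
#' @param dir Directory (created if needed).
#' @return `write_cohort()`: `dir` invisibly; `read_cohort()`: a
#'   `cohort_dataset`.
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel_bed(dataset$panel, file.path(dir, "panel.bed"))
  readr::write_tsv(dataset$panel$genes, file.path(dir, "panel_genes.tsv"))
  write_manifest(dataset$samples, file.path(dir, "manifest.tsv"))
  write_cohort_vcf(dataset, file.path(dir, "calls.vcf"))
  ann <- dataset$variants %>%
    select(-dplyr::all_of(c("sample_id", "genotype"))) %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .keep_all = TRUE) %>%
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  readr::write_tsv(ann, file.path(dir, "annotations.tsv"), na = "NA")
  readr::write_tsv(dataset$constraints, file.path(dir, "constraints.tsv"), na = "NA")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  panel <- read_panel_bed(
    file.path(dir, "panel.bed"),
    genes = readr::read_tsv(file.path(dir, "panel_genes.tsv"),
                            col_types = "cll")
  )
  constraints <- readr::read_tsv(file.path(dir, "constraints.tsv"),
                                 col_types = "cddddd", na = c("", "NA"))
  read_variant_annotations(
    vcf_path = file.path(dir, "calls.vcf"),
    annotation_path = file.path(dir, "annotations.tsv"),
    manifest_path = file.path(dir, "manifest.tsv"),
    panel = panel, constraints = constraints
  )
}
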