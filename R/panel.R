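#' Construct a panel design from interval and gene tables
#'
#' A panel design couples the capture intervals (BED convention: 0-based,
#' half-open) with the per-gene category labels used by tier assignment:
#' whether a gene is an established disease gene or a research candidate.
#'
#' @param intervals A data frame with columns `chrom`, `start`, `end`, `gene`
#'   (0-based half-open coordinates).
#' @param genes Optional data frame with columns `gene`,
#'   `known_disease_gene`, `candidate_gene`. Defaults to all genes flagged as
#'   candidates.
#' @return A `panel_design` object: a list with tibbles `intervals` (sorted
#'   by chromosome then start) and `genes`.
#' @export
#' @examples
#' panel_design(tibble::tibble(
#'   chrom = "1", start = c(0, 200), end = c(100, 250), gene = "GENE1"
#' ))
panel_design <- function(intervals, genes = NULL) {
  intervals <- as_tibble(intervals)
  req <- c("chrom", "start", "end", "gene")
  miss <- setdiff(req, names(intervals))
  if (length(miss) > 0) {
    abort(paste0("panel intervals missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(intervals) == 0) abort("no intervals")
  if (any(!nzchar(intervals$chrom) | is.na(intervals$chrom))) {
    abort("interval chrom must be non-empty")
  }
  bad <- which(intervals$start >= intervals$end)
  if (length(bad) > 0) {
    abort(paste0("interval start >= end at row ", bad[1]))
  }
  intervals <- intervals %>%
    select(dplyr::all_of(req)) %>%
    arrange(.data$chrom, .data$start, .data$end, .data$gene)
  if (is.null(genes)) {
    genes <- tibble(
      gene = sort(unique(intervals$gene)),
      known_disease_gene = FALSE,
      candidate_gene = TRUE
    )
  } else {
    genes <- as_tibble(genes)
    extra <- setdiff(unique(intervals$gene), genes$gene)
    if (length(extra) > 0) {
      abort(paste0("genes table missing panel gene(s): ",
                   paste(head(extra, 5), collapse = ", ")))
    }
    genes <- genes %>%
      select(dplyr::all_of(c("gene", "known_disease_gene", "candidate_gene"))) %>%
      arrange(.data$gene)
  }
  structure(list(intervals = intervals, genes = genes), class = "panel_design")
}

#' Read a panel design from a 4-column BED file
#'
#' Expects `chrom start end gene`, tab-separated, 0-based half-open, no
#' header. Extra columns are ignored; malformed lines are reported with
#' their line number.
#'
#' @param path Path to the BED file.
#' @param genes Optional gene-category table passed to [panel_design()].
#' @return A `panel_design`.
#' @export
read_panel_bed <- function(path, genes = NULL) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) abort("no intervals")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_f <- lengths(fields)
  if (any(n_f < 4)) {
    abort(paste0("malformed BED line ", which(n_f < 4)[1],
                 ": fewer than 4 tab-separated fields"))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    abort(paste0("malformed BED line ", which(is.na(start) | is.na(end))[1],
                 ": non-numeric coordinate"))
  }
  intervals <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start,
    end = end,
    gene = vapply(fields, `[[`, "", 4L)
  )
  if (any(intervals$start >= intervals$end)) {
    abort(paste0("invalid interval at BED line ",
                 which(intervals$start >= intervals$end)[1], ": start >= end"))
  }
  panel_design(intervals, genes = genes)
}

#' Write a panel design to a 4-column BED file
#' @param panel A `panel_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(inherits(panel, "panel_design"))
  readr::write_tsv(panel$intervals, path, col_names = FALSE)
  invisible(path)
}

#' Panel summary quantities
#'
#' `panel_n_genes()` counts distinct gene symbols, `panel_span()` sums
#' interval widths (bp).
#'
#' @param panel A `panel_design`.
#' @return A single number.
#' @export
panel_n_genes <- function(panel) {
  stopifnot(inherits(panel, "panel_design"))
  dplyr::n_distinct(panel$intervals$gene)
}

#' @rdname panel_n_genes
#' @export
panel_span <- function(panel) {
  stopifnot(inherits(panel, "panel_design"))
  sum(panel$intervals$end - panel$intervals$start)
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("<panel_design> %d genes, %d intervals, %s bp\n",
              panel_n_genes(x), nrow(x$intervals),
              format(panel_span(x), big.mark = ",")))
  invisible(x)
}

# TRUE for each (chrom, pos[1-based]) inside a panel interval. This is the
# single place where 1-based variant coordinates meet 0-based BED intervals.
in_panel <- function(chrom, pos, panel) {
  iv <- panel$intervals
  out <- logical(length(chrom))
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    ivc <- iv[iv$chrom == cc, , drop = FALSE]
    if (nrow(ivc) == 0) next
    p <- pos[sel]
    hit <- vapply(p, function(x) any(x > ivc$start & x <= ivc$end), logical(1))
    out[sel] <- hit
  }
  out
}

# All 1-based panel positions as a tibble(chrom, pos). Used by QC and the
# coverage simulator; panels are expected to be desk-scale here.
panel_positions <- function(panel) {
  iv <- panel$intervals
  tibble(
    chrom = rep(iv$chrom, iv$end - iv$start),
    pos = unlist(purrr::map2(iv$start, iv$end, ~ seq(.x + 1L, .y))),
    gene = rep(iv$gene, iv$end - iv$start)
  )
}
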