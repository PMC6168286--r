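#' Resolve transcription start sites
#'
#' Fills a `tss` column on a gene table. Where an experimental TSS table
#' provides a position for a gene (the strongest TSS called for that gene),
#' it is used; otherwise the start of the CDS is substituted, strand-aware:
#' `cds_start` for `+` genes, `cds_end` for `-` genes (the half-open end
#' coordinate, i.e. the first transcribed base is `cds_end - 1`).
#'
#' @param genes Tibble with `gene_id`, `chrom`, `strand`, `cds_start`,
#'   `cds_end`.
#' @param tss_table Optional tibble with `gene_id`, `tss`. Entries for genes
#'   absent from `genes` are an error.
#' @return `genes` with a `tss` column (integer position, 0-based).
#' @export
resolve_tss <- function(genes, tss_table = NULL) {
  check_cols(genes, c("gene_id", "chrom", "strand", "cds_start", "cds_end"),
             "genes")
  if (any(genes$cds_start >= genes$cds_end)) {
    abort("genes must satisfy cds_start < cds_end")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  fallback <- ifelse(genes$strand == "+", genes$cds_start, genes$cds_end)
  tss <- fallback
  if (!is.null(tss_table)) {
    check_cols(tss_table, c("gene_id", "tss"), "tss_table")
    unknown <- setdiff(tss_table$gene_id, genes$gene_id)
    if (length(unknown) > 0) {
      abort(sprintf("tss_table refers to gene(s) absent from annotation: %s",
                    paste(utils::head(unknown, 5), collapse = ", ")))
    }
    i <- match(genes$gene_id, tss_table$gene_id)
    tss <- ifelse(is.na(i), fallback, tss_table$tss[i])
  }
  genes$tss <- as.integer(tss)
  genes
}

#' Promoter intervals downstream of the TSS
#'
#' The promoter window runs from the TSS `offset` bp in the direction of
#' transcription: `[tss, tss + offset)` for `+` genes and
#' `[tss - offset, tss)` for `-` genes, clipped at chromosome ends so its
#' length is at most `offset`.
#'
#' @param genes Gene tibble carrying a `tss` column (see [resolve_tss()]).
#' @param genome A [genome_model()] for clipping.
#' @param offset Window extent in bp (default 500).
#' @return `genes` with `promoter_start`, `promoter_end` columns.
#' @export
promoter_intervals <- function(genes, genome, offset = 500) {
  check_cols(genes, c("gene_id", "chrom", "strand", "tss"), "genes")
  if (offset <= 0) abort("offset must be positive")
  len <- chrom_length(genome, genes$chrom)
  if (any(genes$tss < 0 | genes$tss > len)) {
    abort("TSS outside chromosome bounds")
  }
  ps <- ifelse(genes$strand == "+", genes$tss, pmax(0L, genes$tss - offset))
  pe <- ifelse(genes$strand == "+", pmin(len, genes$tss + offset), genes$tss)
  genes$promoter_start <- as.integer(ps)
  genes$promoter_end <- as.integer(pe)
  genes
}

#' Select genes with unambiguous promoters
#'
#' Flags the genes whose promoter window (TSS to TSS+`offset` in the
#' direction of transcription) can be unambiguously attributed to that gene:
#' the window must not intersect any excluded region (age-amplified
#' sequence) and must not intersect the ORF body of any *other* annotated
#' gene on either strand. The gene whose promoter is contaminated is the one
#' removed; the overlapping ORF itself stays in the annotation.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `cds_start`,
#'   `cds_end`, optional `tss`).
#' @param genome A [genome_model()].
#' @param excluded Optional region tibble of excluded intervals. The
#'   expanded rDNA interval is always excluded.
#' @param tss_table Optional TSS table passed to [resolve_tss()] when
#'   `genes` lacks a `tss` column.
#' @param offset Promoter extent in bp (default 500).
#' @return `genes` with `tss`, `promoter_start`, `promoter_end`,
#'   `overlaps_excluded`, `overlaps_orf` and `unambiguous` columns.
#' @export
select_unambiguous_genes <- function(genes, genome, excluded = NULL,
                                     tss_table = NULL, offset = 500) {
  if (!"tss" %in% names(genes)) genes <- resolve_tss(genes, tss_table)
  genes <- promoter_intervals(genes, genome, offset = offset)

  excl <- rdna_expanded_region(genome)[, c("chrom", "start", "end")]
  if (!is.null(excluded)) {
    check_cols(excluded, c("chrom", "start", "end"), "excluded")
    excl <- dplyr::bind_rows(excl, excluded[, c("chrom", "start", "end")])
  }

  prom <- tibble(chrom = genes$chrom, start = genes$promoter_start,
                 end = genes$promoter_end)
  ok <- prom$start < prom$end   # fully clipped promoters are degenerate
  hits_excl <- rep(FALSE, nrow(genes))
  hits_excl[ok] <- overlaps_any_tbl(prom[ok, ], excl)

  orf <- tibble(chrom = genes$chrom, start = genes$cds_start,
                end = genes$cds_end)
  hit <- find_hits(prom[ok, ], orf)
  idx <- which(ok)
  self <- idx[S4Vectors::queryHits(hit)] == S4Vectors::subjectHits(hit)
  hits_orf <- rep(FALSE, nrow(genes))
  hits_orf[unique(idx[S4Vectors::queryHits(hit)[!self]])] <- TRUE

  genes$overlaps_excluded <- hits_excl
  genes$overlaps_orf <- hits_orf
  genes$unambiguous <- ok & !hits_excl & !hits_orf
  genes
}
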