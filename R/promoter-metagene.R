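#' Promoter-window ChIP signal per gene
#'
#' Counts ChIP reads (by their 5' position) falling in each gene's promoter
#' window (TSS to TSS+500 bp in the direction of transcription) and applies
#' the sample's spike normalization factor. Restricted to the supplied gene
#' set, normally the unambiguous-promoter genes from
#' [select_unambiguous_genes()].
#'
#' @param reads ChIP read tibble: `sample_id`, `chrom`, `pos` (0-based 5'
#'   position).
#' @param genes Gene tibble carrying `promoter_start`, `promoter_end`
#'   (see [promoter_intervals()]); rows with `unambiguous == FALSE` are
#'   dropped when that column is present.
#' @param factors Optional `spike_factors` table; when given the counts are
#'   normalized.
#' @param scale Readability scale used with `factors`.
#' @return Tibble of class `promoter_signal`: `gene_id`, `sample_id`,
#'   `count` and (with factors) `norm_count`; zero-filled for covered genes
#'   with no reads.
#' @export
promoter_signal <- function(reads, genes, factors = NULL, scale = 1e6) {
  check_cols(reads, c("sample_id", "chrom", "pos"), "reads")
  check_cols(genes, c("gene_id", "chrom", "promoter_start", "promoter_end"),
             "genes")
  if ("unambiguous" %in% names(genes)) {
    genes <- genes[genes$unambiguous, , drop = FALSE]
  }
  genes <- genes[genes$promoter_start < genes$promoter_end, , drop = FALSE]

  rgr <- tbl_to_gr(tibble(chrom = reads$chrom, start = reads$pos,
                          end = reads$pos + 1L))
  pgr <- tbl_to_gr(tibble(chrom = genes$chrom, start = genes$promoter_start,
                          end = genes$promoter_end))
  hit <- GenomicRanges::findOverlaps(rgr, pgr, ignore.strand = TRUE)
  tallied <- tibble(
    sample_id = reads$sample_id[S4Vectors::queryHits(hit)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hit)]
  ) |>
    dplyr::count(.data$sample_id, .data$gene_id, name = "count")

  out <- tidyr::expand_grid(sample_id = unique(reads$sample_id),
                            gene_id = genes$gene_id) |>
    dplyr::left_join(tallied, by = c("sample_id", "gene_id")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  if (!is.null(factors)) out <- apply_norm(out, factors, scale = scale)
  class(out) <- c("promoter_signal", class(out))
  out
}

#' TSS-anchored metagene profile
#'
#' Averages normalized ChIP signal over all genes in strand-oriented bins
#' spanning TSS +/- `flank` bp. Profiles of `-` strand genes are flipped so
#' positive offsets always point downstream of transcription; genes whose
#' flanks run off a chromosome end are dropped. Genes are averaged with
#' equal weight (total bin count divided by gene count).
#'
#' @param reads ChIP read tibble: `sample_id`, `chrom`, `pos`.
#' @param genes Gene tibble with `tss` and `strand` (see [resolve_tss()]).
#' @param genome A [genome_model()] (for the flank-coverage check).
#' @param factors Optional `spike_factors` table.
#' @param flank Half-width of the profiled region in bp (default 2000).
#' @param bin Bin width in bp (default 50).
#' @param scale Readability scale used with `factors`.
#' @return Tibble of class `metagene_profile`: `sample_id`, `offset` (bin
#'   start relative to TSS), `signal`, `n_genes`.
#' @export
metagene_profile <- function(reads, genes, genome, factors = NULL,
                             flank = 2000, bin = 50, scale = 1e6) {
  check_cols(reads, c("sample_id", "chrom", "pos"), "reads")
  check_cols(genes, c("gene_id", "chrom", "strand", "tss"), "genes")
  if (flank %% bin != 0) abort("flank must be a multiple of bin")
  len <- chrom_length(genome, genes$chrom)
  keep <- genes$tss - flank >= 0 & genes$tss + flank + 1 <= len
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0) abort("no gene has full flanks within its chromosome")

  rgr <- tbl_to_gr(tibble(chrom = reads$chrom, start = reads$pos,
                          end = reads$pos + 1L))
  # window widened by 1 bp so the offset filter below, not the overlap edge,
  # decides membership on both strands (keeps strand-mirror symmetry exact)
  ggr <- tbl_to_gr(tibble(chrom = genes$chrom, start = genes$tss - flank,
                          end = genes$tss + flank + 1L))
  hit <- GenomicRanges::findOverlaps(rgr, ggr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hit)
  si <- S4Vectors::subjectHits(hit)
  offset <- ifelse(genes$strand[si] == "+",
                   reads$pos[qi] - genes$tss[si],
                   genes$tss[si] - reads$pos[qi])
  ok <- offset >= -flank & offset < flank
  binned <- tibble(
    sample_id = reads$sample_id[qi[ok]],
    bin_start = (floor((offset[ok] + flank) / bin)) * bin - flank
  ) |>
    dplyr::count(.data$sample_id, .data$bin_start, name = "count")

  grid <- tidyr::expand_grid(
    sample_id = unique(reads$sample_id),
    bin_start = seq.int(-flank, flank - bin, by = bin)
  )
  out <- grid |>
    dplyr::left_join(binned, by = c("sample_id", "bin_start")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  n_genes = nrow(genes),
                  signal = .data$count / .data$n_genes) |>
    dplyr::rename(offset = "bin_start")
  if (!is.null(factors)) {
    i <- match(out$sample_id, factors$sample_id)
    if (anyNA(i)) abort("missing normalization factor for a sample")
    out$signal <- out$signal * factors$factor[i] * scale
  }
  class(out) <- c("metagene_profile", class(out))
  out
}
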