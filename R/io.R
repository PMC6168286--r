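#' Read a two-column chrom.sizes file
#'
#' @param path Tab-separated file: chromosome name, length.
#' @param mito Name of the mitochondrial contig, if any.
#' @return Tibble suitable for [genome_model()]'s `chroms` argument.
#' @export
read_chrom_sizes <- function(path, mito = NULL) {
  tbl <- readr::read_tsv(path, col_names = c("name", "length"),
                         col_types = readr::cols(
                           name = readr::col_character(),
                           length = readr::col_integer()))
  tbl$is_mito <- !is.null(mito) & tbl$name %in% mito
  tbl
}

#' Read gene annotation from GFF3/GTF
#'
#' Imports features of type `gene` (falling back to `CDS` when no gene
#' features exist) and converts to the package's 0-based half-open
#' convention. GFF3 is 1-based closed, so `cds_start = start - 1`,
#' `cds_end = end`.
#'
#' @param path GFF3 or GTF file.
#' @return Gene tibble (`gene_id`, `chrom`, `strand`, `cds_start`,
#'   `cds_end`).
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path)
  types <- as.character(gr$type)
  keep <- if (any(types == "gene")) types == "gene" else types == "CDS"
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else NULL
  if (is.null(id) && "gene_id" %in% names(md)) id <- as.character(md$gene_id)
  if (is.null(id) && "Name" %in% names(md)) id <- as.character(md$Name)
  if (is.null(id)) abort("no ID/gene_id/Name attribute in annotation")
  tibble(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    cds_start = GenomicRanges::start(gr) - 1L,
    cds_end = GenomicRanges::end(gr)
  )
}

#' Read a BED file of regions
#'
#' @param path BED3+ file (0-based half-open on disk).
#' @param label Label attached to every interval.
#' @return Region tibble (`chrom`, `start`, `end`, `label`).
#' @export
read_bed_regions <- function(path, label = "excluded") {
  gr <- rtracklayer::import(path, format = "BED")
  out <- gr_to_tbl(gr)
  out$label <- label
  out
}

#' Read a TSS table from BED6
#'
#' Each record is one called TSS with `name` = gene id and `score` = TSS
#' strength; where a gene has several records the strongest is kept, ties
#' broken by position for determinism.
#'
#' @param path BED6 file.
#' @return Tibble (`gene_id`, `tss`) usable with [resolve_tss()].
#' @export
read_tss_table <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tbl <- tibble(
    gene_id = gr$name,
    tss = GenomicRanges::start(gr) - 1L,
    score = if (!is.null(gr$score)) gr$score else 0
  )
  tbl |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$score), .data$tss) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::select("gene_id", "tss")
}

#' Write intervals as BED
#'
#' @param tbl Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(tbl, path) {
  check_cols(tbl, c("chrom", "start", "end"), "tbl")
  cols <- list(tbl$chrom, tbl$start, tbl$end)
  if ("name" %in% names(tbl)) {
    cols <- c(cols, list(tbl$name,
                         if ("score" %in% names(tbl)) tbl$score else 0,
                         if ("strand" %in% names(tbl)) tbl$strand else "."))
  }
  out <- do.call(data.frame, stats::setNames(cols, paste0("V", seq_along(cols))))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-window track as bedGraph
#'
#' @param track Tibble with `chrom`, `start`, `end` and the value column.
#' @param path Output path.
#' @param value Name of the value column (default `"value"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = "value") {
  check_cols(track, c("chrom", "start", "end", value), "track")
  out <- data.frame(track$chrom, track$start, track$end, track[[value]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
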