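#' Disambiguate reads between target and spike-in genomes
#'
#' Reads aligned to both the target genome and the spike-in genome are
#' classified so that every read lands in exactly one category. Any read
#' with alignments in *both* genomes is discarded from all downstream
#' counting, in both genomes; this is applied symmetrically, so the order of
#' the two cross-mapping passes does not matter.
#'
#' Categories: `target` (target genome only), `spike_unique` (spike genome
#' only, uniquely mapping), `spike_multi` (spike genome only, multi-mapping),
#' `cross_discarded` (both genomes), `unmapped` (neither).
#'
#' @param reads Read-hit tibble with logical columns `maps_target`,
#'   `maps_spike`, `spike_unique`, a `read_id` column, and optionally
#'   `sample_id`. `read_id` must be unique within a sample.
#' @return `reads` with a `label` factor column.
#' @export
disambiguate_reads <- function(reads) {
  check_cols(reads, c("read_id", "maps_target", "maps_spike", "spike_unique"),
             "reads")
  key <- if ("sample_id" %in% names(reads)) {
    paste(reads$sample_id, reads$read_id)
  } else {
    reads$read_id
  }
  if (anyDuplicated(key)) abort("duplicate read_id within a sample")
  if (any(reads$spike_unique & !reads$maps_spike)) {
    abort("spike_unique implies maps_spike")
  }
  reads$label <- factor(
    dplyr::case_when(
      reads$maps_target & reads$maps_spike ~ "cross_discarded",
      reads$maps_target ~ "target",
      reads$maps_spike & reads$spike_unique ~ "spike_unique",
      reads$maps_spike ~ "spike_multi",
      TRUE ~ "unmapped"
    ),
    levels = c("target", "spike_unique", "spike_multi", "cross_discarded",
               "unmapped")
  )
  reads
}

#' Per-sample assignment summary and the Y / D counts
#'
#' Tallies disambiguation categories and computes the two counts feeding
#' spike-in normalization: `Y`, target-genome reads lying outside the
#' expanded rDNA interval and off the mitochondrial contig, and `D`,
#' uniquely mapping spike-in reads. Optionally `Y` can additionally exclude
#' a wider excluded-region set.
#'
#' @param reads Labelled read tibble from [disambiguate_reads()]. Target
#'   reads must carry `chrom` and `pos` (0-based position used for region
#'   membership).
#' @param genome A [genome_model()].
#' @param excluded Optional region tibble also excluded from `Y` (off by
#'   default; the normalization count named in the method excludes only
#'   rDNA and mitochondrial sequence).
#' @return One-row-per-sample tibble with `n_target`, `n_spike_unique`,
#'   `n_spike_multi`, `n_cross_discarded`, `n_unmapped`, `n_total`, `Y`,
#'   `D`.
#' @export
assignment_summary <- function(reads, genome, excluded = NULL) {
  if (!"label" %in% names(reads)) abort("run disambiguate_reads() first")
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "sample"
  if (!"chrom" %in% names(reads)) reads$chrom <- NA_character_
  if (!"pos" %in% names(reads)) reads$pos <- NA_integer_
  tgt <- reads[reads$label == "target", , drop = FALSE]
  if (nrow(tgt) > 0) {
    check_cols(tgt, c("chrom", "pos"), "reads (target rows)")
    len <- chrom_length(genome, tgt$chrom)
    if (any(tgt$pos < 0 | tgt$pos >= len)) {
      abort("read position outside chromosome bounds")
    }
  }

  in_y <- function(chrom, pos) {
    rd <- genome$rdna
    out <- !(chrom %in% mito_chrom(genome)) &
      !(chrom == rd$chrom & pos >= rd$expanded_start & pos < rd$expanded_end)
    if (!is.null(excluded)) {
      for (i in seq_len(nrow(excluded))) {
        out <- out & !(chrom == excluded$chrom[i] &
                         pos >= excluded$start[i] & pos < excluded$end[i])
      }
    }
    out
  }

  reads |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_target = sum(.data$label == "target"),
      n_spike_unique = sum(.data$label == "spike_unique"),
      n_spike_multi = sum(.data$label == "spike_multi"),
      n_cross_discarded = sum(.data$label == "cross_discarded"),
      n_unmapped = sum(.data$label == "unmapped"),
      n_total = dplyr::n(),
      Y = sum(.data$label == "target" & in_y(.data$chrom, .data$pos)),
      D = sum(.data$label == "spike_unique"),
      .groups = "drop"
    )
}
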