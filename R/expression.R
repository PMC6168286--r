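#' Normalize a strand-resolved expression matrix
#'
#' Size factors are the per-sample totals of mRNA-derived reads over
#' annotated ORFs, excluding rDNA-locus and mitochondrial genes. In
#' opposite-strand-specific (dUTP) libraries the mRNA-derived reads are the
#' ones mapping antisense to the ORF; in the count table produced by
#' [sense_antisense_counts()] that orientation is already resolved into the
#' `sense` column. Excluding the rDNA is essential in aged samples, where
#' polyadenylated rDNA non-coding RNAs can dominate the library. Samples
#' are rescaled to the smallest eligible total.
#'
#' @param counts Tibble `gene_id`, `sample_id`, `sense`, `antisense`.
#' @param genes Gene tibble with logical `is_rdna`, `is_mito` columns (or
#'   `chrom`/coordinates plus `genome` to derive them).
#' @param genome Optional [genome_model()] used to derive the flags when
#'   absent.
#' @return `counts` with `sense_norm`, `antisense_norm` columns; the factor
#'   table is attached as attribute `"size_factors"`.
#' @export
normalize_expression <- function(counts, genes, genome = NULL) {
  check_cols(counts, c("gene_id", "sample_id", "sense", "antisense"), "counts")
  genes <- flag_rdna_mito(genes, genome)
  eligible <- genes$gene_id[!genes$is_rdna & !genes$is_mito]
  totals <- counts |>
    dplyr::filter(.data$gene_id %in% eligible) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$sense), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort("zero eligible mRNA-strand total for a sample; cannot normalize")
  }
  totals$size_factor <- min(totals$total) / totals$total
  i <- match(counts$sample_id, totals$sample_id)
  counts$sense_norm <- counts$sense * totals$size_factor[i]
  counts$antisense_norm <- counts$antisense * totals$size_factor[i]
  attr(counts, "size_factors") <- totals
  counts
}

flag_rdna_mito <- function(genes, genome = NULL) {
  if (all(c("is_rdna", "is_mito") %in% names(genes))) return(genes)
  if (is.null(genome)) {
    abort("genes lack is_rdna/is_mito flags and no genome was supplied")
  }
  check_cols(genes, c("chrom", "cds_start", "cds_end"), "genes")
  rd <- genome$rdna
  genes$is_rdna <- genes$chrom == rd$chrom &
    genes$cds_end > rd$expanded_start & genes$cds_start < rd$expanded_end
  genes$is_mito <- genes$chrom %in% mito_chrom(genome)
  genes
}

#' Strand-resolved per-gene read counts
#'
#' Assigns stranded RNA-seq reads to annotated ORF bodies and splits them
#' by orientation. Under the dUTP (opposite-strand-specific) convention the
#' mRNA of a gene yields reads on the strand *opposite* the ORF, so
#' `sense` (mRNA abundance) counts opposite-strand reads and `antisense`
#' (pervasive/antisense transcription) counts same-strand reads; the
#' `"forward"` convention swaps the two.
#'
#' @param reads Stranded read tibble: `sample_id`, `chrom`, `pos`,
#'   `strand` (`"+"`/`"-"`; anything else is an error).
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `cds_start`,
#'   `cds_end`).
#' @param convention `"dUTP"` (default) or `"forward"`.
#' @return Tibble `gene_id`, `sample_id`, `sense`, `antisense`,
#'   zero-filled.
#' @export
sense_antisense_counts <- function(reads, genes,
                                   convention = c("dUTP", "forward")) {
  convention <- match.arg(convention)
  check_cols(reads, c("sample_id", "chrom", "pos", "strand"), "reads")
  check_cols(genes, c("gene_id", "chrom", "strand", "cds_start", "cds_end"),
             "genes")
  if (!all(reads$strand %in% c("+", "-"))) {
    abort("unstranded or invalid read strand; library must be stranded")
  }
  rgr <- tbl_to_gr(tibble(chrom = reads$chrom, start = reads$pos,
                          end = reads$pos + 1L))
  ggr <- tbl_to_gr(tibble(chrom = genes$chrom, start = genes$cds_start,
                          end = genes$cds_end))
  hit <- GenomicRanges::findOverlaps(rgr, ggr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hit)
  si <- S4Vectors::subjectHits(hit)
  opposite <- reads$strand[qi] != genes$strand[si]
  is_sense <- if (convention == "dUTP") opposite else !opposite

  tallied <- tibble(
    sample_id = reads$sample_id[qi],
    gene_id = genes$gene_id[si],
    orientation = c("antisense", "sense")[is_sense + 1L]
  ) |>
    dplyr::count(.data$sample_id, .data$gene_id, .data$orientation)

  tidyr::expand_grid(sample_id = unique(reads$sample_id),
                     gene_id = genes$gene_id,
                     orientation = c("sense", "antisense")) |>
    dplyr::left_join(tallied, by = c("sample_id", "gene_id", "orientation")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "orientation", values_from = "n") |>
    dplyr::select("gene_id", "sample_id", "sense", "antisense")
}

#' Per-gene expression change across age
#'
#' Computes, for every gene, the change between a reference age (log phase)
#' and a terminal age in the two conventions in circulation: the
#' *difference* of mean normalized counts (terminal minus reference) and
#' the *ratio* (terminal over reference). With `center = "mean"` each
#' sample is first rescaled so its mean gene signal is constant, making
#' "change relative to the average gene" explicit.
#'
#' @param counts Normalized count tibble (`gene_id`, `sample_id`, value
#'   column `value_col`).
#' @param samples Sample sheet (`sample_id`, `age`).
#' @param reference,terminal Age labels (defaults `"log"`, `"48h"`).
#' @param value_col Column to analyse (default `"sense_norm"`).
#' @param center `"none"` (default) or `"mean"` (average-normalized).
#' @param pseudocount Added to both means in ratio mode (default 0).
#' @return Tibble `gene_id`, `mean_ref`, `mean_term`, `age_diff`,
#'   `age_ratio`.
#' @export
age_fold_changes <- function(counts, samples, reference = "log",
                             terminal = "48h", value_col = "sense_norm",
                             center = c("none", "mean"), pseudocount = 0) {
  center <- match.arg(center)
  check_cols(counts, c("gene_id", "sample_id", value_col), "counts")
  check_cols(samples, c("sample_id", "age"), "samples")
  for (a in c(reference, terminal)) {
    if (!a %in% samples$age) abort(sprintf("age '%s' absent from samples", a))
  }
  use <- samples[samples$age %in% c(reference, terminal), , drop = FALSE]
  x <- counts |>
    dplyr::inner_join(dplyr::select(use, "sample_id", "age"), by = "sample_id") |>
    dplyr::mutate(value = .data[[value_col]])
  if (center == "mean") {
    x <- x |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(value = .data$value / mean(.data$value)) |>
      dplyr::ungroup()
  }
  x |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      mean_ref = mean(.data$value[.data$age == reference]),
      mean_term = mean(.data$value[.data$age == terminal]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      age_diff = .data$mean_term - .data$mean_ref,
      age_ratio = (.data$mean_term + pseudocount) /
        (.data$mean_ref + pseudocount)
    )
}

#' Per-gene expression change on histone depletion
#'
#' Difference and ratio of mean library-size-normalized counts between the
#' post- and pre-depletion conditions of a (non-stranded) histone-depletion
#' RNA-seq experiment.
#'
#' @param counts Tibble `gene_id`, `sample_id`, `count`.
#' @param samples Sample sheet (`sample_id`, `condition` with values
#'   `"pre"` and `"post"`).
#' @param pseudocount Added to both means in ratio mode (default 0).
#' @return Tibble `gene_id`, `mean_pre`, `mean_post`, `depl_diff`,
#'   `depl_ratio`.
#' @export
depletion_fold_changes <- function(counts, samples, pseudocount = 0) {
  check_cols(counts, c("gene_id", "sample_id", "count"), "counts")
  check_cols(samples, c("sample_id", "condition"), "samples")
  if (!all(c("pre", "post") %in% samples$condition)) {
    abort("samples must include 'pre' and 'post' conditions")
  }
  x <- counts |>
    dplyr::inner_join(dplyr::select(samples, "sample_id", "condition"),
                      by = "sample_id") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(value = .data$count / sum(.data$count) * 1e6) |>
    dplyr::ungroup()
  x |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      mean_pre = mean(.data$value[.data$condition == "pre"]),
      mean_post = mean(.data$value[.data$condition == "post"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      depl_diff = .data$mean_post - .data$mean_pre,
      depl_ratio = (.data$mean_post + pseudocount) /
        (.data$mean_pre + pseudocount)
    )
}

#' Assemble the fold-change table for the age/depletion filter
#'
#' Joins age fold-changes, depletion fold-changes and the
#' galactose-repression flags on the common gene index.
#'
#' @param age_fc Output of [age_fold_changes()].
#' @param depl_fc Output of [depletion_fold_changes()].
#' @param gal_flags Tibble `gene_id`, `gal_repressed` (logical).
#' @return Tibble with `age_*`, `depl_*` and `gal_repressed` columns for
#'   every gene present in both fold-change tables.
#' @export
fold_change_table <- function(age_fc, depl_fc, gal_flags) {
  check_cols(gal_flags, c("gene_id", "gal_repressed"), "gal_flags")
  out <- age_fc |>
    dplyr::inner_join(depl_fc, by = "gene_id") |>
    dplyr::left_join(gal_flags, by = "gene_id")
  out
}

#' Age-induced, depletion-insensitive gene filter
#'
#' Selects the genes whose expression rises with age more than the
#' threshold but does not rise comparably on histone depletion, after
#' removing genes repressed by the galactose-to-glucose shift used in the
#' depletion experiment (whose depletion response is therefore not
#' determined). A gene passes iff `age change > age_threshold` and
#' `depletion change < depletion_threshold` and not `gal_repressed`. The
#' per-gene audit records every criterion outcome.
#'
#' @param fc Fold-change table from [fold_change_table()]; must carry
#'   non-missing `gal_repressed` flags for all genes.
#' @param age_threshold,depletion_threshold Thresholds (default 2 and 2).
#' @param mode `"ratio"` (default; uses `age_ratio`/`depl_ratio`) or
#'   `"difference"` (uses `age_diff`/`depl_diff`).
#' @return `fc` with logical `fail_age`, `fail_depletion`, `fail_gal`,
#'   `pass` columns; class `age_filter`.
#' @export
age_depletion_filter <- function(fc, age_threshold = 2,
                                 depletion_threshold = 2,
                                 mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  cols <- if (mode == "ratio") c("age_ratio", "depl_ratio")
          else c("age_diff", "depl_diff")
  check_cols(fc, c(cols, "gal_repressed"), "fc")
  if (anyNA(fc$gal_repressed)) {
    abort("gal_repressed flags missing for some genes; supply them explicitly")
  }
  age_val <- fc[[cols[1]]]
  dep_val <- fc[[cols[2]]]
  fc$fail_age <- !(age_val > age_threshold)
  fc$fail_depletion <- !(dep_val < depletion_threshold)
  fc$fail_gal <- fc$gal_repressed
  fc$pass <- !fc$fail_age & !fc$fail_depletion & !fc$fail_gal
  attr(fc, "thresholds") <- list(age = age_threshold,
                                 depletion = depletion_threshold, mode = mode)
  class(fc) <- c("age_filter", class(fc))
  fc
}
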