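#' Copy-number-corrected window density
#'
#' For each 1 kb window the spike-normalized ChIP count is divided by the
#' matched input count, cancelling local copy number so that per-copy
#' occupancy is comparable between amplified and single-copy regions. Two
#' input-normalization modes are provided: `"spike"` (default) scales each
#' input by its own library's non-rDNA/non-mito target total `Y_input`,
#' making the ratio comparable across samples; `"raw"` divides by the raw
#' input count.
#'
#' Windows whose input count falls below `input_floor` carry no usable
#' copy-number information; their density is set to `NA` and flagged rather
#' than silently zeroed.
#'
#' @param chip_counts,input_counts Window count tibbles (`sample_id`,
#'   `window_id`, `chrom`, `start`, `end`, `compartment`, `count`) on the
#'   same grid. `chip_counts$sample_id` must appear in `factors$sample_id`.
#' @param factors A `spike_factors` table ([norm_factor_table()]); its
#'   `input_id` column links each ChIP sample to its input sample.
#' @param mode `"spike"` or `"raw"` input normalization.
#' @param input_floor Minimum raw input count for a defined ratio
#'   (default 1).
#' @param scale Readability scale for the normalized ChIP counts.
#' @return Tibble of class `window_density_track`: per window `norm_chip`,
#'   `norm_input`, `density`, `low_input`.
#' @export
window_density <- function(chip_counts, input_counts, factors,
                           mode = c("spike", "raw"), input_floor = 1,
                           scale = 1e6) {
  mode <- match.arg(mode)
  check_cols(chip_counts, c("sample_id", "window_id", "count"), "chip_counts")
  check_cols(input_counts, c("sample_id", "window_id", "count"), "input_counts")
  check_cols(factors, c("sample_id", "input_id", "factor", "y_input"),
             "factors")

  chip <- apply_norm(chip_counts, factors, scale = scale)
  i <- match(chip$sample_id, factors$sample_id)
  chip$input_id <- factors$input_id[i]
  chip$y_input <- factors$y_input[i]

  inp <- dplyr::select(input_counts, input_id = "sample_id", "window_id",
                       input_count = "count")
  out <- dplyr::left_join(chip, inp, by = c("input_id", "window_id"))
  if (anyNA(out$input_count)) {
    abort("window grid mismatch between ChIP and input counts")
  }
  out$norm_input <- switch(mode,
    spike = out$input_count / out$y_input * scale,
    raw = out$input_count
  )
  out$low_input <- out$input_count < input_floor
  out$density <- ifelse(out$low_input, NA_real_,
                        out$norm_count / out$norm_input)
  out <- dplyr::rename(out, norm_chip = "norm_count")
  class(out) <- c("window_density_track", class(out))
  out
}

#' Aggregate density over window classes
#'
#' Summarises a [window_density()] track over groups of windows as the
#' ratio of summed normalized ChIP to summed normalized input (a
#' count-weighted aggregate). For comparing region *classes* — rDNA versus
#' euchromatin, amplified versus single-copy — this estimator is preferred
#' over averaging per-window ratios, whose expectation is inflated by the
#' squared coefficient of variation of the input counts in low-coverage
#' windows.
#'
#' @param dens A `window_density_track` from [window_density()].
#' @param regions Optional region tibble; windows fully inside these are
#'   grouped as `"inside"`, the remaining euchromatic windows as
#'   `"outside"`. Without `regions`, grouping is by `compartment`.
#' @return Tibble `sample_id`, `group`, `density`, `n_windows`.
#' @export
compartment_density <- function(dens, regions = NULL) {
  check_cols(dens, c("sample_id", "compartment", "norm_chip", "norm_input"),
             "dens")
  if (is.null(regions)) {
    dens$group <- dens$compartment
  } else {
    check_cols(dens, c("chrom", "start", "end"), "dens")
    inside <- rep(FALSE, nrow(dens))
    for (i in seq_len(nrow(regions))) {
      inside <- inside | (dens$chrom == regions$chrom[i] &
                            dens$start >= regions$start[i] &
                            dens$end <= regions$end[i])
    }
    dens$group <- ifelse(inside, "inside", "outside")
    dens <- dens[dens$compartment == "euchromatic", , drop = FALSE]
  }
  dens |>
    dplyr::group_by(.data$sample_id, .data$group) |>
    dplyr::summarise(density = sum(.data$norm_chip) / sum(.data$norm_input),
                     n_windows = dplyr::n(), .groups = "drop")
}

#' Compartment totals and the rDNA share of a mark
#'
#' Sums spike-normalized ChIP signal over the rDNA and euchromatic
#' compartments per sample, and reports the rDNA fraction of the total.
#' Because rDNA reads collapse onto the consensus unit, copy-number
#' amplification is inherent in the compartment total; no further scaling
#' is applied. When sample ages are supplied, per-compartment and total
#' fold-changes versus the reference age are added.
#'
#' @param norm_counts Window tibble with `sample_id`, `compartment`,
#'   `norm_count` (e.g. from [apply_norm()] on window counts).
#' @param exclude Optional region tibble; windows overlapping these
#'   (age-amplified excluded regions) are dropped from the euchromatic
#'   totals.
#' @param samples Optional sample sheet (`sample_id`, `age`).
#' @param reference Reference age label for fold-changes (default the
#'   first age encountered).
#' @return Tibble of class `compartment_summary`: per sample `total_rdna`,
#'   `total_euchromatic`, `total`, `fraction_rdna`, and fold-change columns
#'   when `samples` is given.
#' @export
compartment_totals <- function(norm_counts, exclude = NULL, samples = NULL,
                               reference = NULL) {
  check_cols(norm_counts, c("sample_id", "compartment", "norm_count"),
             "norm_counts")
  if (!is.null(exclude) && nrow(exclude) > 0) {
    check_cols(norm_counts, c("chrom", "start", "end"), "norm_counts")
    drop <- overlaps_any_tbl(norm_counts, exclude) &
      norm_counts$compartment == "euchromatic"
    norm_counts <- norm_counts[!drop, , drop = FALSE]
  }
  out <- norm_counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      total_rdna = sum(.data$norm_count[.data$compartment == "rDNA"]),
      total_euchromatic =
        sum(.data$norm_count[.data$compartment == "euchromatic"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      total = .data$total_rdna + .data$total_euchromatic,
      fraction_rdna = ifelse(.data$total > 0,
                             .data$total_rdna / .data$total, NA_real_)
    )
  if (!is.null(samples)) {
    check_cols(samples, c("sample_id", "age"), "samples")
    out <- dplyr::left_join(out, dplyr::select(samples, "sample_id", "age"),
                            by = "sample_id")
    reference <- reference %||% samples$age[1]
    if (!reference %in% out$age) abort("reference age absent from samples")
    ref <- out |>
      dplyr::filter(.data$age == reference) |>
      dplyr::summarise(r_rdna = mean(.data$total_rdna),
                       r_eu = mean(.data$total_euchromatic),
                       r_tot = mean(.data$total))
    out <- out |>
      dplyr::mutate(
        fold_rdna = .data$total_rdna / ref$r_rdna,
        fold_euchromatic = .data$total_euchromatic / ref$r_eu,
        fold_total = .data$total / ref$r_tot
      )
  }
  class(out) <- c("compartment_summary", class(out))
  out
}
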