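#' Copy-number profile from input coverage
#'
#' Per-window copy number is the per-base input read density divided by the
#' genome-wide *median* per-base density over euchromatic windows, so the
#' typical single-copy window sits at CN 1 regardless of sequencing depth.
#' Because all rDNA reads collapse onto the consensus repeat unit, rDNA
#' windows report the total array copy number (baseline copies times any
#' age-linked amplification).
#'
#' @param input_counts Window count tibble: `sample_id`, `window_id`,
#'   `chrom`, `start`, `end`, `compartment`, `count` (input library).
#' @return Tibble of class `copy_number_track` with `density` (per-base)
#'   and `cn` columns added.
#' @export
copy_number_profile <- function(input_counts) {
  check_cols(input_counts,
             c("sample_id", "chrom", "start", "end", "compartment", "count"),
             "input_counts")
  out <- input_counts |>
    dplyr::mutate(density = .data$count / (.data$end - .data$start)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      cn = .data$density /
        stats::median(.data$density[.data$compartment == "euchromatic"])
    ) |>
    dplyr::ungroup()
  if (any(!is.finite(out$cn))) {
    bad <- out |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(tot = sum(.data$count), .groups = "drop")
    if (any(bad$tot == 0)) abort("all-zero input counts for a sample")
  }
  class(out) <- c("copy_number_track", class(out))
  out
}

#' rDNA copy number per sample
#'
#' Aggregates input coverage over the consensus rDNA unit (count-weighted:
#' total unit reads per total unit length) relative to a single-copy
#' euchromatic reference density, one estimate per sample.
#'
#' By default the reference is the euchromatic median density, matching
#' the per-window track. When the excluded-region set is supplied, the
#' reference is instead the *mean* density over euchromatic windows
#' outside those regions: with amplified sequence masked by construction,
#' the mean needs no robustness and, unlike the median of low-count
#' windows, is not integer-quantized, so the scalar estimate stays
#' unbiased at modest sequencing depth.
#'
#' @param cn A `copy_number_track` from [copy_number_profile()].
#' @param exclude Optional region tibble (age-amplified excluded regions)
#'   masked from the reference.
#' @return Tibble `sample_id`, `rdna_cn`.
#' @export
rdna_copy_number <- function(cn, exclude = NULL) {
  check_cols(cn, c("sample_id", "compartment", "count", "start", "end",
                   "density"), "cn")
  eu <- cn$compartment == "euchromatic"
  if (is.null(exclude) || nrow(exclude) == 0) {
    ref_fun <- function(d) {
      stats::median(d$density[d$compartment == "euchromatic"])
    }
  } else {
    keep <- eu & !overlaps_any_tbl(cn, exclude)
    cn$in_ref <- keep
    ref_fun <- function(d) {
      sum(d$count[d$in_ref]) / sum((d$end - d$start)[d$in_ref])
    }
  }
  cn |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ tibble(
      rdna_cn = (sum(.x$count[.x$compartment == "rDNA"]) /
                   sum((.x$end - .x$start)[.x$compartment == "rDNA"])) /
        ref_fun(.x)
    )) |>
    dplyr::ungroup()
}

#' Detect amplified regions from a copy-number track
#'
#' Scans euchromatic windows for maximal runs of at least `min_run`
#' consecutive (coordinate-adjacent) windows whose CN reaches `threshold`,
#' and merges each run into one region. Used to derive the excluded-region
#' set from an aged input sample.
#'
#' @param cn A `copy_number_track` (one sample; subset first if several).
#' @param threshold CN fold threshold (default 2).
#' @param min_run Minimum run length in windows (default 2).
#' @return Region tibble (`chrom`, `start`, `end`, `label`, `mean_cn`).
#' @export
detect_amplified_regions <- function(cn, threshold = 2, min_run = 2) {
  check_cols(cn, c("chrom", "start", "end", "compartment", "cn"), "cn")
  if (dplyr::n_distinct(cn$sample_id %||% "s") > 1) {
    abort("detect_amplified_regions() expects a single sample")
  }
  eu <- cn |>
    dplyr::filter(.data$compartment == "euchromatic") |>
    dplyr::arrange(.data$chrom, .data$start)
  hi <- eu$cn >= threshold
  empty <- tibble(chrom = character(0), start = integer(0),
                  end = integer(0), label = character(0),
                  mean_cn = double(0), n_windows = integer(0))
  if (!any(hi)) return(empty)
  adjacent <- c(FALSE, eu$chrom[-1] == eu$chrom[-nrow(eu)] &
                  eu$start[-1] == eu$end[-nrow(eu)])
  new_run <- hi & (!dplyr::lag(hi, default = FALSE) | !adjacent)
  eu$run <- cumsum(new_run)
  eu$run[!hi] <- NA_integer_
  out <- eu |>
    dplyr::filter(!is.na(.data$run)) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
      n_windows = dplyr::n(), mean_cn = mean(.data$cn), .groups = "drop"
    ) |>
    dplyr::filter(.data$n_windows >= min_run) |>
    dplyr::mutate(label = "amplified") |>
    dplyr::select("chrom", "start", "end", "label", "mean_cn", "n_windows")
  if (nrow(out) == 0) empty else out
}
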