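#' Spike-in normalization factor
#'
#' The per-sample multiplicative factor applied to target-genome ChIP read
#' counts is
#' \deqn{(1/D_{ChIP}) \times (D_{input}/Y_{input})}
#' where \eqn{D_{ChIP}} and \eqn{D_{input}} are uniquely mapping spike-in
#' genome reads in the ChIP and matched input libraries, and
#' \eqn{Y_{input}} is the count of input reads on the target genome outside
#' the rDNA and mitochondrial sequence. `1/D_ChIP` calibrates ChIP depth to
#' the constant spike-in chromatin mass; `D_input/Y_input` converts that to
#' a per-target-genome scale, so normalized signal is comparable per cell
#' across samples even when genome content changes.
#'
#' @param d_chip,d_input,y_input Counts; vectorized, all must be positive.
#' @return Numeric factor(s).
#' @examples
#' norm_factor(2000, 1000, 5e6)  # 1e-7
#' @export
norm_factor <- function(d_chip, d_input, y_input) {
  if (any(d_chip <= 0) || any(d_input <= 0) || any(y_input <= 0)) {
    abort(paste("degenerate spike-in: D_chip, D_input and Y_input must all",
                "be positive counts"))
  }
  (1 / d_chip) * (d_input / y_input)
}

#' Per-sample spike normalization factor table
#'
#' Pairs ChIP samples with their matched inputs and evaluates the
#' normalization factor for each pair.
#'
#' @param pairs Tibble with one row per ChIP sample: `sample_id` (the ChIP
#'   sample), `input_id` (its matched input), `d_chip`, `d_input`,
#'   `y_input`. Alternatively supply `chip_summary` / `input_summary` from
#'   [assignment_summary()] plus a `pairing` tibble (`sample_id`,
#'   `input_id`) and the counts are filled in.
#' @param chip_summary,input_summary,pairing See above.
#' @return Tibble of class `spike_factors`: `sample_id`, `input_id`,
#'   `d_chip`, `d_input`, `y_input`, `factor`.
#' @export
norm_factor_table <- function(pairs = NULL, chip_summary = NULL,
                              input_summary = NULL, pairing = NULL) {
  if (is.null(pairs)) {
    if (is.null(chip_summary) || is.null(input_summary) || is.null(pairing)) {
      abort("supply either `pairs` or chip/input summaries with a pairing")
    }
    check_cols(pairing, c("sample_id", "input_id"), "pairing")
    pairs <- pairing |>
      dplyr::left_join(dplyr::select(chip_summary, "sample_id", d_chip = "D"),
                       by = "sample_id") |>
      dplyr::left_join(dplyr::select(input_summary, input_id = "sample_id",
                                     d_input = "D", y_input = "Y"),
                       by = "input_id")
    if (anyNA(pairs$d_chip) || anyNA(pairs$d_input)) {
      abort("pairing refers to samples missing from the summaries")
    }
  }
  check_cols(pairs, c("sample_id", "d_chip", "d_input", "y_input"), "pairs")
  pairs$factor <- norm_factor(pairs$d_chip, pairs$d_input, pairs$y_input)
  class(pairs) <- c("spike_factors", class(pairs))
  pairs
}

#' Apply spike normalization factors to counts
#'
#' Multiplies each count by its sample's factor (times a global readability
#' scale shared by all samples of a comparison, so cross-sample ratios are
#' unaffected). Linear and order-preserving.
#'
#' @param counts Tibble with `sample_id` and a `count` column.
#' @param factors A `spike_factors` table (or any tibble with `sample_id`,
#'   `factor`).
#' @param scale Global scale applied uniformly (default `1e6`).
#' @param count_col Name of the count column (default `"count"`).
#' @return `counts` with a `norm_count` column.
#' @export
apply_norm <- function(counts, factors, scale = 1e6, count_col = "count") {
  check_cols(counts, c("sample_id", count_col), "counts")
  check_cols(factors, c("sample_id", "factor"), "factors")
  i <- match(counts$sample_id, factors$sample_id)
  if (anyNA(i)) {
    abort(sprintf("no normalization factor for sample(s): %s",
                  paste(unique(counts$sample_id[is.na(i)]), collapse = ", ")))
  }
  counts$norm_count <- counts[[count_col]] * factors$factor[i] * scale
  counts
}

#' @export
print.spike_factors <- function(x, ...) {
  cat(sprintf("<spike_factors> %d ChIP/input pair(s)\n", nrow(x)))
  NextMethod()
}
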