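#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an age/depletion filter result
#'
#' One row per gene with the pass flag and the per-criterion audit.
#'
#' @param x An `age_filter` from [age_depletion_filter()].
#' @param ... Unused.
#' @return Tibble `gene_id`, `pass`, `fail_age`, `fail_depletion`,
#'   `fail_gal`.
#' @export
tidy.age_filter <- function(x, ...) {
  as_tibble(x)[, c("gene_id", "pass", "fail_age", "fail_depletion",
                   "fail_gal")]
}

#' Summarise an age/depletion filter result
#'
#' @param x An `age_filter`.
#' @param ... Unused.
#' @return One-row tibble with gene counts per outcome and the thresholds
#'   used.
#' @export
glance.age_filter <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(
    n_genes = nrow(x), n_pass = sum(x$pass),
    n_fail_age = sum(x$fail_age),
    n_fail_depletion = sum(x$fail_depletion),
    n_fail_gal = sum(x$fail_gal),
    age_threshold = th$age, depletion_threshold = th$depletion,
    mode = th$mode
  )
}

#' Tidy a compartment summary
#'
#' @param x A `compartment_summary` from [compartment_totals()].
#' @param ... Unused.
#' @return Long tibble `sample_id`, `compartment`, `total`.
#' @export
tidy.compartment_summary <- function(x, ...) {
  as_tibble(x) |>
    dplyr::select("sample_id", rDNA = "total_rdna",
                  euchromatic = "total_euchromatic") |>
    tidyr::pivot_longer(c("rDNA", "euchromatic"),
                        names_to = "compartment", values_to = "total")
}

#' Summarise a compartment summary
#'
#' @param x A `compartment_summary`.
#' @param ... Unused.
#' @return One-row tibble with the range of the rDNA fraction across
#'   samples.
#' @export
glance.compartment_summary <- function(x, ...) {
  tibble(
    n_samples = nrow(x),
    min_fraction_rdna = min(x$fraction_rdna, na.rm = TRUE),
    max_fraction_rdna = max(x$fraction_rdna, na.rm = TRUE)
  )
}

#' Summarise a spike-factor table
#'
#' @param x A `spike_factors` table.
#' @param ... Unused.
#' @return One-row tibble with the factor range.
#' @export
glance.spike_factors <- function(x, ...) {
  tibble(n_samples = nrow(x), min_factor = min(x$factor),
         max_factor = max(x$factor))
}
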