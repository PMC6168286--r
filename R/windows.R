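#' Tile a genome into fixed-size windows
#'
#' Produces the analysis grid for copy-number and density profiling: every
#' non-mitochondrial chromosome minus the expanded rDNA interval (and any
#' extra masks) is split into `size`-bp windows, and the rDNA consensus unit
#' is tiled separately as its own compartment. Windows never span a mask
#' boundary, and terminal or mask-abutting windows may be shorter than
#' `size`, so summed window lengths per chromosome exactly equal chromosome
#' length minus masked length.
#'
#' @param genome A [genome_model()].
#' @param masks Optional region tibble (`chrom`, `start`, `end`) of extra
#'   intervals to exclude from the euchromatic grid (e.g. excluded regions).
#' @param size Window size in bp (default 1000).
#' @return Tibble with columns `window_id`, `chrom`, `start`, `end`,
#'   `compartment` (`"euchromatic"` or `"rDNA"`).
#' @export
tile_windows <- function(genome, masks = NULL, size = 1000) {
  if (size <= 0) abort("window size must be positive")
  size <- as.integer(size)
  rd <- genome$rdna
  mask_tbl <- rdna_expanded_region(genome)[, c("chrom", "start", "end")]
  if (!is.null(masks)) {
    check_cols(masks, c("chrom", "start", "end"), "masks")
    if (any(masks$end > chrom_length(genome, masks$chrom))) {
      abort("mask extends beyond chromosome end")
    }
    mask_tbl <- dplyr::bind_rows(mask_tbl, masks[, c("chrom", "start", "end")])
  }

  # split one kept piece [s0, e0) at the fixed grid lines k * size
  split_piece <- function(s0, e0) {
    cuts <- seq.int((s0 %/% size + 1L) * size, by = size,
                    length.out = max(0L, (e0 - 1L) %/% size - s0 %/% size))
    bounds <- c(s0, cuts, e0)
    tibble(start = bounds[-length(bounds)], end = bounds[-1])
  }

  tile_one <- function(chrom, len) {
    m <- mask_tbl[mask_tbl$chrom == chrom, , drop = FALSE]
    if (nrow(m) > 0) {
      mir <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
      keep <- IRanges::setdiff(IRanges::IRanges(1L, len), mir)
      pieces <- tibble(s0 = IRanges::start(keep) - 1L, e0 = IRanges::end(keep))
    } else {
      pieces <- tibble(s0 = 0L, e0 = len)
    }
    win <- purrr::map2_dfr(pieces$s0, pieces$e0, split_piece)
    tibble(chrom = chrom, start = win$start, end = win$end,
           compartment = "euchromatic")
  }

  eu_chroms <- genome$chroms[!genome$chroms$is_mito, ]
  eu <- purrr::map2_dfr(eu_chroms$name, eu_chroms$length, tile_one)

  rstarts <- seq.int(rd$unit_start, rd$unit_end - 1L, by = size)
  rdna <- tibble(chrom = rd$chrom, start = rstarts,
                 end = pmin(rstarts + size, rd$unit_end),
                 compartment = "rDNA")

  out <- dplyr::bind_rows(eu, rdna)
  out <- dplyr::arrange(out, match(.data$chrom, genome$chroms$name), .data$start,
                        .data$compartment)
  out$window_id <- seq_len(nrow(out))
  dplyr::relocate(out, "window_id")
}
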