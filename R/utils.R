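# Internal helpers. Coordinates are 0-based half-open everywhere inside the
# package; IRanges (1-based closed) is used only transiently for interval
# arithmetic, via the two converters below.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# tibble (chrom, start, end) -> GRanges, 0-based half-open in, 1-based out
tbl_to_gr <- function(tbl, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(tbl)))
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = if ("strand" %in% names(tbl)) tbl$strand else "*"
  )
}

gr_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# overlap queries between two interval tibbles on a shared seqlevel set
# (avoids seqlevel-merge warnings when chromosome sets are disjoint)
find_hits <- function(ta, tb) {
  lv <- union(unique(as.character(ta$chrom)), unique(as.character(tb$chrom)))
  ga <- GenomicRanges::GRanges(factor(ta$chrom, lv),
                               IRanges::IRanges(ta$start + 1L, ta$end))
  gb <- GenomicRanges::GRanges(factor(tb$chrom, lv),
                               IRanges::IRanges(tb$start + 1L, tb$end))
  GenomicRanges::findOverlaps(ga, gb)
}

overlaps_any_tbl <- function(ta, tb) {
  out <- rep(FALSE, nrow(ta))
  out[S4Vectors::queryHits(find_hits(ta, tb))] <- TRUE
  out
}

# half-open interval overlap width, vectorized
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

check_cols <- function(tbl, cols, what = deparse(substitute(tbl))) {
  miss <- setdiff(cols, names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(tbl)
}

# named per-age parameter vector: recycle / validate against age labels
per_age <- function(x, ages, what = deparse(substitute(x))) {
  if (is.null(names(x))) {
    if (length(x) == 1) x <- rep(x, length(ages))
    if (length(x) != length(ages)) {
      abort(sprintf("`%s` must have one value per age", what))
    }
    names(x) <- ages
  }
  miss <- setdiff(ages, names(x))
  if (length(miss) > 0) {
    abort(sprintf("`%s` lacks values for age(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
  x[ages]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
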