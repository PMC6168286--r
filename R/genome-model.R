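#' Describe an rDNA locus
#'
#' The rDNA array is represented by a single consensus repeat unit (9 kb by
#' convention) onto which all rDNA-derived reads collapse, plus an expanded
#' exclusion interval around the array that also covers flanking high-copy
#' sequence. In the reference yeast genome the expanded interval is
#' Chr XII 451,000-491,000.
#'
#' @param chrom Chromosome carrying the array.
#' @param unit_start,unit_end Consensus repeat unit, 0-based half-open.
#'   Defaults give a 9 kb unit.
#' @param expanded_start,expanded_end Expanded exclusion interval; must
#'   contain the unit.
#' @param baseline_copies Haploid genomic copy number of the repeat before
#'   any age-linked amplification. The reference assembly collapses the
#'   array, so read density over the unit is proportional to this number.
#' @return A list of class `rdna_locus`.
#' @export
rdna_locus <- function(chrom, unit_start, unit_end = unit_start + 9000,
                       expanded_start = 451000, expanded_end = 491000,
                       baseline_copies = 150) {
  if (unit_end <= unit_start) abort("rDNA unit interval is empty")
  if (expanded_start > unit_start || expanded_end < unit_end) {
    abort("expanded rDNA interval must contain the consensus unit")
  }
  if (baseline_copies <= 0) abort("baseline_copies must be positive")
  structure(
    list(chrom = chrom, unit_start = as.integer(unit_start),
         unit_end = as.integer(unit_end),
         expanded_start = as.integer(expanded_start),
         expanded_end = as.integer(expanded_end),
         baseline_copies = baseline_copies),
    class = "rdna_locus"
  )
}

#' Assemble a genome model
#'
#' Bundles chromosome sizes, the rDNA locus, the mitochondrial contig and
#' the identity of the spike-in genome into the object every coordinate-aware
#' function takes. All coordinates in the package are 0-based half-open.
#'
#' @param chroms Tibble with columns `name`, `length` and optionally
#'   `is_mito` (logical; at most one mitochondrial contig).
#' @param rdna An [rdna_locus()].
#' @param spike_genome Label for the spike-in (reference chromatin) genome.
#' @return A list of class `genome_model`.
#' @examples
#' gm <- genome_model(
#'   tibble::tibble(name = c("chrA", "chrM"), length = c(500000L, 20000L),
#'                  is_mito = c(FALSE, TRUE)),
#'   rdna_locus("chrA", 455000, expanded_start = 451000,
#'              expanded_end = 491000)
#' )
#' @export
genome_model <- function(chroms, rdna, spike_genome = "spikein") {
  check_cols(chroms, c("name", "length"), "chroms")
  if (!"is_mito" %in% names(chroms)) chroms$is_mito <- FALSE
  if (anyDuplicated(chroms$name)) abort("chromosome names must be unique")
  if (any(chroms$length <= 0)) abort("chromosome lengths must be positive")
  if (sum(chroms$is_mito) > 1) abort("at most one mitochondrial contig")
  if (!inherits(rdna, "rdna_locus")) abort("`rdna` must be an rdna_locus()")
  if (!rdna$chrom %in% chroms$name) abort("rDNA chromosome not in `chroms`")
  rlen <- chroms$length[chroms$name == rdna$chrom]
  if (rdna$expanded_end > rlen) abort("expanded rDNA interval exceeds chromosome")
  structure(
    list(chroms = as_tibble(chroms), rdna = rdna, spike_genome = spike_genome),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosomes, %s bp total\n",
              nrow(x$chroms), format(sum(x$chroms$length), big.mark = ",")))
  cat(sprintf("  rDNA: %s [%d,%d) unit, [%d,%d) expanded, %g baseline copies\n",
              x$rdna$chrom, x$rdna$unit_start, x$rdna$unit_end,
              x$rdna$expanded_start, x$rdna$expanded_end,
              x$rdna$baseline_copies))
  mito <- x$chroms$name[x$chroms$is_mito]
  cat(sprintf("  mito: %s | spike-in genome: %s\n",
              if (length(mito)) mito else "<none>", x$spike_genome))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chroms$name)
  if (anyNA(i)) abort(sprintf("unknown chromosome(s): %s",
                              paste(unique(chrom[is.na(i)]), collapse = ", ")))
  genome$chroms$length[i]
}

mito_chrom <- function(genome) {
  m <- genome$chroms$name[genome$chroms$is_mito]
  if (length(m)) m else NA_character_
}

#' Build a region set
#'
#' A validated tibble of half-open genomic intervals, used for excluded
#' regions (age-amplified sequence masked from chromatin analyses) and other
#' masks.
#'
#' @param chrom,start,end Vectors defining the intervals (0-based half-open).
#' @param label Region class label.
#' @param genome Optional [genome_model()] for bounds checking.
#' @return Tibble with columns `chrom`, `start`, `end`, `label`.
#' @export
region_set <- function(chrom, start, end, label = "excluded", genome = NULL) {
  tbl <- tibble(chrom = as.character(chrom), start = as.integer(start),
                end = as.integer(end), label = label)
  if (any(tbl$start >= tbl$end)) abort("regions must satisfy start < end")
  if (any(tbl$start < 0)) abort("regions must have start >= 0")
  if (!is.null(genome)) {
    if (any(tbl$end > chrom_length(genome, tbl$chrom))) {
      abort("region extends beyond chromosome end")
    }
  }
  tbl
}

# expanded rDNA interval as a one-row region tibble
rdna_expanded_region <- function(genome) {
  region_set(genome$rdna$chrom, genome$rdna$expanded_start,
             genome$rdna$expanded_end, label = "rDNA_expanded")
}
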