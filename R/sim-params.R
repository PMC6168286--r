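#' Default synthetic genome
#'
#' A yeast-like genome for the simulator: six chromosomes totalling about
#' 12 Mb of euchromatin, an 86 kb mitochondrial contig, and a collapsed
#' rDNA array on chrXII (9 kb consensus unit inside the expanded
#' 451,000-491,000 exclusion interval, 150 baseline copies).
#'
#' @param baseline_copies Baseline rDNA copy number (default 150; the
#'   haploid array size is taken as an assumption of the generator, not a
#'   measured quantity).
#' @return A [genome_model()].
#' @export
sim_genome <- function(baseline_copies = 150) {
  chroms <- tibble(
    name = c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrXII", "chrM"),
    length = c(2000000L, 2200000L, 1800000L, 2400000L, 2600000L, 1078000L,
               86000L),
    is_mito = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  genome_model(
    chroms,
    rdna_locus("chrXII", unit_start = 455000, unit_end = 464000,
               expanded_start = 451000, expanded_end = 491000,
               baseline_copies = baseline_copies),
    spike_genome = "dmel"
  )
}

#' Age-amplified fixture regions of the synthetic genome
#'
#' Subtelomeric/transposon-like regions whose copy number rises with age in
#' the simulation, emulating the excluded-region class (telomeres, Ty
#' elements, distal chrXII) that is masked from chromatin analyses.
#'
#' @param genome A [genome_model()] (default [sim_genome()]).
#' @return Region tibble.
#' @export
sim_excluded_regions <- function(genome = sim_genome()) {
  region_set(
    chrom = c("chrV", "chrIV", "chrXII"),
    start = c(0L, 2380000L, 491000L),
    end = c(20000L, 2400000L, 530000L),
    label = "excluded", genome = genome
  )
}

#' Simulation parameters
#'
#' Defines the study conditions the generator emulates: three time points
#' (log phase, 24 h, 48 h of ageing), a 7-fold rDNA copy-number
#' amplification by 48 h, per-copy rDNA H3K4me3 density rising from very
#' low at log phase to the euchromatic level at 48 h, promoter H3K4me3
#' peaks coupled to mRNA induction, a genome-wide rise in antisense
#' transcription, a mild euchromatic H3 decline, and a constant-mass
#' spike-in chromatin admixture in every sample.
#'
#' @param seed Integer seed; every random draw in the generator flows from
#'   it.
#' @param ages Ordered age labels.
#' @param rdna_amplification Per-age fold amplification of the rDNA array
#'   (>= 1).
#' @param rdna_mark_density Per-age per-copy rDNA H3K4me3 density, as a
#'   multiple of the genome-average euchromatic H3K4me3 density at the
#'   first age.
#' @param h3_decline Per-age multiplier on euchromatic H3 density.
#' @param fixture_cn Per-age copy number of the amplified fixture regions.
#' @param antisense_multiplier Per-age multiplier on antisense read rate.
#' @param promoter_peak_gain Exponent coupling promoter-peak H3K4me3
#'   density to relative mRNA level (1 = proportional).
#' @param peak_height Per-copy H3K4me3 density of a promoter peak at
#'   relative expression 1, in units of the euchromatic background.
#' @param k4_background Euchromatic non-peak per-base H3K4me3 density.
#' @param spike_fraction Spike-in DNA mass as a fraction of total DNA at
#'   the first age; the spike *mass* is then held constant across samples.
#' @param spike_mark_density Named per-antigen mark density of the spike
#'   chromatin (per base of spike DNA).
#' @param spike_unique_rate Fraction of spike-derived reads that map
#'   uniquely to the spike genome.
#' @param library_depth Reads per ChIP/input library.
#' @param rna_depth Reads per RNA-seq library.
#' @param n_genes Number of annotated euchromatic genes.
#' @param n_replicates_chip,n_replicates_rna Replicates per time point.
#' @param dispersion Named negative-binomial dispersions for `input`,
#'   `chip` and `rna` counts (Poisson in the limit 0).
#' @param noise `"nb"` for negative-binomial counts, `"none"` for exact
#'   expected values (the noise-free limit used by analytic checks).
#' @param mito_cn Mitochondrial copy number (input DNA only).
#' @param remainder_cn Copy number of the expanded-rDNA remainder (the
#'   flanking high-copy sequence outside the consensus unit), scaled by
#'   the rDNA amplification.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(seed = 1,
                       ages = c("log", "24h", "48h"),
                       rdna_amplification = c(1, 4, 7),
                       rdna_mark_density = c(0.2, 0.5, 1.0),
                       h3_decline = c(1, 0.95, 0.8),
                       fixture_cn = c(1, 2, 3.5),
                       antisense_multiplier = c(1, 2, 3),
                       promoter_peak_gain = 1,
                       peak_height = 6,
                       k4_background = 0.3,
                       spike_fraction = 0.05,
                       spike_mark_density = c(H3K4me3 = 0.5, H3 = 1),
                       spike_unique_rate = 0.9,
                       library_depth = 2e6,
                       rna_depth = 1e6,
                       n_genes = 4000,
                       n_replicates_chip = 2,
                       n_replicates_rna = 5,
                       dispersion = c(input = 0.01, chip = 0.02, rna = 0.05),
                       noise = c("nb", "none"),
                       mito_cn = 8,
                       remainder_cn = 50) {
  noise <- match.arg(noise)
  p <- list(
    seed = as.integer(seed), ages = ages,
    rdna_amplification = per_age(rdna_amplification, ages),
    rdna_mark_density = per_age(rdna_mark_density, ages),
    h3_decline = per_age(h3_decline, ages),
    fixture_cn = per_age(fixture_cn, ages),
    antisense_multiplier = per_age(antisense_multiplier, ages),
    promoter_peak_gain = promoter_peak_gain,
    peak_height = peak_height,
    k4_background = k4_background,
    spike_fraction = spike_fraction,
    spike_mark_density = spike_mark_density,
    spike_unique_rate = spike_unique_rate,
    library_depth = library_depth,
    rna_depth = rna_depth,
    n_genes = as.integer(n_genes),
    n_replicates_chip = as.integer(n_replicates_chip),
    n_replicates_rna = as.integer(n_replicates_rna),
    dispersion = dispersion,
    noise = noise,
    mito_cn = mito_cn,
    remainder_cn = remainder_cn
  )
  if (any(p$rdna_amplification < 1)) abort("rdna_amplification must be >= 1")
  if (p$spike_fraction <= 0 || p$spike_fraction >= 1) {
    abort("spike_fraction must be in (0, 1)")
  }
  if (p$spike_unique_rate < 0 || p$spike_unique_rate > 1) {
    abort("spike_unique_rate must be in [0, 1]")
  }
  if (p$library_depth <= 0 || p$rna_depth <= 0) abort("depths must be positive")
  if (any(p$dispersion < 0)) abort("dispersions must be non-negative")
  if (!all(c("input", "chip", "rna") %in% names(p$dispersion))) {
    abort("dispersion must name input, chip and rna")
  }
  structure(p, class = "sim_params")
}

# NB sampler with Poisson limit; noise = "none" returns the mean itself
sim_counts <- function(mu, dispersion, noise) {
  if (noise == "none") return(mu)
  if (dispersion <= 0) return(stats::rpois(length(mu), mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}
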