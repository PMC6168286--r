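#' Synthetic gene annotation with latent expression programme
#'
#' Lays out non-overlapping ORFs along the euchromatic chromosomes (with a
#' small deliberate fraction of ORFs overlapping the upstream gene's
#' promoter region, so the unambiguous-promoter selection has work to do),
#' adds rDNA-locus and mitochondrial genes, assigns an experimental TSS to
#' 70% of genes, and draws the latent expression programme used by both the
#' chromatin and the expression simulators:
#'
#' * background genes: modest log2 age fold-changes, bounded so that after
#'   average-normalization no background gene exceeds a 2-fold relative
#'   rise;
#' * 20 planted "age-induced, depletion-insensitive" genes (age fold 6,
#'   depletion fold 1) — the set the age/depletion filter should recover;
#' * 15 planted genes induced by both age and histone depletion (both
#'   folds high) — rejected on the depletion criterion;
#' * 10 planted age-induced genes flagged as galactose-repressed —
#'   rejected on the gal criterion.
#'
#' Layout and programme are fully determined by `params$seed`, so the
#' chromatin and expression simulators built from the same parameters share
#' one annotation and one truth.
#'
#' @param genome A [genome_model()].
#' @param params A [sim_params()].
#' @return List with `genes` (annotation tibble with flags and truth
#'   columns), `tss_table`, and `truth` (per-gene latent tibble).
#' @export
sim_genes <- function(genome = sim_genome(), params = sim_params()) {
  withr::with_seed(params$seed + 104729L, {
    eu <- genome$chroms[!genome$chroms$is_mito, ]
    total <- sum(eu$length)
    quota <- pmax(1L, round(params$n_genes * as.numeric(eu$length) / total))
    # keep the exact requested count
    diff <- params$n_genes - sum(quota)
    quota[1] <- quota[1] + diff

    lay_one <- function(chrom, len, n) {
      gap_mean <- max(200, len / n - 1600)
      pos <- 2500
      rows <- vector("list", n)
      k <- 0
      while (k < n && pos < len - 6000) {
        gap <- round(stats::runif(1, 0.3, 1.7) * gap_mean)
        glen <- round(stats::runif(1, 700, 2500))
        s <- pos + gap
        if (s + 300 > len - 100) break   # no room for another ORF
        e <- min(s + glen, len - 100)
        k <- k + 1
        rows[[k]] <- tibble(chrom = chrom, cds_start = as.integer(s),
                            cds_end = as.integer(e),
                            strand = sample(c("+", "-"), 1))
        # occasionally start the next ORF inside this one so its neighbour's
        # promoter (or its own) is contaminated
        pos <- if (stats::runif(1) < 0.04) s + round(glen * 0.5) else e
      }
      dplyr::bind_rows(rows[seq_len(k)])
    }

    genes <- purrr::pmap_dfr(list(eu$name, eu$length, quota), lay_one)
    genes$gene_id <- sprintf("g%05d", seq_len(nrow(genes)))
    genes$is_rdna <- FALSE
    genes$is_mito <- FALSE

    rd <- genome$rdna
    special <- tibble(
      chrom = c(rd$chrom, rd$chrom, mito_chrom(genome), mito_chrom(genome)),
      cds_start = c(rd$unit_start + 500L, rd$unit_start + 4000L, 2000L, 30000L),
      cds_end = c(rd$unit_start + 3900L, rd$unit_start + 8500L, 8000L, 42000L),
      strand = c("+", "-", "+", "+"),
      gene_id = c("RDN-1", "RDN-2", "MT-1", "MT-2"),
      is_rdna = c(TRUE, TRUE, FALSE, FALSE),
      is_mito = c(FALSE, FALSE, TRUE, TRUE)
    )
    genes <- dplyr::bind_rows(genes, special)
    genes <- dplyr::relocate(genes, "gene_id")

    # experimental TSS for ~70% of euchromatic genes, slightly upstream of CDS
    n_eu <- sum(!genes$is_rdna & !genes$is_mito)
    has_tss <- !genes$is_rdna & !genes$is_mito &
      stats::runif(nrow(genes)) < 0.7
    up <- round(stats::runif(nrow(genes), 20, 120))
    tss_pos <- ifelse(genes$strand == "+",
                      pmax(0L, genes$cds_start - up),
                      pmin(chrom_length(genome, genes$chrom),
                           genes$cds_end + up))
    tss_table <- tibble(gene_id = genes$gene_id[has_tss],
                        tss = as.integer(tss_pos[has_tss]))

    # latent expression programme; background age folds are truncated so
    # that no background gene exceeds a 2-fold rise relative to the average
    # gene (the filter's noise-free recovery is then exact by construction)
    n <- nrow(genes)
    base <- stats::rlnorm(n, meanlog = 4, sdlog = 1)
    base[genes$is_rdna] <- 40 * exp(4.5)   # polyA rDNA ncRNAs dominate aged libraries
    base[genes$is_mito] <- 5 * exp(4.5)
    l2_age <- pmin(1.3, pmax(-2.5, stats::rnorm(n, 0.3, 0.7)))
    l2_dep <- pmin(0.9, pmax(-1, stats::rnorm(n, 0.1, 0.3)))
    gal <- rep(FALSE, n)
    class_lab <- rep("background", n)

    eu_idx <- which(!genes$is_rdna & !genes$is_mito)
    planted <- sample(eu_idx, 45)
    i_up <- planted[1:20]
    i_dep <- planted[21:35]
    i_gal <- planted[36:45]
    l2_age[c(i_up, i_dep, i_gal)] <- log2(6)
    l2_dep[i_up] <- 0
    l2_dep[i_dep] <- 2
    l2_dep[i_gal] <- 0
    gal[i_gal] <- TRUE
    class_lab[i_up] <- "age_up"
    class_lab[i_dep] <- "age_and_depletion"
    class_lab[i_gal] <- "gal_repressed"
    class_lab[genes$is_rdna] <- "rdna"
    class_lab[genes$is_mito] <- "mito"

    truth <- tibble(
      gene_id = genes$gene_id,
      base_expression = base,
      log2_age_fold = l2_age,
      age_fold = 2^l2_age,
      depletion_fold = 2^l2_dep,
      gal_repressed = gal,
      planted_class = class_lab
    )
    list(genes = genes, tss_table = tss_table, truth = truth)
  })
}

# relative expression level of every gene at an age: 1 at the first age,
# age_fold at the last, geometric interpolation in between; rDNA genes ride
# the copy-number amplification instead (polyadenylated rDNA ncRNAs)
relative_expression <- function(truth, params, age) {
  ages <- params$ages
  k <- match(age, ages)
  if (is.na(k)) abort(sprintf("unknown age '%s'", age))
  frac <- if (length(ages) == 1) 1 else (k - 1) / (length(ages) - 1)
  rel <- truth$age_fold^frac
  is_rdna <- truth$planted_class == "rdna"
  rel[is_rdna] <- params$rdna_amplification[[age]] * 2^frac
  rel
}
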