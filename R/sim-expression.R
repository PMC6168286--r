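#' Simulate the strand-resolved expression experiment
#'
#' Per-gene sense (mRNA) and antisense counts across ages and replicates,
#' plus a paired non-stranded histone-depletion experiment (pre/post) drawn
#' from the same latent gene programme as [simulate_chromatin_counts()].
#' Sense counts follow each gene's relative expression trajectory; rDNA
#' genes instead track the copy-number amplification (polyadenylated rDNA
#' ncRNAs dominating aged libraries); antisense counts are a fixed small
#' fraction of baseline expression scaled by the genome-wide age-dependent
#' antisense multiplier, independent of the gene's sense change. Each
#' library is scaled to its own sequencing depth, so composition changes —
#' not absolute per-cell signal — drive the raw counts, exactly the
#' situation the normalization has to cope with.
#'
#' @param params A [sim_params()].
#' @param genome A [genome_model()].
#' @return List of class `expression_sim`: `genes`, `samples`, `counts`
#'   (`gene_id`, `sample_id`, `sense`, `antisense`), `depletion_samples`,
#'   `depletion_counts`, `gal_flags`, `truth`, `params`.
#' @export
simulate_expression <- function(params = sim_params(), genome = sim_genome()) {
  ann <- sim_genes(genome, params)
  truth <- ann$truth
  genes <- ann$genes
  ages <- params$ages

  samples <- tidyr::expand_grid(age = ages,
                                replicate = seq_len(params$n_replicates_rna)) |>
    dplyr::mutate(sample_id = paste("rna", .data$age,
                                    paste0("r", .data$replicate), sep = "_"))
  depl_samples <- tidyr::expand_grid(condition = c("pre", "post"),
                                     replicate = 1:2) |>
    dplyr::mutate(sample_id = paste("depl", .data$condition,
                                    paste0("r", .data$replicate), sep = "_"))

  withr::with_seed(params$seed + 7919L, {
    n <- nrow(genes)
    counts_list <- vector("list", nrow(samples))
    for (i in seq_len(nrow(samples))) {
      a <- samples$age[i]
      rel <- relative_expression(truth, params, a)
      sense_mass <- truth$base_expression * rel
      anti_mass <- 0.03 * truth$base_expression *
        params$antisense_multiplier[[a]]
      depth <- params$rna_depth * stats::runif(1, 0.8, 1.2)
      tot <- sum(sense_mass) + sum(anti_mass)
      mu_s <- depth * sense_mass / tot
      mu_a <- depth * anti_mass / tot
      counts_list[[i]] <- tibble(
        gene_id = genes$gene_id,
        sample_id = samples$sample_id[i],
        sense = sim_counts(mu_s, params$dispersion[["rna"]], params$noise),
        antisense = sim_counts(mu_a, params$dispersion[["rna"]], params$noise)
      )
    }

    depl_list <- vector("list", nrow(depl_samples))
    for (i in seq_len(nrow(depl_samples))) {
      fold <- if (depl_samples$condition[i] == "post") truth$depletion_fold
              else rep(1, n)
      mass <- truth$base_expression * fold
      depth <- params$rna_depth * stats::runif(1, 0.8, 1.2)
      mu <- depth * mass / sum(mass)
      depl_list[[i]] <- tibble(
        gene_id = genes$gene_id,
        sample_id = depl_samples$sample_id[i],
        count = sim_counts(mu, params$dispersion[["rna"]], params$noise)
      )
    }
  })

  # closed-form expectations: normalization equalizes eligible mRNA-strand
  # totals, so the expected normalized fold of any signal s_i(a) is
  # s_i(a)/s_i(ref) * S(ref)/S(a) with S(a) the eligible sense mass
  eligible <- !genes$is_rdna & !genes$is_mito
  masses <- purrr::map_dfr(ages, function(a) {
    rel <- relative_expression(truth, params, a)
    tibble(
      age = a,
      sense_mass_eligible = sum(truth$base_expression[eligible] *
                                  rel[eligible]),
      antisense_multiplier = params$antisense_multiplier[[a]]
    )
  })
  masses$expected_antisense_fold <-
    (masses$antisense_multiplier / masses$antisense_multiplier[1]) *
    (masses$sense_mass_eligible[1] / masses$sense_mass_eligible)

  structure(
    list(genes = genes, samples = samples,
         truth_masses = masses,
         counts = dplyr::bind_rows(counts_list),
         depletion_samples = depl_samples,
         depletion_counts = dplyr::bind_rows(depl_list),
         gal_flags = dplyr::select(truth, "gene_id", "gal_repressed"),
         truth = truth, params = params),
    class = "expression_sim"
  )
}

#' Simulate a dual-genome read-hit table
#'
#' A fixture generator for the disambiguation contract: emits reads with a
#' latent origin (`target`, `spike`, `homologous`, `spike_multi`,
#' `unmapped`) and mapping evidence consistent with it — homologous reads
#' map to both genomes and must be discarded; spike multi-mappers map to
#' the spike genome without being unique. Target-mapping reads get uniform
#' positions over the target genome (including the rDNA interval and the
#' mitochondrial contig, so the Y count's exclusions are exercised).
#'
#' @param n_reads Number of reads.
#' @param genome A [genome_model()].
#' @param fractions Named origin probabilities (`target`, `spike`,
#'   `homologous`, `spike_multi`, `unmapped`); normalized internally.
#' @param sample_id Sample label.
#' @param seed Optional seed.
#' @return Read-hit tibble ready for [disambiguate_reads()], with the
#'   latent `true_origin` column retained as ground truth.
#' @export
simulate_read_set <- function(n_reads = 1000, genome = sim_genome(),
                              fractions = c(target = 0.72, spike = 0.12,
                                            homologous = 0.06,
                                            spike_multi = 0.06,
                                            unmapped = 0.04),
                              sample_id = "s1", seed = NULL) {
  need <- c("target", "spike", "homologous", "spike_multi", "unmapped")
  if (!all(need %in% names(fractions))) {
    abort("fractions must name target, spike, homologous, spike_multi, unmapped")
  }
  draw <- function() {
    origin <- sample(need, n_reads, replace = TRUE,
                     prob = fractions[need] / sum(fractions[need]))
    maps_target <- origin %in% c("target", "homologous")
    maps_spike <- origin %in% c("spike", "homologous", "spike_multi")
    spike_unique <- origin == "spike"
    chroms <- genome$chroms
    ci <- sample.int(nrow(chroms), n_reads, replace = TRUE,
                     prob = chroms$length)
    pos <- floor(stats::runif(n_reads) * chroms$length[ci])
    tibble(
      read_id = sprintf("r%06d", seq_len(n_reads)),
      sample_id = sample_id,
      true_origin = origin,
      maps_target = maps_target,
      maps_spike = maps_spike,
      spike_unique = spike_unique,
      chrom = ifelse(maps_target, chroms$name[ci], NA_character_),
      pos = ifelse(maps_target, as.integer(pos), NA_integer_),
      strand = sample(c("+", "-"), n_reads, replace = TRUE)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
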