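#' Pipeline configuration
#'
#' Captures every knob of an end-to-end run in one serializable object. A
#' run is fully reproducible from its config: the same config and seed
#' regenerate identical outputs.
#'
#' @param seed Integer seed forwarded to the generators.
#' @param sim Named list of overrides passed to [sim_params()].
#' @param outdir Output directory.
#' @param input_norm Input-normalization mode for [window_density()].
#' @param fc_mode Filter statistic mode for [age_depletion_filter()].
#' @param age_threshold,depletion_threshold Filter thresholds.
#' @param scale Readability scale for normalized counts.
#' @param reference,terminal Reference and terminal age labels (default the
#'   first and last simulated age).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, sim = list(),
                            outdir = file.path(tempdir(), "spikechip_run"),
                            input_norm = c("spike", "raw"),
                            fc_mode = c("ratio", "difference"),
                            age_threshold = 2, depletion_threshold = 2,
                            scale = 1e6, reference = NULL, terminal = NULL) {
  structure(
    list(seed = as.integer(seed), sim = sim, outdir = outdir,
         input_norm = match.arg(input_norm), fc_mode = match.arg(fc_mode),
         age_threshold = as.numeric(age_threshold),
         depletion_threshold = as.numeric(depletion_threshold),
         scale = as.numeric(scale),
         reference = reference, terminal = terminal),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis over synthetic data
#'
#' Executes every stage in dependency order — simulation, spike-factor
#' computation, normalization, copy-number profiling, window density,
#' compartment accounting, promoter and metagene quantification,
#' expression normalization and the age/depletion filter — writes each
#' stage's table under `config$outdir`, and records a manifest with the
#' config and the md5 of every output file. With a fixed config and seed
#' the whole output tree, manifest included, is byte-identical across
#' runs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `spikechip_run` with all in-memory
#'   stage results, the headline `metrics`, and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(sim_params, c(list(seed = config$seed), config$sim))
  genome <- sim_genome()
  reference <- config$reference %||% params$ages[1]
  terminal <- config$terminal %||% params$ages[length(params$ages)]

  sim <- simulate_chromatin_counts(params, genome)
  genes_sel <- select_unambiguous_genes(sim$genes, genome,
                                        excluded = sim$excluded)

  factors <- norm_factor_table(chip_summary = sim$summaries,
                               input_summary = sim$summaries,
                               pairing = sim$pairing)

  input_counts <-sim$window_counts[grepl("^input", sim$window_counts$sample_id), ]
  k4_counts <- sim$window_counts[grepl("^H3K4me3", sim$window_counts$sample_id), ]
  h3_counts <- sim$window_counts[grepl("^H3_", sim$window_counts$sample_id), ]

  cn <- copy_number_profile(input_counts)
  rcn <- rdna_copy_number(cn, exclude = sim$excluded) |>
    dplyr::left_join(dplyr::select(sim$samples, "sample_id", "age"),
                     by = "sample_id")
  amp <- rcn |>
    dplyr::group_by(.data$age) |>
    dplyr::summarise(rdna_cn = mean(.data$rdna_cn), .groups = "drop") |>
    dplyr::mutate(amplification = .data$rdna_cn /
                    .data$rdna_cn[.data$age == reference])

  dens <- window_density(k4_counts, input_counts, factors,
                         mode = config$input_norm, scale = config$scale)

  k4_norm <- apply_norm(k4_counts, factors, scale = config$scale)
  h3_norm <- apply_norm(h3_counts, factors, scale = config$scale)
  comp_k4 <- compartment_totals(k4_norm, exclude = sim$excluded,
                                samples = sim$samples, reference = reference)
  comp_h3 <- compartment_totals(h3_norm, exclude = sim$excluded,
                                samples = sim$samples, reference = reference)

  rfactors <- norm_factor_table(chip_summary = sim$read_summaries,
                                input_summary = sim$summaries,
                                pairing = sim$pairing[
                                  sim$pairing$sample_id %in%
                                    sim$read_summaries$sample_id, ])
  prom <- promoter_signal(sim$reads, genes_sel, factors = rfactors,
                          scale = config$scale)
  meta <- metagene_profile(sim$reads,
                           genes_sel[genes_sel$unambiguous, ],
                           genome, factors = rfactors, scale = config$scale)

  expr <- simulate_expression(params, genome)
  expr_norm <- normalize_expression(expr$counts, expr$genes, genome)
  eligible <- expr$genes$gene_id[!expr$genes$is_rdna & !expr$genes$is_mito]
  fc_age <- age_fold_changes(
    dplyr::filter(expr_norm, .data$gene_id %in% eligible),
    expr$samples, reference = reference, terminal = terminal,
    center = "mean"
  )
  fc_depl <- depletion_fold_changes(
    dplyr::filter(expr$depletion_counts, .data$gene_id %in% eligible),
    expr$depletion_samples
  )
  fct <- fold_change_table(fc_age, fc_depl, expr$gal_flags)
  filt <- age_depletion_filter(fct, age_threshold = config$age_threshold,
                               depletion_threshold = config$depletion_threshold,
                               mode = config$fc_mode)

  fc_anti <- age_fold_changes(
    dplyr::filter(expr_norm, .data$gene_id %in% eligible),
    expr$samples, reference = reference, terminal = terminal,
    value_col = "antisense_norm", pseudocount = 0.5
  )

  metrics <- run_metrics(sim, amp, comp_k4, comp_h3, prom, filt, fc_age,
                         fc_anti, genes_sel, reference, terminal)

  files <- list(
    windows = sim$windows, window_counts = sim$window_counts,
    sample_summaries = sim$summaries, factors = as_tibble(factors),
    copy_number = as_tibble(cn), rdna_copy_number = rcn,
    amplification = amp, window_density = as_tibble(dens),
    compartments_H3K4me3 = as_tibble(comp_k4),
    compartments_H3 = as_tibble(comp_h3),
    promoter_signal = as_tibble(prom), metagene = as_tibble(meta),
    unambiguous_genes = genes_sel,
    expression_norm = expr_norm, fold_changes = as_tibble(filt)
  )
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(config$outdir, paste0(nm, ".tsv"))
    readr::write_tsv(files[[nm]], p)
    paths[nm] <- p
  }
  mp <- file.path(config$outdir, "metrics.json")
  jsonlite::write_json(metrics, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["metrics"] <- mp

  manifest <- list(
    package = "spikechip",
    version = as.character(utils::packageVersion("spikechip")),
    config = unclass(config),
    files = lapply(stats::setNames(nm = names(paths)), function(nm) {
      list(file = basename(paths[[nm]]),
           md5 = unname(tools::md5sum(paths[[nm]])))
    })
  )
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(structure(
    list(config = config, sim = sim, expr = expr, genes = genes_sel,
         factors = factors, copy_number = cn, amplification = amp,
         density = dens, compartments_H3K4me3 = comp_k4,
         compartments_H3 = comp_h3, promoter_signal = prom, metagene = meta,
         filter = filt, metrics = metrics, manifest = manifest,
         manifest_path = manifest_path, paths = paths),
    class = "spikechip_run"
  ))
}

run_metrics <- function(sim, amp, comp_k4, comp_h3, prom, filt, fc_age,
                        fc_anti, genes_sel, reference, terminal) {
  frac <- function(comp, a) {
    mean(comp$fraction_rdna[comp$age == a])
  }
  fold_total <- function(comp, a) mean(comp$fold_total[comp$age == a])
  fold_eu <- function(comp, a) mean(comp$fold_euchromatic[comp$age == a])

  prom_age <- prom |>
    dplyr::left_join(dplyr::select(sim$samples, "sample_id", "age"),
                     by = "sample_id") |>
    dplyr::group_by(.data$gene_id, .data$age) |>
    dplyr::summarise(signal = mean(.data$norm_count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "age", values_from = "signal")
  prom_change <- (prom_age[[terminal]] + 0.5) / (prom_age[[reference]] + 0.5)
  expr_change <- fc_age$age_ratio[match(prom_age$gene_id, fc_age$gene_id)]
  ok <- is.finite(prom_change) & is.finite(expr_change)
  rho <- stats::cor(prom_change[ok], expr_change[ok], method = "spearman")

  list(
    rdna_amplification_terminal =
      amp$amplification[amp$age == terminal],
    rdna_fraction_H3K4me3_reference = frac(comp_k4, reference),
    rdna_fraction_H3K4me3_terminal = frac(comp_k4, terminal),
    total_H3K4me3_fold_terminal = fold_total(comp_k4, terminal),
    euchromatic_H3_fold_terminal = fold_eu(comp_h3, terminal),
    median_antisense_fold_terminal =
      stats::median(fc_anti$age_ratio, na.rm = TRUE),
    n_genes_annotated = nrow(genes_sel),
    n_genes_unambiguous = sum(genes_sel$unambiguous),
    n_filter_pass = sum(filt$pass),
    promoter_expression_spearman = rho
  )
}

#' @export
print.spikechip_run <- function(x, ...) {
  cat("<spikechip_run>\n")
  m <- x$metrics
  cat(sprintf("  rDNA amplification (terminal): %.2f\n",
              m$rdna_amplification_terminal))
  cat(sprintf("  rDNA H3K4me3 share: %.1f%% -> %.1f%%\n",
              100 * m$rdna_fraction_H3K4me3_reference,
              100 * m$rdna_fraction_H3K4me3_terminal))
  cat(sprintf("  total H3K4me3 fold: %.2f | euchromatic H3 fold: %.2f\n",
              m$total_H3K4me3_fold_terminal, m$euchromatic_H3_fold_terminal))
  cat(sprintf("  median antisense fold: %.2f\n",
              m$median_antisense_fold_terminal))
  cat(sprintf("  unambiguous genes: %d/%d | filter pass: %d\n",
              m$n_genes_unambiguous, m$n_genes_annotated, m$n_filter_pass))
  cat(sprintf("  promoter~expression Spearman: %.3f\n",
              m$promoter_expression_spearman))
  cat(sprintf("  outputs: %s\n", dirname(x$manifest_path)))
  invisible(x)
}
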