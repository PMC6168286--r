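#' Simulate the two-genome ChIP/input experiment
#'
#' Generates, for every age, antigen (H3K4me3, H3) and replicate, a ChIP
#' library and a matched input library over the synthetic genome, in two
#' representations: per-window counts on the analysis grid (the pre-counted
#' path) and, for H3K4me3 ChIP samples, read-level 5' positions (the
#' alignment-ingestion path). Spike-in chromatin of constant mass is mixed
#' into every library, so reads are split between target windows and the
#' spike genome exactly as in the real dual-genome design.
#'
#' The latent model: per-base per-copy mark density is a background level
#' plus promoter-peak layers whose height follows each gene's relative
#' expression; the rDNA consensus unit carries `baseline_copies *
#' amplification(age)` copies at the per-copy density set by
#' `rdna_mark_density`; fixture regions amplify with age at per-copy
#' constant density; input DNA has density 1 per copy everywhere. Expected
#' read counts are proportional to mass = density x copies x length, and
#' observed counts are negative-binomial around them (`noise = "none"`
#' returns the expectations). The `truth` element records every latent
#' mass, so each downstream statistic has a closed-form expectation.
#'
#' @param params A [sim_params()].
#' @param genome A [genome_model()] (default [sim_genome()]).
#' @param reads Emit read-level positions for H3K4me3 ChIP samples
#'   (default TRUE).
#' @return List of class `chromatin_sim`: `genome`, `genes`, `tss_table`,
#'   `windows`, `excluded`, `samples`, `pairing`, `window_counts`,
#'   `summaries`, `reads`, `read_summaries`, `truth`, `params`.
#' @export
simulate_chromatin_counts <- function(params = sim_params(),
                                      genome = sim_genome(),
                                      reads = TRUE) {
  if (any(params$rdna_mark_density > 0) && is.null(genome$rdna)) {
    abort("genome has no rDNA locus but rDNA mark density is nonzero")
  }
  ann <- sim_genes(genome, params)
  windows <- tile_windows(genome)
  fixtures <- sim_excluded_regions(genome)
  fixtures <- fixtures[fixtures$chrom %in% genome$chroms$name, ]

  genes_tss <- resolve_tss(ann$genes, ann$tss_table)
  ref_age <- params$ages[1]

  # genome-average per-copy euchromatic H3K4me3 density at the reference age
  layers_ref <- mark_layers(genome, genes_tss, params, "H3K4me3", ref_age,
                            dbar_ref = 1, truth = ann$truth)
  eu_only <- layers_ref[layers_ref$layer %in% c("bg", "peak"), ]
  eu_len <- sum((eu_only$end - eu_only$start)[eu_only$layer == "bg"])
  dbar_ref <- sum(with(eu_only, dens * (end - start))) / eu_len

  ages <- params$ages
  antigens <- c("H3K4me3", "H3")
  segs <- list()
  for (ag in c(antigens, "input")) {
    for (a in ages) {
      segs[[paste(ag, a)]] <- finalize_copies(
        cn_split(
          mark_layers(genome, genes_tss, params, ag, a, dbar_ref,
                      truth = ann$truth),
          fixtures, params$fixture_cn[[a]]
        ),
        params, a, genome
      )
    }
  }

  dna_mass <- function(a) sum(with(segs[[paste("input", a)]],
                                   dens * copies * (end - start)))
  spike_dna <- params$spike_fraction / (1 - params$spike_fraction) *
    dna_mass(ref_age)
  spike_mass <- c(params$spike_mark_density[antigens], input = 1) * spike_dna
  names(spike_mass) <- c(antigens, "input")

  samples <- tidyr::expand_grid(
    antigen = c(antigens, "input"), age = ages,
    replicate = seq_len(params$n_replicates_chip)
  ) |>
    dplyr::mutate(sample_id = paste(.data$antigen, .data$age,
                                    paste0("r", .data$replicate), sep = "_"))
  pairing <- samples |>
    dplyr::filter(.data$antigen != "input") |>
    dplyr::transmute(sample_id = .data$sample_id,
                     input_id = paste("input", .data$age,
                                      paste0("r", .data$replicate), sep = "_"))

  withr::with_seed(params$seed, {
    samples$depth <- round(params$library_depth *
                             stats::runif(nrow(samples), 0.9, 1.1))

    mass_by_window <- list()
    totals <- list()
    for (key in names(segs)) {
      mw <- window_mass(windows, segs[[key]])
      mass_by_window[[key]] <- mw
      totals[[key]] <- sum(with(segs[[key]], dens * copies * (end - start)))
    }

    counts_list <- list()
    summary_list <- list()
    reads_list <- list()
    read_summary_list <- list()

    for (i in seq_len(nrow(samples))) {
      s <- samples[i, ]
      key <- paste(s$antigen, s$age)
      track <- if (s$antigen == "input") "input" else "chip"
      sm <- spike_mass[[s$antigen]]
      total <- totals[[key]] + sm
      mu_w <- s$depth * mass_by_window[[key]] / total
      cnt <- sim_counts(mu_w, params$dispersion[[track]], params$noise)
      counts_list[[i]] <- tibble(sample_id = s$sample_id,
                                 window_id = windows$window_id, count = cnt)
      d_mu <- s$depth * sm * params$spike_unique_rate / total
      m_mu <- s$depth * sm * (1 - params$spike_unique_rate) / total
      D <- sim_counts(d_mu, params$dispersion[[track]], params$noise)
      n_multi <- sim_counts(m_mu, params$dispersion[[track]], params$noise)
      Y <- sum(cnt[windows$compartment == "euchromatic"])
      summary_list[[i]] <- tibble(sample_id = s$sample_id, D = D,
                                  n_spike_multi = n_multi, Y = Y,
                                  depth = s$depth)

      if (reads && s$antigen == "H3K4me3") {
        sg <- segs[[key]]
        mass <- with(sg, dens * copies * (end - start))
        p <- c(mass, sm * params$spike_unique_rate,
               sm * (1 - params$spike_unique_rate))
        idx <- sample.int(length(p), s$depth, replace = TRUE, prob = p)
        tgt <- idx <= nrow(sg)
        j <- idx[tgt]
        pos <- sg$start[j] +
          floor(stats::runif(sum(tgt)) * (sg$end[j] - sg$start[j]))
        rd_tbl <- tibble(sample_id = s$sample_id, chrom = sg$chrom[j],
                         pos = as.integer(pos))
        reads_list[[length(reads_list) + 1]] <- rd_tbl
        rd <- genome$rdna
        y_reads <- sum(!(rd_tbl$chrom %in% mito_chrom(genome)) &
                         !(rd_tbl$chrom == rd$chrom &
                             rd_tbl$pos >= rd$expanded_start &
                             rd_tbl$pos < rd$expanded_end))
        read_summary_list[[length(read_summary_list) + 1]] <- tibble(
          sample_id = s$sample_id,
          D = sum(idx == nrow(sg) + 1L),
          Y = y_reads, depth = s$depth
        )
      }
    }
  })

  window_counts <- dplyr::bind_rows(counts_list) |>
    dplyr::left_join(windows, by = "window_id") |>
    dplyr::relocate("sample_id", "window_id", "chrom", "start", "end",
                    "compartment", "count")

  truth <- chromatin_truth(segs, fixtures, genome, params, spike_mass,
                           dbar_ref, ann)

  structure(
    list(genome = genome, genes = genes_tss, tss_table = ann$tss_table,
         windows = windows, excluded = fixtures, samples = samples,
         pairing = pairing, window_counts = window_counts,
         summaries = dplyr::bind_rows(summary_list),
         reads = if (length(reads_list)) dplyr::bind_rows(reads_list) else NULL,
         read_summaries = if (length(read_summary_list))
           dplyr::bind_rows(read_summary_list) else NULL,
         truth = truth, params = params),
    class = "chromatin_sim"
  )
}

# density layers for one antigen at one age: additive segments
# (chrom, start, end, dens, layer); copies are attached later by cn_split()
# and finalize_copies()
mark_layers <- function(genome, genes_tss, params, antigen, age, dbar_ref,
                        truth) {
  rd <- genome$rdna
  eu_chroms <- genome$chroms[!genome$chroms$is_mito, ]
  eu_gr <- GenomicRanges::setdiff(
    tbl_to_gr(tibble(chrom = eu_chroms$name, start = 0L,
                     end = eu_chroms$length)),
    tbl_to_gr(rdna_expanded_region(genome))
  )
  eu <- gr_to_tbl(eu_gr)

  bg_dens <- switch(antigen,
    H3K4me3 = params$k4_background,
    H3 = params$h3_decline[[age]],
    input = 1
  )
  layers <- dplyr::mutate(eu, dens = bg_dens, layer = "bg")

  if (antigen == "H3K4me3") {
    g <- genes_tss[!genes_tss$is_rdna & !genes_tss$is_mito, ]
    rel_all <- relative_expression(truth, params, age)
    rel <- rel_all[match(g$gene_id, truth$gene_id)]
    pk <- tibble(
      chrom = g$chrom,
      start = ifelse(g$strand == "+", g$tss + 50L, g$tss - 250L),
      end = ifelse(g$strand == "+", g$tss + 250L, g$tss - 50L),
      dens = params$peak_height * rel^params$promoter_peak_gain,
      layer = "peak"
    )
    pk <- pk[pk$start < pk$end & pk$start >= 0, ]
    # clip peaks into the euchromatic area
    pgr <- tbl_to_gr(pk)
    ov <- GenomicRanges::findOverlaps(pgr, eu_gr)
    qi <- S4Vectors::queryHits(ov)
    inter <- IRanges::pintersect(pgr[qi], eu_gr[S4Vectors::subjectHits(ov)])
    pk2 <- tibble(chrom = as.character(GenomicRanges::seqnames(inter)),
                  start = GenomicRanges::start(inter) - 1L,
                  end = GenomicRanges::end(inter),
                  dens = pk$dens[qi], layer = "peak")
    layers <- dplyr::bind_rows(layers, pk2)
  }

  unit_dens <- switch(antigen,
    H3K4me3 = params$rdna_mark_density[[age]] * dbar_ref,
    H3 = 1,
    input = 1
  )
  rdna_seg <- tibble(chrom = rd$chrom, start = rd$unit_start,
                     end = rd$unit_end, dens = unit_dens, layer = "rdna_unit")
  rem <- tibble(
    chrom = rd$chrom,
    start = c(rd$expanded_start, rd$unit_end),
    end = c(rd$unit_start, rd$expanded_end),
    dens = unit_dens, layer = "rdna_remainder"
  )
  rem <- rem[rem$start < rem$end, ]
  layers <- dplyr::bind_rows(layers, rdna_seg, rem)

  if (antigen == "input" && !is.na(mito_chrom(genome))) {
    layers <- dplyr::bind_rows(layers, tibble(
      chrom = mito_chrom(genome), start = 0L,
      end = chrom_length(genome, mito_chrom(genome)),
      dens = 1, layer = "mito"
    ))
  }
  layers
}

# split euchromatic layers at fixture boundaries and multiply their copy
# number; non-euchromatic layers keep copies = 1 until finalize_copies()
cn_split <- function(layers, fixtures, fixture_mult) {
  layers$copies <- 1
  # fixed-copy layers
  is_eu <- layers$layer %in% c("bg", "peak")
  eu <- layers[is_eu, ]
  other <- layers[!is_eu, ]

  if (nrow(fixtures) > 0 && fixture_mult != 1) {
    fgr <- tbl_to_gr(fixtures)
    egr <- tbl_to_gr(eu)
    ov <- GenomicRanges::findOverlaps(egr, fgr)
    qi <- S4Vectors::queryHits(ov)
    if (length(qi) > 0) {
      inter <- IRanges::pintersect(egr[qi], fgr[S4Vectors::subjectHits(ov)])
      amp <- tibble(chrom = as.character(GenomicRanges::seqnames(inter)),
                    start = GenomicRanges::start(inter) - 1L,
                    end = GenomicRanges::end(inter),
                    dens = eu$dens[qi], layer = eu$layer[qi],
                    copies = fixture_mult)
      # remove the amplified stretches from the original segments
      keep <- GenomicRanges::setdiff(egr, fgr)
      kov <- GenomicRanges::findOverlaps(keep, egr)
      ki <- S4Vectors::queryHits(kov)
      kinter <- IRanges::pintersect(keep[ki], egr[S4Vectors::subjectHits(kov)])
      base <- tibble(chrom = as.character(GenomicRanges::seqnames(kinter)),
                     start = GenomicRanges::start(kinter) - 1L,
                     end = GenomicRanges::end(kinter),
                     dens = eu$dens[S4Vectors::subjectHits(kov)],
                     layer = eu$layer[S4Vectors::subjectHits(kov)],
                     copies = 1)
      eu <- dplyr::bind_rows(base, amp)
    }
  }
  dplyr::bind_rows(eu, other)
}

# copies for the non-euchromatic layers are age-dependent; fill them in
# (helper used by the caller which knows params and age)
finalize_copies <- function(segs, params, age, genome) {
  rd <- genome$rdna
  segs$copies[segs$layer == "rdna_unit"] <-
    rd$baseline_copies * params$rdna_amplification[[age]]
  segs$copies[segs$layer == "rdna_remainder"] <-
    params$remainder_cn * params$rdna_amplification[[age]]
  segs$copies[segs$layer == "mito"] <- params$mito_cn
  segs
}

# expected per-window target mass: sum over segments of dens*copies*overlap
window_mass <- function(windows, segs) {
  wgr <- tbl_to_gr(windows)
  sgr <- tbl_to_gr(segs)
  ov <- GenomicRanges::findOverlaps(wgr, sgr)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  ow <- overlap_width(windows$start[qi], windows$end[qi],
                      segs$start[si], segs$end[si])
  mass <- segs$dens[si] * segs$copies[si] * ow
  out <- numeric(nrow(windows))
  agg <- rowsum(mass, qi)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

chromatin_truth <- function(segs, fixtures, genome, params, spike_mass,
                            dbar_ref, ann) {
  fgr <- if (nrow(fixtures)) tbl_to_gr(fixtures) else NULL
  seg_mass <- function(key, layers = NULL, in_fixture = NA) {
    sg <- segs[[key]]
    keep <- rep(TRUE, nrow(sg))
    if (!is.null(layers)) keep <- sg$layer %in% layers
    if (!is.na(in_fixture) && !is.null(fgr)) {
      infix <- IRanges::overlapsAny(tbl_to_gr(sg), fgr)
      keep <- keep & (if (in_fixture) infix else !infix)
    }
    sum(with(sg[keep, ], dens * copies * (end - start)))
  }
  per <- tidyr::expand_grid(antigen = c("H3K4me3", "H3", "input"),
                            age = params$ages) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      key = paste(.data$antigen, .data$age),
      unit_mass = seg_mass(.data$key, "rdna_unit"),
      euch_mass = seg_mass(.data$key, c("bg", "peak")),
      euch_mass_excl = seg_mass(.data$key, c("bg", "peak"),
                                in_fixture = FALSE),
      remainder_mass = seg_mass(.data$key, "rdna_remainder"),
      total_target = seg_mass(.data$key),
      spike_mass = spike_mass[[.data$antigen]],
      fraction_rdna = .data$unit_mass / (.data$unit_mass + .data$euch_mass),
      fraction_rdna_excl = .data$unit_mass /
        (.data$unit_mass + .data$euch_mass_excl),
      rdna_copies = genome$rdna$baseline_copies *
        params$rdna_amplification[[.data$age]]
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"key")
  list(per_sample_class = per, dbar_ref = dbar_ref,
       spike_dna_mass = spike_mass[["input"]],
       gene_truth = ann$truth,
       rdna_amplification = params$rdna_amplification,
       fixture_cn = params$fixture_cn)
}
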