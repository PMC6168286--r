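# Shared fixtures. Expensive simulations are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small two-chromosome genome with an rDNA locus, for geometry tests
toy_genome <- function(len1 = 30000L, len2 = 20000L, mito = TRUE) {
  chroms <- tibble::tibble(
    name = c("c1", "c2", if (mito) "cM"),
    length = c(len1, len2, if (mito) 5000L),
    is_mito = c(FALSE, FALSE, if (mito) TRUE)
  )
  genome_model(
    chroms,
    rdna_locus("c1", unit_start = 6000L, unit_end = 10000L,
               expanded_start = 5000L, expanded_end = 15000L,
               baseline_copies = 10),
    spike_genome = "spk"
  )
}

toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = "c2",
    strand = c("+", "-", "+"),
    cds_start = c(1000L, 4000L, 9000L),
    cds_end = c(2500L, 6000L, 11000L)
  )
}

# random annotation on a single long chromosome (for oracle tests)
random_annotation <- function(n, chrom_len = 200000L) {
  starts <- sort(sample.int(chrom_len - 4000L, n))
  lens <- sample(300:2500, n, replace = TRUE)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = "c2",
    strand = sample(c("+", "-"), n, replace = TRUE),
    cds_start = starts,
    cds_end = pmin(starts + lens, chrom_len - 1L)
  )
}

default_sim <- function() {
  fixture("default_sim",
          simulate_chromatin_counts(sim_params(), sim_genome()))
}

default_expr <- function() {
  fixture("default_expr", simulate_expression(sim_params(), sim_genome()))
}

default_factors <- function() {
  fixture("default_factors", {
    sim <- default_sim()
    norm_factor_table(chip_summary = sim$summaries,
                      input_summary = sim$summaries, pairing = sim$pairing)
  })
}

# brute-force reclassification of a read-hit table, one row at a time
oracle_classify <- function(reads) {
  vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    if (r$maps_target && r$maps_spike) "cross_discarded"
    else if (r$maps_target) "target"
    else if (r$maps_spike && r$spike_unique) "spike_unique"
    else if (r$maps_spike) "spike_multi"
    else "unmapped"
  }, character(1))
}

# brute-force all-pairs unambiguous-promoter selection
oracle_unambiguous <- function(genes, genome, excluded = NULL, offset = 500) {
  if (!"tss" %in% names(genes)) genes <- resolve_tss(genes)
  genes <- promoter_intervals(genes, genome, offset = offset)
  excl <- rbind(
    data.frame(chrom = genome$rdna$chrom, start = genome$rdna$expanded_start,
               end = genome$rdna$expanded_end),
    if (!is.null(excluded)) excluded[, c("chrom", "start", "end")]
  )
  out <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ps <- genes$promoter_start[i]; pe <- genes$promoter_end[i]
    if (ps >= pe) { out[i] <- FALSE; next }
    bad <- FALSE
    for (k in seq_len(nrow(excl))) {
      if (genes$chrom[i] == excl$chrom[k] &&
          ps < excl$end[k] && excl$start[k] < pe) bad <- TRUE
    }
    for (j in seq_len(nrow(genes))) {
      if (j == i) next
      if (genes$chrom[i] == genes$chrom[j] &&
          ps < genes$cds_end[j] && genes$cds_start[j] < pe) bad <- TRUE
    }
    out[i] <- !bad
  }
  out
}
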