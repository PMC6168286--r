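small_params <- function(n_genes = 300, library_depth = 5e4,
                         rna_depth = 1e5, ...) {
  sim_params(n_genes = n_genes, library_depth = library_depth,
             rna_depth = rna_depth, ...)
}

test_that("identical seeds give byte-identical simulations", {
  p <- small_params(seed = 5)
  a <- simulate_chromatin_counts(p, sim_genome())
  b <- simulate_chromatin_counts(p, sim_genome())
  expect_identical(a$window_counts, b$window_counts)
  expect_identical(a$summaries, b$summaries)
  expect_identical(a$reads, b$reads)
  e1 <- simulate_expression(p, sim_genome())
  e2 <- simulate_expression(p, sim_genome())
  expect_identical(e1$counts, e2$counts)
  expect_identical(e1$depletion_counts, e2$depletion_counts)

  # a different seed moves the data
  c2 <- simulate_chromatin_counts(small_params(seed = 6), sim_genome())
  expect_false(identical(a$window_counts$count, c2$window_counts$count))
})

test_that("zero rDNA mark density yields zero expected rDNA ChIP signal", {
  p <- small_params(noise = "none", rdna_mark_density = c(0, 0.5, 1))
  sim <- simulate_chromatin_counts(p, sim_genome(), reads = FALSE)
  k4log <- sim$window_counts[grepl("^H3K4me3_log", sim$window_counts$sample_id), ]
  expect_true(all(k4log$count[k4log$compartment == "rDNA"] == 0))
  expect_true(any(k4log$count[k4log$compartment == "euchromatic"] > 0))
})

test_that("equal per-copy density makes the rDNA mark share the mass share", {
  # uniform mark: fraction of mark in rDNA equals its share of chromatin
  p <- small_params(noise = "none", peak_height = 0,
                    rdna_mark_density = c(1, 1, 1),
                    rdna_amplification = c(1, 1, 1), fixture_cn = c(1, 1, 1))
  sim <- simulate_chromatin_counts(p, sim_genome(), reads = FALSE)
  tr <- sim$truth$per_sample_class
  k4 <- tr[tr$antigen == "H3K4me3" & tr$age == "log", ]
  L_r <- 9000 * sim$genome$rdna$baseline_copies
  L_e <- sum(sim$windows$end - sim$windows$start) - 9000
  expect_equal(k4$fraction_rdna, L_r / (L_r + L_e), tolerance = 1e-10)
  # and the counts reproduce it exactly in the noise-free limit
  cnt <- sim$window_counts[grepl("^H3K4me3_log_r1", sim$window_counts$sample_id), ]
  est <- sum(cnt$count[cnt$compartment == "rDNA"]) / sum(cnt$count)
  expect_equal(est, k4$fraction_rdna, tolerance = 1e-10)
})

test_that("uniform depth rescaling cancels in spike-normalized totals", {
  p1 <- small_params(noise = "none")
  p2 <- small_params(noise = "none", library_depth = 1e5)
  s1 <- simulate_chromatin_counts(p1, sim_genome(), reads = FALSE)
  s2 <- simulate_chromatin_counts(p2, sim_genome(), reads = FALSE)
  nf <- function(s) {
    f <- norm_factor_table(chip_summary = s$summaries,
                           input_summary = s$summaries, pairing = s$pairing)
    k4 <- s$window_counts[grepl("^H3K4me3", s$window_counts$sample_id), ]
    out <- apply_norm(k4, f) |>
      dplyr::group_by(sample_id) |>
      dplyr::summarise(total = sum(norm_count))
    out$total
  }
  expect_equal(nf(s1), nf(s2), tolerance = 1e-9)
})

test_that("read-level and count-level representations describe one library", {
  sim <- fixture("small_sim_reads",
                 simulate_chromatin_counts(small_params(seed = 2,
                                                        library_depth = 2e5),
                                           sim_genome()))
  # read positions aggregate to the same compartment shares as the counts
  # (windows cover the unit + euchromatin, so reads in the expanded-rDNA
  # remainder and on the mito contig are outside both denominators)
  r1 <- sim$reads[sim$reads$sample_id == "H3K4me3_48h_r1", ]
  rd <- sim$genome$rdna
  in_unit <- r1$chrom == rd$chrom & r1$pos >= rd$unit_start &
    r1$pos < rd$unit_end
  in_euch <- !(r1$chrom %in% "chrM") &
    !(r1$chrom == rd$chrom & r1$pos >= rd$expanded_start &
        r1$pos < rd$expanded_end)
  c1 <- sim$window_counts[sim$window_counts$sample_id == "H3K4me3_48h_r1", ]
  share_reads <- sum(in_unit) / (sum(in_unit) + sum(in_euch))
  share_counts <- sum(c1$count[c1$compartment == "rDNA"]) / sum(c1$count)
  expect_lt(abs(share_reads / share_counts - 1), 0.1)
  # read-level Y/D summaries are consistent with the count-level ones
  # (the pre-counted D carries the ChIP library's dispersion, so only a
  # coarse agreement is expected for that scalar)
  rs <- sim$read_summaries[sim$read_summaries$sample_id == "H3K4me3_48h_r1", ]
  cs <- sim$summaries[sim$summaries$sample_id == "H3K4me3_48h_r1", ]
  expect_lt(abs(rs$Y / cs$Y - 1), 0.05)
  expect_lt(abs(rs$D / cs$D - 1), 0.5)
})

test_that("simulated read sets honour their origin fractions", {
  gm <- sim_genome()
  none <- simulate_read_set(200, gm, fractions = c(target = 1, spike = 0,
                                                   homologous = 0,
                                                   spike_multi = 0,
                                                   unmapped = 0), seed = 1)
  s <- assignment_summary(disambiguate_reads(none), gm)
  expect_equal(s$n_cross_discarded, 0L)

  multi <- simulate_read_set(150, gm, fractions = c(target = 0, spike = 0,
                                                    homologous = 0,
                                                    spike_multi = 1,
                                                    unmapped = 0), seed = 2)
  s2 <- assignment_summary(disambiguate_reads(multi), gm)
  expect_equal(s2$D, 0L)
  expect_equal(s2$n_spike_multi, 150L)

  mix <- simulate_read_set(100, gm, seed = 3)
  lab <- disambiguate_reads(mix)
  expect_equal(sum(lab$label == "cross_discarded"),
               sum(mix$true_origin == "homologous"))
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(sim_params(rdna_amplification = c(0.5, 1, 1)), ">= 1")
  expect_error(sim_params(spike_fraction = 1.2), "spike_fraction")
  expect_error(sim_params(library_depth = 0), "positive")
  expect_error(sim_params(dispersion = c(input = -1, chip = 0, rna = 0)),
               "non-negative")
})
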