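make_reads <- function(origins, gm = toy_genome()) {
  n <- length(origins)
  tibble::tibble(
    read_id = sprintf("r%03d", seq_len(n)),
    sample_id = "s1",
    maps_target = origins %in% c("target", "cross"),
    maps_spike = origins %in% c("spike", "cross", "multi"),
    spike_unique = origins == "spike",
    chrom = ifelse(origins %in% c("target", "cross"), "c2", NA),
    pos = ifelse(origins %in% c("target", "cross"), 100L, NA)
  )
}

test_that("disambiguation labels follow the cross-mapping discard rule", {
  r <- disambiguate_reads(make_reads(c("target", "cross", "spike")))
  expect_equal(as.character(r$label),
               c("target", "cross_discarded", "spike_unique"))

  # constructed 10-read table: 5 target, 2 spike-unique, 2 cross, 1 multi
  r10 <- disambiguate_reads(make_reads(
    c(rep("target", 5), rep("spike", 2), rep("cross", 2), "multi")))
  s <- assignment_summary(r10, toy_genome())
  expect_equal(unlist(s[, c("n_target", "n_spike_unique", "n_spike_multi",
                            "n_cross_discarded", "n_unmapped")],
               use.names = FALSE), c(5L, 2L, 1L, 2L, 0L))
  expect_equal(s$D, 2L)

  dup <- make_reads(c("target", "target"))
  dup$read_id <- "same"
  expect_error(disambiguate_reads(dup), "duplicate")
})

test_that("Y excludes the expanded rDNA interval and the mito contig", {
  gm <- toy_genome()
  r <- make_reads(rep("target", 5))
  # one read on mito, one inside expanded rDNA [5000,15000) on c1
  r$chrom <- c("c2", "c2", "c2", "cM", "c1")
  r$pos <- c(100L, 200L, 300L, 10L, 7000L)
  s <- assignment_summary(disambiguate_reads(r), gm)
  expect_equal(s$Y, 3L)

  # all reads inside the expanded region
  r2 <- make_reads(rep("target", 4))
  r2$chrom <- "c1"; r2$pos <- c(5000L, 9000L, 12000L, 14999L)
  expect_equal(assignment_summary(disambiguate_reads(r2), gm)$Y, 0L)

  # widened exclusion removes further reads
  s3 <- assignment_summary(disambiguate_reads(r), gm,
                           excluded = region_set("c2", 150L, 250L))
  expect_equal(s3$Y, 2L)

  # no spike-unique reads: D = 0 and the factor refuses to proceed
  s4 <- assignment_summary(disambiguate_reads(make_reads(rep("target", 3))),
                           gm)
  expect_equal(s4$D, 0L)
  expect_error(norm_factor(10, s4$D, s4$Y), "degenerate")

  bad <- make_reads("target"); bad$pos <- 999999L
  expect_error(assignment_summary(disambiguate_reads(bad), gm), "bounds")
})

test_that("classification matches a per-row oracle on random tables", {
  gm <- sim_genome()
  withr::with_seed(11, {
    for (rep in 1:20) {
      reads <- simulate_read_set(sample(50:2000, 1), gm)
      lab <- disambiguate_reads(reads)
      expect_identical(as.character(lab$label), oracle_classify(reads))
      # partition conservation
      s <- assignment_summary(lab, gm)
      expect_identical(s$n_target + s$n_spike_unique + s$n_spike_multi +
                         s$n_cross_discarded + s$n_unmapped, s$n_total)
      # row-order invariance
      perm <- sample.int(nrow(reads))
      lab2 <- disambiguate_reads(reads[perm, ])
      expect_identical(as.character(lab2$label),
                       as.character(lab$label)[perm])
      # latent origin agrees with the assigned category
      expect_identical(as.character(lab$label) == "cross_discarded",
                       reads$true_origin == "homologous")
    }
  })
})
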