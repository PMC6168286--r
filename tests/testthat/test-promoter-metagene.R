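test_that("promoter signal counts reads in the oriented TSS window", {
  gm <- toy_genome()
  genes <- tibble::tibble(
    gene_id = c("p", "m"), chrom = "c2", strand = c("+", "-"),
    promoter_start = c(1000L, 4500L), promoter_end = c(1500L, 5000L)
  )
  f <- norm_factor_table(tibble::tibble(
    sample_id = "s1", input_id = "i", d_chip = 1, d_input = 1, y_input = 1))

  # zero-signal genome
  none <- tibble::tibble(sample_id = "s1", chrom = "c2", pos = 9000L)
  got0 <- promoter_signal(none, genes, factors = f, scale = 1)
  expect_true(all(got0$norm_count == 0))

  # a single read inside [TSS, TSS+500) with factor 1 gives signal 1
  one <- tibble::tibble(sample_id = "s1", chrom = "c2",
                        pos = c(1250L, 1500L, 4999L))
  got <- promoter_signal(one, genes, factors = f, scale = 1)
  expect_equal(got$norm_count[got$gene_id == "p"], 1)  # 1500 is outside
  expect_equal(got$norm_count[got$gene_id == "m"], 1)
})

test_that("metagene profiles are flat for uniform coverage and delta for one read", {
  gm <- toy_genome(len2 = 20000L)
  genes <- tibble::tibble(gene_id = "g", chrom = "c2", strand = "+",
                          tss = 10000L)
  uni <- tibble::tibble(sample_id = "s1", chrom = "c2",
                        pos = seq(8000L, 11999L))
  prof <- metagene_profile(uni, genes, gm, bin = 100)
  expect_true(all(prof$signal == prof$signal[1]))

  one <- tibble::tibble(sample_id = "s1", chrom = "c2", pos = 10120L)
  d <- metagene_profile(one, genes, gm, bin = 100)
  expect_equal(sum(d$signal > 0), 1L)
  expect_equal(d$offset[d$signal > 0], 100)
})

test_that("a constructed peak at +150 puts the profile mode there", {
  gm <- toy_genome(len2 = 20000L)
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "c2",
                          strand = c("+", "-"), tss = c(8000L, 14000L))
  withr::with_seed(3, {
    # nucleosome-sized peak centred 150 bp downstream of each TSS
    off <- round(stats::rnorm(4000, 150, 40))
    pos <- c(8000L + off[1:2000], 14000L - off[2001:4000])
    bg <- sample(6000L:16000L, 2000, replace = TRUE)
  })
  reads <- tibble::tibble(sample_id = "s1", chrom = "c2",
                          pos = as.integer(c(pos, bg)))
  prof <- metagene_profile(reads, genes, gm, bin = 50)
  mode_bin <- prof$offset[which.max(prof$signal)]
  expect_lte(abs(mode_bin - 150), 50)
})

test_that("metagene profiles mirror exactly under genome reflection", {
  gm <- toy_genome(len2 = 20000L)
  withr::with_seed(9, {
    genes <- tibble::tibble(
      gene_id = c("a", "b"), chrom = "c2", strand = c("+", "-"),
      tss = c(6000L, 13000L)
    )
    reads <- tibble::tibble(
      sample_id = "s1", chrom = "c2",
      pos = sample(3000L:16000L, 3000, replace = TRUE)
    )
  })
  L <- 20000L
  mirror_genes <- dplyr::mutate(genes, tss = L - 1L - tss,
                                strand = ifelse(strand == "+", "-", "+"))
  mirror_reads <- dplyr::mutate(reads, pos = L - 1L - pos)
  p1 <- metagene_profile(reads, genes, gm, bin = 50)
  p2 <- metagene_profile(mirror_reads, mirror_genes, gm, bin = 50)
  expect_identical(p1$signal, p2$signal)
  expect_identical(p1$offset, p2$offset)
})

test_that("promoter gains track expression induction across age", {
  sim <- default_sim()
  expr <- default_expr()
  gm <- sim$genome
  gsel <- select_unambiguous_genes(sim$genes, gm, excluded = sim$excluded)
  rf <- norm_factor_table(
    chip_summary = sim$read_summaries, input_summary = sim$summaries,
    pairing = sim$pairing[sim$pairing$sample_id %in%
                            sim$read_summaries$sample_id, ])
  prom <- promoter_signal(sim$reads, gsel, factors = rf)
  pa <- prom |>
    dplyr::left_join(dplyr::select(sim$samples, sample_id, age),
                     by = "sample_id") |>
    dplyr::group_by(gene_id, age) |>
    dplyr::summarise(s = mean(norm_count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = age, values_from = s)

  en <- normalize_expression(expr$counts, expr$genes, gm)
  elig <- expr$genes$gene_id[!expr$genes$is_rdna & !expr$genes$is_mito]
  fca <- age_fold_changes(dplyr::filter(en, gene_id %in% elig),
                          expr$samples, center = "mean")
  change <- (pa[["48h"]] + 0.5) / (pa[["log"]] + 0.5)
  ec <- fca$age_ratio[match(pa$gene_id, fca$gene_id)]
  ok <- is.finite(change) & is.finite(ec)
  expect_gt(stats::cor(change[ok], ec[ok], method = "spearman"), 0.9)
})
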