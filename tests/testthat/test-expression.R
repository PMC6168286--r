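simple_genes <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "rdn", "mt"),
    chrom = c("c2", "c2", "c1", "cM"),
    strand = c("+", "-", "+", "+"),
    cds_start = c(1000L, 5000L, 6000L, 100L),
    cds_end = c(2000L, 6000L, 9000L, 1000L),
    is_rdna = c(FALSE, FALSE, TRUE, FALSE),
    is_mito = c(FALSE, FALSE, FALSE, TRUE)
  )
}

test_that("size factors use mRNA-strand totals excluding rDNA and mito", {
  g <- simple_genes()
  counts <- tidyr::expand_grid(gene_id = g$gene_id,
                               sample_id = c("a", "b")) |>
    dplyr::mutate(sense = c(6e5, 12e5, 4e5, 8e5, 9e5, 2e5, 1e5, 3e5)[
      match(paste(gene_id, sample_id),
            c("g1 a", "g1 b", "g2 a", "g2 b", "rdn a", "rdn b",
              "mt a", "mt b"))],
      antisense = 10)
  got <- normalize_expression(counts, g)
  f <- attr(got, "size_factors")
  # eligible totals: a = 1e6, b = 2e6 -> scale to the smaller
  expect_equal(f$total, c(1e6, 2e6))
  expect_equal(f$size_factor, c(1, 0.5))
  # an rDNA gene dominating an aged library does not skew the factor
  expect_false(any(grepl("rdn|mt", f$sample_id)))

  # identical samples stay identical; renormalizing changes nothing
  same <- dplyr::mutate(counts, sense = 100, antisense = 5)
  n1 <- normalize_expression(same, g)
  expect_identical(n1$sense_norm[n1$sample_id == "a"],
                   n1$sense_norm[n1$sample_id == "b"])
  again <- normalize_expression(
    dplyr::transmute(n1, gene_id, sample_id, sense = sense_norm,
                     antisense = antisense_norm), g)
  expect_equal(again$sense_norm, n1$sense_norm)

  zero <- dplyr::mutate(counts, sense = ifelse(sample_id == "a", 0, sense))
  expect_error(normalize_expression(zero, g), "zero")
})

test_that("strand conventions split sense and antisense correctly", {
  g <- simple_genes()[1:2, ]
  # + strand gene with 10 reads on the minus strand: dUTP calls them mRNA
  reads <- tibble::tibble(
    sample_id = "s", chrom = "c2",
    pos = c(rep(1500L, 10), rep(5500L, 4)),
    strand = c(rep("-", 10), rep("-", 4))
  )
  got <- sense_antisense_counts(reads, g)
  expect_equal(got$sense[got$gene_id == "g1"], 10L)
  expect_equal(got$antisense[got$gene_id == "g1"], 0L)
  # for the - strand gene the same reads are antisense transcripts
  expect_equal(got$antisense[got$gene_id == "g2"], 4L)

  # convention duality: flipping swaps the matrices exactly
  fwd <- sense_antisense_counts(reads, g, convention = "forward")
  expect_identical(fwd$sense, got$antisense)
  expect_identical(fwd$antisense, got$sense)

  # no reads in genes -> zeros
  none <- tibble::tibble(sample_id = "s", chrom = "c2", pos = 4000L,
                         strand = "+")
  expect_true(all(sense_antisense_counts(none, g)$sense == 0))

  bad <- dplyr::mutate(reads, strand = "*")
  expect_error(sense_antisense_counts(bad, g), "stranded")
})

test_that("age fold changes report both difference and ratio modes", {
  counts <- tidyr::expand_grid(gene_id = c("g1", "g2"),
                               sample_id = c("l1", "l2", "o1", "o2")) |>
    dplyr::mutate(sense_norm = dplyr::case_when(
      gene_id == "g1" & grepl("^l", sample_id) ~ 10,
      gene_id == "g1" ~ 40,
      TRUE ~ 7
    ))
  samples <- tibble::tibble(sample_id = c("l1", "l2", "o1", "o2"),
                            age = c("log", "log", "48h", "48h"))
  fc <- age_fold_changes(counts, samples)
  expect_equal(fc$age_diff[fc$gene_id == "g1"], 30)
  expect_equal(fc$age_ratio[fc$gene_id == "g1"], 4)
  # identical ages: difference 0, ratio 1
  expect_equal(fc$age_diff[fc$gene_id == "g2"], 0)
  expect_equal(fc$age_ratio[fc$gene_id == "g2"], 1)
  expect_error(age_fold_changes(counts, samples, terminal = "96h"), "absent")
})

test_that("the filter applies all three criteria with an audit trail", {
  fc <- tibble::tibble(
    gene_id = c("pass", "dep", "gal", "weak"),
    age_ratio = c(3.0, 3.0, 4.0, 1.5),
    depl_ratio = c(1.5, 2.5, 1.2, 1.0),
    age_diff = c(3.0, 3.0, 4.0, 1.5) * 10,
    depl_diff = c(1.5, 2.5, 1.2, 1.0),
    gal_repressed = c(FALSE, FALSE, TRUE, FALSE)
  )
  got <- age_depletion_filter(fc)
  expect_equal(got$gene_id[got$pass], "pass")
  expect_true(got$fail_depletion[got$gene_id == "dep"])
  expect_true(got$fail_gal[got$gene_id == "gal"])
  expect_true(got$fail_age[got$gene_id == "weak"])
  g <- glance(got)
  expect_equal(g$n_pass, 1L)
  expect_error(
    age_depletion_filter(dplyr::mutate(fc, gal_repressed = NA)),
    "gal_repressed"
  )
})

test_that("the filter equals brute-force predicate evaluation", {
  withr::with_seed(21, {
    for (rep in 1:30) {
      n <- sample(10:200, 1)
      fc <- tibble::tibble(
        gene_id = sprintf("g%03d", seq_len(n)),
        age_ratio = stats::rlnorm(n, 0.3, 0.8),
        depl_ratio = stats::rlnorm(n, 0.1, 0.6),
        age_diff = stats::rnorm(n, 5, 20),
        depl_diff = stats::rnorm(n, 0, 3),
        gal_repressed = stats::runif(n) < 0.1
      )
      at <- sample(c(1.5, 2, 3), 1); dt <- sample(c(1.5, 2, 3), 1)
      for (mode in c("ratio", "difference")) {
        got <- age_depletion_filter(fc, at, dt, mode = mode)
        a <- if (mode == "ratio") fc$age_ratio else fc$age_diff
        d <- if (mode == "ratio") fc$depl_ratio else fc$depl_diff
        want <- vapply(seq_len(n), function(i) {
          a[i] > at && d[i] < dt && !fc$gal_repressed[i]
        }, logical(1))
        expect_identical(got$pass, want)
      }
    }
  })
})

test_that("planted age-not-depletion genes are recovered exactly without noise", {
  gm <- sim_genome()
  p <- sim_params(noise = "none", n_genes = 600)
  expr <- simulate_expression(p, gm)
  elig <- expr$genes$gene_id[!expr$genes$is_rdna & !expr$genes$is_mito]
  en <- normalize_expression(expr$counts, expr$genes, gm)
  fca <- age_fold_changes(dplyr::filter(en, gene_id %in% elig),
                          expr$samples, center = "mean")
  fcd <- depletion_fold_changes(
    dplyr::filter(expr$depletion_counts, gene_id %in% elig),
    expr$depletion_samples)
  got <- age_depletion_filter(fold_change_table(fca, fcd, expr$gal_flags))
  planted <- expr$truth$gene_id[expr$truth$planted_class == "age_up"]
  expect_setequal(got$gene_id[got$pass], planted)
})

test_that("antisense fold recovery matches the closed-form expectation", {
  gm <- sim_genome()
  # noise-free: exact equality (no pseudocount)
  p0 <- sim_params(noise = "none", n_genes = 600)
  e0 <- simulate_expression(p0, gm)
  elig <- e0$genes$gene_id[!e0$genes$is_rdna & !e0$genes$is_mito]
  n0 <- normalize_expression(e0$counts, e0$genes, gm)
  f0 <- age_fold_changes(dplyr::filter(n0, gene_id %in% elig), e0$samples,
                         value_col = "antisense_norm")
  want <- e0$truth_masses$expected_antisense_fold[
    e0$truth_masses$age == "48h"]
  expect_equal(stats::median(f0$age_ratio), want, tolerance = 1e-10)

  # default noise: the median tracks the expectation
  expr <- default_expr()
  en <- normalize_expression(expr$counts, expr$genes, gm)
  elig2 <- expr$genes$gene_id[!expr$genes$is_rdna & !expr$genes$is_mito]
  fa <- age_fold_changes(dplyr::filter(en, gene_id %in% elig2),
                         expr$samples, value_col = "antisense_norm",
                         pseudocount = 0.5)
  want2 <- expr$truth_masses$expected_antisense_fold[
    expr$truth_masses$age == "48h"]
  expect_lt(abs(stats::median(fa$age_ratio) / want2 - 1), 0.15)

  # constant antisense rate and constant sense composition: folds are 1
  flat <- tidyr::expand_grid(gene_id = sprintf("g%d", 1:20),
                             sample_id = c("l1", "o1")) |>
    dplyr::mutate(sense = 50, antisense = 5)
  gflat <- tibble::tibble(gene_id = sprintf("g%d", 1:20), is_rdna = FALSE,
                          is_mito = FALSE)
  nf <- normalize_expression(flat, gflat)
  ff <- age_fold_changes(nf, tibble::tibble(sample_id = c("l1", "o1"),
                                            age = c("log", "48h")),
                         value_col = "antisense_norm")
  expect_true(all(ff$age_ratio == 1))
})
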