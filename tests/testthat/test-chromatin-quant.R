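window_tbl <- function(counts, compartment = NULL, size = 1000L) {
  n <- length(counts)
  if (is.null(compartment)) compartment <- rep("euchromatic", n)
  tibble::tibble(
    sample_id = "s1", window_id = seq_len(n), chrom = "c2",
    start = (seq_len(n) - 1L) * size, end = seq_len(n) * size,
    compartment = compartment, count = counts
  )
}

test_that("copy number is input density over the euchromatic median", {
  cn <- copy_number_profile(window_tbl(rep(25, 10)))
  expect_true(all(cn$cn == 1))

  cn2 <- copy_number_profile(window_tbl(c(10, 10, 70, 10)))
  expect_equal(cn2$cn, c(1, 1, 7, 1))

  expect_error(copy_number_profile(window_tbl(rep(0, 6))), "all-zero")

  # rDNA windows report array copy number via the count-weighted aggregate
  w <- window_tbl(c(rep(10, 8), 50, 70),
                  compartment = c(rep("euchromatic", 8), "rDNA", "rDNA"))
  got <- rdna_copy_number(copy_number_profile(w))
  expect_equal(got$rdna_cn, (120 / 2000) / (10 / 1000))
})

test_that("amplified-region detection finds maximal runs", {
  expect_equal(nrow(detect_amplified_regions(
    copy_number_profile(window_tbl(rep(10, 8))))), 0L)

  cn <- copy_number_profile(window_tbl(c(10, 30, 30, 10, 10, 10)))
  got <- detect_amplified_regions(cn)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$start, got$end), c(1000L, 3000L))

  # a single high window is below min_run
  cn1 <- copy_number_profile(window_tbl(c(10, 30, 10, 10, 10)))
  expect_equal(nrow(detect_amplified_regions(cn1)), 0L)
})

test_that("window density divides normalized ChIP by input", {
  f <- norm_factor_table(tibble::tibble(
    sample_id = "s1", input_id = "i1", d_chip = 1, d_input = 1,
    y_input = 1000
  ))
  chip <- window_tbl(c(40, 20, 0))
  inp <- window_tbl(c(20, 20, 20)); inp$sample_id <- "i1"

  # raw mode: 40/20 = 2 after the spike factor (here factor*scale = 1)
  d <- window_density(chip, inp, f, mode = "raw", scale = 1)
  expect_equal(d$density, c(2, 1, 0) * f$factor)

  # spike mode scales the input by its library's Y
  d2 <- window_density(chip, inp, f, mode = "spike", scale = 1)
  expect_equal(d2$density, c(40, 20, 0) * f$factor / (20 / 1000))

  # identical tracks give a flat profile
  flat <- window_density(window_tbl(rep(30, 4)),
                         dplyr::mutate(window_tbl(rep(30, 4)),
                                       sample_id = "i1"),
                         f, mode = "raw", scale = 1)
  expect_true(all(flat$density == flat$density[1]))

  # zero-input windows are flagged, not zeroed
  inp0 <- window_tbl(c(20, 0, 20)); inp0$sample_id <- "i1"
  d3 <- window_density(chip, inp0, f, mode = "raw")
  expect_true(d3$low_input[2] && is.na(d3$density[2]))

  expect_error(window_density(chip, inp[1:2, ], f), "mismatch")
})

test_that("compartment totals are additive and give the rDNA fraction", {
  w <- window_tbl(c(40, 30, 30),
                  compartment = c("rDNA", "euchromatic", "euchromatic"))
  w$norm_count <- w$count
  got <- compartment_totals(w)
  expect_equal(got$fraction_rdna, 0.4)
  expect_equal(got$total, sum(w$norm_count))   # additivity, exact

  w0 <- w; w0$norm_count[1] <- 0
  expect_equal(compartment_totals(w0)$fraction_rdna, 0)

  # excluded regions are dropped from the euchromatic totals
  got2 <- compartment_totals(w, exclude = region_set("c2", 1000L, 2000L))
  expect_equal(got2$total_euchromatic, 30)
})

test_that("compartment fractions recover the closed-form expectation", {
  sim <- default_sim()
  f <- default_factors()
  k4 <- sim$window_counts[grepl("^H3K4me3", sim$window_counts$sample_id), ]
  comp <- compartment_totals(apply_norm(k4, f), samples = sim$samples,
                             reference = "log")
  truth <- sim$truth$per_sample_class
  for (a in sim$params$ages) {
    est <- mean(comp$fraction_rdna[comp$age == a])
    exp_f <- truth$fraction_rdna[truth$antigen == "H3K4me3" & truth$age == a]
    expect_lt(abs(est - exp_f), 0.02)
  }
})
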