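test_that("log10 binning uses edges at 10^(k/10) and conserves counts", {
  h <- log_bin_lengths(c(10000))
  expect_equal(h$bin_lo[h$count == 1], 10^4.0)
  expect_equal(h$bin_hi[h$count == 1], 10^4.1)

  lens <- 10^runif(500, 3.5, 5)
  expect_equal(sum(log_bin_lengths(lens)$count), 500)
  expect_equal(nrow(log_bin_lengths(numeric())), 0)
  expect_error(log_bin_lengths(c(100, -5)), "positive")
})

test_that("a degenerate length distribution yields a single full peak", {
  p <- detect_peaks(rep(43400, 1000))
  expect_equal(nrow(p), 1)
  expect_lt(abs(p$center - 43400) / 43400, 0.001)
  expect_equal(p$n_members, 1000L)
  expect_equal(p$share, 1)
})

test_that("a two-component mixture is recovered within 2% of its centers", {
  withr::local_seed(101)
  lens <- 10^c(rnorm(3000, log10(58400), 0.004),
               rnorm(2000, log10(23500), 0.004))
  p <- detect_peaks(lens)
  expect_equal(nrow(p), 2)
  centers <- sort(p$center)
  expect_lt(abs(centers[1] - 23500) / 23500, 0.02)
  expect_lt(abs(centers[2] - 58400) / 58400, 0.02)
  # peaks sorted by member count: the 60% component comes first
  expect_gt(p$n_members[1], p$n_members[2])
  # disjoint membership, bounded by n
  expect_equal(anyDuplicated(unlist(p$members)), 0)
  expect_lte(sum(p$n_members), 5000)
})

test_that("broad (free DNA like) length distributions produce no peak", {
  withr::local_seed(7)
  lens <- 10^rnorm(5000, log10(8000), 0.35)
  expect_equal(nrow(detect_peaks(lens)), 0)
})

test_that("peak centers are equivariant under rescaling all lengths", {
  withr::local_seed(11)
  lens <- 10^rnorm(2000, log10(30000), 0.004)
  c1 <- detect_peaks(lens)$center
  c2 <- detect_peaks(lens * 2.5)$center
  expect_equal(length(c1), length(c2))
  expect_lt(abs(c2 / c1 - 2.5) / 2.5, 0.005)
})

test_that("simulator output yields one accurate peak per single-mechanism run", {
  cm <- phage_community(41700, circular = TRUE)
  H <- 41700 * 1.04
  tr <- simulate_particles(cm, mechanism_params("headful"), 2000, seed = 13)
  p <- detect_peaks(tr$length)
  expect_equal(nrow(p), 1)
  expect_lt(abs(p$center - H) / H, 0.02)

  trc <- simulate_particles(phage_community(102000), mechanism_params("cos"),
                            2000, seed = 13)
  pc <- detect_peaks(trc$length)
  expect_equal(nrow(pc), 1)
  expect_lt(abs(pc$center - 102000) / 102000, 0.001)
})

test_that("too few reads yields an empty result with a notice", {
  expect_message(p <- detect_peaks(rep(10000, 10)), "min_peak_reads")
  expect_equal(nrow(p), 0)
})
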