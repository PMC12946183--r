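test_that("relative abundance is count over total with validation", {
  expect_equal(relative_abundance(10, 1000), 0.01)
  expect_equal(relative_abundance(c(0, 0), 100), c(0, 0))
  expect_lte(sum(relative_abundance(c(30, 50, 20), 200)), 1)
  expect_error(relative_abundance(10, 0), "positive")
  expect_error(relative_abundance(c(60, 60), 100), "at most")
})

test_that("uniform communities produce zero Z-scores and no flags", {
  cc <- tibble::tibble(scaffold_id = letters[1:5], vlp_count = 10,
                       total_count = 20)
  expect_warning(er <- enrichment_z(cc), "equal")
  expect_true(all(er$z == 0))
  expect_false(any(er$flagged))
  expect_error(enrichment_z(cc[1:2, ]), "at least 3")
})

test_that("a single strong outlier is the only flagged scaffold", {
  cc <- tibble::tibble(scaffold_id = sprintf("s%04d", 1:1000),
                       vlp_count = c(rep(10, 999), 40),
                       total_count = 10)
  er <- enrichment_z(cc, vlp_total = 1e5, community_total = 1e5)
  # direct oracle: standardise the ratios by hand
  r <- (cc$vlp_count / 1e5) / (cc$total_count / 1e5)
  z_oracle <- (r - mean(r)) / sd(r)
  expect_equal(er$z, z_oracle)
  expect_equal(which(er$flagged), 1000L)
  expect_lt(abs(mean(er$z)), 1e-12)
  expect_equal(sd(er$z), 1, tolerance = 1e-12)
})

test_that("Z-scores are invariant to rescaling all ratios", {
  withr::local_seed(3)
  cc <- tibble::tibble(scaffold_id = sprintf("s%03d", 1:200),
                       vlp_count = rpois(200, 50) + 1,
                       total_count = rpois(200, 50) + 1)
  z1 <- enrichment_z(cc)$z
  cc2 <- dplyr::mutate(cc, vlp_count = vlp_count * 7)
  z2 <- enrichment_z(cc2, vlp_total = sum(cc$vlp_count),
                     community_total = sum(cc$total_count))$z
  expect_equal(z1, z2, tolerance = 1e-12)
  # the log-ratio variant is likewise scale-invariant
  zl1 <- enrichment_z(cc, log_ratio = TRUE)$z
  zl2 <- enrichment_z(cc2, vlp_total = sum(cc$vlp_count),
                      community_total = sum(cc$total_count),
                      log_ratio = TRUE)$z
  expect_equal(zl1, zl2, tolerance = 1e-12)
})

test_that("raising a scaffold's VLP count never lowers its Z", {
  withr::local_seed(5)
  for (rep in 1:10) {
    cc <- tibble::tibble(scaffold_id = sprintf("s%03d", 1:50),
                         vlp_count = rpois(50, 30),
                         total_count = rpois(50, 30) + 1)
    i <- sample.int(50, 1)
    z0 <- enrichment_z(cc, vlp_total = 1e4, community_total = 1e4)$z[i]
    cc$vlp_count[i] <- cc$vlp_count[i] + 5
    z1 <- enrichment_z(cc, vlp_total = 1e4, community_total = 1e4)$z[i]
    expect_gte(z1, z0 - 1e-9)
  }
})

test_that("null flag rate approaches the upper normal tail beyond 2 SD", {
  withr::local_seed(17)
  rates <- vapply(1:50, function(i) {
    cc <- tibble::tibble(scaffold_id = as.character(1:10000),
                         vlp_count = pmax(rnorm(10000, 100, 10), 1),
                         total_count = 100)
    mean(enrichment_z(cc, vlp_total = 1, community_total = 1)$flagged)
  }, double(1))
  expect_lt(abs(mean(rates) - pnorm(-2)), 0.001)
})

test_that("KS normality diagnostic matches a brute-force statistic", {
  x <- qnorm(((1:1000) - 0.5) / 1000, mean = 2, sd = 0.3)
  ks <- ks_normality(x)
  expect_lt(ks$statistic, 0.02)
  # brute-force D: max deviation between the ECDF and the fitted normal CDF
  xs <- sort(x)
  F_ <- pnorm(xs, mean(x), sd(x))
  D_oracle <- max(pmax(abs((1:1000) / 1000 - F_), abs(F_ - (0:999) / 1000)))
  expect_equal(ks$statistic, D_oracle, tolerance = 1e-9)

  withr::local_seed(23)
  heavy <- c(rnorm(900), rexp(100, rate = 0.3) + 2)
  expect_lt(ks_normality(heavy)$p_value, 0.01)

  expect_error(ks_normality(rep(1, 20)), "constant")
  expect_error(ks_normality(rnorm(5)), "at least 8")
})
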