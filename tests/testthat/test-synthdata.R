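test_that("community specs validate prophage geometry and name offenders", {
  g <- data.frame(genome_id = "chr", length = 1e6)
  expect_error(community_spec(g, data.frame(
    genome_id = "chr", start = 5e5, end = 1.2e6, prophage_id = "ppX")),
    "ppX")
  expect_error(community_spec(g, data.frame(
    genome_id = "chr", start = c(1e5, 1.4e5), end = c(1.5e5, 2e5),
    prophage_id = c("ppA", "ppB"))),
    "overlap")
  expect_error(community_spec(g, data.frame(
    genome_id = "chr", start = 1e5, end = 1.5e5, prophage_id = "ppC",
    pac_offset = 60000)),
    "pac offset")
})

test_that("generated communities have the specified geometry", {
  cm <- generate_community(community_spec(
    data.frame(genome_id = "g1", length = 1e5), seed = 1), sequences = FALSE)
  expect_equal(nrow(cm$scaffolds), 1)
  expect_equal(cm$scaffolds$length, 1e5)

  cm2 <- generate_community(community_spec(
    genomes = data.frame(genome_id = "chr", length = 4e6),
    prophages = data.frame(genome_id = "chr", start = 1e6, end = 1056900,
                           prophage_id = "pp1")), sequences = FALSE)
  expect_equal(cm2$prophages$end - cm2$prophages$start, 56900)

  # scaffolding conserves total length
  cm3 <- generate_community(community_spec(
    genomes = data.frame(genome_id = c("a", "b"), length = c(3e5, 2e5)),
    breakpoints = data.frame(genome_id = "a", pos = c(1e5, 1.7e5))),
    sequences = FALSE)
  expect_equal(sum(cm3$scaffolds$length), 5e5)
  expect_equal(nrow(cm3$scaffolds), 4)
})

test_that("sequences and truth tables are byte-identical across reruns", {
  spec <- community_spec(
    genomes = data.frame(genome_id = "mini", length = 20000,
                         circular = TRUE, domain = "virus"), seed = 42)
  cm1 <- generate_community(spec)
  cm2 <- generate_community(spec)
  expect_identical(cm1$sequences, cm2$sequences)
  expect_equal(nchar(cm1$sequences[["mini"]]), 20000)

  params <- mechanism_params("headful")
  t1 <- simulate_particles(cm1, params, 50, seed = 7)
  t2 <- simulate_particles(cm2, params, 50, seed = 7)
  expect_identical(t1, t2)

  skip_if_not_installed("Biostrings")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_simulation(t1, cm1, d1, fasta = TRUE, seed = 7)
  f2 <- write_simulation(t2, cm2, d2, fasta = TRUE, seed = 7)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("cos packaging emits exact unit-genome molecules", {
  cm <- phage_community(102000)
  tr <- simulate_particles(cm, mechanism_params("cos"), 100, seed = 1)
  expect_equal(nrow(tr), 100)
  expect_true(all(tr$length == 102000))
  expect_true(all(tr$end - tr$start == tr$length))
})

test_that("headful packaging is terminally redundant and circularly permuted", {
  H <- 43400
  cm <- generate_community(community_spec(
    data.frame(genome_id = "phage", length = 41700, circular = TRUE,
               domain = "virus")), sequences = FALSE)
  tr <- simulate_particles(
    cm, mechanism_params("headful", capacity = H, imprecision = 0.02),
    5000, seed = 3)
  # lengths within capacity * (1 +/- imprecision), up to coordinate rounding
  expect_true(all(tr$length >= H * 0.98 - 1 & tr$length <= H * 1.02 + 1))
  # start positions modulo the genome spread over the whole genome
  dec <- table(cut(tr$start %% 41700, breaks = seq(0, 41700, length.out = 11)))
  expect_true(all(dec > 0))
  # one truth row per read
  expect_equal(anyDuplicated(tr$read_id), 0)
})

test_that("mu packaging appends 0.5-3 kb of host DNA and is always chimeric", {
  cm <- phage_community(37000)
  tr <- simulate_particles(
    cm, mechanism_params("mu", mu_host_range = c(500, 3000)), 1000, seed = 5)
  expect_true(all(tr$length >= 37500 & tr$length <= 40000))
  expect_true(all(tr$chimeric))
})

test_that("LT series follow the headful lattice from the prophage pac", {
  cm <- host_with_prophage() # prophage [2e5, 256900), pac offset 46900
  H <- 58400
  N <- 5
  tr <- simulate_particles(
    cm, mechanism_params("LT", capacity = H, series_length = N,
                         imprecision = 0.02), 5000, seed = 9)
  p <- 2e5 + 46900
  # brute-force lattice check: every start within eps*H of pac + (k-1)*H
  expected <- p + (tr$series_k - 1) * H
  expect_true(all(abs(tr$start - expected) <= 0.02 * H + 1))
  # prophage (56.9 kb) shorter than the headful: chimeric share ~ 1/N
  expect_true(all(tr$chimeric == (tr$series_k == 1)))
  expect_lt(abs(mean(tr$chimeric) - 1 / N), 0.02)
})

test_that("GT transducing particles carry host DNA at the configured rate", {
  cm <- gt_community()
  tr <- simulate_particles(
    cm, mechanism_params("GT", transducing_fraction = 0.128), 5000, seed = 2)
  host_share <- mean(tr$genome_id == "host")
  # binomial 99% interval around 0.128 at n = 5000
  expect_lt(abs(host_share - 0.128), 2.576 * sqrt(0.128 * 0.872 / 5000))
  expect_true(all(tr$series_k >= 1))
})

test_that("GTA fragment starts are uniform over the genome", {
  cm <- generate_community(community_spec(
    data.frame(genome_id = "chr", length = 4e6)), sequences = FALSE)
  params <- mechanism_params("GTA", capacity = 13400)
  pvals <- vapply(1:40, function(s) {
    tr <- simulate_particles(cm, params, 2000, seed = s)
    suppressWarnings(stats::ks.test(tr$start, "punif", 0, 4e6)$p.value)
  }, double(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("simulation handles empty and invalid requests", {
  cm <- phage_community()
  expect_equal(nrow(simulate_particles(cm, mechanism_params("cos"), 0, seed = 1)), 0)
  expect_error(simulate_particles(cm, mechanism_params("GTA"), 10, seed = 1),
               "capacity")
  expect_error(simulate_particles(cm, mechanism_params("LT"), 10, seed = 1),
               "prophage")
})

test_that("degradation truncates at the free end and keeps the anchor", {
  cm <- phage_community(58400)
  tr <- simulate_particles(cm, mechanism_params("cos"), 200, seed = 4)

  expect_identical(apply_degradation(tr, degraded_share = 0, seed = 1), tr)

  dg <- apply_degradation(tr, retained_range = c(0.402, 0.402),
                          degraded_share = 1, seed = 1)
  expect_true(all(dg$degraded))
  expect_true(all(dg$length == 23477))
  expect_identical(dg$start, tr$start)
  expect_identical(dg$end, dg$start + dg$length)
})

test_that("contamination is broad-spectrum free DNA at the requested share", {
  cm <- generate_community(community_spec(
    data.frame(genome_id = c("a", "b"), length = c(2e6, 1e6))),
    sequences = FALSE)
  base <- simulate_particles(cm, mechanism_params("GTA", capacity = 8650),
                             1000, seed = 6)
  expect_identical(add_contamination(base, cm, 0, seed = 1), base)

  mixed <- add_contamination(base, cm, 0.5, seed = 1)
  n_c <- sum(mixed$contaminant)
  # binomial 99% interval around 1000 of 2000
  expect_lt(abs(n_c - 1000), 2.576 * sqrt(2000 * 0.25))
  lens <- mixed$length[mixed$contaminant]
  expect_gt(sd(lens) / mean(lens), 0.3)
  # the broad length model contributes no narrow discrete peak
  expect_equal(nrow(detect_peaks(lens)), 0)
})
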