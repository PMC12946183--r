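test_that("pac inference finds the modal start window", {
  res <- infer_pac_site(rep(1e6, 25))
  expect_equal(res$position, 1e6)
  expect_equal(res$confidence, 1)

  withr::local_seed(3)
  p <- 1234567
  starts <- p + rnorm(500, 0, 200)
  res <- infer_pac_site(starts)
  expect_lte(abs(res$position - p), 500)
  # brute-force sliding-window oracle on the same grid
  centers <- seq(min(starts), max(starts), by = 100)
  cnt <- vapply(centers, function(cc)
    sum(starts >= cc - 500 & starts < cc + 500), integer(1))
  expect_equal(res$confidence, max(cnt) / 500)

  withr::local_seed(4)
  expect_null(infer_pac_site(runif(1000, 0, 1e6)))
  expect_error(infer_pac_site(1:10), "at least 20")
})

test_that("read loci partition into within, chimeric and outside", {
  a <- 2e5; b <- 256900; p <- 246900
  spans <- data.frame(
    start = c(a + 100, p,        b + 2e5, p,       a - 30000),
    end   = c(b - 100, b + 30000, b + 2.5e5, b + 1500, p + 500))
  locus <- classify_read_locus(spans, a, b, pac = p)
  # pac-anchored read barely crossing the boundary is within (95% rule);
  # a read ending at the pac and extending far upstream is leftward chimeric
  expect_equal(locus, c("within", "chimeric", "outside", "within", "chimeric"))
  expect_equal(length(locus), nrow(spans))
  expect_true(all(locus %in% c("within", "chimeric", "outside")))
  expect_error(classify_read_locus(spans, b, a), "invalid")
})

test_that("periodicity scoring separates headful lattices from uniform starts", {
  p <- 246900; H <- 58400
  expect_gte(periodicity_score(p + H * (1:3), p, H), 0.9)

  withr::local_seed(6)
  low <- vapply(1:20, function(i)
    periodicity_score(runif(1000, 0, 1e6), p, H), double(1))
  expect_gte(mean(low <= 0.05), 0.95)

  # joint shift invariance
  s <- p + H * (1:5) + rnorm(5, 0, 100)
  expect_equal(periodicity_score(s, p, H),
               periodicity_score(s + 1e5, p + 1e5, H))

  # simulated lateral transduction series scores high
  cm <- host_with_prophage()
  tr <- simulate_particles(cm, mechanism_params("LT", capacity = H),
                           2000, seed = 8)
  out <- tr[tr$series_k > 1, ]
  expect_gte(periodicity_score(out$start, 2e5 + 46900, H), 0.5)
})

test_that("coverage profiles measure uniformity and detect decaying waves", {
  expect_error(coverage_profile(rep(0, 1e4)), "all-zero")

  flat <- coverage_profile(rep(20, 2e5), boundary = 5e4)
  expect_equal(flat$cv, 0)
  expect_null(flat$wave)

  # decaying sawtooth downstream of the boundary, period 58.4 kb
  b <- 5e4; H <- 58400
  x <- 0:(6e5 - 1)
  down <- pmax(x - b, 0)
  phase <- (down %% H) / H
  cover <- ifelse(x < b, 50, 50 * (1 - phase) * 0.8^(down %/% H)) + 1
  prof <- coverage_profile(cover, boundary = b)
  expect_lt(abs(prof$wave$period - H) / H, 0.05)
  expect_true(prof$wave$decay)

  withr::local_seed(9)
  noise <- coverage_profile(runif(400, 10, 30), boundary = 1,
                            per_base = FALSE)
  expect_null(noise$wave)
})

test_that("the decision table reproduces each packaging mode", {
  th <- classify_thresholds()
  ev <- function(b) classify_event(b, th, taxon = "t")$mode

  lt <- make_bundle(center = 58400, prophage_length = 56900,
                    n_within = 1500, n_outside = 400, n_chimeric = 13,
                    chim_max_overrun = 45000, periodicity = 0.6)
  expect_equal(ev(lt), "LT")

  ind <- make_bundle(center = 58400, prophage_length = 56900,
                     n_within = 1900, n_outside = 50)
  expect_equal(ev(ind), "induction")

  st <- make_bundle(center = 58400, prophage_length = 56900,
                    n_within = 300, n_outside = 700, n_chimeric = 3,
                    chim_max_overrun = 30000, periodicity = 0)
  expect_equal(ev(st), "ST")

  gt <- make_bundle(center = 43400, cv = 0.3, scaffold_space = 4.6e6,
                    n_outside = 1000)
  expect_equal(ev(gt), "GT")

  gta <- make_bundle(center = 8650, cv = 0.3, scaffold_space = 2e6,
                     rel_halfwidth = 0.02, n_outside = 1000)
  expect_equal(ev(gta), "GTA")

  amb <- make_bundle(center = 30000, cv = Inf, n_outside = 100)
  expect_equal(ev(amb), "ambiguous")

  # below the event minimum nothing is emitted
  small <- make_bundle(center = 58400, n_members = 30, n_within = 30)
  expect_equal(nrow(classify_event(small, th)), 0)

  # rule traces are recorded for every event
  expect_match(classify_event(lt, th)$rule_trace, "LT:")
})

test_that("removing chimeras and periodicity demotes LT to induction", {
  th <- classify_thresholds()
  lt <- make_bundle(center = 58400, prophage_length = 56900,
                    n_within = 1900, n_outside = 50, n_chimeric = 50,
                    chim_max_overrun = 45000, periodicity = 0.6)
  expect_equal(classify_event(lt, th)$mode, "LT")
  demoted <- make_bundle(center = 58400, prophage_length = 56900,
                         n_within = 1900, n_outside = 50, n_chimeric = 0,
                         periodicity = 0)
  expect_equal(classify_event(demoted, th)$mode, "induction")
})

test_that("end-to-end event calls recover simulated LT and GTA lysates", {
  cm <- host_with_prophage() # 56.9 kb prophage, pac 46.9 kb into it
  tr <- simulate_particles(cm, mechanism_params("LT", capacity = 58400),
                           2000, seed = 21)
  aln <- filter_alignments(truth_to_alignments(tr, cm))
  ev <- call_events(aln, cm$scaffolds, cm$prophages)
  expect_equal(ev$mode, "LT")
  expect_lt(abs(ev$peak_center - 58400) / 58400, 0.02)

  cm2 <- generate_community(community_spec(
    data.frame(genome_id = "fprau", length = 2e6)), sequences = FALSE)
  tr2 <- simulate_particles(cm2, mechanism_params("GTA", capacity = 8650),
                            2000, seed = 22)
  ev2 <- call_events(filter_alignments(truth_to_alignments(tr2, cm2)),
                     cm2$scaffolds, cm2$prophages)
  expect_equal(ev2$mode, "GTA")
  expect_lt(abs(ev2$peak_center - 8650) / 8650, 0.02)
})
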