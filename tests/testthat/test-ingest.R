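paf_line <- function(read, rlen, scaf, slen, tstart, tend, strand = "+") {
  paste(read, rlen, 0, tend - tstart, strand, scaf, slen, tstart, tend,
        tend - tstart, tend - tstart, 60, sep = "\t")
}

test_that("PAF and interval-TSV encodings of an alignment load identically", {
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(paf_line("r1", 5000, "s1", 2e5, 10, 1010), paf)
  a_paf <- read_alignments(paf, "paf")
  expect_equal(a_paf$start, 10)
  expect_equal(a_paf$end, 1010)
  expect_equal(a_paf$aln_len, 1000)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(a_paf, tsv)
  a_tsv <- read_alignments(tsv, "tsv")
  expect_identical(as.data.frame(a_paf), as.data.frame(a_tsv))
})

test_that("alignment loading handles empty and malformed input", {
  f <- withr::local_tempfile(fileext = ".paf")
  file.create(f)
  expect_equal(nrow(read_alignments(f, "paf")), 0)
  writeLines(c(paf_line("r1", 5000, "s1", 2e5, 10, 1010),
               gsub("\t10\t", "\tnope\t", paf_line("r2", 5000, "s1", 2e5, 10, 1010))),
             f)
  expect_error(read_alignments(f, "paf"), "line 2")
})

test_that("length filters drop short reads and short alignments, idempotently", {
  aln <- tibble::tibble(
    read_id = c("a", "b", "c", "d"),
    read_len = c(2999, 3000, 3500, 8000),
    scaffold_id = "s1", start = 0,
    end = c(2000, 2000, 999, 5000), strand = "+",
    aln_len = c(2000, 2000, 999, 5000))
  kept <- filter_alignments(aln)
  expect_equal(kept$read_id, c("b", "d"))
  expect_identical(filter_alignments(kept), kept)
  expect_equal(nrow(filter_alignments(aln[0, ])), 0)
})

test_that("reads go to the scaffold with the greatest alignment-length sum", {
  aln <- tibble::tibble(
    read_id = c("r1", "r1", "r1", "r2", "r3", "r3"),
    read_len = 10000,
    scaffold_id = c("S1", "S1", "S2", "S9", "SB", "SA"),
    start = 0, end = 1, strand = "+",
    aln_len = c(5000, 4000, 8000, 3000, 6000, 6000))
  asg <- assign_reads(aln)
  expect_equal(asg$scaffold_id[asg$read_id == "r1"], "S1") # 9000 > 8000
  expect_equal(asg$scaffold_id[asg$read_id == "r2"], "S9") # single alignment
  expect_equal(asg$scaffold_id[asg$read_id == "r3"], "SA") # tie -> lexicographic
  # totality: one row per distinct read
  expect_equal(sort(asg$read_id), sort(unique(aln$read_id)))
})

test_that("scaffold categories form the documented six-way partition", {
  sc <- tibble::tibble(
    scaffold_id = paste0("s", 1:6),
    length = 1e5,
    bin_id = c(NA, "bin1", "bin1", NA, NA, "bin2"),
    domain = c("virus", "bacteria", "bacteria", "bacteria", "bacteria", "archaea"),
    taxonomy = NA_character_,
    is_viral = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  pp <- tibble::tibble(scaffold_id = c("s3", "s5"), start = 0, end = 5e4,
                       prophage_id = c("p1", "p2"), pac_offset = 0)
  cat <- categorize_scaffolds(sc, pp)$category
  expect_equal(cat, c("Viruses", "MAG bacteria", "MAG bacteria with prophages",
                      "Bacteria unbinned", "Bacteria with prophages", "Archaea"))
  expect_error(categorize_scaffolds(dplyr::mutate(sc, domain = NA)), "domain")
})

test_that("taxon rollup applies rare-entity thresholds and label fallback", {
  sc <- tibble::tibble(
    scaffold_id = c("m1", "u1", "v1"),
    length = 1e5,
    bin_id = c("bin7", NA, NA),
    domain = c("bacteria", "bacteria", "virus"),
    taxonomy = c(NA, "d__Bacteria;g__Faecalibacterium", NA),
    is_viral = c(FALSE, FALSE, TRUE))
  asg <- tibble::tibble(
    read_id = sprintf("r%04d", 1:302),
    read_len = 10000,
    scaffold_id = c(rep("m1", 50), rep("u1", 51), rep("v1", 201)),
    aln_sum = 5000)
  roll <- rollup_taxa(asg, sc)
  # exactly 50 reads -> dropped; 51 -> kept; 201 viral reads -> kept
  expect_setequal(roll$taxon, c("g__Faecalibacterium", "v1"))
  expect_equal(roll$n_reads[roll$taxon == "v1"], 201)
  # bin id would win over taxonomy when present
  expect_equal(rollup_taxa(asg[1:51, ] |>
                             dplyr::mutate(scaffold_id = "m1"), sc)$taxon, "bin7")
  expect_equal(nrow(rollup_taxa(asg[0, ], sc)), 0)
  expect_error(rollup_taxa(dplyr::mutate(asg, scaffold_id = "ghost"), sc),
               "unknown scaffold")
})

test_that("assignment recovers the true source scaffold on simulated data", {
  cm <- generate_community(community_spec(
    genomes = data.frame(genome_id = c("chrA", "chrB"),
                         length = c(2e6, 1e6)),
    breakpoints = data.frame(genome_id = "chrA", pos = 1e6)),
    sequences = FALSE)
  tr <- simulate_particles(cm, mechanism_params("GTA", capacity = 13400),
                           2000, seed = 31, genome_id = "chrA")
  aln <- filter_alignments(truth_to_alignments(tr, cm))
  asg <- assign_reads(aln)
  truth_scaffold <- vapply(seq_len(nrow(tr)), function(i) {
    hits <- aln$scaffold_id[aln$read_id == tr$read_id[i]]
    tr$read_id[i] %in% asg$read_id &&
      asg$scaffold_id[asg$read_id == tr$read_id[i]] %in% hits
  }, logical(1))
  ok <- mean(asg$scaffold_id %in% c("chrA_s01", "chrA_s02"))
  expect_gte(ok, 0.99)
  expect_true(all(truth_scaffold[tr$read_id %in% asg$read_id]))
})
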