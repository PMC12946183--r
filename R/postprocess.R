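#' Truncate a share of packaged molecules at their free end
#'
#' Models partial capsid DNA ejection / degradation after packaging: a
#' degraded molecule keeps its packaging-start end (the truth `start`
#' coordinate is unchanged) and loses sequence from the far end, so the
#' alignment starts of degraded and intact molecules from the same particle
#' class coincide.
#'
#' @param truth a truth tibble from [simulate_particles()].
#' @param retained_range two-element numeric `(lo, hi)`: the retained
#'   fraction of each degraded molecule is drawn uniformly from this range
#'   (default `c(0.1, 0.9)`). Set `lo == hi` for a fixed fraction.
#' @param degraded_share fraction of molecules degraded (default 0).
#' @param seed master seed.
#' @return the truth tibble with updated `end`/`length` and `degraded` flags.
#' @examples
#' cm <- generate_community(community_spec(
#'   data.frame(genome_id = "phi", length = 58400, domain = "virus")),
#'   sequences = FALSE)
#' tr <- simulate_particles(cm, mechanism_params("cos"), 10, seed = 1)
#' apply_degradation(tr, c(0.402, 0.402), degraded_share = 1, seed = 1)
#' @export
apply_degradation <- function(truth, retained_range = c(0.1, 0.9),
                              degraded_share = 0, seed = 1L) {
  if (length(retained_range) != 2 || retained_range[1] > retained_range[2] ||
      any(retained_range < 0) || any(retained_range > 1)) {
    abort("`retained_range` must be c(lo, hi) with 0 <= lo <= hi <= 1")
  }
  check_fraction(degraded_share, "degraded_share")
  if (degraded_share == 0 || nrow(truth) == 0) return(truth)
  with_component_seed(seed, "degradation", {
    hit <- runif(nrow(truth)) < degraded_share
    retained <- runif(sum(hit), retained_range[1], retained_range[2])
    new_len <- pmax(1, round(truth$length[hit] * retained))
    truth$end[hit] <- truth$start[hit] + new_len
    truth$length[hit] <- new_len
    truth$degraded[hit] <- TRUE
    truth
  })
}

#' Spike free bacterial DNA into a simulated particle set
#'
#' Adds contaminant reads modelling free (non-encapsidated) DNA released by
#' cell lysis: drawn uniformly across community genomes (weighted by length)
#' with a broad log-normal length distribution, so they contribute no
#' discrete read-length peak.
#'
#' @param truth a truth tibble.
#' @param community a [generate_community()] result.
#' @param contaminant_share expected share of contaminant reads in the
#'   returned table.
#' @param length_median median contaminant length in bp (default 8000).
#' @param length_sdlog10 log10 standard deviation of contaminant lengths
#'   (default 0.35; coefficient of variation about 0.96).
#' @param seed master seed.
#' @return the truth tibble with contaminant rows appended
#'   (`mechanism = "contaminant"`, `contaminant = TRUE`).
#' @export
add_contamination <- function(truth, community, contaminant_share,
                              length_median = 8000, length_sdlog10 = 0.35,
                              seed = 1L) {
  check_fraction(contaminant_share, "contaminant_share", 0, 1 - 1e-9)
  if (contaminant_share == 0) return(truth)
  n0 <- nrow(truth)
  with_component_seed(seed, "contamination", {
    n_target <- max(1, round(n0 / (1 - contaminant_share)))
    n_c <- rbinom(1, n_target, contaminant_share)
    if (n_c == 0) return(truth)
    genomes <- community$genomes
    gi <- sample.int(nrow(genomes), n_c, replace = TRUE, prob = genomes$length)
    len <- round(rlnorm(n_c, meanlog = log(length_median),
                        sdlog = length_sdlog10 * log(10)))
    len <- pmax(200, pmin(len, genomes$length[gi]))
    start <- floor(runif(n_c, 0, genomes$length[gi] - len + 1))
    contam <- truth_row(sprintf("contam_%06d", seq_len(n_c)), "contaminant",
                        genomes$genome_id[gi], "genome",
                        start, start + len, len)
    contam$contaminant <- TRUE
    bind_rows(truth, contam)
  })
}

#' Convert simulated ground truth into alignment intervals
#'
#' Emulates what an aligner would report for each simulated molecule:
#' 0-based half-open intervals on the community's scaffolds. Fragments that
#' wrap a circular unit (doubled coordinates) or span scaffold breakpoints
#' are split into one alignment row per scaffold piece; free-phage Mu
#' molecules align over the phage span only (their host overhang is
#' exogenous to the community).
#'
#' @param truth a truth tibble.
#' @param community a [generate_community()] result.
#' @return an alignment tibble (`read_id`, `read_len`, `scaffold_id`,
#'   `start`, `end`, `strand`, `aln_len`) in the ingest dialect.
#' @export
truth_to_alignments <- function(truth, community) {
  empty <- tibble(read_id = character(), read_len = double(),
                  scaffold_id = character(), start = double(),
                  end = double(), strand = character(), aln_len = double())
  if (nrow(truth) == 0) return(empty)
  g <- community$genomes
  tr <- truth
  tr$glen <- g$length[match(tr$genome_id, g$genome_id)]
  tr$circular <- g$circular[match(tr$genome_id, g$genome_id)]

  # wrap geometry: genome-circle rows wrap at the genome end back to 0,
  # prophage-circle rows wrap at the prophage end back to its start
  pros <- community$prophages
  on_pp <- tr$circle != "genome"
  a_abs <- b_abs <- rep(NA_real_, nrow(tr))
  if (any(on_pp)) {
    j <- match(tr$circle[on_pp], pros$prophage_id)
    off <- community$scaffolds$offset[
      match(pros$scaffold_id[j], community$scaffolds$scaffold_id)]
    a_abs[on_pp] <- pros$start[j] + off
    b_abs[on_pp] <- pros$end[j] + off
  }
  cut <- ifelse(on_pp, b_abs, ifelse(tr$circular, tr$glen, Inf))
  wrap_to <- ifelse(on_pp, a_abs, 0)

  end1 <- pmin(tr$end, cut, tr$glen)
  has2 <- tr$end > cut
  pieces <- tibble(read_id = tr$read_id, read_len = tr$length,
                   genome_id = tr$genome_id, start = tr$start, end = end1)
  if (any(has2)) {
    pieces <- bind_rows(pieces, tibble(
      read_id = tr$read_id[has2], read_len = tr$length[has2],
      genome_id = tr$genome_id[has2], start = wrap_to[has2],
      end = wrap_to[has2] + (tr$end[has2] - cut[has2])))
  }
  pieces <- pieces[pieces$end > pieces$start, ]

  # place the pieces onto scaffolds
  scaff <- community$scaffolds
  n_sc <- table(scaff$genome_id)
  single <- names(n_sc)[n_sc == 1]
  simple <- pieces$genome_id %in% single
  out <- list()
  if (any(simple)) {
    ps <- pieces[simple, ]
    sid <- scaff$scaffold_id[match(ps$genome_id, scaff$genome_id)]
    out[[1]] <- tibble(read_id = ps$read_id, read_len = ps$read_len,
                       scaffold_id = sid, start = ps$start, end = ps$end)
  }
  if (any(!simple)) {
    pm <- pieces[!simple, ]
    out[[2]] <- purrr::map_dfr(seq_len(nrow(pm)), function(i) {
      hit <- map_interval_to_scaffolds(community, pm$genome_id[i],
                                       pm$start[i], pm$end[i])
      hit$read_id <- pm$read_id[i]
      hit$read_len <- pm$read_len[i]
      hit
    })
  }
  rows <- bind_rows(out)
  if (nrow(rows) == 0) return(empty)
  rows$strand <- "+"
  rows$aln_len <- rows$end - rows$start
  rows <- rows[order(match(rows$read_id, truth$read_id)), ]
  rows[, c("read_id", "read_len", "scaffold_id", "start", "end",
           "strand", "aln_len")]
}

#' Extract read sequences for simulated molecules
#'
#' @param community a community generated with `sequences = TRUE`.
#' @param truth a truth tibble.
#' @param seed master seed, used only to synthesise the exogenous host
#'   overhang of free-phage Mu reads.
#' @return named character vector of read sequences.
#' @export
read_sequences <- function(community, truth, seed = 1L) {
  if (is.null(community$sequences)) {
    abort("community was generated with `sequences = FALSE`")
  }
  seqs <- community$sequences
  out <- character(nrow(truth))
  extra <- with_component_seed(seed, "mu-host-overhang", {
    lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      gap <- tr$length - (tr$end - tr$start)
      if (tr$mechanism == "mu" && gap > 0) {
        paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE), collapse = "")
      } else ""
    })
  })
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    g <- community$genomes[community$genomes$genome_id == tr$genome_id, ]
    s <- seqs[[tr$genome_id]]
    if (tr$circle != "genome") {
      pp <- community$prophages[community$prophages$prophage_id == tr$circle, ]
      off <- community$scaffolds$offset[
        community$scaffolds$scaffold_id == pp$scaffold_id]
      a <- pp$start + off; b <- pp$end + off
      body <- if (tr$end > b) {
        paste0(substr(s, tr$start + 1, b), substr(s, a + 1, a + (tr$end - b)))
      } else {
        substr(s, tr$start + 1, tr$end)
      }
    } else if (tr$end > g$length && g$circular) {
      body <- paste0(substr(s, tr$start + 1, g$length),
                     substr(s, 1, tr$end - g$length))
    } else {
      body <- substr(s, tr$start + 1, min(tr$end, g$length))
    }
    out[i] <- paste0(body, extra[[i]])
  }
  setNames(out, truth$read_id)
}

#' Write simulated reads as FASTA
#'
#' @param sequences named character vector from [read_sequences()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("writing FASTA requires the Biostrings package")
  }
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Write the simulation artefacts for one sample
#'
#' Emits the ingest-dialect files: alignment interval TSV, truth TSV,
#' scaffold metadata TSV and prophage BED (plus optional FASTA reads).
#'
#' @param truth truth tibble.
#' @param community a [generate_community()] result.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default `"sample"`).
#' @param fasta also write read sequences as FASTA (requires a community with
#'   sequences)?
#' @param seed seed forwarded to [read_sequences()].
#' @return named character vector of the files written.
#' @export
write_simulation <- function(truth, community, dir, prefix = "sample",
                             fasta = FALSE, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(ext) file.path(dir, paste0(prefix, ext))
  aln <- truth_to_alignments(truth, community)
  readr::write_tsv(aln, f(".alignments.tsv"))
  readr::write_tsv(truth, f(".truth.tsv"))
  scaff <- community$scaffolds[, c("scaffold_id", "length", "bin_id",
                                   "domain", "taxonomy", "is_viral")]
  readr::write_tsv(scaff, f(".scaffolds.tsv"))
  bed <- community$prophages
  bed_df <- tibble(chrom = bed$scaffold_id, chromStart = bed$start,
                   chromEnd = bed$end, name = bed$prophage_id,
                   score = bed$pac_offset, strand = "+")
  readr::write_tsv(bed_df, f(".prophages.bed"), col_names = FALSE)
  files <- c(alignments = f(".alignments.tsv"), truth = f(".truth.tsv"),
             scaffolds = f(".scaffolds.tsv"), prophages = f(".prophages.bed"))
  if (isTRUE(fasta)) {
    write_reads_fasta(read_sequences(community, truth, seed = seed),
                      f(".reads.fasta"))
    files <- c(files, reads = f(".reads.fasta"))
  }
  files
}
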