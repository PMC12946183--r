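read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  config
}

lol_to_tibble <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(as_tibble(x))
  bind_rows(lapply(x, function(row) as_tibble(row[!vapply(row, is.null, TRUE)])))
}

#' Run a configured simulation
#'
#' Builds the community, draws particles for every sample and mechanism in
#' the configuration, applies degradation and contamination, and writes the
#' ingest-dialect artefacts plus a checksum manifest. Outputs are
#' deterministic for a fixed seed: the manifest of two runs with the same
#' config is identical.
#'
#' @param config a list, or path to a YAML file, with entries:
#'   `seed`; `outdir`; `community` (`genomes`, optional `prophages`,
#'   `breakpoints`); `samples` — a list of samples, each with `sample_id`,
#'   optional `donor`/`fraction`, a `mechanisms` list (each with
#'   `mechanism`, `n_particles`, optional `genome_id`/`prophage_id`/
#'   `phage_genome_id` and `params` overrides for [mechanism_params()]),
#'   and optional `degradation` (`share`, `retained_range`) and
#'   `contamination` (`share`, `length_median`, `length_sdlog10`) blocks;
#'   optional `fasta` (default `FALSE`) and `sequences`.
#' @param outdir overrides the configured output directory.
#' @return (invisibly) the manifest tibble (`file`, `md5`).
#' @export
run_simulate <- function(config, outdir = NULL) {
  cfg <- read_config(config)
  seed <- cfg$seed %||% 1L
  outdir <- outdir %||% cfg$outdir %||% abort("config needs `outdir`")
  if (is.null(cfg$community) || is.null(cfg$community$genomes)) {
    abort("config needs `community$genomes`")
  }
  spec <- community_spec(
    genomes = lol_to_tibble(cfg$community$genomes),
    prophages = lol_to_tibble(cfg$community$prophages),
    breakpoints = lol_to_tibble(cfg$community$breakpoints),
    seed = seed)
  want_fasta <- isTRUE(cfg$fasta)
  community <- generate_community(
    spec, sequences = want_fasta || isTRUE(cfg$sequences))
  if (is.null(cfg$samples) || !length(cfg$samples)) abort("config needs `samples`")

  files <- character()
  for (smp in cfg$samples) {
    sid <- smp$sample_id %||% abort("every sample needs `sample_id`")
    truth <- empty_truth()
    for (i in seq_along(smp$mechanisms)) {
      m <- smp$mechanisms[[i]]
      params <- do.call(mechanism_params,
                        c(list(mechanism = m$mechanism), m$params))
      tr <- simulate_particles(
        community, params, m$n_particles %||% 0,
        seed = component_seed(seed, sprintf("%s:%d:%s", sid, i, m$mechanism)),
        genome_id = m$genome_id, prophage_id = m$prophage_id,
        phage_genome_id = m$phage_genome_id)
      if (nrow(tr)) {
        tr$read_id <- sprintf("%s_%s", sid, tr$read_id)
        truth <- bind_rows(truth, tr)
      }
    }
    if (!is.null(smp$degradation)) {
      truth <- apply_degradation(
        truth, retained_range = unlist(smp$degradation$retained_range) %||% c(0.1, 0.9),
        degraded_share = smp$degradation$share %||% 0,
        seed = component_seed(seed, paste0(sid, ":degradation")))
    }
    if (!is.null(smp$contamination)) {
      truth <- add_contamination(
        truth, community, contaminant_share = smp$contamination$share %||% 0,
        length_median = smp$contamination$length_median %||% 8000,
        length_sdlog10 = smp$contamination$length_sdlog10 %||% 0.35,
        seed = component_seed(seed, paste0(sid, ":contamination")))
    }
    inform(sprintf("simulate: sample %s -> %d reads", sid, nrow(truth)))
    files <- c(files, write_simulation(
      truth, community, dir = outdir, prefix = sid, fasta = want_fasta,
      seed = component_seed(seed, paste0(sid, ":sequences"))))
  }
  manifest <- tibble(file = basename(unname(files)),
                     md5 = unname(tools::md5sum(files)))
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}

#' Run the analysis pipeline over configured samples
#'
#' For every sample: load and filter alignments, assign reads, roll up taxa,
#' detect read-length peaks, assemble evidence and call packaging events.
#' When per-scaffold short-read counts are configured for a donor's VLP and
#' total-community samples, VLP enrichment Z-scores are computed; without a
#' total-community sample enrichment is skipped with a warning.
#'
#' @param config a list or YAML path with entries: `scaffolds` (metadata TSV
#'   path), optional `prophages` (BED path), `samples` — each with
#'   `sample_id`, `alignments` (path), optional `dialect` (`"tsv"` default,
#'   or `"paf"`), `donor`, `fraction` (`"total"`, `"B"` or `"T"`), and
#'   optional `counts` (TSV with `scaffold_id`, `count`); optional
#'   `thresholds` overrides for [classify_thresholds()]; optional `outdir`
#'   to write result tables.
#' @return a list with tibbles `events`, `peaks`, `enrichment`, `summary`.
#' @export
run_analyze <- function(config) {
  cfg <- read_config(config)
  if (is.null(cfg$scaffolds)) abort("config needs `scaffolds`")
  scaffolds <- read_scaffold_metadata(cfg$scaffolds)
  scaffolds <- categorize_scaffolds(
    scaffolds, if (!is.null(cfg$prophages)) read_prophage_bed(cfg$prophages))
  prophages <- if (!is.null(cfg$prophages)) read_prophage_bed(cfg$prophages)
  thresholds <- do.call(classify_thresholds, cfg$thresholds %||% list())

  events <- list(); peaks_tbl <- list(); summary_rows <- list()
  counts_by_sample <- list()
  meta <- list()
  for (smp in cfg$samples) {
    sid <- smp$sample_id %||% abort("every sample needs `sample_id`")
    meta[[sid]] <- list(donor = smp$donor %||% "donor1",
                        fraction = smp$fraction %||% "B")
    aln <- read_alignments(smp$alignments, dialect = smp$dialect %||% "tsv")
    n0 <- length(unique(aln$read_id))
    aln <- filter_alignments(aln,
                             min_read_len = cfg$min_read_len %||% 3000,
                             min_aln_len = cfg$min_aln_len %||% 1000)
    asg <- assign_reads(aln)
    inform(sprintf("analyze[%s]: %d reads aligned, %d retained after filters",
                   sid, n0, nrow(asg)))
    # bacterial-scaffold read share: purely bacterial scaffolds carry no
    # viral fragments and are not viruses themselves
    cat_of <- setNames(scaffolds$category, scaffolds$scaffold_id)
    share_bact <- if (nrow(asg)) {
      mean(cat_of[asg$scaffold_id] %in% c("MAG bacteria", "Bacteria unbinned"))
    } else 0
    summary_rows[[sid]] <- tibble(
      sample = sid, donor = meta[[sid]]$donor, fraction = meta[[sid]]$fraction,
      n_aligned = n0, n_retained = nrow(asg),
      bacterial_read_share = share_bact)

    roll <- rollup_taxa(asg, scaffolds, prophages)
    if (nrow(roll)) {
      pk <- purrr::map_dfr(seq_len(nrow(roll)), function(i) {
        p <- detect_peaks(roll$read_lengths[[i]],
                          min_peak_reads = thresholds$min_event_reads)
        if (nrow(p)) {
          tibble(sample = sid, taxon = roll$taxon[i], peak_id = p$peak_id,
                 center = p$center, rel_halfwidth = p$rel_halfwidth,
                 n_members = p$n_members, share = p$share)
        }
      })
      peaks_tbl[[sid]] <- pk
    }
    ev <- call_events(aln, scaffolds, prophages, thresholds, sample = sid)
    inform(sprintf("analyze[%s]: %d taxa retained, %d event(s) called",
                   sid, nrow(roll), nrow(ev)))
    events[[sid]] <- ev
    if (!is.null(smp$counts)) {
      counts_by_sample[[sid]] <- readr::read_tsv(
        smp$counts, col_types = readr::cols(
          scaffold_id = readr::col_character(),
          count = readr::col_double()), progress = FALSE)
    }
  }

  enrichment <- list()
  donors <- unique(vapply(meta, `[[`, "", "donor"))
  for (d in donors) {
    sids <- names(meta)[vapply(meta, `[[`, "", "donor") == d]
    total_sid <- sids[vapply(meta[sids], `[[`, "", "fraction") == "total"]
    vlp_sids <- setdiff(sids, total_sid)
    vlp_sids <- vlp_sids[vlp_sids %in% names(counts_by_sample)]
    if (!length(vlp_sids)) next
    if (!length(total_sid) || !total_sid[1] %in% names(counts_by_sample)) {
      warn(sprintf("donor %s: no total-community counts; enrichment skipped", d))
      next
    }
    tot <- counts_by_sample[[total_sid[1]]]
    for (v in vlp_sids) {
      cc <- dplyr::full_join(
        rename(counts_by_sample[[v]], vlp_count = "count"),
        rename(tot, total_count = "count"), by = "scaffold_id") |>
        tidyr::replace_na(list(vlp_count = 0, total_count = 0))
      er <- enrichment_z(cc)
      er$sample <- v; er$donor <- d; er$fraction <- meta[[v]]$fraction
      enrichment[[v]] <- er
    }
  }

  res <- list(
    events = if (length(events)) bind_rows(events) else empty_events(),
    peaks = bind_rows(peaks_tbl),
    enrichment = bind_rows(enrichment),
    summary = bind_rows(summary_rows))
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(res$events, file.path(cfg$outdir, "events.tsv"))
    jsonlite::write_json(res$events, file.path(cfg$outdir, "events.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    readr::write_tsv(res$peaks, file.path(cfg$outdir, "peaks.tsv"))
    readr::write_tsv(res$enrichment, file.path(cfg$outdir, "enrichment.tsv"))
    readr::write_tsv(res$summary, file.path(cfg$outdir, "summary.tsv"))
  }
  res
}

benchmark_configs <- function() {
  list(
    cos = list(
      genomes = tibble(genome_id = "hostA", length = 1e6),
      prophages = tibble(genome_id = "hostA", start = 3e5, end = 356900,
                         prophage_id = "ppA", pac_offset = 0),
      params = mechanism_params("cos"), n = 1000, expected = "induction",
      taxon = "hostA"),
    headful = list(
      genomes = tibble(genome_id = "hostB", length = 1e6),
      prophages = tibble(genome_id = "hostB", start = 3e5, end = 341700,
                         prophage_id = "ppB", pac_offset = 20000),
      params = mechanism_params("headful", redundancy = 0.041),
      n = 1000, expected = "induction", taxon = "hostB"),
    mu = list(
      genomes = tibble(genome_id = "hostC", length = 1e6),
      prophages = tibble(genome_id = "hostC", start = 3e5, end = 337000,
                         prophage_id = "ppC", pac_offset = 0),
      params = mechanism_params("mu"), n = 1000, expected = "induction",
      taxon = "hostC"),
    GT = list(
      genomes = tibble(genome_id = c("hostD", "phageD"),
                       length = c(4.6e6, 41700),
                       circular = c(TRUE, TRUE),
                       domain = c("bacteria", "virus")),
      prophages = NULL,
      params = mechanism_params("GT", transducing_fraction = 0.128),
      n = 6000, expected = "GT", taxon = "hostD"),
    LT = list(
      genomes = tibble(genome_id = "hostE", length = 1e6),
      prophages = tibble(genome_id = "hostE", start = 2e5, end = 256900,
                         prophage_id = "ppE", pac_offset = 46900),
      params = mechanism_params("LT", capacity = 58400), n = 1000,
      expected = "LT", taxon = "hostE"),
    GTA = list(
      genomes = tibble(genome_id = "hostF", length = 2e6),
      prophages = NULL,
      params = mechanism_params("GTA", capacity = 8650), n = 2000,
      expected = "GTA", taxon = "hostF")
  )
}

#' Run the labelled six-mechanism classification benchmark
#'
#' Simulates replicate single-mechanism lysates (cos, headful and Mu prophage
#' induction; generalised transduction; lateral transduction; GTA-like
#' packaging), pushes each through the full pipeline (alignment conversion,
#' filters, assignment, peak detection, evidence, decision table) and
#' records the called mode for the event on the expected taxon.
#'
#' @param seed master seed.
#' @param n_replicates seeded replicates per mechanism (default 20).
#' @param thresholds a [classify_thresholds()] list.
#' @return tibble with `mechanism`, `replicate`, `expected`, `called`.
#' @export
run_benchmark <- function(seed = 1L, n_replicates = 20,
                          thresholds = classify_thresholds()) {
  cfgs <- benchmark_configs()
  out <- list()
  for (mech in names(cfgs)) {
    cfg <- cfgs[[mech]]
    community <- generate_community(
      community_spec(cfg$genomes, cfg$prophages, seed = seed),
      sequences = FALSE)
    for (rep in seq_len(n_replicates)) {
      truth <- simulate_particles(
        community, cfg$params, cfg$n,
        seed = component_seed(seed, sprintf("benchmark:%s:%d", mech, rep)))
      aln <- filter_alignments(truth_to_alignments(truth, community))
      ev <- call_events(aln, community$scaffolds, community$prophages,
                        thresholds)
      ev <- ev[ev$taxon == cfg$taxon, ]
      called <- if (nrow(ev)) ev$mode[which.max(ev$n_members)] else "none"
      out[[length(out) + 1]] <- tibble(
        mechanism = mech, replicate = rep,
        expected = cfg$expected, called = called)
    }
  }
  bind_rows(out)
}

#' Per-mechanism recall of a benchmark run
#'
#' @param benchmark output of [run_benchmark()].
#' @return tibble with `mechanism`, `n`, `recall`.
#' @export
benchmark_recall <- function(benchmark) {
  benchmark |>
    group_by(.data$mechanism) |>
    summarise(n = dplyr::n(), recall = mean(.data$called == .data$expected),
              .groups = "drop")
}
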