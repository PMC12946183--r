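# small standard communities used across test files

phage_community <- function(length = 102000, circular = FALSE, seed = 1) {
  generate_community(community_spec(
    data.frame(genome_id = "phage", length = length, circular = circular,
               domain = "virus"), seed = seed), sequences = FALSE)
}

# a 1 Mb host chromosome carrying one prophage
host_with_prophage <- function(pp_start = 2e5, pp_len = 56900,
                               pac_offset = 46900, host_len = 1e6,
                               circular = FALSE, seed = 1) {
  generate_community(community_spec(
    genomes = data.frame(genome_id = "host", length = host_len,
                         circular = circular),
    prophages = data.frame(genome_id = "host", start = pp_start,
                           end = pp_start + pp_len, prophage_id = "pp1",
                           pac_offset = pac_offset),
    seed = seed), sequences = FALSE)
}

gt_community <- function(host_len = 4.6e6, phage_len = 93600, seed = 1) {
  generate_community(community_spec(
    data.frame(genome_id = c("host", "phage"),
               length = c(host_len, phage_len),
               circular = c(TRUE, TRUE),
               domain = c("bacteria", "virus")), seed = seed),
    sequences = FALSE)
}

# minimal evidence bundle for decision-table unit tests
make_bundle <- function(center = 58400, n_members = 2000, rel_halfwidth = 0.02,
                        n_within = 0, n_outside = 0, n_chimeric = 0,
                        chim_max_overrun = NA_real_, periodicity = 0,
                        cv = Inf, scaffold_space = 1e6,
                        prophage_length = NULL, wave = NULL,
                        pac_position = NA_real_) {
  matched <- if (!is.null(prophage_length)) {
    tibble::tibble(scaffold_id = "host", start = 2e5,
                   end = 2e5 + prophage_length, prophage_id = "pp1",
                   pac_offset = 0, pp_len = prophage_length)
  }
  n_counted <- n_within + n_outside + n_chimeric
  structure(list(
    peak = tibble::tibble(center = center, rel_halfwidth = rel_halfwidth,
                          n_members = as.integer(n_members),
                          share = 1),
    n_counted = n_counted, n_within = n_within, n_outside = n_outside,
    n_chimeric = n_chimeric, chim_max_overrun = chim_max_overrun,
    overlap_share = if (n_counted) n_within / n_counted else 0,
    pac = NULL, pac_position = pac_position, periodicity = periodicity,
    cv = cv, scaffold_space = scaffold_space,
    matched_prophage = matched, wave = wave, anchor_scaffold = "host"
  ), class = "evidence_bundle")
}
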