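#' Classifier thresholds
#'
#' All numeric thresholds of the event decision table and evidence builder,
#' exposed in one place. Defaults: events need at least 50 member reads
#' (mirroring the rare-entity filter); within/outside/chimeric counting uses
#' reads of at least 0.7 times the peak center; a prophage "matches" a peak
#' when its length is within \[0.9, 1.1\] of the peak center or it contains
#' the inferred pac; lateral transduction needs 5 chimeras, a periodicity
#' score of 0.3, or a coverage wave with period within 5% of the peak;
#' induction needs 80% prophage overlap and a peak center within \[0.95,
#' 1.10\] of the prophage length; generalised transduction needs coverage
#' CV at most 0.5 over at least 200 kb of scaffold space, a peak center of
#' at least 15 kb and prophage overlap below 0.2; GTA-like packaging needs
#' the same coverage uniformity with a peak center below 15 kb and relative
#' half-width at most 0.05.
#'
#' @param ... named overrides of any default listed above.
#' @return a named list of thresholds.
#' @export
classify_thresholds <- function(...) {
  defaults <- list(
    min_event_reads = 50,
    length_cut_frac = 0.7,
    margin = 2000,
    pac_window = 500,
    pac_step = 100,
    pac_min_share = 0.2,
    pac_min_starts = 20,
    prophage_match_range = c(0.9, 1.1),
    lt_min_chimeric = 5,
    lt_min_periodicity = 0.3,
    periodicity_tol = 0.02,
    min_periodicity_starts = 10,
    wave_period_tol = 0.05,
    induction_min_overlap = 0.8,
    induction_center_range = c(0.95, 1.10),
    gt_max_cv = 0.5,
    gt_min_span = 200000,
    gt_min_center = 15000,
    gt_max_overlap = 0.2,
    gta_max_center = 15000,
    gta_max_halfwidth = 0.05,
    coverage_window = 1000,
    smooth_windows = 5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) abort(sprintf("unknown threshold `%s`", unknown[1]))
  defaults[names(dots)] <- dots
  defaults
}

#' Assemble the evidence bundle for one taxon and peak
#'
#' Gathers everything the decision table consumes: within/outside/chimeric
#' locus counts among reads at or above the length cut, the inferred pac
#' site and its confidence, the periodicity score of out-of-prophage starts,
#' long-read coverage uniformity across the taxon's scaffolds, the prophage
#' overlap share, and the matched prophage (a viral fragment whose length is
#' within the match range of the peak center, or which contains the inferred
#' pac).
#'
#' @param reads one row per taxon read: `read_id`, `read_len`,
#'   `scaffold_id`, `span_start`, `span_end` (alignment span on the assigned
#'   scaffold).
#' @param peak one row of a [detect_peaks()] result.
#' @param scaffolds taxon scaffold metadata (`scaffold_id`, `length`, ...).
#' @param prophages prophage intervals on the taxon scaffolds
#'   (`scaffold_id`, `start`, `end`, `prophage_id`, optional `pac_offset`).
#' @param thresholds a [classify_thresholds()] list.
#' @param short_read_coverage optional per-base short-read coverage of the
#'   anchor scaffold, for coverage-wave detection.
#' @return a list of class `evidence_bundle`.
#' @export
build_evidence <- function(reads, peak, scaffolds, prophages = NULL,
                           thresholds = classify_thresholds(),
                           short_read_coverage = NULL) {
  th <- thresholds
  center <- peak$center
  length_cut <- th$length_cut_frac * center
  counted <- reads[reads$read_len >= length_cut, ]

  # anchor scaffold: the one carrying the most counted reads
  anchor_scaffold <- if (nrow(counted)) {
    names(sort(table(counted$scaffold_id), decreasing = TRUE))[1]
  } else NA_character_
  on_anchor <- counted[!is.na(anchor_scaffold) &
                         counted$scaffold_id %in% anchor_scaffold, ]

  pac <- NULL
  if (nrow(on_anchor) >= th$pac_min_starts) {
    pac <- infer_pac_site(on_anchor$span_start, window = th$pac_window,
                          step = th$pac_step,
                          min_mode_share = th$pac_min_share)
  }

  # candidate prophages on taxon scaffolds
  pp <- if (is.null(prophages)) NULL else
    prophages[prophages$scaffold_id %in% scaffolds$scaffold_id, ]
  matched <- NULL
  anchor_pp <- NULL
  if (!is.null(pp) && nrow(pp) > 0) {
    pp$pp_len <- pp$end - pp$start
    ratio <- pp$pp_len / center
    len_ok <- ratio >= th$prophage_match_range[1] &
      ratio <= th$prophage_match_range[2]
    pac_in <- if (!is.null(pac) && !is.na(anchor_scaffold)) {
      pp$scaffold_id == anchor_scaffold & pp$start <= pac$position &
        pac$position < pp$end
    } else rep(FALSE, nrow(pp))
    cand <- pp[len_ok | pac_in, ]
    if (nrow(cand) > 0) {
      matched <- cand[which.min(abs(cand$pp_len / center - 1)), ]
    }
    # locus counting falls back to the closest-by-length prophage even when
    # no prophage formally matches the peak
    anchor_pp <- if (!is.null(matched)) matched else
      pp[which.min(abs(pp$pp_len / center - 1)), ]
  }

  locus <- rep("outside", nrow(counted))
  chim_max_overrun <- NA_real_
  pac_pos <- NA_real_
  if (!is.null(anchor_pp)) {
    # pac anchor: inferred when available on the prophage scaffold,
    # otherwise the annotated pac offset
    pac_pos <- if (!is.null(pac) && identical(anchor_scaffold,
                                              anchor_pp$scaffold_id)) {
      pac$position
    } else {
      anchor_pp$start + (anchor_pp$pac_offset %||% 0)
    }
    on_pp_scaffold <- counted$scaffold_id == anchor_pp$scaffold_id
    if (any(on_pp_scaffold)) {
      locus[on_pp_scaffold] <- classify_read_locus(
        data.frame(start = counted$span_start[on_pp_scaffold],
                   end = counted$span_end[on_pp_scaffold]),
        anchor_pp$start, anchor_pp$end, pac = pac_pos, margin = th$margin)
    }
    chim <- locus == "chimeric"
    if (any(chim)) {
      chim_max_overrun <- max(
        pmax(counted$span_end[chim] - anchor_pp$end,
             anchor_pp$start - counted$span_start[chim]))
    }
  }
  n_within <- sum(locus == "within")
  n_outside <- sum(locus == "outside")
  n_chimeric <- sum(locus == "chimeric")

  periodicity <- 0
  if (!is.null(anchor_pp) && !is.na(pac_pos)) {
    out_starts <- counted$span_start[locus == "outside" &
                                       counted$scaffold_id == anchor_pp$scaffold_id]
    if (length(out_starts) >= th$min_periodicity_starts) {
      periodicity <- periodicity_score(out_starts, pac_pos, center,
                                       tol = th$periodicity_tol)
    }
  }

  # long-read coverage uniformity across the taxon's scaffold space
  covs <- unlist(lapply(seq_len(nrow(scaffolds)), function(i) {
    sc <- scaffolds[i, ]
    rr <- counted[counted$scaffold_id == sc$scaffold_id, ]
    window_coverage(rr$span_start, rr$span_end, sc$length,
                    window = th$coverage_window)
  }))
  cv <- if (length(covs) && mean(covs) > 0) sd(covs) / mean(covs) else Inf
  scaffold_space <- sum(scaffolds$length)

  wave <- NULL
  if (!is.null(short_read_coverage) && !is.null(anchor_pp)) {
    prof <- coverage_profile(short_read_coverage, boundary = anchor_pp$end,
                             window = th$coverage_window,
                             smooth_windows = th$smooth_windows)
    wave <- prof$wave
  }

  structure(list(
    peak = as_tibble(peak[, c("center", "rel_halfwidth", "n_members", "share")]),
    n_counted = nrow(counted),
    n_within = n_within, n_outside = n_outside, n_chimeric = n_chimeric,
    chim_max_overrun = chim_max_overrun,
    overlap_share = if (nrow(counted)) n_within / nrow(counted) else 0,
    pac = pac, pac_position = pac_pos,
    periodicity = periodicity,
    cv = cv, scaffold_space = scaffold_space,
    matched_prophage = matched,
    wave = wave,
    anchor_scaffold = anchor_scaffold
  ), class = "evidence_bundle")
}

empty_events <- function() {
  out <- tibble(taxon = character(), sample = character(),
                mode = character(), peak_center = double(),
                n_members = integer(), n_within = integer(),
                n_outside = integer(), n_chimeric = integer(),
                overlap_share = double(), periodicity = double(),
                cv = double(), pac_position = double(),
                matched_prophage = character(), prophage_length = double(),
                rule_trace = character())
  class(out) <- c("packaging_events", class(out))
  out
}

#' Classify a packaging event from its evidence bundle
#'
#' Applies the decision table, evaluated in order:
#'
#' 1. **LT** — matched prophage and (chimeric count >= 5, or periodicity
#'    score >= 0.3, or a coverage wave with period within 5% of the peak
#'    center);
#' 2. **induction** — prophage overlap share >= 0.8 and peak center within
#'    \[0.95, 1.10\] of the matched prophage length;
#' 3. **ST** — chimeric reads present but confined within one peak-length of
#'    the prophage boundary, with no periodicity and no wave;
#' 4. **GT** — coverage CV <= 0.5 over >= 200 kb of scaffold space, peak
#'    center >= 15 kb and prophage overlap share < 0.2;
#' 5. **GTA** — coverage CV <= 0.5, peak center < 15 kb and relative
#'    half-width <= 0.05;
#' 6. otherwise **ambiguous**.
#'
#' Every comparison is recorded in the rule trace. Peaks with fewer members
#' than `min_event_reads` yield no event (zero-row result).
#'
#' @param bundle an [build_evidence()] bundle.
#' @param thresholds a [classify_thresholds()] list.
#' @param taxon,sample identifiers copied into the result.
#' @return a `packaging_events` tibble with zero or one row.
#' @export
classify_event <- function(bundle, thresholds = classify_thresholds(),
                           taxon = NA_character_, sample = NA_character_) {
  th <- thresholds
  if (bundle$peak$n_members < th$min_event_reads) return(empty_events())

  trace <- character()
  note <- function(x) trace <<- c(trace, x)
  center <- bundle$peak$center
  has_match <- !is.null(bundle$matched_prophage)
  pp_len <- if (has_match) {
    bundle$matched_prophage$end - bundle$matched_prophage$start
  } else NA_real_

  wave_ok <- !is.null(bundle$wave) &&
    abs(bundle$wave$period - center) <= th$wave_period_tol * center
  note(sprintf("LT: matched_prophage=%s chimeric=%d(>=%d) periodicity=%.3f(>=%.2f) wave=%s",
               has_match, bundle$n_chimeric, th$lt_min_chimeric,
               bundle$periodicity, th$lt_min_periodicity, wave_ok))
  mode <- NULL
  if (has_match && (bundle$n_chimeric >= th$lt_min_chimeric ||
                    bundle$periodicity >= th$lt_min_periodicity || wave_ok)) {
    mode <- "LT"
  }

  if (is.null(mode)) {
    center_ratio <- if (has_match) center / pp_len else NA_real_
    note(sprintf("induction: overlap=%.3f(>=%.2f) center/prophage=%.3f(in [%.2f,%.2f])",
                 bundle$overlap_share, th$induction_min_overlap, center_ratio,
                 th$induction_center_range[1], th$induction_center_range[2]))
    if (has_match && bundle$overlap_share >= th$induction_min_overlap &&
        !is.na(center_ratio) &&
        center_ratio >= th$induction_center_range[1] &&
        center_ratio <= th$induction_center_range[2]) {
      mode <- "induction"
    }
  }

  if (is.null(mode)) {
    confined <- !is.na(bundle$chim_max_overrun) &&
      bundle$chim_max_overrun <= center
    note(sprintf("ST: chimeric=%d(>=1) confined=%s periodicity=%.3f(<%.2f) wave=%s",
                 bundle$n_chimeric, confined, bundle$periodicity,
                 th$lt_min_periodicity, !is.null(bundle$wave)))
    if (bundle$n_chimeric >= 1 && confined &&
        bundle$periodicity < th$lt_min_periodicity && is.null(bundle$wave)) {
      mode <- "ST"
    }
  }

  if (is.null(mode)) {
    note(sprintf("GT: cv=%.3f(<=%.2f) span=%d(>=%d) center=%.0f(>=%d) overlap=%.3f(<%.2f)",
                 bundle$cv, th$gt_max_cv, bundle$scaffold_space,
                 th$gt_min_span, center, th$gt_min_center,
                 bundle$overlap_share, th$gt_max_overlap))
    if (is.finite(bundle$cv) && bundle$cv <= th$gt_max_cv &&
        bundle$scaffold_space >= th$gt_min_span &&
        center >= th$gt_min_center &&
        bundle$overlap_share < th$gt_max_overlap) {
      mode <- "GT"
    }
  }

  if (is.null(mode)) {
    note(sprintf("GTA: cv=%.3f(<=%.2f) center=%.0f(<%d) halfwidth=%.3f(<=%.2f)",
                 bundle$cv, th$gt_max_cv, center, th$gta_max_center,
                 bundle$peak$rel_halfwidth, th$gta_max_halfwidth))
    if (is.finite(bundle$cv) && bundle$cv <= th$gt_max_cv &&
        center < th$gta_max_center &&
        bundle$peak$rel_halfwidth <= th$gta_max_halfwidth) {
      mode <- "GTA"
    }
  }

  if (is.null(mode)) mode <- "ambiguous"
  out <- tibble(
    taxon = taxon, sample = sample, mode = mode, peak_center = center,
    n_members = bundle$peak$n_members, n_within = bundle$n_within,
    n_outside = bundle$n_outside, n_chimeric = bundle$n_chimeric,
    overlap_share = bundle$overlap_share, periodicity = bundle$periodicity,
    cv = bundle$cv, pac_position = bundle$pac_position,
    matched_prophage = if (has_match) bundle$matched_prophage$prophage_id
      else NA_character_,
    prophage_length = pp_len,
    rule_trace = paste(trace, collapse = " | "))
  class(out) <- c("packaging_events", class(out))
  out
}

#' Call packaging events for every taxon in a sample
#'
#' Runs the full per-taxon pipeline: taxon rollup, read-length peak
#' detection, evidence assembly and the decision table — for bacterial
#' (non-viral, non-archaeal) taxa.
#'
#' @param alignments filtered alignment tibble.
#' @param scaffolds scaffold metadata tibble.
#' @param prophages prophage interval tibble or `NULL`.
#' @param thresholds a [classify_thresholds()] list.
#' @param sample sample label copied into the events.
#' @param peak_args list of overrides for [detect_peaks()]
#'   (bandwidth, prominence, max_rel_halfwidth).
#' @param min_reads_mag,min_reads_unbinned,min_reads_viral rare-entity
#'   thresholds forwarded to [rollup_taxa()].
#' @return a `packaging_events` tibble, one row per called event.
#' @export
call_events <- function(alignments, scaffolds, prophages = NULL,
                        thresholds = classify_thresholds(),
                        sample = NA_character_, peak_args = list(),
                        min_reads_mag = 50, min_reads_unbinned = 50,
                        min_reads_viral = 200) {
  assignments <- assign_reads(alignments)
  roll <- rollup_taxa(assignments, scaffolds, prophages,
                      min_reads_mag = min_reads_mag,
                      min_reads_unbinned = min_reads_unbinned,
                      min_reads_viral = min_reads_viral)
  roll <- roll[!roll$category %in% c("Viruses", "Archaea"), ]
  events <- list()
  scaffolds_tax <- scaffolds
  scaffolds_tax$taxon <- taxon_label(scaffolds)
  for (i in seq_len(nrow(roll))) {
    tx <- roll$taxon[i]
    sc <- scaffolds_tax[scaffolds_tax$taxon == tx, ]
    # alignment spans of this taxon's reads on their assigned scaffolds
    asg <- assignments[assignments$scaffold_id %in% roll$scaffold_ids[[i]], ]
    aln <- alignments[alignments$read_id %in% asg$read_id, ]
    aln <- aln |>
      dplyr::semi_join(asg, by = c("read_id", "scaffold_id"))
    reads <- aln |>
      group_by(.data$read_id, .data$scaffold_id) |>
      summarise(read_len = .data$read_len[1],
                span_start = min(.data$start), span_end = max(.data$end),
                .groups = "drop")
    peaks <- do.call(detect_peaks, c(
      list(lengths = roll$read_lengths[[i]],
           min_peak_reads = thresholds$min_event_reads), peak_args))
    for (j in seq_len(nrow(peaks))) {
      bundle <- build_evidence(reads, peaks[j, ], sc, prophages, thresholds)
      ev <- classify_event(bundle, thresholds, taxon = tx, sample = sample)
      events[[length(events) + 1]] <- ev
    }
  }
  out <- if (length(events)) bind_rows(events) else empty_events()
  class(out) <- unique(c("packaging_events", class(out)))
  out
}
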