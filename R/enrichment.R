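#' Relative abundance of scaffolds in one sample
#'
#' Abundance is the number of reads aligned to the scaffold divided by the
#' total number of quality-filtered reads in the sample.
#'
#' @param counts per-scaffold read counts.
#' @param total_reads total quality-filtered reads in the sample; must be at
#'   least `sum(counts)` and positive.
#' @return numeric vector of abundances in `[0, 1]`.
#' @examples
#' relative_abundance(c(10, 0, 5), 1000)
#' @export
relative_abundance <- function(counts, total_reads) {
  if (length(total_reads) != 1 || total_reads <= 0) {
    abort("`total_reads` must be a single positive count")
  }
  if (any(counts < 0) || sum(counts) > total_reads) {
    abort("counts must be non-negative and sum to at most `total_reads`")
  }
  counts / total_reads
}

#' VLP/total enrichment ratios and Z-scores
#'
#' For each scaffold the ratio of its relative abundance in a VLP fraction to
#' its relative abundance in the total community DNA is computed (zero counts
#' receive a pseudocount), standardised to a Z-score across scaffolds within
#' the sample pair, and flagged when more than two standard deviations above
#' the mean.
#'
#' @param counts tibble with columns `scaffold_id`, `vlp_count`,
#'   `total_count` (read counts in the VLP fraction and the total-community
#'   sample).
#' @param vlp_total,community_total total quality-filtered reads in each
#'   sample; default to the respective count sums.
#' @param pseudocount reads added to zero counts before forming the ratio
#'   (default 0.5).
#' @param log_ratio standardise `log(ratio)` instead of the raw ratio
#'   (default `FALSE`: raw ratios, which the [ks_normality()] diagnostic can
#'   show to deviate from normality in the upper tail).
#' @return an `enrichment_records` tibble: `scaffold_id`, `a_vlp`, `a_total`,
#'   `ratio`, `z`, `flagged`.
#' @examples
#' enrichment_z(tibble::tibble(scaffold_id = c("a", "b", "c"),
#'                             vlp_count = c(10, 50, 10),
#'                             total_count = c(10, 10, 10)))
#' @export
enrichment_z <- function(counts, vlp_total = NULL, community_total = NULL,
                         pseudocount = 0.5, log_ratio = FALSE) {
  counts <- as_tibble(counts)
  need <- c("scaffold_id", "vlp_count", "total_count")
  if (!all(need %in% names(counts))) {
    abort(sprintf("`counts` needs columns %s", paste(need, collapse = ", ")))
  }
  nz <- sum(counts$total_count > 0)
  if (nz < 3) abort("need at least 3 scaffolds with nonzero total-community counts")
  vlp_total <- vlp_total %||% sum(counts$vlp_count)
  community_total <- community_total %||% sum(counts$total_count)
  vc <- ifelse(counts$vlp_count == 0, pseudocount, counts$vlp_count)
  tc <- ifelse(counts$total_count == 0, pseudocount, counts$total_count)
  a_vlp <- vc / vlp_total
  a_total <- tc / community_total
  r <- a_vlp / a_total
  r_scale <- if (log_ratio) log(r) else r
  if (sd(r_scale) == 0) {
    # degenerate but well-defined: nothing deviates, nothing is flagged
    warn("all enrichment ratios are equal; all Z set to 0")
    z <- rep(0, length(r))
  } else {
    z <- (r_scale - mean(r_scale)) / sd(r_scale)
  }
  out <- tibble(scaffold_id = counts$scaffold_id,
                a_vlp = counts$vlp_count / vlp_total,
                a_total = counts$total_count / community_total,
                ratio = r, z = z, flagged = z > 2)
  class(out) <- c("enrichment_records", class(out))
  out
}

#' Kolmogorov-Smirnov diagnostic for enrichment-ratio normality
#'
#' One-sample KS test of the ratios against a normal distribution with
#' moment-fitted mean and standard deviation (a Lilliefors-style diagnostic:
#' because the reference is fitted, the asymptotic p-value is approximate and
#' intended as a diagnostic, not a calibrated test).
#'
#' @param ratios enrichment ratios (at least 8 values).
#' @return tibble with the KS `statistic` (D) and asymptotic `p_value`.
#' @export
ks_normality <- function(ratios) {
  if (length(ratios) < 8) abort("need at least 8 ratios")
  m <- mean(ratios); s <- sd(ratios)
  if (s == 0) abort("degenerate input: constant ratios")
  kt <- suppressWarnings(ks.test(ratios, "pnorm", mean = m, sd = s))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value)
}
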