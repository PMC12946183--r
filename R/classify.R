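#' Infer a packaging-initiation (pac) site from alignment starts
#'
#' Headful packaging anchors alignment starts at the pac site, so the pac
#' reveals itself as a strong mode of the start-position distribution. A
#' window of width `2 * window` slides along the start range in `step` bp
#' increments; the window containing the most starts gives the candidate
#' position (its center) and confidence (its share of all starts).
#'
#' @param starts alignment start positions (at least 20).
#' @param window half-width of the sliding window in bp (default 500).
#' @param step slide increment in bp (default 100).
#' @param min_mode_share minimum share of starts the best window must hold
#'   (default 0.2); below this `NULL` is returned (no credible pac).
#' @return `NULL`, or a list with `position` and `confidence`.
#' @examples
#' infer_pac_site(rep(1e6, 25))
#' @export
infer_pac_site <- function(starts, window = 500, step = 100,
                           min_mode_share = 0.2) {
  if (length(starts) < 20) abort("need at least 20 alignment starts")
  ss <- sort(starts)
  centers <- seq(ss[1], ss[length(ss)], by = step)
  hi <- findInterval(centers + window - 1e-9, ss)
  lo <- findInterval(centers - window - 1e-9, ss)
  cnt <- hi - lo
  best <- which.max(cnt)
  conf <- cnt[best] / length(ss)
  if (conf < min_mode_share) return(NULL)
  list(position = centers[best], confidence = conf)
}

#' Classify read loci relative to a prophage
#'
#' Each read span is classified as `within` the prophage (at least 95% of the
#' span inside the margin-extended prophage interval), `chimeric`
#' (pac-anchored and extending at least `margin` bp beyond the prophage
#' boundary — the lateral/specialised transduction hallmark), or `outside`.
#' `within` takes precedence: a read is only called chimeric when a material
#' fraction of it lies beyond the boundary.
#'
#' @param spans tibble/data frame with `start`, `end` (0-based half-open).
#' @param prophage_start,prophage_end prophage interval `[a, b)`.
#' @param pac pac position (same coordinates), or `NA` (disables the
#'   chimeric call).
#' @param margin boundary tolerance in bp (default 2000).
#' @return character vector (`"within"`, `"chimeric"`, `"outside"`).
#' @examples
#' classify_read_locus(data.frame(start = 1100, end = 55000),
#'                     1000, 56000, pac = 46000)
#' @export
classify_read_locus <- function(spans, prophage_start, prophage_end,
                                pac = NA, margin = 2000) {
  if (prophage_start >= prophage_end) abort("invalid prophage interval")
  a <- prophage_start; b <- prophage_end
  s <- spans$start; e <- spans$end
  len <- e - s
  ov <- pmax(0, pmin(e, b + margin) - pmax(s, a - margin))
  within <- ov >= 0.95 * len
  chim <- if (is.na(pac)) rep(FALSE, length(s)) else {
    (abs(s - pac) <= margin & e >= b + margin) |  # rightward packaging
      (abs(e - pac) <= margin & s <= a - margin)  # leftward packaging
  }
  ifelse(within, "within", ifelse(chim, "chimeric", "outside"))
}

#' Score the periodicity of alignment starts against a headful lattice
#'
#' Lateral transduction produces alignment starts at regular multiples of the
#' headful size from the prophage pac site. The score is the observed share
#' of starts within `tol * period` of a lattice point `pac + k * period`
#' (k >= 1), minus the share expected for uniform starts over the observed
#' span, clipped to `[0, 1]`. It is invariant under jointly shifting all
#' starts and the anchor.
#'
#' @param starts alignment start positions.
#' @param pac lattice anchor (pac position).
#' @param period lattice period in bp (the headful size).
#' @param tol relative tolerance (default 0.02).
#' @return a score in `[0, 1]`.
#' @examples
#' periodicity_score(c(58400, 116800, 175200), pac = 0, period = 58400)
#' @export
periodicity_score <- function(starts, pac, period, tol = 0.02) {
  if (period <= 0) abort("`period` must be positive")
  if (length(starts) == 0) return(0)
  k <- round((starts - pac) / period)
  dev <- abs(starts - (pac + k * period))
  hit <- k >= 1 & dev <= tol * period
  obs <- mean(hit)
  span <- diff(range(starts))
  expected <- if (span <= 2 * tol * period) 0 else {
    k_lo <- max(1, ceiling((min(starts) - pac) / period))
    k_hi <- floor((max(starts) - pac) / period)
    n_lattice <- max(0, k_hi - k_lo + 1)
    min(1, n_lattice * 2 * tol * period / span)
  }
  min(1, max(0, obs - expected))
}

#' Windowed coverage of alignment intervals
#'
#' Coverage is evaluated at window midpoints: the number of intervals
#' covering each midpoint.
#'
#' @param starts,ends interval coordinates (0-based half-open).
#' @param length scaffold length in bp.
#' @param window window size in bp (default 1000).
#' @return numeric vector of per-window coverage.
#' @keywords internal
window_coverage <- function(starts, ends, length, window = 1000) {
  mids <- seq(window / 2, length, by = window)
  s <- sort(starts); e <- sort(ends)
  findInterval(mids, s) - findInterval(mids, e)
}

#' Coverage uniformity and wave detection
#'
#' Summarises a coverage profile as the coefficient of variation of smoothed
#' windowed coverage, and searches downstream of a prophage boundary for a
#' periodic coverage wave (the short-read signature of lateral transduction
#' with post-packaging degradation): the dominant positive-lag
#' autocorrelation peak of the mean-removed smoothed profile, accepted only
#' above a Bonferroni-corrected 99% white-noise band. A `decay` flag is set
#' when successive wave crests are monotonically non-increasing.
#'
#' @param coverage per-base coverage vector (or per-window if
#'   `per_base = FALSE`).
#' @param boundary prophage boundary position (bp if `per_base`, window
#'   index otherwise), or `NULL` to skip wave detection.
#' @param window window size in bp (default 1000).
#' @param smooth_windows moving-average width in windows (default 5).
#' @param per_base is `coverage` per-base (default) or already per-window?
#' @return list with `cv` and `wave` (`NULL`, or a list with `period` in bp,
#'   `acf_peak`, `decay`).
#' @export
coverage_profile <- function(coverage, boundary = NULL, window = 1000,
                             smooth_windows = 5, per_base = TRUE) {
  if (all(coverage == 0)) abort("all-zero coverage")
  if (per_base) {
    idx <- (seq_along(coverage) - 1) %/% window
    win_cov <- as.numeric(tapply(coverage, idx, mean))
    b_win <- if (is.null(boundary)) NULL else floor(boundary / window) + 1
  } else {
    win_cov <- as.numeric(coverage)
    b_win <- boundary
  }
  if (length(win_cov) < 5) abort("coverage must span at least 5 windows")
  k <- min(smooth_windows, length(win_cov))
  sm <- as.numeric(stats::filter(win_cov, rep(1 / k, k), sides = 2))
  sm <- sm[!is.na(sm)]
  cv <- sd(sm) / mean(sm)

  wave <- NULL
  if (!is.null(b_win)) {
    down <- win_cov[seq_along(win_cov) >= b_win]
    if (length(down) >= 10) {
      z <- down - mean(down)
      lag_max <- floor(length(down) / 2)
      ac <- acf(z, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[-1]
      n <- length(down)
      band <- qnorm(1 - 0.005 / lag_max) / sqrt(n)
      loc_max <- which(ac > c(-Inf, ac[-length(ac)]) & ac >= c(ac[-1], -Inf))
      loc_max <- loc_max[loc_max >= 2]
      cand <- loc_max[ac[loc_max] > band]
      if (length(cand)) {
        lag <- cand[which.max(ac[cand])]
        # crest decay: successive local maxima of the smoothed downstream
        # profile, at least half a period apart, non-increasing in height
        smd <- as.numeric(stats::filter(down, rep(1 / k, k), sides = 2))
        smd <- smd[!is.na(smd)]
        cr <- which(smd > c(-Inf, smd[-length(smd)]) & smd >= c(smd[-1], -Inf))
        if (length(cr) > 1) {
          sep <- c(TRUE, diff(cr) >= lag / 2)
          cr <- cr[sep]
        }
        decay <- length(cr) >= 2 && all(diff(smd[cr]) <= 1e-9)
        wave <- list(period = lag * window, acf_peak = ac[lag], decay = decay)
      }
    }
  }
  list(cv = cv, wave = wave)
}
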