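#' @export
print.length_peaks <- function(x, ...) {
  cat(sprintf("<length_peaks> %d peak(s) from %s reads\n",
              nrow(x), attr(x, "n_input") %||% "?"))
  NextMethod()
}

#' Tidy a peak table (drops the member list-column)
#' @param x a `length_peaks` object.
#' @param ... unused.
#' @export
tidy.length_peaks <- function(x, ...) {
  as_tibble(x)[, c("peak_id", "center", "rel_halfwidth", "n_members", "share")]
}

#' One-row summary of a peak table
#' @param x a `length_peaks` object.
#' @param ... unused.
#' @export
glance.length_peaks <- function(x, ...) {
  tibble(n_peaks = nrow(x),
         n_reads = attr(x, "n_input") %||% NA_integer_,
         peak_read_share = sum(x$share),
         main_center = if (nrow(x)) x$center[1] else NA_real_)
}

#' Plot a read-length distribution with its detected peaks
#'
#' Log10-scaled histogram of the read lengths with the detected peak centers
#' marked; the standard first look at an encapsidated DNA sample.
#'
#' @param object a `length_peaks` result.
#' @param lengths the read lengths the peaks were detected on.
#' @param bin_width histogram bin width in log10 units (default 0.02).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.length_peaks <- function(object, lengths, bin_width = 0.02, ...) {
  df <- tibble(length = lengths)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = bin_width, fill = "grey65") +
    ggplot2::scale_x_log10(labels = function(x) paste0(x / 1000, " kb")) +
    ggplot2::labs(x = "read length", y = "reads") +
    ggplot2::theme_minimal()
  if (nrow(object)) {
    p <- p + ggplot2::geom_vline(xintercept = object$center,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @export
print.packaging_events <- function(x, ...) {
  cat(sprintf("<packaging_events> %d event(s)\n", nrow(x)))
  NextMethod()
}

#' Tidy an event table (drops the rule trace)
#' @param x a `packaging_events` object.
#' @param ... unused.
#' @export
tidy.packaging_events <- function(x, ...) {
  as_tibble(x)[, setdiff(names(x), "rule_trace")]
}

#' Event counts by packaging mode
#' @param x a `packaging_events` object.
#' @param ... unused.
#' @export
glance.packaging_events <- function(x, ...) {
  modes <- c("induction", "GT", "ST", "LT", "GTA", "ambiguous")
  counts <- table(factor(x$mode, levels = modes))
  out <- as_tibble(as.list(counts))
  out$n_events <- nrow(x)
  out[, c("n_events", modes)]
}

#' Plot called packaging events by mode and peak size
#' @param object a `packaging_events` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.packaging_events <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$peak_center, y = .data$mode,
                               size = .data$n_members)) +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::scale_x_log10(labels = function(x) paste0(x / 1000, " kb")) +
    ggplot2::labs(x = "peak center", y = "packaging mode",
                  size = "member reads") +
    ggplot2::theme_minimal()
}

#' Tidy enrichment records
#' @param x an `enrichment_records` object.
#' @param ... unused.
#' @export
tidy.enrichment_records <- function(x, ...) as_tibble(x)

#' One-row summary of an enrichment analysis
#' @param x an `enrichment_records` object.
#' @param ... unused.
#' @export
glance.enrichment_records <- function(x, ...) {
  ks <- if (nrow(x) >= 8 && sd(x$ratio) > 0) ks_normality(x$ratio) else
    tibble(statistic = NA_real_, p_value = NA_real_)
  tibble(n_scaffolds = nrow(x), n_flagged = sum(x$flagged),
         flag_rate = mean(x$flagged),
         ks_statistic = ks$statistic, ks_p_value = ks$p_value)
}

#' Plot VLP/total enrichment ratios with flagged scaffolds highlighted
#' @param object an `enrichment_records` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.enrichment_records <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$a_total, y = .data$ratio,
                               colour = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "total-community abundance", y = "VLP/total ratio",
                  colour = "> 2 SD") +
    ggplot2::theme_minimal()
}
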