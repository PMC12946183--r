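#' Derive a deterministic sub-seed for a named simulation component
#'
#' All randomness in the simulator flows from one master seed. Each component
#' (per-mechanism particle draws, degradation, contamination, sequence
#' emission, ...) uses an independent substream whose seed is a stable
#' polynomial hash of the component name folded into the master seed, so that
#' adding a component never perturbs the draws of another.
#'
#' @param seed master seed (single non-negative integer).
#' @param component character scalar naming the consuming component.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
component_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(component) == 1)
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double arithmetic
  h <- seed %% m
  for (code in utf8ToInt(as.character(component))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a local, component-specific RNG state
#' @keywords internal
with_component_seed <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(component_seed(seed, component))
  expr
}

#' Assert a scalar numeric lies in a closed range
#' @keywords internal
check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi))
  }
  invisible(x)
}

#' @keywords internal
check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %g", name, min))
  }
  invisible(x)
}
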