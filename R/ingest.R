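#' Read long-read alignments from PAF or interval TSV
#'
#' Both dialects are normalised to the same tibble of 0-based half-open
#' target intervals. PAF parsing uses the 12 mandatory columns (target
#' coordinates); the interval TSV is the escape hatch for precomputed
#' BED-like alignment tables with columns `read_id`, `read_len`,
#' `scaffold_id`, `start`, `end`, `strand`, `aln_len`.
#'
#' @param path file to read.
#' @param dialect `"paf"` or `"tsv"`.
#' @return alignment tibble (`read_id`, `read_len`, `scaffold_id`, `start`,
#'   `end`, `strand`, `aln_len`).
#' @export
read_alignments <- function(path, dialect = c("paf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  empty <- tibble(read_id = character(), read_len = double(),
                  scaffold_id = character(), start = double(),
                  end = double(), strand = character(), aln_len = double())
  if (dialect == "paf") {
    raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    if (nrow(raw) == 0) return(empty)
    if (ncol(raw) < 12) abort("PAF requires at least 12 columns")
    num <- function(col, what) {
      x <- suppressWarnings(as.numeric(raw[[col]]))
      if (anyNA(x)) {
        abort(sprintf("unparseable %s in PAF line %d", what, which(is.na(x))[1]))
      }
      x
    }
    out <- tibble(
      read_id = raw[[1]], read_len = num(2, "read length"),
      scaffold_id = raw[[6]], start = num(8, "target start"),
      end = num(9, "target end"), strand = raw[[5]],
      aln_len = num(9, "target end") - num(8, "target start"))
  } else {
    out <- readr::read_tsv(path, col_types = readr::cols(
      read_id = readr::col_character(), read_len = readr::col_double(),
      scaffold_id = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), strand = readr::col_character(),
      aln_len = readr::col_double()), progress = FALSE)
    if (nrow(out) == 0) return(empty)
    missing <- setdiff(names(empty), names(out))
    if (length(missing)) {
      abort(sprintf("interval TSV lacks column(s): %s",
                    paste(missing, collapse = ", ")))
    }
    out <- out[, names(empty)]
  }
  bad <- which(out$start < 0 | out$end <= out$start)
  if (length(bad)) abort(sprintf("invalid interval on line %d", bad[1]))
  out
}

#' Read scaffold metadata TSV
#'
#' @param path TSV with columns `scaffold_id`, `length`, `bin_id`, `domain`,
#'   `taxonomy`, `is_viral`.
#' @return scaffold tibble.
#' @export
read_scaffold_metadata <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    scaffold_id = readr::col_character(), length = readr::col_double(),
    bin_id = readr::col_character(), domain = readr::col_character(),
    taxonomy = readr::col_character(), is_viral = readr::col_logical()),
    progress = FALSE)
}

#' Read prophage intervals from BED
#'
#' 0-based half-open intervals; the BED score column, when present, carries
#' the pac offset within the prophage (the convention used by
#' [write_simulation()]).
#'
#' @param path BED file.
#' @return tibble with `scaffold_id`, `start`, `end`, `prophage_id`,
#'   `pac_offset`.
#' @export
read_prophage_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(bed) == 0) {
    return(tibble(scaffold_id = character(), start = double(), end = double(),
                  prophage_id = character(), pac_offset = double()))
  }
  tibble(scaffold_id = bed[[1]],
         start = as.numeric(bed[[2]]),
         end = as.numeric(bed[[3]]),
         prophage_id = if (ncol(bed) >= 4) bed[[4]] else
           paste0("pp", seq_len(nrow(bed))),
         pac_offset = if (ncol(bed) >= 5)
           suppressWarnings(as.numeric(bed[[5]])) %||% 0 else 0)
}

#' Filter alignments on read length and alignment length
#'
#' Retains rows with read length at or above `min_read_len` (default 3 kb)
#' and aligned length at or above `min_aln_len` (default 1 kb); row order is
#' preserved and the operation is idempotent.
#'
#' @param alignments alignment tibble.
#' @param min_read_len minimum read length in bp (default 3000).
#' @param min_aln_len minimum alignment length in bp (default 1000).
#' @return the filtered alignment tibble.
#' @export
filter_alignments <- function(alignments, min_read_len = 3000,
                              min_aln_len = 1000) {
  if (min_read_len < 0 || min_aln_len < 0) abort("thresholds must be >= 0")
  alignments[alignments$read_len >= min_read_len &
               alignments$aln_len >= min_aln_len, ]
}

#' Assign each read to its best-supported scaffold
#'
#' A read with alignments to several scaffolds is assigned to the scaffold
#' with the greatest sum of alignment lengths for that read; ties break to
#' the lexicographically smallest scaffold id, so assignment is
#' deterministic.
#'
#' @param alignments filtered alignment tibble.
#' @return assignment tibble with one row per read (`read_id`, `read_len`,
#'   `scaffold_id`, `aln_sum`).
#' @export
assign_reads <- function(alignments) {
  if (nrow(alignments) == 0) {
    return(tibble(read_id = character(), read_len = double(),
                  scaffold_id = character(), aln_sum = double()))
  }
  alignments |>
    group_by(.data$read_id, .data$scaffold_id) |>
    summarise(read_len = .data$read_len[1],
              aln_sum = sum(.data$aln_len), .groups = "drop") |>
    arrange(.data$read_id, dplyr::desc(.data$aln_sum), .data$scaffold_id) |>
    group_by(.data$read_id) |>
    slice(1) |>
    ungroup() |>
    select("read_id", "read_len", "scaffold_id", "aln_sum")
}

#' Assign each scaffold to one of six broad categories
#'
#' The categories cross the scaffold's domain, MAG membership and presence
#' of viral (prophage) fragments: `Viruses`, `MAG bacteria`, `MAG bacteria
#' with prophages`, `Bacteria unbinned`, `Bacteria with prophages` and
#' `Archaea` (binned or unbinned).
#'
#' @param scaffolds scaffold metadata tibble.
#' @param prophages prophage interval tibble (viral fragments on host
#'   scaffolds), or `NULL`.
#' @return the scaffold tibble with a `category` column.
#' @export
categorize_scaffolds <- function(scaffolds, prophages = NULL) {
  if (!"domain" %in% names(scaffolds) || anyNA(scaffolds$domain)) {
    abort("scaffold metadata must carry a `domain` for every scaffold")
  }
  has_pp <- if (is.null(prophages) || nrow(prophages) == 0) {
    rep(FALSE, nrow(scaffolds))
  } else {
    scaffolds$scaffold_id %in% prophages$scaffold_id
  }
  binned <- !is.na(scaffolds$bin_id)
  scaffolds$category <- case_when(
    scaffolds$is_viral | scaffolds$domain == "virus" ~ "Viruses",
    scaffolds$domain == "archaea" ~ "Archaea",
    binned & has_pp ~ "MAG bacteria with prophages",
    binned ~ "MAG bacteria",
    has_pp ~ "Bacteria with prophages",
    TRUE ~ "Bacteria unbinned"
  )
  scaffolds
}

taxon_label <- function(scaffolds) {
  lowest_rank <- vapply(scaffolds$taxonomy, function(t) {
    if (is.na(t) || !nzchar(t)) return(NA_character_)
    parts <- trimws(strsplit(t, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts) & !grepl("^[a-z]__$", parts)]
    if (length(parts)) parts[length(parts)] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  dplyr::coalesce(scaffolds$bin_id, lowest_rank, scaffolds$scaffold_id)
}

#' Roll assigned reads up to taxon units
#'
#' Taxon labels fall back from MAG bin id to the lowest non-empty taxonomy
#' rank to the scaffold id. Rare entities are dropped: taxa at or below the
#' per-category read minimum (<= 50 reads per MAG or unbinned bacterial
#' scaffold, <= 200 per viral scaffold) are removed.
#'
#' @param assignments output of [assign_reads()].
#' @param scaffolds scaffold metadata (with `category`, see
#'   [categorize_scaffolds()]; computed on the fly if absent).
#' @param prophages prophage intervals (used only if categories must be
#'   computed).
#' @param min_reads_mag,min_reads_unbinned,min_reads_viral rare-entity
#'   thresholds (reads <= threshold are dropped).
#' @return tibble with one row per retained taxon: `taxon`, `category`,
#'   `n_reads`, and list-columns `read_lengths`, `scaffold_ids`.
#' @export
rollup_taxa <- function(assignments, scaffolds, prophages = NULL,
                        min_reads_mag = 50, min_reads_unbinned = 50,
                        min_reads_viral = 200) {
  if (!"category" %in% names(scaffolds)) {
    scaffolds <- categorize_scaffolds(scaffolds, prophages)
  }
  empty <- tibble(taxon = character(), category = character(),
                  n_reads = integer(), read_lengths = list(),
                  scaffold_ids = list())
  if (nrow(assignments) == 0) return(empty)
  unknown <- setdiff(assignments$scaffold_id, scaffolds$scaffold_id)
  if (length(unknown)) {
    abort(sprintf("assignments reference unknown scaffold `%s`", unknown[1]))
  }
  scaffolds$taxon <- taxon_label(scaffolds)
  joined <- assignments |>
    left_join(scaffolds[, c("scaffold_id", "taxon", "category")],
              by = "scaffold_id")
  roll <- joined |>
    group_by(.data$taxon) |>
    summarise(category = .data$category[1],
              n_reads = dplyr::n(),
              read_lengths = list(.data$read_len),
              scaffold_ids = list(sort(unique(.data$scaffold_id))),
              .groups = "drop")
  min_for <- ifelse(roll$category == "Viruses", min_reads_viral,
                    ifelse(grepl("^MAG", roll$category), min_reads_mag,
                           min_reads_unbinned))
  roll[roll$n_reads > min_for, ]
}
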