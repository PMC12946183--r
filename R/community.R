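#' Specify a synthetic microbial community
#'
#' A community specification is the blueprint the simulator works from: a set
#' of genomes (bacterial chromosomes, archaea, free phage genomes), the
#' prophages integrated into them, and an optional scaffolding rule that
#' splits each genome into the metagenomic scaffolds the analysis stages see.
#'
#' @param genomes data frame with one row per genome. Required columns:
#'   `genome_id`, `length` (bp). Optional: `circular` (logical, default
#'   `FALSE`), `taxon` (taxonomy label, default the genome id), `bin_id`
#'   (MAG bin, default `NA` = unbinned), `domain` (`"bacteria"`, `"archaea"`
#'   or `"virus"`, default `"bacteria"`).
#' @param prophages data frame of integrated prophages, or `NULL`. Columns:
#'   `genome_id`, `start`, `end` (0-based half-open genome coordinates),
#'   `prophage_id`, `pac_offset` (packaging-initiation site, bp from the
#'   prophage start; default 0).
#' @param breakpoints data frame with columns `genome_id`, `pos` giving
#'   scaffold breakpoints within each genome, or `NULL` (one scaffold per
#'   genome). Breakpoints must partition `[0, length)`.
#' @param seed master seed for all randomness derived from this community.
#'
#' @return an object of class `community_spec`.
#' @examples
#' spec <- community_spec(
#'   genomes   = data.frame(genome_id = "chr1", length = 4e6),
#'   prophages = data.frame(genome_id = "chr1", start = 1e6, end = 1056900,
#'                          prophage_id = "pp1", pac_offset = 46900)
#' )
#' @export
community_spec <- function(genomes, prophages = NULL, breakpoints = NULL,
                           seed = 1L) {
  genomes <- as_tibble(genomes)
  if (!all(c("genome_id", "length") %in% names(genomes))) {
    abort("`genomes` needs columns `genome_id` and `length`")
  }
  genomes$genome_id <- as.character(genomes$genome_id)
  if (anyDuplicated(genomes$genome_id)) abort("duplicate `genome_id`")
  if (any(genomes$length <= 0)) abort("genome lengths must be positive")
  if (!"circular" %in% names(genomes)) genomes$circular <- FALSE
  if (!"taxon" %in% names(genomes)) genomes$taxon <- genomes$genome_id
  if (!"bin_id" %in% names(genomes)) genomes$bin_id <- NA_character_
  if (!"domain" %in% names(genomes)) genomes$domain <- "bacteria"
  bad_dom <- setdiff(unique(genomes$domain), c("bacteria", "archaea", "virus"))
  if (length(bad_dom)) abort(sprintf("unknown domain: %s", bad_dom[1]))

  if (is.null(prophages)) {
    prophages <- tibble(genome_id = character(), start = double(),
                        end = double(), prophage_id = character(),
                        pac_offset = double())
  } else {
    prophages <- as_tibble(prophages)
    if (!"pac_offset" %in% names(prophages)) prophages$pac_offset <- 0
    if (!"prophage_id" %in% names(prophages)) {
      prophages$prophage_id <- paste0("pp", seq_len(nrow(prophages)))
    }
    prophages$genome_id <- as.character(prophages$genome_id)
    for (i in seq_len(nrow(prophages))) {
      pp <- prophages[i, ]
      g <- genomes[genomes$genome_id == pp$genome_id, ]
      if (nrow(g) == 0) {
        abort(sprintf("prophage `%s` references unknown genome `%s`",
                      pp$prophage_id, pp$genome_id))
      }
      if (pp$start < 0 || pp$end > g$length || pp$start >= pp$end) {
        abort(sprintf("prophage `%s` interval [%g, %g) outside genome `%s`",
                      pp$prophage_id, pp$start, pp$end, pp$genome_id))
      }
      if (pp$pac_offset < 0 || pp$pac_offset >= pp$end - pp$start) {
        abort(sprintf("prophage `%s`: pac offset %g outside prophage interval",
                      pp$prophage_id, pp$pac_offset))
      }
    }
    # prophages within one genome must not overlap
    by_g <- split(prophages, prophages$genome_id)
    for (pp in by_g) {
      pp <- pp[order(pp$start), ]
      if (nrow(pp) > 1 && any(pp$start[-1] < pp$end[-nrow(pp)])) {
        j <- which(pp$start[-1] < pp$end[-nrow(pp)])[1] + 1
        abort(sprintf("prophages `%s` and `%s` overlap on genome `%s`",
                      pp$prophage_id[j - 1], pp$prophage_id[j],
                      pp$genome_id[1]))
      }
    }
  }

  if (!is.null(breakpoints)) {
    breakpoints <- as_tibble(breakpoints)
    if (!all(c("genome_id", "pos") %in% names(breakpoints))) {
      abort("`breakpoints` needs columns `genome_id` and `pos`")
    }
    breakpoints$genome_id <- as.character(breakpoints$genome_id)
    for (gid in unique(breakpoints$genome_id)) {
      g <- genomes[genomes$genome_id == gid, ]
      if (nrow(g) == 0) abort(sprintf("breakpoints reference unknown genome `%s`", gid))
      pos <- breakpoints$pos[breakpoints$genome_id == gid]
      if (any(pos <= 0 | pos >= g$length) || anyDuplicated(pos)) {
        abort(sprintf("breakpoints for `%s` must be distinct and inside (0, length)", gid))
      }
    }
  } else {
    breakpoints <- tibble(genome_id = character(), pos = double())
  }

  structure(
    list(genomes = genomes, prophages = prophages,
         breakpoints = breakpoints, seed = as.integer(seed)),
    class = "community_spec"
  )
}

#' Materialise a synthetic community from its specification
#'
#' Generates the scaffold metadata table, prophage interval table and
#' (optionally) i.i.d. uniform ACGT genome sequences for a community
#' specification. The same seed always yields byte-identical sequences and
#' tables.
#'
#' @param spec a [community_spec()].
#' @param sequences emit genome sequences? The analysis stages consume
#'   alignment intervals, so interval-only communities (`sequences = FALSE`)
#'   are sufficient (and much cheaper) for most uses.
#' @return an object of class `community`: a list with `genomes` (the spec
#'   table), `scaffolds` (scaffold metadata in the ingest dialect:
#'   `scaffold_id`, `length`, `bin_id`, `domain`, `taxonomy`, `is_viral`,
#'   plus `genome_id` and `offset` linking back to the source genome),
#'   `prophages` (scaffold-coordinate prophage intervals with `pac_offset`),
#'   and `sequences` (named character vector or `NULL`).
#' @examples
#' cm <- generate_community(community_spec(
#'   data.frame(genome_id = "g1", length = 1e5)), sequences = FALSE)
#' cm$scaffolds
#' @export
generate_community <- function(spec, sequences = TRUE) {
  if (!inherits(spec, "community_spec")) abort("`spec` must be a community_spec")
  genomes <- spec$genomes

  scaff <- purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    g <- genomes[i, ]
    bp <- sort(spec$breakpoints$pos[spec$breakpoints$genome_id == g$genome_id])
    edges <- c(0, bp, g$length)
    k <- length(edges) - 1
    tibble(
      scaffold_id = if (k == 1) g$genome_id else
        sprintf("%s_s%02d", g$genome_id, seq_len(k)),
      genome_id = g$genome_id,
      offset = edges[-length(edges)],
      length = diff(edges),
      bin_id = g$bin_id,
      domain = g$domain,
      taxonomy = g$taxon,
      is_viral = g$domain == "virus"
    )
  })

  pph <- spec$prophages
  pro <- purrr::map_dfr(seq_len(nrow(pph)), function(i) {
    pp <- pph[i, ]
    sc <- scaff[scaff$genome_id == pp$genome_id, ]
    hit <- sc[pp$start >= sc$offset & pp$end <= sc$offset + sc$length, ]
    if (nrow(hit) == 0) {
      abort(sprintf("prophage `%s` spans a scaffold breakpoint", pp$prophage_id))
    }
    tibble(scaffold_id = hit$scaffold_id[1],
           start = pp$start - hit$offset[1],
           end = pp$end - hit$offset[1],
           prophage_id = pp$prophage_id,
           pac_offset = pp$pac_offset,
           genome_id = pp$genome_id)
  })
  if (nrow(pph) == 0) {
    pro <- tibble(scaffold_id = character(), start = double(), end = double(),
                  prophage_id = character(), pac_offset = double(),
                  genome_id = character())
  }

  seqs <- NULL
  if (isTRUE(sequences)) {
    seqs <- vapply(seq_len(nrow(genomes)), function(i) {
      g <- genomes[i, ]
      with_component_seed(spec$seed, paste0("sequence:", g$genome_id), {
        paste(sample(c("A", "C", "G", "T"), g$length, replace = TRUE),
              collapse = "")
      })
    }, character(1))
    names(seqs) <- genomes$genome_id
  }

  structure(
    list(genomes = genomes, scaffolds = scaff, prophages = pro,
         sequences = seqs, seed = spec$seed),
    class = "community"
  )
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("<community> %d genome(s), %d scaffold(s), %d prophage(s)%s\n",
              nrow(x$genomes), nrow(x$scaffolds), nrow(x$prophages),
              if (is.null(x$sequences)) " [intervals only]" else ""))
  invisible(x)
}

#' Map a genome interval onto scaffold coordinates
#'
#' Splits a (possibly origin-wrapping) genome interval into one interval per
#' scaffold it touches. Wrapping intervals on circular genomes use the
#' doubled-coordinate convention (`end` may exceed the genome length).
#'
#' @param community a [generate_community()] result.
#' @param genome_id genome identifier.
#' @param start,end 0-based half-open genome coordinates; `end` may exceed
#'   the genome length for a wrapping fragment on a circular genome.
#' @return tibble with `scaffold_id`, `start`, `end` (scaffold coordinates).
#' @keywords internal
map_interval_to_scaffolds <- function(community, genome_id, start, end) {
  g <- community$genomes[community$genomes$genome_id == genome_id, ]
  L <- g$length
  pieces <- if (end > L) {
    if (!g$circular && end > L) {
      # linear genome: clip at the end
      list(c(start, min(end, L)))
    } else {
      list(c(start, L), c(0, end - L))
    }
  } else {
    list(c(start, end))
  }
  sc <- community$scaffolds[community$scaffolds$genome_id == genome_id, ]
  out <- purrr::map_dfr(pieces, function(p) {
    hit <- sc[p[1] < sc$offset + sc$length & p[2] > sc$offset, ]
    tibble(scaffold_id = hit$scaffold_id,
           start = pmax(p[1], hit$offset) - hit$offset,
           end = pmin(p[2], hit$offset + hit$length) - hit$offset)
  })
  out[out$end > out$start, ]
}
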