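#' Packaging-mechanism parameters
#'
#' Describes how a capsid fills with DNA. The headful family (`headful`,
#' `GT`, `ST`, `LT`, `GTA`) packages `capacity` bp (with a relative length
#' jitter `imprecision`), starting at a pac site and, for series mechanisms,
#' continuing processively for up to `series_length` headfuls. `cos`
#' packaging emits exact unit-genome molecules; `mu` appends a small amount
#' of host DNA to the phage genome.
#'
#' @param mechanism one of `"cos"`, `"headful"`, `"mu"`, `"GT"`, `"ST"`,
#'   `"LT"`, `"GTA"`.
#' @param capacity headful/capsid DNA capacity in bp. When `NULL` it defaults
#'   to `(1 + redundancy)` times the unit genome (the phage genome, or the
#'   prophage interval for integrated contexts). Required for `GTA`.
#' @param redundancy terminal redundancy as a fraction of the unit genome
#'   (headful phages package 2-10% more than one genome; default 0.04).
#' @param imprecision relative packaged-length jitter (default 0.02,
#'   i.e. +/-2%).
#' @param pac packaging-initiation position in bp. For free genomes this is a
#'   genome coordinate (default 0); for integrated prophages the prophage's
#'   own `pac_offset` is used.
#' @param transducing_fraction fraction of particles carrying host DNA
#'   (generalised/specialised transduction context; default 0.05).
#' @param series_length maximum number of headfuls per packaging initiation.
#'   Defaults to 25 for `headful`/`GT` (about `1/redundancy`, so circular
#'   permutation covers the genome) and 5 for `LT`.
#' @param mu_host_range two-element numeric: min and max bp of host DNA
#'   packaged alongside the Mu genome (default `c(500, 3000)`).
#' @param gt_n_pacs number of pseudo-pac sites seeded on the host chromosome
#'   in `GT` mode (default 50).
#' @param direction `"right"` or `"left"`: direction lateral transduction
#'   proceeds from the prophage pac site (default `"right"`).
#'
#' @return an object of class `mechanism_params`.
#' @examples
#' mechanism_params("headful", redundancy = 0.041)
#' mechanism_params("GTA", capacity = 13400)
#' @export
mechanism_params <- function(mechanism = c("cos", "headful", "mu", "GT", "ST",
                                           "LT", "GTA"),
                             capacity = NULL, redundancy = 0.04,
                             imprecision = 0.02, pac = NULL,
                             transducing_fraction = 0.05,
                             series_length = NULL,
                             mu_host_range = c(500, 3000),
                             gt_n_pacs = 50,
                             direction = c("right", "left")) {
  mechanism <- match.arg(mechanism)
  direction <- match.arg(direction)
  if (!is.null(capacity)) {
    if (!is.numeric(capacity) || length(capacity) != 1 || capacity <= 0) {
      abort("`capacity` must be a single positive number")
    }
  }
  check_fraction(redundancy, "redundancy", 0, 0.10)
  check_fraction(imprecision, "imprecision", 0, 0.05)
  check_fraction(transducing_fraction, "transducing_fraction", 0, 1)
  if (length(mu_host_range) != 2 || mu_host_range[1] > mu_host_range[2] ||
      any(mu_host_range < 0)) {
    abort("`mu_host_range` must be c(min, max) with 0 <= min <= max")
  }
  if (is.null(series_length)) {
    series_length <- if (mechanism == "LT") 5L else 25L
  }
  check_count(series_length, "series_length", min = 1)
  check_count(gt_n_pacs, "gt_n_pacs", min = 1)
  structure(
    list(mechanism = mechanism, capacity = capacity, redundancy = redundancy,
         imprecision = imprecision, pac = pac,
         transducing_fraction = transducing_fraction,
         series_length = as.integer(series_length),
         mu_host_range = as.numeric(mu_host_range),
         gt_n_pacs = as.integer(gt_n_pacs), direction = direction),
    class = "mechanism_params"
  )
}

empty_truth <- function() {
  tibble(read_id = character(), mechanism = character(),
         genome_id = character(), circle = character(),
         start = double(), end = double(), length = double(),
         full_length = double(), series_k = integer(),
         chimeric = logical(), degraded = logical(), contaminant = logical())
}

truth_row <- function(read_id, mechanism, genome_id, circle, start, end,
                      length, series_k = NA_integer_, chimeric = FALSE) {
  tibble(read_id = read_id, mechanism = mechanism, genome_id = genome_id,
         circle = circle, start = start, end = end, length = length,
         full_length = length, series_k = as.integer(series_k),
         chimeric = chimeric, degraded = FALSE, contaminant = FALSE)
}

resolve_unit <- function(community, params, genome_id, prophage_id) {
  genomes <- community$genomes
  if (is.null(genome_id)) {
    non_virus <- genomes$genome_id[genomes$domain != "virus"]
    genome_id <- if (length(non_virus)) non_virus[1] else genomes$genome_id[1]
  }
  g <- genomes[genomes$genome_id == genome_id, ]
  if (nrow(g) == 0) abort(sprintf("unknown genome `%s`", genome_id))
  pp <- NULL
  spec_pp <- community$prophages[community$prophages$genome_id == genome_id, ]
  if (!is.null(prophage_id)) {
    pp <- spec_pp[spec_pp$prophage_id == prophage_id, ]
    if (nrow(pp) == 0) {
      abort(sprintf("genome `%s` has no prophage `%s`", genome_id, prophage_id))
    }
  } else if (nrow(spec_pp) > 0) {
    pp <- spec_pp[1, ]
  }
  # prophage coordinates are stored per scaffold; convert back to the genome
  if (!is.null(pp) && nrow(pp) > 0) {
    off <- community$scaffolds$offset[
      community$scaffolds$scaffold_id == pp$scaffold_id]
    pp$g_start <- pp$start + off
    pp$g_end <- pp$end + off
  } else {
    pp <- NULL
  }
  list(genome = g, prophage = pp)
}

jitter_u <- function(n, eps) if (eps > 0) runif(n, -eps, eps) else rep(0, n)

#' Simulate capsid-packaged DNA particles
#'
#' Draws `n_particles` encapsidated DNA molecules from a community under one
#' packaging mechanism and returns their ground truth as a tibble (one row
#' per read). Lengths, start positions and series structure follow the
#' mechanism model:
#'
#' * `cos` — every molecule is the exact unit genome (or exact excised
#'   prophage for an integrated phage).
#' * `headful` — lengths `capacity * (1 + delta)` with `|delta| <=
#'   imprecision`; starts circularly permuted at `pac + (k-1) * capacity`
#'   (plus a bounded jitter) on the concatemer of the unit genome.
#' * `mu` — phage genome plus 500-3000 bp (configurable) of host DNA; all
#'   reads chimeric. Integrated Mu prophages package the contiguous
#'   chromosome interval spanning the prophage plus flanking host DNA
#'   (roughly 100 bp on the left, the remainder on the right).
#' * `GT` — a `transducing_fraction` of particles package host chromosome
#'   fragments in headful series anchored at pseudo-pac sites; the rest are
#'   headful phage genomes.
#' * `ST` — a `transducing_fraction` of particles start at the prophage pac
#'   site and run one headful across the prophage boundary into the host;
#'   the rest are exact excised-prophage molecules.
#' * `LT` — every particle is the k-th headful of an in-situ series running
#'   from the prophage pac into the flanking chromosome; the first headful is
#'   chimeric when it crosses the prophage boundary.
#' * `GTA` — fragment starts uniform over the genome, lengths
#'   `capacity * (1 + delta)`.
#'
#' Truth rows correspond 1:1 to reads. `start`/`end` are 0-based half-open;
#' a fragment wrapping a circular unit uses the doubled-coordinate
#' convention (`end` may exceed the unit length) and is split into two
#' alignment intervals by [truth_to_alignments()].
#'
#' @param community a [generate_community()] result.
#' @param params a [mechanism_params()].
#' @param n_particles number of particles to draw (0 gives empty output).
#' @param seed master seed.
#' @param genome_id target (host) genome; defaults to the first non-viral
#'   genome, or the first genome overall.
#' @param prophage_id prophage to package from, for integrated contexts;
#'   defaults to the target genome's first prophage (if any).
#' @param phage_genome_id for `GT`: the phage whose particles do the
#'   packaging; defaults to the first genome with domain `"virus"`.
#' @return a truth tibble (see [empty_truth] columns).
#' @examples
#' cm <- generate_community(community_spec(
#'   data.frame(genome_id = "phi", length = 102000, domain = "virus")),
#'   sequences = FALSE)
#' simulate_particles(cm, mechanism_params("cos"), 5, seed = 1)
#' @export
simulate_particles <- function(community, params, n_particles, seed,
                               genome_id = NULL, prophage_id = NULL,
                               phage_genome_id = NULL) {
  if (!inherits(community, "community")) abort("`community` must be a community")
  if (!inherits(params, "mechanism_params")) abort("`params` must be mechanism_params")
  check_count(n_particles, "n_particles", min = 0)
  if (n_particles == 0) return(empty_truth())
  mech <- params$mechanism
  with_component_seed(seed, paste0("particles:", mech), {
    switch(mech,
      cos = sim_cos(community, params, n_particles, genome_id, prophage_id),
      headful = sim_headful(community, params, n_particles, genome_id, prophage_id),
      mu = sim_mu(community, params, n_particles, genome_id, prophage_id),
      GT = sim_gt(community, params, n_particles, genome_id, phage_genome_id),
      ST = sim_st(community, params, n_particles, genome_id, prophage_id),
      LT = sim_lt(community, params, n_particles, genome_id, prophage_id),
      GTA = sim_gta(community, params, n_particles, genome_id)
    )
  })
}

read_ids <- function(mech, n) sprintf("%s_%06d", mech, seq_len(n))

sim_cos <- function(community, params, n, genome_id, prophage_id) {
  u <- resolve_unit(community, params, genome_id, prophage_id)
  if (!is.null(u$prophage)) {
    a <- u$prophage$g_start; b <- u$prophage$g_end
    truth_row(read_ids("cos", n), "cos", u$genome$genome_id, "genome",
              rep(a, n), rep(b, n), rep(b - a, n))
  } else {
    G <- u$genome$length
    truth_row(read_ids("cos", n), "cos", u$genome$genome_id, "genome",
              rep(0, n), rep(G, n), rep(G, n))
  }
}

# headful series start positions on a circle of length `unit_len`
headful_starts <- function(n, pac, H, eps, N) {
  k <- sample.int(N, n, replace = TRUE)
  list(k = k, start = pac + (k - 1) * H + jitter_u(n, eps * H))
}

sim_headful <- function(community, params, n, genome_id, prophage_id) {
  u <- resolve_unit(community, params, genome_id, prophage_id)
  eps <- params$imprecision
  if (!is.null(u$prophage)) {
    a <- u$prophage$g_start; b <- u$prophage$g_end
    L <- b - a
    H <- params$capacity %||% ((1 + params$redundancy) * L)
    hs <- headful_starts(n, u$prophage$pac_offset, H, eps, params$series_length)
    start_c <- hs$start %% L
    len <- H * (1 + jitter_u(n, eps))
    truth_row(read_ids("headful", n), "headful", u$genome$genome_id,
              u$prophage$prophage_id, round(a + start_c),
              round(a + start_c + len), round(a + start_c + len) - round(a + start_c),
              series_k = hs$k)
  } else {
    G <- u$genome$length
    H <- params$capacity %||% ((1 + params$redundancy) * G)
    hs <- headful_starts(n, params$pac %||% 0, H, eps, params$series_length)
    start <- hs$start %% G
    len <- H * (1 + jitter_u(n, eps))
    truth_row(read_ids("headful", n), "headful", u$genome$genome_id, "genome",
              round(start), round(start + len), round(start + len) - round(start),
              series_k = hs$k)
  }
}

sim_mu <- function(community, params, n, genome_id, prophage_id) {
  u <- resolve_unit(community, params, genome_id, prophage_id)
  host <- runif(n, params$mu_host_range[1], params$mu_host_range[2])
  if (!is.null(u$prophage)) {
    a <- u$prophage$g_start; b <- u$prophage$g_end
    G <- u$genome$length
    x <- pmin(runif(n, 50, 150), host - 1, a) # left host overhang
    y <- pmin(host - x, G - b)
    start <- round(a - x); end <- round(b + y)
    truth_row(read_ids("mu", n), "mu", u$genome$genome_id, "genome",
              start, end, end - start, chimeric = TRUE)
  } else {
    G <- u$genome$length
    # free phage genome: the appended host DNA is exogenous to the community,
    # so the alignment interval covers the phage span only
    truth_row(read_ids("mu", n), "mu", u$genome$genome_id, "genome",
              rep(0, n), rep(G, n), round(G + host), chimeric = TRUE)
  }
}

sim_gt <- function(community, params, n, genome_id, phage_genome_id) {
  genomes <- community$genomes
  if (is.null(phage_genome_id)) {
    vir <- genomes$genome_id[genomes$domain == "virus"]
    if (length(vir) == 0) abort("GT requires a phage genome (domain = \"virus\") in the community")
    phage_genome_id <- vir[1]
  }
  phage <- genomes[genomes$genome_id == phage_genome_id, ]
  if (nrow(phage) == 0) abort(sprintf("unknown phage genome `%s`", phage_genome_id))
  if (is.null(genome_id)) {
    hosts <- genomes$genome_id[genomes$domain != "virus"]
    if (length(hosts) == 0) abort("GT requires a host genome in the community")
    genome_id <- hosts[1]
  }
  host <- genomes[genomes$genome_id == genome_id, ]
  Gp <- phage$length; Gh <- host$length
  eps <- params$imprecision
  H <- params$capacity %||% ((1 + params$redundancy) * Gp)
  N <- params$series_length
  pseudo_pacs <- runif(params$gt_n_pacs, 0, Gh)
  transducing <- runif(n) < params$transducing_fraction
  nt <- sum(transducing)
  k <- integer(n); start <- double(n); len <- double(n)
  gid <- ifelse(transducing, host$genome_id, phage$genome_id)
  if (nt > 0) {
    pac_i <- sample.int(length(pseudo_pacs), nt, replace = TRUE)
    hs <- headful_starts(nt, 0, H, eps, N)
    s <- pseudo_pacs[pac_i] + hs$start
    s <- if (host$circular) s %% Gh else pmin(s, Gh - 1)
    start[transducing] <- s
    k[transducing] <- hs$k
    len[transducing] <- H * (1 + jitter_u(nt, eps))
  }
  if (nt < n) {
    np <- n - nt
    hs <- headful_starts(np, params$pac %||% 0, H, eps, N)
    start[!transducing] <- hs$start %% Gp
    k[!transducing] <- hs$k
    len[!transducing] <- H * (1 + jitter_u(np, eps))
  }
  end <- round(start + len); start <- round(start)
  # clip linear-genome overruns
  lin_max <- ifelse(transducing,
                    ifelse(host$circular, Inf, Gh),
                    ifelse(phage$circular, Inf, Gp))
  end <- pmin(end, ifelse(is.finite(lin_max), lin_max, end))
  truth_row(read_ids("GT", n), "GT", gid, "genome", start, end, end - start,
            series_k = k)
}

sim_st <- function(community, params, n, genome_id, prophage_id) {
  u <- resolve_unit(community, params, genome_id, prophage_id)
  if (is.null(u$prophage)) abort("ST requires a prophage in the target genome")
  a <- u$prophage$g_start; b <- u$prophage$g_end
  L <- b - a; G <- u$genome$length
  eps <- params$imprecision
  H <- params$capacity %||% ((1 + params$redundancy) * L)
  p <- a + u$prophage$pac_offset
  transducing <- runif(n) < params$transducing_fraction
  len <- H * (1 + jitter_u(n, eps))
  start <- ifelse(transducing, p, a)
  end <- ifelse(transducing, pmin(round(p + len), G), b)
  start <- round(start)
  truth_row(read_ids("ST", n), "ST", u$genome$genome_id, "genome",
            start, end, end - start,
            chimeric = transducing & end > b)
}

sim_lt <- function(community, params, n, genome_id, prophage_id) {
  u <- resolve_unit(community, params, genome_id, prophage_id)
  if (is.null(u$prophage)) abort("LT requires a prophage in the target genome")
  a <- u$prophage$g_start; b <- u$prophage$g_end
  L <- b - a; G <- u$genome$length
  eps <- params$imprecision
  H <- params$capacity %||% ((1 + params$redundancy) * L)
  p <- a + u$prophage$pac_offset
  k <- sample.int(params$series_length, n, replace = TRUE)
  len <- H * (1 + jitter_u(n, eps))
  xi <- jitter_u(n, eps * H)
  if (params$direction == "right") {
    start <- p + (k - 1) * H + xi
    end <- pmin(round(start + len), if (u$genome$circular) Inf else G)
    start <- round(start)
    chim <- k == 1 & start < b & end > b
  } else {
    end <- p - (k - 1) * H - xi
    start <- pmax(round(end - len), if (u$genome$circular) -Inf else 0)
    end <- round(end)
    chim <- k == 1 & end > a & start < a
  }
  if (u$genome$circular) {
    # doubled-coordinate wrap
    wrap <- start %% G
    end <- end + (wrap - start)
    start <- wrap
  }
  truth_row(read_ids("LT", n), "LT", u$genome$genome_id, "genome",
            start, end, end - start, series_k = k, chimeric = chim)
}

sim_gta <- function(community, params, n, genome_id) {
  if (is.null(params$capacity)) abort("GTA requires `capacity` (fragment size)")
  u <- resolve_unit(community, params, genome_id, NULL)
  G <- u$genome$length; eps <- params$imprecision
  len <- params$capacity * (1 + jitter_u(n, eps))
  if (u$genome$circular) {
    start <- runif(n, 0, G)
  } else {
    start <- runif(n, 0, G - max(len))
  }
  start <- round(start); end <- round(start + len)
  truth_row(read_ids("GTA", n), "GTA", u$genome$genome_id, "genome",
            start, end, end - start)
}
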