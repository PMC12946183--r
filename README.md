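# transductr

Single-molecule detection of phage-mediated bacterial DNA packaging from
long-read virome data.

## The problem

Bacteriophages and gene transfer agents (GTAs) move bacterial DNA between
cells inside capsids, but in a complex community — a faecal virome, say — it
is hard to tell genuinely encapsidated bacterial DNA from free DNA released
by lysis. A capsid, however, enforces an almost fixed packaged-DNA length:
cos-type phages cut exact unit genomes, headful phages package
`H = (1 + ρ)·G` bp (terminal redundancy ρ ≈ 2–10%) with ±2% imprecision, and
GTAs package short (~4–13 kb) random chromosome fragments. Sequencing intact
virus-like-particle (VLP) DNA molecules end to end therefore produces
*discrete read-length peaks*, one per particle population, and the mapping
pattern of each peak's reads reveals the packaging mechanism:

* **prophage induction** — reads of ~prophage length, confined to the
  prophage interval;
* **generalised transduction (GT)** — phage-genome-sized reads dispersed
  over the host chromosome;
* **lateral transduction (LT)** — headful series from the prophage *pac*
  site into the chromosome: chimeric reads crossing the boundary, alignment
  starts at `pac + k·H`, and a periodic coverage wave;
* **specialised transduction (ST)** — boundary-confined chimeras without a
  series;
* **GTA-like packaging** — short fragments of near-constant length with
  uniform chromosome coverage.

`transductr` implements this analysis for anyone working with long-read
viromes: alignment ingest with the standard filters (reads ≥ 3 kb,
alignments ≥ 1 kb, greatest-sum read assignment), per-taxon read-length peak
detection (Gaussian KDE in log10 space), VLP/total enrichment Z-scores with
a +2 SD flag, and a rule-based event classifier — plus a fully ground-truthed
simulator of encapsidated DNA (all mechanisms above, with degradation and
free-DNA contamination models) so the whole pipeline is testable without
sequencing data.

## Worked example

Simulate a lateral-transduction lysate — a 56.9 kb prophage with a 58.4 kb
headful capacity and the *pac* site 46.9 kb into the prophage — and run the
pipeline:

```r
library(transductr)

cm <- generate_community(community_spec(
  genomes   = data.frame(genome_id = "bacteroides", length = 1e6),
  prophages = data.frame(genome_id = "bacteroides", start = 2e5, end = 256900,
                         prophage_id = "prophageI", pac_offset = 46900)),
  sequences = FALSE)

truth <- simulate_particles(cm, mechanism_params("LT", capacity = 58400),
                            n_particles = 2000, seed = 1)
aln   <- filter_alignments(truth_to_alignments(truth, cm))

generics::tidy(detect_peaks(aln$read_len))
#> # A tibble: 1 × 5
#>   peak_id center rel_halfwidth n_members share
#>     <int>  <dbl>         <dbl>     <int> <dbl>
#> 1       1 58416.        0.0313      2000     1

events <- call_events(aln, cm$scaffolds, cm$prophages, sample = "demo")
dplyr::select(events, taxon, mode, peak_center, n_within, n_outside,
              n_chimeric, periodicity)
#> # A tibble: 1 × 7
#>   taxon       mode  peak_center n_within n_outside n_chimeric periodicity
#>   <chr>       <chr>       <dbl>    <int>     <int>      <int>       <dbl>
#> 1 bacteroides LT         58416.        0      1607        393       0.930
```

The single peak sits at 58.4 kb (the headful capacity, ±2% imprecision in
the reads), 393 of 2000 reads are pac-anchored chimeras crossing the
prophage boundary, the remaining out-of-prophage reads start on the
`pac + k·58.4 kb` lattice (periodicity 0.93), and the decision table calls
lateral transduction; the full reasoning is recorded in
`events$rule_trace`.

Higher-level entry points: `run_simulate()` / `run_analyze()` drive
multi-sample runs from a YAML or list config (alignments in PAF or interval
TSV, scaffold metadata TSV, prophage BED, optional per-scaffold short-read
counts for enrichment), and `run_benchmark()` replays the labelled
six-mechanism benchmark and reports per-mechanism recall. `autoplot()`
methods draw the standard figures for peaks, events and enrichment records.

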