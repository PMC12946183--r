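---
title: "Single-molecule transductomics: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule transductomics: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transductr)
```

## The measurement model

A phage or gene transfer agent (GTA) capsid holds an almost fixed amount of
DNA. cos-type terminases cut at specific sites and produce exact unit-genome
molecules; headful terminases fill the capsid from a concatemer starting at a
*pac* site, producing terminally redundant, circularly permuted molecules
2–10% longer than the genome with a packaging imprecision of roughly ±2%.
Because of this, single-molecule long reads of encapsidated DNA concentrate
into narrow, discrete length peaks — one per particle population — while free
(non-encapsidated) DNA released by lysis is broadly distributed. Reading
intact virus-like-particle (VLP) DNA molecules end to end therefore turns
read length into a mechanistic signal: each peak indexes a packaging event,
and the mapping pattern of the member reads identifies the mechanism.

`transductr` implements that analysis — peak detection, VLP enrichment
statistics and a mechanism classifier — together with a ground-truthed
simulator of encapsidated DNA, so every stage can be validated without
sequencing data.

## What the simulator emulates

`simulate_particles()` draws packaged molecules under one of seven
mechanisms. Throughout, `H` is the capsid capacity in bp (defaulting to
`(1 + redundancy) * unit genome`), `eps` the relative length jitter, and all
coordinates are 0-based half-open.

| mechanism | molecule model |
|---|---|
| `cos`     | exact unit genome (or exact excised prophage) |
| `headful` | length `H(1+delta)`, `|delta| <= eps`; start at `pac + (k-1)H` (± `eps·H`) on the concatemer, circularly permuted |
| `mu`      | phage genome plus 0.5–3 kb of host DNA (~100 bp on the left end, the rest on the right); always chimeric |
| `GT`      | a `transducing_fraction` of particles package host fragments in headful series seeded at pseudo-*pac* sites; the rest are headful phage genomes |
| `ST`      | a `transducing_fraction` of molecules run one headful from the prophage *pac* across the boundary; the rest are exact excised prophages |
| `LT`      | every molecule is the k-th headful of an in-situ series running from the prophage *pac* into the chromosome; the first headful is chimeric when it crosses the boundary |
| `GTA`     | starts uniform over the chromosome, lengths `H(1+delta)` |

Key defaults, with the reasoning:

* `redundancy = 0.04` — inside the 2–10% terminal-redundancy range typical
  of headful phages; `imprecision = 0.02` — the ±2% packaging imprecision of
  headful systems. Both configurable per mechanism.
* `series_length` — 25 for `headful`/`GT` (about `1/redundancy` successive
  headfuls are needed before the circular permutation covers the genome
  once), 5 for `LT` (in-situ series are short; five headfuls already span
  ~300 kb of chromosome).
* Series starts are drawn as `pac + (k-1)H + U(-eps·H, eps·H)`: the jitter is
  bounded rather than accumulating, which keeps the k-th fragment within
  `eps·H` of its lattice position — the geometry the periodicity score tests.
* `GT` seeds 50 pseudo-*pac* sites uniformly on the chromosome; at the read
  depths used here this reproduces the dispersed, near-uniform coverage that
  distinguishes generalised transduction from prophage-centred packaging.
* `apply_degradation()` models post-packaging DNA loss: a molecule keeps its
  packaging-start end and retains a `U(0.1, 0.9)` fraction of its length.
  The retained-fraction law is a stand-in — real degradation kinetics are
  not characterised; only the anchoring (same alignment start as intact
  molecules) and the mean shortening matter to the analysis.
* `add_contamination()` draws free-DNA reads across genomes (weighted by
  length) with log-normal lengths, median 8 kb and log10-sd 0.35. That gives
  a coefficient of variation near 1 — broad enough that the contamination
  contributes no peak narrower than the 5% detection cap, which is the
  property the pipeline relies on.

Sequences, when emitted, are i.i.d. uniform ACGT. There is no base-calling
error model, no real nucleotide composition, no chimera artefacts from
library preparation, and no extracellular-vesicle DNA model. The analysis
consumes alignment intervals, so these omissions do not weaken the tests of
the interval-level logic — but passing the simulator benchmark shows the
pipeline recovers mechanisms from ideal alignments, not that a real aligner's
output on real reads is this clean.

Randomness is reproducible by construction: one master seed, with each
component (per-mechanism draws, degradation, contamination, sequence
emission) using a substream derived by a stable hash of its name, so adding a
component never perturbs another's draws. Molecules wrapping a circular unit
are stored with a doubled coordinate (`end` beyond the unit length) in the
one-row-per-read truth table and split into two intervals when converted to
alignments.

## Ingest and aggregation

`read_alignments()` accepts minimap2-style PAF (target coordinates) or a
BED-like interval TSV. `filter_alignments()` applies the standard virome
filters: reads of at least 3 kb, alignments of at least 1 kb. Reads mapping
to several scaffolds are assigned by `assign_reads()` to the scaffold with
the greatest sum of alignment lengths; ties break to the lexicographically
smallest scaffold id so reruns are identical. All alignment records of a
read contribute to the per-scaffold sums (a wrapped or split read supports
its scaffold with both pieces). Scaffolds are placed into six categories
(viruses; MAG bacteria with and without prophages; unbinned bacteria with
and without prophages; archaea), and reads roll up to taxa labelled by MAG
bin, else the lowest non-empty taxonomy rank, else the scaffold id. Taxa at
or below the rare-entity thresholds (50 reads for bacterial units, 200 for
viral scaffolds) are dropped — and the same thresholds gate event calling,
since the noise argument that justifies them for plotting applies equally to
classification.

## Peak detection

Peak identification is deliberately automatic (replacing by-eye curation):
local maxima of a Gaussian KDE of `log10(length)` with

* bandwidth 0.01 log10 units (≈ ±2.3%), matched to the ±2% headful
  imprecision so a single particle population forms a single mode;
* topographic prominence of at least 5% of the global density maximum;
* a narrowness cap: relative half-width at half height ≤ 5%, which is what
  separates capsid-packaged populations from broad free-DNA distributions —
  the default contamination model has a half-width around 150% and can never
  pass;
* at least 50 member reads, mirroring the rare-entity filter.

Members are reads within ±5% of the peak center; a read eligible for two
peaks joins the nearer one in log space, with ties going to the taller peak,
so memberships are disjoint and peak shares over a taxon sum to at most 1.
Working in log space makes detection scale-equivariant: rescaling all
lengths rescales the centers.

## VLP enrichment

For each scaffold, `enrichment_z()` forms the ratio of its relative
abundance (reads on the scaffold over total quality-filtered reads) in a VLP
fraction to that in the total-community DNA, adding a 0.5-read pseudocount
to zero counts, standardises the ratios across scaffolds within the sample
pair, and flags scaffolds more than two standard deviations above the mean.
Z-scores are computed on raw ratios by default — the stated procedure for
this statistic — even though heavy upper tails are common; `ks_normality()`
is provided as the diagnostic (a moment-fitted, Lilliefors-style KS, so its
asymptotic p-value is approximate), and `log_ratio = TRUE` switches the
standardisation to log ratios when the tail dominates. Under a normal null
the flag rate converges to `pnorm(-2)`, about 2.28%, which the test suite
verifies by simulation.

## The event classifier

For each taxon and peak, `build_evidence()` gathers: locus counts
(within / outside / chimeric relative to the prophage, among reads of at
least 0.7 × peak center), the inferred *pac* site (modal 1 kb window of
alignment starts, at least a 20% share), the periodicity score of
out-of-prophage starts against the `pac + k·H` lattice (tolerance 2% of the
period, minus the uniform-background expectation), long-read coverage
uniformity (CV of per-kb window coverage across the taxon's scaffolds), and
optionally a short-read coverage wave downstream of the prophage (dominant
positive-lag autocorrelation peak above a Bonferroni-corrected 99%
white-noise band, with a crest-decay flag). A prophage "matches" a peak when
its length is within [0.9, 1.1] of the peak center or it contains the
inferred pac.

`classify_event()` then evaluates, in order: LT (matched prophage plus ≥ 5
chimeras, periodicity ≥ 0.3, or a wave with period within 5% of the peak);
induction (≥ 80% prophage overlap, center within [0.95, 1.10] of the
prophage length); ST (chimeras present but confined within one peak-length
of the boundary, no periodicity, no wave); GT (coverage CV ≤ 0.5 over
≥ 200 kb of scaffold space, center ≥ 15 kb, prophage overlap < 0.2); GTA
(CV ≤ 0.5, center < 15 kb, relative half-width ≤ 0.05); otherwise
ambiguous. Every comparison is recorded in the event's rule trace.

The thresholds are formalisations of by-eye practice, each anchored to an
observable: the 0.7 length cut generalises the "reads above 40 kb" counting
cut used for a 58.4 kb peak; the 15 kb size split separates reported GTA
fragment sizes (4.6–13.4 kb) from phage genome sizes (tens of kb); 5
chimeras and a 0.3 periodicity score are comfortably above what uniform
starts produce at benchmark depths. All of them live in
`classify_thresholds()` and can be overridden.

Two design points deserve emphasis:

* **Locus precedence.** A read is `within` when ≥ 95% of its span lies
  inside the margin-extended prophage, and only non-within reads can be
  `chimeric` (pac-anchored, extending ≥ 2 kb beyond the boundary). Without
  this precedence, Mu-type molecules — whose host overhang is at most ~3 kb,
  always under 5% of the span — would each count as a chimera and every Mu
  induction would masquerade as LT. True LT chimeras extend tens of
  kilobases beyond the boundary and are unaffected.
* **The ST/LT degeneracy.** A specialised-transduction molecule anchored at
  the pac and crossing the boundary is geometrically a single-headful LT
  fragment. With five or more such chimeras and a matched prophage, the
  table calls LT; ST is reachable only for rare-chimera bundles where the
  induction rule also fails. This is honest to the biology — without series
  evidence (periodicity, a coverage wave, fragments beyond one headful) the
  two mechanisms are not distinguishable from these features — and it is why
  the recall benchmark covers cos, headful, Mu, GT, LT and GTA, exercising
  the ST rule separately with constructed evidence bundles. Leftward
  packaging (series running upstream of the prophage) is supported
  symmetrically.

A taxon may yield several events, one per detected peak — a bacterium with
an induced 56.9 kb LT-capable prophage and a second 43 kb prophage produces
separate calls for each peak.

## Benchmark and problem sizes

`run_benchmark()` simulates replicate single-mechanism lysates and scores
the called modes: six mechanisms × 20 replicates at 770–2000 reads per
event, on hosts of 1–4.6 Mb. These sizes keep each event's coverage CV
estimable (mean per-window coverage above ~5) while completing in about a
minute; the acceptance checks require per-mechanism recall of at least 0.9
and no LT/GTA confusion. The validation-system reproductions
(`scripts/acceptance.R`) use the published parameters directly: a 41.7 kb
circular genome with 4.1% redundancy (headful), a 102 kb cos genome, a
13.4 kb GTA capacity on a 4 Mb chromosome, and transducing fractions of
12.8% and 4.5% for the two generalised-transduction systems at 20,000
particles each.

## Limitations

* The classifier consumes alignment intervals; misassembly, repeat-induced
  multi-mapping and chimeric alignment artefacts in real data are outside
  the simulator's scope.
* GTA-like packaging cannot be distinguished from extracellular-vesicle DNA
  by these features when vesicle DNA happens to be narrowly sized; the GTA
  call means "short, uniform, narrowly-sized chromosomal fragments".
* Enrichment Z-scores inherit the raw-ratio normality assumption; use the
  KS diagnostic and the log-ratio switch for heavy-tailed communities.
* ST calls are conservative by construction (see above); genuine ST activity
  with many boundary-crossing molecules will be reported as LT unless series
  evidence is absent *and* chimeras are few.
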