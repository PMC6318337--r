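---
title: "Detecting and dating transposable-element insertion polymorphisms with tipscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating transposable-element insertion polymorphisms with tipscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipscan)
```

# The problem

Transposable-element insertion polymorphisms (TIPs) -- presence/absence
variation of TE copies among individuals of a species -- are a major source of
structural variation in plant genomes, and their frequency spectrum records
the recent transpositional history of each TE family. Genotyping TIPs across
thousands of low-coverage short-read accessions is, however, expensive with
conventional paired-end-mapping callers, which align every read to the whole
genome. `tipscan` implements the inverted strategy: reads are first matched
against the *consensus of a single TE family*, and only the genomic mates of
TE-matching pairs are then placed on the reference. The reference is reduced
to 10-kb windows, so a TIP event is a (family, window) pair, not a base-pair
breakpoint -- a deliberate resolution contract that makes the method fast and
robust at panel scale.

# The detection model

For each accession, read pairs are classified by which mate matches a TE
consensus:

* exactly one mate matches a family -> a *junction pair*; the other mate is a
  candidate anchor;
* both or neither match -> discarded (no junction information).

Anchor mates are placed on the reference with a uniqueness requirement:
a qualifying placement must cover at least 80 bp of the read at >= 95%
identity, and a read is *uniquely anchored* when the best qualifying placement
is the only one or beats the runner-up by at least 10 score units. Each
uniquely anchored junction increments one (accession, family, window) support
cell; ambiguous anchors contribute nothing.

Calls are made in two passes over the panel:

1. **Open** (threshold 5): a (family, window) event is opened when some
   accession supports it with at least five junction pairs.
2. **Rescue** (threshold 2): all accessions are re-scanned within opened
   events only, at a threshold of two pairs. The lower threshold is safe
   because the probability that two chimeric pairs hit the exact same 10-kb
   window already opened in another accession is very small, while it
   substantially improves sensitivity at low coverage.

The rescue threshold applies to every accession, including the opener; the
`pass` field of a call records which regime it met. Accessions are processed
independently and opened sets merge by set union, so results are independent
of processing order. Support counts use distinct pair ids and are not
deduplicated for PCR/optical duplicates. Insertions also present in the
reference are reported like any other event: the method detects TE-adjacency
evidence per window and performs no reference-genotype subtraction.

# The alignment layer

All stages share one internal seed-and-extend local aligner (exact 21-mer
seeding on an indexed target, diagonal clustering, banded affine-gap
Smith-Waterman extension with match +1, mismatch -2, gap open -4, gap
extend -1; a gap of length L costs 4 + L). Two deliberate dialect choices:

* E-value thresholds of database-search tools are database-size dependent, so
  they are translated into explicit length-and-identity gates: >= 80 bp at
  >= 95% identity for short-read anchoring (and tile mappability), >= 250 of
  300 bp at >= 90% for long-read flanks. The gates are configurable.
* Reads matching two families equally (e.g. a shared LTR fragment) are
  assigned to the lexicographically smallest family id and flagged
  `multi_family`, rather than silently dropped; when families are scanned
  independently such ties cannot arise, so this only matters for joint scans.

The banded extension is exact for substitution-dominated Illumina reads;
for indel-rich long reads callers widen the band (default 40 for whole reads,
20 for 300-bp flanks).

# Mappability

Each 10-kb window is sliced into non-overlapping 100-bp tiles (trailing
fragments < 100 bp are excluded from numerator and denominator), and the
window's mappability is the fraction of tiles that place uniquely under *the
same gate as TIP anchoring*. The track is therefore by construction the
detectability bound of junction anchoring: windows with low mappability
cannot accumulate unique anchors, which is the mechanism behind
family-specific sensitivity drops in repeat-rich regions. The test suite
checks the implementation against an exhaustive placement-counting oracle
(complete by a pigeonhole argument: any qualifying placement shares an exact
13-mer with its tile) verified with an independent dynamic-programming
engine.

# Long-read validation

Long reads containing a TE junction are found by aligning family consensi to
the reads; a read is kept only when its best TE match covers at most 80% of
the read length, which eliminates reads consisting only of TE sequence. The
300 bp flanking the TE interval on each side are re-mapped to the reference
with the stringent gate; each uniquely placed flank yields the insertion
position as the flank base adjacent to the TE. Loci are de-duplicated per
(family, window) since several reads can span one insertion. Following the
field's usage, *specificity* is the fraction of short-read TIPs validated by
a long-read insertion in the same window, and *sensitivity* the fraction of
long-read loci recovered by the short-read calls. Single-flank evidence is
accepted and labelled via `flank_side`; the original manual dot-plot review
step is replaced by the automatic gate.

# Genomic paleontology

Complete LTR-retrotransposon copies are discovered by using the family's
RT-domain sequence as a paralog probe (for LARD-like families without coding
capacity, a configured non-repetitive internal interval plays the same role),
extending each hit by 1.5 consensus lengths on both sides, and requiring both
LTRs in the extension. The element is trimmed to the outer LTR bounds, split
into two halves, and one half is aligned against the other: only the LTRs
align, and the identity of the largest local alignment estimates their
divergence. The insertion age follows the LTR molecular clock,

$$ T = \frac{1 - \mathrm{identity}}{2 r}, \qquad r = 1.3\times10^{-8}
\ \mathrm{substitutions\ site^{-1}\ year^{-1}}, $$

with divergence taken as the raw mismatch fraction. No multiple-hit
correction is applied by default because published ages for this system are
consistent with the uncorrected form at the identities involved (>= 96%); a
Jukes-Cantor correction is available behind `correction = "JC69"`.

Orthology across three assemblies (Japonica-like, Indica-like, Aus/Boro-like)
uses the 300 bp upstream of an element as an anchor: the flank must produce
exactly one placement covering >= 90% of its length in the target assembly
(otherwise the element is *unresolved*), and the 15 kb downstream of the
placed flank is searched for the family consensus to decide presence.
Upstream/downstream are defined on the plus strand of the source assembly;
element strand is not inferred. Presence across the trio maps
deterministically onto seven categories (three group-specific, one common to
all, three pairwise-common), and categories are validated against panel
carrier frequencies: >= 60% of the corresponding group for specific
insertions, >= 80% of each implicated group for common ones. Elements are
matched to matrix rows by family and the window containing the element start
in the element's own source assembly; the join is our choice, as the
procedure it mirrors leaves it unstated.

# The simulator and what it does (not) emulate

The simulator provides ground truth for every stage:

* **Reference**: i.i.d. background plus planted duplicated blocks totalling a
  target repeat fraction (default 40%, matching the repeat context the method
  was designed for), with the repeat annotation emitted.
* **Panel**: insertion loci placed uniformly (>= 1 kb apart), each assigned a
  population frequency; the default L-shaped law is log10-uniform on
  [1e-3, 1], so about a third of loci sit below frequency 0.01 and carrier
  counts are dominated by singletons and doubletons (the expected fraction of
  loci with <= 2 carriers is 0.76 at 12 accessions and 0.68 at 20, from the
  law's CDF). Carrier counts are drawn from the binomial conditioned on at
  least one carrier. Elements are spliced in full length with a 5-bp
  target-site duplication; LTR divergence is simulated by independent
  per-site substitution at probability $rt$ on each LTR copy.
* **Reads**: `round(coverage x L / (2 x 100))` pairs with Normal(350, 50)
  inserts, FR orientation, uniform substitution errors (0.5% default),
  constant Phred-30 qualities (detection never uses qualities). Long reads
  follow a log-normal length law (median 8 kb) with substitution+indel
  errors.

Deliberate simplifications: no nested insertions, no solo-LTR formation, no
empirical error-model training, no recombination or demography. Passing tests
therefore show that the pipeline recovers clean full-length insertion signals
at realistic coverage, repeat content and error rates -- not that it handles
truncated, nested or highly diverged real-world copies.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; BED is written
  as-is, GFF/GTF converted on ingest. `window_id` is fixed as
  `"chrom:start-end"` so matrices are joinable across runs.
* The trailing window of a chromosome is tiled as a short window, not
  discarded.
* Detection truth scoring (simulator only) matches a detected (family,
  window) event to a truth locus when the window overlaps +-500 bp of the
  breakpoint: anchors fall on both flanks within roughly one insert size, so
  when a breakpoint lies near a window boundary the evidence legitimately
  opens the adjacent window too; at 10-kb resolution both windows identify
  the same insertion.
* Activity classing (`Recent` / `Continuous` / `Old`) is a declared
  heuristic over the frequency spectrum (>= 80% of events below 0.05 ->
  Recent; >= 50% above 0.5 -> Old), labelled as such; the thresholds are
  configurable and no attempt is made to reproduce per-family labels from
  the study this mirrors.
* Problem sizes in the test-suite: the end-to-end evaluation uses 12
  accessions on a 2-Mb reference with 60 loci at 15x coverage; mappability
  oracle equivalence runs at 1 Mb; the dating round trip uses 200 replicates
  per age point with 2-kb LTRs. These sizes give stable statistics (binomial
  standard errors well inside the asserted bounds) while keeping the default
  suite fast.

# Worked example

```{r example, eval = FALSE}
ref <- simulate_reference(length = 5e5, repeat_fraction = 0.3, seed = 11)
lib <- structure(list(
  famA = simulate_te_family("famA", superfamily = "Gypsy", seed = 21),
  famB = simulate_te_family("famB", superfamily = "Copia", seed = 22)),
  class = "te_library")
panel <- simulate_panel(ref, lib, n_accessions = 4, n_loci = 15, seed = 31)
reads <- lapply(panel$genomes, generate_reads, coverage = 15, seed = 41)

res <- detect_tips(reads, lib, panel$reference)
mp  <- window_mappability(panel$reference, res$windows)
score_detection(res, panel$truth, res$windows, mp, min_mappability = 0.8)
```

# Known limitations

* 10-kb windows are the resolution contract: no breakpoint refinement, no
  split-read sub-algorithm, no absence (deletion) calling, no genotype
  likelihoods.
* The internal aligner is not a general-purpose mapper: no quality-aware
  scoring, no spliced alignment, and banded extension assumes the seed
  cluster pins the correct diagonal.
* Families must be represented in the consensus library; TIPs of families
  absent from the library are invisible, and very short elements (MITEs,
  SINEs) would defeat the TE-first mapping step.
* Category validation inherits the windowing join; elements whose start
  falls in a window with no matrix row are reported as unvalidated with
  reason `"no panel evidence"`.
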