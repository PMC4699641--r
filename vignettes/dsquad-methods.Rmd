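---
title: "Predicting intrastrand and interstrand G-quadruplex forming sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intrastrand and interstrand G-quadruplex forming sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsquad)
```

## The problem

A G-quadruplex (G4) is a four-stranded nucleic-acid structure built from
stacked guanine tetrads. Forming one requires four guanine tracts, usually
of at least three guanines each, close enough together that the intervening
loops stay short. The standard motif used to predict putative
quadruplex-forming sequences (PQS) in genomes,
`G3+N1-7 G3+N1-7 G3+N1-7 G3+` (or its cytosine complement on the other
strand), assumes all four tracts sit on *one* strand.

Genomic DNA is double stranded, and the complementary strand of every
cytosine tract is a guanine tract. A quadruplex can therefore also be
assembled from guanine tracts distributed between *both* strands — a
double-strand-derived PQS (DS-PQS). `dsquad` predicts both kinds: it
enumerates the possible tract-order topologies, scans sequence for each of
them with the exact global-regular-expression semantics the motif definition
implies, merges overlapping predictions into unique sites, summarises
prevalence per chromosome, and tests interval sets (ChIP-seq peaks,
promoters, replication origins) for enrichment in PQS.

## Topology classes

Writing `A` for a guanine tract and `B` for a cytosine tract on the scanned
strand (5' to 3'), a PQS is one of the sixteen 4-letter words over
\{A, B\}. Reading the same duplex site from the other strand reverses the
tract order and swaps the letters, so reverse-complement words describe the
same site and are identified. This partitions the sixteen words into ten
classes: the intrastrand class `AAAA` (with `BBBB`) plus nine interstrand
classes in which both strands contribute guanines:

```{r}
topology_classes()
```

Four interstrand classes (`AABB`, `BBAA`, `ABAB`, `BABA`) are their own
reverse complements; the other five pair a canonical pattern with its
mirror (e.g. `BABB` with `AABA`). Swapping `A` and `B` *without* reversal
maps a quadruplex seeded from the positive strand onto the negative-strand
one; under that relation the nine classes collapse into five groups, with
`ABBA` its own mirror. A legacy numbering of the nine interstrand classes
(1–9) is carried in `cao_number` for cross-referencing with earlier work on
the yeast genome.

Each class admits several loop-polarity conformations; these cannot be told
apart from sequence alone and are not distinguished here. Cytosine-based
i-motifs, which some of the same sequences might form at acidic pH, are out
of scope.

## The matcher

The motif for each class is a Perl-compatible regular expression built by
one rule set (`class_regex()`):

* a tract is `G{3,}` (letter `A`) or `C{3,}` (letter `B`), with the minimum
  configurable via `scan_params(min_tract=)`;
* a loop between two tracts of the *same* letter is `.{1,7}`
  (`same_loop_min`–`same_loop_max`); a gap between tracts of *different*
  letters is `.{0,7}` (`cross_gap_min`–`cross_gap_max`) — abutting
  G- and C-tracts are legal;
* the second and later occurrences of a letter are backreferences to the
  first capture of that letter, so they repeat that tract's exact matched
  string;
* a class with two member patterns is an alternation, canonical member
  first; `AAAA` is the alternation of the all-G and the all-C expression.

```{r}
class_regex("AABB")$regex
```

Matching runs on a backtracking PCRE engine (`gregexpr(perl = TRUE)`)
rather than hand-rolled automata, because the method is *defined by* these
expressions: greediness, backtracking, and backreference semantics all
affect which intervals are reported, and an independent engine is the only
way to inherit them exactly. Three consequences are worth spelling out:

* **Backreferences, not independent quantifiers.** `\1` must repeat the
  first tract's captured string. With greedy capture and backtracking this
  admits later tracts at least as long as the shortest viable first tract,
  with surplus guanines absorbed into the flanking loops; tract lengths are
  coupled across the motif. No normalisation to independent `{3,}`
  quantifiers is applied — it would change genome-wide counts.
* **Global matching.** Each search resumes at the end of the previous
  match (`m//g`), so matches of one class never overlap each other.
  Matches of *different* classes may overlap freely; a separate one-step
  search is run per class, and overlap resolution is deferred to
  `merge_sites()`.
* **Coordinates.** Records are 0-based half-open internally and in BED
  output; the one-line-per-match text dialect prints 1-based starts, the
  convention of classic Perl-based motif scanners. Both conventions are
  documented per interface.

`scan_params()` exposes the knobs that matter: `min_tract` (default 3 nt),
the same-letter loop bounds (1–7 nt) and cross-letter gap bounds (0–7 nt),
and `loop_max_alt = 12` for the relaxed variant used in functional
analyses. Two further choices are deliberately explicit because genome
FASTA files are soft-masked and contain ambiguity codes:

* `case_mode = "fold"` (default) uppercases before scanning, so repeats
  count; `"strict"` never lets lowercase into a tract. The default
  maximises sensitivity; the toggle exists because published genome-wide
  counts depend on this (undocumented) choice.
* `ambiguous_in_loops = TRUE` (default) lets `N` sit in loops — the `.` of
  the expressions matches any character — but tracts are always pure G or
  C. Setting it `FALSE` restricts loops to ACGT.

## Unique sites and per-chromosome statistics

Overlap is "at least one shared base" everywhere in the package. A *unique
site* is a connected component of records under that relation;
`merge_sites()` computes components with a sort-and-sweep (a record joins
the open group while it starts before the group's running maximum end).
Two distinct summaries follow the same convention deliberately: unique
*interstrand* sites merge the nine DS classes only, while "groups of any
type" merge all ten classes — the two numbers answer different questions
and both are reported by `chrom_stats()`, together with per-megabase
densities (computed over full sequence length, N runs included) and the
intrastrand/interstrand count ratio.

For comparing a chromosome's ratio against the genome, `poisson_z()` gives
the asymptotic Poisson z-score `(obs − exp)/sqrt(exp)`. The expectation
construction for sex-chromosome depletion (expected interstrand count =
intrastrand count ÷ genome-wide ratio) is one reasonable reading of a
comparison whose exact null is not fully specified in the literature this
package follows; it is provided as a building block, not an automated
verdict.

## Enrichment against functional intervals

`enrich_peaks()` asks whether a peak set (ChIP-seq, origin mapping,
promoters) contains PQS more often than chance. The observed statistic is
the number of peaks overlapping at least one site of a category
(`intrastrand`, `interstrand`, `any`, or one class). The null needs the
probability that a random peak hits a site; two interchangeable
constructions are provided:

* **closed form** (default): for merged, non-overlapping sites, a uniformly
  placed interval of length $w$ overlaps a site of length $s$ iff its start
  falls in a window of $s + w - 1$ positions, so
  $p_0 = \min\!\big(1, \sum_i (s_i + w - 1) / L\big)$ with $L$ the total
  genome length and $w$ the median peak length. This slightly overstates
  $p_0$ when extended windows of nearby sites overlap, and ignores edge
  effects of order $w/L$ — both negligible at genomic scale and
  conservative for enrichment claims.
* **Monte-Carlo** (`null = "shuffle"`): peaks are re-placed uniformly at
  random (lengths preserved) and the hit fraction averaged over the draws;
  useful as a cross-check of the closed form.

Significance is the upper-tail binomial probability $P(X \ge k)$ for
$X \sim \mathrm{Binomial}(n, p_0)$, and the effect size is the enrichment
ratio $(k/n)/p_0$. No multiple-testing correction is applied across peak
sets; raw bounds are reported.

`topology_composition()` compares the class spectrum of PQS inside peaks
with the genome-wide spectrum. All overlapping predictions are counted —
any of the overlapping PQS could be the functional one — so no unique-site
merging is applied there. Per class, the in-peak count is tested against
the genome fraction scaled to the in-peak total with a Poisson z-score,
over two denominators (all PQS, and DS-PQS only). A class absent from both
sets gets z = 0 and a `degenerate` flag rather than an undefined value.

`fraction_with_pqs()` covers the fixed-region use case (e.g. 1-kb
upstream-of-TSS FASTA files): each record is scanned independently and the
fraction of records with at least one PQS of a category is returned.

## Synthetic data and the placement oracle

`random_sequence()` draws i.i.d. letters at a chosen GC content,
`plant_spec()`/`plant_pqs()` write a motif with known tract and gap lengths
into a background and return exact truth coordinates (loops are filled
from \{A, T\} so they can never extend a tract), and
`brute_force_placements()`/`has_placement()` form an oracle that enumerates
valid tract placements directly from the tract/gap rules, sharing no code
with the regex path. Backreference semantics are mirrored by requiring all
tracts of a letter to repeat the first tract's length, surplus run letters
falling into the adjacent gaps. The existence check propagates feasible
tract-start sets through the chain of gap constraints, which is exact
because the constraints couple only consecutive tracts; full enumeration is
guarded to sequences of at most 500 nt.

The generator emulates base composition only — no isochores, repeats, CpG
islands or mutational structure. That is the right null for validating the
matcher and the interval algebra, and it is why i.i.d. sequence at a given
GC carries far fewer PQS than real genomes of the same GC (real G-runs are
clustered). Passing tests on synthetic data therefore validate the
*machinery*, not any biological claim about a particular genome.

## Problem sizes used by the test suite

The suite checks, among others: exhaustive topology combinatorics over all
sixteen patterns; scanner-versus-oracle existence agreement on 500 random
120-nt sequences per GC level in \{0.3, 0.5, 0.7\} for all ten classes;
exact recovery of 100 motifs (ten per class) planted in a 101-kb A/T
background, where the absence of any G or C certifies the background clean
by construction; merge equivalence against a quadratic union-find oracle on
1,000 random intervals; and null calibration of the binomial test on a
200-kb GC-0.55 genome with 200 replicates of 100 uniformly placed 150-nt
peaks (GC 0.55 chosen so an i.i.d. genome carries a realistic density of
sites, per the note above). A genome-wide reproduction against the hg19
assembly (897,935 DS-PQS records; 550,977 unique interstrand sites;
intrastrand/interstrand ratio 0.68) is wired into the suite but requires a
local copy of the assembly, supplied via
`options(dsquad.hg19_fasta = "/path/to/hg19.fa")`.

## Known limitations

* Presence/absence prediction only: no stability scores or thermodynamics.
* Matches never span FASTA record boundaries; circular sequences are not
  handled.
* Published genome-wide counts depend on unstated case-handling of the
  soft-masked assembly; both `fold` and `strict` modes are provided, and
  small differences against other PQS tools' counts are expected where
  overlapping alternatives are tie-broken differently.
* Peak sets must already be on the coordinate system of the scanned
  assembly; no liftover is performed.
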