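---
title: "Evaluating genome assemblies with asmqc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genome assemblies with asmqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmqc)
```

## The problem

A de novo genome assembly is a set of scaffold sequences — contigs joined by
runs of `N` characters standing in for unsequenced gaps — and there is no
single number that says how good it is. This package implements the family of
evaluation methods developed for community assembly benchmarking of large
vertebrate genomes: contiguity statistics, alignment-based validation against
trusted reference sequence, short-range accuracy scoring with tag pairs,
a paired-read consistency score, and a way to combine many such metrics into
one defensible ranking. It also ships a synthetic corruption simulator so
that every metric can be verified against analytically known ground truth
without any external data.

## Contiguity: N50, NG50 and NG graphs

N50 is the length of the sequence that takes the cumulative sum of lengths,
accumulated longest-first, past 50% of the total assembly size; `nx()`
generalises the threshold. NG50 (`ngx()`) replaces the total assembly size
with the estimated genome size, which makes assemblies of different sizes
comparable, and is 0 when the assembly never reaches the threshold. The NG
graph (`ng_graph()`) evaluates NG(x) at every integer x from 1 to 100: its
first point is the longest scaffold (when that is at least 1% of the genome),
and a series that touches the x-axis reveals an assembly smaller than the
genome.

Two boundary conventions needed fixing because the verbal definition does
not fix them:

* "past 50%" is implemented as *cumulative sum ≥ threshold* (ties included),
  the common N50 convention;
* the NG x-grid is exactly the integers 1..100, with no interpolation.

Because gene annotation is the first use of most assemblies, the gene-sized
content metric (`gene_sized_amount()`) sums all scaffolds of at least 25 Kbp
— the length of an average vertebrate gene, taken here as a configurable
constant rather than recomputed from annotation databases — and the ranking
uses the absolute difference between that amount and the genome size
(lower is better), so both undershooting and inflation are penalised.

## Alignment-based validation

Given local alignments of scaffolds to a trusted (possibly partial)
reference, four length sets are formed: scaffold lengths $S_i$, reference
lengths $R_i$, alignment lengths $A_i$, and the lengths $C_i$ of *coverage
islands*, the maximal intervals of continuous coverage obtained by unioning
alignment footprints on the reference (`coverage_islands()`; abutting
intervals merge). The four metrics of `compass()` are

$$\text{coverage} = \frac{\Sigma C_i}{\Sigma R_i},\quad
  \text{validity} = \frac{\Sigma A_i}{\Sigma S_i},\quad
  \text{multiplicity} = \frac{\Sigma A_i}{\Sigma C_i},\quad
  \text{parsimony} = \frac{\Sigma S_i}{\Sigma C_i}.$$

Parsimony is identically multiplicity/validity, the "cost" of the assembly:
how much assembled sequence must be inspected to find one base of validated
sequence. Multiplicity above 1 indicates repeat expansion or spurious
duplication; below 1, repeat collapse.

Design choices that the definitions leave open:

* $A_i$ is measured as the *reference-interval* length of each alignment.
  This makes $\Sigma A \ge \Sigma C$ structurally true (islands are unions
  of those same intervals). Query-side lengths are retained in the alignment
  table (`s_start`/`s_end`) for diagnostics.
* Overlapping alignments are summed as-is in $\Sigma A$, with no
  de-overlapping; on pathological inputs validity can exceed 1.
* Reference intervals are normalised to the forward strand; strand never
  affects any metric.
* SAM identity is `(aligned bases − NM)/aligned bases` when the `NM` tag is
  present, and unknown otherwise; PAF identity is `matches/alignment length`.
  The stringency defaults — 98% minimum identity, 200 bp minimum scaffold
  length — match established practice for same-sample references, and
  alignments with unknown identity are dropped whenever an identity
  threshold is active.

## Validated regions and tag-pair accuracy

Independently assembled fosmid-sized sequences (~35–40 Kbp) serve as local
trusted references, but may themselves contain misassemblies. Only the
regions supported by at least one qualifying alignment of ≥ 1 Kbp from *any*
assembly are trusted: `derive_vfrs()` unions such footprints per fosmid and
emits each maximal interval as a validated region. "Qualifying" is read as
passing the identity filter, the only definition consistent with the
alignment stringency above.

Short-range accuracy is then scored per assembly (`vfr_tag_report()`):
validated regions are cut into non-overlapping 1,000 nt fragments (trailing
remainders discarded), a 100 nt tag is taken from each end of each fragment,
and tags are mapped against the assembly. A tag matches wherever at least
95 of its 100 bases align; with the bundled matcher that is a full-length
match with at most 5 mismatches, on either strand. Five categories are
counted: **a** tags matching anywhere, **b** tags matching exactly one
scaffold, **c** pairs whose tags share a scaffold, **d** pairs placed
uniquely on one scaffold, and **e** the subset of **d** at the expected
distance of 900 ± 2 nt between tag start coordinates, on the same strand.
The summary score is $c \cdot (e/d)$ (0 when $d = 0$).

Three readings had to be fixed:

* $e/d$ enters as a *fraction*, not a percentage — the theoretical maximum
  score equals the fragment count, which forces this reading;
* "uniquely" means positional uniqueness: a tag matching one scaffold at two
  positions keeps its pair in **c** but out of **d**;
* the ± 2 nt tolerance applies to the distance between mapped start
  coordinates (after strand normalisation), so indels between the tags move
  a pair from **e** while leaving it in **d**, and reverse-complementing a
  scaffold changes nothing.

## Paired-read consistency score

External read-remapping tools report, per assembly, the number of error-free
bases and the scaffold N50 before and after breaking the assembly at
detected scaffolding errors. `reapr_summary()` normalises each of the three
statistics by its within-species maximum (best assembly gets 1) and combines
them as

$$\text{score} = \text{ef}_{\text{norm}} \times
  \frac{\text{broken}_{\text{norm}}^2}{\text{orig}_{\text{norm}}},$$

which rewards local accuracy, contiguity, and correct scaffolding at once.
The score is invariant to rescaling all inputs, and a broken N50 larger than
the original is rejected as inconsistent input.

## Ranking many metrics

`zscore_rank()` standardises each key metric across the assemblies of one
species ($z = (x - \bar x)/s$), negates lower-is-better metrics, and sums.
Choices:

* the *sample* standard deviation (n − 1) is the default; a population-sd
  option is provided since the distinction is conventional;
* missing values contribute 0 to an assembly's sum, and metrics missing for
  a whole species are simply dropped from that species' table — never
  imputed;
* a zero-spread metric contributes 0 everywhere, with a warning.

`loo_bounds()` removes each metric in turn and reports the extreme summed
z-scores — the error bars on the ranking. Because a metric's z-scores do not
depend on the other metrics, each deletion subtracts exactly that metric's
column. Note that both bounds can fall on the same side of the full sum:
for an assembly whose per-metric z-scores all share one sign, every deletion
moves the sum the same way. The bounds are the best and worst achievable
*after omitting one metric*, not an interval around the full sum.

`average_rank()` offers the simpler ordering: rank 1 is best per metric
direction, ties get midranks (consistent with reporting joint places), and
missing values are excluded from that metric. `metric_correlations()`
reports pairwise Pearson r with two-sided p-values over pairwise-complete
assemblies (at least 3).

The ten canonical key metrics, their directions (only the gene-sized
absolute difference is lower-better) and their availability are encoded in
`key_metric_registry()`; metrics produced by external tools (core-gene
detection, optical-map coverage) are accepted in the table but never
computed here.

## The synthetic simulator and what it does (not) show

`generate_genome()` draws uniform random DNA, optionally planting *exact*
copies of repeat units at recorded non-overlapping positions — exact, so
that alignment behaviour stays analytically predictable. `corrupt_assembly()`
applies an ordered plan of operations: fragmentation, N-gap insertion,
duplication, chimeric joins, repeat collapse, and substitutions. Every piece
of the result carries provenance, so the implied ("truth") alignments and
the expected values of all four validation metrics are computed from the
plan itself: a duplication of d bases with k extra copies raises
$\Sigma A$ by $k\,d$ and leaves $\Sigma C$ unchanged, an inserted gap
inflates only $\Sigma S$, and fragmentation changes nothing.

The bundled `align_exact()` — non-overlapping 16-mer seeds located with
Aho–Corasick matching and extended to maximal exact matches on both strands
— recovers those truth alignments exactly on such assemblies, which is what
the ground-truth recovery tests exploit. One subtlety: at a chimeric
junction the flanking base can match the reference continuation by chance,
and any maximal-extension aligner will include those bases; the truth
alignments therefore carry the same maximal-extension semantics.

Two operations are excluded from the exact predictions by design: repeat
collapse (the surviving copy multi-maps, so $\Sigma A$ depends on the
aligner's reporting of secondary sites) and substitutions (which break exact
matching). They are tested directionally instead: collapse drives parsimony
below 1 while coverage stays complete, and substitution at ≤ 0.5% erodes
the 95-of-100 tag matching only marginally.

What passing these tests does *not* show: the simulator has uniform base
composition, exact repeats, no heterozygosity, no sequencing-error profile
and no alignment ambiguity beyond planted repeats. Results on real data
depend on the external aligner's behaviour (gap penalties, ambiguity
scoring, chaining), which the toolkit deliberately treats as given input.

## Numerical and scale choices

All intervals are 0-based half-open internally; 1-based coordinates appear
only where an external format demands them. Scaffold order is preserved
from input and never affects any statistic. The assembly-size inclusion
filter (total ≥ 25% of genome size) is inclusive at the boundary and uses
the scaffold total. Only `N` (case-insensitive) splits scaffolds into
contigs; other ambiguity codes are retained as ordinary bases.

The verification suites run at sizes chosen to exercise every code path
while staying comfortably interactive: synthetic genomes of 20–50 kb for
alignment-backed checks (random 16-mers are effectively unique at that
scale, and a 50 bp minimum alignment length removes chance seed hits),
1,000 random length sets for the N50/NG50 brute-force oracle, 1,000 random
alignment sets for the parsimony identity, and 50 seeded corruption plans
for multiplicity recovery at 1e-6.

## Known limitations

* The package ingests alignments; it does not produce them for real data.
  `align_exact()` is an oracle for synthetic sequence only.
* Validity can exceed 1 when alignments overlap heavily on the query; an
  optional query-side de-overlap is not applied by default because the
  summed-as-is convention is what the metrics are defined on.
* The tag matcher models substitutions but not indels within a tag; indel
  sensitivity in real data comes from ingesting an external aligner's
  tabular output (`read_blast_tags()`).
* Repeat divergence is not simulated; planted repeats are exact copies.
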