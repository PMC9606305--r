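---
title: "Selecting and evaluating circularized complete MAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and evaluating circularized complete MAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmagkit)
```

## The problem

Long-read metagenome assemblers close some contigs into circles. Among
those circles are complete prokaryotic chromosomes, but also phage and
plasmid genomes, and — hardest to spot — chromosomes that closed early
across a repeated sequence and lost a region between the repeat copies.
Marker-gene completeness scores are too coarse to catch these near-complete
genomes, and reference-quality conspecific genomes are unavailable for
most gut microbial species. `cmagkit` instead leans on the one resource
that exists for almost every abundant species: a large catalog of
*fragmented* conspecific MAGs. Although each catalog genome is incomplete,
contigs shared by most conspecific genomes ("core contigs") almost surely
belong to the true genome, so a candidate complete genome must contain
nearly all of them.

## Stages, parameters, and their defaults

All thresholds live in one place, `pipeline_config()`, and flow to the
stage functions.

**Graph screen.** A contig is dropped when its segment participates in a
simple bubble of the assembly graph or carries an assembler repeat flag.
Only simple (two-branch) bubbles are detected — a source node with exactly
two outgoing branches reconverging on one sink through vertex-disjoint
paths whose interior nodes carry no other links, evaluated on the
oriented-node expansion of the GFA. The filter needs a contig-level
yes/no, so superbubble chains, tips and loops are out of scope.

**Biological priors.** Length ≥ 100 kbp; ≥ 100 universal single-copy
markers; rRNA presence; ≥ 20 distinct non-pseudo tRNA isotypes; all bounds
inclusive. Marker counting first picks the dominant namespace (bac120 vs
arc122) per contig and applies the threshold within it, so an archaeal
contig is not penalized for lacking bacterial markers. Whether "rRNA
presence" means all three of 5S/16S/23S or any one of them is genuinely
ambiguous; the default requires all three (`rrna_mode = "all"`), with
`"any"` available, because a complete chromosome missing a whole rRNA
species is exactly the kind of defect the filter is for. Pseudo-flagged
tRNAs are retained at parse time and excluded only at counting time, so
the I/O layer stays lossless.

**Redundancy removal.** Pairs with ANI > 0.99 *and* maximum alignment
coverage > 0.95 (both strict) are redundant; clusters are connected
components (single linkage) — the most inclusive reading, appropriate
because redundancy here comes from the same genome assembled repeatedly
from pooled samples. The representative maximizes the within-cluster ANI
sum; ties go to the longer contig, then the lexicographically smaller id,
making the choice permutation-invariant.

**Conspecific congruency.** The search is genus-restricted and
species-targeted: the query is aligned to each species representative of
its genus, the species with the highest similarity index (ANI × coverage)
is chosen (ties prefer the larger species cluster, then the smaller id),
and all genomes of that cluster are tested against ANI > 0.95 and
coverage > 0.8 (strict). Collection stops at 100 members, in catalog file
order — the traversal order is otherwise unspecified, and file order makes
the cap deterministic. A per-genus ANI override map (default
`Collinsella = 0.94`) generalizes the special case of a genus with an
exceptionally high variant rate. Core contigs must be longer than 5 kbp
and present in more than 80 % of the *other* member genomes — the
denominator excludes the contig's own genome, since presence there is a
tautology. Presence means more than half of the contig's length aligns at
block identity above 0.95. Member-vs-member alignments use unique-anchor
seeding with best-bidirectional filtering; core-vs-query alignment uses
maxmatch seeding without it, because the pooled core set is internally
redundant and unique anchors would vanish; both modes are configurable.
One alignment per unordered member pair serves both presence directions
(query-axis spans one way, reference-axis spans the other), exactly as a
single nucmer/delta-filter run per pair would. The verdict accepts at
retrieval rate ≥ 0.95 with ≥ 5 conspecific genomes (both inclusive:
"below 0.95" and "fewer than five" reject).

**Culturability.** A cMAG has an isolate-derived conspecific when at
least one catalog genome flagged as an isolate reaches ANI > 0.95 and
coverage > 0.6 — the coverage bar is deliberately lower than the 0.8
conspecificity bound because isolate genomes may be partial assemblies.

**Evaluation.** GC skew uses a 1 kbp window sliding by 10 bp; circular
contigs are traversed with wraparound so every position is covered. The
origin and terminus candidates sit at the cumulative-skew minimum and
maximum. Because published skew-pattern quality classes were assigned by
eye, the package emits quantitative surrogates instead: a symmetry score
(Pearson correlation between the ascending arm and the reflected
descending arm of the cumulative curve) and a smoothed peak count,
leaving categorical labels to the user. SNVs are substitution columns in
best-bidirectional blocks; indel columns are excluded, mirroring
`show-snps -I`. The SNV density denominator is matched-plus-substituted
columns — the natural choice that makes densities comparable across
conspecific genomes of different sizes — and percentile ranks refuse to
compute below 100 conspecific densities (configurable). Genome-bin
retrieval rates follow the per-position formula
rate&nbsp;=&nbsp;Σ&nbsp;matched&nbsp;counts&nbsp;/&nbsp;(1,000&nbsp;×&nbsp;#genomes)&nbsp;×&nbsp;100;
the trailing partial bin is normalized by its actual width by default,
since unconditional division by 1,000 would cap a 400 bp trailing bin at
40 % even when fully matched (`partial = "fixed"` reproduces the
unconditional form). Low-retrieval segments are runs of more than five
consecutive bins at ≤ 20 %. Feature-vs-background rate comparisons use
the two-sided Mann–Whitney U test in its normal approximation with tie
and continuity corrections; groups under two bins are flagged untestable.

## The aligner

Every stage consumes the same built-in pairwise aligner:

* seeds are exact k-mer matches, k = 19 by default (minimum 11), unique
  in both sequences for `unique_anchor` mode or all occurrences (capped
  at 64 per k-mer) for `maxmatch`;
* seeds merge into maximal runs and are chained per contig pair and
  strand by a gap-bounded dynamic program (inter-anchor gaps up to
  1 kbp);
* gaps between adjacent anchors close with a small global alignment
  scoring match +1, mismatch −1, gap −2, and chain ends extend gaplessly
  under an X-drop rule;
* N bases never count as matches or substitutions — they can only occupy
  neutral columns.

Coordinates are 0-based half-open everywhere inside the package; GFF3 and
PAF converters own the ±1 shifts, and circularity is metadata rather than
sequence doubling, so origin-spanning homology may split into two blocks,
which merged-interval coverage absorbs. Best-bidirectional filtering
retains blocks greedily by match count, tolerating up to 50 bp of residual
overlap per axis — a small fixed slack that avoids knife-edge rejections
of blocks abutting at a repeat boundary. The scoring constants approximate
the behavior of seed-and-extend genome aligners in the ≥ 0.94 identity
regime where all the workflow's thresholds operate; the suite pins the
aligner to within 2 % of the optimal global-alignment match count on
sequences up to 2 kbp and to exact ANI 1.0 on self-alignment.

## What the simulator does and does not emulate

`make_species()` draws a uniform-ACGT ancestor and plants independent
Poisson substitutions and short indels per genome; `fragment_into_mags()`
cuts exponentially spaced fragments and drops a fraction of them;
`plant_defect()` excises spans or inserts non-homologous islands drawn
from an independent random stream. The pipeline fixture builds a 500 kbp
species with 10 conspecific MAGs at 0.5 % substitution divergence,
~50 kbp fragments with 5 % contig dropout, a complete query, a query with
a 20 % deletion, and a 0.2 %-divergent duplicate — one planted example of
each failure mode the workflow must separate, at sizes a single CPU
handles in seconds per alignment. Unit tests run the same machinery at
40–200 kbp; the planted-defect recovery study runs the full 500 kbp
preset across 20 seeds.

Mutations are i.i.d.: there is no selection, recombination, horizontal
transfer, contamination, or read-level error model, and fragment
boundaries are independent of repeat content. Passing tests therefore
demonstrate that the decision logic and thresholds behave correctly on
genomes whose statistical structure matches these assumptions — not that
the thresholds are optimal for real gut metagenomes, where conspecific
divergence is non-uniform and MAG gaps cluster at repeats and mobile
elements. Real-data behavior also depends on upstream annotation quality
(marker, rRNA and tRNA calls are inputs, not predictions).

## Numerical and degenerate-input conventions

Empty alignments summarize to ANI 0 / coverage 0 rather than NA, so
thresholds reject them without special cases. An empty FASTA is an empty
result, not an error; an empty pipeline input warns and returns an empty
run. Contigs shorter than the skew window, percentile requests below the
minimum sample, and rank tests with a near-empty group refuse explicitly
instead of returning silently unstable numbers. All generators are exact
functions of (parameters, seed). The configuration file format is YAML
(`read_config()`/`write_config()`), chosen over TOML because it is the
format with first-class support in the R ecosystem this package builds
on; keys are identical to `pipeline_config()` arguments.

## Known limitations

* Genus and species labels are inputs; the package performs no taxonomic
  classification, so a wrong genus label sends the conspecific search to
  the wrong shelf (it then fails safe, as `reject_few_conspecific`).
* Species with fewer than five conspecific catalog genomes cannot be
  evaluated — a structural limit of congruency-based filtering that
  penalizes novel species.
* The aligner targets the high-identity regime of the workflow; it is
  not a general-purpose aligner for diverged genomes, and it does not
  reproduce any external aligner's output bit-for-bit.
* GC-skew diagnostics are descriptive; no replication-rate inference is
  attempted.
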