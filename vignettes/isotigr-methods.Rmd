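---
title: "Comparative annotation of assembled isotigs: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative annotation of assembled isotigs: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`isotigr` analyzes assembled transcript consensus sequences (isotigs) from
a species without a reference genome by projecting everything — gene
identity, coding structure, reading frames, even the location of novel
sequence — through alignments to reference species. This vignette explains
the models and procedures, the parameters that matter, what the synthetic
data emulate, and the design choices that were genuinely open.

## Coordinate conventions

All internal coordinates are 0-based half-open. Conversion to the 1-based
inclusive conventions of BLAST tabular and GFF3 happens only in the
readers and writers, and minus-strand hits are stored with ascending
coordinates plus a strand flag. Chaining therefore operates on one
canonical orientation; mixed-strand hit sets are split by the caller and
the better strand's chain kept. Only `N` is accepted as an ambiguity code
in consensus and reads: the flanking filter of the SNP caller needs a
crisp definition of "ambiguous identity", and other IUPAC codes would blur
it.

## HSP chaining and the unique-hit rule

For one query–target pair, the chainer seeks the colinear (ascending in
query and target; descending on target for minus strand), pairwise
non-overlapping subset of HSPs with the largest total query coverage.
"Coverage" is query bases covered, not alignment columns: the annotation
is query-centric, and query bases are what the downstream coverage ratios
compare. The optimum is found by weighted interval-scheduling dynamic
programming over HSPs sorted by query start (quadratic in the number of
HSPs, exact). Ties are resolved deterministically: larger summed
bit-score, then fewer members, then lexicographically smallest member
order. Chained HSPs may not overlap at all; trimming partially
overlapping HSPs was deliberately left out as it changes coordinates that
every later stage depends on. The test suite holds the chainer against
exhaustive subset enumeration on hundreds of random instances of up to 12
HSPs, including the tie-break order.

A query's chains are resolved to genes, merged per gene (maximum coverage
and maximum bit-score over a gene's transcripts), and the best gene is
called **unique** when its coverage and its bit-score are each at least
`unique_ratio` (default 2) times every other gene's. The rule is
conjunctive — both ratios must clear the bar — reading the source
procedure's "and" literally; summed bit-scores per chain are compared,
since per-HSP scores would make the rule depend on how an alignment
happens to fragment. The same-locus exemption is implemented as same-gene
grouping, which requires gene-resolved chains; grouping by raw genomic
overlap without gene models is out of scope.

Clustering selects, per gene, the largest-coverage isotig as
representative and then greedily (by descending coverage) accepts isotigs
whose genomic footprints — member target intervals projected through the
transcript's exon map — are pairwise disjoint, with zero overlap
tolerance. Greedy selection is not guaranteed to maximize total coverage
in general; the source procedure names no algorithm, and greedy is
deterministic, fast and matches exhaustive search on the fixtures tested.

Orthology-consistency categories use the three reference species'
unique gene calls: category 3 when all three genes share one ortholog
group, 2 when exactly one pair shares, 1 otherwise. A species with an
ambiguous or absent call never matches, so the best an isotig missing one
species can do is category 2.

## ORF projection

The isotig is aligned to its best-mapped reference transcript
semi-globally: global in the isotig, free end gaps on the isotig side, so
a partial isotig aligns into the transcript without terminal penalties.
Scoring is match +2, mismatch −3, gap open 12, gap extend 2 (a gap of
length *k* costs 12 + 2*k*). These are configuration constants, not truth
claims; they are the classic "moderately strict" nucleotide set and every
threshold below is exposed as an argument. The original study aligned
each isotig to mouse, rat and human simultaneously with a
multiple-alignment tool; this package projects through a pairwise
alignment against the single best-mapped reference instead, which removes
an external-tool dependency while leaving the projection contract
unchanged. Multi-reference consensus is a non-goal.

Reference CDS columns are mapped through the alignment; the projected
frame is chosen so reference codon 1 maps to frame 0, translation runs
from the projected start to the first stop or the sequence end, and a
stop strictly before the isotig position aligned to the reference stop
codon is a premature termination codon (PTC). `aligned_cds_fraction`
counts reference CDS positions aligned to a base (not identity-weighted:
the completeness claim is about coverage, not conservation), and
projections with fraction > 0.75 are flagged `complete75`. Frameshifting
indels leave translation in the projected frame; resulting spurious stops
are reported as PTCs with a frameshift warning flag, since the source
procedure defines no frameshift handling.

## SNP calling

Pileup columns count A/C/G/T/N over covering reads, minus-strand reads
reverse-complemented first. A column is a candidate biallelic site when

* total read depth ≥ `min_depth` (default 6, inclusive — "depth below 6"
  is read as a threshold at the column itself, not a windowed average);
* the second most frequent non-N base reaches `min_fraction` (default
  0.30) of the **non-N** depth. N is absence of evidence, not an allele.
  The threshold is applied to the minor allele only; for a biallelic
  column the major allele then satisfies it automatically;
* no third base also reaches the fraction threshold (such columns are
  flagged multi-allelic and not called);
* neither adjacent column is ambiguous: consensus N, zero coverage, or
  more than `max_n_fraction` (default 0.2, configurable) of covering
  reads carrying N. The source rule names no numeric criterion, so the
  20% is an operationalization. Calls at consensus ends are judged on the
  existing flank only.

Ties between equally frequent bases break alphabetically, making call
output independent of read order. Per gene, only the isotig with the most
surviving calls is kept (ties: larger chained coverage, then lexicographic
id), removing double counting across splice variants; unmapped isotigs
are kept as their own units. Substitutions are classified by unordered
pair — A↔G/C↔T are transitions — and summarized with the per-class counts,
the rounded transition percentage, and the same figures for the depth ≥ 31
(inclusive) subset.

## Novel transcribed regions

Candidates are gaps between consecutive chained HSPs on the query:
uncovered termini have only one conserved flank and are never candidates,
and gaps of 50 bp or less are `rejected-short` ("more than 50 bp" read
strictly). Each candidate, with up to 50 bp of flank context (trimmed to
the flanking HSP so the context is contiguous with the target span), is
checked against the intervening genomic span of every species carrying
the gene:

1. each flank must anchor — align locally near its own end of the span at
   ≥ 75% identity — otherwise the candidate is `unresolved`, not novel;
2. the candidate itself is locally aligned to the span with the gap-open
   penalty multiplied by `gap_open_multiplier` (default 3; raised gap
   costs keep an exon from fragmenting into scattered blocks). Local
   identity ≥ `identity_reject` (default 70%) over ≥ 80% of the
   candidate's length rejects it as intronic.

Rejection by **any** species rejects the candidate — the conservative
multi-species rule, chosen to keep the false-positive rate of novelty
claims low. The reported `intron_identity` is matches over the full
candidate length, so a short accidental 15-mer match in an intron does not
masquerade as high identity. The identity/coverage thresholds are
defaults, not reconstructions: the source procedure states the realignment
idea but no numbers. Survivors are classified by the genomic gap between
their flanks: ≤ 10 bp means an insertion inside a conserved exon, more
means the flanks map across an intron and the region is a novel exon.
Regions inside a projected CDS are translated in the projected frame:
in-frame and stop-free is `ORF`, anything introducing a stop is `PTC+`,
regions outside any projection stay `untested`.

## Differential expression

Under the random-sampling null, a gene's count in one library conditioned
on the pairwise total is binomial:
k1 | k1+k2 ~ Bin(k1+k2, N1/(N1+N2)). The test is the exact two-sided
binomial probability (summing outcomes no more likely than the observed
one). The cited methodology's normal approximation on the MA plane is
deliberately not reproduced: at the count scales of a 454-style study the
exact conditional test is strictly more defensible and shares the same
null; the package's exact p-values are cross-checked against base R's
binomial test in the suite. M = log2 k1 − log2 k2 and
A = (log2 k1 + log2 k2)/2 use a 0.5 pseudo-count for zero counts, for
display only — tests always use raw counts. The four-library χ² test
compares observed counts with expectations proportional to library totals
(df = 3), flagging cells with expected count below 1. No normalization
beyond library totals is applied: the emulated libraries are
cDNA-normalized upstream, and modelling that is out of scope.

Both published adjustment strategies are emitted side by side, since the
source tables do not say which produced them: Benjamini–Hochberg step-up,
and Storey q-values with a single fixed λ (default 0.5) —
π₀ = #{p > λ}/(m(1−λ)) clipped to (0, 1] — instead of spline smoothing,
keeping the estimate deterministic and desk-checkable. Term enrichment is
the hypergeometric upper tail of the overlap between the significant
genes and each term restricted to the background (all genes tested in the
comparison), BH-adjusted across terms.

## What the synthetic data emulate — and what they do not

The generator builds, per gene, an ancestral transcript with UTRs and a
stop-free CDS, one transcript per pseudo-species (mouse/rat/human labels)
diverged by independent substitution at half the nominal
`substitution_divergence` per species — so any two homologous copies
differ at about the nominal rate (default 5%). Substitutions that would
create an in-frame stop, or destroy the terminal stop, revert to the
ancestral codon: reference reading frames stay intact by construction.
Exons are separated by 200–600 bp introns on per-gene contigs; a fraction
of genes is withheld from one species (category 2 downstream) or
reassigned to fresh ortholog groups in one or both non-focal species
(categories 2 and 1).

Isotigs copy the focal species' transcripts, optionally truncated or with
one internal exon skipped (splice variants). Planted features: biallelic
sites at `snp_rate`/kb with minor fractions 0.3–0.5 and a 0.73 transition
bias (transcriptome variation is strongly transition-biased; the value
mirrors the ~3:1 ratio typical of such data); uniform-random inserts of
60–300 bp (50% GC) inside exons or at exon junctions — random sequence
guarantees no homology to the references by construction; optional
intron-retention inserts copied from the focal intron, which the
realignment filter must reject. Read stacks tile every column at an
exactly drawn depth (default 8–40) with error-free reads except planted
alleles and optionally injected Ns; per-gene counts are multinomial over
the four library weights with Poisson totals (default mean 100, i.e. ~50
reads in a pairwise contrast), planted genes getting 2^lfc times the
weight in one library.

Deliberately **not** modelled: sequencing errors, quality scores,
homopolymer artefacts, chimeric assemblies, paralog families with real
sequence similarity, and per-library depth differences (the source data
give no per-library depth distribution; depths here are free parameters).
Passing the planted-truth suites therefore demonstrates that the filter
logic, coordinate arithmetic and statistics are correct — not that the
thresholds are optimal for noisy real reads, where the flanking filter
and depth thresholds would carry the load the error model carries here.

Determinism: one master seed drives every stage through deterministically
derived sub-seeds, and a full pipeline run under a fixed seed is
byte-identical when repeated (tested via file digests).

## Numerical and edge-case choices

* Planted alt-allele counts are `round(fraction × covering reads)`; a
  planted site whose realized fraction rounds below 0.30 is correctly not
  called, so recovery is measured against realized depths and fractions
  recorded in the truth set.
* At minor fraction exactly 0.5 the major/minor labels come from the
  alphabetical tie-break and may swap relative to the plant.
* Empty call sets summarize to zero counts with the transition percentage
  reported as NA rather than 0.
* An all-zero count record is untestable (p = 1, flagged), not an error.
* Candidate novel regions whose flanks fail to anchor are `unresolved`
  and never counted as novel.
* Stage outputs are written to a temporary path and renamed on success,
  so interrupted runs never leave truncated tables.

## Problem sizes in the shipped checks

The default demo simulation uses 30 genes (~35 isotigs, ~1.4 kb mean);
the chaining oracle runs 200 random instances of ≤ 12 HSPs; the
dominance-rule boundary uses 100 seeded three-gene fixtures per ratio;
SNP recovery uses 30 genes at depths 6–40; novel-region recovery uses 48
genes with one planted insert each, half of the junction inserts being
intron copies; DE calibration uses 1000 null genes and 50 replicates of
100 planted 4-fold genes among 1000 nulls. These sizes give every rate a
denominator large enough to be meaningful while keeping a full check run
in minutes on one core.

## Known limitations

* Only plus-strand reference gene models are supported (the generator
  emits one transcript per contig); minus-strand *hits* are fully
  supported.
* The intron filter tests the span between the flanking alignments only;
  a candidate homologous to a distant locus would not be rejected by it
  (it would already need to have produced no HSP to become a candidate).
* Storey's π₀ with a fixed λ is slightly conservative when the p-value
  distribution is irregular near λ.
* The same-gene exemption of the unique rule requires gene-resolved
  chains; hits to transcripts absent from the gene models are treated as
  distinct loci.
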