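---
title: "Consensus re-annotation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus re-annotation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reannotator)
```

## The problem

Automatically annotated bacterial genomes accumulate vague or wrong
product descriptions, and a large fraction of genes remain "hypothetical
protein". Manual re-annotation reviews each CDS against several
independent tools and promotes genes whose function is supported by
agreeing evidence. This package implements the computations around that
process — evidence filtering, consensus confidence voting, motif
scanning, orthology/synteny/core-genome bookkeeping, COG assignment,
context-based label transfer, and rating-based ROC evaluation of the
tools — plus a simulator that generates all inputs with known ground
truth.

## Gene model and ORF enumeration

A maximal ORF runs from the *first* start codon (ATG, GTG or TTG —
the standard bacterial convention, since translation tables are otherwise
unspecified for this step) after the previous in-frame stop to the next
in-frame stop. The stop codon is counted in the length, and the retention
rule is strict: an ORF is kept only when longer than 60 nt, so a 60-nt
candidate is rejected and a 63-nt one kept. Coordinates are 1-based
inclusive on the forward strand (GFF3 convention); minus-strand ORFs are
mapped back from the reverse complement. Degenerate inputs are handled
conservatively: characters outside A/C/G/T/N are an input error, and an
ORF containing N is discarded rather than ambiguously translated.
Origin-spanning ORFs on circular chromosomes are supported behind
`circular = TRUE` (off by default) and are reported on the unrolled
circle with a `wraps` flag, which keeps `start <= end` without inventing
split features.

Locus tags are `<prefix>_0001` … in start order (ties: '+' before '−' so
tagging is deterministic), zero-padded to four digits, growing to five
with a warning past 9,999 ORFs.

Statistical coding-potential scoring, RNA genes and pseudogene detection
are out of scope: the ORF layer feeds the annotation bookkeeping, it does
not replace a gene caller.

## Evidence filtering and consensus confidence

Five evidence sources are modelled: two alignment tools (PSI-BLAST,
BLASTO), one domain database (Pfam) and two integrated resources
(InterProScan, ANNIE) that re-expose member databases. Filters follow the
printed thresholds: PSI-BLAST best hits need identity strictly above 40 %
and e-value strictly below 1e-52; Pfam-A hits need e-value at most 1e-02.
The Pfam bound is inclusive because it is stated as a plain cut-off with
no inequality; both bounds are configurable.

"Tools that agree on the function" needs an operational equality, which
manual curation does not supply. Descriptions are normalized to token
sets — lower-cased, punctuation stripped, generic filler removed
(protein, domain, containing, family, putative, probable, like,
hypothetical — the last one so that "hypothetical protein" normalizes to
an empty, uninformative set) — and two votes agree when their token
Jaccard similarity reaches 0.6. That default keeps word-order and filler
variation together ("Beta-xylosidase, family 43 glycosyl hydrolase" vs
"glycosyl hydrolase family 43 beta-xylosidase") while separating
genuinely different functions; it is exposed as `agree_threshold`.

Intrinsic overlaps are removed before voting: an InterProScan or ANNIE
record whose `member_database` names a source already voting with an
equivalent description adds no vote, and each source votes at most once
(lowest e-value wins). The confidence level *k*/5 is the size of the
largest *mutually* agreeing cluster of votes (found by subset
enumeration, exact for ≤ 5 sources); the consensus description is the
most frequent raw description in that cluster, ties resolved
lexicographically so results are reproducible.

The DEFINED/PUTATIVE boundary mirrors how putative proteins are defined
in curation practice — function inferred from a conserved motif,
structural feature or limited similarity. A consensus supported only by
domain/motif sources (Pfam, InterProScan), or carrying a
putative/probable marker, is PUTATIVE; an informative consensus
corroborated by an alignment source is DEFINED; no informative surviving
evidence is NONE.

Reclassification promotes HYPOTHETICAL/NEW/PUTATIVE records with a
DEFINED call at confidence ≥ `min_conf_known` to KNOWN. The default is 2
(at least two independent methods): the promotion threshold used in
manual curation is not stated anywhere, so it is a package choice and a
visible parameter rather than a constant. Weaker calls become PUTATIVE
with a `putative ` product prefix; KNOWN genes are never demoted and
pseudogenes never change. `update_census()` does the before/after
bookkeeping as explicit category moves, refusing overdraws and conserving
the total, so a re-annotation report's census is an auditable
computation.

## PROSITE scanning

The compiler supports fixed residues, alternatives `[..]`, exclusions
`{..}`, the wildcard `x`, repeat counts `(n)` and `(n,m)` on any element,
and terminal anchors `<`/`>`. The scanner enumerates *all* satisfying
windows, including overlaps and multiple ends per start for
variable-length patterns — motif occurrences, unlike regular-expression
matches, are not leftmost-longest. Matching is a small recursive
consumer over compiled elements; the test suite checks it against an
independent sliding-window dynamic program on random pattern/sequence
pairs. Ambiguity-at-pattern-end extensions of the full PROSITE language
are not implemented.

## Alignment, minLrap/maxLrap, and orthology

Local alignment is optimal Smith–Waterman under BLOSUM62 with a linear
gap penalty of −8 per gapped position (delegated to
`Biostrings::pairwiseAlignment`; both matrix and penalties are
configurable). No e-values are computed — no Karlin–Altschul calibration
is attempted — so this layer filters on score, identity and coverage
only; e-values appear solely as upstream metadata in evidence tables.

`Lmatch` counts all alignment columns including gap columns (the
convention is ambiguous in platform practice, so it is documented and
switchable to match-columns-only). The coverage ratios are
`minLrap = Lmatch/min(L1, L2)` and `maxLrap = Lmatch/max(L1, L2)`; only
the minLrap formula is ever printed in the methods this package models,
but the three interpretive cases require a maxLrap, and the symmetric
completion is the only consistent reading. The classes are FULL
(both 1), PARTIAL (minLrap 1, maxLrap < 1) and POOR (both < 1), which
partition all outcomes.

Best hits maximize raw score with deterministic tie-breaking (higher
identity, then lexicographic subject id); a best score ≤ 0 means no hit.
BBH pairs are mutual best hits; homolog constraints (minLrap > 0.8,
identity > 30 %) and the essential-gene bound (minLrap > 0.5) are strict
as printed. The essential screen accepts a gene as "found" through
either the BBH+minLrap route or shared synteny-group membership, and
reduces exactly to the BBH criterion when the synteny map is empty.

COG assignment follows the BeT-counting scheme: one best hit per
reference genome, assignment when at least three BeTs (configurable)
share a COG. Multi-domain splitting is deliberately not implemented —
whole proteins only.

## Synteny and context scores

Synteny groups are maximal chains of ortholog pairs with monotone — or
uniformly reversed, for inverted blocks — index progression, with at most
`max_gap` (default 5) intervening genes on both genomes between
consecutive pairs. Chaining is greedy in pivot order with the direction
fixed by the first step, which makes output independent of gene labels.

Context association re-derives, from first principles, scores of the
kind a precomputed interaction database provides: a
neighborhood-conservation score (fraction of genomes containing both
families in which members lie within `max_dist = 3` gene indices on the
same strand — an operon-scale window) and a co-occurrence score (Jaccard
of phylogenetic-profile presence sets). When no genome contains both
families the neighborhood score is 0: absence of evidence is not treated
as evidence. Components combine as `1 − Π(1 − s_i)` — the standard
independent-evidence combination — and an association passes only when
the combined score strictly exceeds 0.4 (medium confidence). Gene-fusion
and text-mining channels are not modelled. Label transfer gives each
uncharacterized gene the majority label among partners on passing edges;
ties yield no call rather than an arbitrary pick.

## Rating-based ROC

Cases pair a binary truth label with an ordinal confidence rating
(declared scale, typically 2–5 as observed in curated data; no
re-mapping is applied). ROC points arise from the threshold family
"positive iff rating ≥ t"; the empirical area is the trapezoidal
integral, which equals the Mann–Whitney statistic
(concordant + ½ tied)/(n₁·n₀) and is therefore invariant under monotone
re-coding of the scale. Accuracy, sensitivity and specificity are
reported at an operating threshold; since the threshold behind published
single-number accuracies is generally unstated, the default is the
Youden-optimal one (ties toward the lower threshold) and the choice is a
parameter. Only the empirical curve is fitted — no binormal model, no
confidence intervals.

## The simulator: what it emulates, and what it does not

`simulate_genome_family()` evolves an ancestral proteome of ~50 genes
(~80-residue proteins) along a star topology: per-branch i.i.d. residue
substitutions (default 2 % per site), per-family losses (10 %), optional
duplications (off by default), and at most one inverted block per genome.
Defaults are desk-scale stand-ins for a real genus-level comparison
(eight genomes of ~2,700 genes): large enough for core/specific/synteny
structure to be non-trivial, small enough that the full pipeline runs in
seconds. Substitution-only evolution (no indels by default) is sufficient
to exercise the coverage-ratio and BBH machinery; it does *not* emulate
domain shuffling, horizontal transfer, paralog families, or length
variation, so passing tests show correctness of the bookkeeping, not
robustness to every real-data pathology. Function labels come from a
fixed vocabulary and decoy labels from a disjoint one, so "agreement" in
tests is unambiguous.

`simulate_evidence()` plants per-source correctness: each gene × source
emits the true label with `p_correct` (default 0.8, with e-values and
identities drawn to pass the filters), a decoy with `p_wrong` (0.1), or
nothing. `simulate_rating_cases()` draws ratings from per-class
distributions with a closed-form expected AUC
(`P(r₁ > r₀) + ½ P(r₁ = r₀)`); the defaults place positives mostly at
4–5 and negatives at 2–3, i.e. a well- but not perfectly separated tool.
Every generator derives an independent stream from the master seed, so
regenerating one input does not perturb another.

## Numerical choices and degenerate inputs

* All stated thresholds keep their printed strictness (>, <); the Pfam
  cut-off is inclusive (see above). None of them are tuned by the
  package.
* Ties are always resolved deterministically (lexicographic ids,
  lower thresholds, '+' before '−') so every run is reproducible.
* Empty inputs return empty, typed results (empty ORF list, NONE calls,
  empty ortholog tables); contract violations (overdrawn census moves,
  unmapped COG ids, mismatched profile lengths, single-class ROC input)
  raise errors naming the offending quantity.
* GC content excludes N from the denominator and errors on sequences
  with no unambiguous base.

## Problem sizes used in the tests

The validation suite runs the comparative stages on 4-genome families of
40 gene families (zero divergence and 0.05 substitutions/site),
essential screens on 20-family genomes with 3 planted deletions,
per-source accuracy recovery on 1,000 genes, ROC recovery on 2,000
cases, and oracle equivalences on exhaustive small enumerations
(alignments to length 10, 100 random motif scans, 50 rating sets, 20
random 2-kb ORF scans). These sizes were chosen so each property is
informative at desk scale; all of them are package choices visible in
the test code.

## Known limitations

* Alignment scores are raw; nothing is said about statistical
  significance of a single alignment.
* The consensus operationalization (token Jaccard) is a proxy for manual
  judgement; descriptions using unrelated synonyms will under-cluster.
* The synteny chainer allows one orientation per chain; nested or
  overlapping rearrangements fragment into several groups.
* The simulator's uniform substitution model has no rate heterogeneity;
  recovery results at a given divergence are optimistic relative to
  real proteins with conserved and variable regions.
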