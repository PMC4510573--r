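# reannotator

Manual re-annotation of a bacterial genome — reviewing every coding sequence
(CDS) against several independent annotation tools and promoting
hypothetical proteins to functions supported by the evidence — involves a
surprising amount of bespoke computation around the tools themselves:
evidence filtering, consensus voting, orthology and synteny bookkeeping,
and a statistical assessment of how trustworthy each tool is. `reannotator`
implements that computational layer as a tested R package, together with a
synthetic genome-family simulator so every stage can be validated against a
known ground truth.

It is aimed at microbial genomicists who curate genome annotations (the
motivating use case is a thermophilic, biomass-degrading,
hydrogen-producing *Caldicellulosiruptor*-style chromosome) and want the
numbers in a re-annotation report — category censuses, COG tables,
core-genome sizes, essential-gene screens, ROC summaries — to be
reproducible from code.

## What it computes

**Gene model and ORFs.** Maximal open reading frames in all six frames
(start codons ATG/GTG/TTG, stop included in the length), retained when
strictly longer than 60 nt, and named `<PREFIX>_0001`-style in start order.
Gene records carry one of five annotation categories: KNOWN, HYPOTHETICAL,
PUTATIVE, NEW, PSEUDOGENE.

**Evidence consensus.** Per-tool hits (PSI-BLAST, BLASTO, Pfam,
InterProScan, ANNIE style) are filtered — PSI-BLAST best hits need identity
> 40 % and e-value < 1e-52, Pfam-A hits an e-value ≤ 1e-02 — then voted
into a consensus function. The confidence level *k*/5 is the size of the
largest cluster of tools whose normalized descriptions mutually agree
(token Jaccard ≥ 0.6 by default), after removing intrinsic overlaps where
an integrated tool re-reports a member database's hit. Confident DEFINED
calls promote hypothetical/new/putative genes to KNOWN; motif-only or
"putative"-marked consensus yields PUTATIVE with a `putative ` product
prefix.

**PROSITE motif scanning.** A compiler and scanner for PROSITE-syntax
patterns (`[HQ]-E-G-P-N-V-F`, `C-x(2)-C`, exclusions `{P}`, anchors
`<`/`>`), reporting every overlapping match.

**Orthology and comparative genomics.** Smith–Waterman local alignment
(BLOSUM62, linear gap) with the alignment-coverage ratios

    minLrap = Lmatch / min(Lprot1, Lprot2)
    maxLrap = Lmatch / max(Lprot1, Lprot2)

classified FULL / PARTIAL / POOR; bidirectional best hits (BBH) as the
orthology proxy; homologs at minLrap > 0.8 and identity > 30 %; core and
genome-specific gene sets against a panel of genomes; essential-gene
screening against a minimal-gene-set reference (found iff BBH with minLrap
> 0.5 or shared synteny group); and COG assignment by genome-specific best
hits with the classical three-BeT cutoff, censused per functional category
with an old/new CDS split.

**Genomic context.** Synteny groups chained from ortholog pairs and gene
order (inversion-aware), neighborhood-conservation and co-occurrence
scores combined as `1 − Π(1 − s_i)` with a strict 0.4 medium-confidence
gate, and majority-label transfer to uncharacterized genes.

**ROC evaluation.** Rating-based empirical ROC for binary-truth cases with
ordinal confidence ratings: ROC points per rating threshold, trapezoidal
area (equal to the Mann–Whitney concordance), accuracy / sensitivity /
specificity at a Youden-optimal operating threshold, and cross-source
mean accuracy.

**Simulator.** `simulate_genome_family()` evolves an ancestral proteome
along a star topology with substitutions, losses, duplications and block
inversions; `simulate_evidence()` plants per-source correctness rates;
`simulate_rating_cases()` draws rating data with a closed-form expected
AUC. All generators are seed-deterministic.

## Worked example

```r
library(reannotator)

tsv <- system.file("extdata", "example_evidence.tsv", package = "reannotator")
ev <- filter_evidence(read_evidence_tsv(tsv))
consensus_calls(ev)
#>       cds_id                  consensus_description confidence call_class
#> 1 CALS8_0437 beta-xylosidase glycoside hydrolase 43          2    DEFINED
#> 2 CALS8_0732                     FMN-binding domain          1   PUTATIVE
#>   supporting_sources
#> 1   BLASTO;PSI_BLAST
#> 2               PFAM
```

`CALS8_0437` keeps two genuinely independent agreeing votes (2/5,
DEFINED): the InterProScan row re-reporting the same Pfam signature is
recognised as an intrinsic overlap and does not vote, and the Pfam and
ANNIE wordings differ too much from the alignment-tool consensus to join
its cluster. `CALS8_0732` has motif evidence only, so its call is
PUTATIVE. A third CDS in the file fails the PSI-BLAST best-hit filter
(identity 25 %) and produces no call at all.

```r
seq <- paste0(strrep("A", 188), "HEGPNVF", strrep("K", 5))
prosite_scan(seq, "[HQ]-E-G-P-N-V-F")
#>   start end
#> 1   189 195
```

The whole pipeline runs on a simulated genome family and writes a report
bundle (annotation TSV, before/after census JSON, COG table, core and
essential gene lists, context associations, ROC summary, Markdown
report):

```r
cfg <- run_config(sim = simulation_config(seed = 1))
res <- run_pipeline(cfg, "report")
```

A thin command-line wrapper with subcommands (`all`, `orfs`, `consensus`,
`scan`, `roc`) is installed at `inst/scripts/reannotator.R`.

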