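# svdosage

Structural variants (SVs) — presence/absence variants, copy-number
variants, inversions and translocations of ≥ 50 bp — act as *dosage
regulators* of nearby genes in plant pan-genomes: the presence of extra
sequence can suppress a gene's expression (typically through DNA
methylation of the inserted, often TE-derived sequence) or promote it
(typically by contributing transcription-factor binding sites).
`svdosage` implements this analysis end-to-end for pan-genome panels and
genotyped populations, for researchers studying crop domestication and
regulatory variation.

## What the package computes

For each SV and its closest gene within a 10-kb radius (the "SV gene"),
samples are split by a reference-free genotype: the allele carrying more
sequence is **presence**, the other **absence**.  With group mean TPMs
$\bar{x}_P$ and $\bar{x}_A$, the SV is called

* **suppressing** if $\bar{x}_A \ge 1.5\,\bar{x}_P$,
* **promoting** if $\bar{x}_P \ge 1.5\,\bar{x}_A$,

in panel mode (≥ 4 genomes per group, gene expressed at TPM ≥ 1 in > 60 %
of a group) or population mode (≥ 60 genotyped, ≥ 10 per group, TPM ≥ 5 in
> 30 % of samples, two-sided Mann–Whitney p < 0.05 required).  Around the
dosage core the package provides:

* nonredundant SV catalog construction (interval and breakpoint merging),
  genomic-context annotation, SV density profiles, TE overlap, private-SV
  statistics, saturation fitting $P(n) = A - B e^{-n/C}$, and the LTR
  insertion-time clock $T = K / (2r)$;
* regulatory signatures: CpG-island detection (≥ 200 bp, GC ≥ 0.5,
  obs/exp CpG ≥ 0.6), weighted methylation levels
  $\sum \text{meth} / \sum \text{total}$ over cytosines at depth ≥ 3,
  permutation tests, and IUPAC motif scanning with per-motif enrichment;
* pan-genome gene-family classification (core / softcore / dispensable /
  private), morphotype-specific loss and homoeolog-retention analyses;
* case–control SV-GWAS by two-tailed Fisher exact test with Bonferroni
  correction, top-fraction signal selection, two-SV haplotype groups,
  LD (r²) against SNPs, and cis/trans labelling of expression
  associations (20-kb window);
* a synthetic-data generator that plants suppressing/promoting SVs,
  CpG-island-bearing and motif-bearing sequences, methylation counts and a
  morphotype-structured population, so every stage can be validated
  against a known truth table.

## Worked example

```r
library(svdosage)

cfg <- simConfig(nGenes = 300, nSVs = 120, seed = 42)
b   <- simulatePanGenome(cfg)
b
#> SyntheticBundle: 300 genes, 120 SVs, 27 panel genomes
#>   planted: 36 suppressing, 30 promoting, 54 null

links <- linkSvToGene(bundleCatalog(b), bundleGenes(b), b@cds)
calls <- callDosagePanel(links, b@panelPresence, b@panelExpression)
table(calls$direction)
#>        none   promoting suppressing
#>          53          31          36

head(subset(calls, direction == "suppressing"),  3)[,
     c("svID", "geneID", "bin", "meanPresence", "meanAbsence", "foldRatio")]
#>      svID    geneID     bin meanPresence meanAbsence foldRatio
#> 1 sv00001 gene00002 0-1.5kb     8.748057    25.10179 0.3485033
#> 3 sv00003 gene00009     CDS     3.223799    20.77745 0.1551585
#> 6 sv00006 gene00017   3-5kb     4.507996    38.33491 0.1175951
```

Each row is one SV-gene pair: `sv00003` sits in a CDS, its six presence
genomes average 3.2 TPM against 20.8 TPM in the absence group — a
0.16-fold ratio, well past the 1.5-fold suppression rule.  Of 120 planted
SVs, 119 directions are recovered (99.2 %).  The split of 36 suppressing
vs 31 promoting calls is not significantly asymmetric here
(`asymmetryBinomial(36, 31)` = 0.63); at real study scale the same test
resolves thousands of calls.  The population half of the pipeline works
the same way through `simulatePopulation()`, `caseControlFisher()` and
`callDosagePopulation()`.

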