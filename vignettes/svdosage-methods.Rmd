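---
title: "Structural variants as dosage regulators of gene expression: methods"
author: "svdosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural variants as dosage regulators of gene expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdosage)
```

# The model

Structural variants (SVs) — presence/absence variants, copy-number variants,
inversions and translocations of at least 50 bp — frequently land in the
regulatory neighbourhood of genes.  `svdosage` implements an analysis of SVs
as *bidirectional dosage regulators* of expression: for every SV within
10 kb of a gene ("SV gene"), the panel of genomes or the population of
accessions is split into a **presence** group (carrying the longer,
sequence-bearing allele — an orientation that is independent of which genome
served as reference during calling) and an **absence** group, and the groups'
mean expression is compared.  An SV is

* **suppressing** when the absence group's mean TPM is at least 1.5-fold
  above the presence group's (the extra sequence lowers expression, the
  typical signature of a methylated, TE-derived insertion), and
* **promoting** when the presence group's mean is at least 1.5-fold above
  the absence group's (the extra sequence raises expression, e.g. by
  carrying transcription-factor binding sites).

The 1.5-fold rule is inclusive ("at least"), and group means — not medians —
are compared.  Two regulatory signatures distinguish the two directions:
suppressing SV sequences are enriched for highly methylated CpG islands,
promoting SV sequences for TF-binding motifs.  At population scale, SVs
strongly associated with a morphotype are found by case–control Fisher-exact
GWAS; the pan-genome context (core/softcore/dispensable/private gene
families, homoeolog retention) frames which genes are variable at all.

# Modes and eligibility filters

**Panel mode** (assembly panel, default 27 genomes) calls a direction from
group means alone.  Eligibility: exactly one SV within the 10-kb radius of
the gene, at least 4 genomes in the minority genotype group, and the gene
expressed (TPM ≥ 1 in strictly more than 60% of at least one group's
members).  With only 27 observations a formal test would be underpowered
against the fold rule, so the panel call is deliberately descriptive.

**Population mode** (default 704 accessions) additionally requires at least
60 genotyped accessions and at least 10 per genotype group, the population
expression rule (TPM ≥ 5 in strictly more than 30% of samples), and a
two-sided Mann–Whitney U test: a direction is assigned only when p < 0.05
*and* the fold rule holds, otherwise `none`.  Missing genotypes are excluded
per SV, never imputed.

Zero-mean edge cases are resolved deterministically: a zero denominator with
a positive numerator counts as an infinite ratio and qualifies; two zero
means give `none`.  This avoids pseudo-count bias at the fold boundary.

# Key parameters

All thresholds live in `analysisConfig()` and can be overridden there or via
a YAML file (`readAnalysisConfig()`):

| parameter | default | meaning |
|---|---|---|
| `linkRadiusBp` | 10 000 | SV-to-gene search radius (bp) |
| `contextFlankBp` | 3 000 | upstream/downstream context window (bp) |
| `foldThreshold` | 1.5 | inclusive dosage fold rule |
| `tpmMinPanel` / `fracMinPanel` | 1 / 0.60 | panel expressed rule (strict fraction) |
| `tpmMinPop` / `fracMinPop` | 5 / 0.30 | population expressed rule |
| `minGenomesPerGroup` | 4 | panel minority-group floor |
| `minGenotyped` / `minGroupSize` | 60 / 10 | population eligibility |
| `cisWindowBp` | 20 000 | cis/trans boundary for expression associations |
| `permNMethylation` / `permNTfbs` | 10 000 / 1 000 | permutation counts |
| `substitutionRate` | 1.3e-8 /site/yr | LTR insertion-time clock |
| `highMethylationThreshold` | 0.80 | "highly methylated" island cutoff |
| `minCpgDepth` | 3 | read-depth floor per cytosine |

# Design choices made where the design was open

* **Distance bins.**  SV-gene links fall into six bins: CDS, intron,
  0–1.5 kb, 1.5–3 kb, 3–5 kb, 5–10 kb.  Only the outer endpoints (CDS and
  5–10 kb) are fixed by the analysis design; the interior boundaries follow
  the natural 1.5/3/5 kb grid of the context windows and are kept in one
  place (`linkSvToGene`).
* **Merging rule.**  Same-type SV intervals that overlap *or are bookended*
  ("continuous") are unioned; carrier sets are unioned with them.
  Zero-width insertions merge when breakpoints lie within 10 bp and
  alternate lengths differ by ≤ 10% — a desk-scale proxy for clustering
  insertion sequences at 95% identity that needs no sequence material.
  Merging is idempotent and order-independent.
* **Context precedence.**  When an SV touches several features the label
  follows exon > intron > upstream > downstream > intergenic: coding impact
  outranks regulatory proximity.
* **CpG islands.**  The analysis adopts the Gardiner–Garden & Frommer
  criteria (≥ 200 bp, GC ≥ 0.50, observed/expected CpG ≥ 0.60) with a
  200-bp step-1 sliding window; qualifying windows are unioned into maximal
  islands.  The "highly methylated" cutoff (weighted methylation ≥ 0.80) is
  a configurable choice.
* **Weighted methylation** is a reads-weighted mean: total methylated CpG
  reads over total CpG reads across cytosines at depth ≥ 3, so pooling
  regions equals reads-weighted combination.
* **Motif matching** uses IUPAC consensus strings on both strands (all
  offsets, overlaps allowed), not position-weight matrices: a reproducible,
  dependency-free proxy for database TFBS scans.  Per-sequence hit counts
  are normalised per kb before the permutation contrast.
* **Two-sided exact tests.**  Fisher and binomial two-sided p-values sum all
  outcomes whose point probability does not exceed the observed one (the
  standard exact rule).  Association tables count *accessions*, not
  alleles; any genotype carrying at least one alternate allele counts as a
  carrier.  Bonferroni multiplies by the number of SVs actually tested.
* **Permutation p-values** use the add-one estimator
  (1 + #exceedances)/(1 + n), which never reports zero and is bounded below
  by 1/(n + 1).
* **Saturation model.**  Cumulative nonredundant SV counts over growing
  panels are fitted with P(n) = A − B·exp(−n/C) by Levenberg–Marquardt
  least squares over random genome orderings; the predicted total is the
  mean asymptote A and its spread across orderings the uncertainty.  The
  exponential form is a documented choice; constant (already saturated)
  curves short-circuit to A equal to the observed count.
* **Pan-class bands** generalise beyond 27 genomes as: core = all,
  softcore = at least ⌈0.9·n⌉ but not all, private = exactly one,
  dispensable = the rest.  "Retained in > 50%" is strict (14 of 27
  qualifies, 13 does not), and a morphotype-specific loss needs strictly
  more than 70% of losing genomes in one morphotype.
* **Coordinates.**  Internally everything is a `GRanges` (1-based, closed
  intervals); pure insertions are zero-width breakpoints.  The VCF dialect
  states its convention in the header (POS = first affected base,
  END = last, insertions END = POS − 1).

# The synthetic-data generator

Because the original panel and population data are external, every stage is
exercised on synthetic data with a *planted truth table*
(`simulatePanGenome()`, `simulatePopulation()`, `simulateMethylome()`).
The generator emulates the study's statistical structure:

* dimensions: 27 panel genomes, 704 accessions whose morphotype composition
  matches the surveyed germplasm (310 cabbage, 153 cauliflower, 63
  broccoli, …, 18 ornamental kale);
* one insertion SV per selected gene, placed across all six distance bins,
  strand-aware on either flank, with 4–23 carrier genomes;
* planted directions — 30% suppressing, 25% promoting, the rest null —
  with folds drawn uniformly from 1.5–10, matching the observed range of
  expression fold changes and the observed excess of suppression;
* expression: per-gene log-normal baselines times multiplicative log-normal
  noise with CV 0.3 (strictly positive TPMs with realistic spread); carrier
  group means are multiplied or divided by the planted fold — a simple,
  invertible ground truth;
* sequences: suppressing SVs carry an embedded 250–400 bp CpG-island
  segment; promoting SVs carry 4–8 embedded copies of a small synthetic
  IUPAC motif panel labelled by familiar TF families (TCP, MYB, NAC, ERF,
  GRAS); null SVs are plain background at 36% GC;
* methylation: CpG sites inside planted islands draw Beta-distributed
  levels around 0.9, background sites around 0.1, at Poisson(30) depth;
* population genotypes: per-SV Beta(2, 2) presence frequencies independent
  of morphotype, except planted morphotype-exclusive SVs (present in every
  accession of one morphotype, absent elsewhere — mirroring the
  ornamental-kale example); calls are masked to missing at 5% by default;
* genotypes are generated directly at accession level
  (presence/absence/missing) — the analysis counts accessions, not alleles,
  so a diploid layer would add nothing the pipeline reads.

All draws flow from a single integer seed; equal configurations yield
byte-identical bundles, and `writeBundle()` emits the whole experiment as a
deterministic fixture directory (VCF/GFF3/TSV/FASTA) that round-trips
through the package's readers.

What the generator does **not** emulate: read-level data, linkage between
SVs, population structure and kinship, expression covariates, chromosome-
scale sequence evolution, and CHG/CHH methylation contexts.  Passing the
recovery tests therefore demonstrates that the statistical machinery is
correct and calibrated — not that real data meet the generator's
independence assumptions.

# Numerical verification

The test suite checks every exact statistic against an independent
brute-force oracle (hypergeometric and binomial enumeration, sweep-line
interval union, per-base overlap, exhaustive window scans, naive motif
scanning) and the pipeline against the planted truth.  Problem sizes were
chosen to keep the default suite around a minute: truth-table recovery runs
at 27 genomes × 2 000 genes × 600 SVs (panel) and 704 accessions × 200 SVs
(population); null calibration uses 200 replicates at 199 permutations.
At those sizes panel dosage calls recover ≥ 90% of planted directions for
folds ≥ 2 with ≥ 10 genomes per group, mislabel ≤ 20% of planted nulls,
and the null rejection rates sit within 0.05 ± 0.02.

# Known limitations

* Panel-mode calls carry no p-value; they are threshold classifications.
* TE overlap of a pure insertion is 0 by construction (the alternate allele
  is not TE-annotated), which understates TE involvement for insertions.
* The eGWAS model fit itself (mixed-model association) is out of scope;
  `classifyCisTrans()` consumes an external association table.
* The insertion-merging proxy can split true duplicates whose breakpoints
  are misplaced by more than 10 bp, and cannot use sequence identity.
* `ldR2()` treats dosages as numeric and ignores phasing.
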