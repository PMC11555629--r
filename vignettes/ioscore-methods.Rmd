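---
title: "Paired expression-ratio scoring across species: methods and design"
author: "IOscore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired expression-ratio scoring across species: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IOscore)
```

## The problem

Sequentially hermaphroditic (protogynous) fishes replace ovarian tissue
with testicular tissue during sex change. Gonadal RNA-seq studies of this
transition exist for several species, but they come from different
laboratories, platforms and designs, so classical count-based differential
expression models (which assume comparable library structure, and whose
batch corrections need within-batch replication) are a poor fit for a
cross-species synthesis. IOscore implements a deliberately simple,
batch-robust alternative: all inference is built from *within-pair
expression ratios*, where each curated pair consists of one intersexual
(transitional) gonad sample and one ovary sample from the same study.

## The scoring model

For a transcript in one curated pair, the **IO-ratio** is

$$\mathrm{IOratio} = \log_2(\mathrm{TPM}_{intersexual} + c) -
  \log_2(\mathrm{TPM}_{ovary} + c),$$

with pseudocount $c = 0.01$ TPM (units of TPM; keeps the ratio finite at
zero expression while being far below biologically meaningful abundance).
A pair is *upregulated* when the IO-ratio strictly exceeds $\log_2 5$,
*downregulated* when strictly below $-\log_2 5$ (a 0.2-fold change), and
*unchanged* otherwise. Two boundary decisions deserve note:

* **Strict inequalities.** A ratio exactly at $\pm\log_2 5$ is unchanged.
  The cutoff is stated as a strict inequality, and ties at an irrational
  boundary occur with probability zero on real data, so this choice only
  matters for adversarial inputs; it is documented and tested.
* **The 5-fold cutoff** is a tunable `ScoringParams` field. The package
  provides `ratioSdDiagnostic()`, which pools all IO-ratios of a species
  and reports `fold_at_2sd` $= 2^{2\hat\sigma}$, the fold change at the
  +2 SD boundary of the empirical ratio distribution, so users can judge
  the cutoff against their own data's dispersion. The diagnostic pools all
  transcripts and pairs of a species into one statistic; an
  `expressedOnly` switch excludes transcripts whose every ratio is exactly
  zero, with no claim that either variant is canonical.

Per species, a transcript's **IO-score** is the count of upregulated pairs
minus the count of downregulated pairs — an integer bounded by the
species' pair count. Because every quantity is a within-pair contrast,
between-study scale and batch differences cancel to first order; this is
the design's central assumption, and its cost is that it discards
magnitude information beyond the threshold crossing.

## Orthology and aggregation

Cross-species aggregation requires a common gene universe. The package
consumes 12-column tabular protein homology searches (BLAST/Diamond
"outfmt 6") between each species and a designated **hub species**, applies
the e-value cutoff (default $10^{-3}$) at parse time so both directions
see the same filtered universe, and resolves **reciprocal best hits**
(RBH): the pair $(h, s)$ is kept iff each is the other's best hit. Best
hits maximise bitscore; ties break by lower e-value, then longer
alignment, then lexicographically smallest subject id. The tie hierarchy
is our own deterministic convention — homology-search practice fixes only
the score — and multiple HSPs of a (query, subject) pair are collapsed to
their strongest record first. RBH gives a 1:1 map by construction
(enforced by the `RBHMap` validity method); many-to-many paralogy is
explicitly out of scope.

RBH maps are consolidated on hub protein ids into `OrthologSet` groups; a
group is **common** iff every non-hub species contributes a member, and
only common groups enter aggregation. The **total IO-score** of a common
ortholog is the sum of its per-species IO-scores. Members without
expression data contribute 0 and flag the record (callers preferring to
drop such groups can filter on the flag; a `strict` mode errors instead).

The calling threshold is derived, not tuned: it is
$\lceil f \cdot N \rceil$ where $N$ is the study-wide curated pair count
and $f = 0.2$, i.e. 20% of the attainable maximum total. With the default
study design's 31 pairs this yields $\pm 7$. Totals exactly at the
threshold are called — "thresholds employed to identify" reads naturally
as inclusive, and an exclusive rule would make the boundary value
unreachable evidence. Both the fraction-of-maximum reading and boundary
inclusion are interpretive choices; they are centralised in
`deriveTotalThreshold()` and `callDEGs()` and covered by tests.

## The synthetic study generator

No public data ships with the package. `simParams()` /
`simulateUniverse()` / `simulateExpression()` generate a complete study
whose default shape mirrors a seven-species protogynous-fish meta-analysis:
per-species pair counts (4, 2, 2, 6, 2, 12, 3) summing to 31, 5000
orthologs, non-hub retention probability 0.9, 1% of orthologs planted up
and 1% down at 25-fold, log-normal baselines ($\log_2$ mean 5, SD 2),
intersexual log2 noise SD 0.25, dropout 0.02, and 200 decoy paralogs per
species. The 25-fold planted effect with 0.25 noise SD puts planted pairs
at $P(\mathcal N(\log_2 25,\ 0.25) > \log_2 5) \approx 1 - 6\times
10^{-21}$ of clearing the cutoff, so recovery failures indicate pipeline
defects, not simulation bad luck; the dropout rate is what injects
realistic label noise.

Generator mechanics worth knowing:

* The ovary sample of a pair carries the per-(transcript, pair) baseline
  exactly; the intersexual sample multiplies in the planted effect and the
  multiplicative noise. Hence the IO-ratio of a null transcript is
  $\mathcal N(0, \sigma_{noise})$ up to pseudocount distortion, which is
  what makes the `fold_at_2sd` diagnostic analytically checkable (noise SD
  1.161 puts it at 5.0).
* TPMs are **not** renormalised to sum to $10^6$ per sample. Scoring uses
  within-transcript ratios only, and renormalisation would couple
  transcripts, obscuring planted truth. This is a documented deviation
  from real quantifier output.
* Decoy paralogs hit a random true group at a bitscore drawn strictly
  below 0.9 of the true pair's, so best hits stay unambiguous unless
  ambiguity is requested via `fracBreakReciprocity`: that fraction of
  decoys outscores the true partner in the hub-to-species direction while
  pointing at a different hub protein in the reverse direction, which
  removes the target group from the RBH set without creating a false pair.
* One master seed drives everything; per-species substreams are derived
  deterministically from it, so identical `SimParams` give byte-identical
  bundles (`writeFixtureBundle()` is pure formatting).

What the generator does **not** emulate: real quant.sf files from reads
(lengths and read counts are plausible placeholders), isoform structure,
library-size or batch artefacts beyond log-normal noise, many-to-many
paralogy, and correlated dropout. Passing recovery tests therefore
demonstrate the pipeline's correctness on data satisfying the scoring
model's assumptions; they cannot certify behaviour under, say, systematic
3' bias or partial ortholog misassignment.

## Numerical and validation choices

All arithmetic is double precision; report files round ratios to 6
decimals at formatting time only. Problem sizes in the test suite are
chosen for statistical interpretability: oracle-equivalence checks run the
best-hit/RBH implementation against an independent brute-force enumeration
on 100 random instances with deliberately tie-heavy scores; recovery and
null-control checks run the full default study (5000 orthologs, 31 pairs)
over 10 seeds each, requiring precision and recall at least 0.9 for both
directions and a null call rate below 1%. The binomial retention model of
the universe (common count $\sim \mathrm{Bin}(n, p^{S-1})$) is verified
against its closed form over 50 seeds.

## Limitations

The method trades power for robustness: single-species signals can reach
the total threshold only via a large pair count in that species (such
calls are flagged `single_species`), unchanged calls near the boundary are
sensitive to the arbitrary 20% fraction, and the RBH universe restricts
inference to genes with 1:1 orthologs in *every* species — genes missing
from one assembly are silently out of scope, which is a feature for
comparability and a caveat for coverage.
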