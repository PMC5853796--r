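---
title: "Hexamer association meta-analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hexamer association meta-analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexameta)
```

## The problem and the model

Transcription factors read short degenerate DNA words. When a hormone such
as auxin reshapes the transcriptome, the binding words of the factors that
mediate the response should be over-represented in the upstream regions of
the responding genes — and, crucially, over-represented *recurrently*
across many independent expression experiments, because any single
experiment's differentially expressed gene (DEG) list is noisy and
condition-specific. hexameta implements that idea as a three-stage
pipeline over canonical hexamers:

1. **Scan.** Every gene's TSS-anchored upstream window (default 1501 bp:
   1500 upstream bases plus the TSS base) is scanned for all 4096
   hexamers. Since double-stranded binding is strand-symmetric, a hexamer
   and its reverse complement are one analysis unit; the 4096 words
   collapse to 2080 canonical classes (2016 complementary pairs + 64
   palindromes), each represented by the lexicographically smaller member.
   The gene-level feature is *presence*: the class occurs at least once in
   the window.

2. **Associate and combine.** For each data set $i$, hexamer $h$ and
   status $s \in \{\text{up}, \text{down}\}$, a $2 \times 2$ table over
   the data set's gene universe (presence × status) is tested with the
   one-sided Fisher exact test for over-representation, giving $P_i$. The
   per-dataset p-values are combined with Fisher's method,
   $\chi^2_{2k} = -2 \sum_{i=1}^{k} \ln P_i$, and the meta p-value is the
   upper tail of the $\chi^2$ distribution with $2k$ degrees of freedom.
   Hexamers with Bonferroni-corrected meta p below 0.005 (family: 2080
   classes × 2 statuses by default) pass the screen.

3. **Permute.** The $\chi^2$ null assumes the $P_i$ are independent and
   uniform. Neither is true: the same genes recur as DEGs across data
   sets, presence indicators of overlapping hexamers are strongly
   correlated, and exact tests are discrete. The empirical answer is a
   promoter-shuffling permutation test: in each of $M$ iterations one
   random bijection reassigns promoters to genes (each promoter used
   exactly once) — a single shared permutation per iteration, for all
   hexamers and data sets, so all dependence is preserved — and stages 1–2
   are recomputed. Since scanning is permutation-invariant, shuffling the
   presence-matrix rows is mathematically identical to re-scanning and is
   what the implementation does. The empirical p-value is
   $(m + 1)/(M + 1)$ with $m$ the number of permutation statistics not
   greater than (i.e. $\le$) the observed meta p.

## Multiplicity at the permutation stage

The family-wise adjustment of the permutation p-values was a genuinely
open design point, and the naive options fail in instructive ways:

* **Explicit Bonferroni over the full family** (2080 × 2 tests) is
  coherent only when $M \gg n_{\text{tests}}/\alpha$: the smallest
  reachable corrected value is $n_{\text{tests}}/(M+1)$, which exceeds
  0.005 for any $M$ below ~832 000. It is offered
  (`run_pipeline(perm_method = "bonferroni")`) for very large $M$, where
  significance effectively means $m = 0$.
* **No correction** ("the screen already paid the multiplicity") is
  unsound: the screen's winner is the minimum of thousands of dependent
  tests, so it is extreme against its *own* permutation null as well. On
  fully null cohorts this confirms a false positive in roughly half the
  replicates in which anything passes the screen — we measured exactly
  that.

The default is therefore the **Westfall–Young minP adjustment**: each
iteration records the *family minimum* of the permuted meta p-values over
all 2080 hexamers × both statuses, and a hypothesis's $m$ counts the
iterations whose family minimum reaches its observed meta p. The result is
a family-wise adjusted empirical p-value that is exact under the
permutation null, exploits the dependence between overlapping hexamers
(less conservative than Bonferroni), and stays informative at moderate
$M$: its floor is $1/(M+1)$, so $M = 200$ already resolves the 0.005
threshold. On null cohorts the pipeline's family-wise false-selection rate
is then the nominal one (measured ≈0–0.5% per cohort at $\alpha = 0.005$).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_len` | 1501 bp | upstream window; the interval notation is ambiguous about including one transcribed base, so the length is a parameter rather than a constant |
| `alpha` | 0.005 | strict threshold on Bonferroni meta p (screen) and adjusted permutation p (selection) |
| `n_tests` | 2080 × 2 | meta-screen Bonferroni family |
| `M` | 1000 | permutations; raise towards 10^6 for publication-grade tails (`method = "per_hexamer"` then becomes usable) |
| `fwer` | 0.05 | threshold for the positional (peak / chromatin-state) enrichment tests |
| `min_degs` | 10 | a data set must contain at least this many DEGs (inclusive) |
| `boundary_h` | 2 h | early/late split; the boundary is counted as early (`early_inclusive = TRUE`), configurable |
| `respect_mask` | FALSE | lowercase (soft-masked) letters are ordinary bases by default; when set, masked windows are invalid, supporting analyses of repeat-masked promoters without re-running a masker |

DEG calling from fold changes and adjusted p-values uses FDR < 0.05
(Benjamini–Yekutieli, via `stats::p.adjust`) with linear fold change
> 3/2 (up) or < 2/3 (down); both thresholds are arguments of
`call_degs()`.

## Positional enrichment analyses

Peak and chromatin-state analyses compare *occupancy* proportions: the
number of 6-bp start positions a canonical class occupies across a
sequence set, over the total number of valid positions. Windows containing
`N` (or masked letters under `respect_mask`) are removed from both
numerator and denominator so the two proportions stay comparable.
Overlapping peaks are merged before counting so no position is counted
twice. Foreground (peak or state-segment occupancy) versus background (all
promoter windows, or the control genes' segments of the same state) is
tested with the same one-sided Fisher exact test, Bonferroni-corrected
over the hexamers (× states) tested, significant at FWER < 0.05. The
chromatin-state association variant simply feeds the 9 per-gene state
indicators through the association + permutation machinery in place of the
2080 hexamer indicators.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` draws i.i.d. promoter sequence at a configurable GC
content (default 0.36, a plant-genome-like value), assigns each gene a
latent status (`up`/`down`/`none`) and per-dataset statuses that copy the
latent label with probability `deg_overlap` (default 0.7) and are redrawn
from the marginal otherwise — reproducing the cross-dataset recurrence of
truly responsive genes. Motifs are planted by *replacing* six bases at a
uniform position (random orientation) with probability `p_fg` in genes
holding the target status in at least one data set and `p_bg` otherwise,
so all windows keep their length. Peaks of configurable width are centered
on a configurable fraction of planted instances; chromatin states tile
each promoter in exponential-length blocks with per-state composition
biases. A toy two-chromosome genome with genes on both strands, GFF3
models, DEG TSVs, BED interval sets and a ground-truth table are emitted
in the standard formats.

Deliberately not emulated: read-level noise, microarray intensity models,
positional preference of real motifs (planting is uniform within the
window), genome composition beyond a single GC parameter, and linkage
between neighbouring genes. Passing recovery tests on these cohorts
therefore demonstrates the statistical machinery — calibration, FWER
control, power at a known effect size — not performance on real
chromatin.

One quantitative lesson from the generator is worth stating because it
shapes what "power" means here: in a 1501-bp window a typical hexamer is
*already present by chance* in roughly 40–50% of promoters
(`expected_presence_rate()` gives the closed form). Planting at
`p_fg = 0.5` vs `p_bg = 0.1` therefore yields a realized presence odds
ratio near 2.7, not the naive 9, and with three data sets of ~160 DEGs the
recovery probability of the full pipeline at $M = 200$ sits near 93–95%,
not at 100%: a ~2σ downward fluctuation of the shared planting realization
occasionally leaves the planted hexamer just above the screen threshold or
within reach of the permuted family minima. Longer gene-level features, more
data sets, or presence defined on smaller windows would all raise power.

## Numerical choices and degenerate inputs

* Fisher exact p-values are computed as exact hypergeometric upper tails
  (`stats::phyper`); the all-zero table returns 1.
* `fisher_method()` clamps an exact zero input to the smallest positive
  double with a warning (exact test p-values can never be zero; the clamp
  only guards user-supplied lists).
* Sequences shorter than 6 bp contribute zero windows; fully masked
  promoters yield empty presence sets; an empty enrichment foreground
  returns p = 1 with a `degenerate` flag.
* Ties in the permutation statistic are counted inclusively (`<=`),
  making the empirical p-value conservative on ties, never liberal.
* Selection thresholds are strict inequalities (`< 0.005`, FWER
  `< 0.05`).
* All randomness flows through explicit integer seeds; a fixed seed makes
  simulation output byte-identical and permutation tables bit-identical.

## Problem sizes used in the shipped analyses

The analysis scripts and recovery checks run at 2000 genes × 1501 bp × 3
data sets with $M$ between 200 and 1000, and the region analyses at a few
hundred genes with 150–400-bp windows — sizes chosen so a complete run of
every script and test finishes on a laptop-class single core in minutes
while leaving every statistical property measurable. All of them scale
linearly in genes × window and in $M$; the per-permutation cost is one
pass over the presence matrix per data set and status.

## Known limitations

* Only $k = 6$ words are first-class; no IUPAC degenerate matching, motif
  alignment or width extension.
* Depletion (under-representation) is not tested; the one-sided
  alternative is over-representation throughout.
* The occupancy tests treat window positions as independent Bernoulli
  draws; for highly autocorrelated words (homopolymers) the exact test on
  position counts is approximate. The Bonferroni threshold absorbs this in
  practice (measured family-wise false-positive rate on random peaks ≈
  nominal), but p-values for such words should be read with care.
* The meta screen alone is anti-conservative when DEG sets recur across
  data sets; its output is a shortlist, and only the permutation-adjusted
  p-values are reported as significant.
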