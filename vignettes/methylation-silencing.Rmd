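---
title: "Identifying genes silenced by CpG-island methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying genes silenced by CpG-island methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylsilence)
library(dplyr)
```

## The question the package answers

Promoter hypermethylation is pervasive in cancer, but observing a
hypermethylated CpG island does not by itself show that the gene is
silenced *by* that methylation: many heavily methylated genes are
expressed normally, and many silent genes are silent for other reasons.
methylsilence implements a contingency-based procedure for deciding, from
paired methylation and expression array data, *how much* differential
island methylation is needed before the association with reduced
expression stops looking like chance — and then calls the genes that
clear that data-driven bar.

The intended setting is a hypomethylated reference sample (in germ cell
tumour work, a seminoma-like cell line) compared against one or more
hypermethylated targets (yolk sac tumour-, embryonal carcinoma- or
teratoma-like lines), with Illumina 450K-style beta values on the
methylation side and normalized expression-array intensities on the
expression side.

## The procedure, step by step

**Probe QC** (`qc_filter()`). Probes are removed when their mean
detection p across samples is strictly above 0.05, when their averaged
log2 signal intensity falls strictly below 11.1 in either channel, when
they map to multiple genomic sites, or when they are annotated to more
than one gene. Samples with a bisulfite conversion ratio at or above 0.2
are flagged but never dropped: a conversion problem taints the whole
sample, and silently removing it would change every downstream
comparison. The boundary conventions (retain at exactly 0.05 and exactly
11.1) follow the filtering rules as stated rather than rounding them.

**Gene-level methylation** (`gene_island_beta()`). For each gene and
sample, the island-probe beta values are averaged in two pools: a
TSS-associated pool (island probes annotated TSS1500, TSS200, 5'UTR or
first exon — i.e. within 1,500 bp upstream of the TSS or in the 5'
UTR/first exon) and a gene-body pool. A gene with several qualifying
islands contributes all of their CpGs to one unweighted mean rather than
an island-wise mean of means; a two-probe island should not carry the
same weight as a ten-probe island, and the CpG-wise pooling matches the
"average across all CpGs analysed" definition of the gene score. Missing
betas are excluded from the mean — never imputed as 0, which is a valid
biological value.

**Differential methylation** (`delta_beta()`). Per gene, target sample
and region basis, delta-beta is the target island mean minus the
reference island mean, kept signed. Negative values (reference more
methylated) are legitimate biology but belong in a reciprocal analysis;
`bin_delta_beta()` sets them aside rather than folding them into the
positive bins.

**Expression side** (`background_filter()`, `fold_changes()`). Genes
below the per-sample background threshold in *every* sample are removed;
everything else is kept, because a gene expressed in even one line is
informative about silencing in the others. Fold changes are computed on
the normalized linear scale as larger/smaller (always at least 1) with a
direction label, and a gene is differentially expressed at the
conventional 2-fold cutoff, inclusive. Genes without expression data
cannot enter any category and are excluded from the contingency table.

**The contingency analysis** (`contingency_table()`,
`select_threshold()`). Non-negative delta-beta values are binned at
width 0.05 (half-open bins, closed top bin at 1.0). Each bin is crossed
with three expression categories — at least 2-fold lower in the target
("correlating" with its hypermethylation), no 2-fold difference, and at
least 2-fold higher ("anti-correlating"). Expected counts come from the
table-wide marginals under the null hypothesis that lower expression
does not correlate with methylation, and each bin is tested with a
Pearson chi-square on 2 degrees of freedom, no continuity correction —
this recomputes the published table's expected counts to within 0.01 and
its p-values to the printed digit. A bin *qualifies* when the observed
correlating count is at least twice its expectation **and** p < 0.05;
the selected delta-beta threshold is the lower bound of the lowest
qualifying bin. On the published yolk-sac-tumour vs seminoma table this
rule lands on 0.65, and removing that bin moves it to 0.70 — the value
the embryonal carcinoma and teratoma comparisons reach.

**Silenced-gene calls** (`classify_silenced()`). A gene is called
silenced when its delta-beta reaches the selected cutoff (inclusive) and
its expression is at least 2-fold higher in the reference. Calls are
made on both the TSS and the body basis; body calls where the gene has
no TSS island aggregate, or a TSS delta-beta below the cut, carry a
`body_only` flag, because body-island methylation correlating with
silencing (rather than the activity reported in other tissues) is a
finding worth keeping visible.

**Validation arms.** `concordance_with_primary()` checks calls against
external per-gene fold-change tables (strictly more than 1.5-fold in
the same direction, case-insensitive exact symbol matching; unmatched
genes are "not assessable" and excluded from both numerator and
denominator). `binomial_overlap()` gives the one-sided binomial tail
for set overlaps, computed in log space so values around 1e-30 survive;
because the published universe sizes behind such bounds are not
recoverable, the null rate p0 is always recorded alongside the result.
`pfaffl_ratio()` implements efficiency-corrected relative quantification,
E_t^dCt_t / E_r^dCt_r with dCt = mean Ct(control) − mean Ct(treated),
for demethylation-reactivation qPCR; `reactivation_test()` attaches a
bootstrap p-value by resampling replicates within each gene-by-condition
cell, since no closed-form test is standard for the ratio itself.

## Boundary and tie conventions

Published boundary conventions are not always internally consistent, so
the package fixes them once, configurably:

* a CpG or gene is **methylated at beta ≥ 0.6** (inclusive) and
  unmethylated below 0.3; sources alternate between ">0.6" and "⩾0.6",
  and the inclusive reading is used everywhere for consistency;
* the silencing filter applies **delta-beta ≥ cut** (inclusive), for the
  same reason;
* delta-beta bins are half-open `[k·w, (k+1)·w)`; a delta of exactly
  1.0 joins the top bin;
* shore/shelf bands are half-open `(0, 2000]` / `(2000, 4000]` bp from
  the nearest island edge, so a probe exactly 2,000 bp out is a shore;
  north/south is assigned 5'/3' of the associated gene, strand-aware;
* bin bounds are rounded to 10 decimals so bins computed in different
  places join exactly despite floating-point multiples of 0.05;
* empty bins are retained with zero counts and an undefined p-value,
  never silently dropped;
* chi-square cells with zero expectation contribute zero when the
  observed count is also zero (structurally empty category) and
  infinity otherwise.

One print-precision artifact is worth recording: the published 0.40-0.45
bin recomputes to p = 0.00100, which the table prints as "0.001" but
stars as p < 0.001; the recomputed value sits exactly on the star
boundary, so the package's stars (`**`) disagree with the printed stars
on that one row while agreeing with the printed p-value itself.

## CpG island discovery

`find_cpg_islands()` implements the classical sliding-window definition:
a 500 bp window qualifies with GC fraction above 0.55 and
observed/expected CpG ratio above 0.65, where O/E = count(CG)·L /
(count(C)·count(G)). Qualifying windows (step 1) are merged when they
overlap or touch; each merged interval is then re-tested as a whole and
trimmed one base from each end per round until it satisfies both
criteria or shrinks below 500 bp. Merging alone can dilute a core below
the thresholds, and trimming from both ends is the simplest symmetric
rule that restores them; it is deliberately conservative and can discard
an off-centre sub-interval that a directed search would keep. Windows
containing N never qualify. The annotation used by the array pipeline
normally comes from the manifest; the finder exists so the same
criteria can be applied to arbitrary sequence (e.g. when characterizing
a candidate gene's promoter).

## What the synthetic generator emulates — and what it does not

`simulate_methylome()` / `simulate_expression()` / `simulate_qpcr()`
exist so the whole pipeline can be tested against a known ground truth.
The generator plants:

* per-gene TSS islands (4-10 probes) and, for 60% of genes, a body
  island, with shore/shelf/open-sea probes at the annotation distance
  bands on one synthetic chromosome;
* island beta values from a Beta distribution with mean 0.1 in the
  hypomethylated reference (shores intermediate at mean 0.5, shelves
  and open sea methylated at mean 0.8, the pattern seen on real
  arrays where islands are the hypomethylated compartment);
* hypermethylation in 10% of TSS islands (5% of body islands) of the
  target lines, with the island-mean delta-beta drawn uniformly from
  0.65-0.9 — the effect range where the real analysis finds its
  threshold — and probe draws recentred so the realized island-mean
  effect equals the planted one (capped so no beta exceeds 1);
* silencing in half of the hypermethylated genes ("about half" of
  differentially methylated genes showing a correlating expression
  loss is the observed structure), with true fold changes log-uniform
  on 2-50 and multiplicative log-normal expression noise at CV 0.2;
* qPCR reactivation as a 3-cycle Ct drop with 0.2-cycle replicate
  noise against a stable ACTB reference.

Each dataset draws from its own RNG stream keyed by (seed, dataset
name), so generating an extra dataset never perturbs an existing one.

The generator does **not** emulate array chemistry (type I/II probe
differences, M/U intensities), batch effects, copy-number confounding,
cell-line heterogeneity, or any dependence between neighbouring genes.
A pipeline that recovers planted effects here is therefore shown to be
*correct* (it computes what it claims from data matching its
assumptions), not shown to be robust to real-array artifacts — that is
what the QC inputs and the cross-study arm are for. Beta-distributed
probe noise is the standard two-parameter model for beta values; no
quantitative replicate-noise model is published for this design, so the
defaults are generator conventions, not claims about the source data.

## Problem sizes and test design

The recovery analysis used in the tests and the acceptance script runs
2,000 genes (roughly 20,000 probes), one target line, effects drawn from
delta-beta 0.7-0.9, silenced folds 3-10 and expression CV 0.1 — strong,
cleanly separated effects, where the pipeline should and does reach
sensitivity ≥ 0.9 at a false-discovery proportion ≤ 0.1 with the
threshold found at 0.70. With all effect fractions set to zero the
threshold search must find no qualifying bin, and does. The published
contingency table itself is the primary worked example: every derived
quantity on it is deterministic and recomputes in milliseconds.

## Known limitations

* The gene score trusts the manifest's gene-region labels; it does not
  recompute TSS distances from coordinates, so manifest annotation
  errors propagate.
* Fold changes on two single arrays have no replicate variance; the
  2-fold rule is a convention, not a test, and the chi-square machinery
  quantifies only the aggregate association per bin.
* Symbol-level matching in the cross-study arm loses genes whose
  aliases differ between platforms; misses are reported as not
  assessable rather than resolved.
* The bootstrap reactivation p is granular for 3 replicates (its
  resolution is limited by 3^12 distinct resample combinations) and is
  intended as a supporting statistic, not a primary endpoint.
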