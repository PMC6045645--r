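---
title: "Beta-binomial differential methylation: model, calibration and design notes"
author: "betameth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-binomial differential methylation: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betameth)
```

## The problem

Bisulfite sequencing reports, per cytosine and per sample, the number of
reads supporting methylation (`k`) out of the reads covering the position
(`N`). In a two-condition RRBS design with a handful of biological
replicates, the question "which CpGs changed methylation?" has to cope with
two nested noise sources: the binomial sampling of reads given a replicate's
true methylation level, and the biological variation of that level between
replicates. Rate-based tests on `k/N` conflate the two and are biased by
uneven coverage; the count model used here keeps them separate.

## Model and test

Per CpG and replicate,

$$k \sim \mathrm{Binomial}(N, p), \qquad p \sim \mathrm{Beta}(\alpha, \beta),$$

with the marginal beta-binomial log-likelihood
$\log \binom{N}{k} + \log B(k+\alpha,\, N-k+\beta) - \log B(\alpha, \beta)$.
We reparameterize as mean $\mu = \alpha/(\alpha+\beta)$ and precision
$\varphi = \alpha+\beta$ and maximize over $(\mathrm{logit}\,\mu, \log\varphi)$
with analytic gradients (L-BFGS-B; method-of-moments start; a Nelder–Mead
polish catches the occasional line-search abort on dispersion profiles that
are nearly flat). Both cytosines of a CpG are strand-merged before fitting, so
one CpG contributes one `(k, N)` pair per sample.

The per-CpG test compares a pooled fit (one $(\mu,\varphi)$ for all samples)
against per-group fits, with $\Lambda = 2(\ell_\text{alt} - \ell_\text{null})$
referred to $\chi^2_2$ (both mean and dispersion freed per group). A shared-
dispersion alternative ($\chi^2_1$, `df_mode = "shared_dispersion"`) is
available; it concentrates the likelihood gain on the mean difference and is
more powerful, but chi-square asymptotics with six observations are less
reliable for it, so the 2-df variant is the default. The effect size
`delta` is the difference of the fitted group means, not of raw count
ratios.

Because single-CpG evidence at 3-vs-3 and ~30x coverage is intrinsically
weak, the chain borrows strength from local coherence: per-site p-values are
combined over all sites within ±`window_bp` (default 200 bp) by Stouffer's
method with equal weights, then BH-adjusted. Sites pass at
`fdr < fdr_threshold` (default 0.01) with `|delta| >= min_delta` (default
0.1). Runs of same-direction significant CpGs with inter-site gaps
≤ `max_gap_bp` (default 1 kb) and at least `min_cpgs` (default 3) members
become DMRs; a significant CpG of the opposite direction breaks a run
(regions are directionally coherent by construction), while non-significant
CpGs neither break nor count. Region ends extend 2 bp past the last member
CpG to cover its dinucleotide, half-open.

### The dispersion box

$\mu$ is clamped to $[10^{-6}, 1-10^{-6}]$ and $\varphi$ to $[10^{-2},
10^{6}]$, keeping boundary data (all-zero or all-full counts, single
replicates) identifiable. The diffuse lower bound has a consequence worth
knowing: a pooled null with $\varphi \ll 1$ puts almost all beta-binomial
mass at $k = 0$ and $k = N$, so even complete group separation (one group
fully unmethylated, the other fully methylated) is partially "explained" as
U-shaped replicate noise, and the single-site p-value stays moderate
(~0.014 for 0/30 vs 30/30 in triplicate). This is deliberate: a hard
dispersion floor would buy single-site significance at degenerate data at
the price of substantially worse region-level power on realistic data
(per-group fits of three replicates also use the flexibility). Regional
aggregation, not the lone CpG, is the unit of discovery.

### Calibration and power at the study conditions

The acceptance suite measures, at the standard conditions (3 vs 3, coverage
~NegBin(30, size 5), replicate noise Beta with precision 10):

* type-I error of the raw per-CpG LRT at nominal 0.05 — the $\chi^2_2$
  reference is mildly anti-conservative at six observations (measured
  ~0.07, within the accepted [0.025, 0.075] band);
* site-level power at the implanted shift of 0.4 and region-level recovery
  (80% of implanted ≥5-CpG regions at the standard fixture, with the
  significant CpGs leaning ~2:1 toward the implanted hypermethylation
  excess).

These two pull in opposite directions through the dispersion box and the
LRT degrees of freedom; the defaults sit where the calibration band holds.
Region recall is boundary-tight under these conditions — deeper coverage,
more replicates, or the 1-df mode raise it, at the cost (for the 1-df mode)
of null inflation.

## Downstream stages

**TSS association.** A gene is promoter-associated with a DMR when its TSS
lies within `max_dist_bp` (default 1 kb) of the region: distance 0 inside
`[start, end)`, otherwise `start - tss` or `tss - end` (bases separating
TSS and region). Many-to-many by design.

**Enrichment fractions.** For each named interval set, the fraction of
significantly hyper-/hypomethylated CpGs among all *profiled* CpGs inside
the set — membership, not multiplicity, so overlapping intervals of one set
count a CpG once. Over a set covering the whole genome this reproduces the
global direction summary exactly (tested).

**Beta-matrix comparison.** Array-style data (probes × samples in [0,1])
are compared between groups by per-probe group-mean differences and one
two-sided Wilcoxon signed-rank test of those differences against zero
(exact for ≤25 probes, normal approximation above; probes missing an entire
group are excluded). One global test matches the "is the whole methylome
shifted?" question; a per-probe Mann–Whitney alternative was considered and
rejected as answering a different (per-probe) question.

**PWM scanning.** Plain log-odds scoring of every window on both strands
(the reverse-strand score applies the motif to the window's reverse
complement), absolute score threshold, windows containing N skipped. No
p-value calibration of thresholds — out of scope.

**Expression.** A deliberately simple stand-in for an off-the-shelf DE
package: median-of-ratios size factors (geometric-mean reference over
all-positive genes); per-gene NB dispersion by pooled within-group method
of moments, floored at 1e-8; two-sided Wald test on log normalized means
with delta-method variances and pseudocount 0.5 (which keeps zero-mean
groups finite and log2 fold-changes symmetric). It is *not* DESeq: no
dispersion shrinkage across genes, no independent filtering. Its null
rejection rate at 5% is checked against [0.02, 0.09] on Poisson data, and
the size factors agree with the reference median-of-ratios implementation
to 1e-8 (tested against DESeq2 where available).

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
a known-truth record for recovery tests:

* CpG positions: sorted uniform integers with minimum spacing 2 on a 1 Mb
  pseudo-chromosome (default 5000 CpGs → mean spacing 200 bp).
* Baseline methylation: the bimodal mixture 0.7·Beta(1,10) + 0.3·Beta(10,1)
  (mostly-low promoter-like CpGs plus a methylated tail), clipped to
  [0.02, 0.98]. CpGs inside implanted regions draw their baseline
  *direction-coherently* — low for hypermethylation targets, high for
  hypomethylation targets — because a shift of +0.4 on an already-methylated
  CpG would be erased by the clip; biologically, hypermethylation hits
  unmethylated promoter-like loci.
* Implanted regions: disjoint runs of 5–8 consecutive CpGs (20 hyper, 10
  hypo by default; the 2:1 excess models a hypermethylation phenotype),
  shift ±0.4 in the mutant group.
* Counts: per strand, coverage ~NegBin(mean coverage/2, size 5); one
  replicate-level p ~ Beta(μφ, (1−μ)φ) shared by both strands (default
  φ = 10, i.e. noticeable biological variance); k ~ Binomial(N, p);
  zero-coverage strand records are omitted. A `logitnorm` switch generates
  mismatched (logit-normal) replicate noise for robustness checks.
* Features: an "enriched" BED set covering affected CpGs at `multiplier` ×
  the background coverage probability (default 3 × 0.15) plus two neutral
  sets; each interval covers exactly one dinucleotide so realized ratios
  are interpretable.
* Expression: NB counts (size 10) with log-normal base means and mild
  sample-level size factors; each implanted region plants one gene TSS
  50–800 bp upstream with a fold-change of *opposite* sign to the
  methylation shift (the classic promoter-methylation/expression
  anticorrelation); 20% of the remaining genes get random fold-changes.
* Beta matrices: one probe per CpG, baseline + global shift in the mutant
  group + Gaussian noise, clipped to [0,1]. The clip slightly attenuates a
  recovered global shift when baselines sit near the bounds (0.05 simulated
  → ~0.043 recovered at noise 0.05), which the tests account for.

Every generator is a pure function of (config, seed); repeated calls are
byte-identical, and all generated files round-trip through the package's
readers.

What passing these tests does **not** show about real data: genomic CpG
density is not uniform (RRBS enriches CpG islands, where neighbor
combination would be stronger); real dispersion varies across loci rather
than being a single φ; coverage is correlated with fragment structure
(MspI sites), not i.i.d.; and real feature sets have length structure that
single-dinucleotide intervals do not emulate. The matched beta-binomial
noise model is intentional — calibration tests need a matched null — and the
logit-normal switch probes, but does not exhaustively cover,
misspecification.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally (BED-native);
  chromosome names compare as exact strings; all character sorting uses
  radix order, so outputs are locale-independent and reruns byte-identical.
* Count files store integer `(k, N)` directly — the model consumes counts,
  and a level × coverage encoding would reintroduce rounding ambiguity.
  Zero-coverage cytosines are unrepresentable; absence means "not
  profiled"; a site is testable when each group has ≥1 covered sample.
* In Stouffer combination, p-values are clipped to
  $[10^{-15}, 1-10^{-15}]$ before the normal quantile: sites whose LRT is
  exactly 0 (p = 1) would otherwise contribute $z = -\infty$ and poison
  whole windows. The single-site identity `p_comb = p_raw` holds exactly
  within that range.
* BH adjustment ignores missing values (they stay missing and do not count
  toward the number of tests).
* Fitting is deterministic: method-of-moments starts, no randomness, ties
  impossible in practice; the optimizer's box and the fallback are
  described above. The convergence flag is honest — a site with any
  non-converged fit gets a missing p-value and is excluded from windows.
* Thresholds (`fdr 0.01`, `min_delta 0.1`, `window 200`, `gap 1000`,
  `min_cpgs 3`, `TSS 1 kb`) are defaults of the config surface, not
  hard-coded; the pipeline manifest echoes the full configuration.

## Problem sizes

The standard fixture (5000 CpGs, 3 vs 3, 200 genes) and the calibration
simulations (5000 null CpGs; 5000 null genes) are sized for a desk-scale
run: the full test suite takes about two minutes and the acceptance script
well under a minute on one core. These sizes are the package's chosen study
conditions; the estimators themselves stream over sites and scale linearly.

## Known limitations

* No covariate/batch terms in the methylation model (two-group design
  only), no smoothing of methylation levels, no 5hmC handling.
* The 2-df LRT is mildly anti-conservative at three replicates per group;
  interpret raw per-site p-values accordingly (the FDR stage operates on
  combined p-values).
* The expression stage is a simplified NB Wald test; for real studies use
  a dedicated DE package and feed its table into
  `join_dmr_expression()`.
* DMRs are directionally pure by construction; a locus with genuinely mixed
  hyper/hypo CpGs will be reported as separate adjacent regions.
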