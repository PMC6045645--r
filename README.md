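# betameth

Differential DNA methylation analysis for reduced representation bisulfite
sequencing (RRBS) count data, built around the beta-binomial count model, with
downstream region calling, genomic-feature attribution and integration with
gene expression. The package targets the common two-condition design in cancer
epigenomics — e.g. isogenic clones of a renal carcinoma cell line with and
without an inactivated tumour suppressor (VHL^wt vs VHL-mutant), profiled in a
few biological replicates — where the scientific questions are: which CpGs and
regions change methylation, in which direction the genome moves overall,
which chromatin states and transcription-factor binding sites concentrate the
changes, and how promoter methylation changes relate to expression changes.

## The model

A bisulfite caller reports, per cytosine and sample, `k` reads supporting
methylation out of `N` reads covering the position. Working with the counts
rather than the rates `k/N` keeps the information about coverage. Counts for
the two cytosines of a CpG dinucleotide (forward-strand C at `p`,
reverse-strand C at `p+1`) are summed per CpG, which also guards against
apparent strand asymmetry from mutated CpGs.

Per CpG, replicate counts are modeled as beta-binomial:

    k ~ Binomial(N, p),   p ~ Beta(alpha, beta)

so that both the binomial sampling noise of reads and the biological variance
of methylation between replicates are represented. The model is
parameterized as mean `mu = alpha/(alpha+beta)` and precision
`phi = alpha+beta`, fitted by maximum likelihood (L-BFGS-B on
`(logit mu, log phi)` with analytic gradients). The per-CpG test is a
likelihood-ratio test of a pooled fit against per-group fits, referred to a
chi-square distribution (2 df by default: mean and dispersion both freed per
group; a 1-df shared-dispersion variant is available). Site p-values are
locally combined across neighbors within ±200 bp (Stouffer's Z, equal
weights) — methylation changes worth reporting are locally coherent — then
Benjamini–Hochberg adjusted. CpGs pass at FDR < 0.01 and |Δmethylation| ≥ 0.1
by default, and consecutive concordant significant CpGs (gap ≤ 1 kb, ≥ 3
CpGs) are merged into directional differentially methylated regions (DMRs).

Around that core: TSS association (gene promoters within 1 kb of a DMR),
enrichment fractions of hyper-/hypomethylated CpGs inside BED interval sets
(ChromHMM states, TF binding-site clusters), PWM scanning of nucleotide
sequences, a whole-matrix group comparison for array-style beta values
(Wilcoxon signed-rank over per-probe group-mean differences), and a
simplified differential-expression stage (median-of-ratios size factors +
per-gene negative-binomial Wald test) joined to promoter DMRs.

A first-class synthetic-data module generates every input the chain consumes
— strand-level cytosine counts with implanted DMRs, feature interval sets
with controlled enrichment, TSS tables, linked expression counts, beta-value
matrices — together with the ground truth, so calibration and recovery are
testable end to end.

## Worked example

The numbered scripts under `analysis/` run the full study on the standard
synthetic fixture (5000 CpGs on a 1 Mb pseudo-chromosome, 3 vs 3 replicates,
~30x coverage, 20 hyper- + 10 hypomethylated implanted regions with
methylation shift 0.4):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_diffmeth.R
Rscript analysis/03_dmr.R
Rscript analysis/04_features.R
Rscript analysis/05_expression.R
Rscript analysis/06_full_pipeline.R
```

Output of the methylation stages:

```
significant CpGs: 74 hyper, 36 hypo (67% hypermethylated)
called 24 DMRs: 15 hyper, 9 hypo
recall vs implanted truth: 80% (24 / 30 regions)
33 DMR-TSS associations (21 distinct DMRs near a promoter)
hypermethylation fraction ratio, enriched vs neutral: 2.56
beta-matrix group shift: 0.0431 over 5000 probes (signed-rank p = 0)
promoter DMR x expression: 33 gene-region pairs, Spearman rho = -0.43
```

Reading these numbers: the significant CpGs lean 2:1 toward
hypermethylation, matching the implanted asymmetry (a genome drifting toward
hypermethylation); 80% of implanted regions are recovered with the correct
direction; the feature set that was built to cover affected CpGs at 3x the
background rate shows a correspondingly elevated fraction of hypermethylated
CpGs; the array-style comparison recovers the simulated global shift of
0.05 (slightly attenuated by clipping at the [0,1] bounds); and promoter
hypermethylation anticorrelates with expression change, as simulated.

Equivalently, one `run_pipeline()` call (script 06) runs everything from a
plain-text config and writes a manifest; reruns are byte-identical.

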