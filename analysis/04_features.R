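#!/usr/bin/env Rscript
# Attribute methylation changes to genomic feature sets: the fraction of
# significantly hyper-/hypomethylated CpGs among profiled CpGs inside each
# interval set (the enriched set covers affected CpGs at 3x background).
# Also: whole-array beta-matrix group comparison and a PWM scan demo on a
# synthetic promoter sequence carrying a hypoxia-response-element-like
# motif (consensus ACGTG).

library(betameth)

res <- utils::read.table("results/sites.tsv", header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
sets <- load_feature_sets("results/data/features")
en <- enrichment_fractions(res, sets)
write_enrichment(en, "results/enrichment.tsv")
print(en, row.names = FALSE)
ratio <- en$frac_hyper[en$feature_name == "enriched"] /
  mean(en$frac_hyper[en$feature_name != "enriched"])
cat(sprintf("hypermethylation fraction ratio, enriched vs neutral: %.2f\n", ratio))

beta <- read_beta_matrix("results/data/beta.csv", "results/data/beta_groups.tsv")
cb <- compare_beta_groups(beta, case = "mut", control = "wt")
cat(sprintf("beta-matrix group shift: %.4f over %d probes (signed-rank p = %.3g)\n",
            cb$mean_delta, cb$n_probes_used, cb$p_value))

# PWM demo: an HRE-like 5-mer planted in a random background
set.seed(2)
mat <- matrix(-2, 5, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
consensus <- c("A", "C", "G", "T", "G")
for (i in seq_along(consensus)) mat[i, consensus[i]] <- 2
pwm <- structure(list(name = "HRE_like", matrix = mat), class = "pwm")
bg <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
bg[200:204] <- consensus
hits <- pwm_scan(paste(bg, collapse = ""), pwm, score_threshold = 10)
cat(sprintf("PWM scan: %d hit(s); planted site found at offset %d (%s)\n",
            nrow(hits), hits$offset[1], hits$strand[1]))
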