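#!/usr/bin/env Rscript
# Simplified differential expression (median-of-ratios normalization +
# per-gene negative-binomial Wald test) and integration with promoter
# methylation: genes whose TSS lies near a called DMR are joined to their
# expression fold-change, where promoter hypermethylation is expected to
# anticorrelate with expression.

library(betameth)

cm <- read_count_matrix("results/data/expression.tsv", "results/data/groups.tsv")
de <- nb_test(cm$counts, cm$group_labels, case = "mut", control = "wt")
utils::write.table(format(de, digits = 15, trim = TRUE), "results/de.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("tested %d genes; %d at FDR < 0.1\n", nrow(de), sum(de$fdr < 0.1)))

dmrs <- utils::read.table("results/dmrs.tsv", header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
assoc <- utils::read.table("results/tss_associations.tsv", header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
joined <- join_dmr_expression(assoc, dmrs, de)
utils::write.table(format(joined, digits = 15, trim = TRUE),
                   "results/dmr_expression.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("promoter DMR x expression: %d gene-region pairs, Spearman rho = %.2f\n",
            nrow(joined), attr(joined, "spearman_rho")))
cat("negative rho: promoter hypermethylation tracks reduced expression\n")

# TF-site view: join the enriched set with an (illustrative) factor gene
en <- utils::read.table("results/enrichment.tsv", header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
tf_map <- c(enriched = de$gene_id[which.max(de$log2fc)])
tf_tab <- tf_site_expression_table(en, de, tf_map)
utils::write.table(format(tf_tab, digits = 6, trim = TRUE),
                   "results/tf_site_expression.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/tf_site_expression.tsv\n")
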