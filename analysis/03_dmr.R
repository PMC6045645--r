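#!/usr/bin/env Rscript
# Aggregate significant CpGs into directional DMRs and associate them with
# gene TSSs (promoter rule: TSS within 1 kb of a region edge). Compares the
# called regions against the generator's ground truth.

library(betameth)

res <- utils::read.table("results/sites.tsv", header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
dmrs <- call_dmrs(res, max_gap_bp = 1000, min_cpgs = 3)
write_dmrs(dmrs, "results/dmrs.bed", "results/dmrs.tsv")
s <- dmr_summary(dmrs)
cat(sprintf("called %d DMRs: %d hyper, %d hypo\n", s$n_total, s$n_hyper, s$n_hypo))

truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
tr <- truth$regions
hit <- vapply(seq_len(nrow(tr)), function(i) {
  any(dmrs$chrom == tr$chrom[i] & dmrs$direction == tr$direction[i] &
        dmrs$start < tr$end[i] & dmrs$end > tr$start[i])
}, TRUE)
cat(sprintf("recall vs implanted truth: %.0f%% (%d / %d regions)\n",
            100 * mean(hit), sum(hit), nrow(tr)))

tss <- read_tss("results/data/tss.tsv")
assoc <- associate_tss(dmrs, tss, max_dist_bp = 1000)
utils::write.table(assoc, "results/tss_associations.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("%d DMR-TSS associations (%d distinct DMRs near a promoter)\n",
            nrow(assoc), length(unique(assoc$dmr_row))))
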