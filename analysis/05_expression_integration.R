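#!/usr/bin/env Rscript
# Stage 5: downstream integration of the differential-expression tables —
# seven-way trajectory classification across the HE-to-progenitor
# transition, figure-style tallies, pairwise concordant/opposing overlap,
# and fold-change correlation with clustering.

library(chromprime)

fix <- "results/analysis/fixtures"
out <- "results/analysis/expression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

de_minus <- read.table(file.path(fix, "de_minus.tsv"), header = TRUE, sep = "\t")
de_plus <- read.table(file.path(fix, "de_plus.tsv"), header = TRUE, sep = "\t")
truth <- read.table(file.path(fix, "de_truth.tsv"), header = TRUE, sep = "\t")

cls <- classify_trajectory(2^de_minus$log2fc, 2^de_plus$log2fc)
write.table(data.frame(gene_id = de_minus$gene_id,
                       category = as.character(cls)),
            file.path(out, "trajectory.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("trajectory recovery vs planted truth: %.1f%%",
                100 * mean(as.character(cls) == truth$category)))
tal <- trajectory_tallies(2^de_minus$log2fc, 2^de_plus$log2fc)
message("tallies: ", paste(names(tal), tal, sep = "=", collapse = " "))

dereg <- list(minus = deregulated_genes(de_minus),
              plus = deregulated_genes(de_plus))
ov <- pairwise_overlap(dereg)
write.table(ov$concordant, file.path(out, "overlap_concordant.tsv"),
            sep = "\t", quote = FALSE)
write.table(ov$opposing, file.path(out, "overlap_opposing.tsv"),
            sep = "\t", quote = FALSE)
message(sprintf("concordant(-dox,+dox) = %d, opposing = %d",
                ov$concordant["minus", "plus"], ov$opposing["minus", "plus"]))

fc <- fold_change_correlation(list(minus = de_minus, plus = de_plus))
write.table(fc$correlation, file.path(out, "foldchange_correlation.tsv"),
            sep = "\t", quote = FALSE)
message(sprintf("fold-change correlation over %d deregulated genes: %.3f",
                length(fc$genes), fc$correlation["minus", "plus"]))
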