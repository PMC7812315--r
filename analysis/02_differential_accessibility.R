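#!/usr/bin/env Rscript
# Stage 2: summit-merged peak union, CPM normalisation and twofold
# differential-accessibility calls, plus the fold-ranked heatmap matrices
# and the sample correlation. Reads only the stage-1 fixture files.

library(chromprime)

fix <- "results/analysis/fixtures"
out <- "results/analysis/diffacc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

minus <- read_peaks(file.path(fix, "peaks_minus.narrowPeak"), "narrowPeak")
plus <- read_peaks(file.path(fix, "peaks_plus.narrowPeak"), "narrowPeak")
track_m <- read_bedgraph(file.path(fix, "track_minus.bedGraph"))
track_p <- read_bedgraph(file.path(fix, "track_plus.bedGraph"))
genes <- read_genes(file.path(fix, "genes.tsv"))

union <- build_peak_union(minus, plus, summit_distance = 400)
message(sprintf("union: %d peaks from %d (-dox) + %d (+dox)",
                nrow(union), nrow(minus), nrow(plus)))

diff <- differential_table(union, track_m, track_p, genes = genes,
                           window = 400, fold_threshold = 2, verbose = TRUE)
write_differential_table(diff, file.path(out, "differential.tsv"))

truth <- read.table(file.path(fix, "truth_experiment.tsv"), header = TRUE,
                    sep = "\t")
m <- match(paste(diff$chrom, diff$start), paste(truth$chrom, truth$start))
acc <- mean(diff$class == truth$class[m], na.rm = TRUE)
message(sprintf("planted class recovery: %.1f%%", 100 * acc))

hm <- ranked_density_matrix(diff, list(minus = track_m, plus = track_p),
                            window = 2000, bin = 10)
for (nm in names(hm))
  write.table(data.frame(name = rownames(hm[[nm]]), hm[[nm]]),
              file.path(out, sprintf("heatmap_%s.tsv", nm)), sep = "\t",
              quote = FALSE, row.names = FALSE)

cc <- correlation_cluster(t(cbind(minus = diff$log2_minus,
                                  plus = diff$log2_plus)))
write.table(cc$correlation, file.path(out, "sample_correlation.tsv"),
            sep = "\t", quote = FALSE)
message(sprintf("-dox/+dox log2 tag-count correlation: %.3f",
                cc$correlation["minus", "plus"]))
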