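#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study fixtures.
#
# A replicated five-cell-type ATAC atlas (2,000 peaks per type, 30%
# exclusive), a paired -dox/+dox accessibility experiment over a
# 10,000-peak distal universe with 10% gained, 10% lost peaks at a planted
# fourfold change, 40% of gained peaks placed on the megakaryocyte
# signature, and paired differential-expression tables. Everything is
# written as plain text so later stages run off files alone.

library(chromprime)

seed <- 17
fix <- "results/analysis/fixtures"
dir.create(fix, recursive = TRUE, showWarnings = FALSE)

atlas <- simulate_atlas(seed = derive_subseed(seed, "atlas"))
expt <- simulate_experiment(atlas,
                            signature_enrichment = c(megakaryocyte = 0.4),
                            seed = derive_subseed(seed, "experiment"))
de <- simulate_de_tables(seed = derive_subseed(seed, "expression"))

write_peaks(expt$peaks$minus, file.path(fix, "peaks_minus.narrowPeak"),
            "narrowPeak")
write_peaks(expt$peaks$plus, file.path(fix, "peaks_plus.narrowPeak"),
            "narrowPeak")
write_bedgraph(expt$tracks$minus, file.path(fix, "track_minus.bedGraph"))
write_bedgraph(expt$tracks$plus, file.path(fix, "track_plus.bedGraph"))
write_genes(expt$genes, file.path(fix, "genes.tsv"))
write.table(expt$truth, file.path(fix, "truth_experiment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(atlas$truth, file.path(fix, "truth_atlas.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (ct in names(atlas$replicates))
  for (r in seq_along(atlas$replicates[[ct]]))
    write_peaks(atlas$replicates[[ct]][[r]],
                file.path(fix, sprintf("atlas_%s_rep%d.narrowPeak", ct, r)),
                "narrowPeak")
for (nm in names(de))
  write.table(de[[nm]], file.path(fix, sprintf("de_%s.tsv", nm)), sep = "\t",
              quote = FALSE, row.names = FALSE)

message(sprintf("atlas: %d distinct peaks (%d shared, %d exclusive)",
                nrow(atlas$truth), sum(atlas$truth$label == "shared"),
                sum(atlas$truth$label != "shared")))
message(sprintf("experiment: %d universe peaks (%d gained, %d lost planted)",
                nrow(expt$truth), sum(expt$truth$class == "gained"),
                sum(expt$truth$class == "lost")))
message("fixtures written to ", fix)
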