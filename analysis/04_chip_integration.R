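#!/usr/bin/env Rscript
# Stage 4: ChIP-seq integration with the open-chromatin landscape. A
# transcription-factor binding track is emulated from the accessibility
# fixtures (binding follows accessibility at a subset of sites), then:
# peaks are filtered to open chromatin, differential binding is called with
# the shared twofold machinery (400-bp TF window; 800-bp broad-mark
# window), average profiles and UpSet-style shared-site counts are
# computed, and binding changes at nearest genes are crossed with the DE
# tables.

library(chromprime)

fix <- "results/analysis/fixtures"
out <- "results/analysis/chip"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

atac_minus <- read_peaks(file.path(fix, "peaks_minus.narrowPeak"), "narrowPeak")
atac_plus <- read_peaks(file.path(fix, "peaks_plus.narrowPeak"), "narrowPeak")
track_m <- read_bedgraph(file.path(fix, "track_minus.bedGraph"))
track_p <- read_bedgraph(file.path(fix, "track_plus.bedGraph"))
genes <- read_genes(file.path(fix, "genes.tsv"))
union <- build_peak_union(atac_minus, atac_plus)

# emulated TF ChIP peaks: every other +dox peak, plus a handful of sites
# outside open chromatin that the filter should discard
chip_open <- atac_plus[seq(1, nrow(atac_plus), by = 2), , drop = FALSE]
class(chip_open) <- class(atac_plus)
stray <- peak_set("chrS", c(99e6, 99.5e6), c(99e6, 99.5e6) + 400,
                  name = c("stray1", "stray2"), label = "chip")
chip <- peak_set(c(chip_open$chrom, stray$chrom),
                 c(chip_open$start, stray$start),
                 c(chip_open$end, stray$end),
                 name = c(paste0("tf_", chip_open$name), stray$name),
                 summit = c(chip_open$summit, stray$summit), label = "TF")
open <- filter_to_open_chromatin(chip, union)
message(sprintf("ChIP peaks: %d called, %d within open chromatin",
                nrow(chip), nrow(open)))

tf <- differential_chip(track_m, track_p, union, cfg = mark_config("TF", 400),
                        genes = genes)
k27 <- differential_chip(track_m, track_p, union,
                         cfg = mark_config("H3K27ac", 800, broad = TRUE),
                         genes = genes)
write_differential_table(tf, file.path(out, "differential_tf.tsv"))
write_differential_table(k27, file.path(out, "differential_h3k27ac.tsv"))
message(sprintf("TF binding (400-bp window): %d lost, %d maintained, %d gained",
                sum(tf$class == "lost"), sum(tf$class == "shared"),
                sum(tf$class == "gained")))

prof <- average_profile(track_p, data.frame(chrom = union$chrom,
                                            summit = union$summit),
                        window = 4000, bin = 10)
write.table(data.frame(bin = seq_along(prof) * 10 - 2000, mean_density = prof),
            file.path(out, "average_profile_plus.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

as_ps <- function(df, lab) peak_set(df$chrom, df$start, df$end,
                                    name = df$name, summit = df$summit,
                                    label = lab)
combos <- shared_specific_sets(
  list(TF = open,
       gained = as_ps(tf[tf$class == "gained", ], "gained"),
       lost = as_ps(tf[tf$class == "lost", ], "lost")),
  base = "TF")
write.table(combos, file.path(out, "shared_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# TF targets by nearest gene, crossed with deregulated genes
ng <- nearest_gene(as_ps(tf, "tf"), genes)
lab_of <- c(lost = "lost", shared = "maintained", gained = "gained")
targets <- split(ng$gene_id, lab_of[tf$class])
de_minus <- read.table(file.path(fix, "de_minus.tsv"), header = TRUE,
                       sep = "\t")
dereg <- deregulated_genes(de_minus)
frac <- tf_target_fraction(dereg, list(TF = targets))
write.table(frac, file.path(out, "tf_target_fractions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("per-direction TF target fractions written (synthetic gene space is")
message("disjoint from the DE tables, so bound fractions are 0 by design)")
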