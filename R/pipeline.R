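#' Default pipeline parameters
#'
#' The analysis defaults used throughout: 400-bp summit-merge distance,
#' 400-bp tag-density window (800 bp for broad marks), 1.5-kb promoter
#' window, twofold differential threshold, 2-kb/10-bp heatmap matrices and
#' 1000 resamples for the priming test.
#'
#' @return Named list of parameter defaults.
#' @export
default_params <- function() {
  list(summit_distance = 400, window = 400, broad_window = 800,
       promoter_window = 1500, fold = 2, heatmap_window = 2000, bin = 10,
       profile_window = 4000, n_resamples = 1000)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(name = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline from a single configuration
#'
#' Stages run in dependency order: synthetic fixtures (or user-supplied
#' files) -> peak union -> normalisation and differential calls -> ranked
#' heatmap matrices and sample correlation -> motif scores -> signature
#' derivation and lineage-priming panel -> expression integration. All
#' randomness flows from the master seed through named sub-seeds, so a rerun
#' with the same configuration produces byte-identical outputs. The manifest
#' lists every output file with its MD5 content hash; the run log records
#' parameters, the counts surviving each filter and any degenerate priming
#' results.
#'
#' @param config a list, or path to a YAML file, with optional entries
#'   `seed` (master seed, default 1), `outdir` (default `"chromprime_run"`),
#'   `params` (overrides for [default_params]), and `simulate` with optional
#'   sub-lists `atlas`, `experiment`, `motifs` (`rates` matrix or rate
#'   vector), `expression` — arguments passed to the corresponding
#'   generators.
#' @param outdir output directory (overrides `config$outdir`).
#' @return Invisibly, a list with `manifest` (data.frame: stage, file, md5)
#'   and `log` (the run log, also written as `run_log.yaml`).
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (is.null(outdir)) outdir <- if (is.null(config$outdir)) "chromprime_run"
                                 else config$outdir
  params <- utils::modifyList(default_params(),
                              if (is.null(config$params)) list()
                              else config$params)
  for (d in c("fixtures", "diffacc", "motifs", "priming", "expression"))
    dir.create(file.path(outdir, d), recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  add <- function(stage, path) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, file = path, stringsAsFactors = FALSE)
    path
  }
  log <- list(seed = seed, params = params, counts = list(),
              degenerate = list())

  ## stage 1: fixtures --------------------------------------------------
  sim <- if (is.null(config$simulate)) list() else config$simulate
  atlas <- do.call(simulate_atlas, utils::modifyList(
    list(seed = derive_subseed(seed, "atlas")),
    if (is.null(sim$atlas)) list() else sim$atlas))
  expt <- do.call(simulate_experiment, utils::modifyList(
    list(atlas = atlas, seed = derive_subseed(seed, "experiment")),
    if (is.null(sim$experiment)) list() else sim$experiment))
  fx <- file.path(outdir, "fixtures")
  add("fixtures", write_peaks(expt$peaks$minus,
                              file.path(fx, "peaks_minus.narrowPeak"),
                              "narrowPeak"))
  add("fixtures", write_peaks(expt$peaks$plus,
                              file.path(fx, "peaks_plus.narrowPeak"),
                              "narrowPeak"))
  add("fixtures", write_bedgraph(expt$tracks$minus,
                                 file.path(fx, "track_minus.bedGraph")))
  add("fixtures", write_bedgraph(expt$tracks$plus,
                                 file.path(fx, "track_plus.bedGraph")))
  add("fixtures", write_genes(expt$genes, file.path(fx, "genes.tsv")))
  add("fixtures", write_tsv(expt$truth, file.path(fx, "truth_experiment.tsv")))
  add("fixtures", write_tsv(atlas$truth, file.path(fx, "truth_atlas.tsv")))
  log$counts$atlas_peaks <- nrow(atlas$truth)
  log$counts$universe_peaks <- nrow(expt$truth)

  ## stage 2: differential accessibility --------------------------------
  union <- build_peak_union(expt$peaks$minus, expt$peaks$plus,
                            summit_distance = params$summit_distance)
  diff <- differential_table(union, expt$tracks$minus, expt$tracks$plus,
                             genes = expt$genes, window = params$window,
                             fold_threshold = params$fold,
                             promoter_window = params$promoter_window)
  da <- file.path(outdir, "diffacc")
  add("diffacc", write_differential_table(diff,
                                          file.path(da, "differential.tsv")))
  log$counts$union_peaks <- nrow(diff)
  log$counts$differential <- as.list(table(diff$class))
  log$counts$element <- as.list(table(diff$element))
  hm <- ranked_density_matrix(diff, list(minus = expt$tracks$minus,
                                         plus = expt$tracks$plus),
                              window = params$heatmap_window, bin = params$bin)
  add("diffacc", write_matrix_tsv(hm$minus, file.path(da, "heatmap_minus.tsv")))
  add("diffacc", write_matrix_tsv(hm$plus, file.path(da, "heatmap_plus.tsv")))
  cc <- correlation_cluster(t(cbind(minus = diff$log2_minus,
                                    plus = diff$log2_plus)))
  add("diffacc", write_matrix_tsv(cc$correlation,
                                  file.path(da, "sample_correlation.tsv")))

  ## stage 3: motif enrichment ------------------------------------------
  gained_ps <- diff[diff$class == "gained", , drop = FALSE]
  lost_ps <- diff[diff$class == "lost", , drop = FALSE]
  if (nrow(gained_ps) > 0 && nrow(lost_ps) > 0) {
    as_ps <- function(df, lab) peak_set(df$chrom, df$start, df$end,
                                        name = df$name, summit = df$summit,
                                        label = lab)
    sets <- list(gained = as_ps(gained_ps, "gained"),
                 lost = as_ps(lost_ps, "lost"))
    rates <- if (!is.null(sim$motifs$rates))
      as.matrix(as.data.frame(sim$motifs$rates))
    else matrix(c(0.4, 0.1, 0.1, 0.4, 0.2, 0.2), nrow = 3, byrow = TRUE,
                dimnames = list(c("RUNX", "GATA", "ETS"),
                                c("gained", "lost")))
    mot <- simulate_motifs(sets, rates, seed = derive_subseed(seed, "motifs"))
    mo <- file.path(outdir, "motifs")
    add("motifs", write_motif_counts(mot$counts,
                                     file.path(mo, "motif_counts.tsv")))
    S <- enrichment_scores(mot$counts)
    add("motifs", write_matrix_tsv(S, file.path(mo, "motif_scores.tsv")))
    log$counts$motifs <- nrow(S)
  }

  ## stage 4: lineage priming -------------------------------------------
  atlas_sig <- derive_signatures(atlas$replicates)
  pr <- file.path(outdir, "priming")
  for (ct in names(atlas_sig$signatures))
    add("priming", write_peaks(atlas_sig$signatures[[ct]],
                               file.path(pr, paste0("signature_", ct, ".bed")),
                               "bed"))
  add("priming", write_tsv(atlas_sig$provenance,
                           file.path(pr, "signature_provenance.tsv")))
  panel <- priming_panel(diff, atlas_sig, n_resamples = params$n_resamples,
                         seed = seed)
  add("priming", write_tsv(panel, file.path(pr, "priming_panel.tsv")))
  log$degenerate$priming <- panel$cell_type[which(panel$degenerate)]
  log$counts$signatures <- stats::setNames(
    as.list(atlas_sig$provenance$n_specific),
    atlas_sig$provenance$cell_type)

  ## stage 5: expression integration ------------------------------------
  de <- do.call(simulate_de_tables, utils::modifyList(
    list(seed = derive_subseed(seed, "expression")),
    if (is.null(sim$expression)) list() else sim$expression))
  ex <- file.path(outdir, "expression")
  add("expression", write_tsv(de$minus, file.path(ex, "de_minus.tsv")))
  add("expression", write_tsv(de$plus, file.path(ex, "de_plus.tsv")))
  traj <- classify_trajectory(2^de$minus$log2fc, 2^de$plus$log2fc,
                              threshold = params$fold)
  add("expression", write_tsv(
    data.frame(gene_id = de$minus$gene_id, category = as.character(traj),
               stringsAsFactors = FALSE),
    file.path(ex, "trajectory.tsv")))
  log$counts$trajectory <- as.list(table(traj))
  dereg <- list(minus = deregulated_genes(de$minus),
                plus = deregulated_genes(de$plus))
  po <- pairwise_overlap(dereg)
  add("expression", write_matrix_tsv(po$concordant,
                                     file.path(ex, "overlap_concordant.tsv")))
  add("expression", write_matrix_tsv(po$opposing,
                                     file.path(ex, "overlap_opposing.tsv")))

  ## manifest and log ----------------------------------------------------
  manifest <- do.call(rbind, manifest)
  manifest$md5 <- unname(tools::md5sum(manifest$file))
  manifest$file <- substring(manifest$file, nchar(outdir) + 2)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))
  invisible(list(manifest = manifest, log = log))
}
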