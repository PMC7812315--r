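# Default mature-cell panel used throughout the synthetic atlas.
.default_celltypes <- c("CMP", "Bcell", "monocyte", "erythroblast",
                        "megakaryocyte")

# Place n non-overlapping width-bp intervals uniformly on [0, genome_length),
# optionally avoiding an existing peak table (any-base overlap). Returns
# 0-based starts, sorted. Assumes the RNG is already seeded by the caller.
place_nonoverlapping <- function(n, width, genome_length, avoid = NULL) {
  if (n == 0) return(numeric(0))
  draw <- function(k) {
    if (k * width > genome_length)
      stop("requested peaks do not fit genome_length without overlap")
    u <- sort(sample.int(genome_length - k * width + 1, k, replace = TRUE)) - 1
    u + (seq_len(k) - 1) * width
  }
  if (is.null(avoid) || nrow(avoid) == 0) return(draw(n))
  avoid_gr <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(avoid$start + 1, avoid$end))
  for (attempt in 1:20) {
    k <- ceiling(n * 1.3 * 2^(attempt - 1)) + 50
    starts <- draw(min(k, floor(genome_length / width)))
    gr <- GenomicRanges::GRanges(
      "chrS", IRanges::IRanges(starts + 1, starts + width))
    ok <- GenomicRanges::countOverlaps(gr, avoid_gr) == 0
    if (sum(ok) >= n) return(starts[ok][seq_len(n)])
  }
  stop("could not place peaks avoiding existing intervals")
}

#' Simulate a replicated mature-cell-type ATAC atlas
#'
#' Places non-overlapping peaks on a single synthetic chromosome (`chrS`) and
#' labels each as shared across all cell types or exclusive to one type, with
#' `specific_fraction` of each type's peaks exclusive. Every cell type gets
#' `n_replicates` replicate peak sets; each peak independently drops out of a
#' replicate with probability `replicate_jitter`. With zero jitter,
#' [derive_signatures] on the output recovers exactly the planted specific
#' labels.
#'
#' @param n_celltypes number of cell types (default 5, named after the
#'   mature-cell panel: CMP, B cell, monocyte, erythroblast, megakaryocyte).
#' @param peaks_per_type peaks per cell type (default 2000).
#' @param specific_fraction fraction of each type's peaks that are exclusive
#'   to it (default 0.3).
#' @param genome_length synthetic chromosome length in bp (default 1e8).
#' @param peak_width peak width in bp (default 400; summit at the centre).
#' @param replicate_jitter per-replicate dropout probability (default 0.05).
#' @param n_replicates replicates per cell type (default 2).
#' @param seed integer seed.
#' @return List of class `atlas_sim`: `replicates` (cell type -> list of
#'   [peak_set]), `truth` (peak coordinates with planted label `shared` or a
#'   cell-type name), and the generating parameters.
#' @export
simulate_atlas <- function(n_celltypes = 5, peaks_per_type = 2000,
                           specific_fraction = 0.3, genome_length = 1e8,
                           peak_width = 400, replicate_jitter = 0.05,
                           n_replicates = 2, seed = 1) {
  stopifnot(specific_fraction >= 0, specific_fraction <= 1,
            replicate_jitter >= 0, replicate_jitter < 1)
  types <- if (n_celltypes == length(.default_celltypes)) .default_celltypes
           else sprintf("type%02d", seq_len(n_celltypes))
  n_spec <- round(peaks_per_type * specific_fraction)
  n_shared <- peaks_per_type - n_spec
  n_distinct <- n_shared + n_celltypes * n_spec
  with_local_seed(seed, {
    starts <- place_nonoverlapping(n_distinct, peak_width, genome_length)
    label <- sample(c(rep("shared", n_shared), rep(types, each = n_spec)))
    truth <- data.frame(
      name = sprintf("atlas_%06d", seq_len(n_distinct)), chrom = "chrS",
      start = starts, end = starts + peak_width,
      summit = starts + peak_width %/% 2, label = label,
      stringsAsFactors = FALSE)
    replicates <- lapply(types, function(ct) {
      mine <- truth[truth$label %in% c("shared", ct), , drop = FALSE]
      lapply(seq_len(n_replicates), function(r) {
        keep <- stats::runif(nrow(mine)) >= replicate_jitter
        sub <- mine[keep, , drop = FALSE]
        peak_set(sub$chrom, sub$start, sub$end,
                 name = paste0(ct, "_r", r, "_", sub$name),
                 summit = sub$summit, label = paste0(ct, "_rep", r))
      })
    })
    names(replicates) <- types
    structure(list(replicates = replicates, truth = truth,
                   params = list(n_celltypes = n_celltypes,
                                 peaks_per_type = peaks_per_type,
                                 specific_fraction = specific_fraction,
                                 genome_length = genome_length,
                                 peak_width = peak_width,
                                 replicate_jitter = replicate_jitter,
                                 n_replicates = n_replicates, seed = seed)),
              class = "atlas_sim")
  })
}

#' Simulate a paired-condition accessibility experiment
#'
#' Builds a universe of `n_union_peaks` non-overlapping peaks on the
#' atlas chromosome with planted gained / lost / shared classes and
#' per-condition bedGraph-style tracks. Gained peaks carry `planted_fold`
#' times the base density in the induced (+dox) condition, lost peaks in the
#' uninduced (-dox) condition; multiplicative log-normal noise with
#' coefficient of variation `noise_cv` is applied per sample. A fraction of
#' gained (and optionally lost) peaks is planted directly on the exclusive
#' peaks of named atlas cell types (`signature_enrichment`), and non-planted
#' peaks overlap each signature at a background rate of
#' `sig_background_rate / n_celltypes` per type (so about
#' `sig_background_rate` of the universe is signature-bearing overall),
#' applied uniformly across classes so that non-planted cell types show no
#' systematic enrichment in any class.
#'
#' @param atlas an `atlas_sim` from [simulate_atlas].
#' @param n_union_peaks universe size (default 10000).
#' @param gained_fraction,lost_fraction planted class fractions (default 0.1
#'   each; the remainder is shared).
#' @param planted_fold planted accessibility fold change (default 4).
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   noise on window densities (default 0.2).
#' @param signature_enrichment named numeric vector: fraction of gained
#'   peaks planted on each named cell type's signature (e.g.
#'   `c(megakaryocyte = 0.4)`).
#' @param lost_signature_enrichment same, for lost peaks.
#' @param sig_background_rate total fraction of non-planted peaks that carry
#'   some cell-type signature (default 0.1, split evenly across types).
#' @param base_density median base tag density per peak (default 10).
#' @param peak_width peak width in bp (default 400).
#' @param n_genes synthetic TSS count; genes are placed away from peaks
#'   (beyond the 1.5-kb promoter window) so the simulated universe is distal
#'   (default 500).
#' @param seed integer seed.
#' @return List of class `experiment_sim`: `peaks` (minus / plus
#'   [peak_set]), `tracks` (minus / plus [tag_track]), `genes`, `truth`
#'   (per-universe-peak class and signature labels), and `params`.
#' @export
simulate_experiment <- function(atlas, n_union_peaks = 10000,
                                gained_fraction = 0.1, lost_fraction = 0.1,
                                planted_fold = 4, noise_cv = 0.2,
                                signature_enrichment = NULL,
                                lost_signature_enrichment = NULL,
                                sig_background_rate = 0.1,
                                base_density = 10, peak_width = 400,
                                n_genes = 500, seed = 1) {
  if (gained_fraction + lost_fraction > 1)
    stop("validation error: gained_fraction + lost_fraction must be <= 1")
  if (planted_fold < 1) stop("validation error: planted_fold must be >= 1")
  se <- signature_enrichment
  if (is.list(se)) se <- unlist(se)
  if (is.list(lost_signature_enrichment))
    lost_signature_enrichment <- unlist(lost_signature_enrichment)
  if (!is.null(se) && (any(se < 0) || sum(se) > 1))
    stop("validation error: signature_enrichment fractions must sum to <= 1")
  types <- names(atlas$replicates)
  genome_length <- atlas$params$genome_length
  n_g <- round(n_union_peaks * gained_fraction)
  n_l <- round(n_union_peaks * lost_fraction)
  n_s <- n_union_peaks - n_g - n_l
  with_local_seed(seed, {
    cls <- sample(c(rep("gained", n_g), rep("lost", n_l), rep("shared", n_s)))
    sig <- rep("none", n_union_peaks)
    # planted enrichment: exact counts of gained (lost) peaks on a signature
    plant <- function(sig, enr, class_name) {
      if (is.null(enr)) return(sig)
      idx_pool <- which(cls == class_name & sig == "none")
      for (ct in names(enr)) {
        k <- round(enr[[ct]] * sum(cls == class_name))
        if (k > length(idx_pool)) stop("enrichment fractions exceed class size")
        take <- idx_pool[seq_len(k)]
        idx_pool <- idx_pool[-seq_len(k)]
        sig[take] <- ct
      }
      sig
    }
    sig <- plant(sig, se, "gained")
    sig <- plant(sig, lost_signature_enrichment, "lost")
    # uniform background, stratified by class: each class carries each
    # type's signature at rate_bg of the class size, so non-planted types
    # keep the universe-level rate inside gained/lost/shared alike
    rate_bg <- sig_background_rate / length(types)
    for (class_name in unique(cls)) {
      free <- which(cls == class_name & sig == "none")
      free <- free[sample.int(length(free))]
      k <- round(rate_bg * sum(cls == class_name))
      for (ct in types) {
        kk <- min(k, length(free))
        sig[free[seq_len(kk)]] <- ct
        free <- free[-seq_len(kk)]
      }
    }
    # coordinates: signature-bearing peaks sit on exclusive atlas peaks of
    # their type; the rest go to fresh locations clear of the atlas
    start <- numeric(n_union_peaks)
    for (ct in types) {
      idx <- which(sig == ct)
      pool <- atlas$truth[atlas$truth$label == ct, , drop = FALSE]
      if (length(idx) > nrow(pool))
        stop("signature demand exceeds planted specific peaks for ", ct)
      start[idx] <- sort(pool$start[sample.int(nrow(pool), length(idx))])
    }
    idx <- which(sig == "none")
    start[idx] <- place_nonoverlapping(length(idx), peak_width, genome_length,
                                       avoid = atlas$truth)
    truth <- data.frame(
      name = sprintf("u%06d", seq_len(n_union_peaks)), chrom = "chrS",
      start = start, end = start + peak_width,
      summit = start + peak_width %/% 2, class = cls, signature = sig,
      stringsAsFactors = FALSE)
    truth <- truth[order(truth$start), , drop = FALSE]
    truth$name <- sprintf("u%06d", seq_len(n_union_peaks))
    rownames(truth) <- NULL
    # densities
    n <- n_union_peaks
    base <- base_density * stats::rlnorm(n, 0, 0.5)
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- function() if (noise_cv > 0)
      stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
    minus_val <- base * ifelse(truth$class == "lost", planted_fold, 1) * noise()
    plus_val <- base * ifelse(truth$class == "gained", planted_fold, 1) * noise()
    minus_val <- round(minus_val, 4)
    plus_val <- round(plus_val, 4)
    # condition peak sets: -dox has lost + shared, +dox has gained + shared
    in_minus <- truth$class %in% c("lost", "shared")
    in_plus <- truth$class %in% c("gained", "shared")
    peaks_minus <- peak_set(truth$chrom[in_minus], truth$start[in_minus],
                            truth$end[in_minus],
                            name = paste0("m_", truth$name[in_minus]),
                            summit = truth$summit[in_minus], label = "minus")
    peaks_plus <- peak_set(truth$chrom[in_plus], truth$start[in_plus],
                           truth$end[in_plus],
                           name = paste0("p_", truth$name[in_plus]),
                           summit = truth$summit[in_plus], label = "plus")
    tracks <- list(
      minus = tag_track(truth$chrom, truth$start, truth$end, minus_val),
      plus = tag_track(truth$chrom, truth$start, truth$end, plus_val))
    # genes: TSS placed clear of all peaks by more than the promoter window
    avoid <- rbind(
      data.frame(start = pmax(truth$start - 2000, 0), end = truth$end + 2000),
      data.frame(start = pmax(atlas$truth$start - 2000, 0),
                 end = atlas$truth$end + 2000))
    tss <- place_nonoverlapping(n_genes, 1, genome_length, avoid = avoid)
    genes <- data.frame(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
                        chrom = "chrS",
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        tss = tss, stringsAsFactors = FALSE)
    structure(list(peaks = list(minus = peaks_minus, plus = peaks_plus),
                   tracks = tracks, genes = genes, truth = truth,
                   params = list(n_union_peaks = n_union_peaks,
                                 gained_fraction = gained_fraction,
                                 lost_fraction = lost_fraction,
                                 planted_fold = planted_fold,
                                 noise_cv = noise_cv,
                                 signature_enrichment = se,
                                 lost_signature_enrichment =
                                   lost_signature_enrichment,
                                 sig_background_rate = sig_background_rate,
                                 base_density = base_density,
                                 peak_width = peak_width, n_genes = n_genes,
                                 seed = seed)),
              class = "experiment_sim")
  })
}

#' Simulate motif hits over peak sets
#'
#' Per motif and set, the number of motif-bearing sites is binomial:
#' `n_ij ~ Binomial(m_j, rate_ij)`. Hit positions are uniform within the
#' peaks that carry the motif (one position per carrying peak).
#'
#' @param peak_sets named list of [peak_set] objects (one per set `j`).
#' @param rates numeric matrix, motifs x sets, of per-peak hit
#'   probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return List: `counts` (a [motif_counts]) and `positions` (data.frame
#'   `motif`, `set`, `chrom`, `pos`).
#' @export
simulate_motifs <- function(peak_sets, rates, seed = 1) {
  rates <- as.matrix(rates)
  if (any(rates < 0) || any(rates > 1))
    stop("validation error: rates must be in [0, 1]")
  if (ncol(rates) != length(peak_sets))
    stop("one rate column per peak set required")
  if (is.null(colnames(rates))) colnames(rates) <- names(peak_sets)
  if (is.null(rownames(rates)))
    rownames(rates) <- sprintf("motif_%03d", seq_len(nrow(rates)))
  m <- vapply(peak_sets, nrow, integer(1))
  with_local_seed(seed, {
    n <- matrix(0L, nrow(rates), ncol(rates), dimnames = dimnames(rates))
    pos <- list()
    for (j in seq_along(peak_sets)) {
      ps <- peak_sets[[j]]
      for (i in seq_len(nrow(rates))) {
        nij <- stats::rbinom(1, m[j], rates[i, j])
        n[i, j] <- nij
        if (nij > 0) {
          carriers <- ps[sample.int(m[j], nij), , drop = FALSE]
          offs <- floor(stats::runif(nij) * (carriers$end - carriers$start))
          pos[[length(pos) + 1]] <- data.frame(
            motif = rownames(rates)[i], set = colnames(rates)[j],
            chrom = carriers$chrom, pos = carriers$start + offs,
            stringsAsFactors = FALSE)
        }
      }
    }
    positions <- if (length(pos)) do.call(rbind, pos) else
      data.frame(motif = character(), set = character(), chrom = character(),
                 pos = numeric(), stringsAsFactors = FALSE)
    rownames(positions) <- NULL
    list(counts = motif_counts(n, m), positions = positions)
  })
}

#' Simulate paired differential-expression tables with planted trajectories
#'
#' Assigns each gene a trajectory category from `mix` and emits noiseless
#' fold changes at the planted magnitude, so [classify_trajectory] recovers
#' the planted categories exactly. Changed genes get adjusted p 1e-4,
#' unchanged genes 0.5.
#'
#' @param n_genes number of genes (default 2000).
#' @param mix named probabilities over the seven trajectory categories
#'   (default: 70% unchanged, the rest split evenly).
#' @param fold planted linear fold magnitude for changed genes (default 4).
#' @param seed integer seed.
#' @return List: `minus` and `plus` DE data.frames (`gene_id`, `log2fc`,
#'   `adj_p`, `contrast`) and `truth` (gene_id, category).
#' @export
simulate_de_tables <- function(n_genes = 2000, mix = NULL, fold = 4,
                               seed = 1) {
  if (is.null(mix)) {
    mix <- c(rep(0.05, 6), 0.7)
    names(mix) <- .trajectory_levels
  }
  if (!setequal(names(mix), .trajectory_levels))
    stop("mix must be named over the seven trajectory categories")
  if (abs(sum(mix) - 1) > 1e-8) stop("validation error: mix must sum to 1")
  mix <- mix[.trajectory_levels]
  with_local_seed(seed, {
    ns <- round(n_genes * mix)
    ns[length(ns)] <- n_genes - sum(ns[-length(ns)])
    category <- sample(rep(names(ns), ns))
    fc_of <- function(dir) ifelse(dir == "up", fold,
                                  ifelse(dir == "down", 1 / fold, 1))
    dir_minus <- ifelse(category %in% c("up_both", "up_minus_only"), "up",
                 ifelse(category %in% c("down_both", "down_minus_only"),
                        "down", "flat"))
    dir_plus <- ifelse(category %in% c("up_both", "up_plus_only"), "up",
                ifelse(category %in% c("down_both", "down_plus_only"),
                       "down", "flat"))
    gene_id <- sprintf("gene_%05d", seq_len(n_genes))
    mk <- function(dir, contrast) data.frame(
      gene_id = gene_id, log2fc = log2(fc_of(dir)),
      adj_p = ifelse(dir == "flat", 0.5, 1e-4), contrast = contrast,
      stringsAsFactors = FALSE)
    list(minus = mk(dir_minus, "minus"), plus = mk(dir_plus, "plus"),
         truth = data.frame(gene_id = gene_id, category = category,
                            stringsAsFactors = FALSE))
  })
}
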