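#' Expression filter on raw counts
#'
#' Keeps genes detected with at least `min_reads` reads in at least one
#' sample.
#'
#' @param counts integer matrix, genes x samples, with gene row names.
#' @param min_reads detection threshold (default 50).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(counts, min_reads = 50) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0) return(character(0))
  if (any(counts < 0)) stop("validation error: counts must be >= 0")
  keep <- apply(counts, 1, max) >= min_reads
  rownames(counts)[keep]
}

.trajectory_levels <- c("up_both", "up_minus_only", "up_plus_only",
                        "down_minus_only", "down_plus_only", "down_both",
                        "unchanged")

#' Classify expression trajectories across two conditions
#'
#' Given linear fold changes across the HE-to-progenitor transition in the
#' uninduced (`fc_minus`) and induced (`fc_plus`) condition, a gene is "up"
#' in a condition when its fold is at least `threshold` and "down" when at
#' most `1/threshold`. Each gene maps to exactly one of seven categories:
#' up/down in both, up/down in only one condition, or unchanged. Discordant
#' genes (up in one condition, down in the other) are assigned to the
#' condition with the larger absolute log2 fold change; on a tie the
#' up-regulated side wins, which keeps the classification exactly symmetric
#' under swapping conditions. Use [trajectory_tallies] for figure-style
#' counts where discordant genes contribute to both per-condition tallies.
#'
#' @param fc_minus,fc_plus positive linear fold changes.
#' @param threshold fold threshold (default 2).
#' @return Factor with the seven trajectory levels.
#' @export
classify_trajectory <- function(fc_minus, fc_plus, threshold = 2) {
  if (any(fc_minus <= 0) || any(fc_plus <= 0))
    stop("validation error: fold changes must be positive")
  um <- fc_minus >= threshold
  dm <- fc_minus <= 1 / threshold
  up <- fc_plus >= threshold
  dp <- fc_plus <= 1 / threshold
  lm <- abs(log2(fc_minus))
  lp <- abs(log2(fc_plus))
  cls <- rep("unchanged", length(fc_minus))
  cls[um & up] <- "up_both"
  cls[dm & dp] <- "down_both"
  cls[um & !up & !dp] <- "up_minus_only"
  cls[dm & !dp & !up] <- "down_minus_only"
  cls[up & !um & !dm] <- "up_plus_only"
  cls[dp & !dm & !um] <- "down_plus_only"
  disc_mu <- um & dp   # up in -dox, down in +dox
  disc_pu <- up & dm   # up in +dox, down in -dox
  cls[disc_mu] <- ifelse(lm[disc_mu] >= lp[disc_mu],
                         "up_minus_only", "down_plus_only")
  cls[disc_pu] <- ifelse(lp[disc_pu] >= lm[disc_pu],
                         "up_plus_only", "down_minus_only")
  factor(cls, levels = .trajectory_levels)
}

#' Trajectory tallies with discordant genes in both condition columns
#'
#' Figure-style counts: a discordant gene (up in one condition, down in the
#' other) contributes to the "-only" tally of each condition, so the tallies
#' can sum to more than the number of genes.
#'
#' @inheritParams classify_trajectory
#' @return Named integer vector over the seven categories.
#' @export
trajectory_tallies <- function(fc_minus, fc_plus, threshold = 2) {
  if (any(fc_minus <= 0) || any(fc_plus <= 0))
    stop("validation error: fold changes must be positive")
  um <- fc_minus >= threshold; dm <- fc_minus <= 1 / threshold
  up <- fc_plus >= threshold;  dp <- fc_plus <= 1 / threshold
  c(up_both = sum(um & up),
    up_minus_only = sum(um & !up),
    up_plus_only = sum(up & !um),
    down_minus_only = sum(dm & !dp),
    down_plus_only = sum(dp & !dm),
    down_both = sum(dm & dp),
    unchanged = sum(!um & !dm & !up & !dp))
}

#' Pairwise concordant / opposing overlap of deregulated gene sets
#'
#' For every pair of contrasts, the concordant count is mutual-up plus
#' mutual-down, and the opposing count is up-in-row and down-in-column
#' (generally asymmetric).
#'
#' @param de_sets named list; each element is a list with character vectors
#'   `up` and `down`.
#' @return List with matrices `concordant` and `opposing`, plus `flagged`:
#'   names of contrasts whose up and down sets are both empty.
#' @export
pairwise_overlap <- function(de_sets) {
  if (length(de_sets) < 2) stop("need >= 2 contrasts")
  nm <- names(de_sets)
  k <- length(nm)
  conc <- opp <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    conc[i, j] <- length(intersect(de_sets[[i]]$up, de_sets[[j]]$up)) +
      length(intersect(de_sets[[i]]$down, de_sets[[j]]$down))
    opp[i, j] <- length(intersect(de_sets[[i]]$up, de_sets[[j]]$down))
  }
  flagged <- nm[vapply(de_sets, function(s)
    length(s$up) == 0 && length(s$down) == 0, logical(1))]
  list(concordant = conc, opposing = opp, flagged = flagged)
}

#' Deregulated genes from a DE table
#'
#' Twofold deregulation; when an `adj_p` column is present (and non-NA) the
#' adjusted-p cutoff is applied as well, otherwise the fold rule alone is
#' used (matching figure captions that state only "twofold up- or
#' down-regulated").
#'
#' @param de data.frame with `gene_id`, `log2fc` and optionally `adj_p`.
#' @param fold_threshold linear fold threshold (default 2).
#' @param adj_p_threshold adjusted-p cutoff (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
deregulated_genes <- function(de, fold_threshold = 2, adj_p_threshold = 0.05) {
  lfc <- de$log2fc
  sig <- if ("adj_p" %in% names(de) && !all(is.na(de$adj_p)))
    !is.na(de$adj_p) & de$adj_p < adj_p_threshold else rep(TRUE, nrow(de))
  thr <- log2(fold_threshold)
  list(up = de$gene_id[sig & lfc >= thr],
       down = de$gene_id[sig & lfc <= -thr])
}

#' Fold-change correlation across contrasts
#'
#' Builds the contrast x gene matrix of log2 fold changes over the union of
#' deregulated genes across all contrasts and delegates to
#' [correlation_cluster]. Genes missing from a contrast are imputed with
#' log2fc = 0 (kept-common feature space) unless `drop_missing = TRUE`, in
#' which case only genes present in every contrast are used.
#'
#' @param tables named list of DE data.frames (`gene_id`, `log2fc`, optional
#'   `adj_p`).
#' @param fold_threshold,adj_p_threshold deregulation rule, as in
#'   [deregulated_genes].
#' @param drop_missing drop genes absent from any contrast instead of
#'   imputing 0.
#' @return As [correlation_cluster], plus element `genes` (the feature
#'   space).
#' @export
fold_change_correlation <- function(tables, fold_threshold = 2,
                                    adj_p_threshold = 0.05,
                                    drop_missing = FALSE) {
  if (length(tables) < 2) stop("need >= 2 contrasts")
  dereg <- lapply(tables, deregulated_genes, fold_threshold, adj_p_threshold)
  genes <- sort(unique(unlist(lapply(dereg, unlist), use.names = FALSE)))
  if (length(genes) < 2) stop("fewer than 2 deregulated genes across contrasts")
  if (drop_missing) {
    present <- lapply(tables, function(t) t$gene_id)
    genes <- Reduce(intersect, present, genes)
    if (length(genes) < 2) stop("fewer than 2 shared deregulated genes")
  }
  mat <- t(vapply(tables, function(t) {
    v <- t$log2fc[match(genes, t$gene_id)]
    v[is.na(v)] <- 0
    v
  }, numeric(length(genes))))
  colnames(mat) <- genes
  out <- correlation_cluster(mat)
  out$genes <- genes
  out
}
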