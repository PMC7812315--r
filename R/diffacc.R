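#' Build a summit-merged peak union across two conditions
#'
#' Peaks from the uninduced (`set_minus`) and induced (`set_plus`) samples are
#' merged whenever their summits lie within `summit_distance` bp on the same
#' chromosome. Merging is transitive (chain rule, as in `bedtools merge`): the
#' merged summit is the floor of the arithmetic mean of all member summits —
#' for two peaks, the midpoint between the original summits — and the merged
#' interval spans min start to max end. Unmerged peaks pass through unchanged.
#'
#' @param set_minus,set_plus [peak_set] objects for the two conditions.
#' @param summit_distance maximum summit separation (bp) for merging.
#' @return A data frame of class `union_peaks`, sorted by `(chrom, start)`,
#'   with columns `name`, `chrom`, `start`, `end`, `summit`, `n_members`,
#'   `members_minus`, `members_plus` (comma-separated source peak names).
#' @export
build_peak_union <- function(set_minus, set_plus, summit_distance = 400) {
  if (summit_distance < 0)
    stop("validation error: summit_distance must be >= 0")
  cond_df <- function(ps, cond)
    data.frame(chrom = ps$chrom, start = ps$start, end = ps$end,
               summit = ps$summit, src = ps$name,
               cond = rep(cond, nrow(ps)), stringsAsFactors = FALSE)
  all <- rbind(cond_df(set_minus, "minus"), cond_df(set_plus, "plus"))
  if (nrow(all) == 0) {
    out <- data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(), summit = numeric(),
                      n_members = integer(), members_minus = character(),
                      members_plus = character(), stringsAsFactors = FALSE)
    return(structure(out, class = c("union_peaks", "data.frame")))
  }
  all <- all[order(all$chrom, all$summit, all$start, all$src), , drop = FALSE]
  new_grp <- c(TRUE, all$chrom[-1] != all$chrom[-nrow(all)] |
                 diff(all$summit) > summit_distance)
  grp <- cumsum(new_grp)
  agg <- function(f, x) unname(tapply(x, grp, f))
  out <- data.frame(
    chrom = agg(function(x) x[1], all$chrom),
    start = agg(min, all$start),
    end = agg(max, all$end),
    summit = floor(as.numeric(agg(mean, all$summit))),
    n_members = as.integer(agg(length, all$src)),
    members_minus = unname(tapply(seq_len(nrow(all)), grp, function(i)
      paste(all$src[i][all$cond[i] == "minus"], collapse = ","))),
    members_plus = unname(tapply(seq_len(nrow(all)), grp, function(i)
      paste(all$src[i][all$cond[i] == "plus"], collapse = ","))),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out <- cbind(name = sprintf("u%06d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("union_peaks", "data.frame"))
}

#' Promoter-proximal versus distal classification
#'
#' A peak is promoter-proximal when its summit lies within `window` bp
#' (inclusive) of the nearest TSS, distal otherwise. Peaks on chromosomes
#' without annotated genes are distal. Promoter and distal elements are
#' treated separately downstream (normalisation and differential calling run
#' within each class).
#'
#' @param peaks a [peak_set] or `union_peaks` data frame.
#' @param genes gene table as from [read_genes].
#' @param window promoter window in bp (default 1500).
#' @return Character vector, `"promoter"` or `"distal"`, along `peaks` rows.
#' @export
classify_element <- function(peaks, genes, window = 1500) {
  if (nrow(genes) == 0) stop("gene table is empty")
  nt <- nearest_tss(peaks$chrom, peaks$summit, genes)
  ifelse(!is.na(nt$distance) & abs(nt$distance) <= window, "promoter", "distal")
}

#' Counts-per-million normalisation with log transform
#'
#' Scales each sample column so it sums to one million, then log-transforms
#' with a pseudocount: `log2(CPM + 1)`.
#'
#' @param raw numeric matrix, regions x samples, of windowed tag densities.
#' @return List with elements `cpm` and `log2` (matrices of the same shape).
#' @export
cpm_log_normalize <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("validation error: densities must be >= 0")
  cs <- colSums(raw)
  if (any(cs == 0)) {
    nm <- colnames(raw)[which(cs == 0)[1]]
    if (is.null(nm)) nm <- paste0("column ", which(cs == 0)[1])
    stop("zero column sum for sample ", nm)
  }
  cpm <- sweep(raw, 2, cs, "/") * 1e6
  list(cpm = cpm, log2 = log2(cpm + 1))
}

#' Call gained / lost / shared peaks from per-condition CPM
#'
#' The fold change is `(cpm_plus + 1) / (cpm_minus + 1)` (pseudocount 1 keeps
#' zero-coverage peaks well defined). A peak is `gained` when the fold is at
#' least `fold_threshold`, `lost` when at most `1/fold_threshold`, `shared`
#' otherwise; the boundary counts as differential ("at least" a
#' `fold_threshold`-fold difference).
#'
#' @param cpm_minus,cpm_plus CPM vectors for the two conditions.
#' @param fold_threshold fold-change threshold (default 2).
#' @return data.frame with columns `cpm_minus`, `cpm_plus`, `log2_minus`,
#'   `log2_plus`, `fold`, `class`.
#' @export
call_differential <- function(cpm_minus, cpm_plus, fold_threshold = 2) {
  if (fold_threshold <= 1) stop("validation error: fold_threshold must be > 1")
  fold <- (cpm_plus + 1) / (cpm_minus + 1)
  cls <- ifelse(fold >= fold_threshold, "gained",
                ifelse(fold <= 1 / fold_threshold, "lost", "shared"))
  data.frame(cpm_minus = cpm_minus, cpm_plus = cpm_plus,
             log2_minus = log2(cpm_minus + 1), log2_plus = log2(cpm_plus + 1),
             fold = fold, class = cls, stringsAsFactors = FALSE)
}

#' Full differential-accessibility (or differential-binding) table
#'
#' Quantifies summit-centred tag density in each condition, normalises as CPM
#' within each element class (promoter and distal regions separately, since
#' they are analysed separately throughout), and applies the twofold call.
#' The same code path serves ChIP differential analysis, where only the
#' window width changes (see [differential_chip]).
#'
#' @param union a `union_peaks` data frame from [build_peak_union] (any data
#'   frame with `name`, `chrom`, `start`, `end`, `summit` works).
#' @param track_minus,track_plus [tag_track] objects for the two conditions.
#' @param genes gene table for promoter/distal classification, or `NULL` to
#'   treat every peak as one class (`element = "all"`).
#' @param window tag-density window width in bp (default 400).
#' @param fold_threshold fold-change threshold (default 2).
#' @param promoter_window promoter distance in bp (default 1500).
#' @param verbose message the per-class counts (the run log).
#' @return A data frame of class `differential_table` with columns `name`,
#'   `chrom`, `start`, `end`, `summit`, `element`, `cpm_minus`, `cpm_plus`,
#'   `log2_minus`, `log2_plus`, `fold`, `class`.
#' @export
differential_table <- function(union, track_minus, track_plus, genes = NULL,
                               window = 400, fold_threshold = 2,
                               promoter_window = 1500, verbose = FALSE) {
  element <- if (is.null(genes)) rep("all", nrow(union))
             else classify_element(union, genes, promoter_window)
  raw <- cbind(minus = window_tag_density(track_minus, union$chrom,
                                          union$summit, window),
               plus = window_tag_density(track_plus, union$chrom,
                                         union$summit, window))
  cpm <- matrix(NA_real_, nrow(union), 2, dimnames = list(NULL, c("minus", "plus")))
  for (el in unique(element)) {
    i <- element == el
    cpm[i, ] <- cpm_log_normalize(raw[i, , drop = FALSE])$cpm
  }
  calls <- call_differential(cpm[, "minus"], cpm[, "plus"], fold_threshold)
  out <- cbind(union[, c("name", "chrom", "start", "end", "summit")],
               element = element, calls, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (verbose) {
    tab <- table(out$element, out$class)
    message("differential calls: ",
            paste(sprintf("%s/%s=%d", rep(rownames(tab), ncol(tab)),
                          rep(colnames(tab), each = nrow(tab)), as.vector(tab)),
                  collapse = " "))
  }
  structure(out, class = c("differential_table", "data.frame"))
}

#' Write / read a differential table as headered TSV
#' @param x a `differential_table`.
#' @param path file path.
#' @export
write_differential_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_differential_table
#' @export
read_differential_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  structure(x, class = c("differential_table", "data.frame"))
}

#' Fold-ranked tag-density heatmap matrices
#'
#' Rows are union peaks ordered by descending fold change — the same order in
#' every track, so per-condition heatmaps are directly comparable — and
#' columns are `window/bin` bins centred on the summit.
#'
#' @param diff_table a `differential_table`.
#' @param tracks named list of [tag_track] objects.
#' @param window,bin window and bin widths in bp.
#' @return Named list of matrices, one per track, plus attribute `order`
#'   giving the peak names in row order.
#' @export
ranked_density_matrix <- function(diff_table, tracks, window = 2000, bin = 10) {
  ord <- order(-diff_table$fold, diff_table$name)
  dt <- diff_table[ord, , drop = FALSE]
  mats <- lapply(tracks, function(tr)
    density_matrix(tr, dt$chrom, dt$summit, window = window, bin = bin,
                   names = dt$name))
  attr(mats, "order") <- dt$name
  mats
}

#' Pearson correlation with complete-linkage clustering
#'
#' Computes the pairwise Pearson correlation matrix of the sample rows and a
#' complete-linkage hierarchical clustering of the Euclidean distances
#' between sample vectors (the heatmap ordering used for both accessibility
#' and expression fold-change panels).
#'
#' @param mat numeric matrix, samples x features (log2 tag counts or fold
#'   changes).
#' @return List with `correlation` (symmetric, unit diagonal), `order` (leaf
#'   order indices), and `hclust` (the tree).
#' @export
correlation_cluster <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need >= 2 samples")
  if (ncol(mat) < 2) stop("need >= 2 features")
  v <- apply(mat, 1, stats::var)
  if (any(v == 0)) {
    nm <- rownames(mat)[which(v == 0)[1]]
    if (is.null(nm)) nm <- paste0("sample ", which(v == 0)[1])
    stop("zero-variance sample: correlation undefined for ", nm)
  }
  cc <- stats::cor(t(mat))
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  list(correlation = cc, order = hc$order, hclust = hc)
}
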