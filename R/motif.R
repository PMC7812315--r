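#' Motif hit counts across peak sets
#'
#' Container for the inputs of the enrichment score: `n[i, j]` is the number
#' of sites in peak set `j` carrying motif `i`, and `m[j]` is the total
#' number of sites in peak set `j`.
#'
#' @param n integer matrix, motifs x peak sets, of hit counts.
#' @param m integer vector of peak-set sizes, one per column of `n`.
#' @return Object of class `motif_counts`.
#' @export
motif_counts <- function(n, m) {
  n <- as.matrix(n)
  if (length(m) != ncol(n)) stop("length(m) must equal ncol(n)")
  if (any(m <= 0)) stop("validation error: peak-set sizes m must be > 0")
  if (any(n < 0) || any(sweep(n, 2, m, ">")))
    stop("validation error: counts must satisfy 0 <= n_ij <= m_j")
  if (is.null(rownames(n))) rownames(n) <- sprintf("motif_%03d", seq_len(nrow(n)))
  if (is.null(colnames(n))) colnames(n) <- sprintf("set_%02d", seq_len(ncol(n)))
  names(m) <- colnames(n)
  structure(list(n = n, m = m), class = "motif_counts")
}

#' Aggregate a per-peak binary hit table to motif counts
#'
#' Accepts the output of any motif scanner as a long table of per-peak binary
#' calls and collapses it to `motif_counts`: `n_ij` = number of distinct
#' peaks of set `j` with a hit for motif `i`, `m_j` = number of distinct
#' peaks listed for set `j`.
#'
#' @param hits data.frame with columns `set`, `peak`, `motif`, `hit` (0/1).
#' @return A [motif_counts].
#' @export
aggregate_motif_hits <- function(hits) {
  required <- c("set", "peak", "motif", "hit")
  if (!all(required %in% names(hits)))
    stop("hit table must have columns: ", paste(required, collapse = ", "))
  sets <- sort(unique(hits$set))
  motifs <- sort(unique(hits$motif))
  m <- vapply(sets, function(s)
    length(unique(hits$peak[hits$set == s])), integer(1))
  n <- matrix(0L, length(motifs), length(sets),
              dimnames = list(motifs, sets))
  pos <- hits[hits$hit > 0, , drop = FALSE]
  if (nrow(pos)) {
    key <- paste(pos$motif, pos$set, pos$peak, sep = "\r")
    pos <- pos[!duplicated(key), , drop = FALSE]
    tab <- table(factor(pos$motif, motifs), factor(pos$set, sets))
    n[] <- as.integer(tab)
  }
  motif_counts(n, m)
}

#' Read / write motif counts as long TSV (motif, set, n, m)
#' @param path file path.
#' @export
read_motif_counts <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  motifs <- unique(x$motif)
  sets <- unique(x$set)
  n <- matrix(0L, length(motifs), length(sets), dimnames = list(motifs, sets))
  n[cbind(match(x$motif, motifs), match(x$set, sets))] <- x$n
  m <- vapply(sets, function(s) unique(x$m[x$set == s])[1], numeric(1))
  motif_counts(n, m)
}

#' @rdname read_motif_counts
#' @param counts a [motif_counts].
#' @export
write_motif_counts <- function(counts, path) {
  long <- expand.grid(motif = rownames(counts$n), set = colnames(counts$n),
                      stringsAsFactors = FALSE)
  long$n <- as.vector(counts$n)
  long$m <- counts$m[long$set]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Motif enrichment score matrix
#'
#' For motif `i` in peak set `j`, the score is the per-set hit frequency
#' divided by the pooled frequency across all sets:
#' `S_ij = (n_ij / m_j) / (sum_j n_ij / sum_j m_j)`.
#' A score of 1 means no enrichment; values above (below) 1 mean the motif is
#' over- (under-) represented in that set relative to the pool. The
#' `m_j`-weighted mean of each motif row is exactly 1 by construction.
#' Motifs observed in no set are dropped with a warning.
#'
#' @param counts a [motif_counts].
#' @return Numeric matrix of scores, motifs x peak sets.
#' @export
enrichment_scores <- function(counts) {
  n <- counts$n
  m <- counts$m
  tot <- rowSums(n)
  if (any(tot == 0)) {
    warning("dropping ", sum(tot == 0), " motif(s) observed in no peak set")
    n <- n[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  rate <- sweep(n, 2, m, "/")
  global <- tot / sum(m)
  sweep(rate, 1, global, "/")
}

#' Per-row z-scaled scores for display
#'
#' Optional display normalisation of the score matrix: each motif row is
#' centred and scaled to unit SD. Raw scores remain the quantitative output.
#'
#' @param S score matrix from [enrichment_scores].
#' @return Row-z-scored matrix.
#' @export
score_zscale <- function(S) {
  t(scale(t(S)))
}

#' Deterministic clustering of a score matrix
#'
#' Complete-linkage hierarchical clustering of Euclidean distances, applied
#' to motif rows and (when there are at least two) to peak-set columns. Ties
#' are resolved by the deterministic agglomeration sequence, so equal inputs
#' give equal orderings.
#'
#' @param S score matrix (>= 2 motifs for a non-trivial row order).
#' @return List with `row_order` and `col_order` index vectors.
#' @export
cluster_scores <- function(S) {
  S <- as.matrix(S)
  row_order <- if (nrow(S) >= 2)
    stats::hclust(stats::dist(S), method = "complete")$order
  else seq_len(nrow(S))
  col_order <- if (ncol(S) >= 2)
    stats::hclust(stats::dist(t(S)), method = "complete")$order
  else seq_len(ncol(S))
  list(row_order = row_order, col_order = col_order)
}

#' Motif-density matrix around peak summits
#'
#' Counts motif hit positions per bin in a window centred on each reference
#' summit: cell `[r, b]` is the number of hits falling in bin `b` of the
#' half-open window `[summit_r - window/2, summit_r + window/2)`.
#'
#' @param positions data.frame of hit positions with columns `chrom`, `pos`.
#' @param summits data.frame with columns `chrom`, `summit` and optionally
#'   `name` (row names of the result).
#' @param window,bin window and bin widths in bp.
#' @return Integer matrix, references x `window/bin` bins.
#' @export
motif_density_matrix <- function(positions, summits, window = 2000, bin = 10) {
  if (window %% bin != 0) stop("validation error: window must be divisible by bin")
  nb <- window / bin
  out <- matrix(0L, nrow(summits), nb)
  rownames(out) <- summits$name
  colnames(out) <- sprintf("bin_%03d", seq_len(nb))
  half <- window / 2
  for (ch in unique(summits$chrom)) {
    ri <- which(summits$chrom == ch)
    p <- sort(positions$pos[positions$chrom == ch])
    if (length(p) == 0) next
    for (i in ri) {
      w0 <- summits$summit[i] - half
      lo <- findInterval(w0 - 0.5, p) + 1
      hi <- findInterval(w0 + window - 0.5, p)
      if (hi < lo) next
      b <- floor((p[lo:hi] - w0) / bin) + 1
      out[i, ] <- out[i, ] + tabulate(b, nbins = nb)
    }
  }
  out
}
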