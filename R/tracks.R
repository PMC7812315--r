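#' Piecewise-constant signal tracks
#'
#' A `tag_track` holds per-base tag density with bedGraph semantics:
#' non-overlapping covered intervals carry a non-negative value and uncovered
#' bases are implicitly zero. Internally the track is a run-length encoded
#' coverage vector per chromosome, which makes windowed sums around peak
#' summits cheap.
#'
#' @param chrom,start,end interval coordinates (0-based, half-open).
#' @param value non-negative density over each interval.
#' @return An object of class `tag_track`.
#' @export
tag_track <- function(chrom, start, end, value) {
  if (length(chrom) == 1) chrom <- rep(chrom, length(start))
  if (any(value < 0)) stop("validation error: track values must be >= 0")
  if (any(end <= start)) stop("validation error: end must be > start")
  ord <- order(chrom, start)
  chrom <- chrom[ord]; start <- start[ord]; end <- end[ord]; value <- value[ord]
  for (ch in unique(chrom)) {
    i <- chrom == ch
    s <- start[i]; e <- end[i]
    if (length(s) > 1 && any(s[-1] < e[-length(e)]))
      stop("validation error: overlapping track intervals on ", ch)
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  cov <- GenomicRanges::coverage(gr, weight = value)
  structure(list(cov = cov), class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat(sprintf("tag_track: %d chromosome(s), total covered signal %.4g\n",
              length(x$cov), sum(vapply(x$cov, sum, numeric(1)))))
  invisible(x)
}

#' Read a bedGraph signal track
#'
#' Four-column bedGraph (chrom, start, end, value); track lines are handled by
#' the importer. Intervals must be non-overlapping and values non-negative.
#'
#' @param path bedGraph file.
#' @return A [tag_track].
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) && !IRanges::isDisjoint(gr))
    stop("validation error: overlapping intervals in ", path)
  if (length(gr) && any(gr$score < 0))
    stop("validation error: negative track values in ", path)
  cov <- GenomicRanges::coverage(gr, weight = "score")
  structure(list(cov = cov), class = "tag_track")
}

#' Write a track as bedGraph
#'
#' Zero runs are omitted (uncovered bases are implicitly zero). Tab-separated,
#' no header.
#'
#' @param track a [tag_track].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  out <- character(0)
  for (ch in names(track$cov)) {
    r <- track$cov[[ch]]
    v <- S4Vectors::runValue(r)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0, ends[-length(ends)])
    keep <- v != 0
    if (any(keep))
      out <- c(out, sprintf("%s\t%d\t%d\t%s", ch, as.integer(starts[keep]),
                            as.integer(ends[keep]), as.character(v[keep])))
  }
  writeLines(out, path)
  invisible(path)
}

# Sum of track values over 1-based closed windows [s1, e1] on one chromosome
# Rle, with out-of-range bases contributing zero.
rle_window_sums <- function(r, s1, e1) {
  res <- numeric(length(s1))
  len <- length(r)
  if (len == 0) return(res)
  s <- pmax(s1, 1)
  e <- pmin(e1, len)
  ok <- s <= e
  if (any(ok)) {
    v <- IRanges::Views(r, start = s[ok], end = e[ok])
    res[ok] <- IRanges::viewSums(v)
  }
  res
}

#' Mean tag density in fixed windows around summits
#'
#' Computes the average track value over the half-open window
#' `[summit - width/2, summit + width/2)` for each summit. Windows truncated
#' at the chromosome start keep divisor `width`: off-chromosome bases count as
#' zero coverage.
#'
#' @param track a [tag_track].
#' @param chrom,summit parallel vectors locating the window centres.
#' @param width window width in bp; must be positive and even.
#' @return Numeric vector of mean densities.
#' @export
window_tag_density <- function(track, chrom, summit, width = 400) {
  if (width <= 0 || width %% 2 != 0)
    stop("validation error: width must be positive and even")
  res <- numeric(length(summit))
  half <- width / 2
  for (ch in unique(chrom)) {
    i <- chrom == ch
    r <- track$cov[[ch]]
    if (is.null(r)) next
    s0 <- summit[i] - half           # 0-based window start
    res[i] <- rle_window_sums(r, s0 + 1, s0 + width) / width
  }
  res
}

#' Binned tag-density matrix around summits
#'
#' For each summit, the window `[summit - window/2, summit + window/2)` is cut
#' into `window/bin` consecutive bins and the mean density per bin is
#' returned. This is the per-region matrix underlying ranked heatmaps and
#' average profiles.
#'
#' @inheritParams window_tag_density
#' @param window full window width in bp.
#' @param bin bin width in bp; `window` must be divisible by `bin`.
#' @param names optional row names.
#' @return Numeric matrix, one row per summit, `window/bin` columns.
#' @export
density_matrix <- function(track, chrom, summit, window = 2000, bin = 10,
                           names = NULL) {
  if (window %% bin != 0) stop("validation error: window must be divisible by bin")
  nb <- window / bin
  n <- length(summit)
  mat <- matrix(0, nrow = n, ncol = nb)
  half <- window / 2
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    r <- track$cov[[ch]]
    if (is.null(r)) next
    w0 <- summit[i] - half
    bs <- rep(w0, each = nb) + rep.int((seq_len(nb) - 1) * bin, length(i))
    sums <- rle_window_sums(r, bs + 1, bs + bin)
    mat[i, ] <- matrix(sums / bin, ncol = nb, byrow = TRUE)
  }
  rownames(mat) <- names
  colnames(mat) <- sprintf("bin_%03d", seq_len(nb))
  mat
}
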