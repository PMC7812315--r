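# Shared fixtures and independent oracles used across the suite.

# Quick single-chromosome peak set from starts (fixed width).
make_ps <- function(starts, width = 100, chrom = "chr1", label = "",
                    summit = NULL) {
  peak_set(chrom, starts, starts + width, summit = summit, label = label)
}

# Random peak set on a couple of chromosomes; assumes a seeded RNG.
random_ps <- function(n, chroms = c("chr1", "chr2"), span = 1e6,
                      max_width = 500, label = "") {
  start <- sample.int(span, n)
  width <- sample.int(max_width, n)
  peak_set(sample(chroms, n, replace = TRUE), start, start + width,
           name = sprintf("rp_%04d", seq_len(n)), label = label)
}

# Brute-force all-pairs overlap count: query peaks overlapping >= 1 bp of
# any reference peak (half-open arithmetic, no interval tree).
brute_intersect_count <- function(query, reference) {
  sum(vapply(seq_len(nrow(query)), function(i) {
    any(reference$chrom == query$chrom[i] &
          reference$start < query$end[i] &
          reference$end > query$start[i])
  }, logical(1)))
}

# Brute-force transitive summit merge: build the full O(n^2) pairwise
# adjacency (same chromosome, summits within `dist`) and take connected
# components by breadth-first search — no sorting, no sweep.
brute_union_summits <- function(chrom, summit, dist) {
  n <- length(summit)
  adj <- outer(summit, summit, function(a, b) abs(a - b) <= dist) &
    outer(chrom, chrom, `==`)
  grp <- rep(NA_integer_, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (!is.na(grp[i])) next
    g <- g + 1L
    frontier <- i
    while (length(frontier)) {
      grp[frontier] <- g
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(grp))
      frontier <- nxt
    }
  }
  out <- lapply(split(seq_len(n), grp), function(idx)
    list(chrom = chrom[idx][1], summit = floor(mean(summit[idx])),
         size = length(idx)))
  out[order(vapply(out, `[[`, character(1), "chrom"),
            vapply(out, `[[`, numeric(1), "summit"))]
}

# Exact hypergeometric mean/SD of the overlap count when sampling n peaks
# from a universe of N of which K overlap the signature.
hyper_moments <- function(N, K, n) {
  k <- 0:min(K, n)
  p <- stats::dhyper(k, K, N - K, n)
  mu <- sum(k * p)
  list(mu = mu, sigma = sqrt(sum((k - mu)^2 * p)))
}

# Small universe/signature/test triple used by several priming tests:
# 20 spaced universe peaks, signature overlapping the first five, test set
# of 8 of which 4 carry the signature.
worked_priming_instance <- function() {
  uni <- make_ps((0:19) * 1000, width = 400, chrom = "chrS")
  sig <- peak_set("chrS", (0:4) * 1000 + 100, (0:4) * 1000 + 200)
  test <- uni[c(1:4, 10:13), , drop = FALSE]
  class(test) <- class(uni)
  list(universe = uni, signature = sig, test = test)
}
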