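#' Summit-anchored peak sets
#'
#' A `peak_set` is a plain data frame of summit-anchored genomic intervals with
#' columns `chrom`, `start`, `end` (0-based, half-open, BED convention),
#' `name`, `score` and `summit` (absolute base position, `start <= summit <
#' end`). Rows are kept sorted by `(chrom, start, end, name)` and names are
#' unique within a set. The summit is the anchor for every windowed
#' computation in the pipeline (tag density, peak-union merging, motif
#' density, nearest-gene distances).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open coordinates.
#' @param name optional character vector of unique identifiers; generated as
#'   `peak_00001`-style names when `NULL`.
#' @param score optional numeric score (`NA` allowed).
#' @param summit optional absolute summit positions; defaults to the interval
#'   midpoint, rounded down.
#' @param label sample or condition label carried as an attribute.
#' @return A data frame of class `peak_set`.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NA_real_,
                     summit = NULL, label = "") {
  n <- length(start)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (n > 0 && any(start < 0))
    stop("validation error: start must be >= 0")
  if (n > 0 && any(end <= start))
    stop("validation error: end must be > start")
  if (n > 0 && any(!nzchar(chrom)))
    stop("validation error: chrom must be non-empty")
  if (is.null(summit)) summit <- floor((start + end) / 2)
  summit <- as.numeric(summit)
  if (n > 0 && (any(summit < start) || any(summit >= end)))
    stop("validation error: summit must lie within [start, end)")
  if (is.null(name)) name <- sprintf("peak_%05d", seq_len(n))
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("validation error: peak names must be unique within a set")
  score <- rep_len(as.numeric(score), max(n, 0L))
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = name, score = score, summit = summit,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end, df$name), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label, class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("peak_set%s: %d peaks on %d chromosome(s)\n",
              if (nzchar(lab)) paste0(" '", lab, "'") else "",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

# GRanges view of a peak_set (1-based closed), used for all overlap queries.
peaks_gr <- function(ps) {
  GenomicRanges::GRanges(
    seqnames = if (nrow(ps)) ps$chrom else character(),
    ranges = IRanges::IRanges(start = ps$start + 1, end = ps$end))
}

#' Read peak calls from BED-family files
#'
#' Supports three dialects: `bed` (BED3/BED6; summit falls back to the
#' interval midpoint, rounded down), `narrowPeak` (BED6+4; column 10 is the
#' 0-based summit offset from `start`, `-1` meaning unknown and triggering the
#' midpoint fallback), and `summit-bed` (1-bp summit intervals as emitted by
#' peak callers; the summit is the interval start). Track and comment lines
#' are skipped. Malformed lines raise an error naming the offending line
#' number.
#'
#' @param path file to read.
#' @param format one of `"bed"`, `"narrowPeak"`, `"summit-bed"`.
#' @param label label attached to the returned set.
#' @return A [peak_set].
#' @export
read_peaks <- function(path, format = c("bed", "narrowPeak", "summit-bed"),
                       label = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0)
    return(peak_set(character(), numeric(), numeric(), label = label))
  fields <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fields)
  min_cols <- switch(format, bed = 3L, narrowPeak = 10L, `summit-bed` = 3L)
  bad <- which(nf < min_cols)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: expected >= %d fields, found %d",
                 idx[bad[1]], path, min_cols, nf[bad[1]]))
  get_col <- function(j) vapply(fields, function(f) f[[j]], character(1))
  num_col <- function(j, what) {
    v <- suppressWarnings(as.numeric(get_col(j)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("parse error at line %d of %s: non-numeric %s field",
                   idx[bad], path, what))
    }
    v
  }
  chrom <- get_col(1)
  start <- num_col(2, "start")
  end <- num_col(3, "end")
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("validation error at line %d of %s: end <= start",
                 idx[bad[1]], path))
  name <- if (all(nf >= 4)) get_col(4) else NULL
  score <- if (all(nf >= 5)) suppressWarnings(as.numeric(get_col(5))) else NA_real_
  summit <- switch(format,
    bed = NULL,
    `summit-bed` = start,
    narrowPeak = {
      off <- num_col(10, "summit-offset")
      s <- ifelse(off < 0, floor((start + end) / 2), start + off)
      bad <- which(s >= end)
      if (length(bad))
        stop(sprintf("validation error at line %d of %s: summit offset outside interval",
                     idx[bad[1]], path))
      s
    })
  peak_set(chrom, start, end, name = name, score = score, summit = summit,
           label = label)
}

#' Write a peak set in a BED-family dialect
#'
#' Emits tab-separated, newline-terminated records with no header. The
#' `narrowPeak` writer stores the summit as a 0-based offset in column 10 and
#' the `summit-bed` writer emits 1-bp summit intervals, so both dialects
#' round-trip summits exactly; plain `bed` output carries no summit and
#' re-reading applies the midpoint fallback.
#'
#' @param ps a [peak_set].
#' @param path output file.
#' @param format one of `"bed"`, `"narrowPeak"`, `"summit-bed"`.
#' @export
write_peaks <- function(ps, path, format = c("bed", "narrowPeak", "summit-bed")) {
  format <- match.arg(format)
  score <- ifelse(is.na(ps$score), 0, ps$score)
  lines <- switch(format,
    bed = sprintf("%s\t%d\t%d\t%s\t%s\t.", ps$chrom, as.integer(ps$start),
                  as.integer(ps$end), ps$name, as.character(score)),
    narrowPeak = sprintf("%s\t%d\t%d\t%s\t%s\t.\t0\t-1\t-1\t%d",
                         ps$chrom, as.integer(ps$start), as.integer(ps$end),
                         ps$name, as.character(score),
                         as.integer(ps$summit - ps$start)),
    `summit-bed` = sprintf("%s\t%d\t%d\t%s\t%s", ps$chrom,
                           as.integer(ps$summit), as.integer(ps$summit) + 1L,
                           ps$name, as.character(score)))
  writeLines(lines, path)
  invisible(path)
}

#' Which query peaks overlap a reference set
#'
#' Overlap means at least one shared base under the half-open coordinate
#' convention (the `bedtools intersect` default).
#'
#' @param query,reference [peak_set] objects.
#' @return Logical vector along the rows of `query`.
#' @export
overlaps_any <- function(query, reference) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(reference) == 0) return(rep(FALSE, nrow(query)))
  lv <- union(unique(query$chrom), unique(reference$chrom))
  q <- peaks_gr(query)
  r <- peaks_gr(reference)
  GenomeInfoDb::seqlevels(q) <- lv
  GenomeInfoDb::seqlevels(r) <- lv
  GenomicRanges::countOverlaps(q, r) > 0
}

#' Count query peaks overlapping a reference set
#'
#' A query peak overlapping several reference peaks counts once.
#'
#' @inheritParams overlaps_any
#' @return Integer count in `[0, nrow(query)]`.
#' @export
intersect_count <- function(query, reference) {
  sum(overlaps_any(query, reference))
}

#' Remove peaks overlapping a blacklist
#'
#' Retains peaks with zero bases of overlap against any blacklist interval
#' (used to drop artefact-prone regions such as the mm10 blacklist). An empty
#' blacklist returns the input unchanged; the operation is idempotent.
#'
#' @param peaks a [peak_set].
#' @param blacklist a [peak_set] of regions to exclude.
#' @return The filtered [peak_set], order preserved.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (nrow(blacklist) == 0 || nrow(peaks) == 0) return(peaks)
  keep <- !overlaps_any(peaks, blacklist)
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label = attr(peaks, "label"),
            class = c("peak_set", "data.frame"))
}

#' Read a TSS annotation table
#'
#' Headered TSV with columns `gene_id`, `chrom`, `strand`, `tss` (0-based
#' transcription start position). Strand is carried but plays no role in
#' distance computations.
#'
#' @param path file to read.
#' @return data.frame with those four columns.
#' @export
read_genes <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "strand", "tss")
  if (!all(required %in% names(g)))
    stop("gene table must have columns: ", paste(required, collapse = ", "))
  if (anyDuplicated(g$gene_id)) stop("validation error: gene_id must be unique")
  if (any(g$tss < 0)) stop("validation error: tss must be >= 0")
  g[, required]
}

#' Write a TSS annotation table
#' @param genes data.frame as returned by [read_genes].
#' @param path output file.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Signed summit-to-TSS distance (summit - tss) of the nearest gene per peak.
# Ties on |distance| (including several genes at one TSS) go to the
# lexicographically smallest gene_id. Peaks on chromosomes without genes get
# gene_id "unassigned" and NA distance.
nearest_tss <- function(chrom, summit, genes) {
  n <- length(chrom)
  gene_id <- rep("unassigned", n)
  distance <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    pk <- which(chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    utss <- sort(unique(g$tss))
    for (i in pk) {
      s <- summit[i]
      j <- findInterval(s, utss)
      cand <- utss[unique(pmin(pmax(c(j, j + 1), 1), length(utss)))]
      d <- abs(cand - s)
      best_tss <- cand[d == min(d)]
      ids <- g$gene_id[g$tss %in% best_tss]
      winner <- min(ids)
      wt <- g$tss[g$gene_id == winner][1]
      gene_id[i] <- winner
      distance[i] <- s - wt
    }
  }
  data.frame(gene_id = gene_id, distance = distance, stringsAsFactors = FALSE)
}

#' Annotate peaks with their nearest gene
#'
#' Distance is measured from the peak summit to the TSS, signed as
#' `summit - tss`; the minimal absolute distance wins and ties are broken by
#' lexicographic `gene_id`. Peaks on a chromosome carrying no genes map to the
#' sentinel `"unassigned"` with `NA` distance.
#'
#' @param peaks a [peak_set] (or any data frame with `chrom`, `summit`,
#'   `name`).
#' @param genes gene table as from [read_genes].
#' @return data.frame with columns `name`, `gene_id`, `distance`.
#' @export
nearest_gene <- function(peaks, genes) {
  nt <- nearest_tss(peaks$chrom, peaks$summit, genes)
  data.frame(name = peaks$name, gene_id = nt$gene_id,
             distance = nt$distance, stringsAsFactors = FALSE)
}
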