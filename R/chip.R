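#' Per-mark differential window configuration
#'
#' Point-source factors use a 400-bp summit-centred window; broad marks such
#' as H3K27ac use a wider 800-bp window, centred on the ATAC union summit so
#' that signal flanking the open-chromatin site is counted.
#'
#' @param mark mark or factor name.
#' @param window tag-density window in bp (even, positive).
#' @param broad logical; broad-mark semantics.
#' @return List of class `mark_config`.
#' @export
mark_config <- function(mark, window = 400, broad = FALSE) {
  if (window <= 0 || window %% 2 != 0)
    stop("validation error: window must be positive and even")
  structure(list(mark = mark, window = window, broad = broad),
            class = "mark_config")
}

#' Keep ChIP peaks that fall within open chromatin
#'
#' Retains ChIP peaks overlapping at least one ATAC peak by at least one base
#' (any-base overlap, not summit containment). Subset of the input;
#' idempotent.
#'
#' @param chip ChIP [peak_set].
#' @param atac ATAC open-chromatin [peak_set].
#' @return The filtered ChIP [peak_set].
#' @export
filter_to_open_chromatin <- function(chip, atac) {
  keep <- overlaps_any(chip, atac)
  out <- chip[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label = attr(chip, "label"),
            class = c("peak_set", "data.frame"))
}

#' Differential ChIP analysis over ATAC union peaks
#'
#' Identical contract to the differential-accessibility call — same
#' normalisation, pseudocount and twofold rule via [differential_table] —
#' with the tag-density window taken from the mark configuration. Windows are
#' centred on the ATAC union summits for all marks; broad marks simply use a
#' wider window.
#'
#' @param track_minus,track_plus per-condition ChIP [tag_track] objects.
#' @param union_peaks ATAC `union_peaks` (or `differential_table`) rows.
#' @param cfg a [mark_config].
#' @param genes optional gene table for the promoter/distal split.
#' @param fold_threshold fold-change threshold (default 2).
#' @return A `differential_table` of binding changes (`gained` / `lost` /
#'   `shared` corresponds to binding gained / lost / maintained).
#' @export
differential_chip <- function(track_minus, track_plus, union_peaks,
                              cfg = mark_config("TF"), genes = NULL,
                              fold_threshold = 2) {
  differential_table(union_peaks, track_minus, track_plus, genes = genes,
                     window = cfg$window, fold_threshold = fold_threshold)
}

#' Average signal profile around reference summits
#'
#' Column means of the per-reference binned density matrix: the
#' reference-point average profile (e.g. signal in +/- 2 kb around summits).
#'
#' @param track a [tag_track].
#' @param references data frame with `chrom` and `summit` columns.
#' @param window,bin window and bin widths in bp.
#' @return Numeric vector of length `window/bin`.
#' @export
average_profile <- function(track, references, window = 4000, bin = 10) {
  if (nrow(references) == 0) stop("no reference summits")
  m <- density_matrix(track, references$chrom, references$summit,
                      window = window, bin = bin)
  colMeans(m)
}

#' Exclusive shared/specific intersection counts (UpSet-style)
#'
#' Every peak of the designated base set is assigned to exactly one
#' combination: the base set plus the exact subset of other sets it overlaps
#' (any-base rule). Combination counts therefore partition the base set and
#' sum to its size.
#'
#' @param sets named list of [peak_set] objects.
#' @param base name of the base set (default: first).
#' @return data.frame with columns `combination` (names joined by `&`) and
#'   `count`.
#' @export
shared_specific_sets <- function(sets, base = names(sets)[1]) {
  if (length(sets) < 2) stop("need >= 2 sets")
  if (!base %in% names(sets)) stop("unknown base set: ", base)
  bs <- sets[[base]]
  others <- setdiff(names(sets), base)
  memb <- vapply(others, function(nm) overlaps_any(bs, sets[[nm]]),
                 logical(nrow(bs)))
  memb <- matrix(memb, nrow = nrow(bs), dimnames = list(NULL, others))
  combo <- apply(memb, 1, function(row)
    paste(c(base, others[row]), collapse = "&"))
  tab <- table(combo)
  data.frame(combination = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Fractions of deregulated genes bound by each factor / change class
#'
#' For each direction (up / down) and each factor, reports the percentage of
#' deregulated genes whose nearest-gene assignment carries each binding-change
#' label (lost / maintained / gained), plus an `unbound` remainder so that
#' disjoint labels sum to exactly 100 within a direction.
#'
#' @param de_genes list with character vectors `up` and `down`.
#' @param factor_targets nested list: factor name -> label -> character
#'   vector of target genes.
#' @return Long data.frame (`direction`, `factor`, `label`, `n`, `percent`);
#'   directions with no genes are omitted and listed in the
#'   `flagged_absent` attribute.
#' @export
tf_target_fraction <- function(de_genes, factor_targets) {
  rows <- list()
  absent <- character(0)
  for (dir in names(de_genes)) {
    genes <- unique(de_genes[[dir]])
    if (length(genes) == 0) { absent <- c(absent, dir); next }
    for (fac in names(factor_targets)) {
      labels <- factor_targets[[fac]]
      bound <- character(0)
      for (lab in names(labels)) {
        hit <- intersect(genes, labels[[lab]])
        bound <- union(bound, hit)
        rows[[length(rows) + 1]] <- data.frame(
          direction = dir, factor = fac, label = lab, n = length(hit),
          percent = 100 * length(hit) / length(genes),
          stringsAsFactors = FALSE)
      }
      un <- setdiff(genes, bound)
      rows[[length(rows) + 1]] <- data.frame(
        direction = dir, factor = fac, label = "unbound", n = length(un),
        percent = 100 * length(un) / length(genes), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction = character(), factor = character(),
               label = character(), n = integer(), percent = numeric(),
               stringsAsFactors = FALSE)
  attr(out, "flagged_absent") <- absent
  out
}
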