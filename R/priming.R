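# Run code with a locally-seeded RNG, restoring global state afterwards.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic sub-seed from a master seed and string labels
#'
#' FNV-1a hash of the master seed and labels, folded to `[0, 2^31 - 2]`.
#' Used so that each (condition, class, cell type) test draws from its own
#' reproducible stream and adding a cell type never perturbs other tests.
#'
#' @param master integer master seed.
#' @param ... character labels identifying the test.
#' @return Integer sub-seed.
#' @export
derive_subseed <- function(master, ...) {
  txt <- paste(c(as.character(master), ...), collapse = "\x1f")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  two32 <- 2^32
  for (b in bytes) {
    b <- b %% 256
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% two32
  }
  as.integer(h %% (2^31 - 1))
}

#' Derive cell-type-specific chromatin signatures
#'
#' Per cell type, reproducible peaks are the peaks of replicate 1 that
#' overlap every other replicate; a reproducible peak is cell-type specific
#' when it has zero overlap with the union of all other cell types'
#' reproducible peaks. The resulting signature sets are assigned exclusively:
#' a region reproducible in two cell types belongs to neither signature.
#'
#' @param replicates named list; each element is a list of replicate
#'   [peak_set] objects for one cell type (>= 2 cell types).
#' @return List of class `signature_atlas` with elements `signatures` (named
#'   list of [peak_set]) and `provenance` (data.frame of replicate /
#'   reproducible / specific counts per cell type).
#' @export
derive_signatures <- function(replicates) {
  if (length(replicates) < 2)
    stop("specificity undefined with a single cell type")
  reproducible <- lapply(replicates, function(reps) {
    base <- reps[[1]]
    if (length(reps) > 1) {
      for (r in reps[-1]) {
        keep <- overlaps_any(base, r)
        base <- structure(base[keep, , drop = FALSE],
                          label = attr(base, "label"),
                          class = c("peak_set", "data.frame"))
      }
    }
    rownames(base) <- NULL
    base
  })
  signatures <- lapply(names(reproducible), function(ct) {
    others <- reproducible[setdiff(names(reproducible), ct)]
    mine <- reproducible[[ct]]
    drop <- Reduce(`|`, lapply(others, function(o) overlaps_any(mine, o)),
                   rep(FALSE, nrow(mine)))
    out <- mine[!drop, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, label = ct, class = c("peak_set", "data.frame"))
  })
  names(signatures) <- names(reproducible)
  provenance <- data.frame(
    cell_type = names(replicates),
    n_replicates = vapply(replicates, length, integer(1)),
    n_reproducible = vapply(reproducible, nrow, integer(1)),
    n_specific = vapply(signatures, nrow, integer(1)),
    stringsAsFactors = FALSE)
  rownames(provenance) <- NULL
  structure(list(signatures = signatures, provenance = provenance),
            class = "signature_atlas")
}

#' @export
print.signature_atlas <- function(x, ...) {
  cat("signature_atlas:\n")
  print(x$provenance)
  invisible(x)
}

#' Matched-size resampling test for signature enrichment / depletion
#'
#' The observed statistic `x` is the number of test peaks overlapping the
#' signature (any-base rule, each test peak counted once). Each of
#' `n_resamples` resamples draws `|test_peaks|` distinct peaks uniformly
#' without replacement from the universe and records its overlap count. The
#' Z-score is `(x - mu) / sigma` with `mu` and `sigma` the mean and
#' population SD of the resampled counts. Empirical p-values use strict
#' inequalities: `p_enrich` is the proportion of resamples whose count
#' exceeds `x` (low values mean the signature is over-represented) and
#' `p_deplete` the proportion below `x`. When every resample gives the same
#' count (`sigma = 0`) the result is flagged degenerate and `z` is `NA`.
#'
#' @param test_peaks [peak_set] of condition-specific peaks; must be a
#'   subset of `universe` (by name, or by exact interval identity).
#' @param universe [peak_set] to resample from (e.g. all distal union
#'   peaks: condition-specific plus shared).
#' @param signature [peak_set] of cell-type-specific peaks.
#' @param n_resamples number of resamples (default 1000).
#' @param seed integer seed for this test's draws.
#' @param smoothed also report add-one smoothed p-values
#'   `(#{count >= x} + 1) / (n + 1)` (and the depletion analogue) for users
#'   who need p > 0.
#' @return One-row data.frame of class `priming_result`: `x`, `mu`, `sigma`,
#'   `z`, `p_enrich`, `p_deplete`, `n_resamples`, `seed`, `degenerate` (and
#'   smoothed columns when requested).
#' @export
priming_test <- function(test_peaks, universe, signature, n_resamples = 1000,
                         seed = 1, smoothed = FALSE) {
  if (n_resamples < 1) stop("validation error: n_resamples must be >= 1")
  n <- nrow(test_peaks)
  N <- nrow(universe)
  if (n > N) stop("validation error: test set larger than universe")
  by_name <- all(test_peaks$name %in% universe$name)
  if (!by_name) {
    key_u <- paste(universe$chrom, universe$start, universe$end)
    key_t <- paste(test_peaks$chrom, test_peaks$start, test_peaks$end)
    if (!all(key_t %in% key_u))
      stop("validation error: test peaks must be a subset of the universe")
  }
  x <- intersect_count(test_peaks, signature)
  ov <- overlaps_any(universe, signature)
  counts <- with_local_seed(seed, {
    vapply(seq_len(n_resamples),
           function(i) sum(ov[sample.int(N, n)]), numeric(1))
  })
  mu <- mean(counts)
  sigma <- sqrt(mean((counts - mu)^2))
  out <- data.frame(
    x = x, mu = mu, sigma = sigma,
    z = if (sigma > 0) (x - mu) / sigma else NA_real_,
    p_enrich = mean(counts > x), p_deplete = mean(counts < x),
    n_resamples = n_resamples, seed = seed, degenerate = sigma == 0)
  if (smoothed) {
    out$p_enrich_smoothed <- (sum(counts >= x) + 1) / (n_resamples + 1)
    out$p_deplete_smoothed <- (sum(counts <= x) + 1) / (n_resamples + 1)
  }
  structure(out, class = c("priming_result", "data.frame"))
}

#' Lineage-priming panel over a differential table and a signature atlas
#'
#' Runs [priming_test] for the gained and lost distal peak sets of a
#' condition against every cell-type signature. The universe is the full set
#' of distal union peaks of that condition (gained, lost and shared), so a
#' resample can fall anywhere in accessible distal chromatin. Each test uses
#' a deterministic sub-seed derived from the master seed and the
#' (condition, class, cell type) labels.
#'
#' @param differential a `differential_table` (only `element == "distal"`
#'   rows are used; tables without a distal/promoter split use all rows).
#' @param atlas a `signature_atlas` from [derive_signatures].
#' @param n_resamples resamples per test (default 1000).
#' @param seed master seed.
#' @param condition condition label recorded in the output.
#' @return Long data.frame, one row per (class, cell type): `condition`,
#'   `class`, `cell_type`, then the [priming_test] columns plus `absent`
#'   (TRUE when the class had no peaks and the test could not run).
#' @export
priming_panel <- function(differential, atlas, n_resamples = 1000, seed = 1,
                          condition = "experiment") {
  if (length(atlas$signatures) == 0) stop("empty signature atlas")
  rows <- if ("element" %in% names(differential) &&
              any(differential$element == "distal"))
    differential[differential$element == "distal", , drop = FALSE]
  else differential
  as_ps <- function(df) peak_set(df$chrom, df$start, df$end, name = df$name,
                                 summit = df$summit)
  universe <- as_ps(rows)
  out <- list()
  for (cls in c("gained", "lost")) {
    sub <- rows[rows$class == cls, , drop = FALSE]
    for (ct in names(atlas$signatures)) {
      sub_seed <- derive_subseed(seed, condition, cls, ct)
      if (nrow(sub) == 0) {
        res <- data.frame(x = NA_real_, mu = NA_real_, sigma = NA_real_,
                          z = NA_real_, p_enrich = NA_real_,
                          p_deplete = NA_real_, n_resamples = n_resamples,
                          seed = sub_seed, degenerate = NA)
        absent <- TRUE
      } else {
        res <- priming_test(as_ps(sub), universe, atlas$signatures[[ct]],
                            n_resamples = n_resamples, seed = sub_seed)
        absent <- FALSE
      }
      out[[length(out) + 1]] <- cbind(
        data.frame(condition = condition, class = cls, cell_type = ct,
                   stringsAsFactors = FALSE),
        as.data.frame(res), absent = absent)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
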