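test_that("peak union merges summits within range, transitively", {
  # two summits 350 bp apart -> one union peak at their midpoint
  a <- make_ps(0, width = 300, summit = 100)
  b <- make_ps(350, width = 300, summit = 450, label = "plus")
  u <- build_peak_union(a, b)
  expect_equal(nrow(u), 1)
  expect_equal(u$summit, 275)
  expect_equal(u$start, 0)
  expect_equal(u$end, 650)
  # gap 500 > 400 -> untouched
  b2 <- make_ps(500, width = 300, summit = 600)
  u2 <- build_peak_union(a, b2)
  expect_equal(u2$summit, c(100, 600))
  # chain rule: 100, 450, 800 merge into one with the mean summit
  c3 <- peak_set("chr1", c(0, 350, 700), c(300, 650, 1000),
                 summit = c(100, 450, 800))
  u3 <- build_peak_union(c3, peak_set(character(), numeric(), numeric()))
  expect_equal(nrow(u3), 1)
  expect_equal(u3$summit, 450)
  expect_error(build_peak_union(a, b, summit_distance = -1), "summit_distance")
})

test_that("sweep-based union equals brute-force transitive merging", {
  withr::local_seed(400)
  for (rep in 1:20) {
    n <- sample(20:120, 1)
    # summit gaps concentrated around the 400 bp threshold
    gaps <- pmax(1, round(stats::rnorm(n, 400, 150)))
    summits <- cumsum(gaps) + 500
    starts <- summits - sample.int(200, n)
    ends <- summits + sample.int(200, n)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    half <- sample.int(n, n %/% 2)
    mk <- function(idx, lab) peak_set(chrom[idx], starts[idx], ends[idx],
                                      name = paste0(lab, idx),
                                      summit = summits[idx], label = lab)
    u <- build_peak_union(mk(half, "m"), mk(setdiff(seq_len(n), half), "p"))
    oracle <- brute_union_summits(chrom, summits, 400)
    expect_equal(nrow(u), length(oracle))
    ord <- order(u$chrom, u$summit)
    expect_equal(u$summit[ord],
                 unname(vapply(oracle, `[[`, numeric(1), "summit")))
    expect_equal(as.numeric(u$n_members[ord]),
                 unname(vapply(oracle, `[[`, numeric(1), "size")))
  }
})

test_that("promoter/distal split is inclusive at the window boundary", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 10000)
  at <- function(s) peak_set("chr1", s - 50, s + 50, summit = s)
  expect_equal(classify_element(at(11500), genes), "promoter")
  expect_equal(classify_element(at(11501), genes), "distal")
  expect_equal(classify_element(peak_set("chrZ", 0, 100), genes), "distal")
})

test_that("window density averages the track with zero-filled truncation", {
  tr <- tag_track("chr1", 0, 10000, 3)
  expect_equal(window_tag_density(tr, "chr1", 5000, 400), 3)
  tr2 <- tag_track(c("chr1", "chr1"), c(0, 5000), c(5000, 10000), c(2, 4))
  expect_equal(window_tag_density(tr2, "chr1", 5000, 400), 3)
  expect_equal(window_tag_density(tr2, "chrEmpty", 5000, 400), 0)
  # truncated window at the chromosome start keeps divisor = width
  tr3 <- tag_track("chr1", 0, 100, 2)
  expect_equal(window_tag_density(tr3, "chr1", 100, 400), 2 * 100 / 400)
  expect_error(window_tag_density(tr, "chr1", 100, 401), "even")
})

test_that("CPM columns sum to one million and log transform is exact", {
  raw <- matrix(c(5, 5, 1, 3), ncol = 2,
                dimnames = list(NULL, c("s1", "s2")))
  nm <- cpm_log_normalize(raw)
  expect_equal(unname(nm$cpm[, "s1"]), c(5e5, 5e5))
  expect_equal(unname(nm$log2[1, "s1"]), 18.93157, tolerance = 1e-4 / 18.93157)
  withr::local_seed(9)
  for (i in 1:5) {
    raw <- matrix(stats::rexp(300), ncol = 3)
    cpm <- cpm_log_normalize(raw)$cpm
    expect_equal(colSums(cpm), rep(1e6, 3), tolerance = 1e-6)
    expect_true(all(diff(order(cpm[, 1])) ==
                    diff(order(cpm_log_normalize(raw)$log2[, 1]))))
  }
  bad <- matrix(c(1, 2, 0, 0), ncol = 2, dimnames = list(NULL, c("ok", "empty")))
  expect_error(cpm_log_normalize(bad), "empty")
})

test_that("twofold calls follow the pseudocount rule and are antisymmetric", {
  d <- call_differential(c(10, 30, 50), c(40, 20, 20))
  expect_equal(d$fold, c(41 / 11, 21 / 31, 21 / 51))
  expect_equal(d$class, c("gained", "shared", "lost"))
  # boundary at exactly twofold counts as differential
  expect_equal(call_differential(0, 1)$class, "gained")
  withr::local_seed(31)
  for (i in 1:10) {
    m <- stats::rexp(200, 1 / 100)
    p <- stats::rexp(200, 1 / 100)
    fwd <- call_differential(m, p)$class
    rev <- call_differential(p, m)$class
    expect_equal(fwd == "gained", rev == "lost")
    expect_equal(fwd == "shared", rev == "shared")
  }
})

test_that("ranked heatmap matrices share the fold-descending row order", {
  pk <- peak_set("chr1", c(1000, 3000, 5000), c(1400, 3400, 5400),
                 name = c("a", "b", "c"))
  dt <- data.frame(name = pk$name, chrom = pk$chrom, start = pk$start,
                   end = pk$end, summit = pk$summit,
                   fold = c(4, 0.25, 1), stringsAsFactors = FALSE)
  flat <- tag_track("chr1", 0, 10000, 2)
  mats <- ranked_density_matrix(dt, list(t1 = flat, t2 = flat),
                                window = 2000, bin = 10)
  expect_equal(attr(mats, "order"), c("a", "c", "b"))
  expect_equal(rownames(mats$t1), rownames(mats$t2))
  expect_equal(ncol(mats$t1), 200)
  expect_true(all(mats$t1 == 2))
})

test_that("correlation clustering pairs identical samples as siblings", {
  m <- rbind(s1 = c(1, 2, 3, 4), s2 = c(2, 4, 6, 8), s3 = c(4, 3, 2, 1))
  cc <- correlation_cluster(m)
  expect_equal(unname(diag(cc$correlation)), rep(1, 3))
  expect_equal(cc$correlation["s1", "s2"], 1)
  expect_equal(cc$correlation["s1", "s3"], -1)
  expect_true(isSymmetric(cc$correlation))
  m2 <- rbind(a = c(1, 5, 2), b = c(10, 2, 7), c = c(1, 5, 2))
  hc <- correlation_cluster(m2)$hclust
  expect_equal(sort(hc$merge[1, ]), c(-3, -1))  # zero distance merges first
  expect_error(correlation_cluster(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance.*a")
})

test_that("differential_table splits normalisation by element class", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+", tss = 1200)
  pk <- peak_set("chr1", c(1000, 50000, 60000), c(1400, 50400, 60400),
                 name = c("prom", "d1", "d2"))
  u <- cbind(pk[, c("name", "chrom", "start", "end", "summit")])
  tr <- tag_track("chr1", c(1000, 50000, 60000), c(1400, 50400, 60400),
                  c(5, 10, 10))
  d <- differential_table(u, tr, tr, genes = genes)
  expect_equal(d$element, c("promoter", "distal", "distal"))
  # promoter class normalised alone -> its CPM is the full million
  expect_equal(d$cpm_minus[1], 1e6)
  expect_equal(d$cpm_minus[2], 5e5)
  expect_true(all(d$class == "shared"))
})
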