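test_that("signatures are replicate-reproducible and exclusive", {
  # A-specific peak in both A replicates; one peak shared with B; one peak
  # present in only one A replicate
  a1 <- peak_set("chr1", c(100, 1000, 5000), c(200, 1100, 5100),
                 name = c("spec", "shAB", "oneRep"))
  a2 <- peak_set("chr1", c(120, 1020), c(220, 1120), name = c("spec2", "shAB2"))
  b1 <- peak_set("chr1", c(1000, 9000), c(1100, 9100), name = c("shAB3", "bspec"))
  b2 <- peak_set("chr1", c(1010, 9010), c(1110, 9110), name = c("shAB4", "bspec2"))
  atlas <- derive_signatures(list(A = list(a1, a2), B = list(b1, b2)))
  expect_equal(atlas$signatures$A$name, "spec")     # replicate rule + exclusivity
  expect_equal(atlas$signatures$B$name, "bspec")
  expect_equal(atlas$provenance$n_reproducible, c(2, 2))
  expect_equal(atlas$provenance$n_specific, c(1, 1))
  expect_error(derive_signatures(list(A = list(a1, a2))), "single cell type")
})

test_that("resampled moments match the exact hypergeometric oracle", {
  inst <- worked_priming_instance()
  or <- hyper_moments(20, 5, 8)
  expect_equal(or$mu, 2)
  expect_equal(or$sigma, 0.9733285, tolerance = 1e-6)
  res <- priming_test(inst$test, inst$universe, inst$signature,
                      n_resamples = 20000, seed = 3)
  expect_equal(res$x, 4)
  se_mu <- or$sigma / sqrt(20000)
  expect_lt(abs(res$mu - or$mu), 3 * se_mu)
  expect_lt(abs(res$sigma - or$sigma), 3 * or$sigma / sqrt(2 * 20000))
  p_exact <- stats::phyper(4, 5, 15, 8, lower.tail = FALSE)
  expect_lt(abs(res$p_enrich - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 20000))
})

test_that("degenerate resampling is flagged instead of dividing by zero", {
  uni <- make_ps((0:9) * 1000, width = 400, chrom = "chrS")
  test <- uni[1:4, , drop = FALSE]; class(test) <- class(uni)
  # signature covers the whole universe: every count equals |test|
  res <- priming_test(test, uni, uni, n_resamples = 50, seed = 1)
  expect_true(res$degenerate)
  expect_true(is.na(res$z))
  expect_equal(res$x, 4)
  expect_equal(res$sigma, 0)
  # signature disjoint from the universe: all counts zero
  far <- peak_set("chrS", 1e6, 1e6 + 100)
  res0 <- priming_test(test, uni, far, n_resamples = 50, seed = 1)
  expect_true(res0$degenerate)
  expect_equal(res0$x, 0)
})

test_that("priming results are seed-deterministic", {
  inst <- worked_priming_instance()
  r1 <- priming_test(inst$test, inst$universe, inst$signature, 500, seed = 11)
  r2 <- priming_test(inst$test, inst$universe, inst$signature, 500, seed = 11)
  expect_identical(r1, r2)
  r3 <- priming_test(inst$test, inst$universe, inst$signature, 500, seed = 12)
  expect_false(identical(r1$mu, r3$mu))
  # sub-seeds: stable for equal labels, distinct across labels
  expect_identical(derive_subseed(17, "c", "gained", "B"),
                   derive_subseed(17, "c", "gained", "B"))
  seeds <- vapply(c("CMP", "Bcell", "monocyte", "erythroblast", "mega"),
                  function(ct) derive_subseed(17, "c", "gained", ct),
                  integer(1))
  expect_equal(anyDuplicated(seeds), 0)
})

test_that("validation errors fire for malformed test configurations", {
  inst <- worked_priming_instance()
  outside <- peak_set("chrS", c(0, 50000), c(400, 50400),
                      name = c("in", "out"))
  expect_error(priming_test(outside, inst$universe, inst$signature, 10, 1),
               "subset of the universe")
  expect_error(priming_test(inst$test, inst$test, inst$signature, 10, 1),
               NA)  # equal-size test==universe is legal
  expect_error(priming_test(inst$universe, inst$test, inst$signature, 10, 1),
               "larger than")
  expect_error(priming_test(inst$test, inst$universe, inst$signature, 0, 1),
               "n_resamples")
})

test_that("z and the exact enrichment tail are monotone in x", {
  # oracle-level property: with N, K, n fixed, a larger observed overlap
  # never lowers z and never raises the enrichment tail
  or <- hyper_moments(40, 12, 15)
  xs <- 0:12
  z <- (xs - or$mu) / or$sigma
  expect_true(all(diff(z) > 0))
  tail <- stats::phyper(xs, 12, 28, 15, lower.tail = FALSE)
  expect_true(all(diff(tail) <= 0))
})

test_that("the panel tests gained and lost sets against every signature", {
  withr::local_seed(200)
  atlas <- simulate_atlas(n_celltypes = 3, peaks_per_type = 150,
                          specific_fraction = 0.4, genome_length = 5e6,
                          replicate_jitter = 0, seed = 21)
  expt <- simulate_experiment(atlas, n_union_peaks = 600,
                              signature_enrichment = c(type01 = 0.4),
                              noise_cv = 0, n_genes = 50, seed = 22)
  sigs <- derive_signatures(atlas$replicates)
  u <- build_peak_union(expt$peaks$minus, expt$peaks$plus)
  d <- differential_table(u, expt$tracks$minus, expt$tracks$plus,
                          genes = expt$genes)
  panel <- priming_panel(d, sigs, n_resamples = 300, seed = 77)
  expect_equal(nrow(panel), 6)
  expect_equal(sort(unique(panel$class)), c("gained", "lost"))
  planted <- panel[panel$class == "gained" & panel$cell_type == "type01", ]
  expect_gt(planted$z, 0)
  expect_lte(planted$p_enrich, 0.05)
  # identical sub-seed -> identical result
  panel2 <- priming_panel(d, sigs, n_resamples = 300, seed = 77)
  expect_identical(panel, panel2)
  # a table with no lost peaks flags those rows absent
  d_no_lost <- d[d$class != "lost", , drop = FALSE]
  p3 <- priming_panel(d_no_lost, sigs, n_resamples = 50, seed = 1)
  expect_true(all(p3$absent[p3$class == "lost"]))
  expect_true(all(is.na(p3$x[p3$class == "lost"])))
})
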