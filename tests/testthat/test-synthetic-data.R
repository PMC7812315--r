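test_that("generators are seed-deterministic", {
  a1 <- simulate_atlas(n_celltypes = 3, peaks_per_type = 100,
                       genome_length = 5e6, seed = 9)
  a2 <- simulate_atlas(n_celltypes = 3, peaks_per_type = 100,
                       genome_length = 5e6, seed = 9)
  expect_identical(a1, a2)
  e1 <- simulate_experiment(a1, n_union_peaks = 300, n_genes = 30, seed = 4)
  e2 <- simulate_experiment(a2, n_union_peaks = 300, n_genes = 30, seed = 4)
  expect_identical(e1, e2)
  expect_false(identical(
    e1$truth,
    simulate_experiment(a1, n_union_peaks = 300, n_genes = 30, seed = 5)$truth))
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(simulate_atlas(3, 50, genome_length = 2e6, seed = 2))
  expect_identical(stats::runif(1), before)
})

test_that("atlas peaks are non-overlapping with faithful replicate structure", {
  atlas <- simulate_atlas(n_celltypes = 4, peaks_per_type = 200,
                          specific_fraction = 0.25, genome_length = 1e7,
                          replicate_jitter = 0, seed = 31)
  tr <- atlas$truth
  expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))  # sorted, disjoint
  expect_equal(sum(tr$label == "shared"), 150)
  expect_equal(sum(tr$label == "type01"), 50)
  # zero jitter: replicates identical up to names
  r <- atlas$replicates$type02
  expect_equal(r[[1]][c("chrom", "start", "end")],
               r[[2]][c("chrom", "start", "end")])
  # requested peaks must fit the genome
  expect_error(simulate_atlas(2, 1000, genome_length = 1e5, seed = 1),
               "fit genome_length")
})

test_that("signature derivation recovers the planted atlas labels exactly", {
  atlas <- simulate_atlas(n_celltypes = 5, peaks_per_type = 300,
                          specific_fraction = 0.3, genome_length = 2e7,
                          replicate_jitter = 0, seed = 13)
  sigs <- derive_signatures(atlas$replicates)
  for (ct in names(sigs$signatures)) {
    planted <- atlas$truth[atlas$truth$label == ct, ]
    got <- sigs$signatures[[ct]]
    expect_equal(got$start, planted$start)
    expect_equal(got$end, planted$end)
  }
  # specific_fraction 0 leaves no exclusive peaks
  shared_only <- simulate_atlas(3, 100, specific_fraction = 0,
                                genome_length = 5e6, replicate_jitter = 0,
                                seed = 2)
  s0 <- derive_signatures(shared_only$replicates)
  expect_equal(s0$provenance$n_specific, c(0, 0, 0))
})

test_that("noiseless experiments are recovered perfectly by the caller", {
  atlas <- simulate_atlas(3, 150, specific_fraction = 0.4,
                          genome_length = 8e6, replicate_jitter = 0, seed = 5)
  expt <- simulate_experiment(atlas, n_union_peaks = 500, noise_cv = 0,
                              planted_fold = 4, n_genes = 40, seed = 6)
  u <- build_peak_union(expt$peaks$minus, expt$peaks$plus)
  d <- differential_table(u, expt$tracks$minus, expt$tracks$plus,
                          genes = expt$genes)
  m <- match(paste(d$chrom, d$start), paste(expt$truth$chrom, expt$truth$start))
  expect_false(anyNA(m))
  expect_equal(d$class, expt$truth$class[m])
  # planted class counts honour the fractions
  expect_equal(sum(expt$truth$class == "gained"), 50)
  expect_equal(sum(expt$truth$class == "lost"), 50)
  expect_error(
    simulate_experiment(atlas, 100, gained_fraction = 0.7,
                        lost_fraction = 0.5, seed = 1),
    "<= 1")
})

test_that("fixtures round-trip through the package readers", {
  atlas <- simulate_atlas(3, 100, genome_length = 5e6, seed = 8)
  expt <- simulate_experiment(atlas, n_union_peaks = 200, n_genes = 25,
                              seed = 9)
  dir <- withr::local_tempdir()
  f_np <- file.path(dir, "plus.narrowPeak")
  write_peaks(expt$peaks$plus, f_np, "narrowPeak")
  back <- read_peaks(f_np, "narrowPeak")
  expect_equal(back[c("chrom", "start", "end", "name", "summit")],
               expt$peaks$plus[c("chrom", "start", "end", "name", "summit")])
  f_bg <- file.path(dir, "minus.bedGraph")
  write_bedgraph(expt$tracks$minus, f_bg)
  tr <- read_bedgraph(f_bg)
  s <- expt$truth$summit
  expect_equal(window_tag_density(tr, expt$truth$chrom, s, 400),
               window_tag_density(expt$tracks$minus, expt$truth$chrom, s, 400))
  f_g <- file.path(dir, "genes.tsv")
  write_genes(expt$genes, f_g)
  expect_equal(read_genes(f_g), expt$genes)
})

test_that("simulated motif rates reproduce the analytic score expectations", {
  withr::local_seed(300)
  big <- list(
    gained = make_ps(seq(0, by = 1000, length.out = 2000), width = 400),
    lost = make_ps(seq(0, by = 1000, length.out = 2000), width = 400))
  rates <- matrix(c(0.5, 0.25, 1, 1, 0, 0), nrow = 3, byrow = TRUE,
                  dimnames = list(c("enriched", "uniform", "absent"),
                                  c("gained", "lost")))
  sim <- simulate_motifs(big, rates, seed = 44)
  expect_warning(S <- enrichment_scores(sim$counts), "no peak set")
  # E[S] = rate_j / mean(rates) for equal set sizes: (4/3, 2/3)
  expect_equal(unname(S["enriched", ]), c(4 / 3, 2 / 3), tolerance = 0.05)
  expect_equal(unname(S["uniform", ]), c(1, 1))
  expect_false("absent" %in% rownames(S))
  # hit positions lie inside their peaks
  expect_true(all(sim$positions$pos >= 0))
  expect_true(all(sim$positions$pos %% 1000 < 400))
})

test_that("planted DE tables are classified and overlapped exactly", {
  mix <- c(up_both = 0.1, up_minus_only = 0.1, up_plus_only = 0.1,
           down_minus_only = 0.1, down_plus_only = 0.1, down_both = 0.1,
           unchanged = 0.4)
  de <- simulate_de_tables(n_genes = 700, mix = mix, fold = 4, seed = 15)
  got <- classify_trajectory(2^de$minus$log2fc, 2^de$plus$log2fc)
  expect_equal(as.character(got), de$truth$category)
  # pairwise overlap against a set-arithmetic oracle on the truth labels
  ov <- pairwise_overlap(list(minus = deregulated_genes(de$minus),
                              plus = deregulated_genes(de$plus)))
  up_m <- de$truth$category %in% c("up_both", "up_minus_only")
  up_p <- de$truth$category %in% c("up_both", "up_plus_only")
  down_m <- de$truth$category %in% c("down_both", "down_minus_only")
  down_p <- de$truth$category %in% c("down_both", "down_plus_only")
  expect_equal(unname(ov$concordant["minus", "plus"]),
               sum(up_m & up_p) + sum(down_m & down_p))
  expect_equal(unname(ov$opposing["minus", "plus"]), sum(up_m & down_p))
  expect_error(simulate_de_tables(100, mix = mix * 2, seed = 1), "sum to 1")
})
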