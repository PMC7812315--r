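test_that("read_peaks parses the three dialects and applies summit rules", {
  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t600\tp1\t0\t.\t5\t3\t2\t250",
               "chr1\t700\t900\tp2\t0\t.\t5\t3\t2\t-1"), np)
  ps <- read_peaks(np, "narrowPeak")
  expect_equal(ps$summit, c(350, 800))  # start + offset; -1 -> midpoint
  expect_equal(ps$name, c("p1", "p2"))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t600", bed)
  expect_equal(read_peaks(bed, "bed")$summit, 350)  # midpoint fallback

  sb <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t350\t351\tp1\t17", sb)
  ps <- read_peaks(sb, "summit-bed")
  expect_equal(ps$summit, 350)
  expect_equal(ps$score, 17)

  # track/comment lines are skipped, whitespace tolerated
  tr <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=peaks", "# comment", "chr2 5 15"), tr)
  expect_equal(nrow(read_peaks(tr, "bed")), 1)
})

test_that("malformed and invalid rows fail with the offending line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t600\t100"), f)
  expect_error(read_peaks(f, "bed"), "line 2.*end <= start")
  writeLines(c("chr1\t100\t200", "chr1\tx\t300"), f)
  expect_error(read_peaks(f, "bed"), "line 2.*non-numeric")
  writeLines("chr1\t100", f)
  expect_error(read_peaks(f, "bed"), "line 1")
  writeLines("chr1\t100\t200\tp\t0\t.", f)
  expect_error(read_peaks(f, "narrowPeak"), "expected >= 10")
})

test_that("write/read round trip is exact for all three dialects", {
  withr::local_seed(42)
  starts <- sort(sample.int(1e5, 40))
  ps <- peak_set("chr3", starts, starts + 200,
                 name = sprintf("pk%02d", 1:40), score = 1:40,
                 summit = starts + sample.int(199, 40))
  for (fmt in c("narrowPeak", "summit-bed")) {
    f <- withr::local_tempfile()
    write_peaks(ps, f, fmt)
    back <- read_peaks(f, fmt)
    # order may differ for summit-bed (sorted on summit positions): match
    # records by name and require bit-exact summits
    m <- match(ps$name, back$name)
    expect_false(anyNA(m))
    expect_equal(back$summit[m], ps$summit)
    if (fmt == "narrowPeak") {
      expect_equal(back$start[m], ps$start)
      expect_equal(back$end[m], ps$end)
      expect_equal(back$score[m], ps$score)
    }
  }
  # bed carries no summit: midpoint peaks survive unchanged
  mid <- peak_set("chr3", starts, starts + 200, name = sprintf("pk%02d", 1:40))
  f <- withr::local_tempfile()
  write_peaks(mid, f, "bed")
  expect_equal(read_peaks(f, "bed")[c("chrom", "start", "end", "name", "summit")],
               mid[c("chrom", "start", "end", "name", "summit")])
})

test_that("blacklist filtering uses any-base overlap and is idempotent", {
  pk <- peak_set("chr1", c(100, 300), c(200, 400))
  expect_equal(nrow(filter_blacklist(pk, peak_set("chr1", 150, 160))), 1)
  # half-open: touching intervals do not overlap
  expect_equal(nrow(filter_blacklist(pk, peak_set("chr1", 200, 300))), 2)
  expect_identical(filter_blacklist(pk, peak_set(character(), numeric(), numeric())),
                   pk)
  withr::local_seed(7)
  for (i in 1:5) {
    p <- random_ps(200)
    b <- random_ps(50)
    once <- filter_blacklist(p, b)
    expect_identical(filter_blacklist(once, b), once)
    expect_true(all(once$name %in% p$name))
  }
})

test_that("intersect_count matches brute force on random sets", {
  q <- peak_set("chr1", c(0, 200), c(100, 300))
  expect_equal(intersect_count(q, peak_set("chr1", 50, 60)), 1)
  expect_equal(intersect_count(q, q), 2)
  expect_equal(intersect_count(q, peak_set("chrX", 0, 1000)), 0)
  withr::local_seed(101)
  for (i in 1:15) {
    q <- random_ps(sample(50:300, 1))
    r <- random_ps(sample(20:200, 1))
    expect_equal(intersect_count(q, r), brute_intersect_count(q, r))
  }
})

test_that("nearest_gene reports signed summit-to-TSS distance with ties", {
  genes <- data.frame(gene_id = c("gB", "gA", "gC"),
                      chrom = c("chr1", "chr1", "chr1"),
                      strand = c("+", "-", "+"), tss = c(4000, 20000, 6000))
  pk <- peak_set("chr1", 4900, 5200, name = "p1", summit = 5000)
  ng <- nearest_gene(pk, genes)
  expect_equal(ng$gene_id, "gB")
  expect_equal(ng$distance, 1000)  # summit - tss, downstream positive
  # summit exactly on a TSS
  pk0 <- peak_set("chr1", 3900, 4100, name = "p0", summit = 4000)
  expect_equal(nearest_gene(pk0, genes)$distance, 0)
  # equidistant tie -> lexicographically smaller gene_id
  tie <- data.frame(gene_id = c("zz", "aa"), chrom = "chr1",
                    strand = "+", tss = c(4000, 6000))
  expect_equal(nearest_gene(pk, tie)$gene_id, "aa")
  # chromosome with no genes -> sentinel
  px <- peak_set("chrY", 0, 100, name = "px")
  ng <- nearest_gene(px, genes)
  expect_equal(ng$gene_id, "unassigned")
  expect_true(is.na(ng$distance))
})

test_that("peak_set enforces its invariants", {
  expect_error(peak_set("chr1", 600, 100), "end must be > start")
  expect_error(peak_set("chr1", -5, 100), "start must be >= 0")
  expect_error(peak_set("chr1", 0, 100, summit = 200), "summit")
  expect_error(peak_set("chr1", c(0, 10), c(5, 20), name = c("a", "a")),
               "unique")
  # sorted on construction
  ps <- peak_set("chr1", c(500, 10), c(600, 20))
  expect_equal(ps$start, c(10, 500))
})
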