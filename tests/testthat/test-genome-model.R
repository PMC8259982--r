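test_that("interval construction validates its inputs", {
  expect_error(ginterval("chr22", 10, 5), "end")
  expect_error(ginterval("chr22", 0, 5), "start")
  expect_error(ginterval("chr22", NA, 5), "finite")
  iv <- ginterval("chr22", 5, 5)
  expect_equal(interval_length(iv), 0)
})

test_that("interval length matches the subtraction oracle and prints in Mb", {
  expect_equal(interval_length(ginterval("chr22", 42740931, 51244566)),
               8503635)
  expect_equal(interval_length_mb(ginterval("chr22", 42740931, 51244566)),
               "8.503635")
  set.seed(11)
  for (i in 1:200) {
    a <- sort(sample.int(1e8, 2))
    expect_equal(interval_length(ginterval("c", a[1], a[2])), a[2] - a[1])
  }
  # translation invariance
  set.seed(12)
  for (i in 1:50) {
    a <- sort(sample.int(1e6, 2)); k <- sample.int(1e6, 1)
    expect_equal(interval_length(ginterval("c", a[1] + k, a[2] + k)),
                 interval_length(ginterval("c", a[1], a[2])))
  }
})

test_that("overlap uses half-open semantics and matches point enumeration", {
  a <- ginterval("c", 3, 9)
  expect_true(overlaps(a, a))
  expect_false(overlaps(ginterval("c", 1, 10), ginterval("c", 10, 20)))
  expect_error(overlaps(ginterval("c1", 1, 5), ginterval("c2", 1, 5)),
               "different chromosomes")
  set.seed(21)
  for (i in 1:200) {
    p <- sort(sample.int(30, 4, replace = TRUE))[sample(4)]
    x <- ginterval("c", min(p[1], p[2]), max(p[1], p[2]))
    y <- ginterval("c", min(p[3], p[4]), max(p[3], p[4]))
    pts_x <- if (x$end > x$start) seq(x$start, x$end - 1) else integer(0)
    pts_y <- if (y$end > y$start) seq(y$start, y$end - 1) else integer(0)
    expect_identical(overlaps(x, y), length(intersect(pts_x, pts_y)) > 0)
  }
})

test_that("interval distance is zero on overlap and the gap otherwise", {
  expect_equal(interval_distance(ginterval("c", 1, 5),
                                 ginterval("c", 3, 9)), 0)
  expect_equal(interval_distance(ginterval("c", 1, 5),
                                 ginterval("c", 7, 9)), 2)
  # printed coordinates: NAGA end vs the largest deletion's start
  expect_equal(interval_distance(ginterval("chr22", 42454338, 42466846),
                                 ginterval("chr22", 42740931, 51244566)),
               274085)
})

test_that("gene status classification handles all four regimes", {
  del <- list(chrom = "c", start = 1000, end = 9000)
  expect_equal(classify_gene_vs_deletion(
    list(chrom = "c", start = 2000, end = 3000), del), "deleted")
  expect_equal(classify_gene_vs_deletion(
    list(chrom = "c", start = 500, end = 1500), del), "partially_deleted")
  expect_equal(classify_gene_vs_deletion(
    list(chrom = "c", start = 9500, end = 9800), del), "within_window")
  expect_equal(classify_gene_vs_deletion(
    list(chrom = "c", start = 9500, end = 9800), del, window = 100),
    "distal")
  # window = 0 never yields within_window for a positive gap
  set.seed(31)
  for (i in 1:50) {
    g <- sort(sample.int(1e5, 2)); d <- g + sample(2:1e4, 1) + g[2] - g[1]
    st <- classify_gene_vs_deletion(list(chrom = "c", start = g[1],
                                         end = g[2]),
                                    list(chrom = "c", start = d[1],
                                         end = d[2]), window = 0)
    expect_false(st == "within_window")
  }
})

test_that("the fixture reproduces the printed 9x5 presence/absence pattern", {
  d <- pms_deletions()
  g <- pms_gene_panel(include_blood_silent = FALSE)
  expected <- pms_expected_deleted()
  for (j in 1:5) {
    st <- classify_genes(g, d[j, ])
    got_deleted <- st %in% c("deleted", "partially_deleted")
    expect_identical(stats::setNames(got_deleted, g$symbol),
                     expected[g$symbol, j],
                     info = d$patient_id[j])
  }
})

test_that("size classes reproduce the printed labels and honour cutoffs", {
  d <- pms_deletions()
  expect_identical(d$size_class, c("Large", "Large", "Mid", "Small",
                                   "Small"))
  # inclusive upper boundary
  b <- deletion_table("x", "c", 1, 1 + 8e6)
  expect_identical(assign_size_class(b)$size_class, "Large")
  expect_error(assign_size_class(d, cutoffs = c(5e6, 5e6)), "increasing")
})

test_that("TAD map validation rejects unsorted and overlapping maps", {
  good <- data.frame(chrom = "c", start = c(1, 100, 200),
                     end = c(100, 200, 300))
  expect_silent(validate_tad_map(good))
  expect_error(validate_tad_map(
    data.frame(chrom = "c", start = c(100, 1), end = c(200, 100))),
    "sorted")
  expect_error(validate_tad_map(
    data.frame(chrom = "c", start = c(1, 50), end = c(100, 200))),
    "overlapping")
})

test_that("BED input is converted to the 1-based half-open convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines("c\t0\t100\tgeneA\nc\t100\t250\tgeneB", bed)
  g <- read_genes(bed, format = "bed")
  expect_equal(g$start, c(1, 101))
  expect_equal(g$end, c(101, 251))
  expect_equal(g$end - g$start, c(100, 150))  # BED widths preserved
})

test_that("deletion and gene tables round-trip through TSV", {
  d <- pms_deletions()
  p <- tempfile(fileext = ".tsv")
  write_tsv(d, p)
  expect_true(startsWith(readLines(p, n = 1), "#"))
  d2 <- read_deletions(p)
  expect_equal(d2$start, d$start)
  expect_equal(d2$terminal, d$terminal)
  g <- pms_gene_panel()
  pg <- tempfile(fileext = ".tsv")
  write_tsv(g, pg)
  g2 <- read_genes(pg)
  expect_equal(g2$symbol, g$symbol)
  expect_equal(g2$hi_pct, g$hi_pct)
  expect_equal(g2$expressed_in_blood, g$expressed_in_blood)
})

test_that("shipped fixture files load through the readers", {
  d <- read_deletions(system.file("extdata", "pms_deletions.tsv",
                                  package = "tadpose"))
  expect_equal(d$start, pms_deletions()$start)
  g <- read_genes(system.file("extdata", "pms_genes.tsv",
                              package = "tadpose"))
  expect_equal(g$symbol, pms_gene_panel()$symbol)
  expect_equal(sum(!g$expressed_in_blood), 3)
  ph <- read_phenotypes(system.file("extdata", "pms_phenotypes.tsv",
                                    package = "tadpose"))
  expect_setequal(names(ph), paste0("PMS", 1:5))
  expect_true("seizures" %in% ph$PMS1)
})
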