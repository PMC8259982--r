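make_locus <- function(seed = 1, n_genes = 30) {
  gen_locus(n_genes = n_genes, seed = seed)
}

test_that("flanking windows are clipped and terminal-aware", {
  del <- data.frame(patient_id = "x", chrom = "c", start = 1e7, end = 1.2e7,
                    terminal = FALSE)
  w <- flanking_windows(del, window = 2e6)
  expect_equal(nrow(w), 2)
  expect_equal(w$start, c(8e6, 1.2e7))
  expect_equal(w$end, c(1e7, 1.4e7))
  del$terminal <- TRUE
  w <- flanking_windows(del)
  expect_equal(w$side, "proximal")
  expect_equal(c(w$start, w$end), c(8e6, 1e7))
  # clipping at the chromosome origin
  near <- data.frame(patient_id = "y", chrom = "c", start = 1e6, end = 2e6,
                     terminal = TRUE)
  expect_equal(flanking_windows(near, window = 2e6)$start, 1)
  # consistent with the published proximal window of the largest deletion
  pms1 <- pms_deletions()[1, ]
  w1 <- flanking_windows(pms1)
  expect_equal(c(w1$start, w1$end), c(40740931, 42740931))
})

test_that("TAD disruption requires a breakpoint strictly inside a domain", {
  tads <- data.frame(chrom = "c", start = c(1, 1000, 2000),
                     end = c(1000, 2000, 3000))
  del_in <- list(chrom = "c", start = 1500, end = 5000)
  expect_equal(tads_disrupted(del_in, tads)$start, 1000)
  # breakpoint exactly on a boundary disrupts nothing
  del_edge <- list(chrom = "c", start = 2000, end = 5000)
  expect_equal(nrow(tads_disrupted(del_edge, tads)), 0)
  # brute-force containment scan on random deletions and maps
  set.seed(42)
  for (i in 1:50) {
    bounds <- sort(sample.int(1e5, 6))
    tm <- data.frame(chrom = "c", start = bounds[c(1, 3, 5)],
                     end = bounds[c(2, 4, 6)])
    ds <- sample.int(1e5, 1); de <- ds + sample.int(1e4, 1)
    got <- tads_disrupted(list(chrom = "c", start = ds, end = de), tm)
    want <- tm[(tm$start < ds & ds < tm$end) |
               (tm$start < de & de < tm$end), ]
    expect_equal(got$start, want$start)
  }
})

test_that("disrupted-contact counts match enumeration", {
  del <- list(chrom = "c", start = 1e6, end = 2e6)
  contacts <- data.frame(gene_symbol = c("g1", "g1", "g1", "g2"),
                         chrom = "c",
                         start = c(1.5e6, 3e6, 0.5e6, 1.1e6),
                         end = c(1.6e6, 3.1e6, 0.6e6, 1.2e6))
  expect_equal(disrupted_contacts("g1", del, contacts), 1)
  expect_equal(disrupted_contacts("g2", del, contacts), 1)
  expect_equal(disrupted_contacts("g3", del, contacts), 0)
  set.seed(7)
  for (i in 1:50) {
    cs <- sample.int(3e6, 20); ce <- cs + sample.int(1e5, 20, replace = TRUE)
    cc <- data.frame(gene_symbol = "g", chrom = "c", start = cs, end = ce)
    got <- disrupted_contacts("g", del, cc)
    want <- sum(vapply(seq_len(20), function(j)
      cs[j] < del$end && del$start < ce[j], logical(1)))
    expect_equal(got, want)
  }
})

test_that("phenotype overlap is the Jaccard index", {
  expect_equal(phenotype_overlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(phenotype_overlap(c("a", "b"), c("c", "d")), 0)
  expect_equal(phenotype_overlap(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(phenotype_overlap(c("a"), character(0)), 0)
  expect_error(phenotype_overlap(character(0), c("a")), "non-empty")
})

test_that("percentile ranks use strict-below counting with shared ties", {
  expect_equal(percentile_rank(5), 100)
  expect_equal(percentile_rank(1:5), c(0, 25, 50, 75, 100))
  expect_equal(percentile_rank(c(2, 2, 1)), c(50, 50, 0))
  expect_error(percentile_rank(numeric(0)), "non-empty")
  set.seed(3)
  for (i in 1:50) {
    x <- sample.int(20, sample(2:15, 1), replace = TRUE)
    got <- percentile_rank(x)
    want <- vapply(x, function(v)
      100 * sum(sort(x) < v) / (length(x) - 1), numeric(1))
    expect_equal(got, want)
  }
})

test_that("candidate prediction obeys the documented class rules", {
  locus <- make_locus(5)
  del <- gen_cohort(1, seed = 5)
  terms <- sample(locus$vocab, 8)
  res <- predict_candidates(del[1, ], locus$annotation, locus$tads,
                            locus$contacts, terms)
  # classes are mutually exclusive by construction: one label per row
  expect_true(all(res$candidate_class %in%
                  c("by_deletion", "by_position_effect", "none")))
  expect_true(all(res$status != "distal"))
  del_rows <- res$status %in% c("deleted", "partially_deleted")
  expect_true(all(res$candidate_class[del_rows] != "by_position_effect"))
  expect_true(all(res$candidate_class[!del_rows] != "by_deletion"))
  # sorted by rank score
  expect_true(all(diff(res$rank_score) <= 0))
  # empty annotation -> empty result
  empty <- predict_candidates(del[1, ], locus$annotation[0, ], locus$tads,
                              locus$contacts, terms)
  expect_equal(nrow(empty), 0)
})

test_that("a deleted gene with HI and phenotype support is a deletion candidate", {
  ann <- data.frame(symbol = "g1", chrom = "c", start = 2e6, end = 2.1e6,
                    hi_pct = 5, phenotype_terms = "a;b",
                    expressed_in_blood = TRUE)
  del <- data.frame(patient_id = "p", chrom = "c", start = 1e6, end = 3e6,
                    terminal = TRUE)
  tads <- data.frame(chrom = "c", start = 1, end = 4e6)
  res <- predict_candidates(del, ann, tads,
                            data.frame(gene_symbol = character(0),
                                       chrom = character(0),
                                       start = numeric(0),
                                       end = numeric(0)),
                            c("a", "b"))
  expect_equal(res$candidate_class, "by_deletion")
})

test_that("shrinking the window never grows the position-effect set", {
  for (seed in 1:20) {
    locus <- make_locus(seed)
    del <- gen_cohort(1, seed = seed + 100)
    terms <- sample(locus$vocab, 8)
    pe_sets <- lapply(c(2e6, 1e6, 0.5e6), function(w) {
      r <- predict_candidates(del[1, ], locus$annotation, locus$tads,
                              locus$contacts, terms,
                              pe_params(window = w))
      r$gene[r$candidate_class == "by_position_effect"]
    })
    expect_true(all(pe_sets[[2]] %in% pe_sets[[1]]))
    expect_true(all(pe_sets[[3]] %in% pe_sets[[2]]))
  }
})

test_that("no TADs and no contacts means no position-effect candidates", {
  locus <- make_locus(9)
  del <- gen_cohort(1, seed = 9)
  terms <- sample(locus$vocab, 8)
  res <- predict_candidates(
    del[1, ], locus$annotation,
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0)),
    data.frame(gene_symbol = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0)),
    terms)
  expect_equal(sum(res$candidate_class == "by_position_effect"), 0)
})

test_that("contacts naming unknown genes are skipped with a warning", {
  locus <- make_locus(2)
  del <- gen_cohort(1, seed = 2)
  contacts <- rbind(locus$contacts,
                    data.frame(gene_symbol = "NOT_A_GENE", chrom = "chrS",
                               start = 1, end = 100))
  expect_warning(
    predict_candidates(del[1, ], locus$annotation, locus$tads, contacts,
                       sample(locus$vocab, 5)),
    "NOT_A_GENE")
})

test_that("planted position-effect genes rank in the top 3", {
  top3 <- 0; total <- 0
  for (seed in 1:100) {
    locus <- make_locus(seed, n_genes = 50)
    del <- gen_cohort(1, size_range = c(1e6, 6e6), seed = seed + 500)
    terms <- sample(locus$vocab, 10)
    pl <- plant_position_effects(locus, del[1, ], terms, n = 1,
                                 seed = seed)
    if (length(pl$truth$planted_position_effect_genes) == 0) next
    res <- predict_candidates(del[1, ], pl$locus$annotation, pl$locus$tads,
                              pl$locus$contacts, terms)
    total <- total + 1
    if (pl$truth$planted_position_effect_genes[1] %in% res$gene[1:3])
      top3 <- top3 + 1
  }
  expect_gt(total, 50)
  expect_gte(top3 / total, 0.95)
})

test_that("cohort aggregation counts patients per gene and class", {
  locus <- make_locus(4)
  dels <- gen_cohort(3, seed = 4)
  terms <- sample(locus$vocab, 8)
  per <- lapply(1:3, function(i)
    predict_candidates(dels[i, ], locus$annotation, locus$tads,
                       locus$contacts, terms))
  agg1 <- aggregate_cohort(per[1])
  expect_true(all(agg1$n_candidate %in% 0:1))
  agg <- aggregate_cohort(per)
  # duplicating the cohort exactly doubles every count
  agg2 <- aggregate_cohort(c(per, per))
  expect_equal(agg2$n_candidate, 2 * agg$n_candidate)
  expect_equal(agg2$n_by_position_effect, 2 * agg$n_by_position_effect)
  # counting oracle
  all_rows <- do.call(rbind, per)
  for (g in agg$gene) {
    expect_equal(agg$n_candidate[agg$gene == g],
                 sum(all_rows$gene == g & all_rows$candidate_class != "none"))
  }
})
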