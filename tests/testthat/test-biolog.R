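test_that("relative absorbance subtracts the 750 nm background", {
  expect_equal(relative_absorbance(1.2, 0.2), 1.0)
  expect_equal(relative_absorbance(0.5, 0.5), 0)
  a <- runif(20); b <- runif(20)
  expect_equal(relative_absorbance(a, b), a - b)
  expect_error(relative_absorbance(NA, 1), "finite")
})

test_that("empty-plate normalisation subtracts well means with a floor", {
  emp <- data.frame(well = rep(c("A1", "A2"), each = 3),
                    value = c(0.1, 0.1, 0.1, 0.2, 0.3, 0.4))
  rd <- data.frame(well = c("A1", "A2"), value = c(0.8, 0.25))
  out <- normalize_to_empty(rd, emp)
  expect_equal(out$value, c(0.7, 1e-6))  # A2 floored (0.25 - 0.3 < 0)
  expect_error(normalize_to_empty(
    data.frame(well = "B1", value = 1), emp), "B1")
  expect_error(normalize_to_empty(rd, emp[-1, ]), "3 replicates")
  set.seed(5)
  for (i in 1:20) {
    wells <- well_labels()[1:10]
    emp <- data.frame(well = rep(wells, each = 3), value = runif(30))
    rd <- data.frame(well = wells, value = runif(10))
    out <- normalize_to_empty(rd, emp)
    mu <- tapply(emp$value, emp$well, mean)
    expect_equal(out$value, pmax(rd$value - as.numeric(mu[wells]), 1e-6))
  }
})

test_that("log transform is log10 with offset and preserves order", {
  expect_equal(log_transform(1), log10(1 + 1e-6))
  expect_equal(log_transform(10), log10(10 + 1e-6))
  expect_error(log_transform(-0.1), "non-negative")
  x <- sort(runif(100, 0, 5))
  expect_true(all(diff(log_transform(x)) >= 0))
})

test_that("kinetic parameters handle constant, linear and random curves", {
  t96 <- seq(15, 1440, by = 15)
  kc <- kinetic_params(t96, rep(0.7, 96))
  expect_equal(kc$slope, 0)
  expect_equal(kc$endpoint, 0.7)
  expect_equal(kc$auc, 0.7 * (1440 - 15) / 60)
  # linear 0 -> 1 over the sampled span
  lin <- (t96 - 15) / (1440 - 15)
  kl <- kinetic_params(t96, lin)
  expect_equal(kl$endpoint, 1)
  expect_equal(kl$slope, 60 / (1440 - 15), tolerance = 1e-9)
  expect_equal(kl$auc, (1440 - 15) / 60 / 2, tolerance = 1e-9)
  expect_error(kinetic_params(1, 0.5), "2 matched")
  # AUC equals fine-grid integration of the interpolant
  set.seed(10)
  for (i in 1:20) {
    od <- cumsum(rnorm(96, 0.01, 0.02))
    expect_equal(kinetic_params(t96, od)$auc, auc_fine_grid(t96, od),
                 tolerance = 1e-9)
  }
})

test_that("the Mann-Whitney well test matches exact enumeration", {
  r <- mann_whitney_well(c(1, 2), c(3, 4, 5))
  expect_equal(r$p_value, 0.2)
  expect_equal(r$p_value, mw_enum_p(c(1, 2), c(3, 4, 5)))
  expect_false(r$significant)
  # all-ties degenerate case
  r0 <- mann_whitney_well(c(1, 1), c(1, 1, 1))
  expect_equal(r0$p_value, 1)
  expect_equal(r0$direction, "none")
  # enumeration oracle across random small configurations
  set.seed(17)
  for (i in 1:30) {
    x <- runif(sample(2:4, 1)); y <- runif(sample(3:6, 1))
    expect_equal(mann_whitney_well(x, y)$p_value, mw_enum_p(x, y),
                 tolerance = 1e-12)
  }
  # rank statistic: invariant under common monotone transforms
  set.seed(18)
  x <- runif(5); y <- runif(12)
  expect_equal(mann_whitney_well(exp(x), exp(y))$p_value,
               mann_whitney_well(x, y)$p_value)
  expect_error(mann_whitney_well(1, c(1, 2)), "2 sample-side")
})

test_that("direction follows the median difference for significant wells", {
  up <- mann_whitney_well(c(10, 11, 12), c(1, 2, 3, 4, 5, 6))
  expect_true(up$significant)
  expect_equal(up$direction, "increased")
  dn <- mann_whitney_well(c(-5, -6, -7), c(1, 2, 3, 4, 5, 6))
  expect_equal(dn$direction, "decreased")
})

test_that("plate summaries render the printed percentage style", {
  mk <- function(k, n = 96) data.frame(
    significant = rep(c(TRUE, FALSE), c(k, n - k)),
    direction = rep(c("increased", "none"), c(k, n - k)))
  expect_equal(plate_summary(mk(43))$label, "43/96 (44.8%)")
  expect_equal(plate_summary(mk(15))$label, "15/96 (15.6%)")
  expect_equal(plate_summary(mk(96))$label, "96/96 (100%)")
  expect_equal(plate_summary(mk(0))$label, "0/96 (0.0%)")
  expect_equal(plate_summary(mk(76))$label, "76/96 (79.2%)")
  expect_equal(plate_summary(mk(88))$label, "88/96 (91.7%)")
  expect_equal(plate_summary(mk(94))$label, "94/96 (97.9%)")
  # percentage always recomputes as round(100 k / n, 1)
  for (k in c(1, 12, 48, 95))
    expect_equal(plate_summary(mk(k))$percent, round(100 * k / 96, 1))
})

test_that("significance is monotone in alpha and BH never adds wells", {
  set.seed(30)
  pd <- gen_plate_data(n_controls = 20, seed = 30,
                       truth = synthetic_truth(
                         true_well_effects = list("PM-M5" = c(A1 = 4,
                                                              B2 = -4))))
  res05 <- run_biolog_pipeline(pd$endpoint, pd$empty, "S1", alpha = 0.05)
  res01 <- run_biolog_pipeline(pd$endpoint, pd$empty, "S1", alpha = 0.01)
  expect_lte(res01$plates[["PM-M5"]]$n_significant,
             res05$plates[["PM-M5"]]$n_significant)
  res0 <- run_biolog_pipeline(pd$endpoint, pd$empty, "S1", alpha = 0)
  expect_equal(res0$plates[["PM-M5"]]$n_significant, 0)
  bh <- run_biolog_pipeline(pd$endpoint, pd$empty, "S1", adjust = "bh")
  raw_sig <- res05$wells$well[res05$wells$significant]
  bh_sig <- bh$wells$well[bh$wells$significant]
  expect_true(all(bh_sig %in% raw_sig))
})

test_that("kinetic statistics run through the plate pipeline", {
  pd <- gen_plate_data(n_controls = 5, seed = 44, kinetics = TRUE)
  res <- run_biolog_pipeline(pd$endpoint, pd$empty, "S1",
                             kinetics = pd$kinetics, statistic = "auc")
  expect_equal(nrow(res$wells), 96)
  expect_true(all(res$wells$p_value >= 0 & res$wells$p_value <= 1))
})
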