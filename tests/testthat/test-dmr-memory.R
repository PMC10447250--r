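test_that("candidate DMR filtering applies strict cut-offs", {
  dmrs <- data.frame(diff = c(0.25, 0.20, -0.3, 0.5, 0.1),
                     p = c(0.01, 0.01, 0.04, 0.2, 0.01))
  out <- filter_candidate_dmrs(dmrs)
  expect_equal(nrow(out), 2L)           # 0.25/0.01 and -0.3/0.04
  expect_equal(out$diff, c(0.25, -0.3)) # 0.20 exactly is dropped
  expect_equal(unname(attr(out, "dropped")["total"]), 3L)
  expect_error(filter_candidate_dmrs(data.frame(x = 1)), "diff")
})

test_that("classification examples are forced by the thresholds", {
  expect_equal(classify_dmr(-0.35, 0.05), "memory")
  expect_equal(classify_dmr(0.30, 0.30), "aberrant_hyper")
  expect_equal(classify_dmr(-0.35, 0.25), "partial_memory")
  expect_equal(classify_dmr(-0.35, -0.30), "aberrant_hypo")
  expect_equal(classify_dmr(0.30, 0.05), "memory_hyper")
  expect_equal(classify_dmr(0.30, -0.30), "partial_hyper")
  expect_equal(classify_dmr(0.10, 0.90), "below_threshold")
  # equality with the threshold falls on the no-difference side
  expect_equal(classify_dmr(0.2, 0.5), "below_threshold")
  expect_equal(classify_dmr(-0.5, 0.2), "memory")
  expect_error(classify_dmr(NA, 0.1), "defined")
})

test_that("the seven labels tile the delta plane exactly once", {
  set.seed(3)
  de <- runif(5000, -1, 1)
  dfib <- runif(5000, -1, 1)
  lab <- classify_dmr(de, dfib)
  expect_false(anyNA(lab))
  expect_true(all(lab %in% dmr_classes()))
  # independent predicate oracle: each pair satisfies exactly one region
  t <- 0.2
  pred <- cbind(abs(de) <= t,
                de < -t & abs(dfib) <= t,
                de < -t & dfib > t,
                de < -t & dfib < -t,
                de > t & dfib > t,
                de > t & abs(dfib) <= t,
                de > t & dfib < -t)
  expect_true(all(rowSums(pred) == 1))
})

test_that("set classification reports partitioning fractions", {
  lv <- data.frame(fibroblast = c(0.1, 0.1, 0.5, 0.8),
                   hES = c(0.8, 0.8, 0.5, 0.2),
                   primed = c(0.12, 0.45, 0.85, 0.9))
  out <- classify_dmr_set(lv, "primed")
  expect_equal(sum(out$fractions), 1)
  expect_equal(unname(out$counts["memory"]), 1L)
  expect_equal(unname(out$counts["partial_memory"]), 1L)
  expect_equal(unname(out$counts["aberrant_hyper"]), 1L)
  expect_equal(unname(out$counts["memory_hyper"]), 1L)
  expect_equal(out$hypo_fraction, 0.5)
  expect_error(classify_dmr_set(lv, "tnt"), "tnt")
  # all-memory degenerate case
  lv2 <- data.frame(fibroblast = 0.1, hES = 0.8, primed = c(0.1, 0.15))
  expect_equal(unname(classify_dmr_set(lv2, "primed")$fractions["memory"]), 1)
})

test_that("correction is strict and monotone in the threshold", {
  lv <- data.frame(hES = rep(0.5, 10),
                   TNT = 0.5 + c(0.1, 0.25, 0.05, 0, 0.15, 0.3, -0.1,
                                 -0.25, 0.12, -0.05))
  out <- assess_correction(lv, "TNT")
  expect_equal(out$fraction, 0.7)
  expect_false(out$corrected[2])
  # strict boundary: a difference exactly at the threshold is not
  # corrected (exactly representable values avoid float artefacts)
  exact <- data.frame(hES = 0.5, TNT = 0.625)
  expect_equal(assess_correction(exact, "TNT", threshold = 0.125)$fraction, 0)
  expect_equal(assess_correction(exact, "TNT", threshold = 0.25)$fraction, 1)
  # reference against itself is fully corrected
  expect_equal(assess_correction(lv, "hES", "hES")$fraction, 1)
  # monotonicity
  fr <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.5), function(t)
    assess_correction(lv, "TNT", threshold = t)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
  # undefined levels are excluded, not corrected
  lv$TNT[1] <- NA
  out2 <- assess_correction(lv, "TNT")
  expect_equal(out2$n_excluded, 1L)
  expect_equal(out2$n_evaluable, 9L)
})

test_that("time-course deltas track planted methylation gain", {
  g <- test_genome()
  dmr <- regions("chr1", seq(0, 1.9e5, by = 10000),
                 seq(0, 1.9e5, by = 10000) + 1000,
                 id = sprintf("d%d", 1:20))
  # aberrant hyper-methylation appearing late in the time course
  dmr$day0 <- 0.1; dmr$day13 <- 0.1; dmr$day21 <- 0.4
  sim <- generate_methylome(g, baseline = c(day0 = 0.8, day13 = 0.8,
                                            day21 = 0.8),
                            dmrs = dmr, coverage = 30, nonconversion = 0,
                            ca_spacing = 1000, seed = 21,
                            es_group = "none", fib_group = "none")
  tabs <- lapply(sim$tables, collapse_cg_strands)
  d <- timecourse_delta(dmr, tabs, baseline = "day0")
  expect_equal(unname(d["day0"]), 0)
  expect_equal(unname(d["day13"]), 0, tolerance = 0.05)
  expect_equal(unname(d["day21"]), 0.3, tolerance = 0.05)
  expect_true(d["day21"] > 0)
})

test_that("ICR screen recovers balanced imprints and flags erosion", {
  g <- test_genome()
  icr <- regions("chr1", c(10000, 50000), c(14000, 54000),
                 id = c("icr1", "icr2"))
  sim <- generate_methylome(g, baseline = c(s = 0.8), icrs = icr,
                            coverage = 50, nonconversion = 0,
                            ca_spacing = 1000, seed = 5)
  tab <- collapse_cg_strands(sim$tables$s)
  scr <- icr_screen(tab, icr)
  expect_equal(scr$per_icr$level, c(0.5, 0.5), tolerance = 0.1)
  expect_equal(scr$n_flagged, 0L)
  expect_equal(scr$median, 0.5, tolerance = 0.05)
  # a demethylated ICR is flagged
  tab2 <- tab
  sel <- tab2$pos > 10000 & tab2$pos <= 14000
  tab2$mc[sel] <- 0L
  scr2 <- icr_screen(tab2, icr)
  expect_true(scr2$per_icr$flagged[1])
  expect_lt(scr2$per_icr$level[1], 0.05)
})
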