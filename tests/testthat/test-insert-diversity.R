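test_that("alignment filter boundaries follow the stated cut-offs", {
  pairs <- rbind(
    valid_pair(read_id = "ok"),
    valid_pair(read_id = "len799", gstart = 2500L - 799L),   # short
    valid_pair(read_id = "len800", gstart = 2500L - 800L),   # kept
    valid_pair(read_id = "gap50", read_vstart = 1550L,
               read_vend = 2450L),                           # gap 50: kept
    valid_pair(read_id = "gap51", read_vstart = 1551L,
               read_vend = 2451L),                           # gap 51: out
    valid_pair(read_id = "mapq59", mapq = 59L),
    valid_pair(read_id = "mapq61", mapq = 61L),              # != 60: out
    valid_pair(read_id = "secondary", is_primary = FALSE),
    valid_pair(read_id = "single", vstart = NA, vend = NA,
               read_vstart = NA, read_vend = NA))
  out <- filter_alignments(pairs)
  expect_setequal(out$kept$read_id, c("ok", "len800", "gap50"))
  expect_equal(sum(out$rejected) + nrow(out$kept), out$n_input)
  expect_equal(unname(out$rejected["short"]), 1L)
  expect_equal(unname(out$rejected["gap"]), 1L)
  expect_equal(unname(out$rejected["low_mapq"]), 2L)
  expect_equal(unname(out$rejected["non_primary"]), 1L)
  expect_equal(unname(out$rejected["single_mapped"]), 1L)
  # >= variant admits mapq 61
  ge <- filter_alignments(pairs, mapq_ge = TRUE)
  expect_true("mapq61" %in% ge$kept$read_id)
})

test_that("filtering is order-independent and idempotent", {
  g <- test_genome(chr1 = 2e6)
  lib <- generate_insertion_library(50, 4, g, seed = 3,
                                    noise_spec = c(non_primary = 0.1,
                                                   short = 0.1, gap = 0.1))
  f1 <- filter_alignments(lib$pairs)
  shuffled <- lib$pairs[sample(nrow(lib$pairs)), ]
  f2 <- filter_alignments(shuffled)
  expect_setequal(f1$kept$read_id, f2$kept$read_id)
  expect_equal(f1$rejected, f2$rejected)
  f3 <- filter_alignments(f1$kept)
  expect_equal(nrow(f3$kept), nrow(f1$kept))
  expect_equal(sum(f3$rejected), 0L)
})

test_that("junction clustering chains sites transitively within 50 bp", {
  mk <- function(pos) valid_pair(gend = pos, gstart = pos - 1500L)
  # junction = gend on plus strand with vector to the right of genome hit
  cl <- call_insert_sites(do.call(rbind, lapply(c(100L, 140L, 400L),
                                                function(p) mk(p))))
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start, c(100, 400))
  expect_equal(cl$end, c(140, 400))
  expect_equal(cl$coverage, c(2L, 1L))
  # transitive chain 100, 150, 200 joins one cluster
  chain <- call_insert_sites(do.call(rbind, lapply(c(100L, 150L, 200L), mk)))
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$coverage, 3L)
})

test_that("clustering matches the quadratic single-linkage oracle", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    pos <- sample.int(3000, n, replace = TRUE) + 2000L
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    pairs <- do.call(rbind, lapply(seq_len(n), function(j)
      valid_pair(chrom = chrom[j], gend = pos[j], gstart = pos[j] - 1500L)))
    got <- call_insert_sites(pairs)
    for (chr in unique(chrom)) {
      want <- oracle_single_linkage(chrom[chrom == chr], pos[chrom == chr])
      sub <- got[got$chrom == chr, ]
      expect_equal(sub$start, want$start)
      expect_equal(sub$end, want$end)
      expect_equal(sub$coverage, unname(want$coverage))
    }
  }
})

test_that("the fixed point solves the zero-truncated Poisson relation", {
  # independent bisection oracle on N (1 - exp(-R/N)) = n
  bisect <- function(n, R) {
    f <- function(N) N * (1 - exp(-R / N)) - n
    lo <- n; hi <- n * 100
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  fp <- epimemory:::ztp_fixed_point(950, 3000)
  expect_true(fp$converged)
  expect_equal(fp$n_total, bisect(950, 3000), tolerance = 1e-4)
  expect_equal(fp$n_total, 1000, tolerance = 1)
  # saturated limit: lambda so high that nothing is unobserved
  fp2 <- epimemory:::ztp_fixed_point(10, 1000)
  expect_equal(fp2$n_total, 10, tolerance = 1e-6)
  # random instances against the oracle
  set.seed(6)
  for (i in 1:20) {
    n <- sample(50:2000, 1)
    R <- n * runif(1, 1.2, 8)
    fp <- epimemory:::ztp_fixed_point(n, R)
    expect_equal(fp$n_total, bisect(n, R), tolerance = 1e-3)
    expect_gte(fp$n_total, n)
  }
})

test_that("degenerate coverage-one libraries are flagged unbounded", {
  cl <- data.frame(coverage = rep(1L, 20))
  est <- estimate_diversity(cl, n_boot = 0)
  expect_false(est$converged)
  expect_true(is.infinite(est$n_total_hat))
  expect_error(estimate_diversity(data.frame(coverage = 5L)), "at least 2")
})

test_that("diversity estimation recovers a planted insertion landscape", {
  g <- genome_spec(c(chr1 = 5e6, chr2 = 5e6, lambda = 48502), "lambda")
  lib <- generate_insertion_library(1000, 3, g, seed = 7)
  fl <- filter_alignments(lib$pairs)
  expect_equal(sum(fl$rejected), 0L)  # noise-free library: nothing dropped
  cl <- call_insert_sites(fl$kept)
  expect_equal(nrow(cl), 1000 * (1 - exp(-3)), tolerance = 10 / 950)
  est <- estimate_diversity(cl, n_boot = 200, seed = 8)
  expect_true(est$converged)
  expect_equal(est$n_total_hat, 1000, tolerance = 0.05)
  expect_gte(est$n_total_hat, est$n_observed)
  # the point estimate lies inside its own CI
  expect_true(est$ci[1] <= est$n_total_hat && est$n_total_hat <= est$ci[2])
})

test_that("estimator error shrinks as read depth grows", {
  g <- genome_spec(c(chr1 = 5e6, chr2 = 5e6, lambda = 48502), "lambda")
  err <- vapply(c(1, 3, 10), function(lam) {
    e <- vapply(1:5, function(s) {
      lib <- generate_insertion_library(500, lam, g, seed = 100 + s)
      cl <- call_insert_sites(filter_alignments(lib$pairs)$kept)
      est <- estimate_diversity(cl, n_boot = 0)
      abs(est$n_total_hat - 500) / 500
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_true(err[3] < err[1])
})
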