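test_that("dynamic-element filter keeps range >= 0.2 and drops NA rows", {
  m <- rbind(a = c(0.1, 0.35, 0.2),   # range 0.25 -> kept
             b = c(0.5, 0.65, 0.6),   # range 0.15 -> dropped
             c = c(0.4, 0.4, 0.4),    # constant -> dropped
             d = c(0.1, NA, 0.9))     # NA -> dropped
  out <- filter_dynamic_elements(m)
  expect_equal(rownames(out), "a")
  expect_equal(attr(out, "n_dropped_na"), 1L)
  expect_equal(attr(out, "n_dropped_static"), 2L)
  expect_error(filter_dynamic_elements(m["b", , drop = FALSE]), "no dynamic")
})

test_that("membership rows sum to one and the objective never increases", {
  tr <- generate_trajectories(120, paste0("t", 1:5),
                              rbind(c(0.9, 0.7, 0.5, 0.3, 0.1),
                                    c(0.1, 0.3, 0.5, 0.7, 0.9)),
                              noise_sd = 0.05, seed = 41)
  fit <- fuzzy_cmeans(tr$matrix, k = 2, seed = 42)
  expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
  expect_true(fit$converged)
  # returned objective matches an independent re-evaluation at (u, centers)
  xs <- t(scale(t(tr$matrix)))
  d2 <- as.matrix(stats::dist(rbind(fit$centers, xs)))^2
  d2 <- t(d2[seq_len(fit$k), -seq_len(fit$k)])
  expect_equal(sum(fit$membership^fit$m * d2), fit$objective,
               tolerance = 1e-8)
})

test_that("symmetry and coincidence conventions hold", {
  # midpoint between two tight groups gets memberships (0.5, 0.5)
  x <- matrix(c(0, 0, 0, 1, 1, 1, 0.5,
                0, 0, 0, 1, 1, 1, 0.5), ncol = 2,
              dimnames = list(sprintf("p%d", 1:7), c("t1", "t2")))
  fit <- fuzzy_cmeans(x, k = 2, seed = 1, standardize = FALSE)
  mid <- fit$membership["p7", ]
  expect_equal(unname(sort(mid)), c(0.5, 0.5), tolerance = 1e-4)
  # a point at zero distance from a center gets membership exactly 1
  u <- epimemory:::fcm_memberships(matrix(c(0, 2), 1, 2), m = 2)
  expect_equal(unname(u[1, ]), c(1, 0))
})

test_that("planted clusters are recovered and match an independent FCM", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("mclust")
  cents <- rbind(c(0.9, 0.8, 0.5, 0.2, 0.1, 0.1),
                 c(0.1, 0.2, 0.5, 0.8, 0.9, 0.9),
                 c(0.1, 0.6, 0.9, 0.6, 0.2, 0.1))
  tr <- generate_trajectories(180, paste0("t", 1:6), cents,
                              noise_sd = 0.03, seed = 51)
  fit <- fuzzy_cmeans(tr$matrix, k = 3, seed = 52)
  ari <- mclust::adjustedRandIndex(fit$cluster, tr$truth)
  expect_gt(ari, 0.9)
  # e1071's FCM on the same standardized data reaches the same optimum
  # (objective re-evaluated on a common scale at its solution)
  xs <- t(scale(t(tr$matrix)))
  ref <- e1071::cmeans(xs, centers = 3, m = 2, iter.max = 500)
  d2 <- as.matrix(stats::dist(rbind(ref$centers, xs)))^2
  d2 <- t(d2[1:3, -(1:3)])
  expect_equal(fit$objective, sum(ref$membership^2 * d2), tolerance = 1e-4)
  # original-unit centers sit near the planted centroids
  perm <- apply(fit$centers_orig, 1, function(cc)
    which.min(colSums((t(cents) - cc)^2)))
  expect_equal(unname(sort(perm)), 1:3)
  expect_lt(max(abs(fit$centers_orig - cents[perm, ])), 0.05)
})

test_that("small fuzzifier approaches k-means hard assignments", {
  skip_if_not_installed("mclust")
  tr <- generate_trajectories(90, paste0("t", 1:4),
                              rbind(c(0.9, 0.7, 0.3, 0.1),
                                    c(0.1, 0.3, 0.7, 0.9)),
                              noise_sd = 0.02, seed = 61)
  fit <- fuzzy_cmeans(tr$matrix, k = 2, m = 1.05, seed = 62)
  km <- stats::kmeans(t(scale(t(tr$matrix))), centers = 2, nstart = 5)
  expect_equal(mclust::adjustedRandIndex(fit$cluster, km$cluster), 1)
})

test_that("cluster merging follows core Jaccard overlap", {
  tr <- generate_trajectories(150, paste0("t", 1:5),
                              rbind(c(0.9, 0.7, 0.5, 0.3, 0.1),
                                    c(0.1, 0.3, 0.5, 0.7, 0.9),
                                    c(0.5, 0.9, 0.5, 0.1, 0.5)),
                              noise_sd = 0.03, seed = 71)
  a <- fuzzy_cmeans(tr$matrix, k = 3, seed = 72)
  b <- fuzzy_cmeans(tr$matrix, k = 3, seed = 73)
  merged <- merge_overlapping_clusters(a, b)
  # identical data, different inits: all three clusters pair up
  expect_equal(nrow(merged), 3L)
  expect_true(all(merged$jaccard > 0.9))
  expect_equal(sort(merged$cluster_a), 1:3)
  expect_equal(sort(merged$cluster_b), 1:3)
  # disjoint clusterings do not merge
  b2 <- b
  b2$membership <- matrix(0, nrow(b$membership), 3,
                          dimnames = dimnames(b$membership))
  expect_equal(nrow(merge_overlapping_clusters(a, b2)), 0L)
})

test_that("quantile normalization equalizes sample distributions", {
  set.seed(81)
  x <- matrix(rexp(300, 1 / 50), 100, 3,
              dimnames = list(sprintf("g%d", 1:100), c("s1", "s2", "s3")))
  qn <- quantile_normalize(x)
  expect_equal(sort(qn[, 1]), sort(qn[, 2]), ignore_attr = TRUE)
  expect_equal(sort(qn[, 2]), sort(qn[, 3]), ignore_attr = TRUE)
  expect_equal(dimnames(qn), dimnames(x))
})

test_that("weighted expression summaries respect weights and degeneracy", {
  tpm <- matrix(c(10, 20, 30, 40, 50, 60), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("t0", "t1")))
  links <- data.frame(element = c("e1", "e2", "e3"),
                      gene = c("g1", "g2", "g3"),
                      score = c(1, 1, 1))
  clusters <- c(e1 = 1, e2 = 1, e3 = 2)
  out <- weighted_expression_summary(tpm, links, clusters, n_boot = 50,
                                     seed = 91)
  # identity weights: plain means of member TPM
  expect_equal(out$mean[out$cluster == 1 & out$timepoint == "t0"], 15)
  expect_equal(out$mean[out$cluster == 1 & out$timepoint == "t1"], 45)
  # single-gene cluster: degenerate bootstrap, zero-width CI
  single <- out[out$cluster == 2, ]
  expect_equal(single$lower, single$mean)
  expect_equal(single$upper, single$mean)
  # scores scale the contribution
  links2 <- links; links2$score <- c(2, 0, 1)
  out2 <- weighted_expression_summary(tpm, links2, clusters, n_boot = 50,
                                      seed = 92)
  expect_equal(out2$mean[out2$cluster == 1 & out2$timepoint == "t0"],
               (10 * 2 + 20 * 0) / 2)
  # a cluster with no linked genes warns and yields NA
  expect_warning(
    out3 <- weighted_expression_summary(tpm, links[1:2, ],
                                        c(e1 = 1, e2 = 1, e9 = 2),
                                        n_boot = 20, seed = 93),
    "cluster 2")
  expect_true(all(is.na(out3$mean[out3$cluster == 2])))
})
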