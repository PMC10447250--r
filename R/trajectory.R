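#' Filter for dynamic trajectory elements
#'
#' Keeps elements whose methylation range (max minus min over time points)
#' is at least `min_change`; elements with any undefined value are dropped
#' first and counted. Clustering static elements is uninformative, so the
#' default mirrors the >= 0.2 mCG/CG change criterion used for regulatory
#' elements through reprogramming.
#'
#' @param matrix element x time-point numeric matrix (values in \[0, 1\]).
#' @param min_change minimum range (default 0.2).
#' @return the retained rows; attributes `"n_dropped_na"` and
#'   `"n_dropped_static"` report the exclusions.
#' @export
filter_dynamic_elements <- function(matrix, min_change = 0.2) {
  complete <- stats::complete.cases(matrix)
  m <- matrix[complete, , drop = FALSE]
  rng <- apply(m, 1, function(x) max(x) - min(x))
  keep <- rng >= min_change
  out <- m[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no dynamic elements retained")
  attr(out, "n_dropped_na") <- sum(!complete)
  attr(out, "n_dropped_static") <- sum(!keep)
  out
}

# Squared Euclidean distances between rows of x and rows of centers.
dist2 <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
        outer(rep(1, nrow(x)), rowSums(centers^2)) -
        2 * x %*% t(centers)
  pmax(d2, 0)
}

# Membership update for fuzzifier m: u_ij = 1 / sum_l (d_ij/d_lj)^(2/(m-1)).
# A point coincident with a center gets membership 1 for that center.
fcm_memberships <- function(d2, m) {
  eps <- 1e-12
  u <- d2^(-1 / (m - 1))
  zero <- d2 < eps
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    u[cbind(which(hit), max.col(-d2[hit, , drop = FALSE]))] <- 1
  }
  u[!hit, ] <- u[!hit, , drop = FALSE] / rowSums(u[!hit, , drop = FALSE])
  u
}

#' Fuzzy c-means clustering of methylation trajectories
#'
#' Standard Bezdek fuzzy c-means minimizing \eqn{\sum_{i,j} u_{ij}^m
#' d^2(x_j, c_i)} subject to memberships summing to 1 per element, by
#' alternating membership and center updates. Rows are standardized to
#' mean 0, sd 1 before clustering (the usual convention for expression- or
#' methylation-trajectory clustering, so that cluster assignment reflects
#' trajectory shape rather than absolute level); centers are reported both
#' in standardized units and back in original units as the
#' membership-weighted mean of the original rows.
#'
#' @param x element x time-point numeric matrix with row names.
#' @param k number of clusters (>= 2, < number of elements).
#' @param m fuzzifier (> 1; default 2).
#' @param tol convergence tolerance on the maximum center displacement.
#' @param max_iter maximum iterations.
#' @param seed optional integer seed; initialization picks k distinct
#'   random rows as centers.
#' @param standardize standardize rows before clustering (default TRUE).
#' @return object of class `fcm`: `centers` (standardized units),
#'   `centers_orig` (original units), `membership` (element x k, rows sum
#'   to 1), `cluster` (hard assignment), `objective`,
#'   `objective_trace` (per iteration, non-increasing), `iterations`,
#'   `converged`, `k`, `m`.
#' @export
fuzzy_cmeans <- function(x, k, m = 2, tol = 1e-6, max_iter = 1000,
                         seed = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2) stop("k must be at least 2")
  if (k >= n) stop("k must be smaller than the number of elements")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (!is.null(seed)) set.seed(seed)
  xs <- if (standardize) {
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0))
      stop("constant rows cannot be standardized; filter them first")
    t(scale(t(x)))
  } else x
  centers <- xs[sample.int(n, k), , drop = FALSE]
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  u <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    d2 <- dist2(xs, centers)
    u <- fcm_memberships(d2, m)
    um <- u^m
    new_centers <- (t(um) %*% xs) / colSums(um)
    trace <- c(trace, sum(um * dist2(xs, new_centers)))
    move <- max(abs(new_centers - centers))
    centers <- new_centers
    if (move < tol) { converged <- TRUE; break }
  }
  um <- u^m
  centers_orig <- (t(um) %*% x) / colSums(um)
  rownames(centers) <- rownames(centers_orig) <- sprintf("c%d", seq_len(k))
  dimnames(u) <- list(rownames(x), rownames(centers))
  structure(list(k = k, m = m, centers = centers,
                 centers_orig = centers_orig, membership = u,
                 cluster = max.col(u), objective = trace[length(trace)],
                 objective_trace = trace, iterations = iter,
                 converged = converged, standardize = standardize,
                 element_ids = rownames(x)),
            class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  cat("Fuzzy c-means: k =", x$k, ", m =", x$m, ",", length(x$element_ids),
      "elements\n  objective", signif(x$objective, 6), "after",
      x$iterations, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.fcm <- function(object, ...) {
  cat("Fuzzy c-means clustering\n")
  print(object)
  sizes <- table(factor(object$cluster, levels = seq_len(object$k)))
  cat("  hard-assignment sizes:", paste(sizes, collapse = ", "), "\n")
  cat("  centers (original units):\n")
  print(round(object$centers_orig, 3))
  invisible(object)
}

#' Merge overlapping clusters between two clusterings
#'
#' Clusterings from two time courses are matched through their cores (the
#' elements with membership at least `core_membership`): cluster pairs
#' whose cores have a Jaccard index of at least `jaccard_min` are merged
#' greedily in descending Jaccard order, each cluster merging at most
#' once.
#'
#' @param a,b `fcm` objects sharing element ids.
#' @param core_membership membership cut-off defining cluster cores.
#' @param jaccard_min minimum Jaccard index of cores to merge.
#' @return data.frame of merges: `cluster_a`, `cluster_b`, `jaccard`.
#' @export
merge_overlapping_clusters <- function(a, b, core_membership = 0.5,
                                       jaccard_min = 0.5) {
  core <- function(f, j) f$element_ids[f$membership[, j] >= core_membership]
  jac <- matrix(0, a$k, b$k)
  for (i in seq_len(a$k)) for (j in seq_len(b$k)) {
    ca <- core(a, i); cb <- core(b, j)
    un <- length(union(ca, cb))
    jac[i, j] <- if (un == 0) 0 else length(intersect(ca, cb)) / un
  }
  ord <- order(jac, decreasing = TRUE)
  used_a <- logical(a$k); used_b <- logical(b$k)
  out <- data.frame(cluster_a = integer(), cluster_b = integer(),
                    jaccard = numeric())
  for (idx in ord) {
    if (jac[idx] < jaccard_min) break
    i <- (idx - 1) %% a$k + 1
    j <- (idx - 1) %/% a$k + 1
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    out <- rbind(out, data.frame(cluster_a = i, cluster_b = j,
                                 jaccard = jac[idx]))
  }
  rownames(out) <- NULL
  out
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution;
#' after normalization the sorted values of all columns are identical.
#'
#' @param x gene x sample numeric matrix.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  out <- limma::normalizeQuantiles(as.matrix(x))
  dimnames(out) <- dimnames(x)
  out
}

#' Interaction-weighted expression summary per cluster
#'
#' Summarizes the expression of genes linked to the elements of each
#' cluster. Each linked gene's expression is weighted by its
#' element-gene interaction score (TPM x score), down-weighting weakly
#' supported links. Per cluster and time point the mean over linked genes
#' is reported with a nonparametric bootstrap percentile confidence
#' interval (over linked genes).
#'
#' @param tpm gene x sample numeric matrix (e.g. quantile-normalized TPM).
#' @param links data.frame with columns `element`, `gene`, `score`.
#' @param clusters named vector mapping element id -> cluster id.
#' @param n_boot bootstrap replicates (default 1000).
#' @param ci confidence level (default 0.99).
#' @param seed optional integer seed.
#' @return data.frame: `cluster`, `timepoint`, `mean`, `lower`, `upper`,
#'   `n_genes`. Clusters with no linked gene yield `NA` with a warning.
#' @export
weighted_expression_summary <- function(tpm, links, clusters, n_boot = 1000,
                                        ci = 0.99, seed = NULL) {
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  if (any(links$score < 0)) stop("interaction scores must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  alpha <- (1 - ci) / 2
  tps <- colnames(tpm)
  out <- NULL
  for (cl in sort(unique(clusters))) {
    members <- names(clusters)[clusters == cl]
    lk <- links[links$element %in% members & links$gene %in% rownames(tpm), ,
                drop = FALSE]
    if (nrow(lk) == 0L) {
      warning("cluster ", cl, " has no linked genes")
      out <- rbind(out, data.frame(cluster = cl, timepoint = tps,
                                   mean = NA_real_, lower = NA_real_,
                                   upper = NA_real_, n_genes = 0L))
      next
    }
    w <- tpm[lk$gene, , drop = FALSE] * lk$score
    est <- colMeans(w)
    boot <- matrix(NA_real_, n_boot, length(tps))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(w), replace = TRUE)
      boot[b, ] <- colMeans(w[idx, , drop = FALSE])
    }
    qs <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha))
    out <- rbind(out, data.frame(cluster = cl, timepoint = tps,
                                 mean = unname(est),
                                 lower = unname(qs[1, ]),
                                 upper = unname(qs[2, ]),
                                 n_genes = nrow(w)))
  }
  rownames(out) <- NULL
  out
}
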