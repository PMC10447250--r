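# Gap in read coordinates between the genome-side and vector-side
# alignments of a read; 0 when the intervals touch or overlap.
read_gap <- function(pairs) {
  pmax(pmax(pairs$read_vstart - pairs$read_gend,
            pairs$read_gstart - pairs$read_vend), 0L)
}

#' Filter dual-alignment pairs for insertion-site calling
#'
#' Keeps reads that (i) carry a primary genome alignment, (ii) also map to
#' the vector sequence, (iii) have a genome alignment length of at least
#' `min_len` bp, (iv) have the required mapping quality, and (v) show a
#' gap of at most `max_gap` bp between the genome and vector alignment
#' intervals on the read (a read with a gap of 51 bp or more is
#' discarded). Each rejected read is tallied under the first criterion it
#' violates, so the tallies plus the kept reads sum to the input size.
#'
#' @param pairs data.frame of alignment pairs with columns `read_id`,
#'   `chrom`, `gstart`, `gend`, `strand`, `mapq`, `is_primary`,
#'   `read_gstart`, `read_gend`, `vstart`, `vend`, `read_vstart`,
#'   `read_vend`, `read_length` (vector columns `NA` when the read maps
#'   only to the genome).
#' @param min_len minimum genome alignment length (default 800 bp).
#' @param req_mapq required mapping quality (default 60).
#' @param max_gap maximum read-coordinate gap (default 50 bp).
#' @param mapq_ge if `TRUE`, accept `mapq >= req_mapq` instead of exact
#'   equality.
#' @return list with `kept` (the retained rows), `rejected` (named counts
#'   per criterion) and `n_input`.
#' @export
filter_alignments <- function(pairs, min_len = 800, req_mapq = 60,
                              max_gap = 50, mapq_ge = FALSE) {
  n <- nrow(pairs)
  crit <- matrix(FALSE, n, 5,
                 dimnames = list(NULL, c("non_primary", "single_mapped",
                                         "short", "low_mapq", "gap")))
  crit[, "non_primary"] <- !pairs$is_primary
  crit[, "single_mapped"] <- is.na(pairs$read_vstart)
  crit[, "short"] <- (pairs$gend - pairs$gstart) < min_len
  crit[, "low_mapq"] <- if (mapq_ge) pairs$mapq < req_mapq
                        else pairs$mapq != req_mapq
  gap <- read_gap(pairs)
  crit[, "gap"] <- !is.na(gap) & gap > max_gap
  first <- apply(crit, 1, function(x) if (any(x)) which(x)[1] else 0L)
  rejected <- tabulate(first[first > 0], nbins = 5)
  names(rejected) <- colnames(crit)
  kept <- pairs[first == 0L, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, rejected = rejected, n_input = n)
}

# Genome coordinate of the insertion junction for each read: the boundary
# of the genome alignment that sits nearest the vector alignment on the
# read, mapped back through the strand of the genome hit.
junction_coord <- function(pairs) {
  vector_right <- pairs$read_vstart >= pairs$read_gend
  ifelse(vector_right,
         ifelse(pairs$strand == "+", pairs$gend, pairs$gstart),
         ifelse(pairs$strand == "+", pairs$gstart, pairs$gend))
}

#' Call insertion-site clusters from filtered alignment pairs
#'
#' Derives the per-read insertion junction from the genome and vector
#' alignment coordinates, then chains junctions by single linkage:
#' consecutive sorted junctions at most `cluster_interval` bp apart join
#' the same cluster (transitively). Each cluster spans the smallest start
#' and largest end of its member junctions and its coverage is the member
#' count.
#'
#' @param pairs filtered alignment-pair data.frame (see
#'   [filter_alignments()]).
#' @param cluster_interval maximum distance chaining two junctions
#'   (default 50 bp).
#' @return data.frame with one row per cluster: `chrom`, `start`, `end`,
#'   `coverage`, and a list-column `members` of member junction
#'   coordinates.
#' @export
call_insert_sites <- function(pairs, cluster_interval = 50) {
  if (nrow(pairs) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), coverage = integer()))
  pos <- junction_coord(pairs)
  chrom <- pairs$chrom
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  new_cluster <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                           diff(pos) > cluster_interval)
  cl <- cumsum(new_cluster)
  out <- data.frame(chrom = tapply(chrom, cl, `[`, 1),
                    start = as.numeric(tapply(pos, cl, min)),
                    end = as.numeric(tapply(pos, cl, max)),
                    coverage = as.integer(tapply(pos, cl, length)),
                    stringsAsFactors = FALSE)
  out$members <- unname(split(pos, cl))
  rownames(out) <- NULL
  out
}

# Zero-truncated Poisson fixed point: smallest N with N (1 - e^(-R/N)) = n,
# iterated from N0 = n. Returns list(n_total, converged, iterations).
ztp_fixed_point <- function(n, R, tol = 1e-6, max_iter = 10000) {
  if (R <= n) return(list(n_total = Inf, converged = FALSE, iterations = 0L))
  N <- n
  for (i in seq_len(max_iter)) {
    N1 <- n / (1 - exp(-R / N))
    if (abs(N1 - N) < tol)
      return(list(n_total = N1, converged = TRUE, iterations = i))
    N <- N1
  }
  list(n_total = N, converged = FALSE, iterations = max_iter)
}

#' Estimate clonal insertion diversity from site coverage
#'
#' Models per-site read counts as Poisson: with `n` observed unique sites
#' and `R` total supporting reads, the true site count `N` (including
#' unobserved, zero-read sites) satisfies the zero-truncated-Poisson
#' relation `N (1 - exp(-R/N)) = n`, solved by fixed-point iteration from
#' `N = n`. Uncertainty comes from a Poisson bootstrap: every read gets an
#' independent Poisson(1) weight, the unique-site count and read total are
#' recomputed from the surviving weights, the estimator re-run, and a
#' percentile interval reported. The resampled libraries carry a larger
#' zero class than a homogeneous Poisson with the same mean, so raw
#' bootstrap re-estimates are centered below the point estimate; the
#' percentile interval is therefore recentered on the point estimate
#' (bias-corrected percentile), which also guarantees the interval
#' contains the estimate.
#'
#' When every site has coverage 1 (`R = n`) the relation has no finite
#' root; the estimate is returned unbounded with `converged = FALSE`.
#'
#' @param clusters data.frame from [call_insert_sites()] (needs a
#'   `coverage` column).
#' @param n_boot bootstrap replicates (default 1000).
#' @param ci_level confidence level (default 0.95).
#' @param tol fixed-point tolerance.
#' @param max_iter maximum fixed-point iterations.
#' @param seed optional integer seed.
#' @return object of class `diversity_estimate`: `n_observed`,
#'   `total_reads`, `lambda_hat` (reads per true site), `n_total_hat`,
#'   `ci`, `ci_level`, `converged`, `n_boot`.
#' @export
estimate_diversity <- function(clusters, n_boot = 1000, ci_level = 0.95,
                               tol = 1e-6, max_iter = 10000, seed = NULL) {
  cov <- clusters$coverage
  n <- length(cov)
  if (n < 2) stop("need at least 2 observed insertion sites")
  if (!is.null(seed)) set.seed(seed)
  R <- sum(cov)
  fp <- ztp_fixed_point(n, R, tol, max_iter)
  ci <- c(NA_real_, NA_real_)
  if (fp$converged && n_boot > 0) {
    boot <- vapply(seq_len(n_boot), function(b) {
      newcov <- stats::rpois(n, cov)
      nb <- sum(newcov > 0)
      Rb <- sum(newcov)
      if (nb < 2 || Rb <= nb) return(NA_real_)
      ztp_fixed_point(nb, Rb, tol, max_iter)$n_total
    }, numeric(1))
    alpha <- (1 - ci_level) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)) -
      mean(boot, na.rm = TRUE) + fp$n_total
  }
  structure(list(n_observed = n, total_reads = R,
                 lambda_hat = if (is.finite(fp$n_total)) R / fp$n_total
                              else NA_real_,
                 n_total_hat = fp$n_total, ci = ci, ci_level = ci_level,
                 converged = fp$converged, n_boot = n_boot),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat("Clonal insertion diversity (zero-truncated Poisson)\n",
      "  observed sites: ", x$n_observed, " (", x$total_reads, " reads)\n",
      sep = "")
  if (x$converged) {
    cat("  estimated total sites: ", round(x$n_total_hat, 1),
        "  (", 100 * x$ci_level, "% CI ", round(x$ci[1], 1), "-",
        round(x$ci[2], 1), ")\n",
        "  reads per site (lambda): ", round(x$lambda_hat, 2), "\n", sep = "")
  } else {
    cat("  estimate unbounded (all sites at coverage 1); converged = FALSE\n")
  }
  invisible(x)
}
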