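# Uniform random starts for widths w on a single contig of length L,
# optionally avoiding mask intervals (data.frame start/end on that chrom).
# Returns integer starts (0-based); placements are independent.
random_starts <- function(w, L, mask = NULL) {
  if (is.null(mask) || nrow(mask) == 0L) {
    space <- L - w + 1
    if (any(space <= 0))
      stop("interval wider than contig (width ", max(w), ", contig ", L, ")")
    return(as.integer(floor(stats::runif(length(w)) * space)))
  }
  # merge mask, derive allowed gaps once; per width, allowed starts are
  # the union of [gap.start, gap.end - w]
  o <- order(mask$start)
  ms <- mask$start[o]; me <- mask$end[o]
  gs <- integer(0); ge <- integer(0)
  cur <- 0L
  for (i in seq_along(ms)) {
    if (ms[i] > cur) { gs <- c(gs, cur); ge <- c(ge, ms[i]) }
    cur <- max(cur, me[i])
  }
  if (cur < L) { gs <- c(gs, cur); ge <- c(ge, as.integer(L)) }
  vapply(w, function(wi) {
    ok <- ge - gs >= wi
    if (!any(ok))
      stop("interval of width ", wi, " does not fit outside the mask")
    navail <- ge[ok] - gs[ok] - wi + 1L
    seg <- sample.int(sum(ok), 1L, prob = navail)
    gs[ok][seg] + sample.int(navail[seg], 1L) - 1L
  }, integer(1))
}

#' Randomly re-place regions on their chromosomes
#'
#' Each interval is re-placed uniformly at random on its own chromosome
#' with its width preserved, independently of the others and outside an
#' optional mask. This is the null model of the permutation enrichment
#' test: chromosome identity is kept to respect sequence-composition
#' structure.
#'
#' @param query region data.frame.
#' @param genome `genome_spec` or named contig-length vector.
#' @param mask optional region data.frame of excluded intervals.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return region data.frame of the same shape with new coordinates.
#' @export
permute_regions <- function(query, genome, mask = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- contig_lengths(genome)
  out <- query
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    if (!chr %in% names(lens)) stop("contig '", chr, "' not in genome")
    mk <- if (!is.null(mask)) mask[mask$chrom == chr, , drop = FALSE]
    w <- query$end[qi] - query$start[qi]
    s <- random_starts(w, lens[[chr]], mk)
    out$start[qi] <- s
    out$end[qi] <- s + w
  }
  out
}

#' Permutation z-score for overlap enrichment
#'
#' Counts how many query regions overlap the feature set, then re-places
#' the query uniformly at random `n_perm` times and standardizes the
#' observed count against the permutation distribution:
#' z = (observed - mean) / sd. A z of +25 means the observed overlap count
#' is 25 standard deviations above chance. The empirical p-value uses the
#' add-one rule, (1 + #\{perm >= observed\}) / (n_perm + 1) for
#' enrichment; the two-sided variant doubles the smaller tail, capped
#' at 1.
#'
#' @param query,feature region data.frames.
#' @param genome `genome_spec` or named contig-length vector.
#' @param n_perm number of permutations (default 200; at least 20).
#' @param seed optional integer seed.
#' @param mask optional excluded intervals.
#' @param alternative `"greater"` (enrichment) or `"two.sided"`.
#' @return list of class `enrichment_result`: `observed`, `perm_mean`,
#'   `perm_sd`, `z` (`NA` and `degenerate = TRUE` when the permutation sd
#'   is 0), `p_empirical`, `n_perm`.
#' @export
enrichment_z <- function(query, feature, genome, n_perm = 200, seed = NULL,
                         mask = NULL, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 20) stop("n_perm must be at least 20")
  if (!is.null(seed)) set.seed(seed)
  observed <- overlap_count(query, feature)
  perm <- vapply(seq_len(n_perm), function(i) {
    overlap_count(permute_regions(query, genome, mask = mask), feature)
  }, numeric(1))
  perm_mean <- mean(perm)
  perm_sd <- stats::sd(perm)
  degenerate <- perm_sd == 0
  z <- if (degenerate) NA_real_ else (observed - perm_mean) / perm_sd
  p_up <- (1 + sum(perm >= observed)) / (n_perm + 1)
  p_dn <- (1 + sum(perm <= observed)) / (n_perm + 1)
  p <- if (alternative == "greater") p_up else min(1, 2 * min(p_up, p_dn))
  structure(list(observed = observed, perm_mean = perm_mean,
                 perm_sd = perm_sd, z = z, p_empirical = p,
                 degenerate = degenerate, n_perm = n_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Permutation overlap enrichment (", x$n_perm, " permutations)\n",
      "  observed ", x$observed, ", null ", round(x$perm_mean, 2), " +/- ",
      round(x$perm_sd, 2), "\n  z = ", round(x$z, 2),
      ", empirical p = ", signif(x$p_empirical, 3), "\n", sep = "")
  invisible(x)
}

#' Enrichment of a query set across multiple feature tracks
#'
#' One permutation set is shared across tracks: each permuted query is
#' scored against every feature track, and per-track empirical p-values
#' are adjusted by Benjamini-Hochberg.
#'
#' @param query region data.frame.
#' @param features named list of feature region data.frames.
#' @param genome `genome_spec` or named contig-length vector.
#' @param n_perm permutations (default 200).
#' @param seed optional integer seed.
#' @param mask optional excluded intervals.
#' @return data.frame with one row per track: `feature`, `observed`,
#'   `perm_mean`, `perm_sd`, `z`, `p_empirical`, `fdr`.
#' @export
multi_feature_enrichment <- function(query, features, genome, n_perm = 200,
                                     seed = NULL, mask = NULL) {
  if (length(features) == 0L) stop("need at least one feature track")
  if (is.null(names(features)))
    names(features) <- sprintf("feature_%d", seq_along(features))
  if (n_perm < 20) stop("n_perm must be at least 20")
  if (!is.null(seed)) set.seed(seed)
  observed <- vapply(features, overlap_count, numeric(1), query = query)
  perm <- matrix(NA_real_, n_perm, length(features))
  for (i in seq_len(n_perm)) {
    pq <- permute_regions(query, genome, mask = mask)
    perm[i, ] <- vapply(features, overlap_count, numeric(1), query = pq)
  }
  perm_mean <- colMeans(perm)
  perm_sd <- apply(perm, 2, stats::sd)
  z <- ifelse(perm_sd > 0, (observed - perm_mean) / perm_sd, NA_real_)
  p <- vapply(seq_along(features), function(j) {
    (1 + sum(perm[, j] >= observed[j])) / (n_perm + 1)
  }, numeric(1))
  data.frame(feature = names(features), observed = unname(observed),
             perm_mean = perm_mean, perm_sd = perm_sd, z = z,
             p_empirical = p, fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
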