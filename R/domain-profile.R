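# Split [start, end) into n integer bins; when the length is not divisible
# by n, the first (length %% n) bins absorb one extra bp each.
bin_edges <- function(start, end, n) {
  L <- end - start
  if (L < n) stop("region of length ", L, " cannot hold ", n, " bins")
  w <- L %/% n
  widths <- rep.int(w, n)
  r <- L %% n
  if (r > 0) widths[seq_len(r)] <- widths[seq_len(r)] + 1L
  start + cumsum(c(0L, widths))
}

#' Binned methylation profiles over domains with flanks
#'
#' For each domain, the domain body plus equal-length upstream and
#' downstream flanks are each divided into `n_bins` equal-length bins
#' (3 x 30 = 90 bins by default), and the coverage-weighted methylation
#' level of the requested context is computed per bin with non-conversion
#' subtraction. Domains whose flanks do not fit within the contig are
#' skipped with a warning. This is the metaplot layout used to profile
#' mCA/CA across megabase-scale non-CpG methylation domains.
#'
#' @param table methylome data.frame.
#' @param domains region data.frame.
#' @param n_bins bins per block (default 30).
#' @param context methylation context (default `"CA"`).
#' @param genome `genome_spec` or named contig-length vector; defaults to
#'   the maximum observed position per contig.
#' @param nonconversion optional rate override.
#' @return matrix (domains x 3*n_bins) of levels with `NA` for empty bins;
#'   columns are `u1..u30, b1..b30, d1..d30`; attribute
#'   `"normalized" = FALSE`.
#' @export
binned_profile <- function(table, domains, n_bins = 30, context = "CA",
                           genome = NULL, nonconversion = NULL) {
  sel <- context_rows(table, context)
  if (!any(sel)) stop("no sites of context ", context, " in table")
  lens <- if (is.null(genome)) {
    tapply(table$pos, table$chrom, max)
  } else contig_lengths(genome)
  keep <- logical(nrow(domains))
  bins <- NULL
  for (i in seq_len(nrow(domains))) {
    s <- domains$start[i]; e <- domains$end[i]
    L <- e - s
    if (L < n_bins) {
      warning("domain ", domains$id[i], " shorter than n_bins; skipped")
      next
    }
    if (s - L < 0 || e + L > lens[[domains$chrom[i]]]) {
      warning("flanks of domain ", domains$id[i],
              " extend beyond contig; skipped")
      next
    }
    keep[i] <- TRUE
    edges <- c(bin_edges(s - L, s, n_bins)[-(n_bins + 1)],
               bin_edges(s, e, n_bins)[-(n_bins + 1)],
               bin_edges(e, e + L, n_bins))
    bins <- rbind(bins, data.frame(
      chrom = domains$chrom[i],
      start = edges[-(3 * n_bins + 1)],
      end = edges[-1],
      id = sprintf("%s.%d", domains$id[i], seq_len(3 * n_bins)),
      stringsAsFactors = FALSE))
  }
  if (is.null(bins)) stop("no domain admitted a binned profile")
  level <- weighted_methylation(table, bins, context = context,
                                nonconversion = nonconversion)
  prof <- matrix(unname(level), ncol = 3 * n_bins, byrow = TRUE,
                 dimnames = list(domains$id[keep],
                                 c(sprintf("u%d", seq_len(n_bins)),
                                   sprintf("b%d", seq_len(n_bins)),
                                   sprintf("d%d", seq_len(n_bins)))))
  attr(prof, "normalized") <- FALSE
  prof
}

#' Flank-normalize binned profiles
#'
#' Divides every bin of a region by the maximum value over all of that
#' region's bins (body and flanks), so the per-region maximum becomes 1.
#' Normalization is idempotent.
#'
#' @param profile matrix from [binned_profile()] (or a single numeric
#'   vector of bins).
#' @return matrix (or vector) of the same shape, attribute
#'   `"normalized" = TRUE`.
#' @export
flank_normalize <- function(profile) {
  vec <- is.null(dim(profile))
  m <- if (vec) matrix(profile, nrow = 1) else profile
  mx <- apply(m, 1, function(x) suppressWarnings(max(x, na.rm = TRUE)))
  bad <- !is.finite(mx) | mx <= 0
  if (any(bad))
    stop("cannot normalize region(s) with no positive bin: ",
         paste(if (!is.null(rownames(m))) rownames(m)[bad]
               else which(bad), collapse = ", "))
  out <- m / mx
  if (vec) return(as.numeric(out))
  dimnames(out) <- dimnames(m)
  attr(out, "normalized") <- TRUE
  out
}

#' Aggregate binned profiles across regions
#'
#' Per-bin mean over regions, with undefined bins excluded pairwise.
#'
#' @param profiles matrix from [binned_profile()] / [flank_normalize()].
#' @return list with `mean` (numeric per bin) and `n` (regions
#'   contributing per bin).
#' @export
aggregate_profiles <- function(profiles) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  if (nrow(profiles) == 0L) stop("need at least one profile")
  list(mean = colMeans(profiles, na.rm = TRUE),
       n = colSums(!is.na(profiles)))
}

#' Per-domain CG methylation summary
#'
#' Coverage-weighted mCG/CG per domain; used e.g. to reveal the partial CG
#' methylation of partially methylated domains inside non-CpG methylation
#' domains.
#'
#' @param table methylome data.frame (CG strand-collapsed).
#' @param domains region data.frame.
#' @return named numeric vector of mCG/CG levels (`NA` where no CG site is
#'   covered).
#' @export
domain_cg_summary <- function(table, domains) {
  weighted_methylation(table, domains, context = "CG")
}
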