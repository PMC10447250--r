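#' DMR classification vocabulary
#'
#' The seven labels tiling the (delta vs hES, delta vs fibroblast) plane.
#' @return character vector of labels.
#' @export
dmr_classes <- function() {
  c("memory", "partial_memory", "aberrant_hypo",
    "aberrant_hyper", "memory_hyper", "partial_hyper", "below_threshold")
}

#' Filter candidate DMRs by effect size and significance
#'
#' Keeps regions with an absolute methylation difference strictly greater
#' than `min_abs_diff` and a p-value strictly below `max_p` (the upstream
#' region-detection statistics are consumed, not computed, here).
#'
#' @param dmrs data.frame with at least columns `diff` (mCG/CG difference)
#'   and `p`.
#' @param min_abs_diff methylation-difference cut-off (default 0.2).
#' @param max_p p-value cut-off (default 0.05).
#' @return the retained rows; attribute `"dropped"` holds the counts of
#'   regions failing each filter.
#' @export
filter_candidate_dmrs <- function(dmrs, min_abs_diff = 0.2, max_p = 0.05) {
  if (!all(c("diff", "p") %in% names(dmrs)))
    stop("dmrs must carry 'diff' and 'p' columns")
  pass_diff <- abs(dmrs$diff) > min_abs_diff
  pass_p <- dmrs$p < max_p
  keep <- pass_diff & pass_p
  out <- dmrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(diff = sum(!pass_diff),
                            p = sum(!pass_p),
                            total = sum(!keep))
  out
}

#' Classify a DMR into memory/aberrant categories
#'
#' Classification uses two methylation differences of the hiPS line under
#' test: `delta_es` (hiPS minus hES) and `delta_fib` (hiPS minus
#' fibroblast), with a symmetric cut-off `threshold` (default 0.2).
#' Hypo-methylated DMRs (`delta_es < -t`) retaining the fibroblast state
#' (`|delta_fib| <= t`) are somatic-cell \emph{memory}; those above the
#' fibroblast level are \emph{partial_memory}; those below both references
#' are \emph{aberrant_hypo}. Hyper-methylated DMRs (`delta_es > t`) above
#' both references are \emph{aberrant_hyper}; at the fibroblast level,
#' \emph{memory_hyper}; below the fibroblast, \emph{partial_hyper}.
#' `|delta_es| <= t` is \emph{below_threshold}. Exact equality with the
#' threshold always falls on the no-difference side.
#'
#' @param delta_es,delta_fib numeric vectors of methylation differences.
#' @param threshold classification cut-off in mCG/CG units.
#' @return character vector of labels (see [dmr_classes()]).
#' @export
classify_dmr <- function(delta_es, delta_fib, threshold = 0.2) {
  if (length(delta_es) != length(delta_fib))
    stop("delta vectors must have equal length")
  if (anyNA(delta_es) || anyNA(delta_fib))
    stop("deltas must be defined (no NA) for classification")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  t <- threshold
  out <- rep(NA_character_, length(delta_es))
  below <- abs(delta_es) <= t
  hypo <- delta_es < -t
  hyper <- delta_es > t
  out[below] <- "below_threshold"
  out[hypo & abs(delta_fib) <= t] <- "memory"
  out[hypo & delta_fib > t] <- "partial_memory"
  out[hypo & delta_fib < -t] <- "aberrant_hypo"
  out[hyper & delta_fib > t] <- "aberrant_hyper"
  out[hyper & abs(delta_fib) <= t] <- "memory_hyper"
  out[hyper & delta_fib < -t] <- "partial_hyper"
  out
}

#' Classify a set of DMRs and summarize class composition
#'
#' @param levels data.frame of per-group mCG/CG levels (one row per DMR,
#'   one column per group). Rows with an undefined level in any of the
#'   three groups used are excluded and counted.
#' @param test_group hiPS group under test (column name).
#' @param es_group,fib_group reference columns (default `"hES"`,
#'   `"fibroblast"`).
#' @param threshold classification cut-off.
#' @return list with `labels` (per evaluable DMR), `counts`, `fractions`
#'   (over evaluable DMRs, summing to 1), `hypo_fraction`,
#'   `hyper_fraction`, `n_evaluable` and `n_excluded`.
#' @export
classify_dmr_set <- function(levels, test_group, es_group = "hES",
                             fib_group = "fibroblast", threshold = 0.2) {
  for (g in c(test_group, es_group, fib_group))
    if (!g %in% names(levels)) stop("group '", g, "' missing from levels")
  de <- levels[[test_group]] - levels[[es_group]]
  dfib <- levels[[test_group]] - levels[[fib_group]]
  ok <- !is.na(de) & !is.na(dfib)
  labels <- rep(NA_character_, nrow(levels))
  labels[ok] <- classify_dmr(de[ok], dfib[ok], threshold)
  counts <- c(table(factor(labels[ok], levels = dmr_classes())))
  list(labels = labels,
       counts = counts,
       fractions = counts / max(sum(ok), 1L),
       hypo_fraction = mean(de[ok] < -threshold),
       hyper_fraction = mean(de[ok] > threshold),
       n_evaluable = sum(ok),
       n_excluded = sum(!ok))
}

#' Score epigenetic correction of DMRs
#'
#' A DMR is corrected in a test group when its methylation level differs
#' from the reference (hES) level by strictly less than `threshold`. DMRs
#' with an undefined level in either group are excluded and counted.
#'
#' @param levels data.frame of per-group mCG/CG levels.
#' @param test_group group under test (e.g. a TNT- or NTP-reprogrammed
#'   line).
#' @param reference_group reference column (default `"hES"`).
#' @param threshold correction cut-off (default 0.2).
#' @return list with `corrected` (logical per DMR, NA where not
#'   evaluable), `fraction`, `n_evaluable`, `n_excluded`.
#' @export
assess_correction <- function(levels, test_group, reference_group = "hES",
                              threshold = 0.2) {
  for (g in c(test_group, reference_group))
    if (!g %in% names(levels)) stop("group '", g, "' missing from levels")
  d <- abs(levels[[test_group]] - levels[[reference_group]])
  corrected <- d < threshold
  n_eval <- sum(!is.na(corrected))
  if (n_eval == 0L) stop("no evaluable DMRs for correction scoring")
  list(corrected = corrected,
       fraction = sum(corrected, na.rm = TRUE) / n_eval,
       n_evaluable = n_eval,
       n_excluded = sum(is.na(corrected)))
}

#' Mean methylation change at DMRs along a time course
#'
#' For each sample, the mean over DMRs of (level in sample minus level at
#' the baseline day), with DMRs undefined in either sample excluded
#' pairwise. This traces when memory loss or aberrant gain emerges during
#' reprogramming.
#'
#' @param dmrs region data.frame.
#' @param samples named list of methylome data.frames; names are the
#'   time-point labels.
#' @param baseline name of the baseline sample (default the first).
#' @param context methylation context (default `"CG"`).
#' @return named numeric vector of mean deltas, one per sample (`NA` with
#'   a warning when no DMR is evaluable).
#' @export
timecourse_delta <- function(dmrs, samples, baseline = names(samples)[1],
                             context = "CG") {
  if (!baseline %in% names(samples))
    stop("baseline sample '", baseline, "' not present")
  lv <- vapply(samples, weighted_methylation, numeric(nrow(dmrs)),
               regions = dmrs, context = context)
  lv <- matrix(lv, nrow = nrow(dmrs),
               dimnames = list(dmrs$id, names(samples)))
  base <- lv[, baseline]
  out <- vapply(colnames(lv), function(s) {
    d <- lv[, s] - base
    if (all(is.na(d))) {
      warning("no evaluable DMR for sample ", s)
      return(NA_real_)
    }
    mean(d, na.rm = TRUE)
  }, numeric(1))
  out
}

#' Screen methylation at imprint control regions
#'
#' Imprint control regions (ICRs) carry parent-of-origin methylation on
#' one allele and are expected near mCG/CG = 0.5; deviation beyond
#' `margin` flags candidate imprint erosion (e.g. after extended naive
#' culture).
#'
#' @param table methylome data.frame (CG strand-collapsed).
#' @param icrs region data.frame of ICR intervals.
#' @param margin flag threshold on `|level - 0.5|` (default 0.15).
#' @return list with `per_icr` (data.frame id/level/flagged), `median`,
#'   `iqr`, `n_flagged`.
#' @export
icr_screen <- function(table, icrs, margin = 0.15) {
  level <- weighted_methylation(table, icrs, context = "CG")
  flagged <- !is.na(level) & abs(level - 0.5) > margin
  list(per_icr = data.frame(id = icrs$id, level = unname(level),
                            flagged = unname(flagged),
                            stringsAsFactors = FALSE),
       median = stats::median(level, na.rm = TRUE),
       iqr = stats::IQR(level, na.rm = TRUE),
       n_flagged = sum(flagged))
}
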