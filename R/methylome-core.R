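# Row subset of a methylome table matching a methylation context.
# "CG" selects the CpG context, "CH" all non-CpG contexts, and "CA"/"CT"/
# "CC" the individual non-CpG dinucleotides.
context_rows <- function(table, context) {
  switch(context,
         CG = table$context == "CG",
         CH = table$context != "CG",
         CA = table$dinuc == "CA",
         CT = table$dinuc == "CT",
         CC = table$dinuc == "CC",
         stop("unknown context: ", context))
}

# Non-conversion rate to subtract for a context: explicit argument wins,
# then the table's "nonconversion" attribute, then 0. CG levels are never
# corrected (non-conversion inflates only the near-zero CH signal).
resolve_nonconversion <- function(table, context, nonconversion) {
  if (context == "CG") return(0)
  if (!is.null(nonconversion)) return(nonconversion)
  nc <- attr(table, "nonconversion")
  if (!is.null(nc) && context %in% names(nc)) return(unname(nc[context]))
  0
}

#' Collapse stranded CG calls onto symmetric CpG dinucleotides
#'
#' A CpG is palindromic: the plus-strand C at position p and the
#' minus-strand C at position p+1 interrogate the same dinucleotide. Their
#' counts are summed into a single record at the plus-strand position.
#' Unpaired CG sites are kept as-is and non-CG contexts pass through
#' unchanged, so total mc and cov are conserved.
#'
#' @param table methylome data.frame.
#' @return methylome data.frame with collapsed CG records (strand `"+"`).
#' @export
collapse_cg_strands <- function(table) {
  is_cg <- table$context == "CG"
  cg <- table[is_cg, , drop = FALSE]
  rest <- table[!is_cg, , drop = FALSE]
  plus <- cg[cg$strand != "-", , drop = FALSE]
  minus <- cg[cg$strand == "-", , drop = FALSE]
  key_plus <- paste(plus$chrom, plus$pos)
  key_minus <- paste(minus$chrom, minus$pos - 1L)
  m <- match(key_minus, key_plus)
  paired <- !is.na(m)
  if (any(paired)) {
    plus$mc[m[paired]] <- plus$mc[m[paired]] + minus$mc[paired]
    plus$cov[m[paired]] <- plus$cov[m[paired]] + minus$cov[paired]
  }
  out <- rbind(plus, minus[!paired, , drop = FALSE], rest)
  out$strand[out$context == "CG" & out$strand != "-"] <- "+"
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("sample_id", "nonconversion"))
    attr(out, a) <- attr(table, a)
  out
}

# Per-region sums of a numeric site value, via cumulative sums over sites
# sorted by position. A 1-based site pos lies in the 0-based half-open
# region [start, end) iff start < pos <= end.
region_sums <- function(chrom, pos, value, reg) {
  out <- numeric(nrow(reg))
  for (chr in unique(reg$chrom)) {
    ri <- which(reg$chrom == chr)
    si <- which(chrom == chr)
    if (!length(si)) next
    p <- pos[si]; v <- value[si]
    o <- order(p)
    p <- p[o]
    cs <- cumsum(as.numeric(v[o]))
    hi <- findInterval(reg$end[ri], p)
    lo <- findInterval(reg$start[ri], p)
    out[ri] <- ifelse(hi > 0, cs[pmax(hi, 1L)], 0) -
               ifelse(lo > 0, cs[pmax(lo, 1L)], 0)
  }
  out
}

#' Coverage-weighted regional methylation levels
#'
#' For each region, sums methylated calls and total calls over all
#' in-region sites of the requested context and returns mc_total /
#' cov_total — the coverage-weighted mean methylation level. Regions with
#' no covered site of the context return `NA` (undefined), which is
#' distinct from 0. For non-CG contexts the context-specific non-conversion
#' rate is subtracted and the result floored at 0.
#'
#' @param table methylome data.frame. For CG the table should be
#'   strand-collapsed (see [collapse_cg_strands()]); a warning is issued
#'   otherwise.
#' @param regions region data.frame (0-based half-open).
#' @param context one of `"CG"`, `"CA"`, `"CH"`, `"CT"`, `"CC"`.
#' @param nonconversion optional rate overriding the table's
#'   `"nonconversion"` attribute.
#' @return named numeric vector of levels in \[0, 1\] (or `NA`), one per
#'   region, named by region id.
#' @export
weighted_methylation <- function(table, regions, context = "CG",
                                 nonconversion = NULL) {
  sel <- context_rows(table, context)
  if (!any(sel)) stop("no sites of context ", context, " in table")
  if (context == "CG" && any(table$strand[sel] == "-"))
    warning("CG table contains minus-strand calls; collapse_cg_strands() first")
  sub <- table[sel, , drop = FALSE]
  mc <- region_sums(sub$chrom, sub$pos, sub$mc, regions)
  cov <- region_sums(sub$chrom, sub$pos, sub$cov, regions)
  level <- ifelse(cov > 0, mc / cov, NA_real_)
  nc <- resolve_nonconversion(table, context, nonconversion)
  if (nc > 0) level <- pmax(level - nc, 0)
  names(level) <- if (!is.null(regions$id)) regions$id else NULL
  level
}

#' Bisulfite non-conversion rate from the unmethylated spike-in
#'
#' The apparent methylation of a fully unmethylated spike-in contig (e.g.
#' lambda phage DNA) measures incomplete bisulfite conversion. Computed as
#' the coverage-weighted mean over spike-in sites of the given context.
#'
#' @param table methylome data.frame.
#' @param spike_in_contig contig name of the unmethylated control.
#' @param context context whose rate is estimated (`"CG"`, `"CA"`, `"CH"`,
#'   `"CT"`, `"CC"`).
#' @return rate in \[0, 1\].
#' @export
nonconversion_rate <- function(table, spike_in_contig, context = "CH") {
  sel <- context_rows(table, context) & table$chrom == spike_in_contig
  if (!any(sel))
    stop("no covered ", context, " sites on spike-in contig '",
         spike_in_contig, "'")
  sum(table$mc[sel]) / sum(table$cov[sel])
}

#' Sliding-window methylation track
#'
#' Tiles each contig with fixed-width windows from position 0 and reports
#' the coverage-weighted methylation level per window, with the
#' context-specific non-conversion rate subtracted and floored at 0. Only
#' windows fully contained in the contig are emitted, and windows without
#' any covered site are dropped. The defaults (5-kb windows, 1-kb slide,
#' CA context) produce the browser-style mCA/CA track used to visualize
#' non-CpG methylation domains.
#'
#' @param table methylome data.frame.
#' @param context methylation context (default `"CA"`).
#' @param window_bp window width in bp.
#' @param step_bp slide in bp.
#' @param genome `genome_spec` or named contig-length vector; defaults to
#'   the maximum observed position per contig.
#' @param nonconversion optional rate override.
#' @return bedGraph-style data.frame (chrom, start, end, level).
#' @export
sliding_window_track <- function(table, context = "CA", window_bp = 5000,
                                 step_bp = 1000, genome = NULL,
                                 nonconversion = NULL) {
  sel <- context_rows(table, context)
  if (!any(sel)) stop("no sites of context ", context, " in table")
  lens <- if (is.null(genome)) {
    tapply(table$pos[sel], table$chrom[sel], max)
  } else contig_lengths(genome)
  win <- do.call(rbind, lapply(names(lens), function(chr) {
    L <- lens[[chr]]
    if (L < window_bp) return(NULL)
    starts <- seq(0L, as.integer(L) - window_bp, by = step_bp)
    data.frame(chrom = chr, start = starts, end = starts + window_bp,
               stringsAsFactors = FALSE)
  }))
  if (is.null(win)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer(), level = numeric()))
  win$id <- sprintf("w%d", seq_len(nrow(win)))
  level <- weighted_methylation(table, win, context = context,
                                nonconversion = nonconversion)
  out <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                    level = unname(level), stringsAsFactors = FALSE)
  out[!is.na(out$level), , drop = FALSE]
}

#' Classify per-read methylation (epiallele) states
#'
#' Each read is assigned exactly one class from its ordered CG calls:
#' \emph{methylated} reads carry a methylation call at every CG position,
#' \emph{unmethylated} reads carry none, and \emph{partially methylated}
#' reads carry at least one methylated and one unmethylated CG call. A
#' single-call read can only be methylated or unmethylated. At a genomic
#' imprint with intact parent-of-origin methylation the methylated and
#' unmethylated classes are expected near 50/50.
#'
#' @param records data.frame with columns `read_id`, `region_id` and a
#'   list-column `calls` of 0/1 vectors (one call per CG position covered
#'   by the read).
#' @return data.frame with one row per region: counts of `methylated`,
#'   `unmethylated`, `partial` reads and total `n`.
#' @export
classify_reads <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(region_id = character(), methylated = integer(),
                      unmethylated = integer(), partial = integer(),
                      n = integer()))
  len <- lengths(records$calls)
  if (any(len == 0L)) stop("read with empty call list: ",
                           records$read_id[which(len == 0L)[1]])
  n1 <- vapply(records$calls, function(x) sum(x > 0), integer(1))
  cls <- ifelse(n1 == len, "methylated",
                ifelse(n1 == 0L, "unmethylated", "partial"))
  tab <- table(factor(records$region_id),
               factor(cls, levels = c("methylated", "unmethylated", "partial")))
  out <- data.frame(region_id = rownames(tab),
                    methylated = as.integer(tab[, "methylated"]),
                    unmethylated = as.integer(tab[, "unmethylated"]),
                    partial = as.integer(tab[, "partial"]),
                    stringsAsFactors = FALSE)
  out$n <- out$methylated + out$unmethylated + out$partial
  rownames(out) <- NULL
  out
}
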