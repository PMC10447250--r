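#' Read per-cytosine methylation calls
#'
#' Parses base-resolution methylation call tables into the internal
#' methylome table: one row per cytosine with columns `chrom`, `pos`
#' (1-based), `strand`, `context` (CG/CHG/CHH), `dinuc` (CG/CA/CT/CC),
#' `mc` (methylated calls) and `cov` (total C-or-T calls).
#'
#' Two dialects are supported:
#' \describe{
#'   \item{cgmap}{8 columns: chrom, nucleotide (C on plus strand, G on
#'     minus), 1-based position, context, dinucleotide, level, mc, cov.}
#'   \item{bedgraph_counts}{bedGraph with counts: chrom, start, end
#'     (0-based half-open single-base interval), level, mc, cov; strand
#'     and context are not encoded, so calls are taken as unstranded CG.}
#' }
#'
#' Rows with zero or missing coverage are counted, dropped and reported via
#' the `"n_malformed"` attribute. A row with `mc > cov` is a hard error
#' naming the line.
#'
#' @param path input TSV file.
#' @param dialect `"cgmap"` or `"bedgraph_counts"`.
#' @param sample_id optional sample label attached as an attribute.
#' @return methylome data.frame sorted by (chrom, pos).
#' @export
read_cytosine_calls <- function(path, dialect = c("cgmap", "bedgraph_counts"),
                                sample_id = NULL) {
  dialect <- match.arg(dialect)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (dialect == "cgmap") {
    if (ncol(raw) < 8) stop("CGmap dialect requires 8 columns")
    tab <- data.frame(chrom = as.character(raw[[1]]),
                      pos = as.integer(raw[[3]]),
                      strand = ifelse(raw[[2]] == "C", "+", "-"),
                      context = as.character(raw[[4]]),
                      dinuc = as.character(raw[[5]]),
                      mc = as.integer(raw[[7]]),
                      cov = as.integer(raw[[8]]),
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(raw) < 6) stop("bedgraph_counts dialect requires 6 columns")
    tab <- data.frame(chrom = as.character(raw[[1]]),
                      pos = as.integer(raw[[2]]) + 1L,
                      strand = "*",
                      context = "CG",
                      dinuc = "CG",
                      mc = as.integer(raw[[5]]),
                      cov = as.integer(raw[[6]]),
                      stringsAsFactors = FALSE)
  }
  bad <- which(!is.na(tab$mc) & !is.na(tab$cov) & tab$mc > tab$cov)
  if (length(bad))
    stop("mc > cov at line ", bad[1], " of ", path)
  malformed <- is.na(tab$mc) | is.na(tab$cov) | is.na(tab$pos) | tab$cov <= 0L
  n_malformed <- sum(malformed)
  if (n_malformed)
    warning(n_malformed, " malformed row(s) dropped from ", path)
  tab <- tab[!malformed, , drop = FALSE]
  tab <- tab[order(tab$chrom, tab$pos, tab$strand), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_malformed") <- n_malformed
  if (!is.null(sample_id)) attr(tab, "sample_id") <- sample_id
  tab
}

#' Write per-cytosine methylation calls
#'
#' Inverse of [read_cytosine_calls()]; round-trips a methylome table.
#'
#' @param table methylome data.frame.
#' @param path output path.
#' @param dialect output dialect (see [read_cytosine_calls()]).
#' @export
write_cytosine_calls <- function(table, path,
                                 dialect = c("cgmap", "bedgraph_counts")) {
  dialect <- match.arg(dialect)
  level <- ifelse(table$cov > 0, table$mc / table$cov, NA_real_)
  if (dialect == "cgmap") {
    out <- data.frame(table$chrom,
                      ifelse(table$strand == "-", "G", "C"),
                      table$pos, table$context, table$dinuc,
                      round(level, 6), table$mc, table$cov)
  } else {
    out <- data.frame(table$chrom, table$pos - 1L, table$pos,
                      round(level, 6), table$mc, table$cov)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
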