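#' Genome specification
#'
#' Describes the contigs of a (synthetic or real) genome together with the
#' fully unmethylated spike-in contig used to estimate the bisulfite
#' non-conversion rate.
#'
#' @param contigs named numeric vector of contig lengths in bp.
#' @param spike_in name of the unmethylated control contig (must be one of
#'   `names(contigs)`). A lambda-phage spike-in plays this role in real
#'   WGBS libraries.
#' @return An object of class `genome_spec` with elements `contigs` and
#'   `spike_in`.
#' @examples
#' genome_spec(c(chr1 = 1e6, lambda = 48502), spike_in = "lambda")
#' @export
genome_spec <- function(contigs, spike_in) {
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must be a uniquely named vector of lengths")
  if (any(contigs <= 0)) stop("contig lengths must be > 0")
  if (!spike_in %in% names(contigs))
    stop("spike-in contig '", spike_in, "' not among contigs")
  structure(list(contigs = contigs, spike_in = spike_in),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Genome:", length(x$contigs), "contigs,",
      format(sum(x$contigs), big.mark = ","), "bp; spike-in:", x$spike_in, "\n")
  invisible(x)
}

# Named vector of contig lengths from a genome_spec or a named vector.
contig_lengths <- function(genome) {
  if (inherits(genome, "genome_spec")) return(genome$contigs)
  if (is.numeric(genome) && !is.null(names(genome))) return(genome)
  stop("genome must be a genome_spec or a named numeric vector of lengths")
}

#' Construct a region table
#'
#' Regions use BED semantics throughout: 0-based, half-open `[start, end)`.
#'
#' @param chrom,start,end interval coordinates.
#' @param id optional unique identifiers (defaults to `region_1 ...`).
#' @param score,strand optional BED6 columns.
#' @return data.frame with columns chrom/start/end/id (+ score, strand).
#' @export
regions <- function(chrom, start, end, id = NULL, score = NULL, strand = NULL) {
  if (any(start >= end)) stop("regions require start < end")
  if (is.null(id)) id <- sprintf("region_%d", seq_along(chrom))
  if (anyDuplicated(id)) stop("region ids must be unique")
  out <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                    end = as.integer(end), id = as.character(id),
                    stringsAsFactors = FALSE)
  if (!is.null(score)) out$score <- score
  if (!is.null(strand)) out$strand <- strand
  out
}

#' Read a BED file into a region table
#'
#' @param path BED3/BED6 file.
#' @return region data.frame (0-based half-open coordinates).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  as_regions(gr)
}

#' Write a region table to BED
#'
#' @param x region data.frame.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(as_granges(x), path, format = "BED")
  invisible(path)
}

#' Convert a region table to GRanges
#' @param x region data.frame with 0-based half-open coordinates.
#' @return a `GRanges` object.
#' @export
as_granges <- function(x) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if (!is.null(x$strand)) x$strand else "*")
  if (!is.null(x$id)) names(gr) <- x$id
  if (!is.null(x$score)) gr$score <- x$score
  gr
}

#' Convert GRanges to a region table
#' @param gr a `GRanges` object.
#' @return region data.frame with 0-based half-open coordinates.
#' @export
as_regions <- function(gr) {
  id <- if (!is.null(gr$name)) as.character(gr$name)
        else if (!is.null(names(gr))) names(gr)
        else sprintf("region_%d", seq_along(gr))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    id = id, stringsAsFactors = FALSE)
  if (!is.null(gr$score)) out$score <- gr$score
  out
}

# Logical vector: does each query interval overlap >= 1 bp of any feature?
# Sorted scan: a feature overlaps (qs, qe) iff f.start < qe and f.end > qs.
# Among features with start < qe, it suffices that the running maximum of
# ends exceeds qs.
overlaps_any <- function(query, feature) {
  hit <- logical(nrow(query))
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    fi <- feature$chrom == chr
    if (!any(fi)) next
    fs <- feature$start[fi]; fe <- feature$end[fi]
    o <- order(fs)
    fs <- fs[o]; fe <- cummax(fe[o])
    idx <- findInterval(query$end[qi] - 0.5, fs)
    hit[qi] <- idx >= 1L & fe[pmax(idx, 1L)] > query$start[qi]
  }
  hit
}

#' Count query regions overlapping a feature set
#'
#' Counts how many query intervals overlap at least 1 bp of any feature
#' interval; each query region is counted at most once. This is the overlap
#' unit used by the permutation enrichment test.
#'
#' @param query,feature region data.frames.
#' @return integer count.
#' @export
overlap_count <- function(query, feature) {
  if (nrow(query) == 0L || nrow(feature) == 0L) return(0L)
  sum(overlaps_any(query, feature))
}
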