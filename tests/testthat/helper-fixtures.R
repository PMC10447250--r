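# Shared fixture builders for the test suite.

# Minimal methylome table from parallel vectors.
make_methylome <- function(chrom, pos, strand = "+", context = "CG",
                           dinuc = "CG", mc, cov, nonconversion = NULL) {
  tab <- data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
                    context = context, dinuc = dinuc, mc = as.integer(mc),
                    cov = as.integer(cov), stringsAsFactors = FALSE)
  tab <- tab[order(tab$chrom, tab$pos, tab$strand), ]
  rownames(tab) <- NULL
  if (!is.null(nonconversion)) attr(tab, "nonconversion") <- nonconversion
  tab
}

# Random small methylome on one contig (collapsed CG sites).
random_methylome <- function(n_sites = 50, contig = "chr1", max_pos = 1e4) {
  pos <- sort(sample.int(max_pos, n_sites))
  cov <- rpois(n_sites, 10) + 1L
  make_methylome(contig, pos, mc = rbinom(n_sites, cov, runif(1)), cov = cov)
}

# Random region set on one contig.
random_regions <- function(n = 10, contig = "chr1", max_pos = 1e4,
                           max_width = 500) {
  s <- sample.int(max_pos - max_width, n)
  regions(contig, s, s + sample.int(max_width, n, replace = TRUE),
          id = sprintf("r%d", seq_len(n)))
}

# Naive per-site oracle for region-level weighted methylation.
oracle_region_level <- function(table, reg) {
  vapply(seq_len(nrow(reg)), function(i) {
    sel <- table$chrom == reg$chrom[i] &
      table$pos > reg$start[i] & table$pos <= reg$end[i]
    if (!any(sel)) return(NA_real_)
    sum(table$mc[sel]) / sum(table$cov[sel])
  }, numeric(1))
}

# O(n*m) brute-force overlap-count oracle.
oracle_overlap_count <- function(query, feature) {
  sum(vapply(seq_len(nrow(query)), function(i) {
    any(feature$chrom == query$chrom[i] &
          feature$start < query$end[i] &
          feature$end > query$start[i])
  }, logical(1)))
}

# O(n^2) brute-force single-linkage clustering oracle: returns the number
# of clusters and per-cluster (start, end, size) for 1D positions.
oracle_single_linkage <- function(chrom, pos, d = 50) {
  lab <- seq_along(pos)
  repeat {
    changed <- FALSE
    for (i in seq_along(pos)) for (j in seq_along(pos)) {
      if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= d &&
          lab[i] != lab[j]) {
        lab[lab == lab[j]] <- lab[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cl <- split(pos, lab)
  out <- data.frame(start = vapply(cl, min, numeric(1)),
                    end = vapply(cl, max, numeric(1)),
                    coverage = lengths(cl))
  out[order(out$start), ]
}

# Small default genome used across tests.
test_genome <- function(chr1 = 3e5, chr2 = 2e5) {
  genome_spec(c(chr1 = chr1, chr2 = chr2, lambda = 48502),
              spike_in = "lambda")
}

# One fully valid alignment pair; fields can be overridden to violate
# exactly one criterion.
valid_pair <- function(...) {
  base <- data.frame(read_id = "r", chrom = "chr1", gstart = 1000L,
                     gend = 2500L, strand = "+", mapq = 60L,
                     is_primary = TRUE, read_gstart = 0L, read_gend = 1500L,
                     vstart = 0L, vend = 900L, read_vstart = 1510L,
                     read_vend = 2410L, read_length = 2410L,
                     stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}
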