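# Validate planted regions: inside their contig and non-overlapping
# within the class; errors name the offending region pair.
check_planted <- function(df, lens, what) {
  if (is.null(df) || nrow(df) == 0L) return(invisible(NULL))
  if (is.null(df$id)) stop(what, " regions need an 'id' column")
  bad <- df$start < 0 | df$end > lens[df$chrom] | df$start >= df$end
  if (any(bad))
    stop(what, " region ", df$id[which(bad)[1]], " is not within its contig")
  for (chr in unique(df$chrom)) {
    sub <- df[df$chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) < 2) next
    ov <- which(sub$start[-1] < sub$end[-nrow(sub)])
    if (length(ov))
      stop("overlapping ", what, " regions: ", sub$id[ov[1]], " and ",
           sub$id[ov[1] + 1])
  }
  invisible(NULL)
}

# Index of the (sorted, non-overlapping) region containing each 1-based
# position on one chromosome; 0 when outside all regions.
region_index <- function(pos, starts, ends) {
  if (length(starts) == 0L) return(integer(length(pos)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  j <- findInterval(pos - 0.5, starts)
  inside <- j >= 1L & pos <= ends[pmax(j, 1L)]
  out <- integer(length(pos))
  out[inside] <- o[j[inside]]
  out
}

#' Generate synthetic WGBS methylomes with known ground truth
#'
#' Builds per-group methylome tables over a deterministic site map (CpGs
#' every `cpg_spacing` bp on both strands, CA sites every `ca_spacing` bp)
#' with planted features: group-specific DMRs, partially methylated
#' domains (PMDs), low-mCA CH-DMR domains, bimodally methylated imprint
#' control regions (true level 0.5), and a fully unmethylated spike-in
#' contig whose observed methylation equals the non-conversion rate.
#' Per-site coverage is Poisson around the mean (floored at 1 inside
#' planted regions so no planted region goes unobserved) and methylated
#' counts are binomial at the local true level inflated by the
#' non-conversion rate.
#'
#' @param genome a [genome_spec()].
#' @param baseline named vector: per-group background mCG level in
#'   \[0, 1\].
#' @param mca_background named vector (or scalar): per-group background
#'   mCA level (default 0.02).
#' @param dmrs data.frame chrom/start/end/id plus one column per group
#'   giving the true in-region mCG level; regions of one class must not
#'   overlap each other.
#' @param pmds data.frame chrom/start/end/id/group/level: partial CG
#'   methylation planted in one group.
#' @param chdmrs data.frame chrom/start/end/id plus one column per group
#'   giving the true in-domain mCA level.
#' @param icrs data.frame chrom/start/end/id; true mCG 0.5 in every group.
#' @param coverage mean read depth (>= 1).
#' @param nonconversion bisulfite non-conversion rate in \[0, 0.05\].
#' @param cpg_spacing,ca_spacing site spacing in bp.
#' @param seed optional integer seed; identical arguments and seed give
#'   identical output.
#' @param es_group,fib_group group names used to attach true class labels
#'   to the DMR truth table when both are present.
#' @return list with `tables` (named list of methylome data.frames, one
#'   per group; each carries `sample_id` and `nonconversion` attributes)
#'   and `truth` (planted DMR/PMD/CH-DMR/ICR tables, with per-group true
#'   class labels `class_<group>` added to the DMR table).
#' @export
generate_methylome <- function(genome, baseline, mca_background = 0.02,
                               dmrs = NULL, pmds = NULL, chdmrs = NULL,
                               icrs = NULL, coverage = 30,
                               nonconversion = 0.005, cpg_spacing = 100,
                               ca_spacing = 20, seed = NULL,
                               es_group = "hES", fib_group = "fibroblast") {
  stopifnot(inherits(genome, "genome_spec"))
  groups <- names(baseline)
  if (is.null(groups)) stop("baseline must be named by group")
  if (any(baseline < 0 | baseline > 1)) stop("baseline levels must be in [0,1]")
  if (coverage < 1) stop("coverage must be >= 1")
  if (nonconversion < 0 || nonconversion > 0.05)
    stop("nonconversion must be in [0, 0.05]")
  if (length(mca_background) == 1L && is.null(names(mca_background)))
    mca_background <- stats::setNames(rep(mca_background, length(groups)),
                                      groups)
  lens <- genome$contigs
  check_planted(dmrs, lens, "DMR")
  check_planted(pmds, lens, "PMD")
  check_planted(chdmrs, lens, "CH-DMR")
  check_planted(icrs, lens, "ICR")
  if (!is.null(seed)) set.seed(seed)

  # deterministic site map per contig
  site_map <- lapply(names(lens), function(chr) {
    L <- lens[[chr]]
    cpg <- seq.int(cpg_spacing, max(cpg_spacing, L - 1), by = cpg_spacing)
    cpg <- cpg[cpg < L]
    ca <- seq.int(7L, L, by = ca_spacing)  # offset avoids CpG collisions
    list(chr = chr, cpg = cpg, ca = ca)
  })

  planted_cg <- rbind(
    if (!is.null(dmrs)) dmrs[c("chrom", "start", "end")],
    if (!is.null(pmds)) pmds[c("chrom", "start", "end")],
    if (!is.null(icrs)) icrs[c("chrom", "start", "end")])
  planted_ca <- if (!is.null(chdmrs)) chdmrs[c("chrom", "start", "end")]

  make_group <- function(g) {
    rows <- lapply(site_map, function(sm) {
      chr <- sm$chr
      spike <- chr == genome$spike_in
      # --- CG sites (both strands of each CpG) ---
      p <- sm$cpg
      true_cg <- rep(baseline[[g]], length(p))
      if (!spike) {
        if (!is.null(pmds)) {
          sub <- pmds[pmds$chrom == chr & pmds$group == g, , drop = FALSE]
          i <- region_index(p, sub$start, sub$end)
          true_cg[i > 0] <- sub$level[i[i > 0]]
        }
        if (!is.null(icrs)) {
          sub <- icrs[icrs$chrom == chr, , drop = FALSE]
          true_cg[region_index(p, sub$start, sub$end) > 0] <- 0.5
        }
        if (!is.null(dmrs)) {
          sub <- dmrs[dmrs$chrom == chr, , drop = FALSE]
          i <- region_index(p, sub$start, sub$end)
          true_cg[i > 0] <- sub[[g]][i[i > 0]]
        }
      } else true_cg[] <- 0
      in_planted_cg <- if (!spike && !is.null(planted_cg)) {
        sub <- planted_cg[planted_cg$chrom == chr, , drop = FALSE]
        region_index(p, sub$start, sub$end) > 0
      } else rep(FALSE, length(p))
      # --- CA sites ---
      q <- sm$ca
      true_ca <- rep(mca_background[[g]], length(q))
      if (!spike && !is.null(chdmrs)) {
        sub <- chdmrs[chdmrs$chrom == chr, , drop = FALSE]
        i <- region_index(q, sub$start, sub$end)
        true_ca[i > 0] <- sub[[g]][i[i > 0]]
      }
      if (spike) true_ca[] <- 0
      in_planted_ca <- if (!spike && !is.null(planted_ca)) {
        sub <- planted_ca[planted_ca$chrom == chr, , drop = FALSE]
        region_index(q, sub$start, sub$end) > 0
      } else rep(FALSE, length(q))

      pos <- c(p, p + 1L, q)
      strand <- c(rep("+", length(p)), rep("-", length(p)),
                  rep("+", length(q)))
      context <- c(rep("CG", 2L * length(p)), rep("CHH", length(q)))
      dinuc <- c(rep("CG", 2L * length(p)), rep("CA", length(q)))
      true <- c(true_cg, true_cg, true_ca)
      planted <- c(in_planted_cg, in_planted_cg, in_planted_ca)
      cov <- stats::rpois(length(pos), coverage)
      cov[planted] <- pmax(cov[planted], 1L)
      keep <- cov > 0L
      p_obs <- true + (1 - true) * nonconversion
      mc <- stats::rbinom(length(pos), cov, p_obs)
      data.frame(chrom = chr, pos = pos, strand = strand, context = context,
                 dinuc = dinuc, mc = mc, cov = cov,
                 stringsAsFactors = FALSE)[keep, , drop = FALSE]
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$chrom, tab$pos, tab$strand), , drop = FALSE]
    rownames(tab) <- NULL
    attr(tab, "sample_id") <- g
    attr(tab, "nonconversion") <- c(CA = nonconversion, CH = nonconversion,
                                    CT = nonconversion, CC = nonconversion)
    tab
  }

  tables <- stats::setNames(lapply(groups, make_group), groups)

  truth_dmrs <- dmrs
  if (!is.null(dmrs) && all(c(es_group, fib_group) %in% groups)) {
    for (g in setdiff(groups, c(es_group, fib_group))) {
      truth_dmrs[[paste0("class_", g)]] <-
        classify_dmr(dmrs[[g]] - dmrs[[es_group]],
                     dmrs[[g]] - dmrs[[fib_group]])
    }
  }
  list(tables = tables,
       truth = list(dmrs = truth_dmrs, pmds = pmds, chdmrs = chdmrs,
                    icrs = icrs),
       genome = genome,
       params = list(baseline = baseline, mca_background = mca_background,
                     coverage = coverage, nonconversion = nonconversion,
                     cpg_spacing = cpg_spacing, ca_spacing = ca_spacing))
}

#' Generate per-read methylation calls for an imprinted region
#'
#' Draws reads from three epiallele archetypes: fully methylated, fully
#' unmethylated, and partially methylated (at least one methylated and one
#' unmethylated call per read). A balanced imprint corresponds to
#' fractions (0.5, 0.5, 0).
#'
#' @param region_id region label attached to every read.
#' @param epiallele_fractions numeric length 3 (methylated, unmethylated,
#'   partial), summing to 1.
#' @param n_reads number of reads (>= 1).
#' @param cpgs_per_read CG calls per read (>= 2 whenever the partial
#'   fraction is positive).
#' @param seed optional integer seed.
#' @return data.frame with `read_id`, `region_id` and list-column `calls`,
#'   suitable for [classify_reads()].
#' @export
generate_read_level_calls <- function(region_id = "region",
                                      epiallele_fractions, n_reads,
                                      cpgs_per_read = 4, seed = NULL) {
  f <- epiallele_fractions
  if (length(f) != 3 || any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop("epiallele_fractions must be 3 non-negative values summing to 1")
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (cpgs_per_read < 2 && f[3] > 0)
    stop("partial epialleles require cpgs_per_read >= 2")
  if (!is.null(seed)) set.seed(seed)
  k <- cpgs_per_read
  cls <- sample.int(3, n_reads, replace = TRUE, prob = f)
  calls <- lapply(cls, function(ci) {
    if (ci == 1L) rep(1L, k)
    else if (ci == 2L) rep(0L, k)
    else {
      n1 <- sample.int(k - 1L, 1L)
      v <- integer(k)
      v[sample.int(k, n1)] <- 1L
      v
    }
  })
  out <- data.frame(read_id = sprintf("read_%d", seq_len(n_reads)),
                    region_id = region_id, stringsAsFactors = FALSE)
  out$calls <- calls
  out
}

# Sample n 0-based starts from a union of segments (start/end per chrom),
# uniformly over the contained integer positions.
sample_from_segments <- function(segs, n) {
  w <- segs$end - segs$start
  if (n == 0L) return(segs[0, c("chrom", "start")])
  if (sum(w) <= 0) stop("no available placement space")
  seg <- sample.int(nrow(segs), n, replace = TRUE, prob = w)
  data.frame(chrom = segs$chrom[seg],
             start = segs$start[seg] +
               floor(stats::runif(n) * w[seg]),
             stringsAsFactors = FALSE)
}

# Merge intervals (start/end) within one chromosome; assumes sorted input
# not required.
merge_segments <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  os <- numeric(0); oe <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] > me) { os <- c(os, ms); oe <- c(oe, me); ms <- start[i]; me <- end[i] }
    else me <- max(me, end[i])
  }
  data.frame(start = c(os, ms), end = c(oe, me))
}

#' Generate a feature track with controlled overlap enrichment
#'
#' Places `n_features` fixed-width intervals on the genome. Under uniform
#' placement a feature overlaps the query set with probability p0
#' (computed exactly from the query layout); with `fold_enrichment = f`
#' the expected overlapping fraction becomes `f * p0`: a binomial number
#' of features is placed uniformly within the overlap-generating start
#' space and the rest uniformly in its complement. `fold_enrichment = 1`
#' reduces to pure uniform placement (the calibrated null) and
#' `fold_enrichment = 0` yields zero overlaps.
#'
#' @param genome a [genome_spec()].
#' @param query region data.frame the enrichment is measured against.
#' @param fold_enrichment target fold enrichment (>= 0);
#'   `fold_enrichment * p0` may not exceed 1.
#' @param feature_width_bp feature width.
#' @param n_features number of features (>= 1).
#' @param seed optional integer seed.
#' @return region data.frame of the generated features.
#' @export
generate_feature_tracks <- function(genome, query, fold_enrichment = 1,
                                    feature_width_bp = 1000, n_features,
                                    seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  if (n_features < 1) stop("n_features must be >= 1")
  if (fold_enrichment < 0) stop("fold_enrichment must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  w <- feature_width_bp
  lens <- genome$contigs
  lens <- lens[lens >= w]
  allowed <- data.frame(chrom = names(lens), start = 0,
                        end = unname(lens) - w + 1,
                        stringsAsFactors = FALSE)
  # start positions whose feature would overlap >= 1 query interval
  ov <- NULL
  for (chr in intersect(unique(query$chrom), names(lens))) {
    qs <- query$start[query$chrom == chr]
    qe <- query$end[query$chrom == chr]
    seg <- merge_segments(pmax(qs - w + 1, 0),
                          pmin(qe, lens[[chr]] - w + 1))
    seg <- seg[seg$end > seg$start, , drop = FALSE]
    if (nrow(seg))
      ov <- rbind(ov, data.frame(chrom = chr, seg))
  }
  total <- sum(allowed$end - allowed$start)
  ov_total <- if (is.null(ov)) 0 else sum(ov$end - ov$start)
  p0 <- ov_total / total
  if (fold_enrichment == 1) {
    starts <- sample_from_segments(allowed, n_features)
  } else {
    p_target <- fold_enrichment * p0
    if (p_target > 1)
      stop("fold_enrichment demands more overlapping features than exist ",
           "(target fraction ", round(p_target, 3), ")")
    n_ov <- stats::rbinom(1, n_features, p_target)
    if (n_ov > 0 && is.null(ov))
      stop("query has no overlap space on this genome")
    comp <- NULL  # complement of overlap space within allowed starts
    for (chr in allowed$chrom) {
      a <- allowed[allowed$chrom == chr, ]
      o <- if (is.null(ov)) NULL else ov[ov$chrom == chr, , drop = FALSE]
      cur <- a$start
      if (!is.null(o) && nrow(o)) {
        o <- o[order(o$start), , drop = FALSE]
        for (i in seq_len(nrow(o))) {
          if (o$start[i] > cur)
            comp <- rbind(comp, data.frame(chrom = chr, start = cur,
                                           end = o$start[i]))
          cur <- max(cur, o$end[i])
        }
      }
      if (cur < a$end)
        comp <- rbind(comp, data.frame(chrom = chr, start = cur, end = a$end))
    }
    starts <- rbind(
      if (n_ov > 0) sample_from_segments(ov, n_ov),
      if (n_features - n_ov > 0)
        sample_from_segments(comp, n_features - n_ov))
  }
  regions(starts$chrom, starts$start, starts$start + w,
          id = sprintf("feature_%d", seq_len(n_features)))
}

#' Generate a synthetic Cas9-enrichment insertion library
#'
#' Plants `n_true_sites` insertion sites on the genome (well separated so
#' clusters map one-to-one to sites) with Poisson(`mean_reads_per_site`)
#' supporting reads each; sites drawing zero reads remain in the truth
#' table but are unobserved. Every signal read carries a primary,
#' MAPQ-60, >= 800 bp genome alignment abutting a vector alignment on the
#' read. Noise reads, in the per-criterion fractions of `noise_spec`
#' (relative to the signal read count), each violate exactly one filter
#' criterion, making filter audits exact.
#'
#' @param n_true_sites true number of insertion sites (>= 1).
#' @param mean_reads_per_site Poisson mean read coverage per site.
#' @param genome a [genome_spec()] (sites avoid the spike-in contig).
#' @param vector_length_bp length of the inserted vector sequence.
#' @param noise_spec named fractions for `non_primary`, `single_mapped`,
#'   `short`, `low_mapq`, `gap`.
#' @param seed optional integer seed.
#' @return list with `pairs` (alignment-pair data.frame, see
#'   [filter_alignments()]) and `truth` (`sites` data.frame with per-site
#'   read counts, `n_true`).
#' @export
generate_insertion_library <- function(n_true_sites, mean_reads_per_site,
                                       genome, vector_length_bp = 8000,
                                       noise_spec = c(non_primary = 0,
                                                      single_mapped = 0,
                                                      short = 0,
                                                      low_mapq = 0,
                                                      gap = 0),
                                       seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  if (n_true_sites < 1) stop("n_true_sites must be >= 1")
  if (mean_reads_per_site <= 0) stop("mean_reads_per_site must be > 0")
  if (!is.null(seed)) set.seed(seed)
  lens <- genome$contigs[setdiff(names(genome$contigs), genome$spike_in)]
  pad <- 4000
  grid <- do.call(rbind, lapply(names(lens), function(chr) {
    L <- lens[[chr]]
    if (L < 2 * pad + 200) return(NULL)
    data.frame(chrom = chr, pos = seq(pad, L - pad, by = 200),
               stringsAsFactors = FALSE)
  }))
  if (is.null(grid) || nrow(grid) < n_true_sites)
    stop("genome too small for ", n_true_sites, " well-separated sites")
  sites <- grid[sample.int(nrow(grid), n_true_sites), , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  sites$reads <- stats::rpois(n_true_sites, mean_reads_per_site)
  rownames(sites) <- NULL

  signal_read <- function(chrom, site) {
    n <- length(site)
    if (n == 0L) return(NULL)
    aln <- sample(800:3000, n, replace = TRUE)
    gap <- sample(0:10, n, replace = TRUE)
    vlen <- pmin(sample(500:1500, n, replace = TRUE), vector_length_bp)
    data.frame(chrom = chrom, gstart = site - aln, gend = site,
               strand = "+", mapq = 60L, is_primary = TRUE,
               read_gstart = 0L, read_gend = aln,
               vstart = 0L, vend = vlen,
               read_vstart = aln + gap, read_vend = aln + gap + vlen,
               read_length = aln + gap + vlen,
               stringsAsFactors = FALSE)
  }
  rd <- rep(seq_len(n_true_sites), sites$reads)
  pairs <- signal_read(sites$chrom[rd], sites$pos[rd])
  n_signal <- if (is.null(pairs)) 0L else nrow(pairs)

  noise_names <- c("non_primary", "single_mapped", "short", "low_mapq", "gap")
  noise_spec <- noise_spec[intersect(names(noise_spec), noise_names)]
  for (crit in names(noise_spec)) {
    n_c <- round(noise_spec[[crit]] * n_signal)
    if (n_c == 0) next
    pick <- grid[sample.int(nrow(grid), n_c, replace = TRUE), , drop = FALSE]
    nr <- signal_read(pick$chrom, pick$pos)
    if (crit == "non_primary") nr$is_primary <- FALSE
    if (crit == "single_mapped") {
      nr$vstart <- nr$vend <- nr$read_vstart <- nr$read_vend <- NA_integer_
      nr$read_length <- nr$read_gend
    }
    if (crit == "short") {
      aln <- sample(300:799, n_c, replace = TRUE)
      nr$gstart <- nr$gend - aln
      shift <- nr$read_gend - aln
      nr$read_gend <- aln
      nr$read_vstart <- nr$read_vstart - shift
      nr$read_vend <- nr$read_vend - shift
      nr$read_length <- nr$read_length - shift
    }
    if (crit == "low_mapq") nr$mapq <- sample(c(10L, 30L, 50L), n_c,
                                              replace = TRUE)
    if (crit == "gap") {
      extra <- sample(41:140, n_c, replace = TRUE)  # gap becomes 51..150
      nr$read_vstart <- nr$read_vstart + extra
      nr$read_vend <- nr$read_vend + extra
      nr$read_length <- nr$read_length + extra
    }
    pairs <- rbind(pairs, nr)
  }
  if (!is.null(pairs)) {
    pairs$read_id <- sprintf("read_%d", seq_len(nrow(pairs)))
    pairs <- pairs[c("read_id", setdiff(names(pairs), "read_id"))]
    rownames(pairs) <- NULL
  }
  list(pairs = pairs, truth = list(sites = sites, n_true = n_true_sites))
}

#' Generate methylation trajectory matrices with planted clusters
#'
#' Cluster members follow their centroid plus Gaussian noise clipped to
#' \[0, 1\]; background elements are flat (range < 0.2) and are removed by
#' [filter_dynamic_elements()].
#'
#' @param n_elements total number of elements.
#' @param timepoints character vector of ordered time-point labels.
#' @param cluster_centroids k x length(timepoints) matrix of centroid
#'   levels in \[0, 1\].
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param background_fraction fraction of flat background elements.
#' @param seed optional integer seed.
#' @return list with `matrix` (element x time point) and `truth` (named
#'   vector element -> cluster id; 0 marks background).
#' @export
generate_trajectories <- function(n_elements, timepoints, cluster_centroids,
                                  noise_sd = 0.03, background_fraction = 0,
                                  seed = NULL) {
  cc <- as.matrix(cluster_centroids)
  if (ncol(cc) != length(timepoints))
    stop("centroid columns must match timepoints")
  if (any(cc < 0 | cc > 1)) stop("centroid values must be in [0,1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(cc)
  n_bg <- round(background_fraction * n_elements)
  n_cl <- n_elements - n_bg
  assign <- c(sample(rep_len(seq_len(k), n_cl)), rep(0L, n_bg))
  vals <- matrix(NA_real_, n_elements, length(timepoints),
                 dimnames = list(sprintf("e%d", seq_len(n_elements)),
                                 timepoints))
  for (i in seq_len(n_elements)) {
    if (assign[i] > 0) {
      vals[i, ] <- pmin(pmax(cc[assign[i], ] +
                               stats::rnorm(ncol(cc), 0, noise_sd), 0), 1)
    } else {
      base <- stats::runif(1, 0.3, 0.7)
      vals[i, ] <- pmin(pmax(base + stats::runif(ncol(cc), -0.05, 0.05),
                             0), 1)
    }
  }
  list(matrix = vals,
       truth = stats::setNames(assign, rownames(vals)))
}
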