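---
title: "Methods: quantifying epigenetic memory in reprogramming methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying epigenetic memory in reprogramming methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimemory)
```

## The problem

Human induced pluripotent stem (hiPS) cells made by conventional (primed)
OKSM reprogramming differ epigenetically from embryonic stem (hES) cells in
two characteristic ways: *somatic-cell epigenetic memory* — methylation
states of the fibroblast (or other origin cell) that survive reprogramming —
and *aberrant methylation* — states present in neither the origin cell nor
hES cells. These differences concentrate in large repressive chromatin
domains (H3K9me3, lamina-associated domains, partially methylated domains)
and in megabase-scale non-CpG (CH, mostly CA) methylation domains.
Reprogramming strategies that pass through a naive-like state
(transient-naive-treatment, TNT, or naive-to-primed, NTP) can erase much of
this memory; quantifying how much, and where, is the purpose of this
package. All analyses operate downstream of read alignment and methylation
calling: the inputs are per-cytosine call tables, region interval sets, and
alignment summaries.

## Methylation quantification

The elementary statistic everywhere is the **coverage-weighted methylation
level** of a region: the sum of methylated C calls over all in-region sites
of a context, divided by the sum of total (C-or-T) calls,
$\mathrm{mCG/CG} = \sum_i mc_i \big/ \sum_i cov_i$. A region with no
covered site is *undefined* (`NA`), never 0, so downstream differences
cannot fabricate signal. Before CG quantification the two strands of each
palindromic CpG are collapsed into one record by summing counts
(`collapse_cg_strands()`), which conserves total `mc` and `cov`.

Bisulfite conversion is imperfect: unconverted unmethylated cytosines read
as methylated. The non-conversion rate is estimated per context as the
apparent methylation of a fully unmethylated spike-in contig
(`nonconversion_rate()`), and is subtracted from every non-CG level, with
the result floored at 0 (subtraction can go negative at low depth; the
floor keeps levels in $[0,1]$). CG levels are not corrected — the CG signal
is orders of magnitude above the rate, while near-zero CH levels would
otherwise be dominated by it.

Coordinate conventions: cytosine positions are 1-based (the CGmap
convention); all region tables are BED-style 0-based half-open. A 1-based
site $p$ lies in $[start, end)$ iff $start < p \le end$. Conversions happen
only at I/O boundaries.

Two further quantifications mirror standard browser-track practice:

* `sliding_window_track()` computes mCA/CA in 5-kb windows sliding by 1 kb
  (defaults), non-conversion subtracted and floored; windows tile each
  contig from 0 and partial terminal windows are dropped (a deliberate
  edge policy — the alternative of emitting short terminal windows changes
  nothing statistically but complicates comparisons between contigs).
* `classify_reads()` assigns each read exactly one epiallele class from
  its ordered CG calls: *methylated* (every call methylated),
  *unmethylated* (no call methylated), *partially methylated* (at least
  one of each). A single-call read can only be methylated or unmethylated.
  At an intact imprint the methylated/unmethylated classes sit near 50/50.
  Reads are counted in a region when they contribute at least one CG call
  to it; assignment of boundary-spanning reads is not otherwise specified
  by the underlying data model, and this choice is flagged here rather
  than asserted as canonical.

## DMR memory and aberration classification

CG-DMRs (detected upstream, e.g. by dmrseq; detection is out of scope) are
first filtered to $|\Delta\mathrm{mCG/CG}| > 0.2$ and $p < 0.05$ — both
strict inequalities (`filter_candidate_dmrs()`). Each DMR is then placed in
the plane spanned by $\Delta_{ES}$ (hiPS − hES) and $\Delta_{fib}$
(hiPS − fibroblast) and labelled with threshold $t = 0.2$:

| condition on $\Delta_{ES}$ | condition on $\Delta_{fib}$ | label |
|---|---|---|
| $|\Delta_{ES}| \le t$ | any | `below_threshold` |
| $\Delta_{ES} < -t$ | $|\Delta_{fib}| \le t$ | `memory` |
| $\Delta_{ES} < -t$ | $\Delta_{fib} > t$ | `partial_memory` |
| $\Delta_{ES} < -t$ | $\Delta_{fib} < -t$ | `aberrant_hypo` |
| $\Delta_{ES} > t$ | $\Delta_{fib} > t$ | `aberrant_hyper` |
| $\Delta_{ES} > t$ | $|\Delta_{fib}| \le t$ | `memory_hyper` |
| $\Delta_{ES} > t$ | $\Delta_{fib} < -t$ | `partial_hyper` |

The seven labels tile the plane with no gaps or overlaps (property-tested
over $10^5$ random pairs). Two boundary decisions are deliberate and
documented so figures are reproducible: equality with the threshold always
falls on the no-difference side, and correction (below) requires a strict
inequality. The `aberrant_hypo` and `partial_hyper` corners are not named
in the memory/aberration vocabulary of the field; they are labelled here
for completeness so the function is total. DMRs whose re-quantified
$|\Delta_{ES}|$ falls under the threshold are kept as `below_threshold`
rather than silently re-filtered.

A DMR is **corrected** in a reprogrammed line when its level differs from
the hES reference by strictly less than 0.2 (`assess_correction()`); the
corrected fraction is monotonically non-decreasing in the threshold.
`timecourse_delta()` traces the mean level change of a DMR set against the
day-0 baseline with pairwise-complete exclusion of undefined levels, which
is how the emergence time of aberrant methylation is located.
`icr_screen()` reports per-imprint-control-region mCG with median and IQR;
ICRs deviating from the balanced 0.5 by more than 0.15 are flagged. The
0.15 margin is a screening default, not a published cut-off (the
literature shows distributions rather than thresholds); it is exposed as a
parameter.

## Domain profiles

`binned_profile()` divides each CH-DMR (or any domain) and equal-length
upstream and downstream flanks into 30 bins each — 90 bins per region —
and computes the per-bin coverage-weighted level with non-conversion
subtraction. When a domain length is not divisible by 30 the remainder
$r$ is absorbed one extra bp by the first $r$ bins, so bins partition the
region exactly and deterministically. `flank_normalize()` divides all 90
bins of a region by that region's maximum: per-region (not per-dataset)
normalization was chosen because flank plateaus then sit at ≈1 for every
group, which is what makes group profiles comparable. Flanks equal the
body length exactly ("equivalent" flanking regions admit other readings; a
fixed flank size is the rejected alternative). Domains are treated
strand-agnostically and calls from both strands are pooled.
`aggregate_profiles()` averages bins across regions pairwise-complete.

## Permutation enrichment

`enrichment_z()` measures over/under-representation of a query region set
(e.g. corrected CG-DMRs) in a feature track (H3K9me3 peaks, LADs, PMDs).
The overlap unit is the number of query regions overlapping ≥ 1 bp of any
feature — each query counted once. The null re-places every query interval
uniformly at random on its own chromosome, width preserved, independently
(and optionally outside a mask), 200 times by default; the chromosome is
preserved to respect sequence-composition structure (whether published
analyses did the same is not stated; the choice is documented, not
attributed). Then $z = (obs - \overline{perm})/sd(perm)$ — a $z$ of +25
means 25 standard deviations more overlaps than chance — and the empirical
p-value uses the add-one rule $(1 + \#\{perm \ge obs\})/(n_{perm}+1)$, so
it is never exactly 0. `multi_feature_enrichment()` shares one permutation
set across tracks and adjusts p-values by Benjamini–Hochberg (the FDR
method behind reported thresholds is unstated; BH is the default choice).
Degenerate nulls ($sd = 0$) return `NA` with a flag rather than an
infinite score. Under the null generator the $z$ distribution is verified
to be approximately standard normal (mean within ±0.2, sd within
0.8–1.2 across 100 simulated tracks).

## Trajectory clustering

`filter_dynamic_elements()` keeps regulatory elements whose methylation
range over the time course is at least 0.2 and drops incompletely observed
elements. `fuzzy_cmeans()` is a from-scratch standard Bezdek fuzzy
c-means: memberships $u_{ij} = 1/\sum_l (d_{ij}/d_{lj})^{2/(m-1)}$,
centers $c_i = \sum_j u_{ij}^m x_j / \sum_j u_{ij}^m$, iterated until the
maximum center displacement falls below `tol`. Rows are standardized
(mean 0, sd 1) before clustering — the Mfuzz-style convention, so clusters
capture trajectory shape, not absolute level — and centers are reported in
both standardized and original units (the latter as the
$u^m$-weighted mean of the original rows). A point at zero distance from a
center receives membership 1 by convention. The fuzzifier defaults to
$m = 2$ (the common default; the empirical fuzzifier-estimation procedure
of Mfuzz is not reproduced) and $k$ is the caller's choice. The objective
$\sum u^m d^2$ is recorded every iteration and is non-increasing;
memberships row-sum to 1 within $10^{-9}$; initialization picks $k$
distinct data rows under the seed, so results are reproducible.

Two time courses (e.g. primed and naive series) are clustered separately
and then matched by `merge_overlapping_clusters()`: cluster cores are the
elements with membership ≥ 0.5, and core pairs with Jaccard ≥ 0.5 merge
greedily in descending Jaccard, each cluster at most once. Both constants
are exposed as arguments; the underlying merge criterion is not specified
anywhere authoritative, so these defaults are this package's choice.

`weighted_expression_summary()` links clusters to gene expression: each
linked gene's (quantile-normalized) TPM is weighted by its element–gene
interaction score, down-weighting weakly supported links, and per
cluster/time point the mean over linked genes is reported with a
nonparametric bootstrap percentile band (99% by default) over genes.
Quantile normalization delegates to `limma::normalizeQuantiles()`.

## Clonal diversity from insertion reads

Reads from Cas9-enriched nanopore sequencing of a lentiviral insertion
library map partly to the genome and partly to the vector.
`filter_alignments()` keeps reads that are primary, map to both
references, have genome-alignment length ≥ 800 bp, mapping quality exactly
60 (a ≥ variant sits behind `mapq_ge`), and at most a 50-bp gap between
the two alignments in read coordinates (a gap of ≥ 51 bp discards the
read). Each rejected read is tallied under the first criterion it
violates. `call_insert_sites()` takes the genome-alignment boundary
nearest the vector alignment on the read as the junction coordinate (the
exact junction formula is not published; this is the geometrically natural
reading) and chains junctions by transitive single linkage within 50 bp —
the behaviour of interval-cluster tools — rather than fixed windows.

`estimate_diversity()` infers the total number of insertion sites
including unobserved ones. With $n$ observed sites and $R$ total
supporting reads, homogeneous Poisson sampling implies
$N(1 - e^{-R/N}) = n$; the fixed point $N \leftarrow n/(1 - e^{-R/N})$
from $N_0 = n$ converges to the root whenever $R > n$. When every site has
exactly one read ($R = n$) no finite root exists and the estimate is
returned unbounded with `converged = FALSE`. Uncertainty comes from a
Poisson bootstrap — every read gets an independent Poisson(1) weight,
equivalent to redrawing each site's coverage as Poisson(its observed
coverage) — with the estimator re-run per replicate. The raw bootstrap
re-estimates are *not* centered on the point estimate: the resampled
coverage distribution has a heavier zero class than a homogeneous Poisson
of equal mean (for coverage drawn from a zero-truncated Poisson(3), the
resampled zero probability is 0.105 versus 0.050), which biases replicate
estimates downward by roughly 12%. The percentile interval is therefore
recentered on the point estimate (a bias-corrected percentile interval);
this also guarantees the interval contains the estimate. In simulation
(1000 true sites, mean coverage 3) the recentered 95% interval covers the
truth conservatively, and the estimator's relative error decreases with
coverage.

## What the synthetic generator emulates — and what it does not

Every analysis stage is exercised against `generate_methylome()` and its
siblings, which plant known truth: group-specific DMRs, partially
methylated domains, low-mCA CH-DMR domains, balanced (true level 0.5)
imprints, an unmethylated spike-in contig, feature tracks with exact
fold-enrichment control, Poisson-coverage insertion libraries whose noise
reads each violate exactly one filter criterion, and trajectory matrices
with planted centroids plus flat background.

Deliberate simplifications, chosen once:

* CpGs sit on a fixed 100-bp grid and CA sites on a 20-bp grid
  (offset to avoid collisions). Site density is irrelevant to the
  statistics under test, and a deterministic map makes truth bookkeeping
  exact. Real CpG density is non-uniform (islands, deserts).
* Per-site coverage is Poisson around the mean with a floor of 1 inside
  planted regions, so no planted region is silently unobserved; real
  coverage is overdispersed and mappability-structured.
* Methylated counts are binomial at the local true level inflated by the
  non-conversion rate, $p_{obs} = \pi + (1-\pi)\,nc$; real data add
  cell-heterogeneity overdispersion.
* Insertion sites are planted ≥ 200 bp apart so observed clusters map
  one-to-one to true sites; real libraries can harbour closely spaced
  co-integrations.

Passing tests therefore demonstrate correctness of the statistics and
their implementations under the stated sampling models — not robustness
to CpG-density structure, overdispersed coverage, or cell heterogeneity.

## Problem sizes and numerical choices

The test-suite simulations use: 300 planted DMRs at 30× coverage with
effect sizes ≥ 0.3 over 20 seeds (class recovery and correction); 10⁴
spike-in CpGs at 50× (non-conversion, within ±0.001); 10⁴ reads for
epiallele proportions (±0.02); 100 simulated tracks at 200 permutations
each for null calibration and for fold-5 power; 20 seeds of a 3-centroid,
180-element trajectory recovery (adjusted Rand index > 0.9); 100
insertion libraries of 1000 true sites at mean coverage 3 with 200
bootstrap replicates each (interval coverage); and 500 replicates of a
200-gene Gaussian cluster for the 99% expression band (coverage within
±2 points of nominal). Fixed-point tolerance is $10^{-6}$ on the
iterate, FCM tolerance $10^{-6}$ on center displacement with
`max_iter = 1000` and a `converged` flag rather than an error on
non-convergence.

## Known limitations

* DMR and CH-DMR *detection* is out of scope; intervals are consumed.
* The diversity model assumes one homogeneous Poisson rate across sites;
  strongly heterogeneous enrichment efficiencies would bias the estimate
  downward, and the one-sentence published description of the procedure
  admits other formulations (e.g. joint estimation of the rate), so the
  fixed-point interpretation used here is validated by parameter recovery
  rather than by comparison to the original code.
* The permutation null preserves chromosome and width only; GC- or
  gap-matched backgrounds and circular-shift nulls are not implemented.
* bigWig output and BAM-based methylation calling are not provided; the
  bedGraph-with-counts dialect (chrom, start, end, level, mc, cov) is
  this package's documented convention, since bedGraph proper lacks
  counts.
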