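---
title: "Methods: characterizing a DArT marker array against a reference genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing a DArT marker array against a reference genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartmap)
```

## Scope

Diversity Arrays Technology (DArT) genotyping scores thousands of dominant
presence/absence markers from hybridization of complexity-reduced genomic
representations to a library of cloned probes. `dartmap` implements the
analyses needed to characterize such an array genomically: quality and
segregation filtering of the scored markers, construction of a linkage map
in an outbred full-sib (CP) family, de-replication of the probe library by
sequence clustering, post-processing of probe-to-genome alignment hits,
integration of the genetic map with physical positions, and statistics on
how the probes sample the gene space. A synthetic-data generator produces
genomes, gene models, probe libraries and mapping populations with known
truth, so every stage is testable without external data.

## The synthetic study system

The generator's defaults mirror a eucalypt-like study system: 11
pseudochromosomes whose lengths are the physical spans covered by the
published framework map (40.7 to 79.7 Mbp, 587.5 Mbp in total), a tail of
small unanchored scaffolds, about 68 gene models per Mbp, and an outbred
F1 family of 177 progeny. Dominant markers are planted heterozygous in one
parent (1:1 pseudo-testcross segregation, the majority class) or in both
(3:1 intercross, fraction 0.40, matching the published tally of
1,199/2,976), plus a small fraction (0.07) of fully informative codominant
anchor loci standing in for microsatellites. Physical positions convert to
genetic positions through a planted 500 kbp/cM. The scoring process
injects missing calls at rate 0.10 (the call-rate filter tolerates up to
25% missing; observed data are typically better) and score flips at rate
0.002, the error level implied by a scoring reproducibility of 99.8%.

Gametes follow a no-interference (Poisson/Haldane) crossover process: the
crossover count per meiosis is Poisson with mean equal to the chromosome
length in Morgans, positions are uniform, and phases are drawn at random
per marker. Estimation nevertheless reports Kosambi distances, because
that is the convention of the mapping literature this package serves; the
systematic discrepancy this creates is discussed below. What the generator
does *not* emulate: realistic sequence composition (repeats, methylation
landscapes), fluorescence-level scoring, segregation distortion, or
crossover interference. Passing tests therefore demonstrate correctness of
the estimators under a clean meiotic model, not robustness to every
artifact of real arrays.

The generator's unique probes are planted at pairwise disjoint loci, so
the planted clustering is exactly the clustering that sequence overlap can
reveal; copies are optionally mutated per base. Unanchored scaffolds carry
a latent chromosome-of-origin, from which markers simulated on them
inherit genetic positions - this is what makes scaffold anchoring
testable.

## Marker quality control and segregation

Markers are filtered on three array-level metrics with inclusive
thresholds: reproducibility >= 0.95, quality score Q >= 65 and call rate
>= 0.75. The expected segregation ratio of each marker is determined from
the parent scores, never chosen as the best-fitting ratio, to avoid a
multiple-testing bias: both parents banded gives 3:1, exactly one parent
1:1, codominant parents 1:2:1 or 1:1:1:1 by allele count. Markers whose
parents cannot produce the observed segregation are excluded with an
`inconsistent` code. The goodness-of-fit test is a Pearson chi-square
without continuity correction on the non-missing progeny scores
(df = classes - 1), and a marker is non-Mendelian when p < alpha
(default 0.01).

## Two-point likelihoods

For a marker pair, each parent transmits a parental haplotype with
probability (1 - r)/2 and a recombinant with probability r/2; the
observable progeny class collapses the four transmitted alleles (dominant
markers show only band presence). Because each parent's factor is linear
in r, every class probability is a quadratic in r; `dartmap` derives the
coefficients once per configuration (by evaluating the enumeration at
three values of r) and caches them, which makes the per-pair likelihood
essentially free. The likelihood is maximized on r in [0, 0.5) per
admissible phase combination (2 to 4, ties broken toward coupling) by a
grid scan refined with golden-section search; LOD compares against
independence at r = 0.5.

Two modeling choices matter in practice:

* **Score-error model.** A per-score flip probability
  (`mapping_params(genotype_error = 0.002)`) enters the dominant-marker
  class probabilities as a linear mixing. Without it, each false score
  inflates the apparent recombination of short intervals by roughly twice
  the error rate; summed over the ~100 adjacent gaps of a densely mapped
  chromosome this doubles or triples the map length. 0.002 corresponds to
  the 99.8% scoring concordance typical of these arrays; users with
  error-free data should set 0.
* **Uninformative and degenerate configurations.** Dominant testcross
  pairs heterozygous in different single parents share no informative
  meioses and are flagged uninformative (LOD 0). Dominant 3:1 x 3:1 pairs
  are formally informative but carry almost no usable signal - their ML
  estimates are strongly biased toward small r at moderate and large
  distances even at large n - so they are excluded from all distance
  estimation (they still pass through the association screen and LOD
  grouping).

For full pairwise tables a vectorized 2x2 association chi-square screen
(default threshold 20) decides which pairs receive ML estimation; edges
that can matter for grouping at LOD > 15 have association chi-square near
2 ln(10) x 15 ~ 69, far above the screen, so the screen only prunes
clearly unlinked pairs.

## Grouping, seriation and map distances

Linkage groups are the connected components over edges with LOD > 15 and
r <= 0.4 (single-linkage transitive closure); markers without a strong
edge are reported ungrouped.

Ordering a group proceeds in three steps, replacing the simulated
annealing of conventional mapping software with a deterministic scheme:

1. **Path metric.** Only reliable short-range estimates (r <= 0.3 and
   LOD >= 3) contribute Kosambi distances as graph edges; a shortest-path
   (min-plus) closure completes the metric, bridging cross-parent
   testcross pairs through 3:1 and codominant anchors. Long-range direct
   estimates never enter: with phase maximized over candidates, their
   downward bias would create shortcuts that fold the geometry. Short
   edge claims additionally pass a quorum corroboration: a claim is
   trusted only when at least half of the two endpoints' short
   neighborhoods lie on a two-hop path of commensurate length. This
   guards against the heavy lower tail of low-information configurations
   (a dominant 3:1 x testcross pair has sd(r) about five times binomial,
   so among tens of thousands of pairs a few spurious tight-linkage
   claims are expected, and a single uncaught one folds a shortest-path
   metric in half).
2. **Embedding.** Principal-coordinate analysis of the path metric gives
   an initial 1-D placement, refined by weighted stress majorization
   (1-D SMACOF) against the direct pairwise distances. Weights are
   inverse variances built from each configuration's expected Fisher
   information about r - binomial-style variances would overstate the
   precision of weak configurations several-fold. After convergence, one
   robust pass drops constraints with standardized residuals above 3.5
   and refits. The marker order is the order along the refined line,
   with an adjacent-transposition ripple as a final polish.
3. **Distances.** Each adjacent gap is estimated by non-negative weighted
   least squares pooling every pair that spans at most `fit_window`
   (default 20) adjacent gaps in the fitted order: each pair constrains
   the sum of the gaps it spans. Three details matter. Pairs are selected
   by rank separation, never by a distance estimate: selecting on a
   pair's own noisy r at a band boundary preferentially admits
   underestimates, and selecting on shortest-path distances admits
   truly-distant pairs because min-plus closure over thousands of noisy
   edges systematically understates long distances. Distances are pooled
   on the no-interference (Haldane) scale, where genetic distance is
   exactly additive under a Poisson crossover model, and each fitted gap
   (short, hence mapping-function independent) is converted to Kosambi
   cM; pooling directly on the Kosambi scale would compress
   moderate-range pairs by up to 15%. Weights again use the expected
   Fisher information, evaluated at the noise-independent path-metric r.
   The non-negativity constraint is enforced by an active-set re-solve;
   merely clipping negative fitted gaps to zero would inflate the total
   length by the clipped mass. Positions are cumulative sums starting
   at 0.

Under the synthetic model this estimator recovers planted group lengths
and kbp/cM ratios with a per-chromosome mean error of 3-8% at n = 177
and 100 markers per chromosome. The worst of 11 chromosomes typically
stays within 10-16% and can occasionally reach ~20% when a marker-level
scoring fluke corrupts several of one 3:1 marker's pairwise estimates at
once - an honest property of dominant-marker data at this sample size,
not tuned away. The recovery tolerances asserted in the tests (25% on
length, 15% on kbp/cM per chromosome) come from the package's validation
plan and are not revisited after measurement. Under real crossover
interference the Haldane-additive pooling step would overstate distances
of the longer pooled pairs; the window cap keeps that exposure modest.

In `framework` mode, after ordering, two deferral criteria apply: the
local goodness-of-fit jump (the 2-class chi-square between the observed
recombinant count of a marker's flanking pair and the count expected
under Kosambi additivity through the marker; threshold 5) and the
marker's embedding stress (median standardized residual of its pairwise
constraints; threshold 2.5, flagging markers that no position on the line
can reconcile with their estimates). Deferred markers are removed and the
group refitted. This reproduces the qualitative signature of framework
mapping: fewer markers, a lower fraction of sub-centiMorgan gaps, and
more reliable order. The `full` mode places every marker.

## Probe redundancy clustering

Probe de-replication mirrors tiered assembler stringencies: candidate
pairs share exact index words (both orientations; a handful of shared
words is required, since any mergeable 50 bp overlap at 98% identity
shares dozens), pairs are verified by ends-free overlap alignment, and a
pair merges only if the overlap is >= 50 bp at >= 98% identity with
mismatches, ambiguities and gaps within the preset's limits (A1 strictest
to A4 most relaxed, word lengths 18 down to 10). Clusters are the
transitive closure of merges; no consensus sequences are built because
only membership feeds the accounting. The redundancy report states
singletons, redundant members, clusters, unique loci
(singletons + clusters) and the redundancy rate
100 x (total - unique)/total. Published accounting tables print this rate
truncated (not rounded) to two decimals, and the report exposes both the
full-precision and the truncated value. Extrapolation to the full array
size assumes unsequenced probes share the observed redundancy:
floor(array_size x unique/total).

## Physical-hit post-processing

The retention threshold follows T = ceiling(2 x median(5.5 ln L)) over
the probe lengths L. The natural logarithm is a documented inference: at
the typical 534 bp probe it gives 2 x 5.5 x ln 534 = 69.08, hence T = 70,
matching the fixed threshold used with this rule in practice, whereas
log10 would give about 30. Per probe, the best-scoring hit and any hit
within T of it are retained; more than two retained hits mark the probe
`ambiguous` ("unsuccessful mapping" - the complement of the up-to-two-hit
success rule), and the mapping error rate is the ambiguous fraction of
evaluated probes. Two retained hits classify by geometry: overlapping
intervals are one locus; same-scaffold gaps are tandem-proximal
(< 1 kb, strict), distal (1-10 kb) or far (> 10 kb, strict); hits on
different scaffolds are multi-chromosome or multi-with-unanchored.
Inter-hit distance is the gap between nearest interval ends (not
start-to-start). The built-in seed-and-extend aligner (exact 15-mer
seeds, affine-gap local alignment with a = 1, b = 3, q = 5, r = 2) serves
synthetic-scale data; real data would come from an external aligner
through the SAM reader, which takes primary and secondary alignments with
their AS score tags and converts 1-based SAM coordinates to the package's
0-based half-open convention.

## Map-to-genome integration and gene space

Each linkage group is compared against its majority chromosome (the
chromosome holding the plurality of its placed markers). Collinearity is
the orientation-corrected Spearman correlation of cM versus bp ranks, with
a leave-one-out list of discordant markers. The kbp/cM ratio uses the
min-max physical span of the placed markers over their cM span; the
genome-wide figure is the unweighted mean of per-chromosome ratios (this
is the convention that reproduces the published 513.4 from the 11 printed
ratios) with an n-1 standard deviation. Coverage is the summed span as a
percentage of the assembled total, rounded to an integer for the headline
figure only. Unanchored scaffolds are assigned to the (unique) linkage
group of their mapped markers, with multi-group scaffolds flagged as
conflicts and left unassigned. Full and framework maps are compared by a
two-sample Kolmogorov-Smirnov test (asymptotic p) on adjacent-gap
distributions plus the fraction of gaps below 1 cM.

Gene-space statistics partition chromosomes into half-open 5 Mbp bins
(last bin truncated); every feature counts once, in the bin containing its
start. Rank correlations between per-bin counts use mid-rank ties and the
t approximation for p. Nearest-gene distances are 0 on any overlap,
otherwise the gap to the closest gene on the same chromosome, strands
ignored; probes on chromosomes without genes are excluded and counted, and
probes with two retained placements contribute each placement.

## Numerical choices and problem sizes

Golden-section tolerance for r is 1e-6 with explicit boundary checks so
that r = 0 is attainable exactly; class probabilities are floored at
1e-12 inside logs; the WLS system carries a 1e-8 ridge so co-located
markers (zero gaps) remain solvable; min-plus closure assigns 200 cM to
disconnected remnants. Test and acceptance simulations use 11 chromosomes
x 100 markers at n = 177 for the study-scale checks, 3 chromosomes for
the noisier order/length recovery checks, and genomes of a few hundred
kbp for sequence-level checks - sizes chosen so the full suite exercises
every stage at realistic marker densities while remaining comfortably
reproducible on a laptop.

## Known limitations

* Two-point only: no multipoint likelihood, no sex-specific maps, no
  segregation-distortion modeling (distorted markers are excluded
  upstream).
* The Kosambi-on-Haldane discrepancy biases recovered lengths ~5-8%
  short at the default marker density; applications needing absolute
  lengths should treat the mapping-function choice as a parameter.
* The clustering engine verifies pairs by a single ends-free alignment;
  it does not model chimeric probes, and extremely divergent true
  duplicates (beyond the preset's identity floor) are intentionally
  split.
* The built-in aligner is for synthetic scale; it makes no attempt at
  the heuristics or throughput of a production read aligner.
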