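---
title: "Methods: from PCR-level eDNA counts to co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from PCR-level eDNA counts to co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednanet)
```

## Scope and data model

`ednanet` analyses multi-marker eDNA metabarcoding surveys of the kind used
to profile lake biodiversity across trophic levels: separate PCR assays per
marker group (here cyanobacteria 16S, diatom rbcL, invertebrate COI,
vertebrate 12S), triplicate PCRs per DNA extract, and negative-control PCRs
in every run. The raw input is a PCR x OTU table of read counts plus sample
metadata (lake, habitat, column, depth stratum, replicate, marker). Upstream
read processing (demultiplexing, denoising, clustering, taxonomy databases)
is out of scope; the pipeline starts from counts.

Two derived matrices drive all statistics:

* **RRA** (relative read abundance): an OTU's reads divided by the total
  reads of its PCR, averaged over the sample's retained replicate PCRs.
* **Incidence**: 1 when the OTU has a nonzero post-filter count in at least
  one replicate PCR of the sample.

## Preprocessing chain

The filter order is fixed and each rule is exactly thresholded:

1. **Negative-control subtraction.** Within each PCR run (marker x lake),
   the maximum NC count of each OTU is subtracted from every sample PCR,
   clamped at zero. Clamping is standard practice; counts cannot go
   negative.
2. **Low-count zeroing.** Cells with fewer than 5 reads are set to zero.
   We read the rule as per-cell (it is stated per PCR), not as study-wide
   OTU deletion; `min_otu_reads` is configurable.
3. **Shallow-PCR removal.** PCRs with totals below the marker threshold
   (100 reads; 500 for invertebrates) are dropped, boundary inclusive.
4. **Optional OTU exclusion** (e.g. livestock sequences), applied after the
   depth filter and before RRA, mirroring the order in which such lists are
   usually applied; PCRs emptied by exclusion are dropped and reported.
5. **RRA and replicate collapsing.** Per-PCR RRA rows sum to one by
   construction; samples whose replicates were all removed are dropped with
   a warning rather than an error, since field studies routinely exclude
   low-yield samples.

Re-applying the count filters to already-filtered data changes nothing, and
total reads never increase at any stage; both properties are tested.

## Diversity and ordination

Alpha diversity uses Hill numbers: `q = 0` richness, `q = 1` the exponential
of Shannon entropy (limit form, `0 log 0 = 0`), `q = 2` inverse Simpson.
Hill numbers are non-increasing in `q`, which the suite checks as a
property. Beta diversity uses Jaccard on incidence and Bray-Curtis on RRA
(through `vegan::vegdist`). Ordination is classical PCoA
(`stats::cmdscale`); negative eigenvalues are dropped from both the
coordinates and the proportion-explained denominator — no Cailliez or
Lingoes correction, since a correction would change the printed proportions
without changing the ordination's use here.

PERMANOVA is one-way with free permutation of rows, testing one factor at a
time (lake, habitat, depth, column); there is no strata/blocking support.
The pseudo-F comes from distance-based sums of squares. When the number of
distinct label arrangements is at most 10,000 the null is enumerated
exhaustively and the p-value is exact; otherwise 999 random permutations
are drawn (`p = (hits + 1) / (n + 1)`). The switch point keeps desk-scale
analyses deterministic. Rank tests are `stats` wrappers: Wilcoxon rank-sum
(exact for combined n of 12 or less without ties, tie-corrected normal
approximation otherwise), Kruskal-Wallis (tie-corrected, with the
all-values-tied case defined as H = 0), and Benjamini-Hochberg adjustment.

## Indicator taxa

SIMPER decomposes mean between-group Bray-Curtis dissimilarity into per-OTU
contributions (`|x_i - y_i| / sum_j (x_j + y_j)` averaged over between-group
pairs); the contributions reconstruct the mean dissimilarity to 1e-10 by
construction, and no permutation significance is computed. The
specificity-occupancy rule flags OTU S as a specialist of habitat H when
specificity (share of S's mean abundance in H, zeros included) and occupancy
(fraction of H's samples where S occurs) are both at least 0.7, boundaries
inclusive. The habitat grid defaults to lake x habitat in the pipeline and
is configurable to any label.

## Co-occurrence networks

Per network context (lake x habitat), OTUs of the cyanobacteria, diatom and
invertebrate markers are combined (vertebrate eDNA disperses too far from
its source to support co-occurrence inference). Combining keeps each OTU's
within-marker RRA scale; Spearman statistics are rank-based per OTU, so the
per-marker compositional closure does not affect the correlations. OTUs
enter the correlation step only if their mean RRA is at least 0.01% and
they occur in at least 30% of the context's samples, both inclusive.

Edges require `|r| >= 0.75` (inclusive) and BH-adjusted `p < 0.05` (strict),
with the BH family being all unique OTU pairs within one context; contexts
are corrected independently. p-values use the t-approximation on n - 2
degrees of freedom. Isolated nodes are dropped. Modules come from Louvain
maximisation on `|r|` weights with a fixed seed (the algorithm is not
specified in the literature this mirrors; Louvain at resolution 1 is the
common default), and Q is Newman's modularity of the returned partition.
Average path length is taken over connected pairs, with the number of
unreachable pairs reported, since thresholded networks are routinely
disconnected.

**Cohesion** follows the simple formulation: an OTU's positive (negative)
connectedness is the mean of its positive (negative) correlations in the
full prefiltered correlation matrix — not only the correlations surviving
the edge filter, though `edges_only` switches to that — and a sample's
positive (negative) cohesion is the RRA-weighted sum of connectedness. This
is deliberately *not* the null-model-corrected cohesion of Herren &
McMahon (2017); the simple variant is what the surveyed analyses compute.
The negative:positive ratio is |negative| / positive, undefined (NA) when
positive cohesion is zero.

**Zi-Pi roles** use unweighted degree: Zi is the within-module degree
z-score (0 for singleton or zero-variance modules) and
`Pi = 1 - sum_m (k_im / k_i)^2`. Roles follow the (2.5, 0.62) quadrants:
network hubs (Zi > 2.5, Pi > 0.62), module hubs (Zi > 2.5, Pi <= 0.62),
connectors (Zi <= 2.5, Pi > 0.62), peripherals otherwise.

## The synthetic community generator

No public read-level data accompanies desk-scale validation, so the
generator stands in for raw data with the standard compositional
metabarcoding assumptions:

* latent abundances are log-normal: per-OTU baselines
  `N(log_mean, log_sd^2)` plus per-sample deviations that are multivariate
  normal with a block correlation structure (the planted modules;
  `rho_within` inside blocks, `rho_between` elsewhere);
* habitat specialists multiply their latent abundance by `fold_enrichment`
  in the preferred habitat, optionally with a baseline offset;
* read counts are multinomial per PCR with negative-binomial total depth
  (mean 2e4 within the 1e4-4e4 per-PCR range such surveys retain;
  dispersion 5 so the depth filter is occasionally exercised), Bernoulli
  dropout per cell (0.02), and independent Poisson contamination in
  negative controls (mean 0.5 reads per OTU, matching the low NC counts
  such surveys report).

The default study reproduces the two-lake design: CRL with 40 water samples
(12 columns x 4 strata, deepest strata of the last columns omitted) plus 14
sediments, MCL with 36 water plus 11 sediments, triplicate PCRs, 3 NCs per
run. Marker richness defaults to 40/60/80/15 OTUs — deliberately desk-scale
rather than the thousands a real survey yields — so the full pipeline and
its tests run in seconds while every code path (filters, networks, role
classification) is still exercised.

What the generator does *not* emulate: primer bias and amplification
efficiency differences, chimeras, tag jumps beyond what the low-count
filter absorbs, taxonomy assignment error, spatial autocorrelation along
columns, and any real ecological process beyond the planted structure.
Passing recovery tests therefore demonstrates that the chain of estimators
is consistent with its own generative assumptions — not that those
assumptions hold in any particular lake.

## Validation experiments and their design

Two planted-truth experiments back the recovery claims
(`specialist_recovery_experiment()`, `module_recovery_experiment()`):

* **Specialists**: balanced 20 water + 20 sediment samples, 60 OTUs, three
  specialists per habitat at 50-fold enrichment with baseline offset
  `log(0.02)`, depth 1e5. Two design choices matter and were made for
  stated reasons. First, balance: unequal habitat sizes make one habitat's
  mean abundance noisier and inflate spurious specificity. Second, the
  offset and depth: an enriched specialist should sit at parity with a
  typical OTU inside its habitat (not dominate the closed composition,
  which would push every *other* OTU's specificity toward the opposite
  habitat), and the depth must saturate occupancy so that the experiment
  scores the 0.7/0.7 rule rather than sequencing effort — at shallow depth
  a specialist whose baseline draw lands 2-3 sd low can fall under the
  5-read cell filter and lose occupancy in its own habitat.
* **Modules**: 50 samples, 30 OTUs, three blocks of six at
  `rho_within = 0.95`, full chain (prefilter, Spearman, BH, `|r| >= 0.75`,
  Louvain), scored by adjusted Rand index against the planted blocks; a
  block-free run of the same generator measures the null edge count.

With the defaults, specialist recovery is ~99% with ~4% false positives,
module recovery reaches ARI 1.0 in most seeds, and null runs produce
(near-)empty networks. These numbers are recomputed, never asserted as
constants, by the test suite and by `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Subtraction clamps at zero; all boundaries follow the printed rules
  (`>=` for 5/100/500/0.01%/30%/0.7/0.75, `<` for alpha).
* Spearman on zero-variance OTUs is NA and can never form an edge; an OTU
  absent everywhere has undefined (NA) specificity rather than 0/0.
* PERMANOVA with zero within-group variance reports an infinite F; with a
  totally flat distance matrix every permuted F ties the observed one and
  p = 1. Permutation ties are compared with a 1e-12 relative tolerance.
* All-tied rank tests return their degenerate null values (H = 0, p = 1)
  instead of NaN.
* Louvain runs under a caller-supplied seed with the caller's RNG state
  restored afterwards; identical seeds give identical partitions.

## Known limitations

* Spearman co-occurrence on compositional RRA is used as-is to mirror the
  analyses this package reproduces; compositionality-aware estimators
  (SparCC, SPIEC-EASI) are explicit non-goals.
* PERMANOVA is one-way only; nested or blocked designs need external tools.
* SIMPER reports contributions without permutation significance.
* The generator's truth is defined on latent abundances; recovery metrics
  inherit its assumptions (see above).
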