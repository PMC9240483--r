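---
title: "Mapping QTL from bulked-segregant sequencing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QTL from bulked-segregant sequencing: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

## The experimental design this package analyzes

Bulked segregant analysis (BSA) locates quantitative trait loci (QTL) by
sequencing two pooled DNA samples drawn from the phenotypic extremes of a
segregating population, together with the two inbred parents of the cross.
The motivating design is an F2 population of 1,307 rice plants segregating
for grain length, from which the 50 longest-grain individuals form the
L-pool and the 50 shortest the S-pool, sequenced at roughly 70–83x per
pool and 31–38x per parent. At a marker linked to a selected QTL, the
pools' allele frequencies are pulled in opposite directions; away from any
QTL both pools sample the same 1:2:1 F2 segregation and their frequencies
agree up to sampling noise.

Two per-site statistics quantify that skew. With `Laa`/`Saa` the L-pool
reads supporting the L-parent and S-parent alleles, and `Lab`/`Sab` the
same for the S-pool:

* **SNP-index** per pool, `SNPindex(aa) = Laa / (Laa + Saa)` and
  `SNPindex(ab) = Lab / (Lab + Sab)`, and their difference
  `dSNP = SNPindex(aa) - SNPindex(ab)`, which is 0 under the null and
  approaches ±1 at a fully selected locus. This statistic requires
  *orientation*: each allele must be assigned to a parent, which is only
  possible where the parents are homozygous for different alleles.
* **Euclidean distance (ED)**,
  `ED = sqrt(sum_b (f_aa(b) - f_ab(b))^2)` over the four bases
  `b in {A, C, G, T}`, where `f` are per-pool base read frequencies. ED
  needs no parental orientation and is 0 exactly when the pools' frequency
  vectors coincide; for a biallelic site it equals `sqrt(2)` times the
  absolute allele-frequency difference (an identity the test suite checks
  against the general formula). Before window fitting the distance is
  raised to a power (default `k = 2`, i.e. the squared distance), which
  shrinks genome-wide background noise relative to true peaks. `k` is a
  configuration knob; some pipelines use higher powers, but the default
  here is the quadratic.

## Per-track filtering with auditable ledgers

Each statistic has its own filter, applied to the same input table, and
each filter reports a ledger in which every input site is counted exactly
once — retained, or removed under exactly one reason. Because overlapping
reasons are possible (a multi-allelic site may also be shallow), counts
depend on the order reasons are tested; the package fixes one precedence
per track and documents it, so ledgers are reproducible and the partition
property `retained = total_in - sum(removed)` holds on every run (this is
property-tested).

* SNP-index track: `multi_allelic` (more than one ALT),
  `identical_in_bulks`, `low_depth` (either pool's depth < 4 reads),
  `parent_uninformative` (site cannot be oriented), in that order.
* ED track: `low_depth` (any pool < 4 reads), `identical_in_bulks`
  (identical base-frequency vectors, tolerance 1e-9), `multi_aligned`
  (more than one ALT). The parents are deliberately not consulted.

"Identical in the two bulk pools" has no universal operational definition,
and the choice matters. We define it for the SNP-index track as *equal
allele read fractions at integer-depth resolution* (tolerance 1e-9),
which removes exactly the sites carrying no between-pool signal. An
alternative we implemented and rejected — calling each pool's genotype by
thresholding its read fraction at 0.25/0.75 and removing sites whose calls
agree — removes nearly every site at realistic pool depths (~70x) under
the null, because both pools of a segregating F2 are called heterozygous
almost everywhere; the surviving sites are then a biased selection of
sampling extremes and the scan's null calibration collapses. The
thresholded calls are still computed and exposed (`call_aa`, `call_ab`)
as descriptive columns.

Parental read depths are never filtered — only parental *genotypes* are
used, to orient alleles — and no quality-score filtering is applied; the
package assumes an upstream caller has produced a final SNP set.

## Sliding-window fitting

Per-site statistics are noisy at 70x; both tracks are therefore fitted in
1-Mb windows advanced in 10-kb steps (defaults; any `window_size >= step`
is accepted). Windows start at 1, 1 + step, ...; a window is emitted while
its start lies on the chromosome and trailing windows are truncated at the
chromosome end. Two fit methods are exposed:

* `mean` — the unweighted average over the sites in the window (the
  default for the delta SNP-index track), tested for exact equality
  against an independent brute-force implementation;
* `distance_weighted` — a tricube-kernel average with weights
  `(1 - (d/h)^3)^3`, `d` the distance from the site to the window center
  and `h` half the window size, used by default for the powered-ED track.
  A distance-weighted fit concentrates the window's evidence at its
  center, which sharpens peaks relative to the flat mean.

Each window's fitted value is attributed to the window's **center**
coordinate. This is a deliberate design choice with three consequences we
rely on: (i) called regions span window centers, so their endpoints land
on the step grid and a single-window run is a point-like region; (ii)
runs of above-threshold windows separated by even one below-threshold
window yield disjoint regions (no gap bridging, and no overlap between
regions of one track); and (iii) peaks localize correctly — anchoring a
window's value at its left edge would systematically shift called regions
half a window away from the causal locus. Centers of trailing truncated
windows keep their nominal (uncapped) value so they stay distinct and
grid-aligned. Windows containing no sites are marked missing, never
zero-filled, and are excluded from all threshold computations.

## Significance thresholds

**Delta SNP-index.** There is no analytic null at finite bulk size and
depth, so the package simulates one: in each Monte-Carlo replicate, each
pool's allele frequency is the mean of `2 * bulk_size` Bernoulli(1/2)
draws (free F2 segregation among the pooled chromosomes), read counts are
Binomial(depth, frequency), and the threshold at level `q` is the `q`
quantile of `|dSNP|`. Defaults report the 90/95/99% envelope from 10,000
replicates (100,000 in the reproduction script); at least 1,000 are
required. Envelope thresholds shrink as depth or bulk size grow
(property-tested on a grid), and the delta track is compared against the
envelope two-sidedly, on `|fitted|`.

**Powered ED.** Two genome-wide constructions are provided:
`median + 3 * SD` of all non-missing fitted values (sample SD, n−1
denominator) for a broad scan, and the empirical 99% quantile (linear
interpolation between order statistics, R's type 7 — the interpolation
rule is part of the contract since "a 99th percentile" is otherwise
ambiguous) to refine broad signals to their strongest windows. The
median-based rule is deliberately robust: the median and (at genome
scale) the SD are barely moved by a single QTL's windows, so the
threshold tracks the noise floor.

The pipeline calls delta regions at the 99% envelope, ED regions at the
99% quantile, and reports their interval intersection as the candidate
set; with defaults the quantile threshold is the stricter ED criterion,
and the broad `median + 3 SD` regions are reported alongside. Candidate
regions may be annotated with gene counts from a GFF3 annotation, where a
gene is counted if it overlaps a region by at least one base pair (closed
1-based intervals). Region length is reported as `(end - start) / 1e6`
Mb — the endpoint convention, under which published BSA-seq interval
lengths are reproduced exactly from their printed endpoints and a
point-like region has length 0.

## The simulator: what it emulates, and what it does not

`simulate_bulk_sites()` generates the entire experiment with known ground
truth:

1. **Meiosis.** Gametes follow the Haldane model: crossover counts are
   Poisson with mean equal to the map length in Morgans, positions are
   uniform on the genetic map, and there is no interference. The map is
   linear at `recomb_rate_cM_per_Mb` (default 4 cM/Mb, a typical rice
   density). The two-marker recombination fraction therefore follows
   Haldane's map function `r = (1 - exp(-2d))/2`, which the test suite
   checks by simulation.
2. **Phenotype.** A single additive biallelic QTL: phenotype
   `= mu + a (g - 1) + e` with `g` the L-allele count at the QTL marker
   and `e` Gaussian. Given a target proportion of variance explained
   (`pve`, default 0.5485) and a total phenotypic SD (default 1.43 mm
   around a 10.2 mm mean, chosen so the simulated F2 spans roughly the
   7–13 mm grain-length range of the motivating cross), the additive
   effect is `a = sqrt(2 * pve) * sd` since the additive variance under
   1:2:1 F2 frequencies is `a^2 / 2`. No dominance and no second QTL are
   modeled.
3. **Bulks.** The `bulk_size` largest and smallest phenotypes (default
   50 of 1,307). Ties are broken by ascending individual index, L-pool
   first, S-pool from the remainder, so selection is deterministic and
   the pools are always disjoint.
4. **Reads.** Per site and pool, total depth is Poisson (default mean
   70x per bulk, 35x per parent) and allele reads are binomial at the
   pool's true allele frequency, with a symmetric per-read error (default
   0.001). A configurable fraction of sites is emitted as
   parent-uninformative (default 5%) or multi-allelic (default 1%) noise
   so the filters have realistic material to remove.
5. **Output.** An oriented site table, or a four-sample VCFv4.2
   (`GT:AD:DP`) plus a JSON truth manifest; identical seeds give
   byte-identical VCFs.

The simulator is a model of the *statistical design*, not of sequencing
chemistry: it does not emulate mapping bias, duplicated or repetitive
regions, base- or mapping-quality variation, indels, depth
overdispersion beyond Poisson, or linkage disequilibrium structure other
than that induced by meiosis. Passing validation on simulated data
therefore demonstrates that the statistics, thresholds and region logic
behave as specified under the design assumptions — not that any
particular real dataset satisfies those assumptions.

## Validation scale and reproduction

The package validates itself at desk scale: three 30-Mb chromosomes with
20-kb marker spacing (~4,500 markers), the full population of 1,307
individuals, 20 seeded replicates per scenario. At this scale the no-QTL
scenario yields essentially no windows above the 99% envelope and no
intersection regions, while the `pve = 0.5485` scenario localizes the
simulated QTL's argmax window within 2 Mb and covers the true position
with the intersection region in at least 18 of 20 replicates — the
acceptance suite (`tests/testthat/test-acceptance.R`) and
`scripts/acceptance.R` recompute all of this from scratch. Chromosome
count and length are configuration, not constants; the defaults keep a
full two-track scan around a few seconds.

## Numerical and degenerate-input contracts

* Division by zero is an error, never NA/0: zero-depth sites must be
  removed by the filtering stage before statistics are computed.
* Frequency vectors are validated to sum to 1 (tolerance 1e-6);
  identity comparisons use 1e-9.
* Quantile levels must lie strictly inside (0, 1).
* Empty site tables, all-missing tracks, unsorted site positions and
  unsorted or overlapping region inputs are errors, not silent repairs.
* One RNG stream per pipeline stage is derived from the master seed, so
  changing the envelope replicate count does not perturb the simulated
  data, and every documented output is deterministic under a fixed seed.

## Known limitations

* The SNP-index track discards parent-uninformative sites by design; in
  crosses with many such sites the ED track retains more information.
* The Monte-Carlo envelope conditions on a single representative depth
  per pool (the pipeline uses each pool's mean depth) rather than
  per-site depths; at extreme depth heterogeneity the envelope is
  approximate.
* "Multi-allelic" stands in for read-level multiple alignment, which is
  not observable from a called VCF.
* Interval arithmetic assumes one reference genome; no liftover or
  coordinate harmonization is provided.
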