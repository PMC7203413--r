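---
title: "Transmission genetics of autotetraploid backcross populations"
author: "tetrabc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission genetics of autotetraploid backcross populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrabc)
```

## The problem

*Sorghum halepense* (Johnsongrass) is a natural tetraploid (2n = 4x = 40)
derived from hybridization of *S. bicolor* and *S. propinquum*. Crosses of a
colchicine-doubled tetraploid *S. bicolor* inbred to a tetraploid
*S. bicolor* × *S. halepense* F₁ hybrid produce BC₁F₁ populations in which
every segregating donor allele traces back to the F₁'s four homologs.
`tetrabc` models how such alleles are transmitted, builds genetic maps from
GBS genotypes, tests for segregation distortion, and classifies hybrid
alleles by progenitor origin.

## Polysomic segregation and double reduction

A tetraploid transmits two of its four homologous chromosomes (or, with
recombination between locus and centromere, two of its eight chromatids) to
each gamete. Write the F₁'s donor-allele dosage as *d* ∈ {0,…,4}; a gamete
then carries 0, 1, or 2 donor copies. The *double-reduction* coefficient α
is the probability that a gamete receives two chromatids of the *same*
homolog — possible only after a locus–centromere crossover. Three classical
models fix α:

| model | α | simplex (d = 1) het:hom | duplex (d = 2) het:hom |
|---|---|---|---|
| random chromosome | 0 | 1:1 | 5:1 |
| random chromatid | 1/7 | 13:15 | 11:3 |
| maximum equational | 1/6 | 11:13 | 7:2 |

For a simplex locus the gamete dosage distribution is
(p₂, p₁, p₀) = (α/4, (1−α)/2, 1/2 + α/4); for a duplex locus it is
((1+2α)/6, (4−4α)/6, (1+2α)/6); dosages 3 and 4 follow by allele-swap
symmetry. In a backcross to an inbred recurrent parent (null gamete), a
progeny is heterozygous iff the F₁ gamete carries a donor allele, so the
expected het:hom ratio is (1−p₀)/p₀. `gamete_dosage_distribution()` holds
the closed forms and `enumerate_chromatid_gametes()` rederives them by
exhaustive enumeration (6 homolog pairs; 28 chromatid pairs; 24
non-sister-unit chromatid pairs averaged over the 3 bivalent pairings), so
each route checks the other:

```{r ratios}
(1 - enumerate_chromatid_gametes(2, "random_chromosome")$p0) /
  enumerate_chromatid_gametes(2, "random_chromosome")$p0
expected_bc1_ratio(2, "max_equational")
```

## The simulator: what it emulates, and what it does not

`simulate_bc1_population()` performs full multilocus meioses: per meiosis
one of the three bivalent pairings is drawn uniformly, crossovers fall as a
no-interference Poisson process (Haldane) on the cM scale, and the gamete
takes one recombinant chromatid per bivalent. This mechanism realizes
α = 0 at every locus; α > 0 is available only in the single-locus
(unlinked) mode, because modelling double reduction *jointly* with linkage
requires chromatid-level exchange bookkeeping that the data this package
targets cannot discriminate anyway. Crossover interference is not modelled
(no interference model is implied by backcross two-point data).

`simulate_gbs_vcf()` adds the read layer: depth ~ Poisson(mean), alt reads
~ Binomial(depth, f′) with f′ the dosage fraction perturbed by a per-read
error rate, and *diploid-style* 3-value PL fields (alt fraction 0, 1/2, 1),
deliberately mimicking a diploid caller applied to tetraploid samples —
GBS coverage does not resolve heterozygous dosage, so presence/absence is
the usable signal. The simulator does **not** emulate restriction-site
sampling, read mapping, allelic dropout correlated across loci, or index
hopping; passing tests on simulated data therefore validate the arithmetic
of the pipeline, not the error structure of any particular sequencing
platform.

Default study conditions mirror the motivating populations: 141
individuals (the larger of the two published populations), ~50 markers per
chromosome, mean depth 30, per-read error 0.2%, and a simplex/duplex mix
exposed as a parameter (`dosages`) because the true dosage spectrum of an
F₁ hybrid is not observable from presence/absence data.

## Genotype calling

From a multi-sample VCF with PL/DP(/AD): sites are thinned to ≥ 100 bp
(greedy, per chromosome), restricted to biallelic SNPs with mean depth
≥ 10 (missing DP counts 0 — the published rule does not define the
denominator, and the all-samples mean is the stricter reading), and each
cell is called from PL: the minimum-PL genotype wins unless the
second-largest probability 10^(−PL/10) exceeds 0.05 (ambiguity), a
homozygous call has depth < 6 (an unsampled alt allele cannot be excluded),
or the minimum is tied. BB candidates are scored AB by default
(`bb_policy`): in this backcross the alt allele's presence is the datum.
Markers with > 30% missing or no polymorphism are dropped; individuals
whose call rate falls below 20% are removed — failed GBS libraries are
conventionally discarded without a fixed published cutoff, so 0.2 is this
package's default and it is configurable.

## Map construction

Two-point rf on presence/absence coding treats every marker as a diploid
backcross marker — a biased proxy for duplex markers, used deliberately so
that simplex and duplex markers can coexist in one framework. Grouping is
single-linkage at LOD ≥ 10 with the extra requirement r̂ < 0.5, so that
markers co-distorted but unlinked cannot join; phase flips (r̂ > 0.5) are
recorded and the flipped orientation used thereafter. Binning merges
markers within 1 cM of provisional (physical-order) positions, filling
missing data by agreement or majority with ties set missing. De novo
ordering is a greedy nearest-neighbour chain seeded at the max-LOD pair,
polished by 2-opt reversals and single-marker reinsertion on the total
adjacent Kosambi length; tie-breaks are deterministic by (chrom, pos), and
the final orientation puts the physically first marker first, making
output order reproducible. Interval rfs are then re-estimated by EM over a
two-state hidden chain per individual with a genotyping-error emission
(default 0.01), and mapped through Kosambi d = 25·ln((1+2r)/(1−2r)).

Numerical choices: rfs are capped at 0.4995 before Kosambi so distances
stay finite; EM stops at relative log-likelihood change < 1e-6 or 100
iterations (non-convergence warns and returns the last iterate); intervals
between chromosomes inside one (pathological) group get a sentinel gap so
binning never merges across chromosomes.

Note a structural bias worth knowing: simulation is Haldane
(no interference) but distances are Kosambi, and the EM error model
absorbs part of the apparent recombination, so estimated lengths run
5–15% below the Haldane-consistent expectation. The recovery tests
therefore check order (≥ 95% adjacent pairs at the published ~5.5 cM
average spacing, n = 141) and length within ±20%, not exact equality.

## Segregation analysis

`chisq_ratio_test()` is the df = 1 goodness-of-fit X² against any
expected het:hom ratio. "Significantly higher than 5:1" is implemented as
the two-sided X² at α plus a direction filter (an exact one-sided binomial
is available via `method = "binomial"`), so the effective type-I rate of
the directional rule is roughly half the nominal level — the calibration
test checks the observed rate against the exact binomial probability of
the same decision rule rather than against α itself.

Linkage groups are classified by their average AB/AA ratio: > 1.82 donor
enriched, < 0.55 recurrent-parent enriched, boundary values balanced
(strict inequalities). These printed constants are kept as defaults;
`ratio_threshold_from_alpha(n, alpha)` gives the X²-derived counterpart
((√n + √c)/(√n − √c) with c the critical value), which yields ≈ 1.95 at
n = 105, α = 0.001 — close to but not equal to 1.82, so the constants are
treated as conventions, not derivations, and both are configurable.

Cross-population evidence combines by summing genotype counts before one
X² ("pooling"), with Fisher's method as an alternative; regions of
distortion are maximal chains of ≥ 3 flagged markers with inter-marker
gaps ≤ 5 Mb — a gap rule chosen to match the 1–6 Mb scale of reported
distorted regions and exposed in the config.

## Progenitor ancestry

After a Q20 / depth-10 / 30%-missing site filter, each target allele is
labelled *bicolor* (reference), *propinquum* (non-reference allele carried
by the propinquum accession(s)), or *novel*, giving site categories B, P,
H_BP (one allele from each progenitor), H_PM (propinquum/novel — reachable
at multi-allelic sites), and N_M (novel present, no propinquum evidence;
heterozygous reference/novel also lands here). A control accession
polymorphic against the reference makes the site UNKNOWN, as do missing
genotypes; with two propinquum accessions, disagreement is UNKNOWN by
default (`propinquum_consensus = "all"`). Proportions are reported over
non-UNKNOWN sites. Runs of ≥ 3 consecutive propinquum-derived sites are
reported with first/last-site bp, and `run_coverage()` merges overlaps
before dividing by genome length.

## Problem sizes used by the test suite

Simulation-backed tests run at n = 141 individuals with 40–50 markers per
chromosome (order recovery at 270 cM, the published average spacing), 10⁵
meioses for single-locus convergence checks, and 10⁴ null markers for the
type-I calibration; the whole suite completes in well under a minute.
These sizes are the package's choices for stable Monte-Carlo margins (3
SE convergence bands, 2 SE calibration band) at desk scale.

## Known limitations

- Double reduction and linkage are never modelled jointly.
- Presence/absence rf is biased for duplex markers; group-level ratios,
  not marker dosages, carry the duplex signal.
- The ordering heuristic optimizes adjacent length only; it is not a
  multipoint maximum-likelihood order, and at < 3 cM spacing with n ≈ 141
  local swaps become possible.
- Ancestry classification is site-wise; no recombination-aware local
  ancestry smoothing is attempted.
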