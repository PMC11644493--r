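---
title: "Methods: dissecting selection on miRNA target sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting selection on miRNA target sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsel)
```

## The problem

Plant microRNAs bind their target mRNAs with near-perfect complementarity,
so a binding site is a short (about 21 nt) stretch of sequence whose fate
under selection is directly observable in population resequencing data.
`mirsel` analyzes phased population alignments of miRNA target loci from
cultivated rice (*indica*, temperate and tropical *japonica*) and its wild
relatives (*O. rufipogon*, *O. nivara*), with *O. barthii* as outgroup, and
asks two questions: are binding sites of deeply conserved miRNA families
depleted of variation relative to their flanks (purifying selection), and do
rice-specific binding sites instead carry an excess of high-frequency
derived variants (positive and/or artificial selection during
domestication)?

## Target filtering

A candidate site is aligned antiparallel and end-to-end to the mature miRNA
(`pair_profile()`), allowing at most one indel; among equal-penalty
placements the gap is put closest to the miRNA 3' end, where plant pairing
tolerates distortion. `evaluate_filter()` then applies the empirical rules:
no mismatch at positions 10–11 (the cleavage site), at most one mismatch at
positions 2–12, no more than two consecutive mismatches downstream of
position 13, and fewer than 5 mismatches overall, with G:U wobbles counted
as mismatches for the rules.

The numeric score underlying the cutoff of 3 is not defined by a published
formula, so the package adopts the standard plant-target scheme (mismatch
1.0, G:U 0.5, gap 1.0) and reports both the score and the rule verdicts so
the choice can be audited. Whether "downstream of position 13" includes
position 13 is ambiguous; the package defaults to inclusive and exposes
`downstream_inclusive = FALSE`.

## Diversity statistics

`diversity()` computes the number of segregating sites $S$, nucleotide
diversity $\pi$ (mean pairwise difference proportion), and Watterson's
$\theta_W = S/(a_{n-1} L)$ with $a_{n-1} = \sum_{j=1}^{n-1} 1/j$, after
*complete deletion* of columns containing `-` or `N` — matching the
convention of standard polymorphism software where indels are excluded from
the analysis. The divisor is the post-deletion length, and per-kb figures
are per-site values times 1000. An indel-inclusive mode exists only for
SNP-density style counts. Divergence $k$ to the outgroup is uncorrected by
default (whether published values were multiple-hit corrected is unstated);
a Jukes–Cantor flag is available and only increases $k$.

`polarize()` orients alleles with the outgroup: a biallelic ingroup site is
polarized only when the outgroup carries one of the two ingroup alleles;
outgroup gaps, `N`s and third alleles leave the site unpolarized, and
haplotypes with more than three indel positions inside binding sites are
excluded before frequencies are computed.

## The shuffle null for window diversity

Low site diversity could reflect purifying selection or a mutational cold
spot. The resampling null (`resample_null()`) distinguishes them: a
dinucleotide-preserving Altschul–Erickson shuffle of the reference sequence
is realized as a permutation of *alignment columns* and applied uniformly to
every haplotype, so each SNP travels with its column. This is the only
reading consistent with restoring the original alleles after shuffling:
total $\pi$, $S$ and the site-frequency spectrum are exactly invariant, and
only the spatial arrangement of diversity changes. The replicate summary is
the mean 21-nt sliding-window $\pi$ over windows fully inside the site
(windows straddling the boundary are excluded), and the empirical p-value
uses the $(1 + \#\{null \le obs\})/(R + 1)$ estimator, which never returns
zero. The paper does not state its estimator or edge rule; these are the
package's documented defaults.

## Neutrality tests

`fay_wu_H()` computes the unstandardized statistic
$H = \theta_\pi - \theta_H$ with
$\theta_\pi = \sum_i 2\xi_i i(n-i)/(n(n-1))$ and
$\theta_H = \sum_i 2\xi_i i^2/(n(n-1))$; hitchhiking drives $H$ negative.
`h_test()` simulates the null with the built-in Hudson coalescent
conditioned on the observed $S$ (fixed-S mode, robust to misspecifying
$\theta$) and reports a one-tailed p toward negative $H$, the direction of
an excess of high-frequency derived variants.

`mlhka_fit()` implements the maximum-likelihood multilocus HKA test as a
Poisson approximation: $S_i \sim \mathrm{Pois}(k_i\,\theta_i\,a_{n_i-1})$
and $D_i \sim \mathrm{Pois}(\theta_i\,(T+1))$, with the selection parameter
$k_i$ fixed at 1 for reference loci. Putting $k$ on polymorphism only keeps
it identifiable against $\theta$; $(T+1)$ is the divergence mean in
coalescent units (outgroup lineage plus the expected ancestral contribution
with one outgroup sequence) — a documented modeling choice validated by the
simulation calibrations below, not by matching any particular program.
Rather than MCMC or generic multi-start optimization, the fit uses the
profile likelihood: given $T$, every $\theta_i$ has a closed-form MLE and
each selected locus is saturated, and the profile is concave in
$\log(T+1)$, so a single deterministic one-dimensional maximization is
exact. The likelihood-ratio statistic is referred to $\chi^2$ with one
degree of freedom per selected locus. Boundary cases ($S=0$ or $D=0$ at a
selected locus) are flagged in the fit.

## Duplex energetics

`duplex_mfe()` scores miRNA:target hybridization. The built-in engine is a
nearest-neighbor *duplex* model: intermolecular Watson–Crick stacking from
the bundled parameter table (`duplex_params()`; Xia et al. 1998 values at
37&nbsp;°C), a simple affine bulge/internal-loop penalty (3.0 kcal/mol
opening + 0.3 per unpaired nucleotide, loops up to 10 nt per strand),
duplex initiation (+4.09) and a terminal A:U penalty (+0.45). G:U pairs do
not pair in this engine, consistent with the filter treating wobbles as
mismatches; intramolecular structure is not modeled, which is where the
engine deliberately differs from a full cofold computation. Sequences that
admit no stabilizing duplex return the `NA` sentinel. An external
`RNAcofold` engine can be selected when the ViennaRNA binary is available.

Energies are made comparable across site lengths by Rehmsmeier's
normalization, `normalize_mfe()`: $en = e/\log_{10}(m\,n)$ where $m$ is the
target length and $n$ the miRNA length. Although the normalization is
sometimes printed with a leading minus sign, published normalized values
are negative and equal $e/\log_{10}(mn)$ at two decimals, which forces both
the sign convention and the base-10 logarithm used here. For a gapped
haplotype the printed ratios imply the target length counts the gap
character ($m = 22$ throughout), and the haplotype report follows that
convention. Rounding to two decimals happens only at the reporting layer.

`classify_variant()` assigns each site variant to the three-way scheme
(within an existing mismatch; match to a nondisruptive mismatch; match to a
disruptive mismatch) and calls the site fate (retained / lost / gained) by
re-running the filter on both profiles. Multi-variant haplotypes are
decomposed into single-variant steps against the reference, applied along
the miRNA.

## The synthetic-data generator

`simulate_dataset()` produces desk-scale datasets with the statistical
structure the analysis assumes, plus a truth ledger. Defaults are the study
conditions: a panel of 16 *indica*, 17 temperate *japonica*, 17 tropical
*japonica*, 5 *O. nivara* and 19 *O. rufipogon* haplotypes plus one
outgroup accession; 26 loci of 716 bp, each with one 21–22 nt binding site
(24 conserved, 2 rice-specific); wild diversity 5.19/kb (the genome-wide
wild background); a 36% bottleneck reduction in cultivated groups.

Per locus, one neutral Hudson genealogy is drawn over the whole ingroup
panel at the wild $\theta$. Domestication is emulated by *thinning*: each
segregating site reverts its cultivated carriers to the ancestral allele
with probability 0.36, giving the configured expected cultivated/wild
$\pi$ ratio without multi-population coalescent machinery. Purifying
selection is emulated by rejecting mutations that land in conserved sites
with probability $c = 0.95$ (sites are then nearly invariant, as observed);
sweeps by planting derived alleles at rice-specific sites at frequencies
drawn from 0.8–0.95, shared between cultivated and wild pools — mirroring
the observation that the high-frequency derived alleles of cultivars also
segregate in the wild ancestor. The outgroup is the ancestral sequence plus
Poisson substitutions at 0.005 per site, a realistic rice–*O. barthii*
distance on the order of the flanking divergence estimates. Gap columns can
be planted inside rice-specific sites to exercise the indel-exclusion rule.

What the generator does *not* emulate: population structure beyond the
thinning (all groups share one panmictic genealogy), recombination, linked
selection, realistic demography. Passing calibrations therefore show the
estimators and tests are correct under their own assumptions, not that real
rice data meet those assumptions.

## Numerical choices and problem sizes

Randomized checks use fixed seeds. The packaged calibrations run at sizes
chosen to keep the whole suite interactive on a single core: brute-force
diversity oracles on up to 12 haplotypes × 200 columns; coalescent moment
checks at 5000 replicates; Fay & Wu type-I error on 1000 neutral datasets
(n = 20, S-conditioned, 500 null replicates each); MLHKA type-I error and
k-recovery on 500 simulated 11-locus tables (10 reference loci + 1
candidate, $\theta = 5$, $T = 5$, true $k \in \{1, 5\}$); 100 seeded
shuffles across 50 random sequences; a 1000-replicate resampling null; and
200 full default-size datasets for generator recovery of the configured
wild diversity within 10%.

Ties and degenerate inputs: rank-sum comparisons use exact enumeration for
untied groups of at most 8 and the normal approximation with continuity
correction otherwise; identical groups return p = 1 by convention;
chi-square contrasts are run uncorrected on the 2×2 segregating /
non-segregating table. Monomorphic regions return $\pi = \theta_W = 0$; an
empty polarized spectrum gives $H = 0$ by contract and an undefined test
p-value.

## Known limitations

* The built-in duplex engine is validated by hand-summed oracles and
  monotonicity, not by reproducing published kcal/mol values, which were
  produced by a cofold computation including intramolecular structure.
* Exact published test p-values at the two variable loci require the
  deposited resequencing alignments and the identities of the ten neutral
  reference genes, neither of which is printed; synthetic reference loci
  stand in, and the pipeline reproduces the contrasts qualitatively.
* The background genome-wide diversity constants (3.20/5.19 per kb) are
  supplied configuration, never recomputed.
* One printed normalized-energy row (−36.85 → −13.76) is inconsistent with
  every other row of the same table ($e/\log_{10}(484) = -13.73$) and is
  treated as a misprint.

## A worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(sim_config(seed = 1))
report <- run_all(ds, h_reps = 1000, seed = 1)
report$table1        # class means with the background constants
report$reductions    # percent diversity reduction per site class
report$table3_tests  # Fay & Wu H and MLHKA p-values per taxon
```
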