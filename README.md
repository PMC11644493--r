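# mirsel

Selection analysis of microRNA target sites in rice populations.

## What this package is for

Plant miRNAs recognize their target mRNAs through near-perfect
complementarity, so a binding site is a ~21-nt sequence whose evolutionary
fate is directly measurable in population resequencing data. `mirsel` is
for population geneticists who want to dissect the selective regimes acting
on such sites from phased per-locus alignments of cultivated rice
(*indica*, temperate/tropical *japonica*), its wild progenitors
(*O. rufipogon*, *O. nivara*) and an *O. barthii* outgroup: purifying
selection depressing diversity at binding sites of deeply conserved miRNA
families, versus positive/artificial selection elevating high-frequency
derived variation at rice-specific sites during domestication.

The core machinery:

* **Target filter** — antiparallel end-to-end pairing profiles
  (`pair_profile`) pushed through the empirical plant rules
  (`evaluate_filter`): no mismatch at positions 10–11, ≤ 1 mismatch at
  positions 2–12, ≤ 2 consecutive mismatches downstream of position 13,
  < 5 mismatches total, G:U counted as mismatch, score cutoff 3.
* **Diversity** — S, π (mean pairwise difference proportion),
  θ_W = S/(a₍n₋₁₎L) with a₍n₋₁₎ = Σ 1/j, divergence k to the outgroup,
  SNP density, 21-nt sliding windows, complete deletion of `-`/`N` columns
  (`diversity`, `divergence`, `sliding_pi`, `snp_density`).
* **Shuffle null** — an Altschul–Erickson dinucleotide-preserving shuffle
  realized as a column permutation applied uniformly to all haplotypes, so
  π, S and the SFS are exactly conserved and only the spatial arrangement
  is randomized (`dinucleotide_shuffle`, `resample_null`).
* **Neutrality tests** — Fay & Wu's H = θ_π − θ_H from the
  outgroup-polarized spectrum (`polarize`, `fay_wu_H`) with a fixed-S
  Hudson-coalescent null (`h_test`), and the maximum-likelihood multilocus
  HKA test with S_i ~ Pois(k_i θ_i a₍nᵢ₋₁₎), D_i ~ Pois(θ_i (T+1)) and a
  χ² likelihood-ratio test for locus-specific selection (`mlhka_fit`).
* **Duplex energetics** — a nearest-neighbor duplex engine plus
  Rehmsmeier's length normalization en = e/log₁₀(m·n), three-way variant
  classification and gain/loss calls (`duplex_mfe`, `normalize_mfe`,
  `classify_variant`, `haplotype_report`).
* **Synthetic data** — a generator emulating the resequenced panel
  (bottleneck thinning, conserved-site constraint, planted sweeps, outgroup
  divergence) with a truth ledger (`sim_config`, `simulate_dataset`), and
  an orchestration layer producing the standard report tables (`run_all`).

## Worked example

```r
library(mirsel)

# hand-checkable diversity on a toy alignment
diversity(make_fixture("toy_pi"), "pop1")
#> diversity_stats: n=4  S=2  pi=0.11667 (116.67/kb)  theta_W=0.10909  L=10/10

# a full synthetic panel at the study conditions, then the whole analysis
ds  <- simulate_dataset(sim_config(seed = 1))
rep <- run_all(ds, h_reps = 1000, seed = 1)

rep$table1
#>   population background_pi_per_kb conserved_pi_per_kb nonconserved_pi_per_kb
#> 1 cultivated                 3.20                   0                   38.2
#> 2       wild                 5.19                   0                   29.7

rep$reductions
#>           class pi_cultivated pi_wild percent_reduction
#> 1 rice-specific       0.00336 0.00463                27
#> 2     conserved       0.00265 0.00476                44

rep$snp_contrasts$chi_square_p
#> [1] 1.23e-20 1.23e-20
```

Reading the output: conserved binding sites are monomorphic
(`conserved_pi_per_kb = 0`) while rice-specific sites carry the planted
excess of high-frequency derived alleles (`38.2/kb` against the `3.20/kb`
cultivated background constant); whole-locus diversity in cultivated groups
is reduced relative to wild by roughly the configured bottleneck; and the
SNP-density contrast between site classes is overwhelmingly significant.
`rep$table3_tests` holds the per-taxon Fay & Wu H and MLHKA p-values,
`rep$table4_duplex` the per-haplotype duplex energies, e.g.

```r
normalize_mfe(-31.04, 22, 22)   # -> -11.56 at 2 decimals
```

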