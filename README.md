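# igcscan

Detection of interlocus gene conversion (IGC) signals from shared
polymorphisms in segmental duplications.

## The problem

Segmental duplications (SDs) are sequences of at least 1 kb with over
90% identity to another locus. During recombination, non-allelic
homologous pairing between SDs can copy a short tract from one paralog
onto the other (interlocus gene conversion). When the copied tract
spans a segregating allele, the same allele starts segregating at the
one-to-one aligned position of the paralog. The resulting signature in
population SNP data is a **parallelism**: a pair of SNPs at aligned
paralogous positions that segregate identical allele sets (after
strand adjustment).

`igcscan` is for population geneticists who want to call such
parallelisms from paralog alignments plus a SNP call set, separate
them from the two main confounders — mis-mapped short reads over
near-identical duplicates, and independent parallel point mutation —
and estimate the fraction of SD SNPs attributable to IGC.

## The method

1. **Align and mask.** Each SD pair is globally aligned (affine
   Needleman–Wunsch, EMBOSS-stretcher-like DNA scoring 5/−4, gap
   16 + 4k). Three masks remove untrustworthy columns: 100-column
   windows with pairwise sequence identity (PSI) more than 2 standard
   deviations below the alignment mean; columns whose centred 5-column
   sub-alignment has Hamming distance > 2 (gaps count); columns within
   10 of an indel and the first/last 100 columns.
2. **Classify aligned SNP pairs.** At pass columns where both paralogs
   carry a biallelic SNP, identical allele sets give a parallelism;
   allele-set unions of 3 or 4 bases give the alternative-allele
   classes (`alt3`, `alt4`) used by the mutation null. Minus-strand
   paralogs are complemented before comparison.
3. **Filter.** SNP calls supported only by redundantly mapping reads
   (`X0 > 1`, `X1 > 5`, or suboptimal placements fewer than 2
   mismatches worse than the best) are dropped per sample; a SNP
   survives if it maps uniquely in at least one sample. Parallelisms
   containing a CpG-dinucleotide SNP are conservatively excluded, since
   CpG hypermutability inflates parallel mutation.
4. **Group and estimate.** Shared-allele pairs are edges of a graph on
   SNP sites; connected components of dimension n ≥ 3 are higher-order
   parallelisms. The number of SNPs due to IGC is
   **Σₙ k(n−1)** over the observed counts k of n-dimensional groups
   (each group needs only one founding mutation).
5. **Null models.** Under equal mutation rates, parallel mutation
   yields identical alleles at one third of "two-hit" sites, so the
   mutation-only expectation is `alt3 / 2` parallelisms. Coalescent
   simulations conditioned on the observed segregating sites (strong
   recent growth, 2116 haplotypes) give the expected two-hit counts;
   permutation tests assess intra-chromosomal enrichment and
   population sharing (allele-frequency-matched); a chi-square window
   test measures clustering; clone-pool rules validate individual
   parallelisms (with ≥ 5 clones per site, a false heterozygote shows
   one allele with probability at most 2 × 0.5⁵ = 0.0625).

A fully labelled synthetic-data generator (`sim_config()`,
`simulate_cohort()`, `emit_fixture()`) produces paralog pairs at ~94%
identity with indels, growth-skewed population SNPs, injected IGC
tracts with ground truth, read-uniqueness metadata and clone pools, so
the whole pipeline is testable end to end against known events.

## Worked example

```r
library(igcscan)
cfg <- sim_config(seed = 7, ancestral_length = 10000, igc_rate = 0.01)
report <- run_pipeline(pipeline_config(sim = cfg, n_pairs = 4, n_perm = 200))
print(report)
```

```
IGC-detection pipeline report
                                                           tier n_parallelisms
                                                     No filters            107
                                         High quality alignment             97
                 Uniquely mapping SNPs + High quality alignment             97
 Non-CpG Sites + Uniquely mapping SNPs + High quality alignment             39
 n_snps_in_parallelisms n_sd_snps pct_sd_snps
                    214       713       30.01
                    194       650       29.85
                    194       650       29.85
                     78       260       30.00
IGC-derived SNPs (sum k(n-1)): 39 (15.00% of final-tier SD SNPs)
Mutation-only null: observed 39 vs expected 0.0 (ratio NA)
```

Four simulated 10-kb paralog pairs over 2116 haplotypes yield 107
candidate shared-allele pairs; alignment-quality masks trim these to
97, and the CpG exclusion (the generator elevates CpG mutation
10-fold) leaves 39 high-confidence parallelisms, i.e. 39 SNPs
attributed to IGC (15% of the surviving SD SNPs — the generator's
default IGC rate is deliberately high for a short region). No `alt3`
pairs arose here, so the mutation-only expectation is 0: the signal
cannot be explained by parallel mutation. The population-sharing
permutation test on the same report gives observed sharing 1.00 with
p ≈ 0.005 against 200 frequency-matched null datasets, as expected
when shared alleles are physically copied between loci.

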