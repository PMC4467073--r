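---
title: "Detecting interlocus gene conversion from shared paralogous polymorphisms"
author: "igcscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting interlocus gene conversion from shared paralogous polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igcscan)
```

## The model

Interlocus gene conversion (IGC) transfers a short sequence tract from
one segmental duplication (SD) to its paralog without reciprocal
exchange. If the donor tract spans a segregating allele, the acceptor
locus acquires the identical allele at the one-to-one aligned
position. `igcscan` detects the resulting *parallelisms* — aligned SNP
pairs with identical, strand-adjusted allele sets — and attributes
SNPs to IGC with the estimator

$$ N_{IGC} \;=\; \sum_{n=2}^{N} k_n\,(n-1), $$

where $k_n$ is the number of connected groups of $n$ paralogous SNP
sites linked by shared-allele pairs: each group requires only one
founding point mutation, and the remaining $n-1$ members are taken to
be IGC copies. The method cannot polarise donor versus acceptor; it
only counts how many SNPs owe their existence to conversion.

Two processes mimic this signal and are handled explicitly:

* **Read mis-mapping.** Over near-identical duplicates, short reads
  from one paralog can pile up on the other and produce a fake SNP
  whose "alleles" are the two paralogs' fixed bases — automatically a
  parallelism. The uniqueness filter keeps a sample's call only when
  every supporting read unit has a single best placement (`X0 = 1`),
  at most five suboptimal placements (`X1 <= 5`), and suboptimal
  placements at least two mismatches worse than the best; a SNP
  survives when at least one sample passes. Mate-pair rescue is
  assumed to be encoded upstream in the read units.
* **Parallel point mutation.** Two independent mutations at the same
  aligned position with identical ancestral bases produce identical
  derived alleles with probability 1/3 under equal rates (the
  Jukes–Cantor argument), and alternative alleles with probability
  2/3. The mutation-only expectation for the parallelism count is
  therefore half the observed number of three-base aligned SNP pairs
  (`alt3`). CpG-dinucleotide SNPs are excluded outright because CpG
  hypermutability concentrates parallel mutation there.

## Alignment-quality masking

All masking operates in alignment-column space. Pairwise sequence
identity (PSI) is defined as matching columns divided by columns where
both rows carry a base; gap columns enter neither numerator nor
denominator (the convention is a package decision — identity is
otherwise ill-defined against gaps).

* *Windowed PSI* (default window 100 columns, threshold mean − 2 sd
  over complete windows): removes locally mis-aligned or paralogy-
  violating regions. The window statistics are computed before any
  other mask, and a trailing partial window is ignored; whether edge
  trimming should precede the window statistics is genuinely open, and
  we fixed this order so the statistics use the maximum evidence.
* *Local Hamming* (5-column sub-alignment centred on each column,
  masked when distance > 2, gaps counting as mismatches): removes
  short misalignment islands. Columns with `N` in either row are
  masked under the same reason; ambiguity codes admit no allele
  comparison.
* *Indel proximity and edges*: ±10 columns around every gap run
  ("within 10 bp of an indel" is read as 10 alignment columns, since
  masking operates on columns) and the first/last 100 columns.

Masks are unioned; a column passes only when no reason applies. Adding
a mask can only shrink the pass set, so downstream counts are monotone
in mask stringency (a tested invariant).

## Coordinates and counting conventions

Internally every coordinate is 1-based inclusive (the R/IRanges
convention); the genomicSuperDups-dialect pair table and BED exports
use 0-based half-open coordinates, converted only at I/O.

"Parallelism count" means the number of shared-allele aligned pairs
(graph edges) after deduplication by unordered site pair across
redundant nested alignments; group dimension is the component's node
count. Survey tables for higher-order sets could count either edges or
components — both are reported (`n_parallelisms`,
`n_higher_order`), and the tier table uses edges.

Multi-allelic VCF records are skipped with a warning; the analysis is
defined for biallelic SNPs only.

## Null models and tests

* **Conditioned coalescent.** Replicates carry exactly S segregating
  sites on a locus of L discrete positions. Under the infinite-sites
  model conditioned on S, positions are uniform irrespective of
  demography, so the default mode samples S distinct positions
  uniformly without replacement — exactly equivalent and free of
  collision handling. A haplotype mode simulates the full tree under a
  single population with exponential growth (rate 920 entered at
  scaled time 0.0025, sample size 2116 haplotypes) by analytic
  inversion of the piecewise coalescent hazard, and drops S mutations
  with probability proportional to branch length. Expected
  parallelisms are mean two-hit counts divided by 3; the mean two-hit
  count matches the closed form $S_1 S_2 / L$ (a tested oracle).
* **Permutation tests** use the add-one empirical p-value,
  $p = (1 + \#\{null \ge obs\})/(1 + N)$, with N = 1000 by default, so
  p is never 0 and always at least $1/(1+N)$. Intra-chromosomal
  enrichment resamples the observed number of unique pass-mask aligned
  positions agnostic to variant status; the population-sharing test
  matches each member SNP's minor allele frequency within bins of
  width 0.02 (a package choice; empty bins fall back to the nearest
  occupied bin and are logged).
* **Clustering.** Parallelism counts in non-overlapping 1-kb windows
  are compared to the uniform expectation with a chi-square
  goodness-of-fit statistic on windows − 1 degrees of freedom; we read
  the reference chi-square distribution for this df as the intended
  test. Only alignments longer than 10 kb with more than 10
  parallelisms are tested, for power.
* **Clone validation.** With at least five clones per site, a true
  heterozygote shows a single allele with probability at most
  2 × 0.5⁵ = 0.0625; a parallelism is validated when both alleles
  appear at both sites, refuted when coverage suffices but either site
  is single-allele, insufficient otherwise.

## The synthetic-data generator

The generator's defaults are the study conditions the analysis
assumes, fixed once:

| knob | default | rationale |
|---|---|---|
| `target_psi` | 0.94 | average PSI of human SD alignments |
| `ancestral_length` | 10 kb | order of the average SD alignment length |
| haplotypes | 4 × 529 = 2116 | the surveyed cohort's haplotype count (1058 diploids) |
| `snp_density` | 0.0075 /bp | SD SNP density implied by ~1.2 M SNPs over 163 Mb |
| `indel_rate`, `indel_mean_len` | 5e-4 /bp, 3 bp | sparse short indels typical of high-identity SD alignments |
| `cpg_rate_multiplier` | 10 | order-of-magnitude CpG hypermutability |
| `igc_tract_mean` | 200 bp | geometric tracts; no published tract distribution exists, so this is a placeholder, not an inference |
| `igc_rate` | 0.01 /haplotype | deliberately high enough to make signals countable on kb-scale test regions |
| `intra_chrom_fraction` | 0.385 | intra-chromosomal share of SD alignments |

Derived-allele frequencies follow Beta(0.2, 2) clamped to
[1/(2N), 0.5] — a crude stand-in for super-exponential growth. Draws
below 1/(2N) are promoted to singletons rather than redrawn (an allele
that exists at all has frequency at least 1/(2N)); this keeps the
spectrum rare-allele heavy (≥ 60% of SNPs at MAF ≤ 0.05), which
resampling inside the interval would not. Populations are independent
labels with a geometric preference for single-population SNPs; there
is no migration model, no within-population recombination, no
structural variation, and no forward-time engine. Injected IGC copies
inherit one of the donor SNP's populations, so population sharing is
built into true signals the way physical transfer builds it into real
ones.

What passing tests therefore show: the detector recovers every
injected transfer whose site survives the masks, and its false-signal
rate matches the 1:2 mutation null on IGC-free cohorts *with this
statistical structure*. They do not show robustness to misalignment
from structural variation, population structure, genotyping error
models, or reference bias, none of which the generator emulates.

Reproducibility: every stochastic operation derives its seed from
`sim_config$seed` by fixed small offsets (pair = seed, SNPs = seed+1,
IGC = seed+2, fixture metadata = seed+3; cohort pair i uses
seed + 101·i), so each stage is individually reproducible and a fixed
config yields byte-identical fixtures.

## Numerical and degenerate-input choices

* Alignment scoring mirrors EMBOSS stretcher DNA defaults (match +5,
  mismatch −4); a gap run of length k costs 16 + 4k. Tie-breaking is
  delegated to the alignment backend and is deterministic.
* `target_psi` ≤ 0.5 is rejected (far outside the SD identity range);
  alignments shorter than one window skip PSI masking with a warning;
  a 150-column alignment is fully edge-masked by construction.
* An sd of 0 across windows (homogeneous identity) masks nothing; a
  single-window alignment likewise.
* Zero denominators yield `NA` percentages; empty group sets give an
  IGC count of 0.
* Percentages are rounded to 2 decimals to match survey-table
  conventions.

## Problem sizes used in the test suite

The bundled evaluation uses 20 pairs × 100 kb ancestral sequence
(2 Mb) for parameter recovery and null calibration, 1000 replicates
for the two-hit oracle, and 10⁵ draws for the one-third convergence
check; unit tests run on 1–10 kb fixtures. These sizes give
Monte-Carlo errors comfortably inside the asserted tolerances (the
2-Mb IGC-free cohort yields on the order of 100 two-hit sites, so the
observed:expected ratio has a standard error near 0.2, against an
asserted window of [0.7, 1.3]).

## Known limitations

* Donor/acceptor polarisation is out of scope by design.
* The fixture-driven path re-aligns sequences from scratch; near
  indels the optimal alignment can differ from the generator's true
  alignment, which is why indel-adjacent columns are masked rather
  than interpreted.
* The coalescent haplotype mode returns derived allele counts, not
  full genotype matrices, and models a single panmictic population.
* Diverged aligned bases (about 6% of columns at PSI 0.94) make the
  1/3 rule slightly conservative: at such columns parallel mutation
  produces identical allele sets with probability 1/9, so the
  dataset-wide expected ratio under the null is just below 1.
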