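#' Configuration for the synthetic paralog cohort generator
#'
#' Bundles every knob of the synthetic-data generator.  Defaults emulate
#' the statistical structure of human segmental duplications surveyed
#' with a large low-coverage population panel: paralog pairs around 94%
#' pairwise sequence identity with occasional indels, a growth-skewed
#' (rare-allele-heavy) frequency spectrum over 2116 haplotypes, CpG
#' hypermutability, and geometric IGC tracts.
#'
#' @param seed integer seed; a fixed config (including `seed`) yields
#'   byte-identical fixtures.
#' @param ancestral_length length in bases of the simulated ancestral
#'   duplication (>= 1000, the defining minimum length of a segmental
#'   duplication).
#' @param target_psi target pairwise sequence identity of the paralog
#'   pair, in (0.5, 1]; default 0.94, the average identity of human SD
#'   alignments.  Values <= 0.5 are rejected (far outside the >90%
#'   identity that defines segmental duplications).
#' @param indel_rate indel events per ancestral base (default 5e-4).
#' @param indel_mean_len mean indel length in bases (geometric; default 3).
#' @param n_populations number of population labels (default 4).
#' @param haplotypes_per_pop haplotypes per population (default 529, so
#'   the default cohort totals 2116 haplotypes, i.e. 1058 diploids).
#' @param snp_density segregating sites per base per paralog (default
#'   0.0075, the SNP density of duplicated regions in a low-coverage
#'   human panel).
#' @param cpg_rate_multiplier fold-elevation of the mutation rate at
#'   CpG-context sites (default 10), applied when
#'   `mutation_model = "cpg_elevated"`.
#' @param mutation_model `"cpg_elevated"` (default) or `"equal_rates"`.
#' @param igc_rate IGC events per haplotype (default 0.01).
#' @param igc_tract_mean mean IGC tract length in bases (geometric;
#'   default 200).
#' @param uniqueness_mismatch_threshold minimum number of inter-paralog
#'   mismatches within a 100-base window for reads over a SNP to be
#'   considered uniquely mappable (default 2).
#' @param intra_chrom_fraction fraction of simulated pairs placed on a
#'   single chromosome when generating multi-pair cohorts (default
#'   0.385, the intra-chromosomal share of SD alignments).
#' @return an object of class `sim_config`.
#' @seealso [simulate_sd_pair()], [simulate_cohort_snps()],
#'   [inject_igc_events()], [simulate_cohort()], [emit_fixture()]
#' @export
sim_config <- function(seed = 1L,
                       ancestral_length = 10000L,
                       target_psi = 0.94,
                       indel_rate = 5e-4,
                       indel_mean_len = 3,
                       n_populations = 4L,
                       haplotypes_per_pop = 529L,
                       snp_density = 0.0075,
                       cpg_rate_multiplier = 10,
                       mutation_model = c("cpg_elevated", "equal_rates"),
                       igc_rate = 0.01,
                       igc_tract_mean = 200,
                       uniqueness_mismatch_threshold = 2L,
                       intra_chrom_fraction = 0.385) {
  mutation_model <- match.arg(mutation_model)
  if (!is.numeric(target_psi) || target_psi <= 0.5 || target_psi > 1)
    stop("target_psi must lie in (0.5, 1]: values <= 0.5 are outside ",
         "the identity range of segmental duplications")
  rates <- c(indel_rate = indel_rate, snp_density = snp_density,
             igc_rate = igc_rate, cpg_rate_multiplier = cpg_rate_multiplier,
             indel_mean_len = indel_mean_len, igc_tract_mean = igc_tract_mean)
  if (any(rates < 0)) stop("all rates must be >= 0")
  stopifnot(ancestral_length >= 1, n_populations >= 1,
            haplotypes_per_pop >= 1, uniqueness_mismatch_threshold >= 0,
            intra_chrom_fraction >= 0, intra_chrom_fraction <= 1)
  structure(list(
    seed = as.integer(seed),
    ancestral_length = as.integer(ancestral_length),
    target_psi = target_psi,
    indel_rate = indel_rate,
    indel_mean_len = indel_mean_len,
    n_populations = as.integer(n_populations),
    haplotypes_per_pop = as.integer(haplotypes_per_pop),
    snp_density = snp_density,
    cpg_rate_multiplier = cpg_rate_multiplier,
    mutation_model = mutation_model,
    igc_rate = igc_rate,
    igc_tract_mean = igc_tract_mean,
    uniqueness_mismatch_threshold = as.integer(uniqueness_mismatch_threshold),
    intra_chrom_fraction = intra_chrom_fraction
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic paralog cohort configuration\n")
  cat(sprintf("  seed %d | ancestral length %d bp | target PSI %.3f\n",
              x$seed, x$ancestral_length, x$target_psi))
  cat(sprintf("  %d populations x %d haplotypes | SNP density %.4g/bp (%s)\n",
              x$n_populations, x$haplotypes_per_pop, x$snp_density,
              x$mutation_model))
  cat(sprintf("  IGC: %.4g events/haplotype, mean tract %g bp\n",
              x$igc_rate, x$igc_tract_mean))
  invisible(x)
}

pop_labels <- function(config) paste0("POP", seq_len(config$n_populations))

total_haplotypes <- function(config)
  config$n_populations * config$haplotypes_per_pop
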