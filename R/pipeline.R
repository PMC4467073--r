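#' Pipeline configuration
#'
#' Single configuration object for an end-to-end run: either a
#' synthetic-cohort specification (a [sim_config()] plus a number of
#' pairs) or a fixture directory written by [emit_fixture()], plus mask
#' parameters, null-test parameters and an output directory.
#'
#' @param sim a [sim_config()] describing the synthetic cohort, or
#'   `NULL` when reading a fixture.
#' @param n_pairs number of paralog pairs to simulate (default 1).
#' @param fixture_dir fixture directory to read instead of simulating.
#' @param out_dir optional output directory for report files.
#' @param mask_window,indel_radius,edge alignment-mask parameters
#'   (defaults 100 / 10 / 100 columns).
#' @param n_perm permutation replicates for the null tests (default 200).
#' @param run_nulls run the null-model battery (default `TRUE`).
#' @param seed seed for the analysis-stage randomness (default 1).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, n_pairs = 1L, fixture_dir = NULL,
                            out_dir = NULL, mask_window = 100L,
                            indel_radius = 10L, edge = 100L,
                            n_perm = 200L, run_nulls = TRUE, seed = 1L) {
  if (is.null(sim) && is.null(fixture_dir))
    stop("either a sim_config or a fixture_dir is required")
  if (!is.null(fixture_dir) && !dir.exists(fixture_dir))
    stop("fixture_dir does not exist: ", fixture_dir)
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, n_pairs = as.integer(n_pairs),
                 fixture_dir = fixture_dir, out_dir = out_dir,
                 mask_window = as.integer(mask_window),
                 indel_radius = as.integer(indel_radius),
                 edge = as.integer(edge), n_perm = as.integer(n_perm),
                 run_nulls = isTRUE(run_nulls), seed = as.integer(seed)),
            class = "pipeline_config")
}

## genomic-coordinate SNP tables for one simulated pair
sim_snp_sides <- function(sim, ivA, ivB) {
  snps <- sim$snps
  g <- function(side, iv) {
    s <- snps[snps$paralog == side, , drop = FALSE]
    s$pos <- iv$start + s$pos - 1L
    s
  }
  list(A = g("A", ivA), B = g("B", ivB))
}

#' Run the full IGC-detection pipeline
#'
#' Sequences the stages end to end: simulate (or load) the cohort,
#' build per-pair alignments from the generator's true correspondence,
#' apply the alignment-quality masks, classify aligned site pairs,
#' apply the uniqueness and CpG filters, group parallelisms, estimate
#' the IGC-derived SNP count, and (optionally) run the mutation-only
#' null, clustering test and population-sharing test.  All randomness
#' derives from the seeds in the configuration, so reruns on an
#' unchanged configuration reproduce the report exactly.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report`: list with `tier_table`,
#'   `igc_snp_count`, `igc_pct` (against the final-tier SD SNP
#'   denominator), `groups`, `pairs` (classified site pairs with
#'   flags), `mask_summary`, `catalog` (final-tier parallelism
#'   catalog), `null_tests`, `private_table` and per-stage record
#'   counts in `stage_log`.  Written as TSV/JSON when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$fixture_dir)) {
    sims <- list(cohort_from_fixture(config$fixture_dir))
  } else {
    sims <- simulate_cohort(config$sim, config$n_pairs)
  }
  stage_log <- list(n_pairs = length(sims))

  all_pairs <- list()
  snp_status <- list()
  masked_alns <- list()
  cols_by_aln <- list()
  aln_lengths <- numeric(0)
  pool_n <- integer(0)
  pool_intra <- logical(0)
  for (i in seq_along(sims)) {
    sim <- sims[[i]]
    aln <- alignment_from_sim(sim$pair)
    aln <- apply_quality_masks(aln, window = config$mask_window,
                               indel_radius = config$indel_radius,
                               edge = config$edge)
    sides <- sim_snp_sides(sim, aln$intervalA, aln$intervalB)
    pr <- classify_site_pairs(aln, sides$A, sides$B, apply_mask = FALSE,
                              alignment_id = i)
    all_pairs[[i]] <- pr
    snp_status[[i]] <- snp_site_status(aln, sides$A, sides$B)
    masked_alns[[i]] <- aln
    nm <- as.character(i)
    par_cols <- pr$col[pr$klass == "parallelism" & pr$pass_mask]
    cols_by_aln[[nm]] <- par_cols
    aln_lengths[nm] <- aln_length(aln)
    cm <- map_columns(aln)
    passpos <- aln$mask == "pass" & !is.na(cm$posA) & !is.na(cm$posB)
    pool_n <- c(pool_n, sum(passpos))
    pool_intra <- c(pool_intra, aln$intervalA$chrom == aln$intervalB$chrom)
  }
  pairs <- do.call(rbind, all_pairs)
  status <- do.call(rbind, snp_status)
  stage_log$n_site_pairs <- nrow(pairs)
  stage_log$n_snps <- nrow(status)

  tier_table <- summarize_filter_tiers(pairs, status)
  final <- pairs$pass_mask & ifelse(is.na(pairs$uniqueA), TRUE, pairs$uniqueA) &
    ifelse(is.na(pairs$uniqueB), TRUE, pairs$uniqueB) &
    !(pairs$cpgA %in% TRUE) & !(pairs$cpgB %in% TRUE)
  final_pairs <- pairs[final, , drop = FALSE]
  groups <- build_groups(final_pairs)
  denom <- tier_table$n_sd_snps[nrow(tier_table)]
  igc_n <- igc_snp_count(groups, sd_snp_total = denom)
  catalog <- dedup_parallelisms(final_pairs)
  stage_log$n_parallelisms_final <- groups$n_edges

  null_tests <- NULL
  if (config$run_nulls) {
    alt3_final <- sum(final_pairs$klass == "alt3")
    ratio <- mutation_ratio_null(groups$n_edges, alt3_final)
    clust <- clustering_chi2(cols_by_aln, aln_lengths)
    pop_test <- NULL
    if (groups$n_edges >= 2L) {
      snp_table <- data.frame(
        maf = c(pairs$mafA, pairs$mafB),
        populations = c(pairs$popsA, pairs$popsB))
      snp_table <- snp_table[!is.na(snp_table$maf), , drop = FALSE]
      pop_test <- tryCatch(
        population_sharing_test(catalog, snp_table, n_perm = config$n_perm,
                                seed = config$seed),
        error = function(e) NULL)
    }
    intra_test <- NULL
    if (groups$n_edges >= 2L && sum(pool_n) >= groups$n_edges) {
      pool <- data.frame(
        chromA = rep(ifelse(pool_intra, "intra", paste0("a", seq_along(pool_n))),
                     pool_n),
        chromB = rep(ifelse(pool_intra, "intra", paste0("b", seq_along(pool_n))),
                     pool_n))
      intra_test <- tryCatch(
        intra_chromosomal_enrichment(catalog, pool, n_perm = config$n_perm,
                                     seed = config$seed),
        error = function(e) NULL)
    }
    null_tests <- list(mutation_ratio = ratio, clustering = clust,
                       population_sharing = pop_test,
                       intra_chromosomal = intra_test)
  }

  report <- structure(list(
    tier_table = tier_table,
    igc_snp_count = as.integer(igc_n),
    igc_pct = attr(igc_n, "percentage"),
    groups = groups,
    pairs = pairs,
    catalog = catalog,
    mask_summary = mask_summary(masked_alns),
    null_tests = null_tests,
    private_table = private_parallelism_table(final_pairs),
    stage_log = stage_log,
    config = config), class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("IGC-detection pipeline report\n")
  print(x$tier_table[, c("tier", "n_parallelisms", "n_snps_in_parallelisms",
                         "n_sd_snps", "pct_sd_snps")], row.names = FALSE)
  cat(sprintf("IGC-derived SNPs (sum k(n-1)): %d (%.2f%% of final-tier SD SNPs)\n",
              x$igc_snp_count, x$igc_pct))
  if (!is.null(x$null_tests)) {
    mr <- x$null_tests$mutation_ratio
    cat(sprintf("Mutation-only null: observed %d vs expected %.1f (ratio %.2f)\n",
                mr$observed, mr$expected,
                ifelse(is.na(mr$ratio), NA, mr$ratio)))
  }
  invisible(x)
}

## rebuild a minimal cohort object from a fixture directory
cohort_from_fixture <- function(dir) {
  fx <- read_fixture(dir)
  if (nrow(fx$sd_pairs) != 1L)
    stop("fixture must describe exactly one SD pair")
  sd <- fx$sd_pairs[1L, ]
  seqA <- fx$sequences[[sd$chromA]]
  seqB <- fx$sequences[[sd$chromB]]
  aln <- global_align(seqA, seqB,
                      genomic_interval(sd$chromA, sd$startA, sd$endA, "+"),
                      genomic_interval(sd$chromB, sd$startB, sd$endB,
                                       sd$strandB))
  pair <- structure(list(
    seqA = seqA, seqB = seqB, gappedA = aln$gappedA, gappedB = aln$gappedB,
    colmap = NULL, psi = aln$psi, intervalA = aln$intervalA,
    intervalB = aln$intervalB), class = "sd_pair_sim")

  uf <- unique_mapping_filter(fx$reads)
  snps <- fx$snps
  snps$unique_ok <- uf$snps$unique_ok[match(snps$snp_id, uf$snps$snp_id)]
  snps$paralog <- ifelse(snps$chrom == sd$chromA & snps$pos <= sd$endA,
                         "A", "B")
  start <- ifelse(snps$paralog == "A", sd$startA, sd$startB)
  snps$pos <- snps$pos - start + 1L
  bases <- list(A = strsplit(seqA, "", fixed = TRUE)[[1L]],
                B = strsplit(seqB, "", fixed = TRUE)[[1L]])
  snps$cpg <- vapply(seq_len(nrow(snps)), function(i)
    cpg_flagger(bases[[snps$paralog[i]]], snps$pos[i]), logical(1))
  structure(list(pair = pair, snps = snps, truth = fx$truth,
                 events = NULL, transfers = NULL, config = NULL),
            class = "paralog_cohort_sim")
}

#' Write a pipeline report to disk
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tiers = file.path(dir, "tier_summary.tsv"),
             catalog = file.path(dir, "parallelism_catalog.tsv"),
             groups = file.path(dir, "groups.tsv"),
             private = file.path(dir, "private_parallelisms.tsv"),
             report = file.path(dir, "report.json"))
  utils::write.table(report$tier_table, paths[["tiers"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$catalog, paths[["catalog"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$groups$groups, paths[["groups"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$private_table, paths[["private"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nt <- report$null_tests
  jn <- list(
    igc_snp_count = report$igc_snp_count,
    igc_pct = report$igc_pct,
    n_parallelisms = report$groups$n_edges,
    n_higher_order = report$groups$n_higher_order,
    mutation_ratio = if (!is.null(nt)) nt$mutation_ratio[c("observed",
                                                           "expected",
                                                           "ratio")],
    population_sharing_p = if (!is.null(nt) &&
                               !is.null(nt$population_sharing))
      nt$population_sharing$p_value,
    stage_log = report$stage_log)
  jsonlite::write_json(jn, paths[["report"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
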