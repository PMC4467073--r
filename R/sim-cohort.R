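#' Simulate population SNPs on a paralog pair
#'
#' Places biallelic SNPs independently on each copy of a simulated
#' paralog pair.  Derived-allele frequencies follow a truncated
#' Beta(0.2, 2) — a crude stand-in for the rare-allele-heavy spectrum
#' produced by recent super-exponential population growth — truncated to
#' `[1/(2N), 0.5]` where `N` is the total number of haplotypes.  Each
#' SNP is assigned to 1..k populations with a geometric preference for a
#' single population.  Under `mutation_model = "cpg_elevated"` the
#' per-site SNP probability at CpG-context positions is multiplied by
#' `cpg_rate_multiplier` (the alternative allele is always uniform over
#' the three non-reference bases).
#'
#' @param config a [sim_config()].
#' @param pair an `sd_pair_sim` from [simulate_sd_pair()].
#' @return list with `snps` (data frame: `snp_id`, `paralog`, `pos`,
#'   `ref`, `alt`, `maf`, `populations` comma-joined labels, `cpg`,
#'   `unique_ok`) and `truth` (data frame: one row per SNP with
#'   `origin = "point_mutation"`, donor fields `NA`,
#'   `population_origin`).
#' @export
simulate_cohort_snps <- function(config, pair) {
  stopifnot(inherits(config, "sim_config"), inherits(pair, "sd_pair_sim"))
  set.seed(config$seed + 1L)
  labels <- pop_labels(config)
  N2 <- total_haplotypes(config)

  one_side <- function(seqstr, paralog) {
    bases <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
    cpg <- cpg_context(bases)
    w <- rep(1, length(bases))
    if (config$mutation_model == "cpg_elevated")
      w[cpg] <- config$cpg_rate_multiplier
    p <- pmin(0.95, config$snp_density * w / mean(w))
    sel <- which(stats::runif(length(bases)) < p)
    if (!length(sel))
      return(data.frame(snp_id = character(0), paralog = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), maf = numeric(0),
                        populations = character(0), cpg = logical(0),
                        unique_ok = logical(0)))
    ref <- bases[sel]
    alt <- rotate_base(ref, sample.int(3L, length(sel), replace = TRUE))
    daf <- rbeta_trunc(length(sel), 0.2, 2, lo = 1 / N2, hi = 0.5)
    ac <- pmax(1L, round(daf * N2))
    maf <- pmin(ac / N2, 0.5)
    npop <- pmin(1L + stats::rgeom(length(sel), 0.6), config$n_populations)
    pops <- vapply(npop, function(k)
      paste(sort(sample(labels, k)), collapse = ","), character(1))
    data.frame(snp_id = paste0(paralog, "_", sel), paralog = paralog,
               pos = sel, ref = ref, alt = alt, maf = maf,
               populations = pops, cpg = cpg[sel], unique_ok = TRUE)
  }

  snps <- rbind(one_side(pair$seqA, "A"), one_side(pair$seqB, "B"))
  rownames(snps) <- NULL
  truth <- data.frame(
    snp_id = snps$snp_id, paralog = snps$paralog, pos = snps$pos,
    origin = rep("point_mutation", nrow(snps)),
    donor_snp_id = rep(NA_character_, nrow(snps)),
    donor_paralog = rep(NA_character_, nrow(snps)),
    donor_pos = rep(NA_integer_, nrow(snps)),
    population_origin = vapply(strsplit(snps$populations, ",", fixed = TRUE),
                               function(s) if (length(s)) s[[1L]] else
                                 NA_character_, character(1)))
  list(snps = snps, truth = truth)
}

#' Inject interlocus gene conversion events into a simulated cohort
#'
#' Each event copies a donor tract (geometric length, mean
#' `igc_tract_mean`) from a randomly chosen paralog onto the paralogous
#' acceptor region of a recipient haplotype.  Every donor polymorphism
#' inside the tract whose aligned acceptor position exists and whose
#' acceptor reference base belongs to the donor allele set creates (or
#' reinforces) an acceptor SNP segregating the identical allele set;
#' ground-truth labels record those SNPs as `igc_copy` with their donor
#' site.  Donor SNPs falling at unalignable (inserted/deleted) columns,
#' at diverged bases outside the donor allele set, or at acceptor
#' positions already carrying a different SNP transfer nothing and are
#' logged with an outcome code.
#'
#' @param config a [sim_config()].
#' @param pair the `sd_pair_sim` the SNPs were simulated on.
#' @param snps,truth from [simulate_cohort_snps()].
#' @return list with updated `snps` and `truth`, `events` (one row per
#'   IGC event: donor paralog, tract coordinates, recipient population)
#'   and `transfers` (one row per donor SNP considered, with
#'   `outcome` in `transferred`, `reinforced`, `unalignable`,
#'   `divergent_site`, `conflict`).
#' @export
inject_igc_events <- function(config, pair, snps, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(pair, "sd_pair_sim"))
  set.seed(config$seed + 2L)
  n_events <- stats::rpois(1L, config$igc_rate * total_haplotypes(config))

  events <- data.frame(event_id = integer(0), donor_paralog = character(0),
                       tract_start = integer(0), tract_end = integer(0),
                       recipient_pop = character(0))
  transfers <- data.frame(event_id = integer(0), donor_snp_id = character(0),
                          acceptor_paralog = character(0),
                          acceptor_pos = integer(0), outcome = character(0))
  if (n_events == 0L)
    return(list(snps = snps, truth = truth, events = events,
                transfers = transfers))

  labels <- pop_labels(config)
  N2 <- total_haplotypes(config)
  cm <- pair$colmap
  basesA <- strsplit(pair$seqA, "", fixed = TRUE)[[1L]]
  basesB <- strsplit(pair$seqB, "", fixed = TRUE)[[1L]]

  for (e in seq_len(n_events)) {
    donor <- sample(c("A", "B"), 1L)
    acceptor <- if (donor == "A") "B" else "A"
    dlen <- if (donor == "A") length(basesA) else length(basesB)
    tlen <- stats::rgeom(1L, 1 / max(config$igc_tract_mean, 1)) + 1L
    tstart <- sample.int(dlen, 1L)
    tend <- min(dlen, tstart + tlen - 1L)
    rec_pop <- sample(labels, 1L)
    events <- rbind(events, data.frame(
      event_id = e, donor_paralog = donor, tract_start = tstart,
      tract_end = tend, recipient_pop = rec_pop))

    dsnps <- snps[snps$paralog == donor &
                    snps$pos >= tstart & snps$pos <= tend, , drop = FALSE]
    if (!nrow(dsnps)) next
    dpos_col <- if (donor == "A") cm$posA else cm$posB
    apos_col <- if (donor == "A") cm$posB else cm$posA
    acc_bases <- if (acceptor == "A") basesA else basesB

    for (j in seq_len(nrow(dsnps))) {
      d <- dsnps[j, ]
      col <- match(d$pos, dpos_col)
      apos <- if (is.na(col)) NA_integer_ else apos_col[col]
      outcome <- "transferred"
      if (is.na(apos)) {
        outcome <- "unalignable"
      } else {
        acc_ref <- acc_bases[apos]
        dset <- c(d$ref, d$alt)
        if (!acc_ref %in% dset) {
          outcome <- "divergent_site"
        } else {
          new_alt <- setdiff(dset, acc_ref)
          exist <- snps$paralog == acceptor & snps$pos == apos
          if (any(exist)) {
            ex <- snps[which(exist)[1L], ]
            outcome <- if (setequal(c(ex$ref, ex$alt), dset))
              "reinforced" else "conflict"
          } else {
            ## population of the copied allele: one of the donor SNP's
            ## populations, so the parallel pair shares a population
            dpop <- sample(strsplit(d$populations, ",", fixed = TRUE)[[1L]], 1L)
            snps <- rbind(snps, data.frame(
              snp_id = paste0(acceptor, "_", apos), paralog = acceptor,
              pos = apos, ref = acc_ref, alt = new_alt,
              maf = 1 / N2, populations = dpop,
              cpg = cpg_flagger(acc_bases, apos), unique_ok = TRUE))
            truth <- rbind(truth, data.frame(
              snp_id = paste0(acceptor, "_", apos), paralog = acceptor,
              pos = apos, origin = "igc_copy", donor_snp_id = d$snp_id,
              donor_paralog = donor, donor_pos = d$pos,
              population_origin = dpop))
          }
        }
      }
      transfers <- rbind(transfers, data.frame(
        event_id = e, donor_snp_id = d$snp_id, acceptor_paralog = acceptor,
        acceptor_pos = apos, outcome = outcome))
    }
  }
  o <- order(snps$paralog, snps$pos)
  snps <- snps[o, , drop = FALSE]
  truth <- truth[match(snps$snp_id, truth$snp_id), , drop = FALSE]
  rownames(snps) <- rownames(truth) <- NULL
  list(snps = snps, truth = truth, events = events, transfers = transfers)
}

#' Simulate one fully labelled paralog cohort
#'
#' Convenience wrapper chaining [simulate_sd_pair()],
#' [simulate_cohort_snps()] and [inject_igc_events()].
#'
#' @param config a [sim_config()].
#' @return list of class `paralog_cohort_sim` with `pair`, `snps`,
#'   `truth`, `events`, `transfers` and the `config`.
#' @export
simulate_paralog_cohort <- function(config) {
  pair <- simulate_sd_pair(config)
  cs <- simulate_cohort_snps(config, pair)
  ig <- inject_igc_events(config, pair, cs$snps, cs$truth)
  structure(list(pair = pair, snps = ig$snps, truth = ig$truth,
                 events = ig$events, transfers = ig$transfers,
                 config = config),
            class = "paralog_cohort_sim")
}

#' Simulate a multi-pair cohort with genomic placement
#'
#' Generates `n_pairs` independent paralog cohorts and assigns each pair
#' genomic intervals: a fraction `intra_chrom_fraction` of pairs place
#' both copies on one chromosome (copy B offset by 10 Mb), the rest on
#' two chromosomes.  Per-pair seeds are derived deterministically from
#' `config$seed`.
#'
#' @param config a [sim_config()] used as the template for every pair.
#' @param n_pairs number of paralog pairs.
#' @return list of `paralog_cohort_sim` objects, each with
#'   `intervalA`/`intervalB` elements added to `$pair`.
#' @export
simulate_cohort <- function(config, n_pairs) {
  stopifnot(inherits(config, "sim_config"), n_pairs >= 1)
  n_intra <- round(n_pairs * config$intra_chrom_fraction)
  lapply(seq_len(n_pairs), function(i) {
    cfg <- config
    cfg$seed <- (config$seed + i * 101L) %% .Machine$integer.max
    sim <- simulate_paralog_cohort(cfg)
    intra <- i <= n_intra
    chromA <- sprintf("chr%d", i)
    chromB <- if (intra) chromA else sprintf("chr%d_b", i)
    offB <- if (intra) 10000000L else 1L
    sim$pair$intervalA <- genomic_interval(
      chromA, 1L, nchar(sim$pair$seqA), "+")
    sim$pair$intervalB <- genomic_interval(
      chromB, offB, offB + nchar(sim$pair$seqB) - 1L, "+")
    sim
  })
}
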