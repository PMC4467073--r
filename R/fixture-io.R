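#' Write a simulated cohort to disk as standard files
#'
#' Emits the fixture file set for one simulated paralog cohort:
#' sequences as FASTA; the pair as a genomicSuperDups-dialect
#' tab-separated table (`chromA,startA,endA,chromB,startB,endB,strandB,
#' fracMatch`, 0-based half-open coordinates); SNPs as VCF v4.2 with
#' INFO keys `POPS` (comma list) and `AF`; per-SNP/per-sample
#' read-mapping metadata abstracted from BAM tags (`X0`, `X1`,
#' `NM_best`, `NM_subopt_min`, `proper_pair`); clone-pool base calls;
#' and the ground-truth label table.
#'
#' Read-mapping metadata encodes mappability: SNPs in regions with
#' fewer than `uniqueness_mismatch_threshold` inter-paralog mismatches
#' within a 100-base alignment window are flagged multi-mapping
#' (`X0 = 2` for every sample); elsewhere reads map uniquely with
#' suboptimal placements at least two mismatches worse.  Clone pools
#' call `clone_depth` clones per SNP site with unbiased binomial
#' sampling of the two alleles (a heterozygous carrier).
#'
#' @param sim a `paralog_cohort_sim` from [simulate_paralog_cohort()].
#' @param dir output directory (created if needed).
#' @param n_samples number of simulated samples in the read-metadata
#'   table (default 3).
#' @param clone_depth clones per site in the clone table (default 5).
#' @return invisibly, the named vector of file paths.
#' @export
emit_fixture <- function(sim, dir, n_samples = 3L, clone_depth = 5L) {
  stopifnot(inherits(sim, "paralog_cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- sim$config
  set.seed(config$seed + 3L)
  pair <- sim$pair
  snps <- sim$snps
  ivA <- if (!is.null(pair$intervalA)) pair$intervalA else
    genomic_interval("paralogA", 1L, nchar(pair$seqA), "+")
  ivB <- if (!is.null(pair$intervalB)) pair$intervalB else
    genomic_interval("paralogB", 1L, nchar(pair$seqB), "+")

  paths <- c(fasta = file.path(dir, "paralogs.fa"),
             sd_table = file.path(dir, "sd_pairs.tsv"),
             vcf = file.path(dir, "snps.vcf"),
             reads = file.path(dir, "read_metadata.tsv"),
             clones = file.path(dir, "clone_pools.tsv"),
             truth = file.path(dir, "sim_truth.tsv"))

  ## FASTA
  ss <- Biostrings::DNAStringSet(c(pair$seqA, pair$seqB))
  names(ss) <- c(ivA$chrom, ivB$chrom)
  Biostrings::writeXStringSet(ss, paths[["fasta"]])

  ## SD pair table (0-based half-open on disk)
  writeLines(paste(
    c("#chromA", "startA", "endA", "chromB", "startB", "endB", "strandB",
      "fracMatch"), collapse = "\t"), paths[["sd_table"]])
  write(paste(ivA$chrom, ivA$start - 1L, ivA$end, ivB$chrom, ivB$start - 1L,
              ivB$end, ivB$strand, sprintf("%.6f", pair$psi), sep = "\t"),
        paths[["sd_table"]], append = TRUE)

  ## VCF v4.2 (positions are genomic: interval start + local pos - 1)
  gpos <- ifelse(snps$paralog == "A", ivA$start, ivB$start) + snps$pos - 1L
  chrom <- ifelse(snps$paralog == "A", ivA$chrom, ivB$chrom)
  con <- file(paths[["vcf"]], "w")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ivA$chrom, ivA$end),
    if (ivB$chrom != ivA$chrom)
      sprintf("##contig=<ID=%s,length=%d>", ivB$chrom, ivB$end),
    "##INFO=<ID=POPS,Number=.,Type=String,Description=\"Populations in which the alternative allele segregates\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternative allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps)) {
    o <- order(chrom, gpos)
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tPOPS=%s;AF=%.8g",
                       chrom[o], gpos[o], snps$snp_id[o], snps$ref[o],
                       snps$alt[o], snps$populations[o], snps$maf[o]), con)
  }
  close(con)

  ## read-mapping metadata: uniqueness from local inter-paralog divergence
  cm <- pair$colmap
  diffc <- strsplit(pair$gappedA, "", fixed = TRUE)[[1L]] !=
    strsplit(pair$gappedB, "", fixed = TRUE)[[1L]]
  cs <- c(0, cumsum(diffc))
  n_col <- nrow(cm)
  local_mm <- function(col) {
    lo <- pmax(1L, col - 50L)
    hi <- pmin(n_col, col + 49L)
    cs[hi + 1L] - cs[lo]
  }
  snp_col <- ifelse(snps$paralog == "A", match(snps$pos, cm$posA),
                    match(snps$pos, cm$posB))
  mm <- ifelse(is.na(snp_col), 0L, local_mm(snp_col))
  multi <- mm < config$uniqueness_mismatch_threshold
  samples <- sprintf("S%02d", seq_len(n_samples))
  n <- nrow(snps)
  reads <- data.frame(
    snp_id = rep(snps$snp_id, each = n_samples),
    sample = rep(samples, times = n),
    X0 = ifelse(rep(multi, each = n_samples), 2L, 1L),
    X1 = stats::rpois(n * n_samples, 0.5),
    NM_best = stats::rpois(n * n_samples, 1),
    proper_pair = TRUE)
  reads$NM_subopt_min <- ifelse(reads$X1 > 0,
                                reads$NM_best + 2L +
                                  stats::rpois(n * n_samples, 0.5), 0L)
  utils::write.table(reads[, c("snp_id", "sample", "X0", "X1", "NM_best",
                               "NM_subopt_min", "proper_pair")],
                     paths[["reads"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## clone pools: unbiased binomial sampling of the two alleles
  if (n) {
    clone <- data.frame(
      site_id = rep(site_key(chrom, gpos), each = clone_depth),
      clone_id = sprintf("clone%02d", rep(seq_len(clone_depth), times = n)))
    pick <- stats::runif(nrow(clone)) < 0.5
    clone$allele <- ifelse(pick, rep(snps$ref, each = clone_depth),
                           rep(snps$alt, each = clone_depth))
  } else {
    clone <- data.frame(site_id = character(0), clone_id = character(0),
                        allele = character(0))
  }
  utils::write.table(clone, paths[["clones"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a fixture directory back into memory
#'
#' Round-trips the files written by [emit_fixture()]: sequences via
#' FASTA, the SD pair table (converted back to 1-based inclusive
#' coordinates), SNPs via the VCF (with `POPS` and `AF` INFO keys),
#' read-mapping metadata, clone pools and truth labels.  Multi-allelic
#' VCF records are skipped with a warning (the analysis is restricted to
#' biallelic SNPs).
#'
#' @param dir fixture directory.
#' @return list with `sequences` (named character), `sd_pairs` (data
#'   frame, 1-based `startA`..`endB`), `snps`, `reads`, `clones`,
#'   `truth`.
#' @export
read_fixture <- function(dir) {
  fa <- file.path(dir, "paralogs.fa")
  if (!file.exists(fa)) stop("fixture FASTA not found: ", fa)
  ss <- Biostrings::readDNAStringSet(fa)
  sequences <- stats::setNames(as.character(ss), names(ss))

  sd <- utils::read.table(file.path(dir, "sd_pairs.tsv"), sep = "\t",
                          header = FALSE, comment.char = "#",
                          col.names = c("chromA", "startA", "endA", "chromB",
                                        "startB", "endB", "strandB",
                                        "fracMatch"))
  sd$startA <- sd$startA + 1L  # 0-based half-open -> 1-based inclusive
  sd$startB <- sd$startB + 1L

  v <- vcfR::read.vcfR(file.path(dir, "snps.vcf"), verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  snps <- data.frame(
    snp_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    maf = as.numeric(vcfR::extract.info(v, "AF")),
    populations = vcfR::extract.info(v, "POPS"))

  reads <- utils::read.table(file.path(dir, "read_metadata.tsv"),
                             sep = "\t", header = TRUE)
  clones <- utils::read.table(file.path(dir, "clone_pools.tsv"),
                              sep = "\t", header = TRUE,
                              colClasses = "character")
  truth <- utils::read.table(file.path(dir, "sim_truth.tsv"),
                             sep = "\t", header = TRUE)
  list(sequences = sequences, sd_pairs = sd, snps = snps, reads = reads,
       clones = clones, truth = truth)
}
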