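snp_row <- function(pos, ref, alt, maf = 0.1, pops = "POP1", cpg = FALSE,
                    unique_ok = TRUE, id = NULL) {
  data.frame(snp_id = if (is.null(id)) paste0("s", pos) else id,
             pos = pos, ref = ref, alt = alt, maf = maf,
             populations = pops, cpg = cpg, unique_ok = unique_ok)
}

no_snps <- data.frame(snp_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      maf = numeric(0), populations = character(0),
                      cpg = logical(0), unique_ok = logical(0))

test_that("column maps are strand-aware and invertible", {
  # forward/forward, no gaps
  aln <- alignment_from_gapped("ACGTACGT", "ACCTACGT",
                               genomic_interval("chr1", 101, 108, "+"),
                               genomic_interval("chr2", 201, 208, "+"))
  cm <- map_columns(aln)
  expect_identical(cm$posA, 101:108)
  expect_identical(cm$posB, 201:208)
  # minus-strand B: columns map in decreasing genomic order
  alnm <- alignment_from_gapped("ACGTACGT", "ACCTACGT",
                                genomic_interval("chr1", 101, 108, "+"),
                                genomic_interval("chr2", 201, 208, "-"))
  cmm <- map_columns(alnm)
  expect_identical(cmm$posB, 208:201)
  # round trip position -> column -> position, including across gaps
  alng <- alignment_from_gapped("ACGTACGT", "AC-TAC-T",
                                genomic_interval("chr1", 101, 108, "+"),
                                genomic_interval("chr2", 201, 206, "-"))
  cg <- map_columns(alng)
  for (p in 201:206) {
    col <- position_to_column(alng, p, "B")
    expect_identical(cg$posB[col], p)
  }
  expect_error(position_to_column(alng, 199, "B"), "outside")
})

test_that("aligned SNP pairs are classified by strand-adjusted allele sets", {
  aln <- alignment_from_gapped("ACGTACGT", "ACGTACGT",
                               genomic_interval("chr1", 1, 8, "+"),
                               genomic_interval("chr2", 1, 8, "+"))
  # identical sets -> parallelism; 3-base union -> alt3; 4-base -> alt4
  pr <- classify_site_pairs(aln,
                            rbind(snp_row(2, "C", "G"), snp_row(5, "A", "G"),
                                  snp_row(7, "G", "A")),
                            rbind(snp_row(2, "C", "G"), snp_row(5, "A", "C"),
                                  snp_row(7, "G", "C")))
  expect_identical(pr$klass[pr$posA == 2], "parallelism")
  expect_identical(pr$klass[pr$posA == 5], "alt3")
  # {G,A} vs {G,C}: union {A,C,G} = alt3
  expect_identical(pr$klass[pr$posA == 7], "alt3")

  # A/G vs C/T on a minus-strand paralog is a parallelism (complement)
  alnm <- alignment_from_gapped("AAGAAAAA", "AAGAAAAA",
                                genomic_interval("chr1", 1, 8, "+"),
                                genomic_interval("chr2", 1, 8, "-"))
  prm <- classify_site_pairs(alnm, snp_row(3, "A", "G"),
                             snp_row(6, "C", "T"))
  expect_identical(prm$klass, "parallelism")
  # one-sided SNP -> single
  pr1 <- classify_site_pairs(aln, snp_row(4, "T", "A"), no_snps)
  expect_identical(pr1$klass, "single")
})

test_that("SNPs at masked columns are excluded and logged", {
  aln <- alignment_from_gapped("ACGTACGT", "ACGTACGT",
                               genomic_interval("chr1", 1, 8, "+"),
                               genomic_interval("chr2", 1, 8, "+"))
  aln <- combine_masks(aln, list(edge = c(TRUE, TRUE, rep(FALSE, 6))))
  pr <- classify_site_pairs(aln, rbind(snp_row(2, "C", "A"),
                                       snp_row(5, "A", "G")),
                            rbind(snp_row(2, "C", "A"), snp_row(5, "A", "G")))
  expect_identical(pr$posA, 5L)
  expect_equal(unname(attr(pr, "filter_log")["snp_columns_masked"]), 1L)
})

test_that("non-biallelic or duplicated SNP tables are rejected", {
  aln <- alignment_from_gapped("ACGT", "ACGT")
  expect_error(classify_site_pairs(aln, snp_row(2, "C", "C"), no_snps),
               "biallelic")
  expect_error(classify_site_pairs(aln, rbind(snp_row(2, "C", "A"),
                                              snp_row(2, "C", "G")), no_snps),
               "duplicate")
})

test_that("read-uniqueness filter enforces X0, X1 and mismatch-margin rules", {
  mk <- function(X0, X1, nm_best = 1, nm_sub = 3, sample = "s1")
    data.frame(snp_id = "snp", sample = sample, X0 = X0, X1 = X1,
               NM_best = nm_best, NM_subopt_min = nm_sub)
  # multiple best hits fail
  expect_false(unique_mapping_filter(mk(2, 0))$snps$unique_ok)
  # more than five suboptimal hits fail
  expect_false(unique_mapping_filter(mk(1, 6))$snps$unique_ok)
  # suboptimal margin >= 2 passes, margin 1 fails
  expect_true(unique_mapping_filter(mk(1, 3, 1, 3))$snps$unique_ok)
  expect_false(unique_mapping_filter(mk(1, 3, 1, 2))$snps$unique_ok)
  # margin rule is vacuous with no suboptimal hits
  expect_true(unique_mapping_filter(mk(1, 0, 1, 0))$snps$unique_ok)
  # SNP retained iff >= 1 sample passes; a missing sample fails and is logged
  reads <- rbind(mk(2, 0, sample = "s1"), mk(1, 0, sample = "s2"))
  uf <- unique_mapping_filter(reads, samples = c("s1", "s2", "s3"))
  expect_true(uf$snps$unique_ok)
  expect_false(uf$per_sample$pass[uf$per_sample$sample == "s3"])
  expect_equal(unname(attr(uf$per_sample,
                           "filter_log")["samples_missing_metadata"]), 1L)
})

test_that("CpG flagging covers both members of the dinucleotide", {
  expect_true(cpg_flagger("AACGT", 3))   # the C of CpG
  expect_true(cpg_flagger("AACGT", 4))   # the G of CpG
  expect_false(cpg_flagger("AACAT", 3))
  # edges evaluate only the available neighbour
  expect_true(cpg_flagger("GA", 1) == FALSE)
  expect_true(cpg_flagger("CG", 1))
  expect_true(cpg_flagger("CG", 2))
})

test_that("parallelism groups match a transitive-closure oracle", {
  mkpairs <- function(edges) {
    data.frame(alignment_id = 1L, col = seq_len(nrow(edges)),
               chromA = "c", posA = edges[, 1], chromB = "c",
               posB = edges[, 2],
               allelesA = "A/G", allelesB = "A/G",
               klass = "parallelism", pass_mask = TRUE)
  }
  # chain A-B, B-C -> one group of dimension 3
  g <- build_groups(mkpairs(cbind(c(1, 2), c(2, 3))))
  expect_equal(nrow(g$groups), 1L)
  expect_equal(g$groups$dimension, 3L)
  # two disjoint pairs -> two groups of dimension 2
  g <- build_groups(mkpairs(cbind(c(1, 10), c(2, 11))))
  expect_equal(sort(g$groups$dimension), c(2L, 2L))
  # random graphs against the closure oracle
  set.seed(501)
  for (i in 1:10) {
    n_nodes <- sample(5:15, 1)
    n_edges <- sample(3:12, 1)
    edges <- cbind(sample(n_nodes, n_edges, TRUE),
                   sample(n_nodes, n_edges, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    if (!nrow(edges)) next
    g <- build_groups(mkpairs(edges))
    oracle <- closure_components(matrix(paste0("c:", edges), ncol = 2))
    expect_setequal(g$groups$dimension, lengths(oracle))
    expect_equal(nrow(g$groups), length(oracle))
  }
})

test_that("the sum-of-(n-1) estimator counts IGC-derived SNPs", {
  expect_equal(igc_snp_count(data.frame(dimension = 2)), 1L)
  expect_equal(igc_snp_count(data.frame(dimension = 5)), 4L)
  expect_equal(igc_snp_count(data.frame(dimension = c(2, 2, 2, 3, 3, 5))), 11L)
  expect_error(igc_snp_count(data.frame(dimension = 1)), ">= 2")
  out <- igc_snp_count(data.frame(dimension = c(2, 2)), sd_snp_total = 100)
  expect_equal(attr(out, "percentage"), 2)
})

test_that("parallelisms are deduplicated across redundant alignments", {
  pr <- data.frame(alignment_id = 1L, col = 1:2, chromA = "c1",
                   posA = c(5, 9), chromB = "c2", posB = c(105, 109),
                   allelesA = "A/G", allelesB = "A/G",
                   klass = "parallelism", pass_mask = TRUE)
  dup <- rbind(pr, transform(pr, alignment_id = 2L))
  expect_equal(build_groups(dup)$n_edges, build_groups(pr)$n_edges)
})

test_that("strand round-trip leaves the parallelism set invariant", {
  # reverse-complementing paralog B's input and flipping its strand
  # annotation transforms SNP coordinates and alleles but must not
  # change what is detected
  cfg <- sim_config(seed = 31, ancestral_length = 4000, igc_rate = 0.02)
  sim <- simulate_paralog_cohort(cfg)
  aln <- alignment_from_sim(sim$pair)
  snpsA <- sim$snps[sim$snps$paralog == "A", ]
  snpsB <- sim$snps[sim$snps$paralog == "B", ]
  pr_plus <- classify_site_pairs(aln, snpsA, snpsB)

  lenB <- nchar(sim$pair$seqB)
  aln_minus <- alignment_from_gapped(
    sim$pair$gappedA, sim$pair$gappedB,
    genomic_interval("seqA", 1, nchar(sim$pair$seqA), "+"),
    genomic_interval("seqB", 1, lenB, "-"))
  snpsB_rc <- snpsB
  snpsB_rc$pos <- lenB - snpsB$pos + 1L
  snpsB_rc$ref <- igcscan:::comp_base(snpsB$ref)
  snpsB_rc$alt <- igcscan:::comp_base(snpsB$alt)
  pr_minus <- classify_site_pairs(aln_minus, snpsA, snpsB_rc)

  expect_identical(table(pr_plus$klass), table(pr_minus$klass))
  expect_setequal(pr_plus$posA[pr_plus$klass == "parallelism"],
                  pr_minus$posA[pr_minus$klass == "parallelism"])
})

test_that("tier percentages reproduce the published-arithmetic convention", {
  counts <- data.frame(n_snps_in_parallelisms = c(68568, 50413, 28747),
                       n_sd_snps = c(747278, 610166, 554600))
  expect_equal(tier_percentage_table(counts)$pct_sd_snps,
               c(9.18, 8.26, 5.18))
  # zero denominator -> missing percentage
  expect_true(is.na(tier_percentage_table(
    data.frame(n_snps_in_parallelisms = 0, n_sd_snps = 0))$pct_sd_snps))
})

test_that("filter tiers are monotone on a simulated cohort", {
  cfg <- sim_config(seed = 37, ancestral_length = 8000, igc_rate = 0.02)
  rep <- run_pipeline(pipeline_config(sim = cfg, n_pairs = 2,
                                      run_nulls = FALSE))
  tt <- rep$tier_table
  expect_true(all(diff(tt$n_parallelisms) <= 0))
  expect_true(all(diff(tt$n_snps_in_parallelisms) <= 0))
  expect_true(all(diff(tt$n_sd_snps) <= 0))
})

test_that("rare-minor-allele scan matches fixed paralog bases only", {
  aln <- alignment_from_gapped("ACGTACGTACGT", "ACGTACGTACGT",
                               genomic_interval("chr1", 1, 12, "+"),
                               genomic_interval("chr2", 1, 12, "+"))
  # minor (alt) allele G at pos 2 matches paralog base? paralog base is C
  # at pos 2; make alt = C at pos 6 instead (paralog base C at col 6)
  snpsA <- rbind(snp_row(6, "C", "G", maf = 0.005),  # paralog base C: no
                 snp_row(2, "C", "G", maf = 0.005),  # paralog base C: no
                 snp_row(5, "A", "G", maf = 0.005),  # paralog base A: no
                 snp_row(9, "A", "G", maf = 0.02))
  # make the paralog carry G at the position aligned to A-pos 5
  alnG <- alignment_from_gapped("ACGTACGTACGT", "ACGTGCGTACGT",
                                genomic_interval("chr1", 1, 12, "+"),
                                genomic_interval("chr2", 1, 12, "+"))
  out <- rare_minor_match_scan(alnG, snpsA, no_snps, maf_cutoff = 0.01)
  expect_identical(out$pos, 5)
  # above the MAF cutoff: not counted even when matching
  snps9 <- snp_row(9, "A", "G", maf = 0.02)
  aln9 <- alignment_from_gapped("ACGTACGTACGT", "ACGTACGTGCGT",
                                genomic_interval("chr1", 1, 12, "+"),
                                genomic_interval("chr2", 1, 12, "+"))
  expect_equal(nrow(rare_minor_match_scan(aln9, snps9, no_snps)), 0L)
  # paralogous site itself polymorphic: excluded
  out2 <- rare_minor_match_scan(alnG, snpsA, snp_row(5, "G", "T"),
                                maf_cutoff = 0.01)
  expect_false(5L %in% out2$pos)
  # minus-strand paralog: minor allele G counted when paralog shows C
  alnm <- alignment_from_gapped("AAAAAAAAA", "AAAAGAAAA",
                                genomic_interval("chr1", 1, 9, "+"),
                                genomic_interval("chr2", 1, 9, "-"))
  outm <- rare_minor_match_scan(alnm, snp_row(5, "A", "G", maf = 0.005),
                                no_snps)
  expect_identical(outm$pos, 5)
})
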