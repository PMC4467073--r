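test_that("conditioned simulations carry exactly S distinct sites", {
  sims <- simulate_segregating_sites(S = 300, L = 10000, reps = 20, seed = 1)
  expect_true(all(lengths(sims$positions) == 300L))
  expect_true(all(vapply(sims$positions, anyDuplicated, numeric(1)) == 0))
  expect_true(all(unlist(sims$positions) >= 1 &
                    unlist(sims$positions) <= 10000))
  # S = 0 gives empty position sets; S > L is rejected
  s0 <- simulate_segregating_sites(S = 0, L = 100, reps = 3, seed = 1)
  expect_true(all(lengths(s0$positions) == 0L))
  expect_error(simulate_segregating_sites(S = 101, L = 100, reps = 1),
               "exceed")
})

test_that("conditioned site positions are uniform over the locus", {
  sims <- simulate_segregating_sites(S = 50, L = 1000, reps = 200, seed = 2)
  pos <- unlist(sims$positions)
  counts <- tabulate((pos - 1) %/% 100 + 1, nbins = 10)
  stat <- sum((counts - length(pos) / 10)^2 / (length(pos) / 10))
  expect_gt(pchisq(stat, df = 9, lower.tail = FALSE), 0.001)
})

test_that("haplotype mode yields a rare-allele-skewed derived spectrum", {
  sims <- simulate_segregating_sites(S = 40, L = 5000, reps = 30,
                                     n_haplotypes = 50, seed = 3,
                                     haplotypes = TRUE)
  daf <- unlist(sims$derived_counts)
  expect_true(all(daf >= 1 & daf <= 49))
  # under growth most mutations land on the many short recent branches
  expect_gt(mean(daf <= 5), 0.5)
})

test_that("two-hit counts behave like uniform overlaps", {
  # disjoint position sets -> 0 expected parallelisms
  a <- simulate_segregating_sites(S = 10, L = 1000, reps = 5, seed = 4)
  b <- a
  b$positions <- lapply(a$positions, function(p) ((p + 500) %% 1000) + 1)
  b$positions <- lapply(seq_along(b$positions), function(i)
    setdiff(b$positions[[i]], a$positions[[i]]))
  ex0 <- expected_parallelisms_from_sim(a, b)
  expect_equal(ex0$expected_parallelisms, 0, tolerance = 1e-12)
  # identical position sets of size S -> expected S/3
  ex1 <- expected_parallelisms_from_sim(a, a)
  expect_equal(ex1$expected_parallelisms, 10 / 3, tolerance = 1e-12)
  # mean two-hit over many replicates approximates S1*S2/L
  s1 <- simulate_segregating_sites(S = 300, L = 10000, reps = 1000, seed = 5)
  s2 <- simulate_segregating_sites(S = 200, L = 10000, reps = 1000, seed = 6)
  ex <- expected_parallelisms_from_sim(s1, s2)
  se <- sd(ex$two_hit) / sqrt(length(ex$two_hit))
  expect_lt(abs(ex$expected_two_hit - 300 * 200 / 10000), 3 * se)
  # mismatched locus lengths are rejected
  s3 <- simulate_segregating_sites(S = 10, L = 500, reps = 1000, seed = 7)
  expect_error(expected_parallelisms_from_sim(s1, s3), "lengths")
})

test_that("the mutation-only null expects one parallelism per two alt3 sites", {
  mr <- mutation_ratio_null(15790, 6448)
  expect_equal(mr$expected, 3224)
  expect_true(mr$excess)
  expect_equal(mutation_ratio_null(0, 0)$expected, 0)
  expect_true(is.na(mutation_ratio_null(5, 0)$ratio))
})

test_that("parallel mutations at one base share the derived allele a third of the time", {
  share <- parallel_mutation_share(20000, seed = 8)
  expect_equal(share, 1 / 3, tolerance = 0.03)
})

test_that("empirical p-values obey the add-one rule and its bounds", {
  pr <- permutation_result(0.5, c(0.1, 0.2, 0.9))
  expect_equal(pr$p_value, (1 + 1) / (1 + 3))
  # p in [1/(1+N), 1] and monotone non-increasing in the observed value
  null <- runif(100)
  obs <- seq(0, 1, by = 0.1)
  ps <- vapply(obs, function(o) permutation_result(o, null)$p_value,
               numeric(1))
  expect_true(all(ps >= 1 / 101 & ps <= 1))
  expect_true(all(diff(ps) <= 0))
})

test_that("intra-chromosomal enrichment detects constructed clustering", {
  # all parallelisms intra-chromosomal in an all-intra pool: p = 1
  pairs <- data.frame(chromA = "chr1", chromB = "chr1")[rep(1, 10), ]
  pool <- data.frame(chromA = "chr1", chromB = "chr1")[rep(1, 100), ]
  res <- intra_chromosomal_enrichment(pairs, pool, n_perm = 99, seed = 1)
  expect_equal(res$observed, 1)
  expect_equal(res$p_value, 1)
  # parallelisms only in the intra fraction of a mixed pool: small p
  pool2 <- data.frame(chromA = c(rep("chr1", 50), rep("chr1", 50)),
                      chromB = c(rep("chr1", 50), rep("chr2", 50)))
  res2 <- intra_chromosomal_enrichment(pairs, pool2, n_perm = 199, seed = 2)
  expect_lt(res2$p_value, 0.05)
  # determinism and over-request rejection
  res3 <- intra_chromosomal_enrichment(pairs, pool2, n_perm = 199, seed = 2)
  expect_identical(res2$p_value, res3$p_value)
  expect_error(intra_chromosomal_enrichment(
    data.frame(chromA = rep("c", 200), chromB = rep("c", 200)), pool,
    n_perm = 9), "exceeds")
})

test_that("population sharing exceeds frequency-matched random pairs when built in", {
  set.seed(9)
  # parallelism members share a population by construction
  pairs <- data.frame(popsA = sample(c("P1", "P2", "P3"), 40, TRUE),
                      mafA = runif(40, 0.01, 0.49),
                      mafB = runif(40, 0.01, 0.49))
  pairs$popsB <- pairs$popsA
  # background SNPs carry random single populations
  snp_table <- data.frame(populations = sample(c("P1", "P2", "P3"), 400, TRUE),
                          maf = runif(400, 0.01, 0.49))
  res <- population_sharing_test(pairs, snp_table, n_perm = 99, seed = 3)
  expect_equal(res$observed, 1)
  expect_gt(res$observed, mean(res$null))
  expect_lt(res$p_value, 0.05)
  # single-population cohort: sharing is 1 for observed and null alike
  pairs1 <- data.frame(popsA = "P1", popsB = "P1", mafA = 0.1, mafB = 0.1)
  snp1 <- data.frame(populations = rep("P1", 50), maf = runif(50, 0, 0.5))
  res1 <- population_sharing_test(pairs1, snp1, n_perm = 49, seed = 4)
  expect_equal(res1$observed, 1)
  expect_equal(res1$p_value, 1)
  # invariant under joint permutation of population labels
  relab <- c(P1 = "P3", P2 = "P1", P3 = "P2")
  pairs_r <- transform(pairs, popsA = unname(relab[popsA]),
                       popsB = unname(relab[popsB]))
  snp_r <- transform(snp_table, populations = unname(relab[populations]))
  res_r <- population_sharing_test(pairs_r, snp_r, n_perm = 99, seed = 3)
  expect_identical(res_r$observed, res$observed)
})

test_that("window clustering chi-square matches the hand-computed statistic", {
  # perfectly uniform counts -> statistic 0, p = 1
  cols <- as.integer(outer(1:2, (0:9) * 1000, `+`))  # 2 per 1-kb window
  out <- clustering_chi2(list(a = cols), c(a = 10001), min_length = 10000,
                         min_count = 10)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  # all 20 parallelisms in one of 10 windows: sum (obs-2)^2/2 = 162+9*2
  cols2 <- as.integer(1:20 * 40)  # all within the first 1-kb window
  out2 <- clustering_chi2(list(a = cols2), c(a = 10001),
                          min_length = 10000, min_count = 10)
  expect_equal(out2$statistic, 180)
  expect_equal(out2$df, 9L)
  # eligibility: short alignments and sparse alignments are skipped
  out3 <- clustering_chi2(list(a = cols, b = 1:5),
                          c(a = 9000, b = 50000))
  expect_equal(nrow(out3), 0L)
  expect_setequal(attr(out3, "skipped"), c("a", "b"))
  # merging alignments never changes a single alignment's statistic
  out4 <- clustering_chi2(list(a = cols2, b = cols), c(a = 10001, b = 10001),
                          min_length = 10000, min_count = 10)
  expect_equal(out4$statistic[out4$alignment == "a"], 180)
})

test_that("clone probabilities and concordance calls follow the rules", {
  expect_equal(clone_single_allele_prob(5), 0.0625)
  expect_equal(clone_single_allele_prob(1), 1.0)   # capped
  expect_equal(clone_single_allele_prob(10), 0.001953125)
  expect_error(clone_single_allele_prob(0), ">= 1")

  calls <- function(s1, s2) rbind(
    data.frame(site_id = "x:1", clone_id = paste0("c", seq_along(s1)),
               allele = s1),
    data.frame(site_id = "y:2", clone_id = paste0("c", seq_along(s2)),
               allele = s2))
  al <- list("x:1" = c("A", "G"), "y:2" = c("C", "T"))
  # both alleles at both sites with >= 5 clones: validated
  expect_equal(as.character(clone_concordance(
    al, calls(c("A", "A", "G", "G", "A"), c("C", "T", "C", "T", "C")))),
    "validated")
  # one allele only at one covered site: refuted
  expect_equal(as.character(clone_concordance(
    al, calls(c("A", "A", "A", "A", "A"), c("C", "T", "C", "T", "C")))),
    "refuted")
  # fewer than 5 clones at one site: insufficient
  expect_equal(as.character(clone_concordance(
    al, calls(c("A", "G", "A", "G"), c("C", "T", "C", "T", "C")))),
    "insufficient")
  # unknown allele symbols are rejected and logged
  expect_warning(
    out <- clone_concordance(
      al, calls(c("A", "G", "A", "G", "N"), c("C", "T", "C", "T", "C"))),
    "rejected")
  expect_equal(as.character(out), "insufficient")
  expect_equal(attr(out, "n_rejected"), 1L)
})

test_that("catalog-level clone validation classifies each parallelism", {
  pairs <- data.frame(chromA = "c1", posA = c(10, 20), chromB = "c2",
                      posB = c(110, 120), allelesA = c("A/G", "C/T"),
                      allelesB = c("A/G", "C/T"), klass = "parallelism",
                      pass_mask = TRUE)
  clones <- rbind(
    data.frame(site_id = "c1:10", clone_id = paste0("c", 1:5),
               allele = c("A", "G", "A", "G", "A")),
    data.frame(site_id = "c2:110", clone_id = paste0("c", 1:5),
               allele = c("A", "G", "A", "A", "A")),
    data.frame(site_id = "c1:20", clone_id = paste0("c", 1:5),
               allele = c("C", "C", "C", "C", "C")),
    data.frame(site_id = "c2:120", clone_id = paste0("c", 1:5),
               allele = c("C", "T", "C", "T", "C")))
  out <- clone_validate(pairs, clones)
  expect_equal(out$status, c("validated", "refuted"))
})
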