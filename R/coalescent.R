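#' Coalescent replicates conditioned on the number of segregating sites
#'
#' Simulates `reps` replicates of a locus of `L` discrete sites, each
#' carrying exactly `S` segregating sites, under a single population of
#' constant historical size that entered exponential growth (rate
#' `growth_rate` in coalescent units) at scaled time `growth_onset`
#' before the present.  Defaults mirror a strong recent human expansion
#' surveyed with 2116 haplotypes (`-eG 0.0025 0 -G 920` in `ms` terms).
#'
#' Under the infinite-sites model conditioned on S, mutation positions
#' are uniform over the locus irrespective of demography, so the default
#' mode samples S distinct discrete positions uniformly without
#' replacement — an exact equivalence that avoids collision handling.
#' With `haplotypes = TRUE` a full coalescent tree is simulated per
#' replicate (piecewise-analytic inversion of the coalescent hazard
#' under the growth profile), S mutations are dropped on branches with
#' probability proportional to branch length, and each site's derived
#' allele count is returned alongside its position.
#'
#' @param S number of segregating sites per replicate (0 <= S <= L).
#' @param L locus length in sites.
#' @param reps number of replicates (default 1000).
#' @param n_haplotypes sample size for the tree mode (default 2116).
#' @param growth_rate coefficient of exponential growth (default 920).
#' @param growth_onset scaled time at which growth began (default 0.0025).
#' @param seed integer seed.
#' @param haplotypes simulate trees and derived allele counts (default
#'   `FALSE`).
#' @return object of class `coalescent_replicates`: list with
#'   `positions` (list of sorted integer vectors in 1..L, each of length
#'   S), optionally `derived_counts`, and the parameters.
#' @examples
#' sims <- simulate_segregating_sites(S = 10, L = 1000, reps = 5, seed = 1)
#' lengths(sims$positions)
#' @export
simulate_segregating_sites <- function(S, L, reps = 1000L,
                                       n_haplotypes = 2116L,
                                       growth_rate = 920,
                                       growth_onset = 0.0025,
                                       seed = 1L, haplotypes = FALSE) {
  if (S > L) stop("S must not exceed L: cannot place ", S,
                  " distinct sites on ", L, " positions")
  stopifnot(S >= 0, reps >= 1, n_haplotypes >= 2)
  set.seed(seed)
  positions <- vector("list", reps)
  derived <- if (haplotypes) vector("list", reps) else NULL
  for (r in seq_len(reps)) {
    pos <- if (S > 0) sort(sample.int(L, S)) else integer(0)
    positions[[r]] <- pos
    if (haplotypes) {
      tree <- sim_growth_tree(n_haplotypes, growth_rate, growth_onset)
      derived[[r]] <- if (S > 0)
        tree$tip_count[sample.int(length(tree$branch_len), S, replace = TRUE,
                                  prob = tree$branch_len)]
      else integer(0)
    }
  }
  structure(list(positions = positions, derived_counts = derived,
                 S = as.integer(S), L = as.integer(L), reps = reps,
                 n_haplotypes = as.integer(n_haplotypes),
                 growth_rate = growth_rate, growth_onset = growth_onset),
            class = "coalescent_replicates")
}

## one coalescent tree under exponential growth ending at growth_onset;
## returns branch lengths and descendant-tip counts for all non-root nodes
sim_growth_tree <- function(n, alpha, onset) {
  n_nodes <- 2L * n - 1L
  node_time <- numeric(n_nodes)
  tip_count <- c(rep(1L, n), integer(n - 1L))
  parent <- integer(n_nodes)
  active <- seq_len(n)
  t <- 0
  nxt <- n
  x_anc <- exp(-alpha * onset)  # relative ancient population size
  for (k in seq(n, 2L)) {
    Ck <- k * (k - 1) / 2
    E <- stats::rexp(1L)
    if (alpha > 0 && t < onset) {
      Hmax <- Ck * (exp(alpha * onset) - exp(alpha * t)) / alpha
      t <- if (E <= Hmax) log(exp(alpha * t) + alpha * E / Ck) / alpha
           else onset + (E - Hmax) * x_anc / Ck
    } else {
      x_now <- if (alpha > 0) x_anc else 1
      t <- t + E * x_now / Ck
    }
    ij <- sample(length(active), 2L)
    nxt <- nxt + 1L
    node_time[nxt] <- t
    parent[active[ij]] <- nxt
    tip_count[nxt] <- sum(tip_count[active[ij]])
    active <- c(active[-ij], nxt)
  }
  non_root <- seq_len(n_nodes - 1L)
  list(branch_len = node_time[parent[non_root]] - node_time[non_root],
       tip_count = tip_count[non_root])
}

#' Expected parallelisms from paired coalescent replicates
#'
#' Pairs replicate r of the first paralog with replicate r of the
#' second, counts "two-hit" sites (positions variable in both paralogs),
#' and converts the mean to an expected parallelism count by the
#' one-third rule: under equal mutation rates to all nucleotides, one in
#' three two-hit sites segregates the same alleles.
#'
#' @param repsA,repsB `coalescent_replicates` for the two paralogs; must
#'   share `L` and `reps`.
#' @return list with `two_hit` (per-replicate counts),
#'   `expected_two_hit`, `expected_parallelisms` (mean two-hit / 3) and
#'   a `p_value` function of an observed parallelism count (empirical,
#'   add-one rule against the per-replicate two-hit/3 distribution).
#' @export
expected_parallelisms_from_sim <- function(repsA, repsB) {
  stopifnot(inherits(repsA, "coalescent_replicates"),
            inherits(repsB, "coalescent_replicates"))
  if (repsA$L != repsB$L)
    stop("replicate sets were simulated on different locus lengths")
  if (repsA$reps != repsB$reps)
    stop("replicate sets must have the same number of replicates")
  two_hit <- mapply(function(x, y) length(intersect(x, y)),
                    repsA$positions, repsB$positions)
  null_par <- two_hit / 3
  list(two_hit = two_hit,
       expected_two_hit = mean(two_hit),
       expected_parallelisms = mean(null_par),
       p_value = function(observed)
         (1 + sum(null_par >= observed)) / (1 + length(null_par)))
}

#' Mutation-only null for the parallelism / alternative-allele ratio
#'
#' Under equal mutation rates, two of every three parallel mutation
#' events at an identical ancestral base yield aligned SNP pairs
#' segregating alternative alleles (three-base sites), and one in three
#' yields a shared-allele pair.  The expected number of parallelisms
#' under a mutation-only null is therefore half the observed number of
#' three-base aligned SNP pairs.
#'
#' @param n_parallelisms observed shared-allele pair count.
#' @param n_alt3 observed three-base (alternative-allele) pair count.
#' @return list with `observed`, `expected` (`n_alt3 / 2`), `ratio`
#'   (`observed / expected`, `NA` when expected is 0) and `excess`
#'   (`TRUE` when observed exceeds expected).
#' @examples
#' mutation_ratio_null(15790, 6448)$expected # 3224
#' @export
mutation_ratio_null <- function(n_parallelisms, n_alt3) {
  stopifnot(n_parallelisms >= 0, n_alt3 >= 0)
  expected <- n_alt3 / 2
  list(observed = n_parallelisms, expected = expected,
       ratio = if (expected > 0) n_parallelisms / expected else NA_real_,
       excess = n_parallelisms > expected)
}

#' Monte-Carlo share of identical outcomes among parallel mutations
#'
#' Draws pairs of independent point mutations at the same ancestral
#' base, each mutating uniformly to one of the three other nucleotides,
#' and returns the fraction of pairs producing the identical derived
#' allele.  Converges to 1/3.
#'
#' @param n_draws number of simulated mutation pairs.
#' @param seed integer seed.
#' @return fraction of pairs with identical derived alleles.
#' @export
parallel_mutation_share <- function(n_draws, seed = 1L) {
  stopifnot(n_draws >= 1)
  set.seed(seed)
  anc <- sample(DNA_BASES_, n_draws, replace = TRUE)
  mutA <- rotate_base(anc, sample.int(3L, n_draws, replace = TRUE))
  mutB <- rotate_base(anc, sample.int(3L, n_draws, replace = TRUE))
  mean(mutA == mutB)
}
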