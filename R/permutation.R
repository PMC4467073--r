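#' Permutation test result
#'
#' Container for an observed statistic and its permutation null.  The
#' empirical p-value uses the add-one rule,
#' `p = (1 + #\{null >= observed\}) / (1 + N)`, so p is never exactly 0
#' and always lies in `[1/(1+N), 1]`.
#'
#' @param observed observed statistic.
#' @param null numeric vector of null replicate statistics.
#' @return object of class `permutation_result` with `observed`, `null`,
#'   `n_perm`, `p_value`, `null_range`.
#' @export
permutation_result <- function(observed, null) {
  stopifnot(is.numeric(observed), length(observed) == 1L,
            is.numeric(null), length(null) >= 1L)
  structure(list(observed = observed, null = null,
                 n_perm = length(null),
                 p_value = (1 + sum(null >= observed)) / (1 + length(null)),
                 null_range = range(null)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed %.4g, null range [%.4g, %.4g] (N = %d), p = %.4g\n",
    x$observed, x$null_range[1], x$null_range[2], x$n_perm, x$p_value))
  invisible(x)
}

#' Intra-chromosomal enrichment of parallelisms
#'
#' Tests whether parallelisms fall between same-chromosome paralogs more
#' often than expected if they occurred at random within duplicated
#' sequence space.  The observed statistic is the fraction of
#' parallelisms whose two SNPs lie on one chromosome; each null
#' replicate draws the same number of unique one-to-one aligned
#' positions from the supplied pass-mask position pool, agnostic to
#' variant status, and recomputes the fraction.
#'
#' @param pairs parallelism pairs (data frame with `chromA`, `chromB`);
#'   deduplicated internally when `klass` is present.
#' @param position_pool data frame of candidate aligned positions with
#'   `chromA`, `chromB` (one row per unique pass-mask aligned position
#'   across all alignments).
#' @param n_perm permutation replicates (default 1000).
#' @param seed integer seed.
#' @return a [permutation_result()].
#' @export
intra_chromosomal_enrichment <- function(pairs, position_pool,
                                         n_perm = 1000L, seed = 1L) {
  if ("klass" %in% names(pairs)) pairs <- dedup_parallelisms(pairs)
  n <- nrow(pairs)
  if (n == 0L) stop("no parallelisms to test")
  if (n > nrow(position_pool))
    stop("requested sample (", n, ") exceeds available aligned positions (",
         nrow(position_pool), ")")
  observed <- mean(pairs$chromA == pairs$chromB)
  set.seed(seed)
  intra_pool <- position_pool$chromA == position_pool$chromB
  null <- vapply(seq_len(n_perm), function(i)
    mean(intra_pool[sample.int(length(intra_pool), n)]), numeric(1))
  permutation_result(observed, null)
}

#' Shared-population test with allele-frequency matching
#'
#' Tests whether the two SNPs of a parallelism segregate in at least one
#' common population more often than random SNP pairs with matched
#' allele frequencies.  Each null replicate replaces every member SNP by
#' a SNP drawn at random from the full SNP table within the same minor
#' allele frequency bin (width `maf_bin_width`; an empty bin falls back
#' to the nearest non-empty bin, logged in attribute `"bin_log"`) and
#' recomputes the sharing fraction.
#'
#' @param pairs parallelism pairs with `popsA`, `popsB` (comma-joined
#'   population labels) and `mafA`, `mafB`.
#' @param snp_table full SNP table with `populations` and `maf`.
#' @param n_perm permutation replicates (default 1000).
#' @param seed integer seed.
#' @param maf_bin_width frequency bin width for matching (default 0.02).
#' @return a [permutation_result()]; the observed statistic is the
#'   fraction of pairs sharing >= 1 population.
#' @export
population_sharing_test <- function(pairs, snp_table, n_perm = 1000L,
                                    seed = 1L, maf_bin_width = 0.02) {
  if ("klass" %in% names(pairs)) pairs <- dedup_parallelisms(pairs)
  n <- nrow(pairs)
  if (n == 0L) stop("no parallelisms to test")
  levels <- sort(unique(unlist(strsplit(
    c(pairs$popsA, pairs$popsB, snp_table$populations), ",", fixed = TRUE))))
  if (length(levels) > 30L) stop("more than 30 population labels")
  mA <- pops_bitmask(pairs$popsA, levels)
  mB <- pops_bitmask(pairs$popsB, levels)
  observed <- mean(bitwAnd(mA, mB) > 0L)

  bin_of <- function(maf) as.integer(pmin(floor(maf / maf_bin_width),
                                          floor(0.5 / maf_bin_width)) + 1L)
  pool_bin <- bin_of(snp_table$maf)
  pool_mask <- pops_bitmask(snp_table$populations, levels)
  by_bin <- split(seq_along(pool_bin), pool_bin)
  occupied <- as.integer(names(by_bin))
  nearest <- function(b) as.integer(occupied[which.min(abs(occupied - b))])
  fallback <- 0L
  resolve <- function(b) {
    if (as.character(b) %in% names(by_bin)) return(b)
    fallback <<- fallback + 1L
    nearest(b)
  }
  binA <- vapply(bin_of(pairs$mafA), resolve, integer(1))
  binB <- vapply(bin_of(pairs$mafB), resolve, integer(1))

  set.seed(seed)
  draw_mask <- function(bins) {
    idx <- vapply(bins, function(b) {
      cand <- by_bin[[as.character(b)]]
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    pool_mask[idx]
  }
  null <- vapply(seq_len(n_perm), function(i)
    mean(bitwAnd(draw_mask(binA), draw_mask(binB)) > 0L), numeric(1))
  out <- permutation_result(observed, null)
  attr(out, "bin_log") <- c(empty_bin_fallbacks = fallback)
  out
}

#' Window clustering test for parallelism positions
#'
#' Tests, per alignment, whether parallelisms are uniformly distributed
#' along the alignment.  Counts parallelisms in non-overlapping windows
#' of `window` columns (complete windows only) and compares the counts
#' to the uniform expectation (total / number of windows) with a
#' chi-square goodness-of-fit test on `windows - 1` degrees of freedom.
#' Alignments shorter than `min_length` columns or with `min_count` or
#' fewer parallelisms are skipped (logged in attribute `"skipped"`).
#'
#' @param cols_by_aln named list: per alignment, the column indices of
#'   its parallelisms.
#' @param lengths named numeric vector of alignment lengths (columns),
#'   names matching `cols_by_aln`.
#' @param min_length minimum alignment length (default 10000).
#' @param min_count minimum parallelism count, exclusive (default 10).
#' @param window window width in columns (default 1000).
#' @return data frame with one row per tested alignment: `alignment`,
#'   `n_windows`, `n_parallelisms`, `statistic`, `df`, `p_value`, plus
#'   per-window counts in attribute `"window_counts"`.
#' @export
clustering_chi2 <- function(cols_by_aln, lengths, min_length = 10000L,
                            min_count = 10L, window = 1000L) {
  stopifnot(all(names(cols_by_aln) %in% names(lengths)))
  rows <- list()
  counts <- list()
  skipped <- character(0)
  for (nm in names(cols_by_aln)) {
    len <- lengths[[nm]]
    cols <- cols_by_aln[[nm]]
    nw <- len %/% window
    in_span <- cols[cols <= nw * window]
    if (len <= min_length || length(in_span) <= min_count || nw < 2L) {
      skipped <- c(skipped, nm)
      next
    }
    cnt <- tabulate((in_span - 1L) %/% window + 1L, nbins = nw)
    expct <- length(in_span) / nw
    stat <- sum((cnt - expct)^2 / expct)
    df <- nw - 1L
    rows[[nm]] <- data.frame(alignment = nm, n_windows = nw,
                             n_parallelisms = length(in_span),
                             statistic = stat, df = df,
                             p_value = stats::pchisq(stat, df,
                                                     lower.tail = FALSE))
    counts[[nm]] <- cnt
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(alignment = character(0), n_windows = integer(0),
               n_parallelisms = integer(0), statistic = numeric(0),
               df = integer(0), p_value = numeric(0))
  rownames(out) <- NULL
  attr(out, "window_counts") <- counts
  attr(out, "skipped") <- skipped
  out
}
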