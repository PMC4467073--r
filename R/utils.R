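DNA_BASES_ <- c("A", "C", "G", "T")

#' Complement nucleotide characters
#'
#' Vectorised single-character complement; `N` and `-` map to themselves.
#'
#' @param x character vector of single bases.
#' @return character vector of complemented bases.
#' @keywords internal
comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

## rotate a base to one of the other three: k in 1..3
rotate_base <- function(base, k) {
  i <- match(base, DNA_BASES_)
  DNA_BASES_[((i - 1L + k) %% 4L) + 1L]
}

#' CpG dinucleotide context of every position in a sequence
#'
#' A position is in CpG context when it is the C of a CpG or the G of a
#' CpG in the given sequence.  Because CpG is its own reverse complement,
#' scanning the forward strand covers both strands.  At the sequence
#' edges only the available neighbour is consulted.
#'
#' @param bases character vector of single bases (a split sequence).
#' @return logical vector, `TRUE` where the position lies in a CpG.
#' @export
cpg_context <- function(bases) {
  n <- length(bases)
  if (n == 0L) return(logical(0))
  nxt <- c(bases[-1L], "")
  prv <- c("", bases[-n])
  (bases == "C" & nxt == "G") | (bases == "G" & prv == "C")
}

#' Flag a SNP position as CpG-context
#'
#' @param seq a single sequence as a string, or a character vector of bases.
#' @param pos 1-based position within `seq`.
#' @return `TRUE` iff the position is the C or the G of a CpG dinucleotide
#'   on either strand of the reference.
#' @examples
#' cpg_flagger("ACGT", 2) # C of CpG
#' cpg_flagger("ACGT", 3) # G of CpG
#' cpg_flagger("ACAT", 2)
#' @export
cpg_flagger <- function(seq, pos) {
  bases <- if (length(seq) == 1L && nchar(seq[1L]) > 1L)
    strsplit(seq, "", fixed = TRUE)[[1L]] else seq
  stopifnot(pos >= 1L, pos <= length(bases))
  unname(cpg_context(bases)[pos])
}

#' Percentage with fixed rounding
#'
#' `100 * num / den` rounded to `digits` decimals; `NA` on a zero
#' denominator.  Used for all reported shared-SNP percentages.
#'
#' @param num,den numerator and denominator counts.
#' @param digits decimals to keep (default 2).
#' @export
fraction_pct <- function(num, den, digits = 2) {
  ifelse(den == 0, NA_real_, round(100 * num / den, digits))
}

#' Per-alignment fraction of SNPs attributable to IGC
#'
#' For an alignment with `n_parallel_snps` SNPs involved in parallelisms
#' out of `n_snps` SNPs in its well-aligned regions, one member of each
#' parallel pair is taken to be IGC-derived, so the IGC-derived fraction
#' is `(n_parallel_snps / 2) / n_snps`.
#'
#' @param n_parallel_snps number of SNPs involved in parallelisms.
#' @param n_snps total SNPs in high-quality aligned regions.
#' @export
alignment_igc_fraction <- function(n_parallel_snps, n_snps) {
  stopifnot(n_snps > 0)
  (n_parallel_snps / 2) / n_snps
}

## allele set as a canonical "X/Y" key, optionally complemented
allele_key <- function(ref, alt, complement = FALSE) {
  if (complement) {
    ref <- comp_base(ref)
    alt <- comp_base(alt)
  }
  ifelse(ref < alt, paste0(ref, "/", alt), paste0(alt, "/", ref))
}

## Beta sampler clamped to [lo, hi]: draws below lo become singletons
## (an allele observed at all has frequency >= 1/(2N)), draws above hi
## fold onto the maximum minor allele frequency
rbeta_trunc <- function(n, shape1, shape2, lo, hi) {
  pmin(pmax(stats::rbeta(n, shape1, shape2), lo), hi)
}

## comma-joined population labels -> integer bitmask (<= 30 populations)
pops_bitmask <- function(pops, levels) {
  sets <- strsplit(pops, ",", fixed = TRUE)
  vapply(sets, function(s) {
    i <- match(s, levels)
    i <- i[!is.na(i)]
    as.integer(sum(bitwShiftL(1L, i - 1L)))
  }, integer(1))
}
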