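#' Genomic interval
#'
#' Simple 1-based inclusive interval with strand, the unit of paralog
#' pair coordinates.  The genomicSuperDups-style pair table on disk uses
#' 0-based half-open coordinates; conversion happens at I/O only.
#'
#' @param chrom chromosome / sequence identifier.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid interval: require start <= end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand), class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s)\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

interval_width <- function(x) x$end - x$start + 1L

#' Pairwise paralog alignment
#'
#' Container for a global alignment of two paralogous sequences: the
#' gapped rows, the genomic intervals they came from, the pairwise
#' sequence identity (PSI; matching columns over columns where both rows
#' carry a base — gap columns enter neither numerator nor denominator),
#' and a per-column mask with reason codes.  Constructed by
#' [global_align()], [alignment_from_gapped()] or
#' [alignment_from_sim()].
#'
#' @param gappedA,gappedB aligned rows as strings over `A,C,G,T,N,-`;
#'   equal length, no column may be a gap in both rows.
#' @param intervalA,intervalB [genomic_interval()]s of the two rows; when
#'   `NULL`, placeholder intervals spanning the ungapped lengths on
#'   sequences `"seqA"`/`"seqB"` are used.
#' @param score optional alignment score.
#' @return an object of class `paralog_alignment` with elements `colsA`,
#'   `colsB` (character vectors of columns), `gappedA`, `gappedB`,
#'   `intervalA`, `intervalB`, `psi`, `score` and `mask` (character
#'   vector, `"pass"` until masks are applied).
#' @export
alignment_from_gapped <- function(gappedA, gappedB, intervalA = NULL,
                                  intervalB = NULL, score = NA_real_) {
  colsA <- toupper(strsplit(gappedA, "", fixed = TRUE)[[1L]])
  colsB <- toupper(strsplit(gappedB, "", fixed = TRUE)[[1L]])
  if (length(colsA) != length(colsB))
    stop("gapped rows must have equal length")
  if (!length(colsA)) stop("empty alignment")
  bad <- setdiff(unique(c(colsA, colsB)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("unexpected characters in alignment: ", paste(bad, collapse = ","))
  if (any(colsA == "-" & colsB == "-"))
    stop("alignment has columns gapped in both rows")
  lenA <- sum(colsA != "-")
  lenB <- sum(colsB != "-")
  if (is.null(intervalA)) intervalA <- genomic_interval("seqA", 1L, lenA, "+")
  if (is.null(intervalB)) intervalB <- genomic_interval("seqB", 1L, lenB, "+")
  if (interval_width(intervalA) != lenA || interval_width(intervalB) != lenB)
    stop("interval width does not match ungapped row length")
  base_cols <- colsA != "-" & colsB != "-"
  psi <- if (any(base_cols)) mean(colsA[base_cols] == colsB[base_cols])
         else NA_real_
  structure(list(colsA = colsA, colsB = colsB,
                 gappedA = paste(colsA, collapse = ""),
                 gappedB = paste(colsB, collapse = ""),
                 intervalA = intervalA, intervalB = intervalB,
                 psi = psi, score = score,
                 mask = rep("pass", length(colsA))),
            class = "paralog_alignment")
}

#' @export
print.paralog_alignment <- function(x, ...) {
  cat(sprintf("Paralog alignment: %d columns, PSI %.4f, %d masked\n",
              length(x$colsA), x$psi, sum(x$mask != "pass")))
  cat("  A: "); print(x$intervalA)
  cat("  B: "); print(x$intervalB)
  invisible(x)
}

#' Number of alignment columns
#' @param aln a `paralog_alignment`.
#' @keywords internal
aln_length <- function(aln) length(aln$colsA)

#' Globally align two paralogous sequences
#'
#' Optimal global (Needleman-Wunsch) alignment under affine gap scoring,
#' computed with [Biostrings::pairwiseAlignment()].  Default scoring
#' mirrors EMBOSS stretcher DNA defaults: match +5, mismatch -4, gap
#' open 16, gap extend 4; a gap run of length k costs
#' `gap_open + k * gap_extend`.
#'
#' @param seqA,seqB nucleotide sequences (strings); both non-empty.
#' @param intervalA,intervalB optional [genomic_interval()]s.
#' @param scoring list with `match`, `mismatch`, `gap_open`,
#'   `gap_extend`.
#' @return a `paralog_alignment` (see [alignment_from_gapped()]).
#' @examples
#' aln <- global_align("ACGT", "AGT")
#' aln$psi
#' @export
global_align <- function(seqA, seqB, intervalA = NULL, intervalB = NULL,
                         scoring = list(match = 5, mismatch = -4,
                                        gap_open = 16, gap_extend = 4)) {
  if (!nzchar(seqA) || !nzchar(seqB))
    stop("cannot align an empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seqA), Biostrings::DNAString(seqB),
    substitutionMatrix = mat, gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend, type = "global")
  alignment_from_gapped(
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)),
    intervalA, intervalB, score = Biostrings::score(pa))
}

#' Build the alignment object from a simulated pair's true correspondence
#'
#' Uses the generator's known gapped rows instead of re-aligning, so
#' downstream masking and detection operate on the exact simulated
#' homology.
#'
#' @param pair an `sd_pair_sim` from [simulate_sd_pair()]; if the pair
#'   carries `intervalA`/`intervalB` (as from [simulate_cohort()]) they
#'   are used.
#' @return a `paralog_alignment`.
#' @export
alignment_from_sim <- function(pair) {
  stopifnot(inherits(pair, "sd_pair_sim"))
  alignment_from_gapped(pair$gappedA, pair$gappedB,
                        pair$intervalA, pair$intervalB)
}

#' Read a pairwise alignment from aligned FASTA
#'
#' Imports an externally produced pairwise alignment stored as a two-
#' record FASTA of equal-length gapped sequences.
#'
#' @param file path to an aligned FASTA with exactly two records.
#' @inheritParams alignment_from_gapped
#' @return a `paralog_alignment`.
#' @export
read_paralog_alignment <- function(file, intervalA = NULL, intervalB = NULL) {
  ss <- Biostrings::readBStringSet(file)
  if (length(ss) != 2L)
    stop("aligned FASTA must contain exactly two records: ", file)
  alignment_from_gapped(as.character(ss[[1L]]), as.character(ss[[2L]]),
                        intervalA, intervalB)
}

#' Write a pairwise alignment as aligned FASTA
#' @param aln a `paralog_alignment`.
#' @param file output path.
#' @export
write_paralog_alignment <- function(aln, file) {
  ss <- Biostrings::BStringSet(c(aln$gappedA, aln$gappedB))
  names(ss) <- c(sprintf("%s:%d-%d(%s)", aln$intervalA$chrom,
                         aln$intervalA$start, aln$intervalA$end,
                         aln$intervalA$strand),
                 sprintf("%s:%d-%d(%s)", aln$intervalB$chrom,
                         aln$intervalB$start, aln$intervalB$end,
                         aln$intervalB$strand))
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}
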