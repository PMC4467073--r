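#' Map alignment columns to genomic positions
#'
#' Every non-gap cell of the alignment maps to exactly one genomic
#' position of its paralog; minus-strand intervals map columns in
#' decreasing genomic order.  The inverse lookup (position to column) is
#' a `match()` against the returned vectors.
#'
#' @param aln a `paralog_alignment`.
#' @return data frame with `col`, `chromA`, `posA`, `chromB`, `posB`
#'   (positions 1-based, `NA` at gaps).
#' @export
map_columns <- function(aln) {
  stopifnot(inherits(aln, "paralog_alignment"))
  one <- function(cols, interval) {
    isbase <- cols != "-"
    off <- cumsum(isbase)
    if (interval$strand == "+") {
      ifelse(isbase, interval$start + off - 1L, NA_integer_)
    } else {
      ifelse(isbase, interval$end - off + 1L, NA_integer_)
    }
  }
  data.frame(col = seq_len(aln_length(aln)),
             chromA = aln$intervalA$chrom,
             posA = one(aln$colsA, aln$intervalA),
             chromB = aln$intervalB$chrom,
             posB = one(aln$colsB, aln$intervalB))
}

#' Look up the alignment column of a genomic position
#'
#' @param aln a `paralog_alignment`.
#' @param pos genomic position(s), 1-based.
#' @param side `"A"` or `"B"`.
#' @return integer column indices (`NA` when the position is gapped out).
#' @export
position_to_column <- function(aln, pos, side = c("A", "B")) {
  side <- match.arg(side)
  cm <- map_columns(aln)
  iv <- if (side == "A") aln$intervalA else aln$intervalB
  if (any(pos < iv$start | pos > iv$end))
    stop("position outside the paralog interval")
  match(pos, if (side == "A") cm$posA else cm$posB)
}

#' Classify aligned site pairs against SNP calls
#'
#' Intersects a (masked) paralog alignment with per-paralog biallelic
#' SNP tables and classifies every aligned position carrying at least
#' one SNP.  Allele sets are compared in alignment space: alleles of a
#' paralog on the minus strand are complemented before comparison.
#' Classes: `parallelism` (both positions are SNPs with identical
#' allele sets), `alt3` / `alt4` (both SNPs, allele-set union of 3 / 4
#' bases), `single` (one side only).
#'
#' @param aln a `paralog_alignment` (mask applied or not).
#' @param snpsA,snpsB data frames of biallelic SNPs on copy A / copy B
#'   with columns `pos` (genomic, matching the alignment intervals),
#'   `ref`, `alt`; optional `snp_id`, `maf`, `populations`, `cpg`,
#'   `unique_ok` are carried through when present.
#' @param apply_mask drop site pairs at masked columns (default `TRUE`);
#'   when `FALSE` all pairs are returned and the `pass_mask` column
#'   records mask status.
#' @param alignment_id identifier stored with every pair (default 1).
#' @return data frame of classified site pairs (one row per aligned
#'   position with >= 1 SNP) with columns `alignment_id`, `col`,
#'   `chromA`, `posA`, `chromB`, `posB`, ids, allele keys, per-side
#'   `maf`/`populations`/`cpg`/`unique_ok`, `klass` and `pass_mask`.
#'   Attribute `"filter_log"` counts SNP-carrying columns removed by the
#'   mask.
#' @export
classify_site_pairs <- function(aln, snpsA, snpsB, apply_mask = TRUE,
                                alignment_id = 1L) {
  stopifnot(inherits(aln, "paralog_alignment"))
  check_biallelic <- function(s, side) {
    if (!nrow(s)) return(invisible())
    stopifnot(all(c("pos", "ref", "alt") %in% names(s)))
    if (any(s$ref == s$alt) ||
        !all(c(s$ref, s$alt) %in% c("A", "C", "G", "T")))
      stop("SNP table ", side, " must be biallelic over A/C/G/T with ref != alt")
    if (anyDuplicated(s$pos))
      stop("duplicate SNP positions in table ", side)
  }
  check_biallelic(snpsA, "A")
  check_biallelic(snpsB, "B")

  cm <- map_columns(aln)
  iA <- match(cm$posA, snpsA$pos)
  iB <- match(cm$posB, snpsB$pos)
  hit <- !is.na(iA) | !is.na(iB)
  cm <- cm[hit, , drop = FALSE]
  iA <- iA[hit]
  iB <- iB[hit]
  pass <- aln$mask[cm$col] == "pass"

  grab <- function(s, i, field, default) {
    if (field %in% names(s)) s[[field]][i] else rep(default, length(i))
  }
  keyA <- ifelse(is.na(iA), NA_character_,
                 allele_key(snpsA$ref[iA], snpsA$alt[iA],
                            complement = aln$intervalA$strand == "-"))
  keyB <- ifelse(is.na(iB), NA_character_,
                 allele_key(snpsB$ref[iB], snpsB$alt[iB],
                            complement = aln$intervalB$strand == "-"))
  both <- !is.na(iA) & !is.na(iB)
  klass <- rep("single", nrow(cm))
  if (any(both)) {
    basesA <- strsplit(keyA[both], "/", fixed = TRUE)
    basesB <- strsplit(keyB[both], "/", fixed = TRUE)
    usize <- mapply(function(x, y) length(unique(c(x, y))), basesA, basesB)
    klass[both] <- ifelse(keyA[both] == keyB[both], "parallelism",
                          ifelse(usize == 3L, "alt3", "alt4"))
  }

  out <- data.frame(
    alignment_id = alignment_id,
    col = cm$col, chromA = cm$chromA, posA = cm$posA,
    chromB = cm$chromB, posB = cm$posB,
    idA = grab(snpsA, iA, "snp_id", NA_character_),
    idB = grab(snpsB, iB, "snp_id", NA_character_),
    allelesA = keyA, allelesB = keyB,
    mafA = grab(snpsA, iA, "maf", NA_real_),
    mafB = grab(snpsB, iB, "maf", NA_real_),
    popsA = grab(snpsA, iA, "populations", NA_character_),
    popsB = grab(snpsB, iB, "populations", NA_character_),
    cpgA = grab(snpsA, iA, "cpg", NA),
    cpgB = grab(snpsB, iB, "cpg", NA),
    uniqueA = grab(snpsA, iA, "unique_ok", NA),
    uniqueB = grab(snpsB, iB, "unique_ok", NA),
    klass = klass,
    pass_mask = pass)
  n_masked_snp_cols <- sum(!pass)
  if (apply_mask) out <- out[out$pass_mask, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- c(snp_columns_total = length(pass),
                               snp_columns_masked = n_masked_snp_cols)
  out
}

#' Per-sample read-uniqueness filter for a SNP call set
#'
#' A sample's call at a SNP passes iff every supporting read unit maps
#' to a single best location (`X0 == 1`), has at most five suboptimal
#' hit positions (`X1 <= 5`), and every suboptimal placement carries at
#' least two more mismatches than the optimal placement
#' (`NM_subopt_min - NM_best >= 2`, vacuous when `X1 == 0`).  Mate-pair
#' rescue is assumed already encoded in the read units.  A SNP is
#' retained (`unique_ok`) iff at least one sample passes; samples with
#' no metadata fail and are logged.
#'
#' @param reads data frame with columns `snp_id`, `sample`, `X0`, `X1`,
#'   `NM_best`, `NM_subopt_min` (and optionally `proper_pair`).
#' @param samples optional character vector of samples that must be
#'   accounted for at every SNP; missing combinations fail.
#' @return list with `per_sample` (snp_id, sample, pass) and `snps`
#'   (snp_id, unique_ok); attribute `"filter_log"` on `per_sample`
#'   counts missing-metadata failures.
#' @export
unique_mapping_filter <- function(reads, samples = NULL) {
  stopifnot(all(c("snp_id", "sample", "X0", "X1", "NM_best",
                  "NM_subopt_min") %in% names(reads)))
  if (any(reads$X0 < 0 | reads$X1 < 0 | reads$NM_best < 0 |
          reads$NM_subopt_min < 0))
    stop("read-mapping counts must be >= 0")
  ok <- reads$X0 == 1L & reads$X1 <= 5L &
    (reads$X1 == 0L | (reads$NM_subopt_min - reads$NM_best) >= 2L)
  key <- paste(reads$snp_id, reads$sample, sep = "\r")
  pass <- tapply(ok, key, all)
  ps <- data.frame(snp_id = sub("\r.*$", "", names(pass)),
                   sample = sub("^.*\r", "", names(pass)),
                   pass = as.logical(pass))
  n_missing <- 0L
  if (!is.null(samples)) {
    full <- expand.grid(snp_id = unique(reads$snp_id), sample = samples,
                        stringsAsFactors = FALSE)
    full$key <- paste(full$snp_id, full$sample, sep = "\r")
    miss <- !(full$key %in% key)
    n_missing <- sum(miss)
    if (n_missing)
      ps <- rbind(ps, data.frame(snp_id = full$snp_id[miss],
                                 sample = full$sample[miss], pass = FALSE))
  }
  snp_pass <- tapply(ps$pass, ps$snp_id, any)
  attr(ps, "filter_log") <- c(samples_missing_metadata = n_missing)
  list(per_sample = ps,
       snps = data.frame(snp_id = names(snp_pass),
                         unique_ok = as.logical(snp_pass),
                         row.names = NULL))
}
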