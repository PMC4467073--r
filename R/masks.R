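#' Windowed-identity mask
#'
#' Computes PSI in non-overlapping windows of `window` columns (complete
#' windows only; a trailing partial window is ignored) and masks every
#' column of windows whose PSI falls more than two standard deviations
#' below the mean window PSI of the alignment.  Window PSI, like
#' alignment PSI, is matches over gap-free columns; a window with no
#' gap-free columns has undefined PSI and is left unmasked by this rule.
#'
#' @param aln a `paralog_alignment`.
#' @param window window width in columns (default 100).
#' @param n_sd number of standard deviations below the mean (default 2).
#' @return logical vector over columns, `TRUE` where masked
#'   (reason `low_psi_window`), with the per-window PSI table in
#'   attribute `"windows"`.
#' @export
window_psi_mask <- function(aln, window = 100L, n_sd = 2) {
  n <- aln_length(aln)
  nw <- n %/% window
  mask <- logical(n)
  if (nw < 1L) {
    warning("alignment shorter than one window; no windowed-PSI masking")
    attr(mask, "windows") <- data.frame(window = integer(0), psi = numeric(0),
                                        masked = logical(0))
    return(mask)
  }
  head_n <- nw * window
  wid <- rep(seq_len(nw), each = window)
  base_cols <- aln$colsA[1:head_n] != "-" & aln$colsB[1:head_n] != "-"
  match_cols <- base_cols & aln$colsA[1:head_n] == aln$colsB[1:head_n]
  nb <- tapply(base_cols, wid, sum)
  nm <- tapply(match_cols, wid, sum)
  psi_w <- ifelse(nb > 0, nm / nb, NA_real_)
  mu <- mean(psi_w, na.rm = TRUE)
  sdev <- stats::sd(psi_w, na.rm = TRUE)
  bad <- !is.na(psi_w) & !is.na(sdev) & psi_w < mu - n_sd * sdev
  mask[1:head_n] <- bad[wid]
  attr(mask, "windows") <- data.frame(window = seq_len(nw),
                                      psi = as.numeric(psi_w),
                                      masked = as.logical(bad))
  mask
}

#' Local Hamming-distance mask (5-column sub-alignments)
#'
#' For each column with two flanking columns on each side, computes the
#' Hamming distance between the two rows of the centred 5-column
#' sub-alignment, counting a gap opposite a base as a mismatch, and
#' masks the focal column when the distance exceeds 2.  Columns carrying
#' `N` in either row are also masked under this reason (ambiguity codes
#' give no usable allele comparison).
#'
#' @param aln a `paralog_alignment`.
#' @param flank columns on each side of the focal column (default 2).
#' @param max_dist maximum tolerated Hamming distance (default 2).
#' @return logical vector over columns (reason `local_hamming`).
#' @export
local_hamming_mask <- function(aln, flank = 2L, max_dist = 2L) {
  n <- aln_length(aln)
  d <- as.numeric(aln$colsA != aln$colsB)
  width <- 2L * flank + 1L
  mask <- logical(n)
  if (n >= width) {
    rs <- stats::filter(d, rep(1, width), sides = 2)
    mask <- !is.na(rs) & rs > max_dist
  }
  mask | aln$colsA == "N" | aln$colsB == "N"
}

#' Indel-proximity and alignment-edge masks
#'
#' Masks every column within `indel_radius` columns of a gap column
#' (gap columns themselves included; reason `near_indel`) and the first
#' and last `edge` columns of the alignment (reason `edge`).
#'
#' @param aln a `paralog_alignment`.
#' @param indel_radius columns flanking each gap run (default 10).
#' @param edge columns trimmed at each end (default 100).
#' @return list of two logical vectors, `near_indel` and `edge`.
#' @export
boundary_indel_mask <- function(aln, indel_radius = 10L, edge = 100L) {
  n <- aln_length(aln)
  gapc <- aln$colsA == "-" | aln$colsB == "-"
  near <- logical(n)
  if (any(gapc)) {
    ## dilate gap columns by indel_radius via windowed cumulative counts
    cs <- c(0, cumsum(gapc))
    i <- seq_len(n)
    hi <- pmin(n, i + indel_radius)
    lo <- pmax(0L, i - indel_radius - 1L)
    near <- (cs[hi + 1L] - cs[lo + 1L]) > 0
  }
  edge_mask <- logical(n)
  k <- min(edge, n)
  if (k > 0) {
    edge_mask[seq_len(k)] <- TRUE
    edge_mask[seq.int(max(1L, n - k + 1L), n)] <- TRUE
  }
  list(near_indel = near, edge = edge_mask)
}

#' Combine column masks onto an alignment
#'
#' Takes named logical masks (names are reason codes), verifies their
#' length, and stores their union on the alignment: a column passes iff
#' no reason applies.  When several reasons apply to a column the stored
#' reason is the first in the order given.  The full reason matrix and a
#' summary (masked columns, fraction masked, per-reason counts) are
#' attached.
#'
#' @param aln a `paralog_alignment`.
#' @param masks named list of logical vectors, one per reason code.
#' @return the alignment with `$mask` set (`"pass"` or a reason code),
#'   `$mask_matrix` and `$mask_summary`.
#' @export
combine_masks <- function(aln, masks) {
  stopifnot(inherits(aln, "paralog_alignment"), is.list(masks))
  n <- aln_length(aln)
  if (length(masks)) {
    if (is.null(names(masks)) || any(!nzchar(names(masks))))
      stop("masks must be a named list of reason codes")
    lens <- vapply(masks, length, integer(1))
    if (any(lens != n))
      stop("mask length does not match alignment length (",
           n, " columns): ", paste(names(masks)[lens != n], collapse = ","))
  }
  mm <- if (length(masks))
    do.call(cbind, lapply(masks, as.logical))
  else matrix(FALSE, n, 0)
  reason <- rep("pass", n)
  for (nm in rev(names(masks))) reason[masks[[nm]]] <- nm
  aln$mask <- reason
  aln$mask_matrix <- mm
  masked <- reason != "pass"
  aln$mask_summary <- list(
    n_columns = n,
    n_masked = sum(masked),
    fraction_masked = mean(masked),
    by_reason = if (ncol(mm)) colSums(mm) else integer(0))
  aln
}

#' Apply the full alignment-quality masking recipe
#'
#' Runs the three masking rules in order — windowed PSI, local Hamming,
#' indel/edge exclusion — and combines them.  Window PSI statistics are
#' computed over all complete windows before any other mask is applied.
#'
#' @param aln a `paralog_alignment`.
#' @param window windowed-PSI window width (default 100 columns).
#' @param indel_radius columns excluded around each indel (default 10).
#' @param edge columns trimmed at each alignment end (default 100).
#' @return the alignment with masks applied (see [combine_masks()]).
#' @export
apply_quality_masks <- function(aln, window = 100L, indel_radius = 10L,
                                edge = 100L) {
  wp <- suppressWarnings(window_psi_mask(aln, window = window))
  lh <- local_hamming_mask(aln)
  bi <- boundary_indel_mask(aln, indel_radius = indel_radius, edge = edge)
  combine_masks(aln, list(low_psi_window = as.logical(wp),
                          local_hamming = lh,
                          near_indel = bi$near_indel,
                          edge = bi$edge))
}

#' Dataset-wide mask summary
#'
#' @param alns list of masked `paralog_alignment`s.
#' @return data frame with one row per alignment (columns, masked,
#'   fraction) plus the dataset mean fraction in attribute
#'   `"mean_fraction_masked"`.
#' @export
mask_summary <- function(alns) {
  rows <- lapply(seq_along(alns), function(i) {
    s <- alns[[i]]$mask_summary
    if (is.null(s)) stop("alignment ", i, " has no masks applied")
    data.frame(alignment = i, n_columns = s$n_columns,
               n_masked = s$n_masked, fraction_masked = s$fraction_masked)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_fraction_masked") <- mean(out$fraction_masked)
  out
}

#' Export masked columns as BED intervals on paralog A
#'
#' Masked columns are mapped to copy-A genomic coordinates, merged into
#' runs, and written as 0-based half-open BED records with the reason
#' code in the name field.  Columns gapped in A have no A coordinate and
#' are skipped.
#'
#' @param aln a masked `paralog_alignment`.
#' @param file output path.
#' @export
write_mask_bed <- function(aln, file) {
  cm <- map_columns(aln)
  masked <- aln$mask != "pass" & !is.na(cm$posA)
  con <- file(file, "w")
  on.exit(close(con))
  if (any(masked)) {
    pos <- sort(cm$posA[masked])
    reason <- aln$mask[masked][order(cm$posA[masked])]
    brk <- c(TRUE, diff(pos) != 1L | reason[-1L] != reason[-length(reason)])
    run <- cumsum(brk)
    starts <- tapply(pos, run, min)
    ends <- tapply(pos, run, max)
    reasons <- tapply(reason, run, function(x) x[[1L]])
    writeLines(sprintf("%s\t%d\t%d\t%s", aln$intervalA$chrom,
                       as.integer(starts) - 1L, as.integer(ends), reasons),
               con)
  }
  invisible(file)
}
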