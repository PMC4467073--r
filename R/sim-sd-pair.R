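#' Simulate a segmental-duplication paralog pair with known alignment
#'
#' Generates a random ancestral sequence, derives two paralogous copies
#' by sprinkling substitutions to reach the target pairwise sequence
#' identity (PSI), and applies Poisson-distributed insertion/deletion
#' events with geometric lengths.  Because both copies descend from the
#' same ancestral coordinate line, the true column-level correspondence
#' between the copies is known exactly and is returned alongside the
#' sequences; every ancestral position appears in the correspondence
#' with its coordinate in each copy (or a gap when deleted).
#'
#' Divergence model: each ancestral site mismatches with probability
#' `1 - target_psi`; the mismatch is realised by mutating one randomly
#' chosen copy to a uniformly chosen different base.  Realised PSI is
#' therefore binomial around the target.
#'
#' @param config a [sim_config()]; `ancestral_length` must be >= 1000.
#' @return an object of class `sd_pair_sim`: a list with elements
#'   `seqA`, `seqB` (ungapped strings), `gappedA`, `gappedB` (the true
#'   alignment), `colmap` (data frame with `col`, `anc` ancestral
#'   position or `NA` for inserted columns, `posA`, `posB` 1-based
#'   positions or `NA` at gaps), `psi` (realised identity over gap-free
#'   columns) and the `config`.
#' @examples
#' pair <- simulate_sd_pair(sim_config(seed = 7, ancestral_length = 2000))
#' pair$psi
#' @export
simulate_sd_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$ancestral_length
  if (L < 1000L)
    stop("ancestral_length must be >= 1000 (segmental duplications are >= 1 kb)")
  set.seed(config$seed)

  anc <- sample(DNA_BASES_, L, replace = TRUE)
  a <- anc
  b <- anc

  ## substitutions toward the PSI target
  idx <- which(stats::runif(L) < (1 - config$target_psi))
  if (length(idx)) {
    to_a <- sample(c(TRUE, FALSE), length(idx), replace = TRUE)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    ia <- idx[to_a]
    ib <- idx[!to_a]
    if (length(ia)) a[ia] <- rotate_base(a[ia], shift[to_a])
    if (length(ib)) b[ib] <- rotate_base(b[ib], shift[!to_a])
  }

  ## indel events on the ancestral coordinate line
  n_ev <- stats::rpois(1L, config$indel_rate * L)
  delA <- logical(L)
  delB <- logical(L)
  ins <- list()
  if (n_ev > 0) {
    for (e in seq_len(n_ev)) {
      len <- stats::rgeom(1L, 1 / max(config$indel_mean_len, 1)) + 1L
      copy <- sample(c("A", "B"), 1L)
      if (stats::runif(1L) < 0.5) { # deletion of ancestral sequence
        start <- sample.int(max(1L, L - len + 1L), 1L)
        span <- start:min(L, start + len - 1L)
        if (copy == "A") delA[span] <- TRUE else delB[span] <- TRUE
      } else {                      # copy-specific insertion
        ins[[length(ins) + 1L]] <- list(
          anchor = sample.int(L + 1L, 1L) - 1L, # insert after this position
          copy = copy, event = e,
          bases = sample(DNA_BASES_, len, replace = TRUE))
      }
    }
  }

  ## assemble true alignment columns in ancestral order
  keep <- !(delA & delB)
  gA <- ifelse(delA, "-", a)[keep]
  gB <- ifelse(delB, "-", b)[keep]
  ancpos <- which(keep)
  sortkey <- as.numeric(ancpos)
  for (iv in ins) {
    m <- length(iv$bases)
    if (iv$copy == "A") {
      gA <- c(gA, iv$bases)
      gB <- c(gB, rep("-", m))
    } else {
      gA <- c(gA, rep("-", m))
      gB <- c(gB, iv$bases)
    }
    ancpos <- c(ancpos, rep(NA_integer_, m))
    sortkey <- c(sortkey, iv$anchor + (iv$event + seq_len(m) / (m + 1)) /
                   (n_ev + 2))
  }
  o <- order(sortkey)
  gA <- gA[o]
  gB <- gB[o]
  ancpos <- ancpos[o]

  posA <- ifelse(gA == "-", NA_integer_, cumsum(gA != "-"))
  posB <- ifelse(gB == "-", NA_integer_, cumsum(gB != "-"))
  base_cols <- gA != "-" & gB != "-"
  psi <- mean(gA[base_cols] == gB[base_cols])

  structure(list(
    seqA = paste(gA[gA != "-"], collapse = ""),
    seqB = paste(gB[gB != "-"], collapse = ""),
    gappedA = paste(gA, collapse = ""),
    gappedB = paste(gB, collapse = ""),
    colmap = data.frame(col = seq_along(gA), anc = ancpos,
                        posA = posA, posB = posB),
    psi = psi,
    n_indel_events = n_ev,
    config = config
  ), class = "sd_pair_sim")
}

#' @export
print.sd_pair_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated SD pair: %d/%d bp (A/B), %d alignment columns, PSI %.4f\n",
    nchar(x$seqA), nchar(x$seqB), nrow(x$colmap), x$psi))
  invisible(x)
}
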