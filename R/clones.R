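#' Probability that clone sequencing shows a single allele
#'
#' For a balanced heterozygous site covered by `n_clones` independent
#' clone sequences, the probability that only one of the two alleles is
#' represented among the clones is `2 * 0.5^n` (each allele is missed
#' entirely with probability `0.5^n`, assuming no allele bias), capped
#' at 1.
#'
#' @param n_clones number of independent clones covering the site (>= 1).
#' @return probability in (0, 1].
#' @examples
#' clone_single_allele_prob(5) # 0.0625
#' @export
clone_single_allele_prob <- function(n_clones) {
  if (!is.numeric(n_clones) || length(n_clones) != 1L || n_clones < 1)
    stop("n_clones must be a single count >= 1")
  min(1, 2 * 0.5^n_clones)
}

#' Clone-based concordance call for one parallelism
#'
#' Validates a parallelism against clone-pool base calls: `validated`
#' when both sites are covered by at least `min_clones` clones and both
#' alleles of each SNP appear among the clone calls; `refuted` when
#' coverage is sufficient at both sites but only one allele is observed
#' at either site; `insufficient` otherwise.  Clone records with allele
#' symbols other than the site's two alleles are rejected and logged.
#'
#' @param site_alleles list of two character vectors, the (ref, alt)
#'   alleles of the two member SNPs, named by site id.
#' @param clone_calls data frame with `site_id`, `clone_id`, `allele`.
#' @param min_clones minimum clone coverage per site (default 5).
#' @return character scalar: `"validated"`, `"refuted"` or
#'   `"insufficient"`, with attribute `"n_rejected"` counting dropped
#'   clone records.
#' @export
clone_concordance <- function(site_alleles, clone_calls, min_clones = 5L) {
  stopifnot(length(site_alleles) == 2L, !is.null(names(site_alleles)))
  n_rejected <- 0L
  status <- character(2)
  for (i in 1:2) {
    sid <- names(site_alleles)[i]
    alleles <- site_alleles[[i]]
    calls <- clone_calls[clone_calls$site_id == sid, , drop = FALSE]
    bad <- !(calls$allele %in% alleles)
    if (any(bad)) {
      warning(sum(bad), " clone call(s) at ", sid,
              " carry alleles outside {", paste(alleles, collapse = ","),
              "}; rejected")
      n_rejected <- n_rejected + sum(bad)
      calls <- calls[!bad, , drop = FALSE]
    }
    status[i] <- if (nrow(calls) < min_clones) "insufficient"
      else if (all(alleles %in% calls$allele)) "both_alleles"
      else "one_allele"
  }
  out <- if (any(status == "insufficient")) "insufficient"
    else if (all(status == "both_alleles")) "validated"
    else "refuted"
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Validate a parallelism catalog against clone pools
#'
#' Applies [clone_concordance()] to every parallelism whose member sites
#' appear in the clone table.
#'
#' @param pairs parallelism pairs with `chromA`, `posA`, `chromB`,
#'   `posB`, `allelesA`, `allelesB` (allele keys `"X/Y"`).
#' @param clone_calls data frame with `site_id` (`chrom:pos`),
#'   `clone_id`, `allele`.
#' @param min_clones minimum clone coverage per site (default 5).
#' @return data frame with one row per parallelism: `siteA`, `siteB`,
#'   `status`.
#' @export
clone_validate <- function(pairs, clone_calls, min_clones = 5L) {
  if ("klass" %in% names(pairs)) pairs <- dedup_parallelisms(pairs)
  if (!nrow(pairs))
    return(data.frame(siteA = character(0), siteB = character(0),
                      status = character(0)))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    sa <- site_key(pairs$chromA[i], pairs$posA[i])
    sb <- site_key(pairs$chromB[i], pairs$posB[i])
    al <- list(strsplit(pairs$allelesA[i], "/", fixed = TRUE)[[1L]],
               strsplit(pairs$allelesB[i], "/", fixed = TRUE)[[1L]])
    names(al) <- c(sa, sb)
    data.frame(siteA = sa, siteB = sb,
               status = as.character(clone_concordance(al, clone_calls,
                                                       min_clones)))
  })
  do.call(rbind, out)
}
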