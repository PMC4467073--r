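site_key <- function(chrom, pos) paste0(chrom, ":", pos)

## deduplicate parallelism pairs by unordered pair of genomic sites
dedup_parallelisms <- function(pairs) {
  par <- pairs[pairs$klass == "parallelism", , drop = FALSE]
  if (!nrow(par)) return(par)
  kA <- site_key(par$chromA, par$posA)
  kB <- site_key(par$chromB, par$posB)
  ek <- paste(pmin(kA, kB), pmax(kA, kB), sep = "|")
  par[!duplicated(ek), , drop = FALSE]
}

#' Group parallelisms into connected components
#'
#' Builds a graph whose nodes are genomic SNP sites and whose edges are
#' shared-allele aligned pairs (deduplicated by unordered site pair
#' across redundant, nested alignments), and extracts connected
#' components.  A component of dimension n >= 3 is a higher-order
#' parallelism: one SNP site linked to several paralogous acceptor
#' sites.
#'
#' @param pairs classified site pairs from [classify_site_pairs()]
#'   (possibly concatenated over alignments); only rows with
#'   `klass == "parallelism"` are used.
#' @return object of class `parallelism_groups`: list with `groups`
#'   (data frame `group_id`, `dimension`), `membership` (site,
#'   group_id), `n_edges` (deduplicated pairwise parallelisms),
#'   `n_higher_order` (components with dimension >= 3) and `n_snps`
#'   (distinct SNP sites involved).
#' @export
build_groups <- function(pairs) {
  par <- dedup_parallelisms(pairs)
  if (!nrow(par)) {
    return(structure(list(
      groups = data.frame(group_id = integer(0), dimension = integer(0)),
      membership = data.frame(site = character(0), group_id = integer(0)),
      n_edges = 0L, n_higher_order = 0L, n_snps = 0L),
      class = "parallelism_groups"))
  }
  kA <- site_key(par$chromA, par$posA)
  kB <- site_key(par$chromB, par$posB)
  g <- igraph::graph_from_edgelist(cbind(kA, kB), directed = FALSE)
  comp <- igraph::components(g)
  structure(list(
    groups = data.frame(group_id = seq_len(comp$no),
                        dimension = as.integer(comp$csize)),
    membership = data.frame(site = names(comp$membership),
                            group_id = as.integer(comp$membership),
                            row.names = NULL),
    n_edges = nrow(par),
    n_higher_order = sum(comp$csize >= 3L),
    n_snps = igraph::vcount(g)),
    class = "parallelism_groups")
}

#' @export
print.parallelism_groups <- function(x, ...) {
  cat(sprintf(
    "Parallelism groups: %d edges, %d groups (%d of dimension >= 3), %d SNPs\n",
    x$n_edges, nrow(x$groups), x$n_higher_order, x$n_snps))
  invisible(x)
}

#' Number of SNPs attributable to IGC
#'
#' For an n-dimensional parallelism group, n - 1 member SNPs are taken
#' to have arisen via IGC following a single mutation at one paralog;
#' the estimator sums k * (n - 1) over the observed counts k of
#' n-dimensional groups.
#'
#' @param groups a `parallelism_groups` object, or a data frame with a
#'   `dimension` column.
#' @param sd_snp_total optional denominator (SNPs in segmental
#'   duplications surviving the same filters); when given, the
#'   percentage of SD SNPs due to IGC is attached.
#' @return integer count, with attribute `"percentage"` when a
#'   denominator was supplied.
#' @examples
#' g <- data.frame(dimension = c(2, 2, 2, 3, 3, 5))
#' igc_snp_count(g) # 3*1 + 2*2 + 1*4
#' @export
igc_snp_count <- function(groups, sd_snp_total = NULL) {
  dims <- if (inherits(groups, "parallelism_groups")) groups$groups$dimension
          else groups$dimension
  if (is.null(dims)) stop("no group dimensions found")
  if (length(dims) && any(dims < 2L)) stop("group dimensions must be >= 2")
  out <- as.integer(sum(dims - 1L))
  if (!is.null(sd_snp_total))
    attr(out, "percentage") <- fraction_pct(out, sd_snp_total, 2)
  out
}

#' Percentage column for a tier table of printed counts
#'
#' Completes a filter-tier table (as reported for parallelism surveys)
#' by computing the percentage of SD SNPs involved in parallelisms,
#' `100 * n_snps_in_parallelisms / n_sd_snps`, rounded to 2 decimals.
#'
#' @param counts data frame with columns `n_snps_in_parallelisms` and
#'   `n_sd_snps` (other columns are carried through).
#' @return `counts` with a `pct_sd_snps` column appended.
#' @export
tier_percentage_table <- function(counts) {
  stopifnot(all(c("n_snps_in_parallelisms", "n_sd_snps") %in% names(counts)))
  counts$pct_sd_snps <- fraction_pct(counts$n_snps_in_parallelisms,
                                     counts$n_sd_snps, 2)
  counts
}

## per-SNP-site status table used for tier denominators
snp_site_status <- function(aln, snpsA, snpsB) {
  cm <- map_columns(aln)
  one <- function(snps, pos_col, chrom) {
    if (!nrow(snps)) return(NULL)
    col <- match(snps$pos, pos_col)
    data.frame(site = site_key(chrom, snps$pos),
               pass = !is.na(col) & aln$mask[col] == "pass",
               unique_ok = if ("unique_ok" %in% names(snps)) snps$unique_ok
                           else TRUE,
               cpg = if ("cpg" %in% names(snps)) snps$cpg else FALSE)
  }
  rbind(one(snpsA, cm$posA, aln$intervalA$chrom),
        one(snpsB, cm$posB, aln$intervalB$chrom))
}

#' Summarise parallelism counts across the filter tiers
#'
#' Applies the cumulative filter tiers — no filters; high-quality
#' alignment (pass-mask columns); + uniquely mapping SNPs; + non-CpG
#' sites — to a classified pair set and reports, per tier, the number
#' of pairwise parallelisms (deduplicated edges), higher-order groups
#' (dimension >= 3), distinct SNPs in parallelisms, surviving SD SNPs
#' (denominator) and the percentage of SD SNPs in parallelisms.
#'
#' @param pairs classified pairs from [classify_site_pairs()] with
#'   `apply_mask = FALSE`, concatenated over alignments.
#' @param snp_status per-site status table (site, pass, unique_ok, cpg);
#'   build one per alignment with the internal helper used by
#'   [run_pipeline()], or supply your own.  Sites are deduplicated.
#' @return data frame with one row per tier (`tier`, `n_parallelisms`,
#'   `n_higher_order`, `n_snps_in_parallelisms`, `n_sd_snps`,
#'   `pct_sd_snps`).
#' @export
summarize_filter_tiers <- function(pairs, snp_status) {
  snp_status <- snp_status[!duplicated(snp_status$site), , drop = FALSE]
  u <- function(x) ifelse(is.na(x), TRUE, x)  # absent flags do not exclude
  ## CpG: a pair is excluded when either member is flagged; NA -> keep
  tier_defs <- list(
    "No filters" = list(
      pair = rep(TRUE, nrow(pairs)),
      snp  = rep(TRUE, nrow(snp_status))),
    "High quality alignment" = list(
      pair = pairs$pass_mask,
      snp  = snp_status$pass),
    "Uniquely mapping SNPs + High quality alignment" = list(
      pair = pairs$pass_mask & u(pairs$uniqueA) & u(pairs$uniqueB),
      snp  = snp_status$pass & u(snp_status$unique_ok)),
    "Non-CpG Sites + Uniquely mapping SNPs + High quality alignment" = list(
      pair = pairs$pass_mask & u(pairs$uniqueA) & u(pairs$uniqueB) &
        !(pairs$cpgA %in% TRUE) & !(pairs$cpgB %in% TRUE),
      snp  = snp_status$pass & u(snp_status$unique_ok) &
        !(snp_status$cpg %in% TRUE)))

  rows <- lapply(names(tier_defs), function(nm) {
    td <- tier_defs[[nm]]
    bg <- build_groups(pairs[td$pair, , drop = FALSE])
    data.frame(tier = nm,
               n_parallelisms = bg$n_edges,
               n_higher_order = bg$n_higher_order,
               n_snps_in_parallelisms = bg$n_snps,
               n_sd_snps = sum(td$snp))
  })
  tier_percentage_table(do.call(rbind, rows))
}

#' Scan for rare SNPs whose minor allele is fixed at the paralogous site
#'
#' A recent IGC event spanning a fixed difference between paralogs
#' creates a new low-frequency SNP whose minor allele matches the
#' (monomorphic) base at the aligned paralogous position.  This scan
#' counts, over pass-mask columns, SNPs with minor allele frequency at
#' or below `maf_cutoff` whose strand-adjusted minor allele equals the
#' paralogous reference base; aligned positions that are themselves
#' polymorphic are excluded.
#'
#' The minor allele is taken to be the alternative allele (allele
#' frequencies are folded to (0, 0.5]).
#'
#' @param aln a masked `paralog_alignment`.
#' @param snpsA,snpsB SNP tables as in [classify_site_pairs()], with a
#'   `maf` column.
#' @param maf_cutoff maximum minor allele frequency (default 0.01).
#' @return data frame of counted sites (side, chrom, pos, minor allele,
#'   paralog base); the count is `nrow()`.
#' @export
rare_minor_match_scan <- function(aln, snpsA, snpsB, maf_cutoff = 0.01) {
  cm <- map_columns(aln)
  pass <- aln$mask == "pass"
  one_side <- function(snps, own_pos, other_pos, other_cols, own_strand,
                       other_snps, chrom, side) {
    if (!nrow(snps)) return(NULL)
    col <- match(snps$pos, own_pos)
    ok <- !is.na(col) & pass[col] & snps$maf <= maf_cutoff
    ## paralogous position must exist and be monomorphic
    opos <- ifelse(is.na(col), NA_integer_, other_pos[col])
    ok <- ok & !is.na(opos) & !(opos %in% other_snps$pos)
    minor <- snps$alt
    if (own_strand == "-") minor <- comp_base(minor)  # to alignment space
    pbase <- ifelse(is.na(col), NA_character_, other_cols[col])
    ok <- ok & !is.na(pbase) & minor == pbase
    if (!any(ok)) return(NULL)
    data.frame(side = side, chrom = chrom, pos = snps$pos[ok],
               minor_allele = snps$alt[ok], paralog_base = pbase[ok])
  }
  out <- rbind(
    one_side(snpsA, cm$posA, cm$posB, aln$colsB, aln$intervalA$strand,
             snpsB, aln$intervalA$chrom, "A"),
    one_side(snpsB, cm$posB, cm$posA, aln$colsA, aln$intervalB$strand,
             snpsA, aln$intervalB$chrom, "B"))
  if (is.null(out))
    out <- data.frame(side = character(0), chrom = character(0),
                      pos = integer(0), minor_allele = character(0),
                      paralog_base = character(0))
  out
}

#' Tabulate population-private parallelisms
#'
#' A parallelism is private to a population when at least one of its
#' member SNPs segregates in exactly one population.  Returns one row
#' per population with the number of such parallelisms.
#'
#' @param pairs classified pairs (rows with `klass == "parallelism"` are
#'   used) carrying `popsA`/`popsB` comma-joined population labels.
#' @return data frame `population`, `n_private_parallelisms`.
#' @export
private_parallelism_table <- function(pairs) {
  par <- dedup_parallelisms(pairs)
  priv <- function(p) {
    s <- strsplit(ifelse(is.na(p), "", p), ",", fixed = TRUE)
    ifelse(lengths(s) == 1L, vapply(s, function(x)
      if (length(x)) x[[1L]] else NA_character_, character(1)), NA_character_)
  }
  pa <- priv(par$popsA)
  pb <- priv(par$popsB)
  ## a parallelism counts once per population with a private member SNP
  lab <- c(pa, ifelse(!is.na(pb) & (is.na(pa) | pb != pa), pb, NA))
  tab <- table(lab[!is.na(lab)])
  data.frame(population = names(tab),
             n_private_parallelisms = as.integer(tab), row.names = NULL)
}
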