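# Independent oracles used across tests.

# Affine-gap global alignment score by explicit three-state dynamic
# programming (Gotoh). A gap run of length k costs open + k * extend,
# end gaps penalised — the same convention as global_align().
oracle_align_score <- function(a, b, match = 5, mismatch = -4,
                               open = 16, extend = 4) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e12
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1) # gap in B (consumes A)
  Iy <- matrix(NEG, n + 1, m + 1) # gap in A (consumes B)
  M[1, 1] <- 0
  for (i in 0:n) {
    for (j in 0:m) {
      if (i > 0) {
        Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                                Ix[i, j + 1] - extend,
                                Iy[i, j + 1] - open - extend)
      }
      if (j > 0) {
        Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                                Iy[i + 1, j] - extend,
                                Ix[i + 1, j] - open - extend)
      }
      if (i > 0 && j > 0) {
        s <- if (A[i] == B[j]) match else mismatch
        M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      }
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Connected components by brute-force transitive closure on the
# adjacency matrix (boolean matrix powers to fixpoint).
closure_components <- function(edges) {
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  k <- length(nodes)
  R <- diag(TRUE, k)
  for (r in seq_len(nrow(edges))) {
    i <- match(edges[r, 1], nodes)
    j <- match(edges[r, 2], nodes)
    R[i, j] <- R[j, i] <- TRUE
  }
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R > 0)) break
    R <- R2
  }
  sig <- apply(R, 1, function(x) paste(which(x), collapse = ","))
  split(nodes, sig)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# deterministic substitution to a different base
rotate_base_t <- function(b) chartr("ACGT", "CGTA", b)

# For a simulated multi-pair cohort: which injected IGC transfers have
# both donor and acceptor columns surviving the alignment-quality masks,
# and is each such transfer recovered as a detected parallelism?
recovered_transfers <- function(cfg, n_pairs, ...) {
  sims <- simulate_cohort(cfg, n_pairs)
  rows <- list()
  for (i in seq_along(sims)) {
    sim <- sims[[i]]
    tr <- sim$transfers
    tr <- tr[tr$outcome == "transferred", , drop = FALSE]
    if (!nrow(tr)) next
    aln <- apply_quality_masks(alignment_from_sim(sim$pair), ...)
    snps <- sim$snps
    snpsA <- snps[snps$paralog == "A", ]
    snpsB <- snps[snps$paralog == "B", ]
    snpsA$pos <- aln$intervalA$start + snpsA$pos - 1L
    snpsB$pos <- aln$intervalB$start + snpsB$pos - 1L
    pr <- classify_site_pairs(aln, snpsA, snpsB)
    par_cols <- pr$col[pr$klass == "parallelism"]
    cm <- map_columns(aln)
    donor_local <- sim$snps$pos[match(tr$donor_snp_id, sim$snps$snp_id)]
    donor_side <- sim$snps$paralog[match(tr$donor_snp_id, sim$snps$snp_id)]
    col <- ifelse(donor_side == "A",
                  match(aln$intervalA$start + donor_local - 1L, cm$posA),
                  match(aln$intervalB$start + donor_local - 1L, cm$posB))
    pass <- !is.na(col) & aln$mask[col] == "pass"
    rows[[i]] <- data.frame(pair = i, col = col, survives = pass,
                            detected = pass & col %in% par_cols)
  }
  all <- do.call(rbind, rows)
  list(all = all, surviving = all[all$survives, , drop = FALSE])
}

# Small hand-buildable alignment: gapped rows as strings.
tiny_alignment <- function(gappedA, gappedB, strandB = "+", chromB = "chrB") {
  lenB <- nchar(gsub("-", "", gappedB))
  alignment_from_gapped(
    gappedA, gappedB,
    intervalA = genomic_interval("chrA", 1, nchar(gsub("-", "", gappedA)), "+"),
    intervalB = genomic_interval(chromB, 1, lenB, strandB))
}
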