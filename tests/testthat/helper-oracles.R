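# Independent oracles and small random-input generators shared across tests.

# Random annotation with random family labels; no placement contract, so
# chance clustering of family genes is possible (intended for detector
# stress tests against the brute-force oracle).
random_genome <- function(n_genes, n_chrom = 3L, chrom_len = 2e6,
                          family_rate = 0.4) {
  chrom <- sprintf("chr%d", sample.int(n_chrom, n_genes, replace = TRUE))
  start <- sample.int(chrom_len, n_genes)
  len <- sample(500:3000, n_genes, replace = TRUE)
  genes <- gene_table(sprintf("g%04d", seq_len(n_genes)), chrom, start,
                      start + len,
                      strand = sample(c("+", "-", "."), n_genes, replace = TRUE))
  fam <- ifelse(stats::runif(n_genes) < family_rate,
                sample(metabolic_families(), n_genes, replace = TRUE),
                NA_character_)
  keep <- !is.na(fam)
  catalog <- family_catalog(stats::setNames(fam[keep], genes$gene_id[keep]))
  list(genes = genes, catalog = catalog)
}

# Brute-force neighborhood oracle: enumerate every contiguous window of the
# per-chromosome family-gene subsequence, keep windows whose consecutive
# pairs all satisfy the constraints, and emit the maximal ones with at least
# min_genes members. Returns a sorted character vector of comma-joined
# member-ID sets.
chain_oracle <- function(genes, catalog, max_intervening = 3L,
                         max_gap_bp = 50000L, min_genes = 3L) {
  g <- genes[order(genes$chrom, genes$start, genes$end, genes$gene_id), ]
  fam <- unname(catalog$assignments[g$gene_id])
  out <- character(0)
  for (chrom in unique(g$chrom)) {
    idx <- which(g$chrom == chrom)
    fidx <- idx[!is.na(fam[idx])]
    m <- length(fidx)
    if (m == 0L) next
    pair_ok <- function(a, b) {  # a, b consecutive positions in fidx
      i <- fidx[a]; j <- fidx[b]
      intervening <- j - i - 1L
      gap <- max(0L, g$start[j] - g$end[i] - 1L)
      intervening <= max_intervening && gap <= max_gap_bp
    }
    for (a in seq_len(m)) {
      for (b in a:m) {
        if (b - a + 1L < min_genes) next
        all_ok <- TRUE
        if (b > a) {
          for (k in a:(b - 1L)) {
            if (!pair_ok(k, k + 1L)) { all_ok <- FALSE; break }
          }
        }
        if (!all_ok) next
        left_max <- a == 1L || !pair_ok(a - 1L, a)
        right_max <- b == m || !pair_ok(b, b + 1L)
        if (left_max && right_max) {
          out <- c(out, paste(g$gene_id[fidx[a:b]], collapse = ","))
        }
      }
    }
  }
  sort(out)
}

# Counting-based fractional-rank mutual-rank oracle: for each ordered pair,
# rank_i(j) = (#partners with strictly higher pcc) + (#tied partners + 1)/2.
mr_oracle <- function(pcc) {
  n <- nrow(pcc)
  rk <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-i]) {
      others <- setdiff(seq_len(n), i)
      v <- pcc[i, j]
      greater <- sum(pcc[i, others] > v)
      ties <- sum(pcc[i, others] == v)  # includes j itself
      rk[i, j] <- greater + (ties + 1) / 2
    }
  }
  mr <- sqrt(rk * t(rk))
  diag(mr) <- 0
  dimnames(mr) <- dimnames(pcc)
  mr
}

# From-the-definition Pearson correlation via explicit summation.
pcc_oracle <- function(mat) {
  n <- nrow(mat)
  out <- diag(1, n)
  dimnames(out) <- list(rownames(mat), rownames(mat))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      x <- mat[i, ]; y <- mat[j, ]
      xm <- sum(x) / length(x); ym <- sum(y) / length(y)
      num <- sum((x - xm) * (y - ym))
      den <- sqrt(sum((x - xm)^2)) * sqrt(sum((y - ym)^2))
      out[i, j] <- num / den
    }
  }
  out
}

# Random symmetric correlation-like matrix with unit diagonal.
random_corr <- function(n) {
  x <- matrix(stats::rnorm(n * 6), n, 6)
  stats::cor(t(x))
}

# Comma-joined member sets of a region_set, sorted, for comparison against
# chain_oracle output.
member_sets <- function(regions) {
  sort(regions$member_ids)
}
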