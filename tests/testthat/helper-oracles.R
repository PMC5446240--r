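# Independent oracles and small fixture builders shared across tests.

# build a peak_set data.frame by hand (1-based inclusive coordinates)
make_peaks <- function(chrom, start, end, summit = NULL, height = 10,
                       factor = "tf", condition = "with_cofactor") {
  if (is.null(summit)) summit <- as.integer((start + end) / 2)
  df <- data.frame(
    peak_id = sprintf("p%03d", seq_along(chrom)),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    summit = as.integer(summit), height = height,
    factor = factor, condition = condition, stringsAsFactors = FALSE
  )
  class(df) <- c("peak_set", "data.frame")
  df
}

# minimal moderated fit object around a known coefficient matrix
make_fit <- function(beta, s2_post = 1, df = 4, df_prior = 4, n_rep = 2) {
  gl <- genotype_levels()
  colnames(beta) <- gl
  n <- nrow(beta)
  g <- factor(rep(gl, each = n_rep), levels = gl)
  structure(list(
    coefficients = beta,
    sigma2 = rep(mean(s2_post), n),
    df = df,
    n_per_group = table(g),
    genes = if (is.null(rownames(beta))) sprintf("g%04d", seq_len(n))
            else rownames(beta),
    s2_post = rep(s2_post, length.out = n),
    df_prior = df_prior,
    s2_prior = mean(s2_post),
    df_total = df + df_prior
  ), class = "de_fit")
}

# brute-force per-window Hamming scan (string comparison, one window at
# a time) -- deliberately naive, independent of scan_ebox internals
oracle_scan <- function(seq, motif = "CACGTG", max_mm = 2) {
  seq <- toupper(seq)
  m <- strsplit(motif, "")[[1]]
  out <- data.frame(start = integer(0), mismatches = integer(0))
  for (i in seq_len(nchar(seq) - 5L)) {
    w <- strsplit(substr(seq, i, i + 5L), "")[[1]]
    d <- sum(w != m)
    if (d <= max_mm) out <- rbind(out, data.frame(start = i, mismatches = d))
  }
  out
}

# textbook BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# spreadsheet-style TMM: weighted trimmed mean of M over A, reference =
# column whose CPM upper quartile is closest to the mean upper quartile
oracle_tmm <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, stats::quantile, p = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    obs <- counts[, i]; rc <- counts[, ref]
    nO <- lib[i]; nR <- lib[ref]
    M <- log2((obs / nO) / (rc / nR))
    A <- (log2(obs / nO) + log2(rc / nR)) / 2
    w <- (nO - obs) / (nO * obs) + (nR - rc) / (nR * rc)
    ok <- is.finite(M) & is.finite(A)
    M <- M[ok]; A <- A[ok]; w <- w[ok]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# quadratic all-pairs interval overlap
oracle_overlap <- function(a, b) {
  shared_a <- vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom & a$start[i] <= b$end & a$end[i] >= b$start)
  }, logical(1))
  shared_b <- vapply(seq_len(nrow(b)), function(j) {
    any(b$chrom[j] == a$chrom & b$start[j] <= a$end & b$end[j] >= a$start)
  }, logical(1))
  list(shared_a = shared_a, shared_b = shared_b)
}

# exhaustive nearest-and-orientation peak-to-gene assignment
oracle_assign <- function(peaks, genes, allow_cds = FALSE,
                          max_dist = NULL) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    if (!allow_cds &&
        any(peaks$start[i] <= g$cds_end & peaks$end[i] >= g$cds_start)) next
    s <- peaks$summit[i]
    for (side in c("left", "right")) {
      cand <- if (side == "left") g[g$tss < s, , drop = FALSE]
              else g[g$tss >= s, , drop = FALSE]
      if (nrow(cand) == 0) next
      j <- if (side == "left") which.max(cand$tss) else which.min(cand$tss)
      ok <- if (cand$strand[j] == "+") peaks$start[i] <= cand$tss[j]
            else peaks$end[i] >= cand$tss[j]
      if (!ok) next
      if (!is.null(max_dist) && abs(cand$tss[j] - s) > max_dist) next
      rows[[length(rows) + 1]] <-
        paste(peaks$peak_id[i], cand$gene_id[j], sep = "|")
    }
  }
  sort(unique(unlist(rows)))
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
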