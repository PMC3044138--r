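# shared fixtures and independent brute-force oracles

# small infinium-style signal data.frame written to a TSV
tiny_signal_df <- function(pos0 = FALSE) {
  data.frame(site_id = c("cg1", "cg2", "cg3"),
             chrom = "chr1",
             pos = if (pos0) c(0L, 10L, 25L) else c(5L, 10L, 25L),
             A.CVS01 = c(100, 200, 300), A.MBC01 = c(150, 250, 50),
             B.CVS01 = c(900, 80, 10), B.MBC01 = c(30, 40, 700))
}

write_tiny_signal <- function(df = tiny_signal_df()) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# reference fixture for normalization contracts: arrays sharing one
# underlying intensity distribution with smooth intensity-dependent
# trends and mild noise (the cyclic-loess precondition)
loess_fixture <- function(n = 5000, noise = 0.03, seed = 10) {
  set.seed(seed)
  logt <- rnorm(n, 7, 0.5)
  x1 <- exp(logt + rnorm(n, 0, noise))
  x2 <- exp(logt + 0.1 * scale(logt)[, 1] + rnorm(n, 0, noise))
  x3 <- exp(logt - 0.05 * scale(logt)[, 1] + rnorm(n, 0, noise))
  cbind(a = x1, b = x2, c = x3)
}

# worst residual pairwise MA trend after normalization (log2 scale)
worst_ma_trend <- function(m, span = 0.7) {
  lg <- log2(m + 1)
  worst <- 0
  for (i in seq_len(ncol(lg) - 1)) {
    for (j in (i + 1):ncol(lg)) {
      f <- stats::loess((lg[, i] - lg[, j]) ~ I((lg[, i] + lg[, j]) / 2),
                        span = span, degree = 1)
      worst <- max(worst, max(abs(fitted(f))))
    }
  }
  worst
}

eb_prior <- function(d0, s02) {
  structure(list(d0 = d0, s02 = s02), class = "eb_hyperparams")
}

# quadratic-loop BH reference
bh_oracle <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- sum(p <= p[i])
    # min over j with p_j >= p_i of p_j * m / rank_j
    cand <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) p[j] * m / sum(p <= p[j]) else Inf
    }, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# brute-force k-nearest sites, distance ties to the lower coordinate
nearest_oracle <- function(positions, index, k) {
  ord <- order(abs(positions - positions[index]), positions)
  sort(ord[seq_len(min(k, length(positions)))])
}

# factorial-based enumeration of the two-sided Fisher p
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; n1 <- a + c_; tot <- sum(tab)
  lo <- max(0, n1 - (tot - m1)); hi <- min(m1, n1)
  lp <- function(x) {
    lchoose(m1, x) + lchoose(tot - m1, n1 - x) - lchoose(tot, n1)
  }
  dens <- exp(vapply(lo:hi, lp, numeric(1)))
  min(1, sum(dens[dens <= dens[a - lo + 1] * (1 + 1e-7)]))
}

# all-pairs half-open containment
containment_oracle <- function(chrom, pos, fchrom, fstart, fend) {
  vapply(seq_along(pos), function(i) {
    any(fchrom == chrom[i] & fstart <= pos[i] & pos[i] < fend)
  }, logical(1))
}

# quadratic-loop add-one empirical p
empirical_p_oracle <- function(obs, null_sample, tail) {
  vapply(obs, function(o) {
    cnt <- if (tail == "upper") sum(null_sample >= o) else sum(null_sample <= o)
    (1 + cnt) / (1 + length(null_sample))
  }, numeric(1))
}

# small annotation for context tests
tiny_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = c("chr1", "chr1"),
    start = c(5000L, 20000L),
    end = c(9000L, 26000L),
    strand = c("+", "-"),
    tss = c(5000L, 25999L),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB"),
    chrom = "chr1",
    start = c(5000L, 8000L, 21000L),
    end = c(5500L, 8400L, 22000L),
    stringsAsFactors = FALSE)
  cgis <- data.frame(chrom = "chr1", start = 4500L, end = 5600L,
                     stringsAsFactors = FALSE)
  list(genes = genes, exons = exons, cgis = cgis)
}
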