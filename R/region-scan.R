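#' Indices of the k sites nearest a focal site
#'
#' Returns the `k` sites (the focal site included) with the smallest
#' distance `|pos - pos_focal|` among an ascending vector of positions.
#' Distance ties are broken towards the lower coordinate, and near
#' chromosome ends the window becomes asymmetric while keeping size `k`
#' whenever `n >= k`.
#'
#' @param positions strictly increasing site positions.
#' @param index focal site index (1-based).
#' @param k window size (>= 1).
#' @return Sorted integer indices of the window members, of size
#'   `min(k, n)`.
#' @export
nearest_window <- function(positions, index, k) {
  n <- length(positions)
  if (!n) stop("empty site list", call. = FALSE)
  stopifnot(k >= 1, index >= 1, index <= n)
  b <- window_bounds(positions, k)
  seq.int(b$lo[index], b$hi[index])
}

# contiguous [lo, hi] window bounds around every site, vectorized scan
window_bounds <- function(positions, k) {
  n <- length(positions)
  k <- min(k, n)
  lo <- integer(n)
  hi <- integer(n)
  for (i in seq_len(n)) {
    l <- i
    h <- i
    while (h - l + 1L < k) {
      dl <- if (l > 1L) positions[i] - positions[l - 1L] else Inf
      dr <- if (h < n) positions[h + 1L] - positions[i] else Inf
      if (dl <= dr) l <- l - 1L else h <- h + 1L
    }
    lo[i] <- l
    hi[i] <- h
  }
  list(lo = lo, hi = hi)
}

# windowed sums of a flag vector given precomputed bounds (cumsum trick)
window_sums <- function(flags, bounds) {
  cs <- c(0, cumsum(flags))
  cs[bounds$hi + 1L] - cs[bounds$lo]
}

#' Moving hypomethylation rate over nearest-site windows
#'
#' For each site, the proportion of hypomethylated sites among the `k`
#' sites nearest to it (focal site included), i.e. the windowed mean of a
#' binary hypomethylation call vector.
#'
#' @param positions strictly increasing site positions.
#' @param hypo_flags binary (0/1 or logical) vector aligned to `positions`.
#' @param k window size.  If fewer than `k` sites exist, the whole
#'   chromosome is used with denominator `n` (with a warning).
#' @return Numeric vector of rates in `[0, 1]`.
#' @export
moving_hypo_rate <- function(positions, hypo_flags, k) {
  n <- length(positions)
  if (!n) stop("empty site list", call. = FALSE)
  stopifnot(length(hypo_flags) == n)
  if (n < k) {
    warning("fewer sites than the window size; using denominator ", n,
            call. = FALSE)
    k <- n
  }
  b <- window_bounds(positions, k)
  window_sums(as.numeric(hypo_flags), b) / k
}

#' Moving difference in hypomethylation between tissues
#'
#' Windowed `(sum(flags_cvs) - sum(flags_mbc)) / k`; identical to
#' `moving_hypo_rate(cvs) - moving_hypo_rate(mbc)`.
#'
#' @param positions strictly increasing site positions.
#' @param flags_cvs,flags_mbc binary call vectors aligned to `positions`.
#' @param k window size.
#' @return Numeric vector in `[-1, 1]`.
#' @export
moving_hypo_diff <- function(positions, flags_cvs, flags_mbc, k) {
  moving_hypo_rate(positions, flags_cvs, k) -
    moving_hypo_rate(positions, flags_mbc, k)
}

#' Empirical null sample of window statistics
#'
#' Simulates the null model in which hypomethylation is uniform along the
#' chromosome and the two tissues are independent: each replicate draws
#' i.i.d. Bernoulli hypomethylation flags per tissue at the observed
#' chromosome-wide rates, recomputes all window statistics, and pools them
#' across sites and replicates.
#'
#' @param n_sites number of sites per replicate.
#' @param rate_cvs,rate_mbc chromosome-wide hypomethylation rates in
#'   `[0, 1]`.
#' @param k window size.
#' @param n_sim number of replicates (>= 100).
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param positions optional site positions (defaults to a unit grid; with
#'   i.i.d. flags only the window sizes matter).
#' @return List with pooled numeric vectors `rate_cvs`, `rate_mbc`, `diff`,
#'   each of length `n_sites * n_sim`.
#' @export
simulate_null_windows <- function(n_sites, rate_cvs, rate_mbc, k, n_sim,
                                  seed = NULL, positions = NULL) {
  stopifnot(rate_cvs >= 0, rate_cvs <= 1, rate_mbc >= 0, rate_mbc <= 1)
  if (n_sim < 100) stop("n_sim must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) positions <- seq_len(n_sites)
  stopifnot(length(positions) == n_sites)
  b <- window_bounds(positions, min(k, n_sites))
  denom <- min(k, n_sites)
  rc <- matrix(0, n_sites, n_sim)
  rm_ <- matrix(0, n_sites, n_sim)
  for (s in seq_len(n_sim)) {
    fc <- rbinom(n_sites, 1L, rate_cvs)
    fm <- rbinom(n_sites, 1L, rate_mbc)
    rc[, s] <- window_sums(fc, b) / denom
    rm_[, s] <- window_sums(fm, b) / denom
  }
  list(rate_cvs = as.vector(rc), rate_mbc = as.vector(rm_),
       diff = as.vector(rc - rm_))
}

#' Empirical p values against a null sample
#'
#' Add-one empirical tail probabilities:
#' `p_i = (1 + #\{null >= obs_i\}) / (1 + n_null)` for the upper tail and
#' the mirrored count for the lower tail, so p is never exactly 0.
#'
#' @param observed vector of observed statistics.
#' @param null_sample pooled null sample; at least 100 values are needed
#'   for a usefully granular p (smaller samples trigger a warning).
#' @param tail `"upper"` or `"lower"`.
#' @return p values in `(0, 1]`.
#' @export
empirical_pvalues <- function(observed, null_sample,
                              tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (!length(null_sample)) stop("empty null sample", call. = FALSE)
  if (length(null_sample) < 100) {
    warning("null sample has fewer than 100 values; p values are coarse",
            call. = FALSE)
  }
  ns <- sort(null_sample)
  n <- length(ns)
  if (tail == "upper") {
    # #{null >= obs} = n - #{null < obs}
    cnt <- n - findInterval(observed, ns, left.open = TRUE)
  } else {
    cnt <- findInterval(observed, ns)
  }
  (1 + cnt) / (1 + n)
}

#' Tabulated empirical null of window statistics
#'
#' Same null model as [simulate_null_windows()] (identical draws under the
#' same seed), but the pooled sample is stored as exact counts over the
#' discrete support of the statistics -- windowed sums are integers in
#' `0..k` and their difference in `-k..k` -- so whole-chromosome nulls fit
#' in a few hundred integers regardless of `n_sim`.
#'
#' @inheritParams simulate_null_windows
#' @return List with integer count vectors `rate_cvs`, `rate_mbc` (support
#'   `0:k`), `diff` (support `-k:k`), the window size `k` used, and
#'   `n_total` (pooled null size).
#' @export
tabulate_null_windows <- function(n_sites, rate_cvs, rate_mbc, k, n_sim,
                                  seed = NULL, positions = NULL) {
  stopifnot(rate_cvs >= 0, rate_cvs <= 1, rate_mbc >= 0, rate_mbc <= 1)
  if (n_sim < 100) stop("n_sim must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) positions <- seq_len(n_sites)
  stopifnot(length(positions) == n_sites)
  k <- min(k, n_sites)
  b <- window_bounds(positions, k)
  tab_c <- integer(k + 1)
  tab_m <- integer(k + 1)
  tab_d <- integer(2 * k + 1)
  for (s in seq_len(n_sim)) {
    sc <- window_sums(rbinom(n_sites, 1L, rate_cvs), b)
    sm <- window_sums(rbinom(n_sites, 1L, rate_mbc), b)
    tab_c <- tab_c + tabulate(sc + 1L, k + 1L)
    tab_m <- tab_m + tabulate(sm + 1L, k + 1L)
    tab_d <- tab_d + tabulate(sc - sm + k + 1L, 2L * k + 1L)
  }
  list(rate_cvs = tab_c, rate_mbc = tab_m, diff = tab_d, k = k,
       n_total = n_sites * n_sim)
}

# add-one empirical p for integer-valued observed stats against a count
# table; `support` gives the value of the first count bin
empirical_pvalues_tab <- function(observed_int, counts, support_min, tail) {
  n <- sum(counts)
  idx <- observed_int - support_min + 1L
  stopifnot(all(idx >= 1), all(idx <= length(counts)))
  if (tail == "upper") {
    ge <- rev(cumsum(rev(counts)))       # ge[i] = #null >= value i
    cnt <- ge[idx]
  } else {
    le <- cumsum(counts)
    cnt <- le[idx]
  }
  (1 + cnt) / (1 + n)
}

#' Merge significant sites into regions
#'
#' Chains sites whose adjusted p value is `<= alpha` whenever fewer than
#' `max_gap_sites` sites (significant or not) lie between consecutive
#' significant sites, and emits one region per chain spanning its outermost
#' members.  Isolated significant sites become single-site regions.
#'
#' @param positions strictly increasing site positions on one chromosome.
#' @param p_adj adjusted p values aligned to `positions`.
#' @param alpha significance level, default 0.05.
#' @param max_gap_sites merge two significant sites when strictly fewer
#'   than this many sites lie between them; default 50 (the window size).
#' @param chrom chromosome name for the output.
#' @param type region type label for the output.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open,
#'   spanning the outermost member sites), `type`, `n_sites` (significant
#'   members), `min_p_adj`.
#' @export
merge_significant_sites <- function(positions, p_adj, alpha = 0.05,
                                    max_gap_sites = 50L, chrom = "chr",
                                    type = "region") {
  stopifnot(length(positions) == length(p_adj))
  sig <- which(p_adj <= alpha)
  if (!length(sig)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), type = character(),
                      n_sites = integer(), min_p_adj = numeric()))
  }
  # intervening site count between consecutive significant sites
  gaps <- diff(sig) - 1L
  chain <- cumsum(c(0L, gaps >= max_gap_sites))
  pieces <- split(sig, chain)
  out <- lapply(pieces, function(ix) {
    data.frame(chrom = chrom,
               start = positions[min(ix)],
               end = positions[max(ix)] + 1L,
               type = type,
               n_sites = length(ix),
               min_p_adj = min(p_adj[ix]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sliding-window scan of one chromosome
#'
#' Given per-site binary hypomethylation calls for both tissues on one
#' chromosome, computes the three window tracks (hypomethylation rate per
#' tissue and their difference), simulates the empirical null at the
#' observed chromosome-wide rates, assigns add-one empirical p values
#' (upper tail for the rates; both tails for the difference), BH-adjusts
#' each track family separately, and merges significant sites into regions.
#'
#' @param positions strictly increasing site positions.
#' @param flags_cvs,flags_mbc binary hypomethylation calls per tissue.
#' @param chrom chromosome name.
#' @param k window size (default 50).
#' @param n_sim null replicates (default 1000).
#' @param alpha FDR level for site significance (default 0.05).
#' @param seed RNG seed for the null simulation.
#' @return List with `tracks` (per-site data.frame: position, the three
#'   statistics, and per-family empirical/adjusted p values) and `regions`
#'   (region data.frame with types `hypo_CVS`, `hypo_MBC`, `CVS_gt_MBC`,
#'   `MBC_gt_CVS`).
#' @export
scan_chromosome <- function(positions, flags_cvs, flags_mbc, chrom = "chr",
                            k = 50L, n_sim = 1000L, alpha = 0.05,
                            seed = NULL) {
  n <- length(positions)
  stopifnot(length(flags_cvs) == n, length(flags_mbc) == n)
  rate_c <- moving_hypo_rate(positions, flags_cvs, k)
  rate_m <- moving_hypo_rate(positions, flags_mbc, k)
  dif <- rate_c - rate_m
  kk <- min(k, n)
  null <- tabulate_null_windows(n, mean(flags_cvs), mean(flags_mbc),
                                kk, n_sim, seed = seed,
                                positions = positions)
  sum_c <- as.integer(round(rate_c * kk))
  sum_m <- as.integer(round(rate_m * kk))
  p <- list(
    hypo_CVS = empirical_pvalues_tab(sum_c, null$rate_cvs, 0L, "upper"),
    hypo_MBC = empirical_pvalues_tab(sum_m, null$rate_mbc, 0L, "upper"),
    CVS_gt_MBC = empirical_pvalues_tab(sum_c - sum_m, null$diff, -kk,
                                       "upper"),
    MBC_gt_CVS = empirical_pvalues_tab(sum_c - sum_m, null$diff, -kk,
                                       "lower")
  )
  p_adj <- lapply(p, bh_adjust)
  regions <- do.call(rbind, lapply(names(p_adj), function(ty) {
    merge_significant_sites(positions, p_adj[[ty]], alpha = alpha,
                            max_gap_sites = k, chrom = chrom, type = ty)
  }))
  rownames(regions) <- NULL
  tracks <- data.frame(chrom = chrom, pos = positions,
                       rate_cvs = rate_c, rate_mbc = rate_m, diff = dif,
                       p_hypo_CVS = p$hypo_CVS, p_hypo_MBC = p$hypo_MBC,
                       p_CVS_gt_MBC = p$CVS_gt_MBC,
                       p_MBC_gt_CVS = p$MBC_gt_CVS,
                       padj_hypo_CVS = p_adj$hypo_CVS,
                       padj_hypo_MBC = p_adj$hypo_MBC,
                       padj_CVS_gt_MBC = p_adj$CVS_gt_MBC,
                       padj_MBC_gt_CVS = p_adj$MBC_gt_CVS)
  list(tracks = tracks, regions = regions)
}

#' Sliding-window scan of a whole methylation call set
#'
#' Runs [scan_chromosome()] per chromosome (each chromosome gets its own
#' empirical null and its own BH families) on the binary hypomethylation
#' calls of the two tissues and concatenates tracks and regions.
#'
#' @param calls_cvs,calls_mbc per-tissue methylation call tables from
#'   [call_sites()] (contrast `"within"`), aligned on the same sites.
#' @param k,n_sim,alpha,seed as in [scan_chromosome()]; per-chromosome
#'   seeds are derived from `seed`.
#' @return List with concatenated `tracks` and `regions`.
#' @export
scan_regions <- function(calls_cvs, calls_mbc, k = 50L, n_sim = 1000L,
                         alpha = 0.05, seed = NULL) {
  stopifnot(identical(calls_cvs$site_id, calls_mbc$site_id))
  chroms <- unique(calls_cvs$chrom)
  tracks <- list()
  regions <- list()
  for (ci in seq_along(chroms)) {
    cc <- chroms[ci]
    ix <- calls_cvs$chrom == cc
    res <- scan_chromosome(calls_cvs$pos[ix],
                           as.integer(calls_cvs$status[ix] == "hypo"),
                           as.integer(calls_mbc$status[ix] == "hypo"),
                           chrom = cc, k = k, n_sim = n_sim, alpha = alpha,
                           seed = if (is.null(seed)) NULL else seed + ci)
    tracks[[cc]] <- res$tracks
    regions[[cc]] <- res$regions
  }
  list(tracks = do.call(rbind, tracks),
       regions = {
         r <- do.call(rbind, regions)
         rownames(r) <- NULL
         r
       })
}
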