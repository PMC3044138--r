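#' Cyclic loess normalization of array intensities
#'
#' Removes intensity-dependent between-array trends by repeatedly fitting,
#' for every pair of arrays, a loess curve of M = log(x_i) - log(x_j) on
#' A = (log(x_i) + log(x_j))/2 and applying half of the fitted trend to each
#' array of the pair with opposite signs.  The fits are performed on the log
#' scale (via [limma::normalizeCyclicLoess()] with `method = "pairs"`) and
#' the result is returned on the original intensity scale.  Each channel of
#' each platform is normalized separately.
#'
#' @param signals numeric matrix, sites x arrays, strictly positive after
#'   adding `pseudocount`.
#' @param span loess span. Default 0.7.
#' @param n_cycles number of complete cycles over all array pairs.
#'   Default 3 (enough for the residual pairwise trend to fall below
#'   0.01 on the log2 scale for well-behaved arrays).
#' @param pseudocount added before taking logs; subtracted again afterwards
#'   (results are clamped at 0).
#' @return A matrix of the same shape on the intensity scale.
#' @export
cyclic_loess_normalize <- function(signals, span = 0.7, n_cycles = 3L,
                                   pseudocount = 1) {
  signals <- as.matrix(signals)
  if (ncol(signals) < 2) {
    stop("cyclic loess needs at least 2 arrays", call. = FALSE)
  }
  shifted <- signals + pseudocount
  if (any(shifted <= 0) || anyNA(shifted)) {
    stop("intensities must be positive after the pseudocount", call. = FALSE)
  }
  logged <- log2(shifted)
  norm <- limma::normalizeCyclicLoess(logged, span = span,
                                      iterations = n_cycles,
                                      method = "pairs")
  out <- pmax(2^norm - pseudocount, 0)
  dimnames(out) <- dimnames(signals)
  out
}

#' Normalize all channels of a signal set
#'
#' Applies [cyclic_loess_normalize()] to each channel separately (A and B
#' for infinium; HpaII- and HpaII+ for msre), across all arrays of the
#' platform.
#'
#' @param x a [signal_set()].
#' @param span,n_cycles,pseudocount passed to [cyclic_loess_normalize()].
#' @return A `signal_set` with normalized intensities.
#' @export
normalize_signal_set <- function(x, span = 0.7, n_cycles = 3L,
                                 pseudocount = 1) {
  stopifnot(inherits(x, "signal_set"))
  x$ch1 <- cyclic_loess_normalize(x$ch1, span, n_cycles, pseudocount)
  x$ch2 <- cyclic_loess_normalize(x$ch2, span, n_cycles, pseudocount)
  x
}

#' Beta value of a CpG site
#'
#' `beta = B / (A + B + 100)`, the methylated-probe fraction with a +100
#' regularizer in the denominator, so beta lies in `[0, 1)` and is damped
#' for dim probes.  Negative intensities produced by normalization must be
#' clamped to 0 before calling.
#'
#' @param A unmethylated-probe intensity (>= 0), vectorized.
#' @param B methylated-probe intensity (>= 0), vectorized.
#' @return beta values in `[0, 1)`.
#' @export
compute_beta <- function(A, B) {
  if (anyNA(A) || anyNA(B) || any(!is.finite(A)) || any(!is.finite(B))) {
    stop("beta requires finite intensities", call. = FALSE)
  }
  if (any(A < 0) || any(B < 0)) {
    stop("beta requires non-negative intensities (clamp upstream)",
         call. = FALSE)
  }
  B / (A + B + 100)
}

#' Regularized log ratio of two channels
#'
#' `log((num + pseudocount) / (den + pseudocount))`.  Used with (B, A) on
#' the infinium platform, where positive values mean methylated, and with
#' (HpaII-, HpaII+) on the msre platform, where positive values mean
#' hypomethylated (HpaII cuts unmethylated CCGG sites, so digestion removes
#' signal only where the site is unmethylated).
#'
#' @param numerator,denominator intensities >= 0, vectorized.
#' @param pseudocount positive regularizer, default 1.
#' @param base log base: `"e"` (default) or a number.
#' @return Finite log ratios; antisymmetric under swapping the channels.
#' @export
compute_log_ratio <- function(numerator, denominator, pseudocount = 1,
                              base = "e") {
  if (any(numerator < 0) || any(denominator < 0)) {
    stop("log ratio requires non-negative intensities", call. = FALSE)
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be > 0", call. = FALSE)
  }
  r <- log(numerator + pseudocount) - log(denominator + pseudocount)
  if (!identical(base, "e")) r <- r / log(as.numeric(base))
  r
}

#' Per-site methylation scores for a signal set
#'
#' Computes the per-sample score matrices used by all downstream tests:
#' beta values (infinium only) and the platform log ratio -- log(B/A) for
#' infinium (positive = methylated), log(HpaII-/HpaII+) for msre
#' (positive = hypomethylated).
#'
#' @param x a [signal_set()], normally after [normalize_signal_set()].
#' @param pseudocount,base passed to [compute_log_ratio()].
#' @return A list of class `score_table`: `platform`, `sites`, `groups`,
#'   `log_ratio` (sites x samples), and `beta` (infinium only).
#' @export
compute_scores <- function(x, pseudocount = 1, base = "e") {
  stopifnot(inherits(x, "signal_set"))
  out <- list(platform = x$platform, sites = x$sites, groups = x$groups)
  if (x$platform == "infinium") {
    out$beta <- compute_beta(x$ch1, x$ch2)
    out$log_ratio <- compute_log_ratio(x$ch2, x$ch1, pseudocount, base)
  } else {
    out$log_ratio <- compute_log_ratio(x$ch1, x$ch2, pseudocount, base)
  }
  structure(out, class = "score_table")
}
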