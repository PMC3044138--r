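#' Mean methylation score of genomic regions
#'
#' For each region, averages the per-site mean score (over a declared
#' sample subset) of the sites falling inside the region (0-based
#' half-open containment).  Regions containing no site get `NA` and are
#' counted in a warning.
#'
#' @param scores a `score_table` from [compute_scores()].
#' @param regions data.frame with `chrom`, `start`, `end` (and optionally
#'   `region_id`).
#' @param samples sample ids (column names) to average over; default all.
#' @param what which score matrix to use, `"log_ratio"` or `"beta"`.
#' @return Numeric vector of per-region means, aligned to `regions`.
#' @export
aggregate_region_score <- function(scores, regions,
                                   samples = colnames(scores$log_ratio),
                                   what = c("log_ratio", "beta")) {
  stopifnot(inherits(scores, "score_table"))
  what <- match.arg(what)
  m <- scores[[what]]
  if (is.null(m)) stop("score table has no '", what, "' matrix",
                       call. = FALSE)
  site_mean <- rowMeans(m[, samples, drop = FALSE])
  q <- GenomicRanges::GRanges(scores$sites$chrom,
                              IRanges::IRanges(scores$sites$pos + 1L,
                                               width = 1L))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L,
                                               regions$end))
  hits <- GenomicRanges::findOverlaps(s, q)
  out <- rep(NA_real_, nrow(regions))
  agg <- tapply(site_mean[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), mean)
  out[as.integer(names(agg))] <- agg
  n_empty <- sum(is.na(out))
  if (n_empty) {
    warning(n_empty, " region(s) contain no site; returning NA",
            call. = FALSE)
  }
  out
}

#' Cubic smoothing-spline regression with a trace-df F test
#'
#' Fits a cubic smoothing spline of `y` on `x` with the penalty chosen so
#' that the trace of the smoother matrix equals `target_df` (the effective
#' degrees of freedom of the fit), then tests the association with
#' `F = [(RSS0 - RSS1)/(tr(S) - 1)] / [RSS1/(n - tr(S))]` against the F
#' distribution with `(tr(S) - 1, n - tr(S))` degrees of freedom, where
#' RSS0 is the residual sum of squares of the intercept-only model.
#'
#' @param x predictor (e.g. mean promoter log(B/A)); must not be constant.
#' @param y response (e.g. mean log2 expression).
#' @param target_df target trace of the smoother matrix (> 1, < n).
#' @param lambda optional explicit smoothing parameter overriding
#'   `target_df` (passed to [stats::smooth.spline()]; large values
#'   approach the least-squares line).
#' @return List of class `spline_fit`: `fitted` (aligned to `x`), `df`
#'   (realized trace), `rss_null`, `rss_fit`, `F`, `p`, `n`.
#' @export
smoothing_spline_regress <- function(x, y, target_df = 4, lambda = NULL) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 20) stop("need at least 20 observations", call. = FALSE)
  if (sd(x) == 0) stop("x is constant", call. = FALSE)
  if (is.null(lambda) && target_df >= n) {
    stop("target_df must be smaller than n", call. = FALSE)
  }
  quiet_ss <- function(...) {
    withCallingHandlers(smooth.spline(...), warning = function(w) {
      invokeRestart("muffleWarning")
    })
  }
  if (is.null(lambda)) {
    fit <- quiet_ss(x, y, df = target_df, cv = FALSE, keep.data = FALSE,
                    control.spar = list(tol = 1e-6))
    if (abs(fit$df - target_df) > 0.01) {
      # the reduced knot set occasionally collapses the df search;
      # the full knot set is slower but reliable
      fit <- quiet_ss(x, y, df = target_df, cv = FALSE,
                      keep.data = FALSE, all.knots = TRUE,
                      control.spar = list(tol = 1e-6))
    }
    if (abs(fit$df - target_df) > 0.01) {
      # last resort: bisect on spar over numerically stable fits; on the
      # rare designs whose df(spar) map is unstable near the target, the
      # closest stable fit is accepted and its realized trace is used
      eval_fit <- function(sp) {
        tryCatch({
          f <- quiet_ss(x, y, spar = sp, keep.data = FALSE,
                        all.knots = TRUE)
          if (f$df < 1.05 || !is.finite(f$df)) NULL else f
        }, error = function(e) NULL)
      }
      lo <- -1.5
      hi <- 2.5
      f_hi <- eval_fit(hi)
      while (is.null(f_hi) && hi > lo) {
        hi <- hi - 0.1
        f_hi <- eval_fit(hi)
      }
      fit <- f_hi
      if (!is.null(fit) && fit$df < target_df) {
        for (it in 1:40) {
          mid <- (lo + hi) / 2
          f_mid <- eval_fit(mid)
          if (is.null(f_mid)) {           # unstable: shrink towards hi
            lo <- mid
            next
          }
          if (f_mid$df > target_df) lo <- mid else {
            hi <- mid
            fit <- f_mid
          }
          if (abs(f_mid$df - target_df) <= 0.01) {
            fit <- f_mid
            break
          }
        }
      }
      if (is.null(fit)) {
        stop("could not fit a smoothing spline at the requested df",
             call. = FALSE)
      }
    }
  } else {
    fit <- quiet_ss(x, y, lambda = lambda, keep.data = FALSE)
  }
  fitted <- predict(fit, x)$y
  rss_fit <- sum((y - fitted)^2)
  rss_null <- sum((y - mean(y))^2)
  tr <- fit$df
  if (rss_null <= .Machine$double.eps * n) {
    Fstat <- 0
    p <- 1
  } else {
    Fstat <- max(0, (rss_null - rss_fit) / (tr - 1)) / (rss_fit / (n - tr))
    p <- pf(Fstat, tr - 1, n - tr, lower.tail = FALSE)
  }
  structure(list(fitted = fitted, df = tr, rss_null = rss_null,
                 rss_fit = rss_fit, F = Fstat, p = p, n = n,
                 x = x, y = y),
            class = "spline_fit")
}

#' Pearson correlation with the t test
#'
#' @param x,y equal-length non-constant numeric vectors, n >= 3.
#' @return List with `r`, `p` (two-sided, from
#'   `t = r sqrt((n-2)/(1-r^2))` on n-2 df), and `n`.
#' @export
pearson_correlation_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector", call. = FALSE)
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Correlation restricted to one side of a methylation threshold
#'
#' The methylation--expression relationship is nonlinear: negative and
#' roughly linear below a methylation threshold, flat above it.  This
#' helper computes the Pearson correlation on one side of the threshold.
#' Thresholds of record: 0 for infinium log(B/A) (beta = 50 percent) and
#' 0.03 for msre log(HpaII-/HpaII+).
#'
#' @param x methylation scores.
#' @param y expression values.
#' @param threshold split point on `x`.
#' @param side `"below"` (x < threshold) or `"above"` (x >= threshold).
#' @return List with `r`, `p`, `n_used`.
#' @export
piecewise_correlation <- function(x, y, threshold,
                                  side = c("below", "above")) {
  side <- match.arg(side)
  keep <- if (side == "below") x < threshold else x >= threshold
  keep <- keep & is.finite(x) & is.finite(y)
  n_used <- sum(keep, na.rm = TRUE)
  if (n_used < 10) {
    stop("only ", n_used, " points on the '", side,
         "' side; need at least 10", call. = FALSE)
  }
  ct <- pearson_correlation_test(x[keep], y[keep])
  list(r = ct$r, p = ct$p, n_used = n_used)
}

#' CpG observed/expected ratio of a sequence
#'
#' Gardiner-Garden & Frommer form:
#' `O/E = (n_CpG * L) / (n_C * n_G)` with `L` the full sequence length.
#' `N` characters are ignored in the counts but counted in `L`; case is
#' ignored.  Undefined (NA) when the sequence contains no C or no G.
#'
#' @param sequence DNA string (A/C/G/T/N), length >= 2; also accepts a
#'   `Biostrings` XString/XStringSet element coerced via
#'   `as.character()`.
#' @return The O/E ratio, or `NA_real_` when undefined.
#' @export
cpg_oe_ratio <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (length(s) != 1 || nchar(s) < 2) {
    stop("sequence must be a single string of length >= 2", call. = FALSE)
  }
  L <- nchar(s)
  n_c <- lengths(regmatches(s, gregexpr("C", s, fixed = TRUE)))
  n_g <- lengths(regmatches(s, gregexpr("G", s, fixed = TRUE)))
  if (n_c == 0 || n_g == 0) return(NA_real_)
  n_cg <- lengths(regmatches(s, gregexpr("CG", s, fixed = TRUE)))
  (n_cg * L) / (n_c * n_g)
}

#' Split genes by promoter CpG frequency
#'
#' Promoters cluster into a low and a high CpG observed/expected class;
#' the conventional split point is 0.4 (low: `cpg_oe <= cutoff`).  Genes
#' with undefined `cpg_oe` are excluded with a warning.
#'
#' @param table data.frame with a `cpg_oe` column.
#' @param cutoff split point, default 0.4.
#' @return List with data.frames `low` and `high`.
#' @export
split_by_cpg_frequency <- function(table, cutoff = 0.4) {
  stopifnot("cpg_oe" %in% names(table))
  undef <- !is.finite(table$cpg_oe)
  if (any(undef)) {
    warning(sum(undef), " gene(s) with undefined CpG O/E excluded",
            call. = FALSE)
    table <- table[!undef, , drop = FALSE]
  }
  list(low = table[table$cpg_oe <= cutoff, , drop = FALSE],
       high = table[table$cpg_oe > cutoff, , drop = FALSE])
}

#' Per-gene expression / methylation integration table
#'
#' Joins a per-gene expression table with per-gene promoter methylation
#' (mean score over array sites inside the platform promoter window),
#' optional gene-body methylation, and promoter CpG O/E computed from
#' promoter sequences.
#'
#' @param expression data.frame with `gene_id` and `mean_log2_expr`.
#' @param scores a `score_table`; promoter methylation is the mean
#'   `log_ratio` over the sites inside each gene's promoter window,
#'   averaged over `samples`.
#' @param annotation annotation list (for gene TSS/strand and gene
#'   bodies).
#' @param platform promoter convention.
#' @param samples sample ids to average scores over (default: CVS
#'   samples).
#' @param gene_body_scores optional second `score_table` (e.g. msre) used
#'   for gene-body methylation; `NULL` to skip.
#' @param promoter_seqs optional named character vector (or
#'   `DNAStringSet`) of promoter sequences per gene for CpG O/E.
#' @return data.frame with `gene_id`, `mean_log2_expr`, `promoter_meth`,
#'   `gene_body_meth`, `cpg_oe` (NA where unavailable).  Genes absent
#'   from either side of the join are dropped with a warning.
#' @export
build_expression_table <- function(expression, scores, annotation,
                                   platform,
                                   samples = NULL,
                                   gene_body_scores = NULL,
                                   promoter_seqs = NULL) {
  stopifnot(all(c("gene_id", "mean_log2_expr") %in% names(expression)))
  g <- annotation$genes
  keep <- intersect(expression$gene_id, g$gene_id)
  dropped <- nrow(expression) - length(keep)
  if (dropped > 0) {
    warning(dropped, " gene(s) dropped in the expression/annotation join",
            call. = FALSE)
  }
  expression <- expression[match(keep, expression$gene_id), , drop = FALSE]
  g <- g[match(keep, g$gene_id), , drop = FALSE]
  if (is.null(samples)) {
    samples <- colnames(scores$log_ratio)[scores$groups == "CVS"]
  }
  prom <- promoter_window(g$tss, g$strand, platform)
  prom_regions <- data.frame(chrom = g$chrom, start = prom$start,
                             end = prom$end)
  out <- data.frame(gene_id = keep,
                    mean_log2_expr = expression$mean_log2_expr,
                    promoter_meth = suppressWarnings(
                      aggregate_region_score(scores, prom_regions, samples)),
                    gene_body_meth = NA_real_,
                    cpg_oe = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(gene_body_scores)) {
    gb <- data.frame(chrom = g$chrom, start = g$start, end = g$end)
    gb_samples <- colnames(gene_body_scores$log_ratio)[
      gene_body_scores$groups == "CVS"]
    out$gene_body_meth <- suppressWarnings(
      aggregate_region_score(gene_body_scores, gb, gb_samples))
  }
  if (!is.null(promoter_seqs)) {
    seqs <- as.character(promoter_seqs)
    ix <- match(keep, names(seqs))
    out$cpg_oe <- vapply(seq_along(ix), function(i) {
      if (is.na(ix[i])) NA_real_ else cpg_oe_ratio(seqs[ix[i]])
    }, numeric(1))
  }
  out
}
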