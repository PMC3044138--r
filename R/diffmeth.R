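#' Estimate empirical-Bayes variance hyperparameters
#'
#' Method-of-moments fit of the hierarchical variance model in which site
#' variances are distributed as \eqn{s^2 \sim s_0^2 F(d, d_0)} where `d` is
#' the residual degrees of freedom per site.  On `z = log(s2)`,
#' `var(z) = trigamma(d/2) + trigamma(d0/2)`, so `d0` solves
#' `trigamma(d0/2) = max(0, var(z) - trigamma(d/2))` (infinite when the
#' right-hand side is 0) and `s02` follows from `mean(z)` via the digamma
#' bias relation.  The prior `(d0, s02)` is then used to shrink per-site
#' variances in [moderated_t_one_group()] / [moderated_t_two_group()].
#'
#' @param s2 vector of per-site sample variances (>= 0); at least 10
#'   finite positive values are required.
#' @param df_residual residual degrees of freedom per site (>= 1).
#' @return List of class `eb_hyperparams` with `d0` (prior df, possibly
#'   `Inf`) and `s02` (prior variance).
#' @export
estimate_eb_hyperparams <- function(s2, df_residual) {
  stopifnot(is.numeric(s2), df_residual >= 1)
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 10) {
    stop("need at least 10 finite positive variances to fit the prior",
         call. = FALSE)
  }
  df <- df_residual
  z <- log(s2)
  excess <- var(z) - trigamma(df / 2)
  if (excess <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s02 = s02), class = "eb_hyperparams")
}

# solve trigamma(y) = x for y > 0 (x > 0); trigamma is strictly decreasing
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  # Newton iteration on y, with the 1/y ~ sqrt asymptotics as start
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (!is.finite(y) || y <= 0) { # fall back to bisection
      return(uniroot(function(u) trigamma(u) - x,
                     interval = c(1e-8, 1e8), tol = 1e-12)$root)
    }
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

mod_t_result <- function(site_id, effect, s2, n_eff, df, hyper) {
  d0 <- hyper$d0
  s02 <- hyper$s02
  if (d0 == 0) {
    s2_tilde <- s2
    df_total <- df
  } else if (is.infinite(d0)) {
    s2_tilde <- rep(s02, length(s2))
    df_total <- Inf
  } else {
    s2_tilde <- (d0 * s02 + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  se <- sqrt(s2_tilde * n_eff)
  t_mod <- effect / se
  degenerate <- se == 0
  t_mod[degenerate & effect == 0] <- 0
  t_mod[degenerate & effect != 0] <- sign(effect[degenerate & effect != 0]) * Inf
  p <- if (is.infinite(df_total)) {
    2 * pnorm(-abs(t_mod))
  } else {
    2 * pt(-abs(t_mod), df = df_total)
  }
  p[degenerate & effect == 0] <- 1
  p[degenerate & effect != 0] <- 0
  data.frame(site_id = site_id, effect = effect, s2 = s2, t_mod = t_mod,
             df_total = df_total, p = p, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Moderated one-group t test (is the mean score zero?)
#'
#' Tests, per site, whether the mean methylation score differs from 0 using
#' a t statistic whose variance is shrunk towards the empirical-Bayes prior:
#' `s2_tilde = (d0 s02 + (n-1) s2) / (d0 + n - 1)`, with `d0 + n - 1` total
#' degrees of freedom (a normal reference when `d0` is infinite; the
#' ordinary one-sample t when `d0 = 0`).  Two-sided p values.
#'
#' @param values numeric matrix (sites x samples) or a vector for a single
#'   site; n >= 2 samples.
#' @param hyper an `eb_hyperparams` object.
#' @param site_id optional site ids (defaults to rownames).
#' @return data.frame with `site_id`, `effect` (mean score), `s2`, `t_mod`,
#'   `df_total`, `p`, `degenerate`.
#' @export
moderated_t_one_group <- function(values, hyper, site_id = NULL) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  n <- ncol(values)
  if (n < 2) stop("one-group test needs n >= 2 samples", call. = FALSE)
  if (is.null(site_id)) {
    site_id <- rownames(values)
    if (is.null(site_id)) site_id <- as.character(seq_len(nrow(values)))
  }
  mod_t_result(site_id, rowMeans(values), row_vars(values),
               n_eff = 1 / n, df = n - 1, hyper = hyper)
}

#' Moderated two-group t test (do the groups differ?)
#'
#' Pooled-variance two-sample t statistic with empirical-Bayes shrinkage of
#' the pooled variance; `effect` is `mean(group1) - mean(group2)` and the
#' total degrees of freedom are `d0 + n1 + n2 - 2`.  Two-sided p values.
#'
#' @param values_g1,values_g2 matrices (sites x samples) or single-site
#'   vectors; each group needs n >= 2.
#' @param hyper an `eb_hyperparams` object.
#' @param site_id optional site ids.
#' @return data.frame as in [moderated_t_one_group()].
#' @export
moderated_t_two_group <- function(values_g1, values_g2, hyper,
                                  site_id = NULL) {
  if (is.vector(values_g1)) values_g1 <- matrix(values_g1, nrow = 1)
  if (is.vector(values_g2)) values_g2 <- matrix(values_g2, nrow = 1)
  n1 <- ncol(values_g1)
  n2 <- ncol(values_g2)
  if (n1 < 2 || n2 < 2) {
    stop("two-group test needs n >= 2 per group", call. = FALSE)
  }
  if (nrow(values_g1) != nrow(values_g2)) {
    stop("groups must cover the same sites", call. = FALSE)
  }
  if (is.null(site_id)) {
    site_id <- rownames(values_g1)
    if (is.null(site_id)) site_id <- as.character(seq_len(nrow(values_g1)))
  }
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * row_vars(values_g1) + (n2 - 1) * row_vars(values_g2)) / df
  effect <- rowMeans(values_g1) - rowMeans(values_g2)
  mod_t_result(site_id, effect, s2, n_eff = 1 / n1 + 1 / n2, df = df,
               hyper = hyper)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around `p.adjust(..., method = "BH")`: adjusted
#' values are `min_{j >= i} p_(j) m / j` capped at 1, returned in input
#' order.
#'
#' @param p vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Classify tested sites into methylation status calls
#'
#' Applies BH adjustment within the test family and assigns a status from
#' the platform's direction convention.  For a one-group (`"within"`)
#' contrast on infinium data a site is `hypo` when significant with mean
#' log(B/A) < 0 and `hyper` when > 0; on msre data the convention is
#' inverted, since log(HpaII-/HpaII+) is a *hypo*methylation signal:
#' `hypo` requires a mean significantly above 0.  For the two-group
#' (`"between"`) CVS - MBC contrast, `CVS_hypo` means CVS is the less
#' methylated tissue (negative effect on infinium, positive on msre) and
#' `MBC_hypo` the reverse.
#'
#' @param results data.frame from a moderated t function.
#' @param platform `"infinium"` or `"msre"`.
#' @param fdr FDR level, default 0.05.
#' @param contrast `"within"` (one-group) or `"between"` (CVS - MBC).
#' @return The input with `p_adj` and `status` columns appended.
#' @export
classify_sites <- function(results, platform, fdr = 0.05,
                           contrast = c("within", "between")) {
  platform <- match.arg(platform, c("infinium", "msre"))
  contrast <- match.arg(contrast)
  results$p_adj <- bh_adjust(results$p)
  sig <- results$p_adj <= fdr
  # direction in which the effect indicates hypomethylation
  hypo_sign <- if (platform == "infinium") -1 else 1
  eff_sign <- sign(results$effect) * hypo_sign
  status <- if (contrast == "within") {
    ifelse(sig & eff_sign > 0, "hypo", ifelse(sig & eff_sign < 0, "hyper", "ns"))
  } else {
    # effect = mean(CVS) - mean(MBC); CVS_hypo when CVS less methylated
    ifelse(sig & eff_sign > 0, "CVS_hypo",
           ifelse(sig & eff_sign < 0, "MBC_hypo", "ns"))
  }
  results$status <- status
  results
}

#' Site-level methylation calls for a score table
#'
#' High-level driver: estimates the EB prior genome-wide for the platform,
#' runs the moderated t tests and classifies sites.  With
#' `contrast = "within"` the one-group test is run on the samples of
#' `group`; with `contrast = "between"` the two-group CVS vs MBC test is
#' run.
#'
#' @param scores a `score_table` from [compute_scores()].
#' @param contrast `"within"` or `"between"`.
#' @param group tissue for the within contrast (`"CVS"` or `"MBC"`).
#' @param fdr FDR level.
#' @return A methylation call table: the site table joined with the test
#'   columns, `p_adj` and `status`.
#' @export
call_sites <- function(scores, contrast = c("between", "within"),
                       group = "CVS", fdr = 0.05) {
  stopifnot(inherits(scores, "score_table"))
  contrast <- match.arg(contrast)
  lr <- scores$log_ratio
  if (contrast == "within") {
    m <- lr[, scores$groups == group, drop = FALSE]
    hyper <- estimate_eb_hyperparams(row_vars(m), ncol(m) - 1)
    res <- moderated_t_one_group(m, hyper, site_id = scores$sites$site_id)
  } else {
    g1 <- lr[, scores$groups == "CVS", drop = FALSE]
    g2 <- lr[, scores$groups == "MBC", drop = FALSE]
    df <- ncol(g1) + ncol(g2) - 2
    s2 <- ((ncol(g1) - 1) * row_vars(g1) + (ncol(g2) - 1) * row_vars(g2)) / df
    hyper <- estimate_eb_hyperparams(s2, df)
    res <- moderated_t_two_group(g1, g2, hyper,
                                 site_id = scores$sites$site_id)
  }
  res <- classify_sites(res, scores$platform, fdr, contrast)
  cbind(scores$sites[c("chrom", "pos")], res)
}
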