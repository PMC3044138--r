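#' Default parameters of the expression simulator
#'
#' @return Named list: `mu0` (baseline mean log2 expression), `oe_boost`
#'   (added to the baseline of genes with high-CpG promoters),
#'   `sigma` (residual sd in log2 units), `target_r_prom` /
#'   `target_r_body` (genome-wide Pearson correlations the slope
#'   calibration aims for, between expression and promoter log(B/A) /
#'   gene-body log(HpaII-/HpaII+)), `breakpoint` (promoter beta above
#'   which the methylation effect is flat), `h_linear` (disable the
#'   flat-above-breakpoint nonlinearity).
#' @export
expression_sim_config <- function() {
  list(mu0 = 7, oe_boost = 0.75, sigma = 1.0,
       target_r_prom = -0.35, target_r_body = -0.111,
       breakpoint = 0.5, h_linear = FALSE)
}

# decreasing promoter-methylation effect, flat above the breakpoint
h_meth <- function(beta, breakpoint, h_linear) {
  if (h_linear) -beta else -pmin(beta, breakpoint)
}

#' Simulate per-gene expression coupled to methylation
#'
#' Generates `mean_log2_expr = mu_g + a h(beta_prom) - b w_g + N(0,
#' sigma)` where `mu_g` is `mu0` plus `oe_boost` for high-CpG promoters,
#' `h` is linear in promoter beta below the breakpoint and flat above it
#' (the planted nonlinearity: methylation represses expression only
#' below ~50 percent methylation), and `w_g` is the true gene-body
#' hypomethylation score (mean log(HpaII-/HpaII+) implied by the msre
#' truth states over sites in the gene body; 0 when no msre truth is
#' given).  The slopes `a` and `b` are calibrated numerically (fixed
#' point over two monotone root-finders) so that the *expected*
#' genome-wide Pearson correlations between expression and the true
#' promoter log(B/A) and gene-body scores equal `target_r_prom` and
#' `target_r_body`.
#'
#' @param truth truth list from an annotation-coupled
#'   [generate_infinium_dataset()] call (needs `$genes` with
#'   `beta_prom_cvs` and `high_oe`).
#' @param annotation annotation from [generate_annotation()].
#' @param config parameters from [expression_sim_config()].
#' @param seed RNG seed.
#' @param msre_truth optional truth from [generate_msre_dataset()] for
#'   the gene-body component.
#' @return List with `expression` (data.frame `gene_id`,
#'   `mean_log2_expr`) and `truth` (per-gene components, calibrated
#'   slopes `a` and `b`, config, seed).
#' @export
generate_expression <- function(truth, annotation,
                                config = expression_sim_config(),
                                seed = 1L, msre_truth = NULL) {
  cfg <- utils::modifyList(expression_sim_config(), config)
  if (is.null(truth$genes)) {
    stop("truth must come from an annotation-coupled infinium simulation",
         call. = FALSE)
  }
  set.seed(seed)
  g <- truth$genes
  beta <- g$beta_prom_cvs
  x <- log(beta / (1 - beta))            # true promoter log(B/A)
  u <- h_meth(beta, cfg$breakpoint, cfg$h_linear)
  mu <- cfg$mu0 + cfg$oe_boost * as.numeric(g$high_oe)
  w <- rep(0, nrow(g))
  if (!is.null(msre_truth)) {
    ms <- msre_truth$sites
    d_un <- msre_truth$config$d_unmeth
    d_me <- msre_truth$config$d_meth
    site_score <- ifelse(ms$state_cvs == 1L, -log(1 - d_un),
                         -log(1 - d_me))
    ga <- annotation$genes[match(g$gene_id, annotation$genes$gene_id), ]
    qg <- GenomicRanges::GRanges(ga$chrom,
                                 IRanges::IRanges(ga$start + 1L, ga$end))
    qs <- GenomicRanges::GRanges(ms$chrom,
                                 IRanges::IRanges(ms$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(qg, qs)
    agg <- tapply(site_score[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), mean)
    w[as.integer(names(agg))] <- agg
  }
  have_body <- sd(w) > 0

  r_given <- function(a, b, target, v) {
    # correlation of v with mu + a*u - b*w + noise, from sample moments
    sig <- mu + a * u - b * w
    cov_v <- cov(v, sig)
    cov_v / sqrt(var(v) * (var(sig) + cfg$sigma^2)) - target
  }
  a <- 0
  b <- 0
  for (it in 1:8) {
    a <- uniroot(function(aa) r_given(aa, b, cfg$target_r_prom, x),
                 interval = c(-200, 200))$root
    if (have_body) {
      b <- uniroot(function(bb) r_given(a, bb, cfg$target_r_body, w),
                   interval = c(-200, 200))$root
    }
  }
  expr <- mu + a * u - b * w + rnorm(length(x), 0, cfg$sigma)
  expression <- data.frame(gene_id = g$gene_id, mean_log2_expr = expr,
                           stringsAsFactors = FALSE)
  truth_out <- list(
    genes = data.frame(gene_id = g$gene_id, mu = mu, beta_prom = beta,
                       x_prom = x, h_prom = u, w_body = w,
                       stringsAsFactors = FALSE),
    a = a, b = b, config = cfg, seed = seed)
  list(expression = expression, truth = truth_out)
}
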