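#' Default parameters of the infinium-style simulator
#'
#' The generator emulates the statistical structure of a 27,578-site CpG
#' array comparison of placental (CVS) and maternal blood cell (MBC)
#' DNA: a bimodal MBC beta distribution, a flattened CVS distribution in
#' which most fully hypermethylated sites become intermediate, a small
#' panel of planted T-DMR sites with a 5:1 CVS-hypo : MBC-hypo direction
#' bias, and multiplicative lognormal intensity noise with per-array
#' scale factors.
#'
#' @return Named list of generator parameters:
#' \describe{
#'   \item{w_lo, w_hi}{MBC mixture weights of the hypo / hyper beta
#'     components (must sum to 1).}
#'   \item{beta_lo, beta_hi, beta_mid}{shape pairs of the Beta components
#'     (hypo, hyper, intermediate).}
#'   \item{flatten_fraction}{fraction of MBC-hypermethylated sites whose
#'     CVS methylation is drawn from the intermediate component instead
#'     (2/3 of weight 0.45 leaves 0.15 hypermethylated and creates a 0.30
#'     intermediate class).}
#'   \item{tdmr_fraction, tdmr_ratio, min_delta}{size of the planted
#'     T-DMR panel, its CVS-hypo : MBC-hypo ratio, and the minimum |beta
#'     difference| of any true difference.}
#'   \item{total_mu, total_sigma}{lognormal law of per-site total
#'     intensity.}
#'   \item{scale_range}{uniform range of per-array multiplicative scale
#'     factors.}
#'   \item{noise_sd}{sdlog of the per-measurement lognormal noise.}
#' }
#' @export
infinium_sim_config <- function() {
  list(w_lo = 0.55, w_hi = 0.45,
       beta_lo = c(1.5, 30), beta_hi = c(30, 1.5), beta_mid = c(5, 5),
       flatten_fraction = 2 / 3,
       tdmr_fraction = 0.03, tdmr_ratio = 5, min_delta = 0.3,
       total_mu = 7, total_sigma = 0.4,
       scale_range = c(0.7, 1.4), noise_sd = 0.1)
}

draw_beta_comp <- function(n, shapes) rbeta(n, shapes[1], shapes[2])

clamp01 <- function(x, lo = 0.01, hi = 0.99) pmin(pmax(x, lo), hi)

# intensity matrices for a block of samples given true per-site betas
infinium_intensities <- function(beta_mat, cfg) {
  n <- nrow(beta_mat)
  m <- ncol(beta_mat)
  total <- rlnorm(n, cfg$total_mu, cfg$total_sigma)
  scale <- runif(m, cfg$scale_range[1], cfg$scale_range[2])
  base <- total %o% scale
  B <- beta_mat * base * rlnorm(n * m, 0, cfg$noise_sd)
  A <- (1 - beta_mat) * base * rlnorm(n * m, 0, cfg$noise_sd)
  list(A = A, B = B)
}

#' Simulate an infinium-style two-tissue methylation dataset
#'
#' True MBC beta values are drawn from the bimodal mixture
#' `w_lo Beta(1.5, 30) + w_hi Beta(30, 1.5)`.  CVS betas equal the MBC
#' betas except at (i) "flattened" sites -- a `flatten_fraction` of the
#' hypermethylated component whose CVS value is intermediate
#' (`Beta(5, 5)` truncated to keep the difference >= `min_delta`),
#' reproducing the loss of the hypermethylated mode in placental tissue --
#' and (ii) a planted T-DMR panel of `tdmr_fraction` of all sites with
#' direction ratio `tdmr_ratio`:1 (CVS-hypo : MBC-hypo) and
#' |delta beta| >= `min_delta`.  Intensities are
#' `B = beta * T_i * c_j * eps`, `A = (1 - beta) * T_i * c_j * eps'` with
#' per-site lognormal totals, per-array uniform scale factors and
#' per-measurement lognormal noise.
#'
#' With `annotation` supplied, sites are instead placed inside gene
#' promoter windows (`sites_per_promoter` each) and methylation is
#' assigned per gene, coupled to the promoter CpG class: high-O/E
#' promoters are mostly hypomethylated, low-O/E promoters mostly
#' hypermethylated; the CVS flattening and planted panel then operate at
#' the gene level.
#'
#' @param n_sites number of CpG sites (ignored when `annotation` is
#'   given). Default 27578.
#' @param n_cvs,n_mbc samples per tissue. Defaults 12 and 12.
#' @param config parameter list from [infinium_sim_config()].
#' @param seed RNG seed; the generator is a pure function of
#'   (config, seed).
#' @param annotation optional annotation from [generate_annotation()]
#'   for promoter-coupled simulation.
#' @param sites_per_promoter sites placed in each promoter in coupled
#'   mode. Default 2.
#' @return List with `signals` (a [signal_set()]) and `truth`
#'   (`sites`: per-site true betas, delta, `is_tdmr`, `direction`,
#'   `planted`, `shifted`; `genes` in coupled mode: per-gene true
#'   promoter betas and CpG class; plus `config` and `seed`).
#' @export
generate_infinium_dataset <- function(n_sites = 27578L, n_cvs = 12L,
                                      n_mbc = 12L,
                                      config = infinium_sim_config(),
                                      seed = 1L,
                                      annotation = NULL,
                                      sites_per_promoter = 2L) {
  cfg <- utils::modifyList(infinium_sim_config(), config)
  if (abs(cfg$w_lo + cfg$w_hi - 1) > 1e-12) {
    stop("mixture weights w_lo + w_hi must sum to 1", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(annotation)) {
    tr <- infinium_truth_free(n_sites, cfg)
    gene_truth <- NULL
  } else {
    coupled <- infinium_truth_coupled(annotation, sites_per_promoter, cfg)
    tr <- coupled$sites
    gene_truth <- coupled$genes
  }
  n <- nrow(tr)
  beta_cvs_mat <- matrix(tr$beta_cvs, n, n_cvs)
  beta_mbc_mat <- matrix(tr$beta_mbc, n, n_mbc)
  sig <- infinium_intensities(cbind(beta_cvs_mat, beta_mbc_mat), cfg)
  samples <- c(sprintf("CVS%02d", seq_len(n_cvs)),
               sprintf("MBC%02d", seq_len(n_mbc)))
  colnames(sig$A) <- colnames(sig$B) <- samples
  signals <- signal_set("infinium",
                        tr[c("site_id", "chrom", "pos")],
                        ch1 = sig$A, ch2 = sig$B)
  truth <- list(sites = tr, genes = gene_truth, config = cfg, seed = seed)
  list(signals = signals, truth = truth)
}

# site-level truth without annotation coupling
infinium_truth_free <- function(n_sites, cfg) {
  comp <- sample(c("lo", "hi"), n_sites, replace = TRUE,
                 prob = c(cfg$w_lo, cfg$w_hi))
  beta_mbc <- numeric(n_sites)
  beta_mbc[comp == "lo"] <- draw_beta_comp(sum(comp == "lo"), cfg$beta_lo)
  beta_mbc[comp == "hi"] <- draw_beta_comp(sum(comp == "hi"), cfg$beta_hi)
  beta_mbc <- clamp01(beta_mbc)
  beta_cvs <- beta_mbc
  shifted <- rep(FALSE, n_sites)
  planted <- rep(FALSE, n_sites)

  eligible_hi <- which(comp == "hi" & beta_mbc >= cfg$min_delta + 0.05)
  n_shift <- round(cfg$flatten_fraction * length(eligible_hi))
  shift_ix <- sample(eligible_hi, n_shift)
  beta_cvs[shift_ix] <- clamp01(
    pmin(draw_beta_comp(n_shift, cfg$beta_mid),
         beta_mbc[shift_ix] - cfg$min_delta))
  shifted[shift_ix] <- TRUE

  n_planted <- round(cfg$tdmr_fraction * n_sites)
  n_chypo <- round(n_planted * cfg$tdmr_ratio / (cfg$tdmr_ratio + 1))
  n_mhypo <- n_planted - n_chypo
  pool_hi <- setdiff(eligible_hi, shift_ix)
  pool_lo <- which(comp == "lo" & beta_mbc <= 1 - cfg$min_delta - 0.05)
  chypo_ix <- sample(pool_hi, min(n_chypo, length(pool_hi)))
  mhypo_ix <- sample(pool_lo, min(n_mhypo, length(pool_lo)))
  beta_cvs[chypo_ix] <- clamp01(
    pmin(draw_beta_comp(length(chypo_ix), cfg$beta_mid),
         beta_mbc[chypo_ix] - cfg$min_delta))
  beta_cvs[mhypo_ix] <- clamp01(
    pmax(draw_beta_comp(length(mhypo_ix), cfg$beta_mid),
         beta_mbc[mhypo_ix] + cfg$min_delta))
  planted[c(chypo_ix, mhypo_ix)] <- TRUE

  pos <- cumsum(5000L + sample.int(20000L, n_sites, replace = TRUE))
  finish_infinium_truth(
    data.frame(site_id = sprintf("cg%07d", seq_len(n_sites)),
               chrom = "chr1", pos = pos, stringsAsFactors = FALSE),
    beta_mbc, beta_cvs, shifted, planted, cfg)
}

# gene-level truth coupled to promoter CpG class
infinium_truth_coupled <- function(annotation, sites_per_promoter, cfg) {
  g <- annotation$genes
  if (is.null(g$cpg_oe)) {
    stop("annotation genes need a cpg_oe column for coupled simulation",
         call. = FALSE)
  }
  ng <- nrow(g)
  high_oe <- g$cpg_oe > 0.4
  # component probabilities (lo, mid, hi) per CpG class
  p_high <- c(0.60, 0.10, 0.30)
  p_low <- c(0.15, 0.10, 0.75)
  comp <- character(ng)
  comp[high_oe] <- sample(c("lo", "mid", "hi"), sum(high_oe), TRUE, p_high)
  comp[!high_oe] <- sample(c("lo", "mid", "hi"), sum(!high_oe), TRUE, p_low)
  beta_mbc <- numeric(ng)
  for (cc in c("lo", "mid", "hi")) {
    ix <- comp == cc
    beta_mbc[ix] <- draw_beta_comp(sum(ix),
                                   cfg[[paste0("beta_", cc)]])
  }
  beta_mbc <- clamp01(beta_mbc)
  beta_cvs <- beta_mbc
  shifted <- rep(FALSE, ng)
  planted <- rep(FALSE, ng)
  eligible_hi <- which(comp == "hi" & beta_mbc >= cfg$min_delta + 0.05)
  shift_ix <- sample(eligible_hi,
                     round(cfg$flatten_fraction * length(eligible_hi)))
  beta_cvs[shift_ix] <- clamp01(
    pmin(draw_beta_comp(length(shift_ix), cfg$beta_mid),
         beta_mbc[shift_ix] - cfg$min_delta))
  shifted[shift_ix] <- TRUE
  n_planted <- round(cfg$tdmr_fraction * ng)
  n_chypo <- round(n_planted * cfg$tdmr_ratio / (cfg$tdmr_ratio + 1))
  pool_hi <- setdiff(eligible_hi, shift_ix)
  pool_lo <- which(comp == "lo" & beta_mbc <= 1 - cfg$min_delta - 0.05)
  chypo_ix <- sample(pool_hi, min(n_chypo, length(pool_hi)))
  mhypo_ix <- sample(pool_lo, min(n_planted - n_chypo, length(pool_lo)))
  beta_cvs[chypo_ix] <- clamp01(
    pmin(draw_beta_comp(length(chypo_ix), cfg$beta_mid),
         beta_mbc[chypo_ix] - cfg$min_delta))
  beta_cvs[mhypo_ix] <- clamp01(
    pmax(draw_beta_comp(length(mhypo_ix), cfg$beta_mid),
         beta_mbc[mhypo_ix] + cfg$min_delta))
  planted[c(chypo_ix, mhypo_ix)] <- TRUE

  # sites: sites_per_promoter positions near each TSS, shared jitter
  offsets <- lapply(seq_len(ng), function(i) {
    sort(sample.int(1000L, sites_per_promoter) - 500L)
  })
  site_gene <- rep(seq_len(ng), each = sites_per_promoter)
  pos <- g$tss[site_gene] + unlist(offsets)
  jit <- rnorm(length(pos), 0, 0.02)
  sites <- data.frame(
    site_id = sprintf("cg%07d", seq_along(pos)),
    chrom = g$chrom[site_gene],
    pos = as.integer(pos),
    gene_id = g$gene_id[site_gene],
    stringsAsFactors = FALSE)
  tr <- finish_infinium_truth(sites,
                              clamp01(beta_mbc[site_gene] + jit),
                              clamp01(beta_cvs[site_gene] + jit),
                              shifted[site_gene], planted[site_gene], cfg)
  genes <- data.frame(gene_id = g$gene_id, cpg_oe = g$cpg_oe,
                      high_oe = high_oe, comp = comp,
                      beta_prom_mbc = beta_mbc, beta_prom_cvs = beta_cvs,
                      shifted = shifted, planted = planted,
                      stringsAsFactors = FALSE)
  list(sites = tr, genes = genes)
}

finish_infinium_truth <- function(sites, beta_mbc, beta_cvs, shifted,
                                  planted, cfg) {
  delta <- beta_cvs - beta_mbc
  # tolerance guards the truncation atom at exactly +/- min_delta
  big <- abs(delta) >= cfg$min_delta - 1e-9
  tr <- cbind(sites,
              data.frame(beta_mbc = beta_mbc, beta_cvs = beta_cvs,
                         delta = delta,
                         is_tdmr = big,
                         direction = ifelse(
                           !big, "none",
                           ifelse(delta < 0, "CVS_hypo", "MBC_hypo")),
                         shifted = shifted, planted = planted,
                         stringsAsFactors = FALSE))
  ord <- order(tr$chrom, tr$pos)
  tr <- tr[ord, , drop = FALSE]
  rownames(tr) <- NULL
  tr
}
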