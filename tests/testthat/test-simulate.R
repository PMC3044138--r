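# generator sizes here are reduced for speed; the study-scale runs live in
# the acceptance suite

small_inf <- function(seed, ...) {
  generate_infinium_dataset(n_sites = 4000, n_cvs = 6, n_mbc = 6,
                            config = list(...), seed = seed)
}

small_msre_cfg <- list(chrom_sites = c(chrA = 4000L, chrB = 3000L),
                       scale = 1, n_regions_fwd = 3L, n_regions_rev = 1L,
                       region_sites = c(60L, 120L))

test_that("all generators are pure functions of (config, seed)", {
  expect_identical(small_inf(31), small_inf(31))
  expect_identical(generate_msre_dataset(small_msre_cfg, seed = 32),
                   generate_msre_dataset(small_msre_cfg, seed = 32))
  ms <- generate_msre_dataset(small_msre_cfg, seed = 32)
  a1 <- generate_annotation(60, seed = 33, msre_truth = ms$truth)
  a2 <- generate_annotation(60, seed = 33, msre_truth = ms$truth)
  expect_identical(a1, a2)
  inf <- generate_infinium_dataset(annotation = a1, seed = 34)
  e1 <- generate_expression(inf$truth, a1, seed = 35,
                            msre_truth = ms$truth)
  e2 <- generate_expression(inf$truth, a1, seed = 35,
                            msre_truth = ms$truth)
  expect_identical(e1, e2)
  # different seeds differ
  expect_false(identical(small_inf(31), small_inf(36)))
})

test_that("infinium truth encodes the planted structure", {
  d <- small_inf(37)
  tr <- d$truth$sites
  expect_true(all(abs(tr$delta[tr$is_tdmr]) >= 0.3 - 1e-9))
  expect_true(all(tr$direction[tr$is_tdmr & tr$delta < 0] == "CVS_hypo"))
  expect_equal(sum(tr$planted), round(0.03 * 4000))
  expect_error(generate_infinium_dataset(
    n_sites = 500, config = list(w_lo = 0.5, w_hi = 0.4)), "sum to 1")

  # MBC betas are bimodal: both extreme modes populated, valley empty-ish
  h <- hist(tr$beta_mbc, breaks = seq(0, 1, length.out = 51),
            plot = FALSE)$counts
  expect_gt(sum(h[1:10]), 0.3 * 4000)        # mode below 0.2
  expect_gt(sum(h[41:50]), 0.1 * 4000)       # mode above 0.8
  expect_lt(sum(h[21:30]), sum(h[1:10]) / 4) # sparse middle
  # CVS loses most of the hypermethylated mode
  expect_gt(mean(tr$beta_mbc > 0.8), 2.5 * mean(tr$beta_cvs > 0.8))
})

test_that("msre truth has clustered states and well-separated planted regions", {
  ms <- generate_msre_dataset(small_msre_cfg, seed = 38)
  tr <- ms$truth
  # n_regions_rev is a genome-wide total, allocated across chromosomes
  expect_equal(nrow(tr$regions), 2 * 3 + 1)
  expect_equal(sum(tr$regions$type == "MBC_hypo"), 1L)
  # inside planted regions the tissues are forced apart
  for (i in seq_len(nrow(tr$regions))) {
    ix <- tr$sites$chrom == tr$regions$chrom[i] &
      tr$sites$pos >= tr$regions$start[i] &
      tr$sites$pos < tr$regions$end[i]
    if (tr$regions$type[i] == "CVS_hypo") {
      expect_true(all(tr$sites$state_cvs[ix] == 1L))
      expect_true(all(tr$sites$state_mbc[ix] == 0L))
    } else {
      expect_true(all(tr$sites$state_mbc[ix] == 1L))
      expect_true(all(tr$sites$state_cvs[ix] == 0L))
    }
  }
  # outside, the background state is shared and spatially clustered
  out <- tr$sites$region_id == 0
  expect_true(all(tr$sites$state_cvs[out] == tr$sites$state_mbc[out]))
  runs <- rle(tr$sites$state_cvs[out & tr$sites$chrom == "chrA"])
  expect_gt(mean(runs$lengths[runs$values == 1]), 5)

  # the hypomethylation score separates the true states (construction)
  sc <- compute_scores(ms$signals)
  for (s in 1:3) {
    m2 <- generate_msre_dataset(small_msre_cfg, seed = 40 + s)
    s2 <- compute_scores(m2$signals)
    lr <- rowMeans(s2$log_ratio[, s2$groups == "CVS"])
    expect_gt(mean(lr[m2$truth$sites$state_cvs == 1]), 1)
    expect_lt(abs(mean(lr[m2$truth$sites$state_cvs == 0])), 0.05)
  }

  # an infeasible layout errors
  expect_error(generate_msre_dataset(list(
    chrom_sites = c(chrA = 300L), scale = 1, n_regions_fwd = 8L,
    n_regions_rev = 0L), seed = 1), "exceed")
})

test_that("annotation respects gene structure and the CpG O/E mixture", {
  ms <- generate_msre_dataset(small_msre_cfg, seed = 44)
  ann <- generate_annotation(80, seed = 44, msre_truth = ms$truth)
  g <- ann$genes
  expect_true(all(g$start < g$end))
  expect_true(all(g$tss == ifelse(g$strand == "+", g$start, g$end - 1)))
  ex <- ann$exons
  ix <- match(ex$gene_id, g$gene_id)
  expect_true(all(ex$start >= g$start[ix] & ex$end <= g$end[ix]))

  # realized O/E hits its target within the documented tolerance
  expect_true(all(abs(g$cpg_oe - g$oe_target) <= 0.05))
  oracle_oe <- vapply(ann$promoter_seqs[g$gene_id], cpg_oe_ratio,
                      numeric(1))
  expect_equal(unname(oracle_oe), g$cpg_oe, tolerance = 1e-12)
  # both mixture modes are populated
  expect_gt(mean(g$cpg_oe <= 0.4), 0.25)
  expect_gt(mean(g$cpg_oe > 0.4), 0.25)
  # CGIs sit at high-O/E promoters only
  expect_true(all(g$cpg_oe[g$has_cgi] > 0.4))

  # gene-desert coupling: genes avoid planted regions; without coupling
  # they do overlap them at a rate consistent with region coverage
  overlaps <- function(genes, regions) {
    mean(vapply(seq_len(nrow(regions)), function(i) {
      any(genes$chrom == regions$chrom[i] &
            genes$start < regions$end[i] &
            genes$end > regions$start[i])
    }, logical(1)))
  }
  expect_equal(overlaps(g, ms$truth$regions), 0)
  ann_free <- generate_annotation(80, seed = 44, msre_truth = ms$truth,
                                  gene_desert_coupling = FALSE)
  expect_gt(overlaps(ann_free$genes, ms$truth$regions), 0)

  # promoter FASTA round-trip
  fa <- tempfile(fileext = ".fa")
  write_promoter_fasta(ann$promoter_seqs, fa)
  expect_equal(read_promoter_fasta(fa), ann$promoter_seqs)
})

test_that("expression coupling is calibrated and exact in the noiseless limit", {
  ms <- generate_msre_dataset(small_msre_cfg, seed = 46)
  ann <- generate_annotation(100, seed = 46, msre_truth = ms$truth)
  inf <- generate_infinium_dataset(annotation = ann, seed = 46)
  expect_error(generate_expression(list(genes = NULL), ann), "coupled")

  # noiseless, gene-body-free, fully linear coupling: the sample
  # correlation equals its moment-form value exactly
  ex0 <- generate_expression(inf$truth, ann,
                             config = list(sigma = 0, h_linear = TRUE),
                             seed = 47)
  g <- ex0$truth$genes
  r_sample <- cor(g$x_prom, ex0$expression$mean_log2_expr)
  sig <- g$mu + ex0$truth$a * g$h_prom - ex0$truth$b * g$w_body
  r_analytic <- cov(g$x_prom, sig) / sqrt(var(g$x_prom) * var(sig))
  expect_equal(r_sample, r_analytic, tolerance = 1e-6)

  # with defaults the calibration equation is satisfied at the solution
  ex <- generate_expression(inf$truth, ann, seed = 47,
                            msre_truth = ms$truth)
  gt <- ex$truth$genes
  sig <- gt$mu + ex$truth$a * gt$h_prom - ex$truth$b * gt$w_body
  r_exp <- cov(gt$x_prom, sig) /
    sqrt(var(gt$x_prom) * (var(sig) + ex$truth$config$sigma^2))
  expect_equal(r_exp, -0.35, tolerance = 1e-6)
  r_body <- cov(gt$w_body, sig) /
    sqrt(var(gt$w_body) * (var(sig) + ex$truth$config$sigma^2))
  expect_equal(r_body, -0.111, tolerance = 1e-4)
  # high-CpG promoters are more expressed on average
  ann_oe <- ann$genes$cpg_oe[match(gt$gene_id, ann$genes$gene_id)]
  expect_gt(mean(ex$expression$mean_log2_expr[ann_oe > 0.4]),
            mean(ex$expression$mean_log2_expr[ann_oe <= 0.4]))
})
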