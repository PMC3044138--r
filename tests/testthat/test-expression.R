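test_that("region scores average member-site means and flag empty regions", {
  path <- write_tiny_signal()
  sc <- compute_scores(read_signal_table(path, "infinium"))
  # sites at pos 5, 10, 25
  one <- data.frame(chrom = "chr1", start = 0L, end = 6L)
  expect_equal(aggregate_region_score(sc, one),
               mean(sc$log_ratio[1, ]))
  both <- data.frame(chrom = "chr1", start = 0L, end = 11L)
  expect_equal(aggregate_region_score(sc, both),
               mean(rowMeans(sc$log_ratio)[1:2]))
  expect_warning(v <- aggregate_region_score(
    sc, data.frame(chrom = "chr1", start = 100L, end = 200L)), "no site")
  expect_true(is.na(v))

  # loop-based oracle on a random fixture
  ms <- generate_msre_dataset(config = list(
    chrom_sites = c(chrA = 800L), scale = 1, n_regions_fwd = 1L,
    n_regions_rev = 0L, region_sites = c(30L, 60L)), seed = 21)
  scm <- compute_scores(ms$signals)
  set.seed(22)
  st <- sort(sample(ms$truth$sites$pos, 10))
  regions <- data.frame(chrom = "chrA", start = st, end = st + 50000L)
  got <- suppressWarnings(aggregate_region_score(scm, regions))
  site_mean <- rowMeans(scm$log_ratio)
  want <- vapply(seq_len(10), function(i) {
    inside <- scm$sites$pos >= regions$start[i] &
      scm$sites$pos < regions$end[i]
    if (!any(inside)) NA_real_ else mean(site_mean[inside])
  }, numeric(1))
  expect_equal(got, want)
})

test_that("smoothing spline hits its target df and tests association", {
  set.seed(23)
  x <- runif(200)
  y <- sin(2 * pi * x) + rnorm(200, 0, 0.1)
  f <- smoothing_spline_regress(x, y, target_df = 6)
  expect_lt(abs(f$df - 6), 0.01)
  expect_lt(f$p, 1e-6)
  expect_lte(f$rss_fit, f$rss_null)
  expect_gte(f$F, 0)

  # constant response: no association
  f0 <- smoothing_spline_regress(x, rep(2, 200), target_df = 4)
  expect_equal(f0$F, 0)
  expect_equal(f0$p, 1)

  # very large penalty reproduces the least-squares line
  yl <- 1 + 2 * x + rnorm(200, 0, 0.2)
  big <- smooth.spline(x, yl, spar = 2)$lambda
  fl <- smoothing_spline_regress(x, yl, lambda = big)
  expect_lt(max(abs(fl$fitted - fitted(lm(yl ~ x)))), 1e-3)

  expect_error(smoothing_spline_regress(rep(1, 30), rnorm(30), 4),
               "constant")
  expect_error(smoothing_spline_regress(runif(30), rnorm(30), 31),
               "target_df")
  expect_error(smoothing_spline_regress(runif(10), rnorm(10), 4),
               "at least 20")
})

test_that("correlation tests match closed forms and cor.test", {
  expect_equal(pearson_correlation_test(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson_correlation_test(1:4, -(1:4))$r, -1)
  r <- pearson_correlation_test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$r, 0.8)
  expect_equal(r$p, 2 * pt(-0.8 * sqrt(2 / 0.36), 2), tolerance = 1e-12)
  expect_error(pearson_correlation_test(rep(1, 5), rnorm(5)), "constant")

  set.seed(24)
  for (i in 1:20) {
    x <- rnorm(10 + i)
    y <- rnorm(10 + i)
    got <- pearson_correlation_test(x, y)
    ct <- cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("piecewise correlations partition on the threshold", {
  set.seed(25)
  x <- c(runif(50, -2, 0), runif(50, 0, 2))
  y <- c(-2 * x[1:50], rep(0, 50)) + rnorm(100, 0, 0.3)
  lo <- piecewise_correlation(x, y, 0, "below")
  hi <- piecewise_correlation(x, y, 0, "above")
  expect_equal(lo$n_used + hi$n_used, 100L)
  expect_lt(lo$p, 0.01)
  expect_lt(lo$r, 0)
  expect_lt(abs(hi$r), 0.3)
  expect_error(piecewise_correlation(x, y, -10, "below"), "side")
})

test_that("CpG O/E follows the Gardiner-Garden & Frommer form", {
  expect_equal(cpg_oe_ratio("CGCGCGCGCG"), 2)
  expect_equal(cpg_oe_ratio("ACGT"), 4)
  expect_true(is.na(cpg_oe_ratio("ATATAT")))
  expect_equal(cpg_oe_ratio("acgt"), 4)          # case-insensitive
  expect_equal(cpg_oe_ratio("ACGTNN"), 6)        # N counts in L only
  expect_equal(cpg_oe_ratio(Biostrings::DNAString("ACGT")), 4)
  expect_error(cpg_oe_ratio("A"), "length >= 2")
})

test_that("genes split on the CpG frequency cutoff with the <= convention", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    cpg_oe = c(0.2, 0.4, 0.41))
  sp <- split_by_cpg_frequency(tab, 0.4)
  expect_equal(sp$low$gene_id, c("a", "b"))
  expect_equal(sp$high$gene_id, "c")

  same <- data.frame(cpg_oe = rep(0.4, 3))
  expect_equal(nrow(split_by_cpg_frequency(same, 0.4)$high), 0L)
  empty <- data.frame(cpg_oe = numeric())
  expect_equal(nrow(split_by_cpg_frequency(empty, 0.4)$low), 0L)
  withna <- data.frame(cpg_oe = c(0.2, NA))
  expect_warning(sp2 <- split_by_cpg_frequency(withna, 0.4), "undefined")
  expect_equal(nrow(sp2$low), 1L)
})
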