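test_that("nearest-site windows match the brute-force oracle", {
  pos <- c(10, 20, 30, 100, 110)
  expect_equal(nearest_window(pos, 1, 3), 1:3)
  expect_equal(nearest_window(pos, 4, 3), 3:5)
  expect_equal(nearest_window(pos, 2, 5), 1:5)
  expect_error(nearest_window(numeric(0), 1, 3), "empty")

  set.seed(5)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    p <- sort(sample.int(10000, n))
    k <- sample.int(n, 1)
    idx <- sample.int(n, 1)
    expect_equal(nearest_window(p, idx, k), nearest_oracle(p, idx, k))
  }
})

test_that("moving averages equal windowed means and the tissue difference identity", {
  pos <- c(10, 20, 30, 100, 110)
  expect_equal(moving_hypo_rate(pos, c(1, 0, 1, 0, 0), 3),
               c(2, 2, 2, 1, 1) / 3)
  expect_equal(moving_hypo_rate(pos, rep(1, 5), 3), rep(1, 5))
  expect_equal(moving_hypo_rate(pos, rep(0, 5), 3), rep(0, 5))
  expect_warning(r <- moving_hypo_rate(pos, rep(1, 5), 10), "fewer sites")
  expect_equal(r, rep(1, 5))

  expect_equal(moving_hypo_diff(c(1, 2, 3), c(1, 1, 0), c(0, 1, 0), 3),
               rep(1 / 3, 3))
  set.seed(6)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    p <- sort(sample.int(1e6, n))
    fc <- rbinom(n, 1, 0.4)
    fm <- rbinom(n, 1, 0.3)
    k <- sample(3:15, 1)
    expect_equal(moving_hypo_diff(p, fc, fm, k),
                 moving_hypo_rate(p, fc, k) - moving_hypo_rate(p, fm, k))
    expect_equal(moving_hypo_diff(p, fm, fc, k),
                 -moving_hypo_diff(p, fc, fm, k))
  }
})

test_that("the simulated null has binomial window moments", {
  expect_error(simulate_null_windows(100, 0.3, 0.3, 10, 50), "n_sim")
  z <- simulate_null_windows(200, 0, 0, 10, 100, seed = 1)
  expect_true(all(z$rate_cvs == 0) && all(z$diff == 0))

  ns <- simulate_null_windows(2000, 0.3, 0.2, 50, 200, seed = 2)
  # ~ n/k quasi-independent windows per replicate
  se_mean <- sqrt(0.3 * 0.7 / 50 / (200 * 2000 / 50))
  expect_lt(abs(mean(ns$rate_cvs) - 0.3), 3 * se_mean)
  expect_lt(abs(var(ns$rate_cvs) - 0.3 * 0.7 / 50) / (0.3 * 0.7 / 50), 0.15)
  expect_lt(abs(var(ns$diff) - (0.3 * 0.7 + 0.2 * 0.8) / 50) /
              ((0.3 * 0.7 + 0.2 * 0.8) / 50), 0.15)

  # the tabulated null is the same sample under the same seed
  tb <- tabulate_null_windows(2000, 0.3, 0.2, 50, 200, seed = 2)
  expect_identical(tabulate(round(ns$rate_cvs * 50) + 1L, 51L), tb$rate_cvs)
  expect_identical(tabulate(round(ns$diff * 50) + 51L, 101L), tb$diff)
})

test_that("empirical p values use the add-one rule on either tail", {
  null99 <- 1:99
  expect_equal(suppressWarnings(empirical_pvalues(100, null99, "upper")),
               0.01)
  expect_equal(suppressWarnings(empirical_pvalues(0.5, null99, "upper")),
               1)
  expect_equal(suppressWarnings(empirical_pvalues(0.5, null99, "lower")),
               0.01)
  expect_error(empirical_pvalues(1, numeric(0), "upper"), "empty")
  expect_warning(empirical_pvalues(1, 1:50, "upper"), "coarse")

  set.seed(7)
  null <- rnorm(500)
  obs <- rnorm(50)
  for (tail in c("upper", "lower")) {
    expect_equal(empirical_pvalues(obs, null, tail),
                 empirical_p_oracle(obs, null, tail))
  }
})

test_that("significant sites merge by the fewer-than-k intervening rule", {
  pos <- seq(0, 10000, by = 50)  # 201 sites
  p <- rep(1, 201)

  p1 <- p; p1[c(100, 149)] <- 0.01      # 48 intervening sites
  r1 <- merge_significant_sites(pos, p1, alpha = 0.05, max_gap_sites = 50)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$start, pos[100])
  expect_equal(r1$end, pos[149] + 1)
  expect_equal(r1$n_sites, 2L)

  p2 <- p; p2[c(100, 151)] <- 0.01      # exactly 50 intervening sites
  r2 <- merge_significant_sites(pos, p2, alpha = 0.05, max_gap_sites = 50)
  expect_equal(nrow(r2), 2L)

  p3 <- p; p3[7] <- 0.01
  r3 <- merge_significant_sites(pos, p3, alpha = 0.05, max_gap_sites = 50)
  expect_equal(nrow(r3), 1L)
  expect_equal(c(r3$start, r3$end), c(pos[7], pos[7] + 1))

  r0 <- merge_significant_sites(pos, p, alpha = 0.05, max_gap_sites = 50)
  expect_equal(nrow(r0), 0L)
})

test_that("the chromosome scan localizes a planted difference block", {
  set.seed(11)
  n <- 1500
  pos <- cumsum(5 + rpois(n, 20))
  base <- rbinom(n, 1, 0.25)
  fc <- base
  fm <- base
  fc[700:800] <- 1
  fm[700:800] <- 0
  res <- scan_chromosome(pos, fc, fm, chrom = "chrT", k = 50,
                         n_sim = 300, seed = 12)
  reg <- res$regions[res$regions$type == "CVS_gt_MBC", ]
  expect_gte(nrow(reg), 1L)
  # the top region overlaps the planted block
  top <- reg[which.min(reg$min_p_adj), ]
  expect_lt(top$start, pos[800])
  expect_gt(top$end, pos[700])
  # regions of one type never overlap
  for (ty in unique(res$regions$type)) {
    r <- res$regions[res$regions$type == ty, ]
    if (nrow(r) > 1) {
      r <- r[order(r$start), ]
      expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    }
  }
  # track statistics are bounded
  expect_true(all(abs(res$tracks$diff) <= 1))
  expect_true(all(res$tracks$rate_cvs >= 0 & res$tracks$rate_cvs <= 1))
})
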