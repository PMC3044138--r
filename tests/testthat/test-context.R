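test_that("promoter windows follow the platform and strand conventions", {
  expect_equal(unlist(promoter_window(5000, "+", "infinium")),
               c(start = 3500, end = 6500))
  expect_equal(unlist(promoter_window(5000, "+", "msre")),
               c(start = 3500, end = 6000))
  expect_equal(unlist(promoter_window(5000, "-", "msre")),
               c(start = 4001, end = 6501))
  expect_equal(promoter_window(300, "+", "infinium")$start, 0)
  expect_error(promoter_window(5000, "+", "epic"), "arg")
  expect_error(promoter_window(5000, "*", "msre"), "strand")

  # the minus-strand window mirrors the plus-strand one about the TSS
  pw_p <- promoter_window(10000, "+", "msre")
  pw_m <- promoter_window(10000, "-", "msre")
  expect_equal(pw_p$end - 1 - 10000, 10000 - pw_m$start)
  expect_equal(10000 - pw_p$start, pw_m$end - 1 - 10000)
})

test_that("site annotation agrees with all-pairs containment", {
  ann <- tiny_annotation()
  sites <- data.frame(site_id = c("s1", "s2", "s3", "s4"),
                      chrom = c("chr1", "chr1", "chr1", "chr9"),
                      pos = c(5000L, 6500L, 6499L, 100L))
  fm <- annotate_sites(sites, ann, "infinium")
  # a site exactly at a + strand TSS is in the promoter and the gene body
  expect_true(fm$in_promoter[1] && fm$in_gene_body[1] && fm$in_cgi[1])
  # half-open boundary: tss + 1500 is outside the infinium promoter
  expect_false(fm$in_promoter[2])
  expect_true(fm$in_promoter[3])
  # unknown chromosome gives all-false flags
  expect_false(any(unlist(fm[4, -1])))
  # exon membership implies gene-body membership
  expect_true(all(!fm$in_exon | fm$in_gene_body))

  set.seed(13)
  n_feat <- 100
  fchrom <- sample(c("chr1", "chr2"), n_feat, TRUE)
  fstart <- sample.int(50000, n_feat)
  fend <- fstart + sample.int(3000, n_feat)
  rsites <- data.frame(site_id = sprintf("r%d", 1:1000),
                       chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                       pos = sample.int(55000, 1000))
  rsites <- rsites[order(rsites$chrom, rsites$pos), ]
  got <- sites_in_intervals(rsites$chrom, rsites$pos, fchrom, fstart, fend)
  want <- containment_oracle(rsites$chrom, rsites$pos, fchrom, fstart, fend)
  expect_equal(got, want)
})

test_that("two-sided Fisher test matches exhaustive enumeration", {
  expect_equal(fisher_exact_two_sided(rbind(c(1, 1), c(1, 1)))$p, 1)
  expect_equal(fisher_exact_two_sided(rbind(c(5, 0), c(0, 5)))$p, 2 / 252)
  expect_error(fisher_exact_two_sided(rbind(c(-1, 1), c(1, 1))),
               "non-negative")

  # exhaustive over all small tables
  for (tot in c(6, 10, 14)) {
    comps <- expand.grid(a = 0:tot, b = 0:tot, c = 0:tot)
    comps <- comps[rowSums(comps) <= tot, ]
    for (r in seq_len(nrow(comps))) {
      tab <- rbind(c(comps$a[r], comps$b[r]),
                   c(comps$c[r], tot - sum(comps[r, ])))
      if (sum(tab) == 0) next
      expect_equal(fisher_exact_two_sided(tab)$p, fisher_oracle(tab),
                   tolerance = 1e-12)
    }
  }

  # larger random tables against stats::fisher.test as a second oracle
  set.seed(14)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 30), 2)
    expect_equal(fisher_exact_two_sided(tab)$p,
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("feature enrichment builds the right table and proportions", {
  calls <- data.frame(site_id = sprintf("s%d", 1:100),
                      status = rep(c("CVS_hypo", "ns"), c(40, 60)))
  membership <- data.frame(site_id = calls$site_id,
                           in_gene_body = rep(c(TRUE, FALSE), 50),
                           in_promoter = FALSE,
                           in_exon = FALSE,
                           in_cgi = c(rep(FALSE, 40), rep(TRUE, 60)))
  en <- enrichment_by_feature(calls, membership, "CVS_hypo", "ns",
                              "in_cgi")
  expect_equal(unname(en$table[1, ]), c(0, 40))
  expect_equal(unname(en$table[2, ]), c(60, 0))
  expect_equal(unname(en$proportions), c(0, 1))

  # swapping the statuses reciprocates the odds ratio, p unchanged
  m2 <- membership
  m2$in_gene_body <- c(rep(TRUE, 30), rep(FALSE, 70))
  e1 <- enrichment_by_feature(calls, m2, "CVS_hypo", "ns", "in_gene_body")
  e2 <- enrichment_by_feature(calls, m2, "ns", "CVS_hypo", "in_gene_body")
  expect_equal(e1$odds_ratio, 1 / e2$odds_ratio)
  expect_equal(e1$p, e2$p)

  # universal membership is uninformative
  m3 <- membership
  m3$in_exon <- TRUE
  expect_equal(enrichment_by_feature(calls, m3, "CVS_hypo", "ns",
                                     "in_exon")$p, 1)
  expect_error(enrichment_by_feature(calls, membership, "MBC_hypo", "ns",
                                     "in_cgi"), "MBC_hypo")
})

test_that("GO-style enrichment excludes the gene set from its complement", {
  universe <- sprintf("g%03d", 1:786)
  term <- setNames(rep(FALSE, 786), universe)
  gene_set <- universe[1:20]
  term[universe[1:9]] <- TRUE          # 9 of 20 in the set
  term[universe[101:172]] <- TRUE      # 72 of the other 766
  res <- go_term_enrichment(gene_set, universe, term)
  expect_equal(unname(res$table[1, ]), c(9, 11))
  expect_equal(unname(res$table[2, ]), c(72, 694))

  expect_error(go_term_enrichment(c("zz"), universe, term), "subset")
  expect_error(go_term_enrichment(universe, universe, term), "complement")
  none <- setNames(rep(FALSE, 786), universe)
  r0 <- go_term_enrichment(gene_set, universe, none)
  expect_equal(r0$p, 1)
  expect_true(is.nan(r0$odds_ratio))
})
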