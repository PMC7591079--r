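# Annotation statistics: acceptance regions, Fisher, chi-squared, BH,
# enrichment and proportion comparisons.

test_that("exact acceptance region matches binomial enumeration", {
  # n = 5: even a 0:5 split has two-sided p = 0.0625 > 0.05
  r5 <- equal_ratio_acceptance(5, 0.05, "exact_binomial")
  expect_equal(unname(r5), c(0, 1))
  expect_equal(stats::binom.test(0, 5, 0.5)$p.value, 0.0625)
  # n = 6 is the smallest n at which 0:n is significant (p = 0.03125)
  r6 <- equal_ratio_acceptance(6, 0.05, "exact_binomial")
  expect_gt(r6[["lo"]], 0)
  expect_lt(r6[["hi"]], 1)
  expect_equal(stats::binom.test(0, 6, 0.5)$p.value, 0.03125)
  for (n in 2:5) {
    r <- equal_ratio_acceptance(n, 0.05, "exact_binomial")
    expect_equal(unname(r), c(0, 1))
  }
  # region boundaries agree with binom.test over a range of n
  for (n in c(10, 25, 60, 200)) {
    r <- equal_ratio_acceptance(n, 0.05, "exact_binomial")
    k <- 0:n
    inside <- vapply(k, function(kk)
      stats::binom.test(kk, n, 0.5)$p.value > 0.05, logical(1))
    expect_equal(min(k[inside]) / n, r[["lo"]])
    expect_equal(max(k[inside]) / n, r[["hi"]])
  }
})

test_that("acceptance regions are symmetric about 0.5 and shrink with n", {
  widths <- vapply(c(6, 20, 50, 200), function(n) {
    r <- equal_ratio_acceptance(n)
    expect_equal(r[["lo"]] + r[["hi"]], 1, tolerance = 1e-12)
    r[["hi"]] - r[["lo"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(equal_ratio_acceptance(1), "n >= 2")
})

test_that("Wald region matches the closed form", {
  r <- equal_ratio_acceptance(100, 0.05, "normal_wald")
  expect_equal(r[["lo"]], 0.5 - stats::qnorm(0.975) * 0.05, tolerance = 1e-9)
  expect_equal(r[["hi"]], 0.5 + stats::qnorm(0.975) * 0.05, tolerance = 1e-9)
  expect_equal(round(unname(r), 3), c(0.402, 0.598))
})

test_that("term scan flags planted asymmetries and keeps balanced terms", {
  counts <- data.frame(term_id = c("BAL", "PLANT", "TINY"),
                       count_focal = c(10, 20, 1),
                       count_sister = c(10, 2, 0))
  res <- term_ratio_scan(counts)
  expect_equal(res$term_id, c("BAL", "PLANT"))  # n >= 2 only
  expect_false(res$significant[1])
  expect_true(res$significant[2])
  expect_equal(res$direction, c("none", "focal"))
  # oracle: exact binomial p-value of the planted 20:2 split
  expect_lt(stats::binom.test(20, 22, 0.5)$p.value, 0.05)
})

test_that("swapping species labels flips directions and nothing else", {
  tc <- simulate_term_counts(n_terms = 40, planted = data.frame(
    count_focal = c(18, 1), count_sister = c(2, 15)), seed = 4)
  r1 <- term_ratio_scan(tc)
  tc2 <- tc
  tc2$count_focal <- tc$count_sister
  tc2$count_sister <- tc$count_focal
  r2 <- term_ratio_scan(tc2)
  expect_identical(r1$significant, r2$significant)
  flip <- c(none = "none", focal = "sister", sister = "focal")
  expect_identical(unname(flip[r1$direction]), r2$direction)
})

test_that("Fisher p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(0, 5, 0, 7), 1)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:25) {
    cells <- stats::rpois(4, 6)
    if (sum(cells) == 0) next
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4]),
                 oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "empty")
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("level A Fisher uses count vs total-minus-count margins", {
  counts <- data.frame(category = c("EQ", "DIFF"),
                       count_focal = c(20, 22), count_sister = c(20, 40))
  res <- levelA_fisher(counts, c(focal = 134, sister = 130))
  expect_equal(res$p[1], fisher_exact_2x2(20, 114, 20, 110))
  expect_equal(res$p[2], fisher_exact_2x2(22, 112, 40, 90))
  # equal counts, equal totals -> p = 1
  eq <- levelA_fisher(data.frame(category = "X", count_focal = 5,
                                 count_sister = 5),
                      c(focal = 50, sister = 50))
  expect_equal(eq$p, 1)
  expect_error(levelA_fisher(data.frame(category = "X", count_focal = 60,
                                        count_sister = 5),
                             c(focal = 50, sister = 50)), "exceeds")
})

test_that("chi-squared statistic matches the textbook formula", {
  r <- levelB_chi2(matrix(c(10, 20, 20, 10), nrow = 2))
  expect_equal(r$statistic, 60 * (10 * 10 - 20 * 20)^2 /
                 (30 * 30 * 30 * 30), tolerance = 1e-9)
  expect_equal(r$df, 1)
  expect_equal(r$p, stats::pchisq(r$statistic, 1, lower.tail = FALSE))
  # identical distributions -> statistic 0, p 1
  r0 <- levelB_chi2(matrix(c(5, 10, 5, 10), nrow = 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # random tables vs independent Pearson computation
  set.seed(5)
  for (i in 1:10) {
    tab <- matrix(stats::rpois(8, 10) + 1, nrow = 4)
    r <- levelB_chi2(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(r$statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
    expect_equal(r$df, 3)
  }
  expect_warning(levelB_chi2(matrix(c(0, 5, 3, 0, 4, 2), nrow = 3)),
                 "zero-margin")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(10)
  for (i in 1:10) {
    p <- stats::runif(sample(3:30, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("enrichment scan finds planted overrepresentation and respects subsets", {
  genes <- sprintf("G%03d", 1:200)
  cand <- genes[1:20]
  # planted term: 10-fold enriched among candidates; null terms uniform
  set.seed(77)
  tabs <- list(data.frame(orthogroup_id = c(cand[1:15], genes[30:33]),
                          term_id = "PLANT"))
  for (t in 1:10) {
    tabs[[t + 1]] <- data.frame(orthogroup_id = sample(genes, 30),
                                term_id = sprintf("NULL%02d", t))
  }
  transcriptome <- do.call(rbind, tabs)
  res <- enrichment_vs_transcriptome(
    transcriptome[transcriptome$orthogroup_id %in% cand, ], transcriptome,
    candidate_genes = cand, transcriptome_genes = genes)
  expect_true(res$significant[res$term_id == "PLANT"])
  expect_equal(res$direction[res$term_id == "PLANT"], "over")
  expect_false(any(res$significant[res$term_id != "PLANT"]))
  expect_error(enrichment_vs_transcriptome(
    data.frame(orthogroup_id = "ZZZ", term_id = "T"), transcriptome),
    "subset")
})

test_that("proportional candidate annotation yields no enrichment", {
  genes <- sprintf("G%03d", 1:100)
  cand <- genes[1:25]
  tab <- data.frame(orthogroup_id = rep(genes, 2),
                    term_id = rep(c("T1", "T2"), each = 100))
  res <- enrichment_vs_transcriptome(tab[tab$orthogroup_id %in% cand, ], tab,
                                     candidate_genes = cand,
                                     transcriptome_genes = genes)
  expect_false(any(res$significant))
  expect_true(all(res$p == 1))
})

test_that("proportion comparison reproduces the closed-form Wald interval", {
  counts <- data.frame(category = c("A", "B"),
                       count_candidate = c(100, 10),
                       count_transcriptome = c(1000, 400))
  res <- proportion_comparison_vs_transcriptome(counts, 400, 4000)
  expect_equal(res$prop_candidate[1], 0.25)
  expect_equal(res$ci_lo_candidate[1], 0.2076, tolerance = 1e-3)
  expect_equal(res$ci_hi_candidate[1], 0.2924, tolerance = 1e-3)
  # equal proportions -> z = 0, not significant
  expect_equal(res$z[1], 0, tolerance = 1e-12)
  expect_false(res$significant[1])
  # category B: 2.5% vs 10% should be flagged lower
  expect_true(res$significant[2])
  expect_equal(res$direction[2], "lower")
})
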