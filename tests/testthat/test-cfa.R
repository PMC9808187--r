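test_that("configuration tables count children into the eight cells", {
  a <- data.frame(stunted = c(TRUE, TRUE, FALSE), wasted = c(TRUE, FALSE, FALSE),
                  underweight = c(TRUE, FALSE, FALSE))
  b <- data.frame(stunted = rep(FALSE, 3), wasted = FALSE, underweight = FALSE)
  tab <- build_config_table(a, b, c("g1", "g2"))
  expect_equal(tab$observed[, 1], c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 1L))
  expect_equal(tab$observed[, 2], c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 3L))
  expect_equal(sum(tab$observed), nrow(a) + nrow(b))
  expect_equal(unname(tab$group_totals), c(3L, 3L))
  expect_error(build_config_table(a[0, ], b), "empty group")
})

test_that("expected frequencies reproduce the published two-group values", {
  gdhs  <- c(40, 0, 188, 415, 74, 74, 18, 1332)
  gmics <- c(164, 0, 693, 1042, 179, 106, 116, 4232)
  gsps  <- c(103, 0, 135, 332, 148, 61, 14, 815)
  ea <- expected_frequencies(cfa_table_from_counts(gdhs, gmics))
  expect_equal(round(unname(ea[1, 1]), 1), 50.4)
  expect_equal(round(unname(ea[1, 2]), 1), 153.6)
  expect_equal(round(unname(ea[8, 1]), 1), 1373.5)
  expect_equal(round(unname(ea[6, 1]), 1), 44.4)
  eb <- expected_frequencies(cfa_table_from_counts(gsps, gdhs))
  expect_equal(round(unname(eb[1, 1]), 1), 61.3)
  expect_equal(round(unname(eb[1, 2]), 1), 81.7)
  ec <- expected_frequencies(cfa_table_from_counts(gsps, gmics))
  expect_equal(round(unname(ec[5, 1]), 1), 64.6)
  expect_equal(round(unname(ec[7, 1]), 1), 25.7)
  expect_equal(round(unname(ec[7, 2]), 1), 104.3)
})

test_that("expected frequencies conserve both margins exactly", {
  set.seed(51)
  for (i in 1:30) {
    tab <- cfa_table_from_counts(rpois(8, 40), rpois(8, 90))
    e <- expected_frequencies(tab)
    expect_equal(colSums(e), colSums(tab$observed))
    expect_equal(rowSums(e), rowSums(tab$observed))
  }
})

test_that("zero-row configurations test at p = 1", {
  tab <- cfa_table_from_counts(c(0, 0, 1, 2, 3, 4, 5, 6),
                               c(0, 0, 6, 5, 4, 3, 2, 1))
  expect_equal(config_test(tab, 1), 1)
  expect_equal(config_test(tab, c(TRUE, TRUE, FALSE)), 1)
})

test_that("the exact test matches full hypergeometric enumeration", {
  # frozen case: 2x2 (3,0 / 0,3) -> two of twenty equally-margined tables
  # are as extreme, p = 0.1 exactly
  tab <- cfa_table_from_counts(c(3, 0, 0, 0, 0, 0, 0, 0),
                               c(0, 0, 0, 0, 0, 0, 0, 3))
  expect_equal(config_test(tab, 1), 0.1, tolerance = 1e-12)
  expect_equal(fisher_enum_p(3, 0, 0, 3), 0.1, tolerance = 1e-12)
  # enumeration oracle over all small 2x2 tables
  tables <- all_2x2_tables(16)
  for (i in seq_len(nrow(tables))) {
    tb <- tables[i, ]
    if (tb[1] + tb[2] == 0) next
    ct <- cfa_table_from_counts(c(tb[1], 0, 0, 0, 0, 0, 0, tb[3]),
                                c(tb[2], 0, 0, 0, 0, 0, 0, tb[4]))
    expect_equal(config_test(ct, 1), fisher_enum_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-9)
  }
  # seeded larger tables up to grand total 60
  set.seed(52)
  for (i in 1:200) {
    tb <- as.vector(stats::rmultinom(1, sample(20:60, 1), runif(4, 0.05, 1)))
    ct <- cfa_table_from_counts(c(tb[1], 0, 0, 0, 0, 0, 0, tb[3]),
                                c(tb[2], 0, 0, 0, 0, 0, 0, tb[4]))
    expect_equal(config_test(ct, 1), fisher_enum_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-9)
  }
})

test_that("p-values are symmetric under group relabelling", {
  set.seed(53)
  for (i in 1:10) {
    a <- rpois(8, 30); b <- rpois(8, 70)
    ta <- cfa_table_from_counts(a, b)
    tb <- cfa_table_from_counts(b, a)
    pa <- vapply(1:8, function(j) config_test(ta, j), numeric(1))
    pb <- vapply(1:8, function(j) config_test(tb, j), numeric(1))
    expect_equal(pa, pb)
    expect_equal(expected_frequencies(ta), expected_frequencies(tb)[, 2:1],
                 ignore_attr = TRUE)
  }
})

test_that("discrimination typing thresholds adjusted p-values", {
  p <- c(.015, 1, .002, .000, .014, .000, .001, .002)
  expect_equal(which(discriminate_pvalues(p, 0.05, "bonferroni")),
               c(3L, 4L, 6L, 7L, 8L))
  expect_equal(which(discriminate_pvalues(p, 0.05, "none")),
               c(1L, 3L, 4L, 5L, 6L, 7L, 8L))
  expect_false(any(discriminate_pvalues(rep(1, 8), 0.05, "bonferroni")))
  expect_error(discriminate_pvalues(p, 0), "alpha")
})

test_that("the discrimination set grows with alpha", {
  set.seed(54)
  tab <- cfa_table_from_counts(rpois(8, 25), rpois(8, 60))
  for (adj in c("bonferroni", "holm", "none")) {
    small <- discrimination_types(tab, alpha = 0.01, adjustment = adj)
    large <- discrimination_types(tab, alpha = 0.10, adjustment = adj)
    expect_true(all(large$discrimination[small$discrimination]))
  }
})

test_that("discrimination results carry conserved expected counts", {
  tab <- cfa_table_from_counts(c(40, 0, 188, 415, 74, 74, 18, 1332),
                               c(164, 0, 693, 1042, 179, 106, 116, 4232),
                               labels = c("GDHS", "GMICS"))
  res <- discrimination_types(tab)
  expect_equal(sum(res$exp_a), sum(res$obs_a))
  expect_equal(sum(res$exp_b), sum(res$obs_b))
  expect_equal(res$exp_a + res$exp_b, res$obs_a + res$obs_b)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})
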