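test_that("weighted quantiles agree with the interpolated order-statistic oracle", {
  expect_equal(weighted_quantile(1:100, 0.5), 50.5)
  set.seed(61)
  for (i in 1:10) {
    n <- sample(40:1000, 1)
    x <- rnorm(n)
    taus <- default_tau_grid()
    expect_equal(weighted_quantile(x, taus),
                 unname(quantile(x, taus, type = 5)), tolerance = 1e-12)
  }
  # up-weighting a point pulls the quantile toward it, and the curve stays
  # monotone in tau
  expect_lt(weighted_quantile(c(1, 2, 3), 0.5, w = c(10, 1, 1)),
            weighted_quantile(c(1, 2, 3), 0.5))
  expect_true(all(diff(weighted_quantile(rnorm(200), default_tau_grid())) >= 0))
  expect_error(weighted_quantile(1:5, 0), "strictly inside")
})

test_that("weighted quantiles approximately minimize the pinball loss", {
  # cross-check against quantile regression on the same data: the two can
  # differ only within one order-statistic gap
  set.seed(62)
  x <- rnorm(400)
  for (tau in c(0.1, 0.25, 0.5, 0.9)) {
    rq_fit <- unname(coef(suppressWarnings(quantreg::rq(x ~ 1, tau = tau))))
    gap <- max(diff(sort(x)))
    expect_lt(abs(weighted_quantile(x, tau) - rq_fit), gap + 1e-9)
  }
})

test_that("profiles are monotone, symmetric and translation-equivariant", {
  set.seed(63)
  n <- 400
  x <- rnorm(n)
  psu <- sample(1:20, n, replace = TRUE)
  two <- fit_quantile_profile(c(x, x), rep(c("a", "b"), each = n),
                              psu = c(psu, psu), n_boot = 59)
  a <- two[two$group == "a", ]; b <- two[two$group == "b", ]
  expect_equal(a$estimate, b$estimate)
  expect_true(all(diff(a$estimate) >= 0))
  # shifted group: profile shifts by exactly delta at every tau
  delta <- 1.37
  sh <- fit_quantile_profile(c(x, x + delta), rep(c("a", "b"), each = n),
                             psu = c(psu, psu), n_boot = 19)
  expect_equal(sh$estimate[sh$group == "b"],
               sh$estimate[sh$group == "a"] + delta, tolerance = 1e-12)
  # positive affine maps act on the whole profile
  aff <- fit_quantile_profile(2.5 * x - 1, rep("a", n), psu = psu, n_boot = 19)
  base <- fit_quantile_profile(x, rep("a", n), psu = psu, n_boot = 19)
  expect_equal(aff$estimate, 2.5 * base$estimate - 1, tolerance = 1e-12)
})

test_that("bootstrap bands are reproducible under a fixed seed", {
  set.seed(64)
  x <- rnorm(300)
  g <- rep("s", 300)
  psu <- sample(1:15, 300, replace = TRUE)
  p1 <- fit_quantile_profile(x, g, psu, n_boot = 99, seed = 7)
  p2 <- fit_quantile_profile(x, g, psu, n_boot = 99, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1$ci_low <= p1$estimate + 1e-9))
  expect_true(all(p1$ci_high >= p1$estimate - 1e-9))
})

test_that("too-few observations raise a named error", {
  expect_error(fit_quantile_profile(rnorm(10), rep("tiny", 10), psu = 1:10),
               "tiny")
})

test_that("band separation flags disjoint bands only", {
  taus <- c(0.25, 0.5, 0.75)
  mk <- function(est, half) data.frame(group = "g", tau = taus, estimate = est,
                                       ci_low = est - half, ci_high = est + half)
  same <- band_differences(mk(c(0, 1, 2), 0.2), mk(c(0, 1, 2), 0.2))
  expect_false(any(same$significant))
  apart <- band_differences(mk(c(0, 1, 2), 0.2), mk(c(10, 11, 12), 0.2))
  expect_true(all(apart$significant))
  expect_error(band_differences(mk(c(0, 1, 2), 0.2)[1:2, ], mk(c(0, 1, 2), 0.2)),
               "grids")
})

test_that("unequal spread shows up in the tails, not the center", {
  set.seed(65)
  n <- 2000
  psu <- rep(1:50, each = n / 50)
  a <- rnorm(n, 0, 1)
  b <- rnorm(n, 0, 2)  # equal medians, heavier tails
  prof <- fit_quantile_profile(c(a, b), rep(c("a", "b"), each = n),
                               psu = c(psu, psu), n_boot = 199, seed = 3)
  sig <- band_differences(prof[prof$group == "a", ], prof[prof$group == "b", ])
  expect_true(sig$significant[sig$tau == 0.05])
  expect_true(sig$significant[sig$tau == 0.95])
  expect_false(sig$significant[sig$tau == 0.5])
})

test_that("age grouping splits at 24 completed months", {
  expect_equal(as.character(age_group(c(6, 23, 24, 59))),
               c("6-23", "6-23", "24-59", "24-59"))
  expect_true(is.na(age_group(4)))
})

test_that("the profile report covers indicators x strata x groups", {
  cfg <- sim_config(regions = default_sim_regions(n_psu = 8, psu_pool_size = 24),
                    children_per_household = 1.2, seed = 66L)
  sv <- generate_survey(cfg, test_ref)
  z <- compute_zscores(sv$records, test_ref)
  z$survey <- "s1"
  rep1 <- profile_report(z, indicators = c("haz", "whz"), n_boot = 9,
                         taus = c(0.25, 0.5, 0.75))
  # 2 indicators x (2 sex + 2 age group strata) x 1 group x 3 taus
  expect_equal(nrow(rep1), 2 * 4 * 1 * 3)
  expect_setequal(unique(rep1$stratifier), c("sex", "age_group"))
})
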