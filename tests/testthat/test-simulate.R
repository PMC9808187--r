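small_cfg <- function(...) {
  sim_config(regions = default_sim_regions(n_psu = 10, psu_pool_size = 30), ...)
}

test_that("generation is a deterministic function of config and seed", {
  cfg <- small_cfg(seed = 71L)
  a <- generate_survey(cfg, test_ref)
  b <- generate_survey(cfg, test_ref)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c <- generate_survey(cfg, test_ref, seed = 72L)
  expect_false(identical(a$records, c$records))
})

test_that("latent z-scores roundtrip through measurements", {
  cfg <- small_cfg(seed = 73L)
  sv <- generate_survey(cfg, test_ref)
  z <- compute_zscores(sv$records, test_ref, restricted = FALSE)
  expect_lt(max(abs(z$haz - sv$records$latent_haz)), 1e-6)
  expect_lt(max(abs(z$whz - sv$records$latent_whz)), 1e-6)
})

test_that("a null configuration produces standard-normal HAZ", {
  regs <- default_sim_regions(n_psu = 15, psu_pool_size = 45)
  regs$mean_shift_haz <- 0
  regs$mean_shift_whz <- 0
  cfg <- sim_config(regions = regs, icc = 0, sd_haz = 1, sd_whz = 1,
                    children_per_household = 1, seed = 74L)
  sv <- generate_survey(cfg, test_ref)
  z <- compute_zscores(sv$records, test_ref, restricted = FALSE)
  expect_gt(nrow(z), 1500)
  expect_gt(stats::ks.test(z$haz, "pnorm")$p.value, 0.01)
})

test_that("configured shifts hit their normal-tail prevalence targets", {
  regs <- default_sim_regions(n_psu = 25, psu_pool_size = 75)
  regs$mean_shift_haz <- -2.05
  cfg <- sim_config(regions = regs, icc = 0, sd_haz = 1,
                    children_per_household = 1.4, seed = 75L)
  sv <- generate_survey(cfg, test_ref)
  n <- nrow(sv$records)
  expect_gt(n, 4000)
  target <- pnorm(-2 - (-2.05))  # ~0.52
  mc_se <- sqrt(target * (1 - target) / n)
  # cluster effects are off, so 4 crude MC SEs is a generous band
  expect_lt(abs(sv$truth$national[["stunting"]] - target), 4 * mc_se)
})

test_that("sampling weights are Horvitz-Thompson consistent for region totals", {
  cfg <- small_cfg(children_per_household = 1, seed = 76L)
  reg1 <- cfg$regions$label[1]
  expected_total <- cfg$regions$psu_pool_size[1] * cfg$household_pool_size *
    cfg$children_per_household
  set.seed(760)
  seeds <- sample.int(1e6, 25)
  tot <- vapply(seeds, function(s) {
    sv <- generate_survey(cfg, test_ref, seed = s)
    sum(sv$records$sampling_weight[sv$records$region == reg1])
  }, numeric(1))
  expect_lt(abs(mean(tot) - expected_total),
            3 * sd(tot) / sqrt(length(tot)))
})

test_that("weighted prevalence recovers the generator's truth per region", {
  cfg <- small_cfg(children_per_household = 1, seed = 77L)
  sv <- generate_survey(cfg, test_ref)
  z <- compute_zscores(sv$records, test_ref)
  cl <- classify_records(z)
  design <- survey_design_spec()
  est <- regional_prevalence(cl, design, index = "eciaf")
  truth <- sv$truth$by_region
  m <- merge(est, truth, by.x = "domain", by.y = "region")
  mc_se <- sqrt(m$eciaf_burden * (1 - m$eciaf_burden) / m$n.y)
  expect_true(all(abs(m$estimate - m$eciaf_burden) <= pmax(3 * mc_se, 1e-9)))
})

test_that("the three-survey scenario has the designed contrasts", {
  sims <- generate_three_survey_scenario(scale = 0.35, seed = 20111,
                                         ref = test_ref)
  expect_named(sims, c("gmics_like", "gdhs_like", "gsps_like"))
  # heavier panel-survey tails: more wasting despite similar medians
  expect_gt(sims$gsps_like$truth$national[["wasting"]],
            sims$gmics_like$truth$national[["wasting"]])
  expect_gt(sims$gsps_like$truth$national[["overweight"]],
            sims$gmics_like$truth$national[["overweight"]])
  # pipeline smoke: exclusions stay rare
  for (s in sims) {
    z <- compute_zscores(s$records, test_ref)
    ex <- apply_exclusions(z)
    expect_lt(sum(ex$tally) / nrow(z), 0.05)
  }
  # CFA finds at least one discrimination type between panel and MICS styles
  cl <- lapply(sims[c("gsps_like", "gmics_like")], function(s)
    classify_records(apply_exclusions(compute_zscores(s$records, test_ref))$included))
  tab <- build_config_table(cl[[1]], cl[[2]], labels = c("gsps", "gmics"))
  res <- discrimination_types(tab)
  expect_gte(sum(res$discrimination), 1)
})

test_that("scenario scale controls the sample size, not the strata", {
  big <- generate_three_survey_scenario(scale = 0.5, seed = 5, ref = test_ref)
  small <- generate_three_survey_scenario(scale = 0.05, seed = 5, ref = test_ref)
  ratio <- nrow(big$gmics_like$records) / nrow(small$gmics_like$records)
  expect_gt(ratio, 5); expect_lt(ratio, 20)
  expect_setequal(unique(small$gmics_like$records$region),
                  unique(big$gmics_like$records$region))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(icc = 1), "icc")
  expect_error(sim_config(corr_haz_whz = 1.2), "corr")
  expect_error(sim_config(sd_haz = 0), "positive")
  regs <- default_sim_regions(n_psu = 10, psu_pool_size = 5)
  expect_error(sim_config(regions = regs), "psu_pool_size")
})
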