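#' Configuration for the two-stage cluster survey simulator
#'
#' Defines a stratified two-stage design: regions are strata, clusters (PSUs)
#' are sampled without replacement from a per-region pool, a fixed number of
#' households is sampled from each cluster's household pool, and every child
#' in a sampled household is measured. Child-level anthropometry is driven by
#' a latent bivariate (HAZ, WHZ) normal: region mean shift + cluster random
#' effect (variance `icc * sd^2`, independent across indicators) + child
#' effect (variance `(1 - icc) * sd^2`, correlation `corr_haz_whz`). Heights
#' and weights are produced by inverting the LMS reference, so weight-for-age
#' and BMI-for-age emerge from the generated measurements rather than being
#' simulated separately.
#'
#' @param label Survey label stamped on every record.
#' @param regions Data frame with columns `label`, `mean_shift_haz`,
#'   `mean_shift_whz` (SD units), `n_psu`, `psu_pool_size`. Defaults to the
#'   ten Ghanaian regions with a realistic stunting gradient.
#' @param households_per_psu Households sampled per cluster.
#' @param household_pool_size Households available per cluster (sets the
#'   second-stage inclusion probability).
#' @param children_per_household Mean of the Poisson number of eligible
#'   children per sampled household.
#' @param icc Intra-cluster correlation of the latent scores, in `[0, 1)`.
#' @param corr_haz_whz Child-level correlation between latent HAZ and WHZ.
#' @param sd_haz,sd_whz Total latent standard deviations (SD units).
#' @param age_range_months Inclusive range of completed months.
#' @param sex_ratio Proportion male.
#' @param seed Default RNG seed used by [generate_survey()].
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(label = "synthetic",
                       regions = default_sim_regions(),
                       households_per_psu = 15,
                       household_pool_size = 30,
                       children_per_household = 0.8,
                       icc = 0.1,
                       corr_haz_whz = 0.2,
                       sd_haz = 1.1,
                       sd_whz = 1.1,
                       age_range_months = c(6, 59),
                       sex_ratio = 0.512,
                       seed = 1L) {
  cfg <- list(label = label, regions = regions,
              households_per_psu = households_per_psu,
              household_pool_size = household_pool_size,
              children_per_household = children_per_household,
              icc = icc, corr_haz_whz = corr_haz_whz,
              sd_haz = sd_haz, sd_whz = sd_whz,
              age_range_months = age_range_months, sex_ratio = sex_ratio,
              seed = seed)
  need <- c("label", "mean_shift_haz", "mean_shift_whz", "n_psu", "psu_pool_size")
  miss <- setdiff(need, names(regions))
  if (length(miss)) stop("regions missing columns: ", paste(miss, collapse = ", "))
  if (any(regions$n_psu > regions$psu_pool_size)) {
    stop("n_psu may not exceed psu_pool_size in any region")
  }
  if (!(icc >= 0 && icc < 1)) stop("icc must be in [0, 1)")
  if (!(abs(corr_haz_whz) < 1)) stop("corr_haz_whz must be in (-1, 1)")
  if (sd_haz <= 0 || sd_whz <= 0) stop("latent standard deviations must be positive")
  if (households_per_psu > household_pool_size) {
    stop("households_per_psu may not exceed household_pool_size")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default region strata for the simulator
#'
#' Ten regions with latent HAZ shifts spanning roughly -0.9 to -1.7 SD
#' (urban south to rural north gradient) and milder WHZ shifts, so realized
#' regional burdens span a wide range.
#' @param n_psu Clusters sampled per region.
#' @param psu_pool_size Clusters available per region.
#' @return Data frame usable as the `regions` field of [sim_config()].
#' @export
default_sim_regions <- function(n_psu = 20, psu_pool_size = 60) {
  data.frame(
    label = c("Western", "Central", "Greater Accra", "Volta", "Eastern",
              "Ashanti", "Brong Ahafo", "Northern", "Upper East", "Upper West"),
    mean_shift_haz = c(-1.30, -1.45, -0.90, -1.35, -1.25,
                       -1.15, -1.20, -1.70, -1.55, -1.65),
    mean_shift_whz = c(-0.30, -0.35, -0.20, -0.30, -0.30,
                       -0.25, -0.30, -0.50, -0.45, -0.45),
    n_psu = n_psu,
    psu_pool_size = psu_pool_size
  )
}

# Latent scores -> physical measurements via the inverse LMS transform.
.latent_to_measurements <- function(haz, whz, age, sex, ref) {
  ph <- lms_params(ref, "height_for_age", sex, age)
  height <- lms_inverse(haz, ph$L, ph$M, ph$S)
  pw <- lms_params(ref, "weight_for_height", sex, height)
  weight <- lms_inverse(whz, pw$L, pw$M, pw$S)
  list(height_cm = height, weight_kg = weight)
}

# Latent-scale classification used for ground truth (WAZ derived from the
# generated weight; the restricted adjustment never moves a score across the
# +/-2 thresholds, so raw scores suffice).
.latent_truth_class <- function(haz, whz, age, sex, weight, ref) {
  pa <- lms_params(ref, "weight_for_age", sex, age)
  waz <- lms_zscore(weight, pa$L, pa$M, pa$S)
  data.frame(stunted = haz < -2, wasted = whz < -2,
             underweight = waz < -2, overweight = whz > 2)
}

#' Generate one synthetic two-stage cluster survey
#'
#' Draws a survey under a [sim_config()] and returns raw child records
#' (identifiers, design variables, sex, age, height, weight, sampling
#' weight) together with the realized ground truth: latent stunting,
#' wasting, underweight, overweight, CIAF and eCIAF burden rates per region
#' and nationally. Sampling weights are the inverse inclusion probabilities
#' `(psu_pool_size / n_psu) * (household_pool_size / households_per_psu)`.
#' Output is a deterministic function of the configuration and seed.
#'
#' @param config A [sim_config()].
#' @param ref LMS reference table (default the packaged synthetic one).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return List with `records` (data frame) and `truth` (list with
#'   `by_region`, `national`, `label`).
#' @export
generate_survey <- function(config, ref = default_lms_reference(),
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  regs <- config$regions
  icc <- config$icc; rho <- config$corr_haz_whz
  ages_all <- seq(config$age_range_months[1], config$age_range_months[2])

  rows <- vector("list", nrow(regs))
  for (r in seq_len(nrow(regs))) {
    reg <- regs[r, ]
    psu_ids <- sort(sample.int(reg$psu_pool_size, reg$n_psu))
    w <- (reg$psu_pool_size / reg$n_psu) *
      (config$household_pool_size / config$households_per_psu)
    psu_rows <- vector("list", reg$n_psu)
    for (j in seq_len(reg$n_psu)) {
      hh_ids <- sort(sample.int(config$household_pool_size,
                                config$households_per_psu))
      kids <- stats::rpois(config$households_per_psu, config$children_per_household)
      n <- sum(kids)
      b_h <- stats::rnorm(1, 0, sqrt(icc) * config$sd_haz)
      b_w <- stats::rnorm(1, 0, sqrt(icc) * config$sd_whz)
      if (n == 0) next
      e_h <- stats::rnorm(n)
      e_w <- rho * e_h + sqrt(1 - rho^2) * stats::rnorm(n)
      haz <- reg$mean_shift_haz + b_h + sqrt(1 - icc) * config$sd_haz * e_h
      whz <- reg$mean_shift_whz + b_w + sqrt(1 - icc) * config$sd_whz * e_w
      age <- sample(ages_all, n, replace = TRUE)
      sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
      psu_rows[[j]] <- data.frame(
        survey = config$label, region = reg$label, psu = psu_ids[j],
        household = rep(hh_ids, kids), sex = sex, age_months = age,
        latent_haz = haz, latent_whz = whz, sampling_weight = w
      )
    }
    rows[[r]] <- do.call(rbind, psu_rows)
  }
  rec <- do.call(rbind, rows)
  if (is.null(rec) || !nrow(rec)) stop("configuration produced no children")
  rownames(rec) <- NULL
  meas <- .latent_to_measurements(rec$latent_haz, rec$latent_whz,
                                  rec$age_months, rec$sex, ref)
  rec$height_cm <- meas$height_cm
  rec$weight_kg <- meas$weight_kg
  rec$child_id <- sprintf("%s-%05d", config$label, seq_len(nrow(rec)))

  cls <- .latent_truth_class(rec$latent_haz, rec$latent_whz, rec$age_months,
                             rec$sex, rec$weight_kg, ref)
  fail_under <- cls$stunted | cls$wasted | cls$underweight
  fail_any <- fail_under | cls$overweight
  agg <- function(idx) c(
    stunting = mean(cls$stunted[idx]), wasting = mean(cls$wasted[idx]),
    underweight = mean(cls$underweight[idx]),
    overweight = mean(cls$overweight[idx]),
    ciaf_burden = mean(fail_under[idx]), eciaf_burden = mean(fail_any[idx]),
    n = sum(idx))
  by_region <- t(vapply(regs$label, function(l) agg(rec$region == l),
                        numeric(7)))
  truth <- list(label = config$label,
                by_region = data.frame(region = regs$label, by_region,
                                       row.names = NULL),
                national = agg(rep(TRUE, nrow(rec))))

  keep <- c("child_id", "survey", "region", "psu", "household", "sex",
            "age_months", "weight_kg", "height_cm", "sampling_weight",
            "latent_haz", "latent_whz")
  list(records = rec[, keep], truth = truth)
}

#' Superpopulation burden under a simulator configuration
#'
#' Monte-Carlo estimate of the model-implied (superpopulation) prevalence
#' rates: children are drawn from the latent model with regions mixed in
#' proportion to their population size (PSU pool x household pool x mean
#' children, i.e. proportional to `psu_pool_size` when the per-cluster
#' parameters are shared). Clustering does not change the marginal latent
#' law, so cluster effects are folded into the total variance.
#'
#' @param config A [sim_config()].
#' @param ref LMS reference table.
#' @param n Number of Monte-Carlo children (default 100000).
#' @param seed RNG seed.
#' @return Named vector: stunting, wasting, underweight, overweight,
#'   ciaf_burden, eciaf_burden.
#' @export
superpopulation_burden <- function(config, ref = default_lms_reference(),
                                   n = 100000, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  regs <- config$regions
  share <- regs$psu_pool_size / sum(regs$psu_pool_size)
  ridx <- sample.int(nrow(regs), n, replace = TRUE, prob = share)
  icc <- config$icc; rho <- config$corr_haz_whz
  b_h <- stats::rnorm(n, 0, sqrt(icc) * config$sd_haz)
  b_w <- stats::rnorm(n, 0, sqrt(icc) * config$sd_whz)
  e_h <- stats::rnorm(n)
  e_w <- rho * e_h + sqrt(1 - rho^2) * stats::rnorm(n)
  haz <- regs$mean_shift_haz[ridx] + b_h + sqrt(1 - icc) * config$sd_haz * e_h
  whz <- regs$mean_shift_whz[ridx] + b_w + sqrt(1 - icc) * config$sd_whz * e_w
  age <- sample(seq(config$age_range_months[1], config$age_range_months[2]),
                n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
  meas <- .latent_to_measurements(haz, whz, age, sex, ref)
  cls <- .latent_truth_class(haz, whz, age, sex, meas$weight_kg, ref)
  fail_under <- cls$stunted | cls$wasted | cls$underweight
  c(stunting = mean(cls$stunted), wasting = mean(cls$wasted),
    underweight = mean(cls$underweight), overweight = mean(cls$overweight),
    ciaf_burden = mean(fail_under),
    eciaf_burden = mean(fail_under | cls$overweight))
}

#' Packaged three-survey comparison scenario
#'
#' Generates three surveys mimicking the qualitative contrast between a
#' large MICS-style survey, a mid-sized DHS-style survey, and a smaller
#' panel-style survey with much heavier two-sided weight-for-height tails
#' (similar medians, but more wasting AND more overweight) -- the pattern
#' that makes composite-failure comparisons interesting. Downstream, the CFA
#' between the panel-style and MICS-style sets finds discrimination types at
#' the default level.
#'
#' @param scale Positive size multiplier on clusters per region (1 gives
#'   roughly 3300 / 1500 / 1200 children).
#' @param seed RNG seed (one stream; the three surveys draw from it in
#'   order).
#' @param ref LMS reference table.
#' @return Named list of three `generate_survey()` results
#'   (`gmics_like`, `gdhs_like`, `gsps_like`).
#' @export
generate_three_survey_scenario <- function(scale = 1, seed = 20111,
                                           ref = default_lms_reference()) {
  stopifnot(scale > 0)
  npsu <- function(base) max(2L, as.integer(round(base * scale)))
  mk_regions <- function(n) {
    r <- default_sim_regions(n_psu = n, psu_pool_size = max(3L * n, n + 1L))
    r
  }
  cfgs <- list(
    gmics_like = sim_config(
      label = "GMICS-like", regions = mk_regions(npsu(40)),
      children_per_household = 0.55, icc = 0.08, corr_haz_whz = 0.2,
      sd_haz = 1.05, sd_whz = 1.10, seed = seed),
    gdhs_like = sim_config(
      label = "GDHS-like", regions = mk_regions(npsu(18)),
      children_per_household = 0.55, icc = 0.08, corr_haz_whz = 0.2,
      sd_haz = 1.15, sd_whz = 1.35, seed = seed + 1L),
    gsps_like = sim_config(
      label = "GSPS-like", regions = mk_regions(npsu(14)),
      children_per_household = 0.55, icc = 0.08, corr_haz_whz = 0.2,
      sd_haz = 1.70, sd_whz = 2.20, seed = seed + 2L)
  )
  # the panel-style survey has slightly higher medians but heavier tails
  cfgs$gsps_like$regions$mean_shift_whz <- cfgs$gsps_like$regions$mean_shift_whz + 0.4
  cfgs$gsps_like$regions$mean_shift_haz <- cfgs$gsps_like$regions$mean_shift_haz + 0.1
  lapply(cfgs, generate_survey, ref = ref)
}
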