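#' Relative change between two prevalence estimates
#'
#' `(followup - baseline) / baseline * 100`, in percent; negative values are
#' decreases. [render_change()] gives the conventional rounded phrasing.
#'
#' @param baseline,followup Prevalences in percent; `baseline > 0`.
#' @return Signed percent change (full precision).
#' @export
relative_change <- function(baseline, followup) {
  if (any(baseline <= 0)) stop("baseline prevalence must be positive")
  (followup - baseline) / baseline * 100
}

#' Render a relative change as "Decrease/Increase of N%"
#'
#' Rounds half-up to the nearest integer percent at render time only.
#'
#' @param change Signed percent change from [relative_change()].
#' @return Character vector.
#' @export
render_change <- function(change) {
  n <- floor(abs(change) + 0.5)
  ifelse(change < 0, paste0("Decrease of ", n, "%"),
         ifelse(change > 0, paste0("Increase of ", n, "%"),
                "No change (0%)"))
}

#' Assess progress against the 2025 global nutrition targets
#'
#' Applies the target rules to baseline/follow-up prevalence pairs:
#' stunting -- at least a 40% relative reduction; wasting -- follow-up
#' prevalence below 5%; overweight -- follow-up prevalence below 6%.
#' Because a reduction rounding to 40% may sit just above the strict -40
#' cutoff, both the raw verdict (`met`) and the verdict on the rounded
#' change (`met_rounded`, stunting only) are reported.
#'
#' @param assessments Data frame with columns `indicator` (one of
#'   `"stunting"`, `"wasting"`, `"overweight"`), `baseline`, `followup`
#'   (percent), and optionally `source`.
#' @return Data frame adding `relative_change`, `rendered`, `target_rule`,
#'   `met`, `met_rounded`.
#' @export
assess_targets <- function(assessments) {
  stopifnot(all(c("indicator", "baseline", "followup") %in% names(assessments)))
  ind <- as.character(assessments$indicator)
  bad <- setdiff(ind, c("stunting", "wasting", "overweight"))
  if (length(bad)) stop("unknown indicator(s): ", paste(unique(bad), collapse = ", "))
  rc <- relative_change(assessments$baseline, assessments$followup)
  rule <- c(stunting = "reduction_40pct", wasting = "prevalence_lt_5",
            overweight = "prevalence_lt_6")[ind]
  met <- ifelse(ind == "stunting", rc <= -40,
                ifelse(ind == "wasting", assessments$followup < 5,
                       assessments$followup < 6))
  met_rounded <- ifelse(ind == "stunting", floor(abs(rc) + 0.5) >= 40 & rc < 0, met)
  cbind(assessments,
        data.frame(relative_change = rc, rendered = render_change(rc),
                   target_rule = unname(rule), met = met,
                   met_rounded = met_rounded))
}

#' Descriptive comparison table across surveys
#'
#' Summarizes each survey -- counts and percentages for sex, age group and
#' the four conventional indicators; medians and interquartile ranges for
#' age, height, weight and the four z-scores -- with between-survey
#' homogeneity p-values (chi-square for categorical variables,
#' Kruskal-Wallis for continuous ones; one-way ANOVA behind
#' `continuous_test = "anova"`). With a single survey no p-values are
#' computed.
#'
#' @param records Classified record data frame (one `survey` column).
#' @param continuous_test `"kruskal"` (default) or `"anova"`.
#' @return Long data frame: `variable`, `level`, one `n (pct)` or
#'   `median (IQR)` column per survey, `p_value`.
#' @export
descriptive_table <- function(records, continuous_test = c("kruskal", "anova")) {
  continuous_test <- match.arg(continuous_test)
  if (!"survey" %in% names(records)) stop("records need a 'survey' column")
  if (!"age_group" %in% names(records)) {
    records$age_group <- age_group(records$age_months)
  }
  surveys <- unique(as.character(records$survey))
  multi <- length(surveys) > 1
  fmt_pct <- function(n, N) sprintf("%d (%.1f)", n, 100 * n / N)
  fmt_med <- function(x) sprintf("%.1f (%.1f)", stats::median(x, na.rm = TRUE),
                                 stats::IQR(x, na.rm = TRUE))
  rows <- list()
  add <- function(df) rows[[length(rows) + 1]] <<- df

  cat_vars <- list(sex = records$sex, age_group = records$age_group,
                   stunting = records$stunted, wasting = records$wasted,
                   underweight = records$underweight,
                   overweight = records$overweight)
  for (vn in names(cat_vars)) {
    v <- cat_vars[[vn]]
    if (is.null(v)) next
    if (is.logical(v)) v <- factor(ifelse(v, "Yes", "No"), levels = c("Yes", "No"))
    tab <- table(v, records$survey)[, surveys, drop = FALSE]
    p <- if (multi) tryCatch(stats::chisq.test(tab)$p.value, error = function(e) NA_real_)
         else NA_real_
    cells <- vapply(surveys, function(s)
      fmt_pct(as.integer(tab[, s]), sum(tab[, s]))[seq_len(nrow(tab))],
      character(nrow(tab)))
    cells <- matrix(cells, nrow = nrow(tab))
    df <- data.frame(variable = vn, level = rownames(tab),
                     stringsAsFactors = FALSE)
    for (i in seq_along(surveys)) df[[surveys[i]]] <- cells[, i]
    df$p_value <- c(p, rep(NA_real_, nrow(tab) - 1))
    add(df)
  }

  cont_vars <- c(age = "age_months", height = "height_cm", weight = "weight_kg",
                 bmiz = "bmiz", whz = "whz", haz = "haz", waz = "waz")
  for (vn in names(cont_vars)) {
    col <- cont_vars[[vn]]
    if (!col %in% names(records)) next
    x <- records[[col]]
    p <- if (multi) {
      if (continuous_test == "kruskal") {
        stats::kruskal.test(x, factor(records$survey))$p.value
      } else {
        stats::anova(stats::lm(x ~ factor(records$survey)))[["Pr(>F)"]][1]
      }
    } else NA_real_
    df <- data.frame(variable = vn, level = "median (IQR)",
                     stringsAsFactors = FALSE)
    for (s in surveys) df[[s]] <- fmt_med(x[records$survey == s])
    df$p_value <- p
    add(df)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!multi) out$p_value <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' simulate -> z-score -> classify -> prevalence -> CFA -> quantile profiles
#' -> target report, writing CSV/JSON artifacts plus a manifest of produced
#' files with row counts. Deterministic given the seed.
#'
#' @param config Either a list / YAML path with fields `seed`, `scale`,
#'   `output_dir`, `alpha`, `n_boot`, or `NULL` for the packaged demo
#'   scenario.
#' @param output_dir Where artifacts are written (created if needed);
#'   overrides `config$output_dir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory artifacts and the manifest.
#' @export
run_pipeline <- function(config = NULL, output_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 20111L
  scale <- if (!is.null(config$scale)) config$scale else 0.5
  alpha <- if (!is.null(config$alpha)) config$alpha else 0.05
  n_boot <- if (!is.null(config$n_boot)) as.integer(config$n_boot) else 199L
  out_dir <- if (!is.null(output_dir)) output_dir
             else if (!is.null(config$output_dir)) config$output_dir
             else stop("run_pipeline needs an output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  ref <- default_lms_reference()

  stage <- "simulate"
  arts <- tryCatch({
    say("simulating three-survey scenario (scale = ", scale, ")")
    sims <- generate_three_survey_scenario(scale = scale, seed = seed, ref = ref)

    stage <- "zscore"
    recs <- lapply(sims, function(s)
      compute_zscores(s$records, ref, restricted = TRUE, flag = TRUE))

    stage <- "classify"
    cls <- lapply(recs, function(r) classify_records(apply_exclusions(r)$included))
    all_rec <- do.call(rbind, c(cls, make.row.names = FALSE))

    stage <- "prevalence"
    design <- survey_design_spec()
    prev <- do.call(rbind, lapply(names(cls), function(nm)
      cbind(survey = cls[[nm]]$survey[1],
            subtype_prevalence_table(cls[[nm]], design, index = "eciaf"))))
    regional <- do.call(rbind, lapply(names(cls), function(nm)
      cbind(survey = cls[[nm]]$survey[1],
            regional_prevalence(cls[[nm]], design, index = "eciaf"))))

    stage <- "cfa"
    pairs <- utils::combn(names(cls), 2, simplify = FALSE)
    cfa <- do.call(rbind, lapply(pairs, function(pr) {
      labels <- c(cls[[pr[1]]]$survey[1], cls[[pr[2]]]$survey[1])
      tab <- build_config_table(cls[[pr[1]]], cls[[pr[2]]], labels = labels)
      cbind(comparison = paste(labels, collapse = " vs "),
            discrimination_types(tab, alpha = alpha))
    }))

    stage <- "quantiles"
    profiles <- profile_report(all_rec, n_boot = n_boot, seed = seed)

    stage <- "report"
    desc <- descriptive_table(all_rec)
    list(records = all_rec, prevalence = prev, regional = regional,
         cfa = cfa, profiles = profiles, descriptive = desc,
         exclusions = lapply(recs, function(r) apply_exclusions(r)$tally))
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  files <- list(
    records = "records_classified.csv", prevalence = "prevalence.csv",
    regional = "prevalence_regional.csv", cfa = "cfa.csv",
    profiles = "quantile_profiles.csv", descriptive = "descriptive_table.csv")
  manifest <- data.frame(artifact = character(), file = character(),
                         rows = integer())
  for (nm in names(files)) {
    path <- file.path(out_dir, files[[nm]])
    utils::write.csv(arts[[nm]], path, row.names = FALSE)
    manifest <- rbind(manifest, data.frame(artifact = nm, file = files[[nm]],
                                           rows = nrow(arts[[nm]])))
  }
  excl_path <- file.path(out_dir, "exclusions.json")
  jsonlite::write_json(arts$exclusions, excl_path, auto_unbox = TRUE)
  manifest <- rbind(manifest, data.frame(artifact = "exclusions",
                                         file = "exclusions.json",
                                         rows = length(arts$exclusions)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"))
  say("wrote ", nrow(manifest) + 1, " artifacts to ", out_dir)
  arts$manifest <- manifest
  invisible(arts)
}
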