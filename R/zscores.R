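#' @title Plausibility limits for anthropometric z-scores
#' @description Closed-interval limits outside which a z-score is flagged as
#'   biologically implausible, following the standard fixed-exclusion ranges
#'   used with the 2006 growth standards. Editing this single block changes
#'   the policy package-wide.
#' @format Named list of `c(lower, upper)` pairs for `haz`, `waz`, `whz`,
#'   `bmiz`.
#' @export
zscore_flag_limits <- list(
  haz  = c(-6, 6),
  waz  = c(-6, 5),
  whz  = c(-5, 5),
  bmiz = c(-5, 5)
)

.zcols <- c("haz", "waz", "whz", "bmiz")

#' Compute anthropometric z-scores for survey records
#'
#' Adds `haz`, `waz`, `whz` and `bmiz` columns to a child-record data frame,
#' using LMS parameters linearly interpolated in the reference key (age in
#' completed months; measured height for weight-for-height). The restricted
#' tail adjustment (linear re-expression beyond +/-3 SD, anchored at the
#' +/-2 and +/-3 SD curves) is applied to the weight-based scores WAZ, WHZ
#' and BMIZ -- never to HAZ. Children younger than 6 months are marked with
#' `under_6_months`; plausibility flags are set by [flag_implausible()]
#' (called here unless `flag = FALSE`). Missing measurements yield missing
#' z-scores, never an error.
#'
#' @param records Data frame with at least `sex` (`"male"`/`"female"`),
#'   `age_months`, `weight_kg`, `height_cm`.
#' @param ref LMS reference table (see [read_lms_reference()]).
#' @param restricted Apply the restricted tail adjustment to WAZ/WHZ/BMIZ
#'   (default `TRUE`).
#' @param flag Also set plausibility flags (default `TRUE`).
#' @return `records` with added columns `haz`, `waz`, `whz`, `bmiz`,
#'   `under_6_months`, and (if `flag`) `haz_flag`, `waz_flag`, `whz_flag`,
#'   `bmiz_flag`.
#' @export
compute_zscores <- function(records, ref, restricted = TRUE, flag = TRUE) {
  stopifnot(is.data.frame(records))
  need <- c("sex", "age_months", "weight_kg", "height_cm")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  validate_lms_reference(ref)
  n <- nrow(records)
  sex <- as.character(records$sex)
  age <- as.numeric(records$age_months)
  wt  <- as.numeric(records$weight_kg)
  ht  <- as.numeric(records$height_cm)
  if (any(!is.na(wt) & wt <= 0) || any(!is.na(ht) & ht <= 0)) {
    stop("invalid measurement: weight_kg and height_cm must be positive")
  }
  bmi <- wt / (ht / 100)^2

  one <- function(indicator, x, key) {
    p <- lms_params(ref, indicator, sex, key)
    ok <- !is.na(x) & !is.na(p$M)
    z <- rep(NA_real_, n)
    z[ok] <- lms_zscore(x[ok], p$L[ok], p$M[ok], p$S[ok])
    if (restricted && indicator != "height_for_age" && any(ok)) {
      curve <- function(zz) lms_inverse(zz, p$L[ok], p$M[ok], p$S[ok])
      z[ok] <- restricted_adjust(z[ok], x[ok], curve)
    }
    z
  }

  records$haz  <- one("height_for_age", ht, age)
  records$waz  <- one("weight_for_age", wt, age)
  records$whz  <- one("weight_for_height", wt, ht)
  records$bmiz <- one("bmi_for_age", bmi, age)
  records$under_6_months <- !is.na(age) & age < 6
  if (flag) records <- flag_implausible(records)
  records
}

#' Flag biologically implausible z-scores
#'
#' Sets logical columns `haz_flag`, `waz_flag`, `whz_flag`, `bmiz_flag`
#' according to [zscore_flag_limits]. Limits are closed intervals: a score
#' exactly on the boundary is plausible. Missing components are skipped.
#' Flagging marks records; exclusion is a separate step
#' ([apply_exclusions()]).
#'
#' @param records Data frame carrying `haz`, `waz`, `whz`, `bmiz` columns.
#' @param limits Named list of `c(lower, upper)` pairs; defaults to the
#'   package policy [zscore_flag_limits].
#' @return `records` with the four `*_flag` columns set.
#' @export
flag_implausible <- function(records, limits = zscore_flag_limits) {
  for (col in .zcols) {
    if (!col %in% names(records)) stop("missing z-score column: ", col)
    lim <- limits[[col]]
    z <- records[[col]]
    records[[paste0(col, "_flag")]] <- !is.na(z) & (z < lim[1] | z > lim[2])
  }
  records
}

#' Apply the study exclusion rules
#'
#' Removes children younger than 6 months and children with any
#' implausibility flag, tallying exclusions by reason. A record failing both
#' rules is counted once, under the age rule (applied first).
#'
#' @param records Data frame with `under_6_months` and the `*_flag` columns
#'   (as produced by [compute_zscores()]).
#' @return List with elements `included` (the retained records) and `tally`
#'   (named integer vector `under_6_months`, `flagged`).
#' @export
apply_exclusions <- function(records) {
  need <- c("under_6_months", paste0(.zcols, "_flag"))
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  under6 <- records$under_6_months
  flagged <- Reduce(`|`, lapply(paste0(.zcols, "_flag"), function(c) records[[c]]))
  drop_age  <- under6
  drop_flag <- flagged & !under6
  list(
    included = records[!(drop_age | drop_flag), , drop = FALSE],
    tally = c(under_6_months = sum(drop_age), flagged = sum(drop_flag))
  )
}

#' Read child survey records from CSV
#'
#' Expects columns `child_id, survey, region, psu, household, sex,
#' age_months, weight_kg, height_cm, sampling_weight`; empty fields are read
#' as missing. Basic validity (nonnegative weights, recognized sex codes) is
#' checked.
#'
#' @param path CSV path.
#' @return Data frame of child records.
#' @export
read_child_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("child_id", "survey", "region", "psu", "household", "sex",
            "age_months", "weight_kg", "height_cm", "sampling_weight")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("record file missing columns: ", paste(miss, collapse = ", "))
  if (!all(rec$sex %in% c("male", "female", NA))) stop("sex must be coded male/female")
  if (any(!is.na(rec$sampling_weight) & rec$sampling_weight < 0)) {
    stop("sampling_weight must be nonnegative")
  }
  rec
}
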