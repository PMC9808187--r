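#' Human-readable labels for the eCIAF groups
#' @format Named character vector keyed by group code.
#' @export
eciaf_labels <- c(
  A = "No failure",
  B = "Wasting only",
  C = "Wasting and underweight",
  D = "Stunting, wasting, and underweight",
  E = "Stunting and underweight",
  F = "Stunting only",
  Y = "Underweight only",
  G = "Stunting and overweight",
  H = "Overweight only",
  X = "Stunting and wasting (not underweight)"
)

#' Conventional anthropometric indicators from z-scores
#'
#' Applies the standard case definitions: stunted if HAZ < -2, wasted if
#' WHZ < -2, underweight if WAZ < -2, overweight if WHZ > +2 (or BMIZ > +2
#' when `overweight_on = "bmiz"`). Inequalities are strict: a score of
#' exactly -2.0 is not a failure.
#'
#' @param records Data frame with `haz`, `waz`, `whz` (and `bmiz` if used for
#'   overweight). Flagged or missing components yield `NA` indicators.
#' @param overweight_on `"whz"` (default, the survey convention) or `"bmiz"`.
#' @return `records` with added logical columns `stunted`, `wasted`,
#'   `underweight`, `overweight`.
#' @export
classify_conventional <- function(records, overweight_on = c("whz", "bmiz")) {
  overweight_on <- match.arg(overweight_on)
  for (col in c("haz", "waz", "whz")) {
    if (!col %in% names(records)) stop("classification requires component: ", col)
  }
  ow_src <- records[[overweight_on]]
  if (is.null(ow_src)) stop("classification requires component: ", overweight_on)
  records$stunted     <- records$haz < -2.0
  records$wasted      <- records$whz < -2.0
  records$underweight <- records$waz < -2.0
  records$overweight  <- ow_src > 2.0
  records
}

#' eCIAF group codes from indicator booleans
#'
#' Maps each combination of stunting, wasting, underweight and overweight to
#' the mutually exclusive groups of the extended composite index of
#' anthropometric failure: A no failure; B wasting only; C wasting and
#' underweight; D stunting, wasting and underweight; E stunting and
#' underweight; F stunting only; Y underweight only; G stunting and
#' overweight; H overweight only. The stunted-and-wasted-but-not-underweight
#' configuration has no letter in the original taxonomy and is returned as
#' the sentinel `X` (still an anthropometric failure). Wasted and overweight
#' cannot co-occur (both are defined on WHZ) and raise an error; underweight
#' with overweight -- logically possible, outside the taxonomy -- maps to H
#' (G if stunted) with a data-quality warning.
#'
#' @param stunted,wasted,underweight,overweight Logical vectors, recycled to
#'   a common length. `NA` in any input yields `NA` output.
#' @return Factor of group codes with levels `A,B,C,D,E,F,Y,G,H,X`.
#' @export
classify_eciaf <- function(stunted, wasted, underweight, overweight) {
  n <- max(length(stunted), length(wasted), length(underweight), length(overweight))
  s <- rep_len(stunted, n); w <- rep_len(wasted, n)
  u <- rep_len(underweight, n); o <- rep_len(overweight, n)
  if (any(w & o, na.rm = TRUE)) {
    stop("wasted and overweight cannot both be true (both defined on WHZ)")
  }
  if (any(u & o, na.rm = TRUE)) {
    warning("underweight co-occurring with overweight: outside the CIAF taxonomy, mapped to H/G")
  }
  code <- rep(NA_character_, n)
  done <- is.na(s) | is.na(w) | is.na(u) | is.na(o)
  set <- function(cond, letter) {
    idx <- !done & cond
    idx[is.na(idx)] <- FALSE
    code[idx] <<- letter
    done[idx] <<- TRUE
  }
  set(o & s, "G")
  set(o, "H")
  set(s & w & u, "D")
  set(s & w, "X")
  set(s & u, "E")
  set(s, "F")
  set(w & u, "C")
  set(w, "B")
  set(u, "Y")
  set(rep(TRUE, n), "A")
  factor(code, levels = names(eciaf_labels))
}

#' CIAF group codes (undernutrition only)
#'
#' As [classify_eciaf()] but ignoring over-nutrition: the CIAF partitions
#' children only by stunting, wasting and underweight, so a child who is
#' overweight-only is "no failure" (A) and stunting-and-overweight collapses
#' to stunting only (F).
#'
#' @inheritParams classify_eciaf
#' @return Factor of group codes (levels as in [classify_eciaf()]; G and H
#'   unused).
#' @export
classify_ciaf <- function(stunted, wasted, underweight) {
  classify_eciaf(stunted, wasted, underweight, overweight = FALSE)
}

#' Classify a record table into CIAF and eCIAF groups
#'
#' Convenience wrapper: derives the conventional indicators (if absent) and
#' adds `ciaf_group` and `eciaf_group` columns.
#'
#' @inheritParams classify_conventional
#' @return `records` with indicator and group columns added.
#' @export
classify_records <- function(records, overweight_on = c("whz", "bmiz")) {
  if (!all(c("stunted", "wasted", "underweight", "overweight") %in% names(records))) {
    records <- classify_conventional(records, overweight_on)
  }
  records$ciaf_group <- classify_ciaf(records$stunted, records$wasted,
                                      records$underweight)
  records$eciaf_group <- classify_eciaf(records$stunted, records$wasted,
                                        records$underweight, records$overweight)
  records
}

#' Overall burden of anthropometric failure
#'
#' The proportion of children in any failure group (code other than A),
#' i.e. `1 - P(A)`: overall undernutrition under the CIAF, overall
#' malnutrition under the eCIAF.
#'
#' @param codes Vector of group codes (as from [classify_eciaf()] or
#'   [classify_ciaf()]); `NA` codes are dropped.
#' @return Proportion in `[0, 1]`.
#' @export
overall_burden <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("overall_burden: no classified children")
  mean(codes != "A")
}
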