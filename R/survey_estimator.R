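#' Survey design specification
#'
#' Names the columns of a record table that carry the two-stage stratified
#' design: stratum (region), primary sampling unit (cluster), secondary
#' sampling unit (household) and the sampling weight. With first-stage
#' Taylor linearization the SSU never enters the variance; it is retained in
#' the specification for fidelity to the source designs.
#'
#' @param stratum_field,psu_field,ssu_field,weight_field Column names.
#' @return Object of class `survey_design_spec`.
#' @export
survey_design_spec <- function(stratum_field = "region", psu_field = "psu",
                               ssu_field = "household",
                               weight_field = "sampling_weight") {
  structure(list(stratum_field = stratum_field, psu_field = psu_field,
                 ssu_field = ssu_field, weight_field = weight_field),
            class = "survey_design_spec")
}

.design_frame <- function(records, design) {
  for (f in c(design$stratum_field, design$psu_field, design$weight_field)) {
    if (!f %in% names(records)) stop("design column not found in records: ", f)
  }
  w <- as.numeric(records[[design$weight_field]])
  if (any(is.na(w)) || any(w < 0)) stop("sampling weights must be nonnegative and non-missing")
  data.frame(
    stratum = as.character(records[[design$stratum_field]]),
    # PSU ids are only guaranteed unique within a stratum in these surveys
    psu = paste(records[[design$stratum_field]], records[[design$psu_field]], sep = "\r"),
    w = w
  )
}

#' Design-weighted prevalence with a Taylor-linearized confidence interval
#'
#' Estimates `sum(w*y)/sum(w)` for a binary outcome under a stratified
#' multi-stage design, with the variance from first-stage Taylor
#' linearization of the ratio estimator under the with-replacement PSU
#' approximation: within stratum `h` holding `n_h` PSUs, the contribution is
#' `n_h/(n_h - 1) * sum_j (z_hj - mean_h(z))^2` where `z_hj` totals the
#' linearized scores `w_i * (y_i - p) / sum(w)` over PSU `j`. The 95%
#' interval is Wald on the proportion scale (`p +/- 1.96 se`), clipped to
#' `[0, 1]`; a logit-scale interval is available via `ci_scale = "logit"`.
#'
#' @param records Classified record data frame.
#' @param design A [survey_design_spec()].
#' @param predicate Either a column name of a logical column, a group code
#'   (matched against `group_col`), or a logical vector aligned with
#'   `records`.
#' @param domain Optional stratum (region) label restricting estimation to a
#'   subpopulation; `NULL` (default) estimates nationally.
#' @param group_col Column holding group codes when `predicate` is a code
#'   (default `"eciaf_group"`).
#' @param single_psu How to handle strata with a single PSU: `"error"`
#'   (default), `"certainty"` (zero variance contribution) or `"collapse"`
#'   (merge with the next stratum).
#' @param ci_scale `"proportion"` (default) or `"logit"`.
#' @param level Confidence level (default 0.95).
#' @return A one-row data frame of class `prevalence_estimate`: `domain`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `n` (unweighted count).
#' @export
weighted_prevalence <- function(records, design, predicate, domain = NULL,
                                group_col = "eciaf_group",
                                single_psu = c("error", "certainty", "collapse"),
                                ci_scale = c("proportion", "logit"),
                                level = 0.95) {
  single_psu <- match.arg(single_psu)
  ci_scale <- match.arg(ci_scale)
  df <- .design_frame(records, design)

  if (is.logical(predicate)) {
    if (length(predicate) != nrow(records)) stop("logical predicate must match records length")
    y <- predicate
  } else if (is.character(predicate) && length(predicate) == 1 &&
             predicate %in% names(records) && is.logical(records[[predicate]])) {
    y <- records[[predicate]]
  } else if (is.character(predicate) && length(predicate) == 1) {
    if (!group_col %in% names(records)) stop("group column not found: ", group_col)
    y <- as.character(records[[group_col]]) == predicate
  } else stop("predicate must be a logical vector, a logical column name, or a group code")

  keep <- !is.na(y)
  if (!is.null(domain)) {
    known <- unique(df$stratum)
    if (!domain %in% known) {
      stop("unknown region '", domain, "'; known regions: ",
           paste(sort(known), collapse = ", "))
    }
    keep <- keep & df$stratum == domain
  }
  df <- df[keep, , drop = FALSE]
  y <- y[keep]
  if (!nrow(df) || sum(df$w) <= 0) stop("empty domain or all-zero weights")

  W <- sum(df$w)
  p <- sum(df$w * y) / W

  if (single_psu == "collapse") {
    repeat {
      npsu <- tapply(df$psu, df$stratum, function(p) length(unique(p)))
      singles <- names(npsu)[npsu < 2]
      if (!length(singles)) break
      strata <- sort(unique(df$stratum))
      if (length(strata) < 2) {
        stop("cannot collapse: the design has a single stratum with one PSU")
      }
      s <- singles[1]
      pos <- match(s, strata)
      partner <- if (pos < length(strata)) strata[pos + 1] else strata[pos - 1]
      df$stratum[df$stratum %in% c(s, partner)] <-
        paste(sort(c(s, partner)), collapse = "+")
    }
  }

  z <- df$w * (y - p) / W
  psu_tot <- rowsum(z, group = df$psu, reorder = FALSE)
  psu_stratum <- df$stratum[!duplicated(df$psu)][match(rownames(psu_tot), unique(df$psu))]
  v <- 0
  for (h in unique(psu_stratum)) {
    zh <- psu_tot[psu_stratum == h, 1]
    nh <- length(zh)
    if (nh < 2) {
      if (single_psu == "certainty") next
      stop("stratum '", sub("\r.*", "", h), "' has a single PSU; ",
           "set single_psu = 'collapse' or 'certainty'")
    }
    v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  se <- sqrt(v)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  if (ci_scale == "logit" && p > 0 && p < 1 && se > 0) {
    lg <- stats::qlogis(p)
    se_lg <- se / (p * (1 - p))
    ci <- stats::plogis(lg + c(-1, 1) * zq * se_lg)
  } else {
    ci <- pmin(pmax(p + c(-1, 1) * zq * se, 0), 1)
  }
  out <- data.frame(domain = if (is.null(domain)) "national" else domain,
                    estimate = p, se = se, ci_low = ci[1], ci_high = ci[2],
                    n = nrow(df), stringsAsFactors = FALSE)
  class(out) <- c("prevalence_estimate", class(out))
  out
}

#' Prevalence table over CIAF/eCIAF groups
#'
#' One design-based prevalence row per group code plus an overall-burden row
#' (proportion with any failure, `1 -` the no-failure row). Point estimates
#' of the group rows sum to one with the no-failure row, exactly.
#'
#' @inheritParams weighted_prevalence
#' @param index `"eciaf"` (default) or `"ciaf"`; selects the group column.
#' @return Data frame with a `group` column (codes plus `"overall"`) and the
#'   [weighted_prevalence()] fields.
#' @export
subtype_prevalence_table <- function(records, design, index = c("eciaf", "ciaf"),
                                     domain = NULL, ...) {
  index <- match.arg(index)
  gcol <- paste0(index, "_group")
  if (!gcol %in% names(records)) stop("records lack group column ", gcol,
                                      "; run classify_records() first")
  present <- if (index == "eciaf") names(eciaf_labels) else
    setdiff(names(eciaf_labels), c("G", "H"))
  rows <- lapply(present, function(cd)
    cbind(group = cd, weighted_prevalence(records, design, cd, domain = domain,
                                          group_col = gcol, ...)))
  overall <- weighted_prevalence(records, design,
                                 as.character(records[[gcol]]) != "A",
                                 domain = domain, ...)
  rows[[length(rows) + 1]] <- cbind(group = "overall", overall)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regional overall-burden estimates
#'
#' Domain estimation of the overall CIAF/eCIAF burden for every region
#' (stratum) in the data: weights are used as-is and the variance is
#' restricted to the region's own PSUs (regions are design strata, so the
#' restriction is exact).
#'
#' @inheritParams subtype_prevalence_table
#' @return Data frame of one [weighted_prevalence()] row per region.
#' @export
regional_prevalence <- function(records, design, index = c("eciaf", "ciaf"), ...) {
  index <- match.arg(index)
  gcol <- paste0(index, "_group")
  if (!gcol %in% names(records)) stop("records lack group column ", gcol)
  regions <- sort(unique(as.character(records[[design$stratum_field]])))
  out <- do.call(rbind, lapply(regions, function(r)
    weighted_prevalence(records, design,
                        as.character(records[[gcol]]) != "A",
                        domain = r, group_col = gcol, ...)))
  rownames(out) <- NULL
  out
}

#' Do two confidence intervals overlap?
#'
#' Closed-interval convention: intervals sharing exactly one endpoint
#' overlap. Non-overlap is the common reporting screen for a significant
#' difference between two prevalence estimates.
#'
#' @param a,b `prevalence_estimate` rows (or any objects with `ci_low` /
#'   `ci_high`).
#' @return `TRUE` if the intervals intersect.
#' @export
ci_overlap <- function(a, b) {
  a$ci_low <= b$ci_high && b$ci_low <= a$ci_high
}
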