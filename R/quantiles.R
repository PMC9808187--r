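#' Default quantile grid
#'
#' Every 2.5th percentile from the 5th to the 95th: 37 levels.
#' @return Numeric vector of quantile levels.
#' @export
default_tau_grid <- function() seq(0.05, 0.95, by = 0.025)

#' Weighted sample quantiles
#'
#' Interpolated weighted quantile: observations are sorted and assigned the
#' midpoint positions `(cumsum(w) - w/2) / sum(w)`; the tau-quantile is read
#' off by linear interpolation, clamped to the extremes. With equal weights
#' this is exactly `quantile(x, tau, type = 5)`, and it minimizes the
#' weighted pinball loss up to the interpolation within the flat region of
#' the loss.
#'
#' @param x Numeric values (missing values dropped, with their weights).
#' @param taus Quantile levels in (0, 1).
#' @param w Nonnegative weights (default equal).
#' @return Numeric vector, one quantile per tau.
#' @export
weighted_quantile <- function(x, taus, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x))
  keep <- !is.na(x) & !is.na(w) & w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) stop("no observations for quantile estimation")
  if (any(taus <= 0 | taus >= 1)) stop("taus must lie strictly inside (0, 1)")
  o <- order(x)
  x <- x[o]; w <- w[o]
  pos <- (cumsum(w) - 0.5 * w) / sum(w)
  if (length(x) == 1) return(rep(x, length(taus)))
  stats::approx(pos, x, xout = taus, rule = 2, ties = "ordered")$y
}

#' Quantile profile of z-scores per survey group
#'
#' Estimates the tau-quantile of a z-score distribution for each group over a
#' grid of levels, with 95% confidence bands from a cluster bootstrap that
#' resamples PSUs with replacement within group (percentile method).
#' Estimates are nondecreasing in tau by construction; bootstrap band edges
#' are monotone-rearranged in case replicate noise makes them cross.
#'
#' @param values Numeric z-scores.
#' @param group Group labels aligned with `values`.
#' @param psu PSU (cluster) labels aligned with `values`; used for the
#'   bootstrap.
#' @param weights Optional sampling weights (applied inside the quantile).
#' @param taus Quantile levels; defaults to [default_tau_grid()].
#' @param n_boot Bootstrap replicates (default 999).
#' @param seed RNG seed for the bootstrap (default 1).
#' @param level Band level (default 0.95).
#' @param min_n Minimum observations per group (default 30).
#' @return Data frame of class `quantile_profile`: `group`, `tau`,
#'   `estimate`, `ci_low`, `ci_high`.
#' @export
fit_quantile_profile <- function(values, group, psu, weights = NULL,
                                 taus = default_tau_grid(), n_boot = 999,
                                 seed = 1, level = 0.95, min_n = 30) {
  stopifnot(length(group) == length(values), length(psu) == length(values))
  if (is.null(weights)) weights <- rep(1, length(values))
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- as.character(group[keep])
  psu <- as.character(psu[keep]); weights <- weights[keep]
  set.seed(seed)
  out <- lapply(unique(group), function(g) {
    xi <- values[group == g]; wi <- weights[group == g]; ci <- psu[group == g]
    if (length(xi) < min_n) {
      stop("too few observations (", length(xi), " < ", min_n, ") in group '", g, "'")
    }
    est <- weighted_quantile(xi, taus, wi)
    clusters <- unique(ci)
    idx_by <- split(seq_along(xi), ci)
    boot <- matrix(NA_real_, n_boot, length(taus))
    for (b in seq_len(n_boot)) {
      take <- sample(clusters, length(clusters), replace = TRUE)
      idx <- unlist(idx_by[take], use.names = FALSE)
      boot[b, ] <- weighted_quantile(xi[idx], taus, wi[idx])
    }
    a <- (1 - level) / 2
    lo <- sort(apply(boot, 2, stats::quantile, probs = a, names = FALSE))
    hi <- sort(apply(boot, 2, stats::quantile, probs = 1 - a, names = FALSE))
    data.frame(group = g, tau = taus, estimate = sort(est),
               ci_low = lo, ci_high = hi)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("quantile_profile", class(out))
  out
}

#' Per-tau band separation between two profiles
#'
#' A tau is flagged significant when the two 95% bands are disjoint there --
#' the polygon-overlap criterion used when plotting quantile profiles.
#'
#' @param profile_a,profile_b Single-group `quantile_profile` data frames on
#'   the same tau grid.
#' @return Data frame `tau`, `significant`.
#' @export
band_differences <- function(profile_a, profile_b) {
  if (length(unique(profile_a$group)) != 1 || length(unique(profile_b$group)) != 1) {
    stop("band_differences expects single-group profiles")
  }
  if (nrow(profile_a) != nrow(profile_b) ||
      any(abs(profile_a$tau - profile_b$tau) > 1e-12)) {
    stop("profiles are on different tau grids")
  }
  disjoint <- profile_a$ci_low > profile_b$ci_high |
    profile_b$ci_low > profile_a$ci_high
  data.frame(tau = profile_a$tau, significant = disjoint)
}

#' Age-group factor used throughout the pipeline
#'
#' Younger children are 6-23 completed months inclusive; older are 24-59.
#' @param age_months Numeric ages in completed months.
#' @return Factor with levels `"6-23"`, `"24-59"` (`NA` outside 6-59).
#' @export
age_group <- function(age_months) {
  cut(age_months, breaks = c(6, 24, 60), right = FALSE,
      labels = c("6-23", "24-59"))
}

#' Quantile-profile report across indicators and strata
#'
#' Fits one profile per indicator x stratifier level x survey group --
#' the computation behind sex- and age-stratified z-score distribution
#' comparisons. Empty strata are omitted with a warning.
#'
#' @param records Data frame with z-score columns, `survey`, `sex`,
#'   `age_months`, `psu`, and optionally `sampling_weight`.
#' @param indicators Z-score columns to profile (default all four).
#' @param stratify_by Any of `"sex"`, `"age_group"` (default both).
#' @param ... Passed to [fit_quantile_profile()] (`taus`, `n_boot`, `seed`,
#'   ...).
#' @return Long data frame: `indicator`, `stratifier`, `stratum`, plus the
#'   `quantile_profile` columns.
#' @export
profile_report <- function(records, indicators = c("haz", "waz", "whz", "bmiz"),
                           stratify_by = c("sex", "age_group"), ...) {
  stratify_by <- match.arg(stratify_by, several.ok = TRUE)
  if ("age_group" %in% stratify_by && !"age_group" %in% names(records)) {
    records$age_group <- age_group(records$age_months)
  }
  w <- if ("sampling_weight" %in% names(records)) records$sampling_weight else NULL
  out <- list()
  for (ind in indicators) {
    if (!ind %in% names(records)) stop("missing indicator column: ", ind)
    for (sb in stratify_by) {
      for (lev in levels(factor(records[[sb]]))) {
        sel <- !is.na(records[[sb]]) & records[[sb]] == lev
        if (!sum(sel, na.rm = TRUE)) {
          warning("empty stratum ", sb, " = ", lev, "; omitted")
          next
        }
        prof <- fit_quantile_profile(records[[ind]][sel],
                                     group = records$survey[sel],
                                     psu = paste(records$region[sel], records$psu[sel]),
                                     weights = w[sel], ...)
        out[[length(out) + 1]] <- cbind(indicator = ind, stratifier = sb,
                                        stratum = lev, prof)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
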