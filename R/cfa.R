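#' Configuration order of the stunting x wasting x underweight table
#'
#' The eight boolean triples in the conventional reporting order: YYY, YYN,
#' YNY, YNN, NYY, NYN, NNY, NNN.
#' @format Data frame with logical columns `stunting`, `wasting`,
#'   `underweight`.
#' @export
cfa_configs <- data.frame(
  stunting    = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
  wasting     = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
  underweight = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
)

#' Build the two-group configuration table
#'
#' Cross-classifies two groups of classified children over the eight
#' stunting x wasting x underweight configurations. Counts are unweighted:
#' the configural frequency analysis operates on observed frequencies, not
#' design-weighted prevalences.
#'
#' @param group_a,group_b Data frames carrying logical `stunted`, `wasted`,
#'   `underweight` columns (children with a missing component are dropped).
#' @param labels Character vector of length 2 naming the groups.
#' @return Object of class `cfa_config_table`: list with `configs`,
#'   `observed` (8 x 2 integer matrix), `group_labels`, `group_totals`.
#' @export
build_config_table <- function(group_a, group_b, labels = c("group1", "group2")) {
  count_one <- function(g, nm) {
    for (col in c("stunted", "wasted", "underweight")) {
      if (!col %in% names(g)) stop("group '", nm, "' lacks column ", col)
    }
    ok <- !(is.na(g$stunted) | is.na(g$wasted) | is.na(g$underweight))
    g <- g[ok, , drop = FALSE]
    if (!nrow(g)) stop("empty group: ", nm)
    key_obs <- paste(g$stunted, g$wasted, g$underweight)
    key_cfg <- paste(cfa_configs$stunting, cfa_configs$wasting, cfa_configs$underweight)
    as.integer(table(factor(key_obs, levels = key_cfg)))
  }
  observed <- cbind(count_one(group_a, labels[1]), count_one(group_b, labels[2]))
  colnames(observed) <- labels
  structure(list(configs = cfa_configs, observed = observed,
                 group_labels = labels, group_totals = colSums(observed)),
            class = "cfa_config_table")
}

#' Construct a configuration table from printed counts
#'
#' For working directly from published tables: takes the 8 observed counts
#' per group (in the [cfa_configs] order) instead of record-level data.
#'
#' @param observed_a,observed_b Integer vectors of length 8.
#' @inheritParams build_config_table
#' @return A `cfa_config_table`.
#' @export
cfa_table_from_counts <- function(observed_a, observed_b,
                                  labels = c("group1", "group2")) {
  stopifnot(length(observed_a) == 8, length(observed_b) == 8)
  if (any(observed_a < 0) || any(observed_b < 0) ||
      any(observed_a != round(observed_a)) || any(observed_b != round(observed_b))) {
    stop("observed counts must be nonnegative integers")
  }
  observed <- cbind(as.integer(observed_a), as.integer(observed_b))
  colnames(observed) <- labels
  structure(list(configs = cfa_configs, observed = observed,
                 group_labels = labels, group_totals = colSums(observed)),
            class = "cfa_config_table")
}

#' Expected frequencies under the margin (independence) model
#'
#' The chance model of the two-group CFA: configuration and group membership
#' independent, so `E[c, g] = row_total_c * N_g / (N_1 + N_2)`. Both margins
#' are conserved exactly.
#'
#' @param table A `cfa_config_table`.
#' @return 8 x 2 numeric matrix of expected counts.
#' @export
expected_frequencies <- function(table) {
  obs <- table$observed
  grand <- sum(obs)
  if (grand <= 0) stop("empty configuration table")
  row_tot <- rowSums(obs)
  e <- outer(row_tot, colSums(obs)) / grand
  dimnames(e) <- dimnames(obs)
  e
}

#' Per-configuration exact test
#'
#' Two-sided Fisher exact p-value for the 2x2 table contrasting one
#' configuration against all others across the two groups (conditional
#' hypergeometric test, minimum-likelihood two-sided rule). A configuration
#' observed in neither group returns p = 1.
#'
#' @param table A `cfa_config_table`.
#' @param config Row index 1..8, or a logical triple
#'   `(stunting, wasting, underweight)`.
#' @return p-value in `[0, 1]`.
#' @export
config_test <- function(table, config) {
  i <- if (length(config) == 3) {
    which(cfa_configs$stunting == config[1] & cfa_configs$wasting == config[2] &
          cfa_configs$underweight == config[3])
  } else as.integer(config)
  if (length(i) != 1 || is.na(i) || i < 1 || i > 8) stop("unknown configuration")
  obs <- table$observed
  a <- obs[i, ]
  if (sum(a) == 0) return(1)
  m <- rbind(a, colSums(obs) - a)
  stats::fisher.test(m)$p.value
}

#' Threshold a vector of per-configuration p-values
#'
#' The multiplicity rule of the two-group CFA, factored out so it can be
#' applied to published p-values as well as recomputed ones: a configuration
#' is a discrimination type when its adjusted p-value does not exceed
#' `alpha` (for Bonferroni over K configurations this is the local level
#' `alpha / K`).
#'
#' @param p Numeric vector of p-values.
#' @param alpha Family-wise level in (0, 1).
#' @param adjustment `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return Logical vector.
#' @export
discriminate_pvalues <- function(p, alpha = 0.05,
                                 adjustment = c("bonferroni", "holm", "none")) {
  adjustment <- match.arg(adjustment)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  stats::p.adjust(p, method = adjustment) <= alpha
}

#' Discrimination typing of the configuration table
#'
#' Runs [config_test()] for all eight configurations and marks the
#' "discrimination types": configurations whose frequencies differ between
#' the two surveys after multiplicity adjustment. The default is Bonferroni
#' over the 8 configurations, i.e. a local level of `alpha / 8`.
#'
#' @param table A `cfa_config_table`.
#' @param alpha Family-wise level in (0, 1); default 0.05.
#' @param adjustment `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return Data frame of class `cfa_result`: configuration booleans,
#'   observed and expected counts per group, `p_value`, `p_adjusted`,
#'   `discrimination`.
#' @export
discrimination_types <- function(table, alpha = 0.05,
                                 adjustment = c("bonferroni", "holm", "none")) {
  adjustment <- match.arg(adjustment)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  e <- expected_frequencies(table)
  p <- vapply(1:8, function(i) config_test(table, i), numeric(1))
  p_adj <- stats::p.adjust(p, method = adjustment)
  disc <- discriminate_pvalues(p, alpha, adjustment)
  out <- data.frame(
    stunting = cfa_configs$stunting,
    wasting = cfa_configs$wasting,
    underweight = cfa_configs$underweight,
    obs_a = table$observed[, 1], exp_a = e[, 1],
    obs_b = table$observed[, 2], exp_b = e[, 2],
    p_value = p, p_adjusted = p_adj,
    discrimination = disc
  )
  attr(out, "group_labels") <- table$group_labels
  attr(out, "alpha") <- alpha
  attr(out, "adjustment") <- adjustment
  class(out) <- c("cfa_result", class(out))
  out
}
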