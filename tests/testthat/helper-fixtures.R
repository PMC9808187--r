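# Shared fixtures: built in code, no files.

test_ref <- synthetic_lms_reference()

# A record frame with direct z-score and flag columns (bypasses measurement
# computation for classifier/exclusion tests).
zset_records <- function(haz = 0, waz = 0, whz = 0, bmiz = 0, age = 24) {
  n <- max(length(haz), length(waz), length(whz), length(bmiz), length(age))
  df <- data.frame(haz = rep_len(haz, n), waz = rep_len(waz, n),
                   whz = rep_len(whz, n), bmiz = rep_len(bmiz, n),
                   age_months = rep_len(age, n))
  df$under_6_months <- df$age_months < 6
  flag_implausible(df)
}

# Equal-weight, self-weighting design: one stratum, each child its own PSU.
self_weighting <- function(n, extra = list()) {
  df <- data.frame(region = "all", psu = seq_len(n), household = seq_len(n),
                   sampling_weight = 1)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# Independent brute-force two-sided Fisher p (minimum-likelihood rule) for a
# 2x2 table given as counts (a, b; c, d), via full hypergeometric enumeration.
fisher_enum_p <- function(a, b, c, d) {
  N <- a + b + c + d
  r <- a + b
  k <- a + c
  xs <- max(0, k - (N - r)):min(r, k)
  probs <- dhyper(xs, r, N - r, k)
  p_obs <- dhyper(a, r, N - r, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All 2x2 tables with grand total <= nmax (one triangle per total).
all_2x2_tables <- function(nmax) {
  out <- list()
  for (N in 1:nmax) {
    for (a in 0:N) for (b in 0:(N - a)) for (c in 0:(N - a - b)) {
      out[[length(out) + 1]] <- c(a, b, c, N - a - b - c)
    }
  }
  do.call(rbind, out)
}
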