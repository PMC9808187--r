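#' LMS z-score transform
#'
#' Computes a z-score from a measurement and the LMS parameters of a growth
#' reference: a Box-Cox power `L`, a median `M`, and a coefficient of
#' variation `S`. For `L != 0` the transform is `((x/M)^L - 1) / (L * S)`;
#' for `L == 0` it degenerates to `log(x/M) / S`.
#'
#' @param x Measurement in indicator units (cm, kg, or kg/m^2). Must be
#'   positive.
#' @param L,M,S LMS parameters; `M > 0`, `S > 0`. All arguments are recycled
#'   to a common length.
#' @return Numeric vector of z-scores in standard-deviation units.
#' @seealso [lms_inverse()] for the inverse transform.
#' @export
#' @examples
#' lms_zscore(11, L = 1, M = 10, S = 0.1) # exactly 1
lms_zscore <- function(x, L, M, S) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  bad <- !is.na(x) & !is.na(M) & !is.na(S) & (x <= 0 | M <= 0 | S <= 0)
  if (any(bad)) {
    stop("invalid measurement or reference parameters: x, M and S must be positive")
  }
  z <- ifelse(L == 0, log(x / M) / S, ((x / M)^L - 1) / (L * S))
  as.numeric(z)
}

#' Inverse LMS transform
#'
#' Maps a z-score back to the measurement scale of a growth reference:
#' `M * (1 + L*S*z)^(1/L)` for `L != 0`, `M * exp(S*z)` for `L == 0`.
#' Outside the transform's domain (`1 + L*S*z <= 0`) an error is raised.
#'
#' @inheritParams lms_zscore
#' @param z Z-score in standard-deviation units.
#' @return Measurement in indicator units.
#' @export
lms_inverse <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(!is.na(M) & M <= 0) || any(!is.na(S) & S <= 0)) {
    stop("invalid reference parameters: M and S must be positive")
  }
  base <- 1 + L * S * z
  if (any(L != 0 & !is.na(base) & base <= 0)) {
    stop("z outside the domain of the inverse LMS transform (1 + L*S*z <= 0)")
  }
  x <- ifelse(L == 0, M * exp(S * z), M * base^(1 / L))
  as.numeric(x)
}

#' Restricted tail adjustment of a z-score
#'
#' Weight-based z-scores (WAZ, WHZ, BMIZ) beyond +/-3 SD are re-expressed on
#' a linear scale anchored at the reference's +/-2 and +/-3 SD curves: for
#' `z_raw > 3`, `z = 3 + (x - SD3) / (SD3 - SD2)`, mirrored below -3. Scores
#' within +/-3 SD are returned unchanged; the adjustment is continuous at the
#' knots.
#'
#' @param z_raw Raw LMS z-score(s).
#' @param x Measurement(s) on the indicator scale, same length as `z_raw`.
#' @param sd_curve Function mapping a z-score to the measurement scale for
#'   this child's reference row (typically a closure over [lms_inverse()]).
#'   Must be evaluable at -3, -2, 2 and 3.
#' @return Adjusted z-score(s).
#' @export
restricted_adjust <- function(z_raw, x, sd_curve) {
  sd3p <- sd_curve(3);  sd2p <- sd_curve(2)
  sd3n <- sd_curve(-3); sd2n <- sd_curve(-2)
  if (any(sd3p - sd2p <= 0) || any(sd2n - sd3n <= 0)) {
    stop("degenerate reference: +/-2 and +/-3 SD curves coincide")
  }
  z <- z_raw
  hi <- !is.na(z_raw) & z_raw > 3
  lo <- !is.na(z_raw) & z_raw < -3
  if (any(hi)) {
    z[hi] <- 3 + (x[hi] - rep_len(sd3p, length(z))[hi]) /
      (rep_len(sd3p - sd2p, length(z))[hi])
  }
  if (any(lo)) {
    z[lo] <- -3 + (x[lo] - rep_len(sd3n, length(z))[lo]) /
      (rep_len(sd2n - sd3n, length(z))[lo])
  }
  z
}

.lms_indicators <- c("height_for_age", "weight_for_age",
                     "weight_for_height", "bmi_for_age")

#' Validate an LMS reference table
#'
#' Checks the structural invariants of a reference table: required columns,
#' positive `M` and `S`, and strictly increasing keys within each
#' (indicator, sex) block.
#'
#' @param ref Data frame with columns `indicator`, `sex`, `key`, `L`, `M`, `S`.
#' @return `ref`, invisibly, after validation.
#' @export
validate_lms_reference <- function(ref) {
  need <- c("indicator", "sex", "key", "L", "M", "S")
  miss <- setdiff(need, names(ref))
  if (length(miss)) stop("reference table missing columns: ", paste(miss, collapse = ", "))
  if (!all(ref$indicator %in% .lms_indicators)) {
    stop("unknown indicator in reference table; expected one of: ",
         paste(.lms_indicators, collapse = ", "))
  }
  if (!all(ref$sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  if (any(ref$M <= 0) || any(ref$S <= 0)) stop("reference table has nonpositive M or S")
  ok <- vapply(split(ref$key, paste(ref$indicator, ref$sex)),
               function(k) all(diff(sort(k)) > 0) && !is.unsorted(k),
               logical(1))
  if (!all(ok)) stop("reference keys must be strictly increasing within each indicator/sex block")
  invisible(ref)
}

#' Read an LMS reference table from CSV
#'
#' @param path Path to a CSV with header `indicator,sex,key,L,M,S`.
#' @return Validated reference data frame.
#' @export
read_lms_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_lms_reference(ref)
  ref
}

#' Interpolated LMS parameters at arbitrary keys
#'
#' Linearly interpolates `L`, `M`, `S` between the bracketing rows of the
#' reference for one indicator and per-record sex/key. Keys outside the
#' table's range raise a coverage error naming the indicator.
#'
#' @param ref Validated LMS reference table.
#' @param indicator One of `"height_for_age"`, `"weight_for_age"`,
#'   `"weight_for_height"`, `"bmi_for_age"`.
#' @param sex Character vector (`"male"`/`"female"`), recycled against `key`.
#' @param key Numeric vector of lookup keys (age in completed months, or
#'   height in cm for weight-for-height).
#' @return Data frame with columns `L`, `M`, `S`, one row per key.
#' @export
lms_params <- function(ref, indicator, sex, key) {
  indicator <- match.arg(indicator, .lms_indicators)
  n <- max(length(sex), length(key))
  sex <- rep_len(sex, n); key <- rep_len(key, n)
  out <- data.frame(L = rep(NA_real_, n), M = NA_real_, S = NA_real_)
  for (s in unique(sex[!is.na(sex)])) {
    block <- ref[ref$indicator == indicator & ref$sex == s, , drop = FALSE]
    if (!nrow(block)) stop("reference table has no rows for ", indicator, " / ", s)
    idx <- which(sex == s & !is.na(key))
    if (!length(idx)) next
    k <- key[idx]
    if (any(k < min(block$key) - 1e-9 | k > max(block$key) + 1e-9)) {
      stop("key outside reference coverage for indicator '", indicator,
           "' (", min(block$key), "-", max(block$key), ")")
    }
    k <- pmin(pmax(k, min(block$key)), max(block$key))
    out$L[idx] <- stats::approx(block$key, block$L, xout = k, rule = 1)$y
    out$M[idx] <- stats::approx(block$key, block$M, xout = k, rule = 1)$y
    out$S[idx] <- stats::approx(block$key, block$S, xout = k, rule = 1)$y
  }
  out
}
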