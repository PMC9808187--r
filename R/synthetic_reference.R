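#' Synthetic LMS growth reference
#'
#' Builds a smooth, internally consistent LMS reference table covering ages
#' 0-60 completed months (height-for-age, weight-for-age, BMI-for-age) and
#' heights 38-150 cm (weight-for-height), for both sexes. The curves are
#' SYNTHETIC: they follow the broad shape of early-childhood growth (median
#' length ~50 cm at birth rising to ~110 cm at 59 months, median weight
#' ~3.3 kg rising to ~18 kg) but are not the WHO 2006 standard values, which
#' are distributed under their own terms. The table is intended for
#' simulation, testing and methods work; substitute the real standard (same
#' CSV layout) for substantive analyses.
#'
#' The BMI-for-age median is derived from the height and weight medians at
#' each age, keeping the four indicators mutually consistent so that a child
#' sitting on every median scores near zero on every index.
#'
#' @return Data frame with columns `indicator`, `sex`, `key`, `L`, `M`, `S`,
#'   valid under [validate_lms_reference()].
#' @export
#' @examples
#' ref <- synthetic_lms_reference()
#' lms_params(ref, "height_for_age", "male", 24)
synthetic_lms_reference <- function() {
  ages <- 0:60
  heights <- 38:150

  m_height <- function(a, sex) {
    b0 <- ifelse(sex == "male", 49.9, 49.1)
    b1 <- ifelse(sex == "male", 8.11, 8.02)
    b0 + b1 * (sqrt(a + 0.1) - sqrt(0.1))
  }
  m_weight <- function(a, sex) {
    w0 <- ifelse(sex == "male", 3.3, 3.2)
    w1 <- ifelse(sex == "male", 5.5, 5.1)
    w2 <- ifelse(sex == "male", 0.155, 0.150)
    w0 + w1 * (1 - exp(-a / 7)) + w2 * a
  }
  m_wfh <- function(h, sex) {
    a <- ifelse(sex == "male", 15.68, 15.40)
    a * (h / 100)^1.8
  }

  blocks <- list()
  for (s in c("male", "female")) {
    mh <- m_height(ages, s)
    mw <- m_weight(ages, s)
    blocks[[length(blocks) + 1]] <- data.frame(
      indicator = "height_for_age", sex = s, key = ages,
      L = 1, M = mh, S = 0.038)
    blocks[[length(blocks) + 1]] <- data.frame(
      indicator = "weight_for_age", sex = s, key = ages,
      L = -0.2, M = mw, S = 0.12)
    blocks[[length(blocks) + 1]] <- data.frame(
      indicator = "bmi_for_age", sex = s, key = ages,
      L = -1.2, M = mw / (mh / 100)^2, S = 0.08)
    blocks[[length(blocks) + 1]] <- data.frame(
      indicator = "weight_for_height", sex = s, key = heights,
      L = -0.35, M = m_wfh(heights, s), S = 0.082)
  }
  ref <- do.call(rbind, blocks)
  rownames(ref) <- NULL
  validate_lms_reference(ref)
  ref
}

#' Path to (or default copy of) the packaged synthetic reference
#'
#' Convenience loader: reads the CSV fixture shipped under `extdata` if
#' present, else rebuilds the table in memory.
#'
#' @return Validated LMS reference data frame.
#' @export
default_lms_reference <- function() {
  p <- system.file("extdata", "lms_reference_synthetic.csv", package = "eciaf")
  if (nzchar(p)) read_lms_reference(p) else synthetic_lms_reference()
}
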