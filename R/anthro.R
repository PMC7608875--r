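#' Read an LMS growth-reference table
#'
#' Reads a weight-for-height LMS reference from CSV. The table must have
#' columns `sex`, `height_cm`, `L`, `M`, `S`, with one row per (sex, height)
#' grid point; `M` (the median weight, kg) and `S` (coefficient of
#' variation) must be positive. Values between grid rows are obtained by
#' linear interpolation of L, M and S within sex.
#'
#' The package ships a small synthetic reference
#' (`system.file("extdata", "lms_reference_synthetic.csv", package =
#' "swdecomp")`) on a coarse 45-120 cm grid for testing and examples; for
#' real analyses supply a full growth-standard table in the same format.
#'
#' @param path Path to a CSV file with columns sex, height_cm, L, M, S.
#' @return An object of class `lms_reference` (a data frame).
#' @export
read_lms_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(ref, c("sex", "height_cm", "L", "M", "S"))
  if (any(ref$M <= 0) || any(ref$S <= 0))
    stop("LMS reference requires M > 0 and S > 0", call. = FALSE)
  ref <- ref[order(ref$sex, ref$height_cm), ]
  if (any(duplicated(ref[c("sex", "height_cm")])))
    stop("duplicated (sex, height) rows in LMS reference", call. = FALSE)
  class(ref) <- c("lms_reference", "data.frame")
  ref
}

#' Interpolate L, M, S at given heights
#' @noRd
lms_at <- function(ref, sex, height) {
  stopifnot(length(sex) == length(height))
  out <- matrix(NA_real_, length(height), 3,
                dimnames = list(NULL, c("L", "M", "S")))
  for (s in unique(sex)) {
    idx <- which(sex == s)
    sub <- ref[ref$sex == s, ]
    if (!nrow(sub))
      stop(sprintf("sex '%s' not present in LMS reference", s), call. = FALSE)
    h <- height[idx]
    if (any(h < min(sub$height_cm) - 1e-9 | h > max(sub$height_cm) + 1e-9))
      stop(sprintf(
        "height outside LMS reference coverage [%g, %g] cm for sex '%s'",
        min(sub$height_cm), max(sub$height_cm), s), call. = FALSE)
    for (v in c("L", "M", "S"))
      out[idx, v] <- stats::approx(sub$height_cm, sub[[v]], xout = h,
                                   rule = 1)$y
  }
  out
}

#' Weight at a given z-score under LMS parameters (inverse transform)
#' @noRd
lms_inverse <- function(L, M, S, z) {
  ifelse(abs(L) < 1e-12, M * exp(S * z), M * (1 + L * S * z)^(1 / L))
}

#' Weight-for-height z-score from an LMS reference
#'
#' Converts weight to a z-score against the reference median for the
#' child's sex and height: `z = ((weight/M)^L - 1) / (L*S)` for `L != 0`
#' and `z = log(weight/M)/S` for `L = 0`.
#'
#' Beyond three standard deviations the LMS transformation is replaced by
#' the restricted (linear-tail) adjustment used with growth standards: for
#' raw z above 3, `z = 3 + (weight - SD3)/(SD3 - SD2)`; for raw z below
#' -3, `z = -3 + (weight - SD(-3))/(SD(-2) - SD(-3))`, where `SD(k)` is
#' the weight at z-score k under the LMS parameters. This keeps extreme
#' z-scores on an interpretable linear scale.
#'
#' @param weight Weight in kg (positive).
#' @param height Height/length in cm, within reference coverage.
#' @param sex Sex codes matching the reference table (e.g. "male",
#'   "female"); recycled if length 1.
#' @param ref An [read_lms_reference()] object.
#' @param adjust Apply the restricted adjustment beyond |z| > 3
#'   (default `TRUE`).
#' @return Numeric vector of z-scores.
#' @seealso [flag_severe_wasting()]
#' @export
whz_zscore <- function(weight, height, sex, ref, adjust = TRUE) {
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weight must be positive and finite", call. = FALSE)
  if (length(sex) == 1L) sex <- rep(sex, length(weight))
  stopifnot(length(weight) == length(height))
  p <- lms_at(ref, sex, height)
  L <- p[, "L"]; M <- p[, "M"]; S <- p[, "S"]
  z <- ifelse(abs(L) < 1e-12,
              log(weight / M) / S,
              ((weight / M)^L - 1) / (L * S))
  if (adjust) {
    hi <- !is.na(z) & z > 3
    lo <- !is.na(z) & z < -3
    if (any(hi)) {
      sd3 <- lms_inverse(L[hi], M[hi], S[hi], 3)
      sd2 <- lms_inverse(L[hi], M[hi], S[hi], 2)
      z[hi] <- 3 + (weight[hi] - sd3) / (sd3 - sd2)
    }
    if (any(lo)) {
      sd3n <- lms_inverse(L[lo], M[lo], S[lo], -3)
      sd2n <- lms_inverse(L[lo], M[lo], S[lo], -2)
      z[lo] <- -3 + (weight[lo] - sd3n) / (sd2n - sd3n)
    }
  }
  unname(z)
}

#' Flag severe wasting from weight-for-height z-scores
#'
#' A child is flagged as severely wasted when the weight-for-height
#' z-score is strictly below the cutoff (default -3 SD) *and* the z-score
#' is biologically plausible. Records with `|z|` beyond `plausible_limit`
#' (default 5, the standard weight-for-height flagging bound) are treated
#' as measurement errors: they are never flagged as severe wasting and
#' should be excluded from prevalence denominators via [whz_flags()].
#'
#' @param z Numeric z-scores (finite).
#' @param cutoff Severity cutoff, default -3 (strict `<`).
#' @param plausible_limit Absolute z bound beyond which a record is
#'   implausible, default 5.
#' @return Logical vector.
#' @export
flag_severe_wasting <- function(z, cutoff = -3, plausible_limit = 5) {
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  plausible <- abs(z) <= plausible_limit
  (z < cutoff) & plausible
}

#' Z-score, plausibility and severe-wasting flag in one table
#'
#' @inheritParams flag_severe_wasting
#' @return Data frame with columns `z`, `plausible`, `severe_wasting`.
#' @export
whz_flags <- function(z, cutoff = -3, plausible_limit = 5) {
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  plausible <- abs(z) <= plausible_limit
  data.frame(z = z, plausible = plausible,
             severe_wasting = (z < cutoff) & plausible)
}
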