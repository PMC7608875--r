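# Internal helpers shared across modules.

#' Weighted mean with positive-weight check
#' @noRd
wmean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(x) == length(w))
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  sum(w * x) / sum(w)
}

#' Weighted standard deviation (population denominator sum(w))
#' @noRd
wsd <- function(x, w) {
  m <- wmean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

#' Lower-boundary weighted quantile: smallest x with cumulative weight
#' share >= p, after sorting by x.
#' @noRd
wquantile <- function(x, w, p) {
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(w[ord]) / sum(w)
  vapply(p, function(pp) xs[which(cs >= pp - 1e-12)[1]], numeric(1))
}

#' Assign weight-balanced quantile groups (1 = lowest score).
#' Ties at a cut point share the lower group: group = 1 + #cuts strictly
#' below the score.
#' @noRd
wquantile_groups <- function(x, w, k = 5L) {
  cuts <- wquantile(x, w, seq_len(k - 1L) / k)
  1L + vapply(x, function(v) sum(v > cuts), integer(1))
}

#' @noRd
check_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(sprintf("'%s' must be a probability in [0, 1]", what), call. = FALSE)
  invisible(p)
}

#' @noRd
check_count <- function(n, what) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop(sprintf("'%s' must be a single integer >= 1", what), call. = FALSE)
  invisible(as.integer(n))
}

#' @noRd
check_columns <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(data)
}

#' Format percentages to one decimal, as in published summary tables
#' @noRd
fmt_pct <- function(x) sprintf("%.1f", x)
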