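#' Survey-weighted prevalence
#'
#' Weighted prevalence of a binary outcome, in percent:
#' `100 * sum(w*y) / sum(w)`.
#'
#' @param y Binary (0/1 or logical) outcome vector.
#' @param w Positive weights (default equal).
#' @param label Optional subgroup label used in error messages.
#' @return Prevalence in percent.
#' @export
weighted_prevalence <- function(y, w = NULL, label = "subgroup") {
  y <- as.numeric(y)
  if (!length(y))
    stop(sprintf("cannot estimate a prevalence for empty %s", label),
         call. = FALSE)
  if (is.null(w)) w <- rep(1, length(y))
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  100 * wmean(y, w)
}

#' Poor/non-poor risk difference per 1000 children
#'
#' Converts two prevalences in percent into a risk difference per 1000:
#' `(prev_poor - prev_nonpoor) * 10`. Positive values indicate pro-poor
#' inequality (the outcome is concentrated among children from poor
#' households); negative values indicate pro-non-poor inequality.
#'
#' @param prev_poor,prev_nonpoor Prevalences in percent, in \[0, 100\].
#' @return Risk difference per 1000 children.
#' @examples
#' risk_difference(12.3, 8.4)  # pro-poor, 39 per 1000
#' @export
risk_difference <- function(prev_poor, prev_nonpoor) {
  if (any(prev_poor < 0 | prev_poor > 100) ||
      any(prev_nonpoor < 0 | prev_nonpoor > 100))
    stop("prevalences must be in [0, 100] percent", call. = FALSE)
  (prev_poor - prev_nonpoor) * 10
}

#' Per-country risk-difference inference
#'
#' Estimates the weighted severe-wasting prevalence overall and by wealth
#' group for one country, the poor/non-poor risk difference per 1000
#' children, and its uncertainty. The default variance estimator is a
#' cluster-robust (PSU-level) Taylor linearization of the two weighted
#' prevalences, appropriate for multi-stage surveys where children are
#' sampled within clusters; `variance = "binomial"` gives the plain
#' independent-binomial variance for comparison.
#'
#' @param records Data frame with one row per child.
#' @param outcome,group,weight,cluster Column names for the binary
#'   outcome, wealth dichotomy (levels poor / non-poor), sampling weight
#'   and PSU id.
#' @param conf Confidence level (default 0.95).
#' @param variance `"cluster"` (default) or `"binomial"`.
#' @param country Optional country label carried into the result.
#' @return One-row data frame of class `country_inequality`: `country`,
#'   `n`, `prev_all`, `prev_poor`, `prev_nonpoor` (percent), `rd`, `se`,
#'   `lcl`, `ucl` (per 1000) and `significant` (CI excludes 0).
#' @export
rd_inference <- function(records, outcome = "severe_wasting",
                         group = "wealth", weight = "weight",
                         cluster = "cluster", conf = 0.95,
                         variance = c("cluster", "binomial"),
                         country = NA_character_) {
  variance <- match.arg(variance)
  check_columns(records, c(outcome, group, weight, cluster))
  y <- as.numeric(records[[outcome]])
  g <- as.character(records[[group]])
  w <- records[[weight]]
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  pn <- sum(g == "poor"); nn <- sum(g == "non-poor")
  if (pn == 0L || nn == 0L)
    stop(sprintf("wealth group '%s' absent in country '%s'",
                 if (pn == 0L) "poor" else "non-poor", country),
         call. = FALSE)

  prev_all <- weighted_prevalence(y, w)
  prev_poor <- weighted_prevalence(y[g == "poor"], w[g == "poor"], "poor")
  prev_np <- weighted_prevalence(y[g == "non-poor"], w[g == "non-poor"],
                                 "non-poor")
  rd <- risk_difference(prev_poor, prev_np)

  # variance of p_poor - p_nonpoor on the proportion scale
  if (variance == "cluster") {
    ip <- g == "poor"; inp <- !ip
    Wp <- sum(w[ip]); Wnp <- sum(w[inp])
    # linearized contribution of each record to the RD (ratio estimators)
    d <- numeric(nrow(records))
    d[ip] <- w[ip] * (y[ip] - prev_poor / 100) / Wp
    d[inp] <- -w[inp] * (y[inp] - prev_np / 100) / Wnp
    dc <- as.vector(rowsum(d, records[[cluster]]))
    k <- length(dc)
    if (k < 2L) stop("cluster-robust variance needs >= 2 clusters", call. = FALSE)
    v <- k / (k - 1) * sum((dc - mean(dc))^2)
  } else {
    v <- prev_poor / 100 * (1 - prev_poor / 100) / pn +
      prev_np / 100 * (1 - prev_np / 100) / nn
  }
  se <- sqrt(v) * 1000  # per-1000 scale
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  lcl <- rd - zq * se
  ucl <- rd + zq * se
  out <- data.frame(country = country, n = nrow(records),
                    prev_all = prev_all, prev_poor = prev_poor,
                    prev_nonpoor = prev_np, rd = rd, se = se,
                    lcl = lcl, ucl = ucl,
                    significant = (lcl > 0 | ucl < 0))
  class(out) <- c("country_inequality", "data.frame")
  out
}

#' Breslow-Day test of odds-ratio homogeneity (Tarone-corrected)
#'
#' Tests whether the odds ratio is constant across K 2x2 strata, as used
#' to flag countries whose poor/non-poor association differs across
#' strata. The statistic compares each stratum's observed `a` cell with
#' its conditional expectation under the Mantel-Haenszel common odds
#' ratio, with Tarone's correction, and is referred to a chi-squared
#' distribution with K - 1 degrees of freedom.
#'
#' @param tables A 2x2xK array (rows: exposure poor/non-poor; columns:
#'   outcome yes/no), or a list of 2x2 matrices.
#' @param correct Add 0.5 to every cell of strata containing a zero
#'   margin (default `TRUE`). Strata with an empty row or column after
#'   correction are dropped.
#' @return An object of class `htest` with the statistic, df and p-value.
#' @export
homogeneity_test <- function(tables, correct = TRUE) {
  if (is.list(tables)) tables <- simplify2array(tables)
  if (length(dim(tables)) != 3L || any(dim(tables)[1:2] != 2L))
    stop("tables must be a 2x2xK array or list of 2x2 matrices", call. = FALSE)
  K0 <- dim(tables)[3]
  keep <- logical(K0)
  for (k in seq_len(K0)) {
    t2 <- tables[, , k]
    if (correct && any(rowSums(t2) == 0 | colSums(t2) == 0) && sum(t2) > 0)
      tables[, , k] <- t2 <- t2 + 0.5
    keep[k] <- all(rowSums(t2) > 0) && all(colSums(t2) > 0)
  }
  tables <- tables[, , keep, drop = FALSE]
  K <- dim(tables)[3]
  if (K < 2L)
    stop("homogeneity test requires >= 2 non-degenerate strata (df = K - 1)",
         call. = FALSE)

  a <- tables[1, 1, ]; b <- tables[1, 2, ]
  c_ <- tables[2, 1, ]; d <- tables[2, 2, ]
  or_mh <- sum(a * d / (a + b + c_ + d)) / sum(b * c_ / (a + b + c_ + d))

  stat <- 0; corr_num <- 0; corr_den <- 0
  for (k in seq_len(K)) {
    r1 <- a[k] + b[k]; c1 <- a[k] + c_[k]; n <- a[k] + b[k] + c_[k] + d[k]
    # conditional expectation of a under common OR: quadratic in e
    if (abs(or_mh - 1) < 1e-12) {
      e <- r1 * c1 / n
    } else {
      A <- or_mh - 1
      B <- -((r1 + c1) * or_mh + (n - r1 - c1))
      C <- or_mh * r1 * c1
      disc <- sqrt(pmax(B^2 - 4 * A * C, 0))
      e1 <- (-B + disc) / (2 * A)
      e2 <- (-B - disc) / (2 * A)
      ok <- function(e) e > max(0, r1 + c1 - n) - 1e-9 && e < min(r1, c1) + 1e-9
      e <- if (ok(e2)) e2 else e1
    }
    v <- 1 / (1 / e + 1 / (r1 - e) + 1 / (c1 - e) + 1 / (n - r1 - c1 + e))
    stat <- stat + (a[k] - e)^2 / v
    corr_num <- corr_num + (a[k] - e)
    corr_den <- corr_den + v
  }
  stat_tarone <- stat - corr_num^2 / corr_den
  df <- K - 1
  p <- stats::pchisq(stat_tarone, df, lower.tail = FALSE)
  structure(list(statistic = c("Breslow-Day (Tarone)" = stat_tarone),
                 parameter = c(df = df), p.value = p,
                 estimate = c("common OR (MH)" = or_mh),
                 method = "Breslow-Day test of homogeneity of odds ratios with Tarone correction",
                 data.name = deparse(substitute(tables))),
            class = "htest")
}

#' Build per-stratum 2x2 tables of outcome by wealth group
#'
#' Tabulates unweighted counts of (poor/non-poor) x (case/non-case) for
#' each stratum (by default the survey cluster), for use with
#' [homogeneity_test()].
#'
#' @inheritParams rd_inference
#' @param stratum Column defining the strata (default `cluster`).
#' @return A 2x2xK array.
#' @export
strata_tables <- function(records, outcome = "severe_wasting",
                          group = "wealth", stratum = "cluster") {
  check_columns(records, c(outcome, group, stratum))
  g <- factor(as.character(records[[group]]), levels = c("poor", "non-poor"))
  y <- factor(as.numeric(records[[outcome]]), levels = c(1, 0))
  tab <- table(g, y, records[[stratum]])
  array(tab, dim = dim(tab))
}

#' DerSimonian-Laird random-effects pooling of country risk differences
#'
#' Pools per-country risk differences by inverse-variance random-effects
#' meta-analysis with the DerSimonian-Laird moment estimator of the
#' between-country variance tau^2, giving the overall poor/non-poor risk
#' difference irrespective of country of residence.
#'
#' @param rd Country risk differences (per 1000).
#' @param se Their standard errors (same scale, finite, not all zero).
#' @param labels Optional country labels.
#' @param conf Confidence level (default 0.95).
#' @return List of class `meta_result`: `pooled`, `se`, `lcl`, `ucl`,
#'   `tau2`, `weights` (normalized random-effects weights) and `k`.
#' @export
pool_random_effects <- function(rd, se, labels = NULL, conf = 0.95) {
  ok <- is.finite(rd) & is.finite(se)
  rd <- rd[ok]; se <- se[ok]
  if (!length(rd)) stop("no countries with finite RD and SE", call. = FALSE)
  if (all(se == 0))
    stop("degenerate variances: all standard errors are zero", call. = FALSE)
  fit <- metafor::rma.uni(yi = rd, sei = se, method = "DL",
                          level = conf * 100)
  wts <- 1 / (se^2 + fit$tau2)
  out <- list(pooled = as.numeric(fit$beta), se = fit$se,
              lcl = fit$ci.lb, ucl = fit$ci.ub, tau2 = fit$tau2,
              weights = wts / sum(wts), k = length(rd),
              labels = if (is.null(labels)) NULL else labels[ok])
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Random-effects (DerSimonian-Laird) pooled RD: %.2f per 1000 (95%% CI %.2f to %.2f)\n",
    x$pooled, x$lcl, x$ucl))
  cat(sprintf("tau^2 = %.3f across %d countries\n", x$tau2, x$k))
  invisible(x)
}

#' Classify countries by prevalence level and direction of inequality
#'
#' Places each country in one of four quadrants: severe-wasting
#' prevalence low/high crossed with pro-poor (RD > 0) versus pro-non-poor
#' (RD <= 0) inequality. The default prevalence threshold is the mean of
#' the country prevalences, each country counting once; prevalence
#' strictly above the threshold is "high". (The mean, rather than a
#' median, separates the handful of high-burden countries from the long
#' tail of low-prevalence ones in right-skewed prevalence distributions.)
#'
#' @param prevalence Country prevalences in percent.
#' @param rd Country risk differences per 1000.
#' @param threshold High/low prevalence cut (default mean of
#'   `prevalence`).
#' @param labels Optional country labels.
#' @return Data frame of class `quadrant_label` with `country`, `level`
#'   (low/high), `inequality` (pro-poor/pro-non-poor) and `label`.
#' @export
classify_quadrant <- function(prevalence, rd, threshold = NULL,
                              labels = NULL) {
  stopifnot(length(prevalence) == length(rd))
  if (is.null(threshold)) threshold <- mean(prevalence)
  level <- ifelse(prevalence > threshold, "high", "low")
  ineq <- ifelse(rd > 0, "pro-poor", "pro-non-poor")
  out <- data.frame(
    country = if (is.null(labels)) seq_along(rd) else labels,
    level = level, inequality = ineq,
    label = paste0(level, " SW / ", ineq))
  class(out) <- c("quadrant_label", "data.frame")
  out
}
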