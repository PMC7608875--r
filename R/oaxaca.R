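# Blinder-Oaxaca decomposition of the poor/non-poor outcome gap.
#
# Group convention throughout: A = poor, B = non-poor, gap = Ybar_A -
# Ybar_B. The threefold decomposition is taken from the viewpoint of
# group B (covariate differences weighted by group B's coefficients).

#' Build a design matrix for decomposition fits
#'
#' Categorical covariates are expanded with deviation (sum-to-zero)
#' contrasts by default, which makes per-covariate detailed contributions
#' invariant to the choice of omitted category; `normalization =
#' "treatment"` gives conventional dummy coding, whose detailed
#' contributions depend on the omitted base category (a warning is
#' issued).
#'
#' @noRd
build_design <- function(data, covariates, normalization = "deviation",
                         warn = TRUE) {
  check_columns(data, covariates)
  df <- data[covariates]
  for (v in covariates)
    if (is.character(df[[v]]) || is.logical(df[[v]]))
      df[[v]] <- factor(df[[v]])
  if (normalization == "treatment" && warn &&
      any(vapply(df, is.factor, logical(1))))
    warning("treatment (dummy) coding: detailed contributions depend on the omitted base category",
            call. = FALSE)
  ctr <- if (normalization == "deviation") "contr.sum" else "contr.treatment"
  contrasts <- lapply(df[vapply(df, is.factor, logical(1))],
                      function(x) ctr)
  f <- stats::reformulate(covariates)
  mm <- stats::model.matrix(f, df, contrasts.arg =
                              if (length(contrasts)) contrasts else NULL)
  mm
}

#' Fit a group-specific outcome model for decomposition
#'
#' Fits the outcome model for one wealth group: weighted least squares
#' for `link = "identity"` or weighted maximum-likelihood logistic
#' regression for `link = "logit"`. The fitted object carries the
#' coefficient vector, the weighted covariate means (with a leading 1 for
#' the constant), the weighted mean outcome, the coefficient covariance
#' and the design matrix, which together are all the decomposition needs.
#'
#' @param data Data frame with the records of one wealth group.
#' @param outcome Name of the binary (or numeric) outcome column.
#' @param covariates Character vector of covariate columns; categorical
#'   columns are expanded per `normalization`.
#' @param weights Name of the weight column, or NULL for equal weights.
#' @param link `"logit"` (default) or `"identity"`.
#' @param group Group label carried into the object (e.g. "poor").
#' @param normalization `"deviation"` (sum-to-zero, default) or
#'   `"treatment"` dummy coding for categorical covariates.
#' @return Object of class `group_model`.
#' @export
fit_group_model <- function(data, outcome, covariates, weights = NULL,
                            link = c("logit", "identity"),
                            group = NA_character_,
                            normalization = c("deviation", "treatment")) {
  link <- match.arg(link)
  normalization <- match.arg(normalization)
  check_columns(data, outcome)
  y <- as.numeric(data[[outcome]])
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  X <- build_design(data, covariates, normalization)
  fit_group_model_xy(X, y, w, link, group)
}

#' Fit from a prebuilt design matrix (internal workhorse)
#' @noRd
fit_group_model_xy <- function(X, y, w, link, group = NA_character_) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)),
                                   qrX$pivot[seq_len(qrX$rank)])]
    stop("collinear design: aliased column(s) ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (link == "logit") {
    if (all(y == 0) || all(y == 1))
      stop(sprintf("group '%s' has no %s: logistic fit impossible", group,
                   if (all(y == 0)) "events" else "non-events"),
           call. = FALSE)
    fit <- stats::glm.fit(X, y, weights = w,
                          family = stats::quasibinomial(),
                          control = stats::glm.control(epsilon = 1e-12,
                                                       maxit = 200))
    if (!fit$converged || max(abs(fit$linear.predictors)) > 30) {
      culprit <- names(which.max(abs(fit$coefficients[-1])))
      stop("possible complete separation (covariate ", culprit,
           "): logistic estimates unbounded", call. = FALSE)
    }
    beta <- fit$coefficients
    vc <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
    converged <- fit$converged
  } else {
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    r <- y - drop(X %*% beta)
    sigma2 <- sum(w * r^2) / (length(y) - ncol(X))
    vc <- sigma2 * chol2inv(chol(crossprod(X * sqrt(w))))
    converged <- TRUE
  }
  dimnames(vc) <- list(names(beta), names(beta))
  out <- list(group = group, link = link, coef = beta,
              xbar = drop(crossprod(X, w)) / sum(w),
              ybar = wmean(y, w), vcov = vc, n = length(y),
              X = X, y = y, w = w,
              assign = attr(X, "assign"), converged = converged)
  class(out) <- "group_model"
  out
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("Group model [%s], link = %s, n = %d, weighted mean outcome = %.4f\n",
              x$group, x$link, x$n, x$ybar))
  print(round(x$coef, 4))
  invisible(x)
}

#' @noRd
linkinv <- function(eta, link)
  if (link == "logit") stats::plogis(eta) else eta

#' Mean prediction under coefficients `beta`:
#' record-level weighted average ("population") or link applied to the
#' mean covariate vector ("at_means").
#' @noRd
mean_prediction <- function(model, beta, scheme) {
  if (scheme == "at_means" || model$link == "identity")
    linkinv(sum(model$xbar * beta), model$link)
  else
    wmean(linkinv(drop(model$X %*% beta), model$link), model$w)
}

#' @noRd
check_compatible <- function(model_A, model_B) {
  if (!identical(model_A$link, model_B$link))
    stop("group models must share the same link", call. = FALSE)
  if (!identical(names(model_A$coef), names(model_B$coef)))
    stop("group models have mismatched covariate sets: ",
         paste(union(setdiff(names(model_A$coef), names(model_B$coef)),
                     setdiff(names(model_B$coef), names(model_A$coef))),
               collapse = ", "), call. = FALSE)
}

#' The gap being decomposed. The observed weighted outcome gap, except
#' in the logit at-the-means scheme, where the gap is the model-implied
#' at-the-means gap F(xbar_A' beta_A) - F(xbar_B' beta_B): components
#' and gap must share an evaluation scheme for the additivity and
#' regrouping identities to be exact. (For converged ML fits the two
#' gaps differ only by the Jensen gap between the mean prediction and
#' the prediction at the mean.)
#' @noRd
decomposition_gap <- function(model_A, model_B, scheme) {
  if (model_A$link == "logit" && scheme == "at_means")
    mean_prediction(model_A, model_A$coef, "at_means") -
      mean_prediction(model_B, model_B$coef, "at_means")
  else
    model_A$ybar - model_B$ybar
}

#' Map Yun weights onto an aggregate component; exact elementwise terms
#' under the identity link are handled by the callers.
#' @noRd
yun_detail <- function(elementwise, aggregate, what) {
  den <- sum(elementwise)
  if (abs(den) < 1e-12) {
    if (abs(aggregate) < 1e-10) return(elementwise * 0)
    stop("Yun weights undefined for the ", what,
         " component: elementwise terms sum to zero while the aggregate is nonzero",
         call. = FALSE)
  }
  elementwise / den * aggregate
}

#' Threefold Blinder-Oaxaca decomposition
#'
#' Splits the poor/non-poor gap in mean outcomes, `gap = Ybar_A -
#' Ybar_B`, into endowments (E), coefficients (C) and interaction (I),
#' from the viewpoint of group B:
#' `E = (Xbar_A - Xbar_B)' beta_B`, `C = Xbar_B' (beta_A - beta_B)`,
#' `I = (Xbar_A - Xbar_B)' (beta_A - beta_B)`.
#'
#' Under the logit link the components are defined on the probability
#' scale through counterfactual mean predictions:
#' `E = P(X_A, beta_B) - P(X_B, beta_B)`,
#' `C = P(X_B, beta_A) - P(X_B, beta_B)`, and `I = gap - E - C`, where
#' `P(X, beta)` is either the weighted mean of record-level predicted
#' probabilities (`scheme = "population"`, default) or the logistic
#' function applied to the mean covariate vector (`scheme =
#' "at_means"`). The interaction closes the identity `E + C + I = gap`
#' by construction in both schemes.
#'
#' Per-covariate detail is exact elementwise under the identity link and
#' allocated by Yun's weights (normalized at-the-means linear terms)
#' under the logit link; any closure residual is assigned to the
#' intercept's interaction/coefficients term.
#'
#' @param model_A,model_B [fit_group_model()] objects for the poor (A)
#'   and non-poor (B) groups, sharing link and covariate ordering.
#' @param scheme `"population"` or `"at_means"` (logit only).
#' @return Object of class `oaxaca_threefold` with `gap`, `E`, `C`, `I`,
#'   a column-level `detail` data frame and a term-level `detail_terms`.
#' @export
decompose_threefold <- function(model_A, model_B,
                                scheme = c("population", "at_means")) {
  scheme <- match.arg(scheme)
  check_compatible(model_A, model_B)
  link <- model_A$link
  gap <- decomposition_gap(model_A, model_B, scheme)
  dx <- model_A$xbar - model_B$xbar
  db <- model_A$coef - model_B$coef

  if (link == "identity") {
    Ek <- dx * model_B$coef
    Ck <- model_B$xbar * db
    Ik <- dx * db
    E <- sum(Ek); C <- sum(Ck); I <- gap - E - C
    # closure residual (WLS fitted-mean identity) goes to the intercept
    Ik[1] <- Ik[1] + (I - sum(Ik))
  } else {
    E <- mean_prediction(model_A, model_B$coef, scheme) -
      mean_prediction(model_B, model_B$coef, scheme)
    C <- mean_prediction(model_B, model_A$coef, scheme) -
      mean_prediction(model_B, model_B$coef, scheme)
    I <- gap - E - C
    Ek <- yun_detail(dx * model_B$coef, E, "endowment")
    Ck <- yun_detail(model_B$xbar * db, C, "coefficients")
    Ik <- yun_detail(dx * db, I, "interaction")
  }
  detail <- data.frame(column = names(model_A$coef),
                       term = term_of(model_A),
                       E = Ek, C = Ck, I = Ik, row.names = NULL)
  out <- list(gap = gap, E = E, C = C, I = I, link = link,
              scheme = scheme, detail = detail,
              detail_terms = roll_terms(detail, c("E", "C", "I")))
  class(out) <- "oaxaca_threefold"
  out
}

#' Twofold Blinder-Oaxaca decomposition
#'
#' Splits the gap into an explained ("quantity") part Q and an
#' unexplained part U relative to a nondiscriminatory reference
#' coefficient vector `beta*`:
#' `Q = (Xbar_A - Xbar_B)' beta*` and
#' `U = Xbar_A'(beta_A - beta*) + Xbar_B'(beta* - beta_B)`.
#' `beta*` is chosen as group B's coefficients (`reference = "B"`,
#' default: no discrimination against the non-poor), group A's
#' (`reference = "A"`), or the coefficients of a pooled fit over both
#' groups (`reference = "pooled"`, including a group-membership indicator
#' unless `pooled_group_indicator = FALSE`).
#'
#' Under the logit link the probability-scale analogue is used:
#' `Q = P(X_A, beta*) - P(X_B, beta*)`, `U = gap - Q` (see
#' [decompose_threefold()] for the `scheme` argument). With `reference =
#' "B"` the twofold split regroups the threefold as `(Q, U) = (E, C +
#' I)`; with `reference = "A"`, `(Q, U) = (E + I, C)`.
#'
#' @inheritParams decompose_threefold
#' @param reference `"B"`, `"A"` or `"pooled"`.
#' @param pooled_group_indicator Include a group indicator in the pooled
#'   reference fit (default `TRUE`).
#' @return Object of class `oaxaca_twofold` with `gap`, `Q`, `U`,
#'   `reference`, `beta_star`, column-level `detail` and term-level
#'   `detail_terms`.
#' @export
decompose_twofold <- function(model_A, model_B,
                              reference = c("B", "A", "pooled"),
                              scheme = c("population", "at_means"),
                              pooled_group_indicator = TRUE) {
  reference <- match.arg(reference)
  scheme <- match.arg(scheme)
  check_compatible(model_A, model_B)
  link <- model_A$link
  beta_star <- switch(reference,
    B = model_B$coef,
    A = model_A$coef,
    pooled = pooled_coefficients(model_A, model_B, pooled_group_indicator))
  gap <- decomposition_gap(model_A, model_B, scheme)
  dx <- model_A$xbar - model_B$xbar
  uk <- model_A$xbar * (model_A$coef - beta_star) +
    model_B$xbar * (beta_star - model_B$coef)

  if (link == "identity") {
    Qk <- dx * beta_star
    Q <- sum(Qk); U <- gap - Q
    uk[1] <- uk[1] + (U - sum(uk))  # closure residual to the intercept
    Uk <- uk
  } else {
    Q <- mean_prediction(model_A, beta_star, scheme) -
      mean_prediction(model_B, beta_star, scheme)
    U <- gap - Q
    Qk <- yun_detail(dx * beta_star, Q, "explained")
    Uk <- yun_detail(uk, U, "unexplained")
  }
  detail <- data.frame(column = names(model_A$coef),
                       term = term_of(model_A),
                       Q = Qk, U = Uk, row.names = NULL)
  out <- list(gap = gap, Q = Q, U = U, reference = reference,
              beta_star = beta_star, link = link, scheme = scheme,
              detail = detail,
              detail_terms = roll_terms(detail, c("Q", "U")))
  class(out) <- "oaxaca_twofold"
  out
}

#' Coefficients of the weighted stacked (pooled) fit
#' @noRd
pooled_coefficients <- function(model_A, model_B, group_indicator = TRUE) {
  X <- rbind(model_A$X, model_B$X)
  if (group_indicator)
    X <- cbind(X, .group = rep(c(1, 0), c(model_A$n, model_B$n)))
  y <- c(model_A$y, model_B$y)
  w <- c(model_A$w, model_B$w)
  fit <- fit_group_model_xy(X, y, w, model_A$link, "pooled")
  beta <- fit$coef
  beta[setdiff(names(beta), ".group")]
}

#' @noRd
term_of <- function(model) {
  a <- model$assign
  cols_n <- length(model$coef)
  # hand-built design matrices carry no assign: treat each column as a term
  if (is.null(a)) a <- c(0L, seq_len(cols_n - 1L))
  out <- character(length(a))
  out[a == 0L] <- "(Intercept)"
  # recover term labels from column names when term.labels are absent
  cols <- names(model$coef)
  for (i in which(a > 0L)) out[i] <- term_label_guess(cols[i], a, i, cols)
  out
}

#' @noRd
term_label_guess <- function(col, assign, i, cols) {
  same <- cols[assign == assign[i]]
  prefix <- longest_common_prefix(same)
  if (nzchar(prefix)) prefix else col
}

#' @noRd
longest_common_prefix <- function(x) {
  if (length(x) == 1L) return(sub("[0-9]+$", "", x))
  p <- x[1]
  for (s in x[-1]) {
    while (nzchar(p) && substr(s, 1, nchar(p)) != p)
      p <- substr(p, 1, nchar(p) - 1L)
  }
  p
}

#' @export
print.oaxaca_threefold <- function(x, digits = 4, ...) {
  cat(sprintf("Threefold decomposition (%s link, %s scheme)\n", x$link,
              x$scheme))
  cat(sprintf("  gap = %.*f  (poor - non-poor)\n", digits, x$gap))
  cat(sprintf("  endowments   E = %.*f\n  coefficients C = %.*f\n  interaction  I = %.*f\n",
              digits, x$E, digits, x$C, digits, x$I))
  invisible(x)
}

#' @export
print.oaxaca_twofold <- function(x, digits = 4, ...) {
  cat(sprintf("Twofold decomposition (%s link, reference = %s)\n", x$link,
              x$reference))
  cat(sprintf("  gap = %.*f\n  explained   Q = %.*f\n  unexplained U = %.*f\n",
              digits, x$gap, digits, x$Q, digits, x$U))
  invisible(x)
}

#' Per-covariate contributions of a decomposition
#'
#' Returns the per-covariate detail of a two- or threefold decomposition
#' as a tidy table with each component's contribution and its share of
#' the total gap. `by = "term"` (default) aggregates the expanded
#' contrast columns of a categorical covariate into a single row;
#' `by = "column"` keeps one row per design-matrix column.
#'
#' @param decomposition An `oaxaca_threefold` or `oaxaca_twofold` object.
#' @param by `"term"` or `"column"`.
#' @return Data frame with `term` (or `column`), one column per
#'   component, and `share_*` columns (component / gap).
#' @export
detailed_contributions <- function(decomposition, by = c("term", "column")) {
  by <- match.arg(by)
  comps <- if (inherits(decomposition, "oaxaca_threefold")) c("E", "C", "I")
           else if (inherits(decomposition, "oaxaca_twofold")) c("Q", "U")
           else stop("not a decomposition object", call. = FALSE)
  d <- if (by == "term") decomposition$detail_terms else decomposition$detail
  for (cc in comps)
    d[[paste0("share_", cc)]] <- if (abs(decomposition$gap) > 0)
      d[[cc]] / decomposition$gap else NA_real_
  d
}

#' @noRd
roll_terms <- function(detail, comps) {
  agg <- stats::aggregate(detail[comps], list(term = detail$term), sum)
  agg[order(match(agg$term, unique(detail$term))), , drop = FALSE]
}

#' Model-implied gap on the probability scale
#'
#' The weighted mean predicted probability of group A under its own
#' covariates and coefficients minus the same for group B. For a
#' converged weighted ML logistic fit with an intercept this equals the
#' raw weighted prevalence gap (the score equations force the weighted
#' mean fitted probability to match the weighted mean outcome).
#'
#' @inheritParams decompose_threefold
#' @return The gap on the probability scale.
#' @export
nonlinear_gap <- function(model_A, model_B) {
  check_compatible(model_A, model_B)
  mean_prediction(model_A, model_A$coef, "population") -
    mean_prediction(model_B, model_B$coef, "population")
}

#' One-call decomposition from raw records
#'
#' Convenience wrapper: builds a common design (factor levels taken from
#' the full data so both groups share columns), fits the two group
#' models and returns the requested decomposition.
#'
#' @param data Data frame containing both wealth groups.
#' @param outcome,covariates,weights,link,normalization As in
#'   [fit_group_model()].
#' @param group Name of the group column; must contain exactly the
#'   levels `poor` and `non-poor` (A = poor, B = non-poor).
#' @param type `"threefold"` or `"twofold"`.
#' @param reference,scheme Passed to the decomposition.
#' @return The decomposition object, with the two `group_model`s attached
#'   as attributes `model_A` and `model_B`.
#' @export
oaxaca_decompose <- function(data, outcome, covariates, group = "wealth",
                             weights = NULL,
                             link = c("logit", "identity"),
                             type = c("threefold", "twofold"),
                             reference = "B",
                             scheme = c("population", "at_means"),
                             normalization = c("deviation", "treatment")) {
  link <- match.arg(link); type <- match.arg(type)
  scheme <- match.arg(scheme)
  normalization <- match.arg(normalization)
  check_columns(data, c(outcome, group))
  g <- as.character(data[[group]])
  if (!all(g %in% c("poor", "non-poor")))
    stop("group column must contain only 'poor' and 'non-poor'", call. = FALSE)
  X <- build_design(data, covariates, normalization)
  y <- as.numeric(data[[outcome]])
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  iA <- g == "poor"
  mA <- fit_group_model_xy(X[iA, , drop = FALSE], y[iA], w[iA], link, "poor")
  mB <- fit_group_model_xy(X[!iA, , drop = FALSE], y[!iA], w[!iA], link,
                           "non-poor")
  out <- if (type == "threefold") decompose_threefold(mA, mB, scheme)
         else decompose_twofold(mA, mB, reference, scheme)
  attr(out, "model_A") <- mA
  attr(out, "model_B") <- mB
  out
}

#' Cluster-bootstrap standard errors for a decomposition
#'
#' Resamples primary sampling units (clusters) with replacement --
#' within country when a country column is given -- refits both group
#' models and recomputes the decomposition on each replicate. Standard
#' errors are the replicate standard deviations; confidence intervals
#' are percentile intervals. Replicates whose fits fail (e.g. a resample
#' without events in one group) are dropped and counted; more than 20%
#' failures aborts.
#'
#' @inheritParams oaxaca_decompose
#' @param cluster Name of the PSU column.
#' @param country Optional country column; resampling is stratified
#'   within country.
#' @param replicates Number of bootstrap replicates (>= 50).
#' @param seed Integer seed for reproducibility.
#' @param conf Confidence level for percentile intervals.
#' @return List of class `oaxaca_bootstrap`: `estimate` (the point
#'   decomposition), `se` and `ci` for the aggregate components,
#'   `detail_se` for term-level detail, `replicates` kept and `failures`.
#' @export
oaxaca_bootstrap <- function(data, outcome, covariates, group = "wealth",
                             weights = NULL, cluster = "cluster",
                             country = NULL,
                             link = c("logit", "identity"),
                             type = c("threefold", "twofold"),
                             reference = "B",
                             scheme = c("population", "at_means"),
                             normalization = c("deviation", "treatment"),
                             replicates = 200, seed = 1, conf = 0.95) {
  link <- match.arg(link); type <- match.arg(type)
  scheme <- match.arg(scheme)
  normalization <- match.arg(normalization)
  if (replicates < 50) stop("need at least 50 replicates", call. = FALSE)
  check_columns(data, c(cluster, country))

  point <- oaxaca_decompose(data, outcome, covariates, group, weights,
                            link, type, reference, scheme, normalization)
  comps <- if (type == "threefold") c("E", "C", "I") else c("Q", "U")

  # design built once on the full data (fixed factor levels); replicates
  # resample rows of the prebuilt matrices
  X <- suppressWarnings(build_design(data, covariates, normalization))
  y <- as.numeric(data[[outcome]])
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  g <- as.character(data[[group]])

  strat <- if (is.null(country)) rep("all", nrow(data))
           else as.character(data[[country]])
  cl <- data[[cluster]]
  idx_by_cluster <- split(seq_len(nrow(data)), list(strat, cl), drop = TRUE)
  cl_strat <- vapply(idx_by_cluster, function(i) strat[i[1]], character(1))
  clusters_in <- split(names(idx_by_cluster), cl_strat)

  decompose_rows <- function(rows) {
    iA <- g[rows] == "poor"
    mA <- fit_group_model_xy(X[rows[iA], , drop = FALSE], y[rows[iA]],
                             w[rows[iA]], link, "poor")
    mB <- fit_group_model_xy(X[rows[!iA], , drop = FALSE], y[rows[!iA]],
                             w[rows[!iA]], link, "non-poor")
    if (type == "threefold") decompose_threefold(mA, mB, scheme)
    else decompose_twofold(mA, mB, reference, scheme)
  }

  set.seed(seed)
  stats_mat <- matrix(NA_real_, replicates, 1 + length(comps))
  detail_list <- vector("list", replicates)
  failures <- 0L
  for (r in seq_len(replicates)) {
    take <- unlist(lapply(clusters_in, function(cls)
      sample(cls, length(cls), replace = TRUE)), use.names = FALSE)
    rows <- unlist(idx_by_cluster[take], use.names = FALSE)
    rep_d <- tryCatch(suppressWarnings(decompose_rows(rows)),
                      error = function(e) NULL)
    if (is.null(rep_d)) { failures <- failures + 1L; next }
    stats_mat[r, ] <- c(rep_d$gap, unlist(rep_d[comps]))
    detail_list[[r]] <- rep_d$detail_terms
  }
  if (failures > 0.2 * replicates)
    stop(sprintf("bootstrap aborted: %d of %d replicate fits failed",
                 failures, replicates), call. = FALSE)
  ok <- stats::complete.cases(stats_mat)
  stats_mat <- stats_mat[ok, , drop = FALSE]
  colnames(stats_mat) <- c("gap", comps)
  se <- apply(stats_mat, 2, stats::sd)
  alpha <- (1 - conf) / 2
  ci <- t(apply(stats_mat, 2, stats::quantile, probs = c(alpha, 1 - alpha)))

  detail_arr <- simplify2array(lapply(detail_list[ok],
                                      function(d) as.matrix(d[comps])))
  detail_se <- as.data.frame(apply(detail_arr, c(1, 2), stats::sd))
  detail_se <- cbind(term = detail_list[[which(ok)[1]]]$term, detail_se)

  out <- list(estimate = point, se = se, ci = ci, detail_se = detail_se,
              replicates = sum(ok), failures = failures, conf = conf,
              draws = stats_mat)
  class(out) <- "oaxaca_bootstrap"
  out
}

#' @export
print.oaxaca_bootstrap <- function(x, ...) {
  print(x$estimate)
  cat(sprintf("Cluster bootstrap: %d replicates kept, %d failed\n",
              x$replicates, x$failures))
  tab <- cbind(se = x$se, x$ci)
  print(round(tab, 5))
  invisible(x)
}
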