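# Synthetic multi-country survey generator with known decomposition
# ground truth. Emulates the hierarchical structure of household-survey
# children's data: countries -> clusters (PSUs) -> children, with
# relative sampling weights, a latent household wealth score driving
# both asset ownership and the poor/non-poor label, categorical
# covariates whose distribution differs by wealth group, and a binary
# severe-wasting outcome drawn from group-specific logistic models.

#' Default covariate mix for the generator
#'
#' Four categorical covariates (maternal education, media access,
#' residence, child age) with group-specific category probabilities
#' chosen to reproduce a realistic pooled low/middle-income survey
#' profile: poor households have markedly less education, media access
#' and urban residence, while child age is nearly balanced across
#' groups.
#'
#' @return Named list of covariate specifications (levels,
#'   `probs_poor`, `probs_nonpoor`).
#' @export
default_covariates <- function() {
  list(
    maternal_education = list(
      levels = c("none", "primary", "secondary"),
      probs_poor = c(0.462, 0.295, 0.243),
      probs_nonpoor = c(0.185, 0.217, 0.598)),
    media_access = list(
      levels = c("no", "yes"),
      probs_poor = c(0.567, 0.433),
      probs_nonpoor = c(0.195, 0.805)),
    residence = list(
      levels = c("rural", "urban"),
      probs_poor = c(0.908, 0.092),
      probs_nonpoor = c(0.512, 0.488)),
    child_age = list(
      levels = c("under12m", "12-59m"),
      probs_poor = c(0.199, 0.801),
      probs_nonpoor = c(0.201, 0.799)))
}

#' Simulation configuration for the synthetic survey generator
#'
#' Describes a multi-country survey: countries, clusters per country,
#' children per cluster, the poor fraction, the covariate mix by wealth
#' group, the two group-specific logistic outcome models, the sampling
#' weight distribution, and the asset-ownership model driven by a latent
#' household wealth score.
#'
#' The outcome model for group g is `P(SW = 1) = plogis(X' beta_g)`
#' where X is the treatment-coded dummy expansion of the covariates
#' (intercept first, then `levels[-1]` of each covariate in order). The
#' default coefficient vectors produce group prevalences of about 5.3%
#' (poor) and 4.2% (non-poor), the pooled levels typical of this
#' setting.
#'
#' @param n_countries Number of countries (>= 1).
#' @param clusters_per_country Clusters (PSUs) per country.
#' @param children_per_cluster Mean children per cluster; cluster sizes
#'   are Poisson around this mean (minimum 1).
#' @param poor_fraction Proportion of children from poor households,
#'   recycled per country.
#' @param covariates Covariate specification list, see
#'   [default_covariates()]. Each element needs `levels` plus either
#'   `probs` (shared) or `probs_poor`/`probs_nonpoor`.
#' @param beta_poor,beta_nonpoor Coefficient vectors of the
#'   group-specific logistic outcome models (intercept first), matching
#'   the dummy expansion of `covariates`.
#' @param weight_meanlog,weight_sdlog Lognormal sampling-weight
#'   parameters; weights are normalized to mean 1 within country.
#' @param n_assets Number of binary household asset indicators.
#' @param asset_slope Slope of asset ownership on the latent wealth
#'   score (logit scale; monotone increasing).
#' @param cluster_sd SD of a cluster-level random intercept on the
#'   outcome logit (default 0: no neighbourhood effect, matching a
#'   single-level decomposition).
#' @param seed Integer seed used by [generate_population()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_countries = 3,
                       clusters_per_country = 50,
                       children_per_cluster = 25,
                       poor_fraction = 0.456,
                       covariates = default_covariates(),
                       beta_poor = c(-2.1154, -0.30, -0.45, -0.30, -0.15, -0.60),
                       beta_nonpoor = c(-2.2547, -0.20, -0.35, -0.15, -0.05, -0.65),
                       weight_meanlog = 0, weight_sdlog = 0.5,
                       n_assets = 8, asset_slope = 1.2,
                       cluster_sd = 0, seed = 1L) {
  cfg <- list(n_countries = check_count(n_countries, "n_countries"),
              clusters_per_country = check_count(clusters_per_country,
                                                "clusters_per_country"),
              children_per_cluster = check_count(children_per_cluster,
                                                "children_per_cluster"),
              poor_fraction = rep_len(poor_fraction, n_countries),
              covariates = covariates,
              beta_poor = beta_poor, beta_nonpoor = beta_nonpoor,
              weight_meanlog = weight_meanlog,
              weight_sdlog = weight_sdlog,
              n_assets = check_count(n_assets, "n_assets"),
              asset_slope = asset_slope,
              cluster_sd = cluster_sd, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  check_prob(cfg$poor_fraction, "poor_fraction")
  if (!length(cfg$covariates))
    stop("configuration error: 'covariates' is empty", call. = FALSE)
  for (nm in names(cfg$covariates)) {
    cv <- cfg$covariates[[nm]]
    if (is.null(cv$levels) || length(cv$levels) < 2L)
      stop(sprintf("configuration error: covariate '%s' needs >= 2 levels", nm),
           call. = FALSE)
    for (pr in c("probs", "probs_poor", "probs_nonpoor")) {
      if (!is.null(cv[[pr]])) {
        check_prob(cv[[pr]], paste0(nm, "$", pr))
        if (length(cv[[pr]]) != length(cv$levels))
          stop(sprintf("configuration error: %s$%s length mismatch", nm, pr),
               call. = FALSE)
        if (abs(sum(cv[[pr]]) - 1) > 1e-8)
          stop(sprintf("configuration error: %s$%s must sum to 1", nm, pr),
               call. = FALSE)
      }
    }
    # [[ with exact = TRUE: $ would partially match probs_poor/_nonpoor
    if (is.null(cv[["probs", exact = TRUE]]) &&
        (is.null(cv[["probs_poor", exact = TRUE]]) ||
         is.null(cv[["probs_nonpoor", exact = TRUE]])))
      stop(sprintf(
        "configuration error: covariate '%s' needs 'probs' or both 'probs_poor' and 'probs_nonpoor'",
        nm), call. = FALSE)
  }
  p <- 1L + sum(vapply(cfg$covariates,
                       function(cv) length(cv$levels) - 1L, integer(1)))
  if (length(cfg$beta_poor) != p || length(cfg$beta_nonpoor) != p)
    stop(sprintf(
      "configuration error: beta_poor/beta_nonpoor must have length %d (intercept + dummies)",
      p), call. = FALSE)
  if (cfg$weight_sdlog < 0)
    stop("configuration error: weight_sdlog must be >= 0", call. = FALSE)
  if (cfg$cluster_sd < 0)
    stop("configuration error: cluster_sd must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' @noRd
group_probs <- function(cv, group) {
  shared <- cv[["probs", exact = TRUE]]
  if (!is.null(shared)) return(shared)
  if (group == "poor") cv[["probs_poor"]] else cv[["probs_nonpoor"]]
}

#' Dummy-expansion column names matching the beta vectors
#' @noRd
design_names <- function(covariates) {
  c("(Intercept)",
    unlist(lapply(names(covariates), function(nm)
      paste0(nm, covariates[[nm]]$levels[-1])), use.names = FALSE))
}

#' Generate a synthetic multi-country child-level survey table
#'
#' Draws one record per child following the hierarchy countries ->
#' clusters -> children. A standard-normal latent household wealth score
#' determines the poor/non-poor label (children below the country's
#' `poor_fraction` quantile are poor) and drives binary asset ownership
#' through monotone logistic item curves; covariates are drawn from the
#' group-specific categorical distributions and the severe-wasting
#' outcome from the group's logistic model. Sampling weights are
#' lognormal, normalized to mean 1 within country. Regeneration with the
#' same config (including its seed) is bit-identical.
#'
#' @param config A [sim_config()] object.
#' @return Data frame with columns `country`, `cluster`, `child_id`,
#'   `weight`, `latent_wealth`, asset indicators `asset_1..k`, `wealth`
#'   (factor poor/non-poor), the configured covariates and
#'   `severe_wasting` (0/1).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  rows <- vector("list", config$n_countries)
  for (ci in seq_len(config$n_countries)) {
    sizes <- pmax(1L, stats::rpois(config$clusters_per_country,
                                   config$children_per_cluster))
    n <- sum(sizes)
    cluster <- paste0("C", ci, "_", rep(seq_along(sizes), sizes))
    latent <- stats::rnorm(n)
    poor <- latent < stats::qnorm(config$poor_fraction[ci])
    wealth <- factor(ifelse(poor, "poor", "non-poor"),
                     levels = c("poor", "non-poor"))
    w <- stats::rlnorm(n, config$weight_meanlog, config$weight_sdlog)
    w <- w / mean(w)

    # monotone asset item curves spread over the wealth distribution
    a_int <- seq(-1.5, 1.5, length.out = config$n_assets)
    assets <- vapply(seq_len(config$n_assets), function(j)
      as.integer(stats::runif(n) <
                   stats::plogis(a_int[j] + config$asset_slope * latent)),
      integer(n))
    colnames(assets) <- paste0("asset_", seq_len(config$n_assets))

    covs <- lapply(names(config$covariates), function(nm) {
      cv <- config$covariates[[nm]]
      k <- length(cv$levels)
      lev <- character(n)
      for (g in c("poor", "non-poor")) {
        idx <- which(as.character(wealth) == g)
        if (length(idx))
          lev[idx] <- sample(cv$levels, length(idx), replace = TRUE,
                             prob = group_probs(cv, g))
      }
      factor(lev, levels = cv$levels)
    })
    names(covs) <- names(config$covariates)

    X <- cbind(1, do.call(cbind, lapply(names(covs), function(nm) {
      lv <- config$covariates[[nm]]$levels
      vapply(lv[-1], function(l) as.numeric(covs[[nm]] == l), numeric(n))
    })))
    colnames(X) <- design_names(config$covariates)
    eta <- ifelse(poor, drop(X %*% config$beta_poor),
                  drop(X %*% config$beta_nonpoor))
    if (config$cluster_sd > 0) {
      u <- stats::rnorm(length(sizes), 0, config$cluster_sd)
      eta <- eta + rep(u, sizes)
    }
    y <- as.integer(stats::runif(n) < stats::plogis(eta))

    rows[[ci]] <- data.frame(country = paste0("country_", ci),
                             cluster = cluster,
                             child_id = seq_len(n),
                             weight = w, latent_wealth = latent,
                             assets, wealth = wealth,
                             as.data.frame(covs),
                             severe_wasting = y,
                             check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Joint covariate distribution of one group (independent covariates)
#' @noRd
enumerate_cells <- function(config, group) {
  probs <- lapply(config$covariates, group_probs, group = group)
  grids <- lapply(config$covariates, function(cv) seq_along(cv$levels))
  cells <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  p <- apply(cells, 1, function(ix)
    prod(mapply(function(pr, i) pr[i], probs, ix)))
  X <- cbind(1, do.call(cbind, lapply(seq_along(config$covariates),
    function(j) {
      k <- length(config$covariates[[j]]$levels)
      vapply(2:k, function(l) as.numeric(cells[[j]] == l),
             numeric(nrow(cells)))
    })))
  colnames(X) <- design_names(config$covariates)
  list(prob = p, X = X)
}

#' Analytic decomposition ground truth of a simulation configuration
#'
#' Computes, without any sampling, the population quantities implied by
#' a [sim_config()]: group covariate mean vectors, exact group
#' prevalences and risk difference (by enumerating the joint categorical
#' covariate distribution), and the threefold (E, C, I) and twofold
#' (Q, U for references A and B) decomposition components on the
#' probability scale. Components are reported in two evaluation schemes:
#' `at_means` (logistic function applied to mean covariate vectors, the
#' definition shared with the estimator's `scheme = "at_means"`) and
#' `population` (exact expectation over the covariate distribution,
#' matching `scheme = "population"`).
#'
#' @param config A [sim_config()] object.
#' @return List of class `ground_truth`: `xbar_poor`, `xbar_nonpoor`,
#'   `prev_poor`, `prev_nonpoor` (percent), `rd` (per 1000),
#'   `threefold` and `twofold` (each a list with `at_means` and
#'   `population` component vectors).
#' @export
true_decomposition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  eA <- enumerate_cells(config, "poor")
  eB <- enumerate_cells(config, "non-poor")
  bA <- config$beta_poor; bB <- config$beta_nonpoor
  xbarA <- drop(crossprod(eA$X, eA$prob))
  xbarB <- drop(crossprod(eB$X, eB$prob))

  pop <- function(e, beta) sum(e$prob * stats::plogis(drop(e$X %*% beta)))
  atm <- function(xbar, beta) stats::plogis(sum(xbar * beta))

  mk <- function(P) {
    gap <- P$AA - P$BB
    E <- P$AB - P$BB          # endowments, weighted by beta_B
    C <- P$BA - P$BB          # coefficients, at group B's covariates
    I <- gap - E - C
    QA <- P$AA - P$BA; QB <- P$AB - P$BB
    list(gap = gap, E = E, C = C, I = I,
         twofold = list(
           A = c(Q = QA, U = gap - QA),
           B = c(Q = QB, U = gap - QB)))
  }
  P_pop <- list(AA = pop(eA, bA), AB = pop(eA, bB),
                BA = pop(eB, bA), BB = pop(eB, bB))
  P_atm <- list(AA = atm(xbarA, bA), AB = atm(xbarA, bB),
                BA = atm(xbarB, bA), BB = atm(xbarB, bB))
  t_pop <- mk(P_pop); t_atm <- mk(P_atm)

  out <- list(xbar_poor = xbarA, xbar_nonpoor = xbarB,
              prev_poor = 100 * P_pop$AA, prev_nonpoor = 100 * P_pop$BB,
              rd = risk_difference(100 * P_pop$AA, 100 * P_pop$BB),
              threefold = list(at_means = t_atm[c("gap", "E", "C", "I")],
                               population = t_pop[c("gap", "E", "C", "I")]),
              twofold = list(at_means = t_atm$twofold,
                             population = t_pop$twofold))
  class(out) <- "ground_truth"
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("True prevalences: poor %.3f%%, non-poor %.3f%% (RD %.2f per 1000)\n",
              x$prev_poor, x$prev_nonpoor, x$rd))
  tm <- x$threefold$at_means
  cat(sprintf("Threefold (at means): gap %.5f = E %.5f + C %.5f + I %.5f\n",
              tm$gap, tm$E, tm$C, tm$I))
  invisible(x)
}

#' Write / read a generated population and its configuration
#'
#' The population table round-trips through CSV (one header row, one
#' record per child) and the configuration through YAML; reading back
#' reproduces the original objects.
#'
#' @param records Data frame from [generate_population()].
#' @param path Output file path.
#' @return `write_population` returns `path` invisibly;
#'   `read_population` the data frame.
#' @export
write_population <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @param config_levels Optional `sim_config` whose covariate levels are
#'   restored as factor levels on read.
#' @export
read_population <- function(path, config_levels = NULL) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  out$wealth <- factor(out$wealth, levels = c("poor", "non-poor"))
  if (!is.null(config_levels))
    for (nm in names(config_levels$covariates))
      out[[nm]] <- factor(out[[nm]],
                          levels = config_levels$covariates[[nm]]$levels)
  out
}

#' @rdname write_population
#' @param config A `sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_population
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw[setdiff(names(raw), character(0))])
}
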