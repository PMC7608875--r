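#' Asset-based household wealth index by principal components
#'
#' Scores households on the first principal component of their asset
#' indicators, the standard construction for survey wealth indices where
#' no income or expenditure data exist. Indicators are standardized using
#' weighted means and standard deviations, so the component is extracted
#' from the weighted correlation matrix and the score is invariant to
#' rescaling any asset column. The sign is oriented so that a higher
#' score means more assets: the average loading on the (ownership-coded)
#' indicators is made positive, with exact ties broken toward a positive
#' loading on the first asset column.
#'
#' Households are then cut into weight-balanced quintiles (cut points at
#' the weighted 20/40/60/80 percentiles; households with identical scores
#' share the lower quintile) labelled `poorest` to `richest`, and
#' dichotomized into `poor` (poorest, poorer) versus `non-poor` (middle,
#' richer, richest).
#'
#' @param assets Data frame or matrix of numeric (binary/ordinal) asset
#'   indicators, one row per household. All-constant columns are dropped;
#'   at least two informative columns and five households are required.
#' @param weights Positive household weights (default equal).
#' @param id Optional household identifiers (default row index).
#' @return Data frame of class `wealth_assignment` with columns `id`,
#'   `score`, `quintile` (ordered factor) and `dichotomy` (factor
#'   poor/non-poor).
#' @examples
#' set.seed(1)
#' a <- matrix(rbinom(500, 1, 0.5), 100, 5)
#' head(compute_wealth_index(a))
#' @export
compute_wealth_index <- function(assets, weights = NULL, id = NULL) {
  x <- as.matrix(as.data.frame(assets))
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(id)) id <- seq_len(n)
  if (any(weights <= 0)) stop("weights must be strictly positive", call. = FALSE)
  if (n < 5L) stop("need at least 5 households", call. = FALSE)
  if (anyNA(x)) stop("asset indicators must be non-missing", call. = FALSE)

  sds <- apply(x, 2, wsd, w = weights)
  keep <- sds > 0
  if (sum(keep) < 2L)
    stop("degenerate asset matrix: fewer than 2 informative (non-constant) asset columns",
         call. = FALSE)
  x <- x[, keep, drop = FALSE]
  score <- first_pc_score(x, weights)

  q <- wquantile_groups(score, weights, 5L)
  quintile <- factor(wealth_quintile_labels()[q],
                     levels = wealth_quintile_labels(), ordered = TRUE)
  out <- data.frame(id = id, score = score, quintile = quintile,
                    dichotomy = dichotomize_wealth(quintile))
  class(out) <- c("wealth_assignment", "data.frame")
  out
}

#' First principal component score on the weighted correlation matrix,
#' sign-oriented by majority-positive loadings.
#' @noRd
first_pc_score <- function(x, w) {
  mu <- apply(x, 2, wmean, w = w)
  sd <- apply(x, 2, wsd, w = w)
  zs <- sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
  wn <- w / sum(w)
  corr <- crossprod(zs * sqrt(wn), zs * sqrt(wn))
  v <- eigen(corr, symmetric = TRUE)$vectors[, 1]
  s <- sum(sign(v))
  if (s < 0 || (s == 0 && v[1] < 0)) v <- -v
  drop(zs %*% v)
}

#' @noRd
wealth_quintile_labels <- function()
  c("poorest", "poorer", "middle", "richer", "richest")

#' Dichotomize wealth quintiles into poor and non-poor
#'
#' Maps the five asset-quintile labels onto the binary comparison used in
#' decomposition analyses: the bottom two quintiles (`poorest`, `poorer`)
#' are `poor`, the top three (`middle`, `richer`, `richest`) are
#' `non-poor`.
#'
#' @param quintile Character or factor vector of quintile labels.
#' @return Factor with levels `poor`, `non-poor`.
#' @export
dichotomize_wealth <- function(quintile) {
  q <- as.character(quintile)
  known <- q %in% wealth_quintile_labels()
  if (any(!known))
    stop("unknown wealth quintile label(s): ",
         paste(unique(q[!known]), collapse = ", "), call. = FALSE)
  factor(ifelse(q %in% c("poorest", "poorer"), "poor", "non-poor"),
         levels = c("poor", "non-poor"))
}

#' Neighbourhood socioeconomic disadvantage index
#'
#' Summarizes each survey cluster (primary sampling unit, read here as a
#' "neighbourhood") by the weighted proportions of respondents without
#' education, unemployed, living in rural areas and living below the
#' poverty line, then scores clusters on the first principal component of
#' the four proportions. The score is oriented so that higher means more
#' disadvantaged. Clusters are cut into weighted quintiles labelled
#' `"1 (highest SES)"` through `"5 (lowest SES)"`, with cluster weight
#' taken as the total record weight in the cluster.
#'
#' @param records Data frame with one row per child/respondent.
#' @param cluster Name of the cluster id column (default `"cluster"`).
#' @param weight Name of the weight column (default `"weight"`), or NULL
#'   for equal weights.
#' @param indicators Named character vector mapping the four indicator
#'   roles (`no_education`, `unemployed`, `rural`, `below_poverty`) to
#'   columns of `records`; columns must be 0/1 or logical.
#' @return Data frame of class `neighbourhood_ses`: cluster id, the four
#'   proportions, `disadvantage` score and `ses_quintile`.
#' @export
compute_neighbourhood_ses <- function(records,
                                      cluster = "cluster",
                                      weight = "weight",
                                      indicators = c(
                                        no_education = "no_education",
                                        unemployed = "unemployed",
                                        rural = "rural",
                                        below_poverty = "below_poverty")) {
  roles <- c("no_education", "unemployed", "rural", "below_poverty")
  if (!all(roles %in% names(indicators)))
    stop("indicators must name columns for: ",
         paste(roles, collapse = ", "), call. = FALSE)
  check_columns(records, c(cluster, indicators))
  w <- if (is.null(weight)) rep(1, nrow(records)) else records[[weight]]
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  cl <- records[[cluster]]

  ids <- sort(unique(cl))
  if (length(ids) < 2L)
    stop("neighbourhood SES quintiles are undefined with a single cluster",
         call. = FALSE)
  agg <- function(col) {
    v <- as.numeric(records[[col]])
    check_prob(v, col)
    as.vector(rowsum(v * w, cl) / rowsum(w, cl))
  }
  props <- vapply(indicators[roles], agg, numeric(length(ids)))
  colnames(props) <- roles
  cw <- as.vector(rowsum(w, cl))  # rowsum sorts by group

  sds <- apply(props, 2, wsd, w = cw)
  if (all(sds == 0)) {
    # all clusters identical: zero score, everyone in the lowest quintile
    # by the shared-lower-quintile tie rule
    score <- rep(0, length(ids))
  } else {
    score <- first_pc_score(props[, sds > 0, drop = FALSE], cw)
  }
  q <- wquantile_groups(score, cw, 5L)
  labels <- c("1 (highest SES)", "2", "3", "4", "5 (lowest SES)")
  out <- data.frame(cluster = ids, props,
                    disadvantage = score,
                    ses_quintile = factor(labels[q], levels = labels,
                                          ordered = TRUE))
  class(out) <- c("neighbourhood_ses", "data.frame")
  out
}
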