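# Shared fixtures: hand-built group models, tiny LMS references and
# random decomposition instances. Everything is generated in code.

# A group_model built directly from means and coefficients (no fitting),
# for closed-form decomposition arithmetic. For the identity link ybar
# is implied by the model; for logit a record-level design is attached
# so both evaluation schemes work.
toy_model <- function(xbar, beta, link = "identity", group = "A",
                      n = 50, X = NULL, w = NULL, ybar = NULL) {
  names(beta) <- names(xbar) <- paste0("x", seq_along(beta) - 1)
  names(beta)[1] <- names(xbar)[1] <- "(Intercept)"
  if (is.null(X)) X <- matrix(rep(xbar, each = n), n,
                              dimnames = list(NULL, names(beta)))
  if (is.null(w)) w <- rep(1, nrow(X))
  if (is.null(ybar)) {
    eta <- drop(X %*% beta)
    ybar <- sum(w * (if (link == "logit") plogis(eta) else eta)) / sum(w)
  }
  structure(list(group = group, link = link, coef = beta,
                 xbar = drop(crossprod(X, w)) / sum(w), ybar = ybar,
                 vcov = diag(length(beta)), n = nrow(X), X = X,
                 y = NULL, w = w, assign = NULL, converged = TRUE),
            class = "group_model")
}

# Random compatible pair of group models (shared link and covariates)
random_model_pair <- function(p = 3, n = 40, link = "identity") {
  mk <- function(group) {
    X <- cbind(1, matrix(rnorm(n * p), n, p))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p)))
    beta <- rnorm(p + 1, sd = 0.5)
    w <- rlnorm(n, 0, 0.3)
    toy_model(drop(crossprod(X, w)) / sum(w), beta, link, group,
              X = X, w = w)
  }
  list(A = mk("poor"), B = mk("non-poor"))
}

# Minimal in-memory LMS reference written to a temp CSV
write_lms_fixture <- function(rows) {
  f <- tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE)
  f
}

flat_lms <- function(L, M, S, heights = c(60, 100), sex = "female") {
  expand.grid(sex = sex, height_cm = heights, L = L, M = M, S = S,
              stringsAsFactors = FALSE)
}

# Synthetic single-country survey with independent records (no cluster
# effect), equal true prevalence in both groups unless rd_shift is set.
null_country <- function(n = 20000, p = 0.05, rd_shift = 0,
                         n_clusters = 100) {
  g <- rep(c("poor", "non-poor"), length.out = n)
  pr <- ifelse(g == "poor", p + rd_shift, p)
  data.frame(country = "X",
             cluster = sample.int(n_clusters, n, replace = TRUE),
             weight = rlnorm(n, 0, 0.4),
             wealth = factor(g, levels = c("poor", "non-poor")),
             severe_wasting = as.integer(runif(n) < pr))
}
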