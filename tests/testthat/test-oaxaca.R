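# Toy used repeatedly: means (1,2) vs (1,1), beta_A = (0.1, 0.3),
# beta_B = (0.2, 0.1), identity link. Direct arithmetic gives
# gap = 0.4, E = 0.1, C = 0.1, I = 0.2; twofold ref B = (0.1, 0.3),
# ref A = (0.3, 0.1).
toy_pair <- function() {
  list(A = toy_model(c(1, 2), c(0.1, 0.3), group = "poor"),
       B = toy_model(c(1, 1), c(0.2, 0.1), group = "non-poor"))
}

test_that("threefold decomposition reproduces direct arithmetic and its limits", {
  tp <- toy_pair()
  d3 <- decompose_threefold(tp$A, tp$B)
  expect_equal(d3$gap, 0.4)
  expect_equal(d3$E, 0.1)
  expect_equal(d3$C, 0.1)
  expect_equal(d3$I, 0.2)

  # equal coefficients: C = I = 0, gap = E
  same_b <- toy_model(c(1, 2), c(0.2, 0.1), group = "poor")
  d_eq <- decompose_threefold(same_b, tp$B)
  expect_equal(d_eq$C, 0)
  expect_equal(d_eq$I, 0)
  expect_equal(d_eq$gap, d_eq$E)

  # equal covariate means: E = I = 0, gap = C
  same_x <- toy_model(c(1, 1), c(0.1, 0.3), group = "poor")
  d_x <- decompose_threefold(same_x, tp$B)
  expect_equal(d_x$E, 0)
  expect_equal(d_x$I, 0)
  expect_equal(d_x$gap, d_x$C)
})

test_that("twofold decomposition matches Eq-style arithmetic and regroups the threefold", {
  tp <- toy_pair()
  dB <- decompose_twofold(tp$A, tp$B, reference = "B")
  expect_equal(c(dB$Q, dB$U), c(0.1, 0.3))
  dA <- decompose_twofold(tp$A, tp$B, reference = "A")
  expect_equal(c(dA$Q, dA$U), c(0.3, 0.1))

  # beta_A = beta_B: U = 0 for every reference
  same <- toy_model(c(1, 2), c(0.2, 0.1), group = "poor")
  for (ref in c("A", "B"))
    expect_equal(decompose_twofold(same, tp$B, reference = ref)$U, 0)

  expect_error(decompose_twofold(tp$A, toy_model(c(1, 1, 0), c(1, 1, 1))),
               "mismatched covariate sets")
})

test_that("detailed contributions allocate the explained part per covariate", {
  tp <- toy_pair()
  dB <- decompose_twofold(tp$A, tp$B, reference = "B")
  det <- detailed_contributions(dB, by = "column")
  # the single non-constant covariate takes all of Q: 0.1 = 25% of gap 0.4
  expect_equal(det$Q[det$column == "x1"], 0.1)
  expect_equal(det$share_Q[det$column == "x1"], 0.25)
  expect_equal(det$Q[det$column == "(Intercept)"], 0)
  expect_equal(sum(det$Q), dB$Q)
  expect_equal(sum(det$U), dB$U)
})

test_that("Yun shares match a finite-difference oracle for a logit toy", {
  # two covariates with known parameters; perturbing one group-A mean at
  # a time measures each covariate's contribution to the explained gap
  set.seed(3)
  n <- 4000
  XA <- cbind(1, rbinom(n, 1, 0.6), rbinom(n, 1, 0.3))
  XB <- cbind(1, rbinom(n, 1, 0.3), rbinom(n, 1, 0.1))
  colnames(XA) <- colnames(XB) <- c("(Intercept)", "x1", "x2")
  bB <- c(-2.5, 0.8, 0.5)
  mA <- toy_model(colMeans(XA), c(-2.0, 0.9, 0.6), link = "logit",
                  group = "poor", X = XA)
  mB <- toy_model(colMeans(XB), bB, link = "logit", group = "non-poor",
                  X = XB)
  dB <- decompose_twofold(mA, mB, reference = "B", scheme = "at_means")
  det <- detailed_contributions(dB, by = "column")

  # finite-difference oracle at the means under beta_B
  F <- plogis
  base <- F(sum(mB$xbar * bB))
  d1 <- F(sum(c(1, mA$xbar[2], mB$xbar[3]) * bB)) - base
  d2 <- F(sum(c(1, mB$xbar[2], mA$xbar[3]) * bB)) - base
  shares_fd <- c(d1, d2) / (d1 + d2)
  shares_yun <- det$Q[2:3] / sum(det$Q[2:3])
  expect_equal(shares_yun, shares_fd, tolerance = 0.05)
  expect_equal(sum(det$Q), dB$Q, tolerance = 1e-12)
})

test_that("group fits recover simulated coefficients and respect preconditions", {
  set.seed(12)
  n <- 50000
  x <- rnorm(n)
  y <- as.integer(runif(n) < plogis(-3 + 0.5 * x))
  d <- data.frame(x = x, y = y, w = rlnorm(n, 0, 0.3))
  m <- fit_group_model(d, "y", "x", weights = "w", link = "logit",
                       group = "poor")
  se <- sqrt(diag(m$vcov))
  expect_lt(abs(m$coef[1] - (-3)) / se[1], 3)
  expect_lt(abs(m$coef[2] - 0.5) / se[2], 3)

  # no events
  d0 <- transform(d, y = 0)
  expect_error(fit_group_model(d0, "y", "x", link = "logit"), "no events")

  # weight invariance
  d7 <- transform(d, w = w * 7)
  m7 <- fit_group_model(d7, "y", "x", weights = "w", link = "logit")
  expect_equal(m$coef, m7$coef, tolerance = 1e-10)

  # collinearity reported with the aliased column
  d$x2 <- 2 * d$x
  expect_error(fit_group_model(d, "y", c("x", "x2"), link = "identity"),
               "collinear.*x2")

  # complete separation reported
  ds <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                   y = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_group_model(ds, "y", "x", link = "logit"), "separation")
})

test_that("identity-link WLS satisfies the fitted-mean identity", {
  set.seed(13)
  d <- data.frame(x = rnorm(200), z = rbinom(200, 1, 0.4),
                  w = rlnorm(200, 0, 0.5))
  d$y <- 0.2 + 0.1 * d$x - 0.05 * d$z + rnorm(200, 0, 0.1)
  m <- fit_group_model(d, "y", c("x", "z"), weights = "w",
                       link = "identity")
  expect_equal(sum(m$xbar * m$coef), m$ybar, tolerance = 1e-12)
})

test_that("additivity and regrouping hold on random instances for both links and schemes", {
  set.seed(99)
  for (i in 1:60) {
    link <- if (i %% 2) "identity" else "logit"
    scheme <- if (i %% 3) "population" else "at_means"
    pr <- random_model_pair(p = sample(1:4, 1), link = link)
    d3 <- decompose_threefold(pr$A, pr$B, scheme = scheme)
    tol <- if (link == "identity") 1e-10 else 1e-8
    expect_equal(d3$E + d3$C + d3$I, d3$gap, tolerance = tol)
    expect_equal(sum(d3$detail$E), d3$E, tolerance = tol)
    expect_equal(sum(d3$detail$C), d3$C, tolerance = tol)
    expect_equal(sum(d3$detail$I), d3$I, tolerance = tol)
    for (ref in c("A", "B")) {
      d2 <- decompose_twofold(pr$A, pr$B, reference = ref, scheme = scheme)
      expect_equal(d2$Q + d2$U, d2$gap, tolerance = tol)
    }
    dB <- decompose_twofold(pr$A, pr$B, reference = "B", scheme = scheme)
    dA <- decompose_twofold(pr$A, pr$B, reference = "A", scheme = scheme)
    expect_equal(dB$Q, d3$E, tolerance = 1e-12)
    expect_equal(dB$U, d3$C + d3$I, tolerance = 1e-12)
    expect_equal(dA$Q, d3$E + d3$I, tolerance = 1e-12)
    expect_equal(dA$U, d3$C, tolerance = 1e-12)
  }
})

test_that("identity-link decomposition equals a brute-force raw-sums oracle", {
  set.seed(17)
  for (i in 1:20) {
    n <- 60
    d <- data.frame(
      x1 = rnorm(2 * n), x2 = runif(2 * n),
      wealth = factor(rep(c("poor", "non-poor"), each = n),
                      c("poor", "non-poor")),
      w = rlnorm(2 * n, 0, 0.4))
    d$y <- 0.1 + 0.2 * d$x1 - 0.1 * d$x2 +
      0.15 * (d$wealth == "poor") * d$x1 + rnorm(2 * n, 0, 0.2)
    dec <- oaxaca_decompose(d, "y", c("x1", "x2"), group = "wealth",
                            weights = "w", link = "identity",
                            type = "threefold")
    # independent brute force from raw sums: weighted normal equations
    # and termwise products, no package code
    bf <- lapply(split(d, d$wealth), function(g) {
      X <- cbind(1, g$x1, g$x2)
      A <- t(X * g$w) %*% X
      b <- solve(A, t(X * g$w) %*% g$y)
      list(beta = drop(b), xbar = colSums(X * g$w) / sum(g$w),
           ybar = sum(g$w * g$y) / sum(g$w))
    })
    E_bf <- sum((bf$poor$xbar - bf$`non-poor`$xbar) * bf$`non-poor`$beta)
    C_bf <- sum(bf$`non-poor`$xbar * (bf$poor$beta - bf$`non-poor`$beta))
    gap_bf <- bf$poor$ybar - bf$`non-poor`$ybar
    expect_equal(dec$gap, gap_bf, tolerance = 1e-10)
    expect_equal(dec$E, E_bf, tolerance = 1e-10)
    expect_equal(dec$C, C_bf, tolerance = 1e-10)
    expect_equal(dec$I, gap_bf - E_bf - C_bf, tolerance = 1e-10)
  }
})

test_that("the model-implied logit gap equals the weighted prevalence gap", {
  set.seed(23)
  n <- 6000
  d <- data.frame(
    x1 = rbinom(n, 1, 0.5), x2 = rnorm(n),
    wealth = factor(sample(c("poor", "non-poor"), n, TRUE),
                    c("poor", "non-poor")),
    w = rlnorm(n, 0, 0.4))
  eta <- ifelse(d$wealth == "poor", -2.3 + 0.6 * d$x1 + 0.3 * d$x2,
                -2.6 + 0.4 * d$x1 + 0.2 * d$x2)
  d$y <- as.integer(runif(n) < plogis(eta))
  dec <- oaxaca_decompose(d, "y", c("x1", "x2"), group = "wealth",
                          weights = "w", link = "logit",
                          type = "threefold")
  mA <- attr(dec, "model_A"); mB <- attr(dec, "model_B")
  prev_gap <- weighted_prevalence(d$y[d$wealth == "poor"],
                                  d$w[d$wealth == "poor"]) / 100 -
    weighted_prevalence(d$y[d$wealth == "non-poor"],
                        d$w[d$wealth == "non-poor"]) / 100
  expect_equal(nonlinear_gap(mA, mB), prev_gap, tolerance = 1e-6)
  # identical groups give a zero gap
  expect_equal(nonlinear_gap(mA, mA), 0)
})

test_that("deviation coding makes detailed contributions invariant to the base category", {
  set.seed(29)
  n <- 3000
  d <- data.frame(
    edu = sample(c("none", "primary", "secondary"), n, TRUE),
    wealth = factor(sample(c("poor", "non-poor"), n, TRUE),
                    c("poor", "non-poor")),
    w = 1)
  d$y <- as.integer(runif(n) < plogis(-2 + 0.5 * (d$edu == "none") -
                                        0.3 * (d$wealth == "non-poor")))
  d2 <- d
  d2$edu <- factor(d2$edu, levels = c("secondary", "none", "primary"))
  det1 <- detailed_contributions(
    oaxaca_decompose(d, "y", "edu", weights = "w", link = "logit",
                     type = "twofold"), by = "term")
  det2 <- detailed_contributions(
    oaxaca_decompose(d2, "y", "edu", weights = "w", link = "logit",
                     type = "twofold"), by = "term")
  i1 <- det1$term != "(Intercept)"
  expect_equal(sort(det1$Q[i1]), sort(det2$Q[i1]), tolerance = 1e-8)
  # treatment coding warns about base-category dependence
  expect_warning(
    oaxaca_decompose(d, "y", "edu", weights = "w", link = "logit",
                     type = "twofold", normalization = "treatment"),
    "omitted base category")
})

test_that("pooled reference lies between the group references on a smooth design", {
  set.seed(31)
  n <- 4000
  d <- data.frame(
    x = rnorm(n),
    wealth = factor(rep(c("poor", "non-poor"), each = n / 2),
                    c("poor", "non-poor")))
  d$y <- 0.3 + 0.2 * d$x + 0.1 * (d$wealth == "poor") * d$x +
    0.05 * (d$wealth == "poor") + rnorm(n, 0, 0.3)
  dp <- decompose_twofold(
    attr(oaxaca_decompose(d, "y", "x", link = "identity",
                          type = "twofold"), "model_A"),
    attr(oaxaca_decompose(d, "y", "x", link = "identity",
                          type = "twofold"), "model_B"),
    reference = "pooled")
  expect_equal(dp$Q + dp$U, dp$gap, tolerance = 1e-10)
  expect_true(all(is.finite(dp$beta_star)))
  expect_false(".group" %in% names(dp$beta_star))
})

test_that("cluster bootstrap is reproducible and matches sampling variability", {
  set.seed(41)
  n_cl <- 150; per <- 12
  mkdata <- function() {
    cl <- rep(seq_len(n_cl), each = per)
    d <- data.frame(
      country = "X", cluster = cl,
      x = rnorm(n_cl * per),
      wealth = factor(sample(c("poor", "non-poor"), n_cl * per, TRUE),
                      c("poor", "non-poor")),
      weight = 1)
    d$y <- 0.3 + 0.15 * d$x + 0.08 * (d$wealth == "poor") +
      rnorm(nrow(d), 0, 0.25)
    d
  }
  d <- mkdata()
  b1 <- oaxaca_bootstrap(d, "y", "x", weights = "weight",
                         link = "identity", type = "threefold",
                         replicates = 150, seed = 5)
  b2 <- oaxaca_bootstrap(d, "y", "x", weights = "weight",
                         link = "identity", type = "threefold",
                         replicates = 150, seed = 5)
  expect_identical(b1$se, b2$se)
  expect_equal(b1$failures, 0L)

  # Monte-Carlo oracle: sd of E over fresh datasets
  E_draws <- vapply(1:150, function(i) {
    oaxaca_decompose(mkdata(), "y", "x", link = "identity",
                     type = "threefold")$E
  }, numeric(1))
  expect_lt(abs(b1$se["E"] - sd(E_draws)) / sd(E_draws), 0.35)
})

test_that("a degenerate constant outcome gives zero components and zero bootstrap SE", {
  d <- data.frame(country = "X",
                  cluster = rep(1:30, each = 6),
                  x = rnorm(180),
                  wealth = factor(rep(c("poor", "non-poor"), 90),
                                  c("poor", "non-poor")),
                  weight = 1, y = 0.5)
  b <- oaxaca_bootstrap(d, "y", "x", weights = "weight",
                        link = "identity", type = "twofold",
                        replicates = 60, seed = 2)
  expect_equal(unname(b$se), rep(0, 3), tolerance = 1e-12)
  expect_equal(b$estimate$gap, 0)
})
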