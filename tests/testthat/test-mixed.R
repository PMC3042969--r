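test_that("Henderson III extra sums of squares match two least-squares fits", {
  set.seed(10)
  for (i in 1:20) {
    n <- 30
    Xr <- cbind(1, matrix(rnorm(n * 2), n))
    Xf <- cbind(Xr, matrix(rnorm(n * 2), n))
    y <- rnorm(n)
    h <- henderson3_extra_ss(y, Xf, Xr)
    rss_r <- sum(lm.fit(Xr, y)$residuals^2)
    rss_f <- sum(lm.fit(Xf, y)$residuals^2)
    expect_equal(h$ssr_extra, rss_r - rss_f, tolerance = 1e-10)
    expect_equal(h$sse, rss_f, tolerance = 1e-10)
  }
})

test_that("extra sum of squares is invariant to reparameterization and ordering", {
  set.seed(11)
  n <- 40
  Xr <- cbind(1, rnorm(n), rnorm(n))
  Xf <- cbind(Xr, rnorm(n))
  y <- rnorm(n)
  h0 <- henderson3_extra_ss(y, Xf, Xr)
  A <- matrix(rnorm(9), 3); while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3)
  h1 <- henderson3_extra_ss(y, cbind(Xr %*% A, Xf[, 4]), Xr %*% A)
  expect_equal(h1$ssr_extra, h0$ssr_extra, tolerance = 1e-8)
  h2 <- henderson3_extra_ss(y, Xf[, c(4, 2, 1, 3)], Xr[, c(3, 1, 2)])
  expect_equal(h2$ssr_extra, h0$ssr_extra, tolerance = 1e-8)
  # identical designs give zero extra SS
  expect_equal(henderson3_extra_ss(y, Xr, Xr)$ssr_extra, 0)
  # y orthogonal to the reduced-adjusted extra column gives zero extra SS
  e_perp <- residuals(lm(Xf[, 4] ~ 0 + Xr))
  y_orth <- y - e_perp * sum(e_perp * y) / sum(e_perp^2)
  expect_lt(henderson3_extra_ss(y_orth, Xf, Xr)$ssr_extra, 1e-16 * sum(y_orth^2))
  expect_error(henderson3_extra_ss(rnorm(3), cbind(1, rnorm(3), rnorm(3), rnorm(3)),
                                   matrix(1, 3, 1)), "degenerate")
})

test_that("partial F equals the textbook nested-model F and is scale invariant", {
  set.seed(12)
  for (i in 1:100) {
    n <- 25 + (i %% 10)
    p <- 2 + (i %% 3)
    Xr <- cbind(1, matrix(rnorm(n * p), n))
    Xf <- cbind(Xr, matrix(rnorm(n * 2), n))
    y <- rnorm(n)
    pf <- partial_f(y, Xf, Xr)
    rss_r <- sum(lm.fit(Xr, y)$residuals^2)
    rss_f <- sum(lm.fit(Xf, y)$residuals^2)
    Fref <- ((rss_r - rss_f) / 2) / (rss_f / (n - ncol(Xf)))
    expect_equal(pf$F, Fref, tolerance = 1e-8)
    expect_equal(partial_f(10 * y, Xf, Xr)$F, pf$F, tolerance = 1e-8)
  }
  # y inside the span of the extra columns: F guarded to infinity
  n <- 20
  Xr <- matrix(1, n, 1); xe <- rnorm(n)
  pf <- partial_f(xe - mean(xe), cbind(Xr, xe), Xr)
  expect_true(is.infinite(pf$F))
  expect_error(partial_f(rnorm(n), Xr, Xr), "undefined test")
})

test_that("partial F is calibrated under the null", {
  set.seed(13)
  n <- 40
  Xr <- cbind(1, rnorm(n))
  Xf <- cbind(Xr, rnorm(n), rnorm(n))
  crit <- qf(0.95, 2, n - 4)
  rej <- mean(replicate(2000, partial_f(rnorm(n), Xf, Xr)$F > crit))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.068)
})

test_that("REML matches the closed-form balanced one-way estimator", {
  set.seed(14)
  a <- 12; m <- 15
  g <- gl(a, m)
  U <- model.matrix(~ g - 1)
  y <- drop(U %*% rnorm(a, 0, 1.5)) + rnorm(a * m, 0, 0.8)
  r <- reml_components(y, matrix(1, a * m, 1), list(grp = U))
  ms <- anova(lm(y ~ g))
  s2e <- ms$`Mean Sq`[2]
  s2g <- max((ms$`Mean Sq`[1] - s2e) / m, 0)
  expect_true(r$converged)
  expect_equal(unname(r$sigma2["residual"]), s2e, tolerance = 1e-4)
  expect_equal(unname(r$sigma2["grp"]), s2g, tolerance = 1e-3)
})

test_that("REML agrees with lme4 on an unbalanced two-term design", {
  skip_if_not_installed("lme4")
  set.seed(15)
  n <- 180
  g1 <- factor(sample(letters[1:8], n, TRUE))
  g2 <- factor(sample(LETTERS[1:5], n, TRUE))
  x <- rnorm(n)
  U1 <- model.matrix(~ g1 - 1); U2 <- model.matrix(~ g2 - 1)
  y <- 1 + 0.5 * x + drop(U1 %*% rnorm(8, 0, 1.2)) +
    drop(U2 %*% rnorm(5, 0, 0.9)) + rnorm(n, 0, 0.7)
  r <- reml_components(y, cbind(1, x), list(g1 = U1, g2 = U2))
  lf <- lme4::lmer(y ~ x + (1 | g1) + (1 | g2), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(r$sigma2["g1"]), vc$vcov[vc$grp == "g1"], tolerance = 1e-3)
  expect_equal(unname(r$sigma2["g2"]), vc$vcov[vc$grp == "g2"], tolerance = 1e-3)
  expect_equal(unname(r$sigma2["residual"]), vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-3)
})

test_that("REML drives absent variance components to the boundary", {
  set.seed(16)
  n <- 300
  g <- gl(10, 30)
  U <- model.matrix(~ g - 1)
  y <- rnorm(n)  # no group structure at all
  r <- reml_components(y, matrix(1, n, 1), list(grp = U))
  expect_lt(unname(r$sigma2["grp"]), 0.02)
  expect_equal(unname(r$sigma2["residual"]), 1, tolerance = 0.15)
})

test_that("GLS reduces to OLS under identity covariance and AUP is centred", {
  set.seed(17)
  n <- 120
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("mu", "x1", "x2")
  sx <- cbind(as.numeric(rep(1:2, n / 2) == 1), as.numeric(rep(1:2, n / 2) == 2))
  y <- drop(X %*% c(1, 2, -1)) + drop(sx %*% c(1.5, -1.5)) + rnorm(n)
  g <- gls_fixed(y, X, diag(n))
  expect_equal(unname(g$b), unname(coef(lm(y ~ 0 + X))), tolerance = 1e-10)
  r <- reml_components(y, X, list(S = sx))
  V <- silkqtl:::build_V(n, list(S = sx), r$sigma2)
  e <- aup_random(y, X, list(S = sx), V, r$sigma2)
  expect_equal(sum(e$S), 0, tolerance = 1e-10)
  # prediction points the right way and matches the estimated component scale
  expect_gt(e$S[1], 0)
  expect_equal(var(e$S) * 1, unname(r$sigma2["S"]), tolerance = 1e-6)
})

test_that("AUP predictions track realized random effects increasingly well", {
  set.seed(18)
  cors <- vapply(c(0.3, 3), function(s2) {
    n <- 400; q <- 20
    g <- gl(q, n / q)
    U <- model.matrix(~ g - 1)
    X <- matrix(1, n, 1)
    eff <- rnorm(q, 0, sqrt(s2))
    y <- drop(U %*% eff) + rnorm(n)
    r <- reml_components(y, X, list(g = U))
    V <- silkqtl:::build_V(n, list(g = U), r$sigma2)
    e <- aup_random(y, X, list(g = U), V, r$sigma2)
    cor(e$g, eff)
  }, numeric(1))
  expect_true(all(cors > 0))
  expect_gt(cors[2], cors[1])
})

test_that("Gibbs posterior matches the conjugate normal-model posterior", {
  set.seed(19)
  n <- 80
  y <- rnorm(n, 3, 2)
  X <- matrix(1, n, 1, dimnames = list(NULL, "mu"))
  fit <- gibbs_estimate(y, X, U_list = list(), n_iter = 6000, burn_in = 1000,
                        seed = 42)
  # under a flat prior the posterior of mu is centred at the sample mean
  # with scale s/sqrt(n)
  expect_equal(fit$fixed$mean, mean(y), tolerance = 3 * sd(y) / sqrt(n) / 10)
  expect_equal(fit$fixed$sd, sd(y) / sqrt(n), tolerance = 0.2 * sd(y) / sqrt(n))
  expect_equal(fit$variance_components$mean[1], var(y), tolerance = 0.15 * var(y))
  # reproducibility under the seed
  fit2 <- gibbs_estimate(y, X, U_list = list(), n_iter = 6000, burn_in = 1000,
                         seed = 42)
  expect_identical(fit$fixed$mean, fit2$fixed$mean)
})

test_that("Gibbs recovers fixed and random structure of a mixed design", {
  set.seed(20)
  n <- 240
  x <- rnorm(n)
  sx <- cbind(S1 = as.numeric(rep(1:2, n / 2) == 1),
              S2 = as.numeric(rep(1:2, n / 2) == 2))
  X <- cbind(mu = 1, x = x)
  y <- 2 + 1.5 * x + drop(sx %*% c(2, -2)) + rnorm(n, 0, 1)
  init <- fit_mixed_model(y, X, list(S = sx))
  fit <- gibbs_estimate(y, X, list(S = sx), init = init,
                        n_iter = 4000, burn_in = 1000, seed = 7)
  expect_equal(fit$fixed$mean[fit$fixed$term == "x"], 1.5, tolerance = 0.2)
  s_pred <- fit$random$mean[fit$random$term == "S"]
  expect_gt(s_pred[1], 1)
  expect_lt(s_pred[2], -1)
  expect_true(fit$fixed$significant[fit$fixed$term == "x"])
})
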