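test_that("t statistics match hand arithmetic", {
  # paired differences [1, 2, 0, 3]: mean 1.5, sample variance 5/3
  x <- c(2, 4, 1, 6); y <- c(1, 2, 1, 3)
  d <- x - y
  tHand <- mean(d) / (sqrt(sum((d - mean(d))^2) / 3) / 2)
  expect_equal(tHand, 1.5 / (sqrt(5 / 3) / 2))
  res <- pairedT(x, y)
  expect_equal(unname(res["t"]), tHand, tolerance = 1e-12)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(unname(res["t"]), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(unname(res["p"]), ref$p.value, tolerance = 1e-12)
  # identical pairs: zero statistic, p = 1
  expect_equal(unname(pairedT(x, x)), c(0, 1))
  # mean equal to the null value
  expect_equal(unname(oneSampleT(1:5, 3)["t"]), 0)
  expect_error(oneSampleT(c(2, 2, 2), 0), "degenerate")
  expect_error(pairedT(1:3, 1:4), "length")
})

test_that("LMM log-likelihood matches a dense-covariance oracle", {
  set.seed(14)
  d <- simulateResponseData(nSubj = 4, nFroi = 2,
                            versions = "standard")  # 16 rows
  fit <- fitLmm(d, response ~ condition + (1 | subject) + (1 | froi),
                method = "ML")
  # independent dense ML: profile beta and sigma2, optimize the two
  # variance ratios on V = l1 Zs Zs' + l2 Zf Zf' + I
  X <- stats::model.matrix(~ condition, d)
  Zs <- stats::model.matrix(~ 0 + subject, d)
  Zf <- stats::model.matrix(~ 0 + froi, d)
  y <- d$response
  n <- length(y)
  profLL <- function(l) {
    V <- exp(l[1]) * tcrossprod(Zs) + exp(l[2]) * tcrossprod(Zf) + diag(n)
    Vi <- solve(V)
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    s2 <- as.numeric(t(r) %*% Vi %*% r) / n
    -0.5 * (n * log(2 * pi * s2) + as.numeric(determinant(V)$modulus) + n)
  }
  # coarse grid then local refinement, independent of lme4
  grid <- expand.grid(l1 = seq(-8, 4, by = 0.5), l2 = seq(-8, 4, by = 0.5))
  lls <- apply(grid, 1, profLL)
  start <- as.numeric(grid[which.max(lls), ])
  opt <- optim(start, function(l) -profLL(l), method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-4)
})

test_that("zero random-effect variance collapses to ordinary regression", {
  set.seed(8)
  d <- simulateResponseData(nSubj = 6, nFroi = 3, sdSubj = 0, sdFroi = 0,
                            sdResid = 0.5)
  # remove even the sampling variability between group means so the
  # variance components are squarely at the zero boundary
  e <- d$response - ave(d$response, d$condition, d$version)
  d$response <- d$response - ave(e, d$subject) - ave(e, d$froi)
  fit <- fitLmm(d, response ~ condition + version + (1 | subject) +
                  (1 | froi))
  ols <- lm(response ~ condition + version, d)
  expect_equal(fit$coefficients$beta, unname(coef(ols)), tolerance = 1e-4)
  expect_true(fit$singular)
  # Wald t converges to the OLS t at the boundary
  expect_equal(fit$coefficients$t[2],
               summary(ols)$coefficients[2, "t value"], tolerance = 1e-3)
})

test_that("interaction LRT has power against the built-in effect pattern", {
  set.seed(99)
  full <- response ~ condition * version + (1 | subject) + (1 | froi)
  red <- response ~ condition + version + (1 | subject) + (1 | froi)
  rej <- replicate(20, {
    # sentences up, nonwords down under speeded presentation
    d <- simulateResponseData(betaCond = 1.5, betaVer = -0.43,
                              betaInter = 0.72)
    lrtInteraction(d, full, red)$p < 0.05
  })
  expect_gt(mean(rej), 0.8)
  d <- simulateResponseData()
  expect_error(lrtInteraction(d, red, full), "nesting error")
  out <- lrtInteraction(d, full, red)
  expect_gte(out$chisq, 0)
  expect_equal(out$df, 1L)
  expect_true(out$p > 0 && out$p <= 1)
})

test_that("mixed R2 matches a from-scratch variance decomposition", {
  set.seed(3)
  d <- simulateResponseData()
  fit <- fitLmm(d, response ~ condition + version + (1 | subject) +
                  (1 | froi))
  # recompute from the fitted parameters directly
  lfit <- fit$fit
  vf <- var(as.vector(stats::model.matrix(lfit) %*% lme4::fixef(lfit)))
  vc <- as.data.frame(lme4::VarCorr(lfit))
  vr <- sum(vc$vcov[vc$grp != "Residual"])
  ve <- vc$vcov[vc$grp == "Residual"]
  expect_equal(fit$r2_marginal, vf / (vf + vr + ve), tolerance = 1e-6)
  expect_equal(fit$r2_conditional, (vf + vr) / (vf + vr + ve),
               tolerance = 1e-6)
  expect_lte(fit$r2_marginal, fit$r2_conditional)
  expect_lte(fit$r2_conditional, 1)
  # no fixed effects beyond the intercept: marginal R2 is 0
  fit0 <- fitLmm(d, response ~ 1 + (1 | subject) + (1 | froi))
  expect_equal(fit0$r2_marginal, 0, tolerance = 1e-12)
})

test_that("fits are invariant to row order", {
  set.seed(6)
  d <- simulateResponseData(nSubj = 8, nFroi = 3)
  f <- response ~ condition + version + (1 | subject) + (1 | froi)
  a <- fitLmm(d, f)
  b <- fitLmm(d[sample(nrow(d)), ], f)
  expect_equal(a$coefficients$beta, b$coefficients$beta, tolerance = 1e-8)
  expect_equal(a$loglik, b$loglik, tolerance = 1e-8)
})
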