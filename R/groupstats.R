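#' Fit a linear mixed-effects model on a response table
#'
#' Fits the Gaussian LMM with the given fixed effects and crossed random
#' intercepts via \pkg{lme4}/\pkg{lmerTest}, and reports fixed-effect
#' estimates with Satterthwaite degrees of freedom, variance components,
#' the log-likelihood, and marginal/conditional R-squared
#' (Nakagawa-Schielzeth). REML is the default for reported coefficients;
#' use ML when the fit feeds a likelihood-ratio comparison.
#'
#' A singular fit (a variance component estimated at the zero boundary) is
#' reported through the \code{singular} flag, not treated as failure.
#'
#' @param data long-format data.frame (e.g. a cross-validated response
#'   table with columns \code{response}, \code{condition}, \code{version},
#'   \code{subject}, \code{froi}).
#' @param formula an \pkg{lme4} formula, e.g.
#'   \code{response ~ condition + version + (1 | subject) + (1 | froi)}.
#' @param method "REML" or "ML".
#' @return A list of class \code{MixedModelResult} with elements
#'   \code{coefficients} (term, beta, se, df, t, p), \code{varcomp},
#'   \code{loglik}, \code{r2_marginal}, \code{r2_conditional},
#'   \code{singular}, and the underlying \code{fit}.
#' @export
fitLmm <- function(data, formula, method = c("REML", "ML")) {
  method <- match.arg(method)
  resp <- all.vars(formula)[1]
  if (!all(is.finite(data[[resp]]))) stop("response must be finite")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- lmerTest::lmer(formula, data = data, REML = method == "REML",
                        control = ctrl)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), beta = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  r2 <- mixedR2(fit)
  structure(list(coefficients = coefs, varcomp = varcomp,
                 loglik = as.numeric(logLik(fit)),
                 r2_marginal = r2[["r2_marginal"]],
                 r2_conditional = r2[["r2_conditional"]],
                 singular = lme4::isSingular(fit), method = method,
                 formula = formula, fit = fit),
            class = "MixedModelResult")
}

#' @export
print.MixedModelResult <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), logLik %.3f%s\n", x$method,
              x$loglik, if (x$singular) " [singular fit]" else ""))
  print(x$coefficients, digits = 4)
  cat("Variance components:\n")
  print(x$varcomp, digits = 4)
  cat(sprintf("R2 marginal %.3f, conditional %.3f\n", x$r2_marginal,
              x$r2_conditional))
  invisible(x)
}

#' Likelihood-ratio test for a fixed-effect term
#'
#' Both models are (re)fit by maximum likelihood (LRTs on fixed effects
#' are invalid under REML), and the test statistic is
#' \code{2 * (loglik_full - loglik_reduced)} (clipped at 0) on the
#' difference in fixed-effect count, with an upper-tail chi-square
#' p-value. Typical use: the condition-by-version interaction.
#'
#' @param data long-format data.frame.
#' @param full,reduced \pkg{lme4} formulas; \code{reduced} must be nested
#'   in \code{full} (its fixed-effect terms are a subset).
#' @return A list of class \code{LRTResult}: \code{chisq}, \code{df},
#'   \code{p}, and the two ML log-likelihoods.
#' @export
lrtInteraction <- function(data, full, reduced) {
  fxTerms <- function(f) attr(stats::terms(lme4::nobars(f)), "term.labels")
  if (!all(fxTerms(reduced) %in% fxTerms(full)))
    stop("nesting error: reduced fixed effects must be a subset of full")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fitF <- lme4::lmer(full, data = data, REML = FALSE, control = ctrl)
  fitR <- lme4::lmer(reduced, data = data, REML = FALSE, control = ctrl)
  df <- length(lme4::fixef(fitF)) - length(lme4::fixef(fitR))
  if (df < 1L) stop("nesting error: full model adds no fixed effects")
  chisq <- max(0, 2 * (as.numeric(logLik(fitF)) - as.numeric(logLik(fitR))))
  structure(list(chisq = chisq, df = df,
                 p = pchisq(chisq, df, lower.tail = FALSE),
                 loglik_full = as.numeric(logLik(fitF)),
                 loglik_reduced = as.numeric(logLik(fitR))),
            class = "LRTResult")
}

#' @export
print.LRTResult <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: chisq = %.3f, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Paired and one-sample t-tests
#'
#' Classical two-sided Student statistics. When all differences are
#' exactly zero the statistic is 0 with p = 1; a constant nonzero
#' difference (zero variance) is a degenerate input and raises an error.
#'
#' @param x,y paired numeric vectors (\code{pairedT}) or a single sample
#'   (\code{oneSampleT}).
#' @param mu0 null mean for the one-sample test.
#' @return Named numeric \code{c(t =, p =)}.
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must match in length")
  oneSampleT(x - y, 0)
}

#' @rdname pairedT
#' @export
oneSampleT <- function(x, mu0 = 0) {
  n <- length(x)
  if (n < 2L) stop("need at least two observations")
  s <- sd(x)
  if (s == 0) {
    if (mean(x) == mu0) return(c(t = 0, p = 1))
    stop("degenerate input: zero variance with nonzero mean difference")
  }
  tval <- (mean(x) - mu0) / (s / sqrt(n))
  c(t = tval, p = 2 * pt(-abs(tval), df = n - 1))
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Nakagawa-Schielzeth decomposition: marginal R2 is the fixed-effect
#' predicted variance over the total (fixed + random-intercept variances +
#' residual); conditional R2 adds the random-component variances to the
#' numerator.
#'
#' @param fit an \code{lmerMod}/\code{lmerModLmerTest} fit or a
#'   \code{MixedModelResult}.
#' @return Named numeric \code{c(r2_marginal =, r2_conditional =)}.
#' @export
mixedR2 <- function(fit) {
  if (inherits(fit, "MixedModelResult")) fit <- fit$fit
  X <- lme4::getME(fit, "X")
  varFix <- var(as.vector(X %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varRand <- sum(vc$vcov[vc$grp != "Residual"])
  varResid <- vc$vcov[vc$grp == "Residual"]
  tot <- varFix + varRand + varResid
  c(r2_marginal = varFix / tot, r2_conditional = (varFix + varRand) / tot)
}
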