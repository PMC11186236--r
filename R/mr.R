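#' @include AllClasses.R
NULL

.mr_result <- function(id, outcomeId, method, beta = NA_real_, se = NA_real_,
                       pval = NA_real_, k = 0L, binary = FALSE,
                       qStat = NA_real_, qDf = NA_integer_, qPval = NA_real_,
                       eggerIntercept = NA_real_, eggerInterceptP = NA_real_,
                       status = "ok", metadata = list()) {
  if (!is.na(pval)) pval <- max(pval, .Machine$double.xmin)
  if (binary && !is.na(beta) && !is.na(se)) {
    orPoint <- exp(beta)
    orLow <- exp(beta - qnorm(0.975) * se)
    orHigh <- exp(beta + qnorm(0.975) * se)
  } else orPoint <- orLow <- orHigh <- NA_real_
  new("MRResult", id = id, outcomeId = outcomeId, method = method,
      beta = beta, se = se, pval = pval, nInstruments = as.integer(k),
      orPoint = orPoint, orLow = orLow, orHigh = orHigh,
      qStat = qStat, qDf = qDf, qPval = qPval,
      eggerIntercept = eggerIntercept, eggerInterceptP = eggerInterceptP,
      status = status, metadata = metadata)
}

.pair_matrix <- function(x) {
  p <- if (is(x, "InstrumentSet")) x@pairs@pairs
       else if (is(x, "HarmonizedPairs")) keptPairs(x)@pairs
       else as.data.frame(x)
  p
}

#' Wald ratio estimate from a single instrument
#'
#' Single-instrument causal estimate: the outcome effect divided by the
#' exposure effect, with a delta-method standard error. The default
#' first-order SE is \code{se_out/|beta_exp|}; with
#' \code{secondOrder=TRUE} the term
#' \code{beta_out^2 se_exp^2 / beta_exp^4} is added under the square root,
#' propagating uncertainty in the exposure effect as well.
#'
#' @param betaExp,seExp exposure association and SE.
#' @param betaOut,seOut outcome association and SE.
#' @param secondOrder logical; use the second-order delta SE.
#' @param binary logical; outcome on the log-odds scale, so odds-ratio
#'   fields are filled by exponentiation.
#' @param id,outcomeId identifiers carried into the result.
#' @return an \linkS4class{MRResult} with method \code{"wald"}.
#' @export
waldRatio <- function(betaExp, seExp, betaOut, seOut, secondOrder = FALSE,
                      binary = TRUE, id = "exposure", outcomeId = "outcome") {
  if (betaExp == 0) stop("Wald ratio undefined: exposure beta is zero")
  beta <- betaOut / betaExp
  se <- if (secondOrder)
    sqrt(seOut^2 / betaExp^2 + betaOut^2 * seExp^2 / betaExp^4)
  else seOut / abs(betaExp)
  pval <- 2 * pnorm(-abs(beta / se))
  .mr_result(id, outcomeId, "wald", beta, se, pval, 1L, binary,
             metadata = list(delta_order = if (secondOrder) 2L else 1L))
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Fixed-effect IVW over k harmonized instruments:
#' \code{beta = sum(w bx by) / sum(w bx^2)} with weights
#' \code{w = 1/se_out^2} and \code{se = 1/sqrt(sum(w bx^2))} -- the weighted
#' least-squares line through the origin of outcome on exposure effects.
#' Cochran's Q \code{= sum(w bx^2 (by/bx - beta)^2)} with k-1 df measures
#' heterogeneity of the per-instrument ratios; it is reported, never used to
#' exclude instruments. A single instrument dispatches to
#' \code{\link{waldRatio}}.
#'
#' @param x an \linkS4class{InstrumentSet}, \linkS4class{HarmonizedPairs},
#'   or data.frame with beta_exp/se_exp/beta_out/se_out columns.
#' @param binary logical; outcome is binary (log-odds scale).
#' @param id,outcomeId identifiers.
#' @return an \linkS4class{MRResult} with method \code{"ivw"} (or
#'   \code{"wald"} for k = 1).
#' @export
mrIVW <- function(x, binary = TRUE, id = "exposure", outcomeId = "outcome") {
  p <- .pair_matrix(x)
  if (is(x, "InstrumentSet")) id <- x@id
  k <- nrow(p)
  if (k == 0L)
    return(.mr_result(id, outcomeId, "none", k = 0L, status = "no_instruments"))
  if (k == 1L)
    return(waldRatio(p$beta_exp, p$se_exp, p$beta_out, p$se_out,
                     binary = binary, id = id, outcomeId = outcomeId))
  bx <- p$beta_exp; by <- p$beta_out
  w <- 1 / p$se_out^2
  swx2 <- sum(w * bx^2)
  if (swx2 == 0) stop("all exposure betas are zero")
  beta <- sum(w * bx * by) / swx2
  se <- 1 / sqrt(swx2)
  pval <- 2 * pnorm(-abs(beta / se))
  q <- sum(w * bx^2 * (by / bx - beta)^2)
  qDf <- k - 1L
  qPval <- pchisq(q, df = qDf, lower.tail = FALSE)
  .mr_result(id, outcomeId, "ivw", beta, se, pval, k, binary,
             qStat = q, qDf = qDf, qPval = qPval,
             metadata = list(model = "fixed_effect"))
}

## Weighted least squares with intercept solved from the normal equations;
## matches stats::lm(y ~ x, weights = w) coefficients and classical SEs.
.wls <- function(x, y, w) {
  X <- cbind(1, x)
  XtW <- t(X * w)
  A <- XtW %*% X
  coef <- solve(A, XtW %*% y)
  res <- y - X %*% coef
  k <- length(y)
  s2 <- sum(w * res^2) / (k - 2)
  se <- sqrt(diag(solve(A)) * s2)
  list(intercept = coef[1], slope = coef[2],
       se_intercept = se[1], se_slope = se[2], df = k - 2L)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression (weights 1/se_out^2) of outcome on
#' exposure effects with a free intercept, after orienting instruments so
#' all exposure betas are nonnegative (joint sign flips; the standard
#' InSIDE bookkeeping). The slope is the pleiotropy-adjusted causal
#' estimate; an intercept departing from zero (p < 0.05) signals
#' directional horizontal pleiotropy. Inference uses the t reference with
#' k-2 degrees of freedom.
#'
#' @inheritParams mrIVW
#' @return an \linkS4class{MRResult} with method \code{"egger"}; with fewer
#'   than 3 instruments the result is flagged \code{not_computable}.
#' @export
mrEgger <- function(x, binary = TRUE, id = "exposure", outcomeId = "outcome") {
  p <- .pair_matrix(x)
  if (is(x, "InstrumentSet")) id <- x@id
  k <- nrow(p)
  if (k < 3L)
    return(.mr_result(id, outcomeId, "egger", k = k, status = "not_computable"))
  flip <- sign(p$beta_exp)
  flip[flip == 0] <- 1
  bx <- p$beta_exp * flip
  by <- p$beta_out * flip
  w <- 1 / p$se_out^2
  fit <- .wls(bx, by, w)
  t_slope <- fit$slope / fit$se_slope
  t_int <- fit$intercept / fit$se_intercept
  .mr_result(id, outcomeId, "egger", fit$slope, fit$se_slope,
             2 * pt(-abs(t_slope), df = fit$df), k, binary,
             eggerIntercept = fit$intercept,
             eggerInterceptP = 2 * pt(-abs(t_int), df = fit$df),
             metadata = list(reference = "t", df = fit$df))
}

#' Per-protein MR bundle
#'
#' Runs the primary estimator for one protein's instrument set -- the Wald
#' ratio for a single instrument, IVW for two or more -- and attaches
#' MR-Egger (when at least 3 instruments) and Cochran's Q as diagnostics.
#'
#' @param instruments an \linkS4class{InstrumentSet} (possibly empty).
#' @param binary logical; outcome binary.
#' @param outcomeId outcome label.
#' @return list with elements \code{primary} (\linkS4class{MRResult}),
#'   \code{egger} (\linkS4class{MRResult} or NULL), \code{fStats},
#'   \code{status}.
#' @export
runProteinMR <- function(instruments, binary = TRUE, outcomeId = "outcome") {
  stopifnot(is(instruments, "InstrumentSet"))
  k <- nrow(instruments@pairs@pairs)
  if (k == 0L)
    return(list(primary = .mr_result(instruments@id, outcomeId, "none",
                                     k = 0L, status = "no_instruments"),
                egger = NULL, fStats = instruments@fStats,
                status = "no_instruments"))
  primary <- mrIVW(instruments, binary = binary, outcomeId = outcomeId)
  egger <- if (k >= 3L) mrEgger(instruments, binary = binary,
                                outcomeId = outcomeId) else NULL
  list(primary = primary, egger = egger, fStats = instruments@fStats,
       status = "ok")
}
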