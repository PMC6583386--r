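#' Convert a per-ln-unit log odds ratio to the per-2-fold scale
#'
#' MR estimates are computed as ln-odds-ratios per 1-ln-unit increment in
#' the biomarker. For reporting, they are rescaled to the odds ratio per
#' 2-fold (doubling) increment: `OR_2fold = exp(beta * ln 2)`, i.e. the
#' per-ln-unit odds ratio raised to the power ln 2. The CI bounds are the
#' monotone image of the additive 95% CI.
#'
#' @param beta effect on the ln-OR per ln-unit scale.
#' @param se standard error of `beta` (>= 0).
#' @return named numeric vector `c(or, low, high)`.
#' @examples
#' toFoldScale(0, 0.1)       # null maps to OR 1
#' toFoldScale(1, 0)[["or"]] # 2: one ln-unit per doubling
#' @export
toFoldScale <- function(beta, se) {
  stopifnot(length(beta) == 1L, length(se) == 1L)
  if (is.na(beta) || is.na(se)) stop("beta and se must be non-missing")
  if (se < 0) stop("se must be non-negative", call. = FALSE)
  hi <- (abs(beta) + Z95 * se) * log(2)
  if (hi > 700)
    stop("numeric overflow on the fold scale: |beta| + 1.96 se = ",
         format(abs(beta) + Z95 * se), call. = FALSE)
  c(or = exp(beta * log(2)),
    low = exp((beta - Z95 * se) * log(2)),
    high = exp((beta + Z95 * se) * log(2)))
}

#' Per-variant Wald ratio estimates
#'
#' For each retained variant, the causal-effect estimate is the ratio of
#' the variant-outcome to the variant-exposure association,
#' `ratio = by / bx`, with first-order delta-method standard error
#' `sy / |bx|` (the exposure association treated as known — the NOME
#' assumption). The inverse-variance weight `se^-2` is attached for use by
#' the pooled estimators.
#'
#' @param h a [HarmonizedSet-class].
#' @return `data.frame` with columns `snp`, `ratio`, `se`, `weight`.
#' @seealso [mrIvw()], [mrMedian()], [attenuationStats()]
#' @export
mrRatio <- function(h) {
  stopifnot(is(h, "HarmonizedSet"))
  d <- h@data
  zero <- d$bx == 0
  if (any(zero))
    stop("degenerate instrument(s) with zero exposure effect: ",
         paste(d$snp[zero], collapse = ", "), call. = FALSE)
  se <- d$sy / abs(d$bx)
  data.frame(snp = d$snp, ratio = d$by / d$bx, se = se,
             weight = se^-2, stringsAsFactors = FALSE)
}

cochranQStat <- function(ratio, weight) {
  betaF <- sum(weight * ratio) / sum(weight)
  sum(weight * (ratio - betaF)^2)
}

#' Inverse-variance-weighted estimate
#'
#' Pools per-variant ratio estimates by their inverse-variance weights:
#' `beta = sum(w * ratio) / sum(w)`. Under the fixed-effects model the
#' standard error is `sum(w)^-0.5`; under multiplicative random effects it
#' is inflated by `sqrt(max(1, Q / (L - 1)))` with `Q` the Cochran
#' heterogeneity statistic, so heterogeneity widens but never narrows the
#' interval. The point estimate is identical under both models.
#'
#' @param est per-variant estimates from [mrRatio()].
#' @param effectsModel `"multiplicative_random"` (default) or `"fixed"`.
#' @return an [MREstimate-class].
#' @examples
#' est <- data.frame(snp = c("rs1", "rs2"), ratio = c(0.1, 0.2),
#'                   se = c(0.02, 0.04), weight = c(2500, 625))
#' mrBeta(mrIvw(est, "fixed"))  # 0.12
#' @export
mrIvw <- function(est, effectsModel = c("multiplicative_random", "fixed")) {
  effectsModel <- match.arg(effectsModel)
  if (nrow(est) < 2L)
    stop("insufficient instruments: IVW needs at least 2 (got ",
         nrow(est), ")", call. = FALSE)
  w <- est$weight
  beta <- sum(w * est$ratio) / sum(w)
  se <- sum(w)^-0.5
  L <- nrow(est)
  if (effectsModel == "multiplicative_random") {
    q <- cochranQStat(est$ratio, w)
    se <- se * sqrt(max(1, q / (L - 1)))
  }
  newMREstimate("ivw", effectsModel, beta, se, L)
}

#' IVW for correlated instruments (generalized weighted regression)
#'
#' When instruments are in linkage disequilibrium their ratio estimates are
#' correlated and plain IVW overstates precision. This estimator fits the
#' generalized weighted regression of `by` on `bx` through the origin with
#' covariance `Omega = diag(sy) %*% rho %*% diag(sy)`:
#' `beta = (bx' Omega^-1 bx)^-1 bx' Omega^-1 by`, with standard error
#' `(bx' Omega^-1 bx)^-0.5`, inflated under multiplicative random effects
#' by the square root of the residual dispersion (floored at 1). With an
#' identity LD matrix it reduces exactly to fixed-effects IVW.
#'
#' @param h a [HarmonizedSet-class].
#' @param ld an [LDMatrix-class] covering every retained variant.
#' @param effectsModel `"multiplicative_random"` (default) or `"fixed"`.
#' @return an [MREstimate-class].
#' @export
mrIvwCorrelated <- function(h, ld,
                            effectsModel = c("multiplicative_random",
                                             "fixed")) {
  effectsModel <- match.arg(effectsModel)
  stopifnot(is(h, "HarmonizedSet"), is(ld, "LDMatrix"))
  d <- h@data
  L <- nrow(d)
  if (L < 2L)
    stop("insufficient instruments: need at least 2", call. = FALSE)
  idx <- match(tolower(d$snp), tolower(ld@snpIds))
  if (anyNA(idx))
    stop("LD matrix does not cover variant(s): ",
         paste(d$snp[is.na(idx)], collapse = ", "), call. = FALSE)
  rho <- ld@rho[idx, idx, drop = FALSE]
  omega <- rho * tcrossprod(d$sy)
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < sqrt(.Machine$double.eps) * max(diag(ch)))
    stop("conditioning error: instrument covariance is numerically ",
         "singular; consider pruning near-duplicate instruments",
         call. = FALSE)
  oiBx <- backsolve(ch, forwardsolve(t(ch), d$bx))
  oiBy <- backsolve(ch, forwardsolve(t(ch), d$by))
  xwx <- sum(d$bx * oiBx)
  beta <- sum(d$bx * oiBy) / xwx
  se <- xwx^-0.5
  if (effectsModel == "multiplicative_random") {
    resid <- d$by - d$bx * beta
    oiR <- backsolve(ch, forwardsolve(t(ch), resid))
    phi <- sum(resid * oiR) / (L - 1)
    se <- se * sqrt(max(1, phi))
  }
  newMREstimate("correlated_ivw", effectsModel, beta, se, L)
}

weightedMedianCore <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  wn <- weight[o] / sum(weight)
  s <- cumsum(wn) - wn / 2          # cumulative midpoints
  if (s[1] >= 0.5) return(r[1])     # clamp when 0.5 precedes the grid
  L <- length(r)
  if (s[L] <= 0.5) return(r[L])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The weighted median is the 50% point of the weighted empirical
#' distribution of the per-variant ratio estimates: ratios are sorted, each
#' is placed at the cumulative midpoint of its normalized weight, and the
#' estimate is the linear interpolation of the ordered ratios at 0.5
#' (clamped to the extreme ratios when 0.5 falls outside the midpoint
#' range). It is consistent when variants contributing more than half of
#' the total weight are valid instruments. The standard error is obtained
#' by parametric bootstrap: each ratio is resampled from a normal with its
#' own standard error, the weighted median recomputed, and the standard
#' deviation across replicates taken.
#'
#' @param est per-variant estimates from [mrRatio()] (at least 3).
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed mandatory seed for the bootstrap.
#' @return an [MREstimate-class] (method `"weighted_median"`).
#' @examples
#' est <- data.frame(ratio = c(0.1, 0.2, 0.3), se = rep(0.05, 3),
#'                   weight = rep(400, 3))
#' mrBeta(mrMedian(est, seed = 1))  # simple median: 0.2
#' @export
mrMedian <- function(est, nBoot = 1000L, seed) {
  if (nrow(est) < 3L)
    stop("insufficient instruments: weighted median needs at least 3 ",
         "(got ", nrow(est), ")", call. = FALSE)
  beta <- weightedMedianCore(est$ratio, est$weight)
  L <- nrow(est)
  boots <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      weightedMedianCore(stats::rnorm(L, est$ratio, est$se), est$weight)
    }, numeric(1))
  })
  newMREstimate("weighted_median", "bootstrap", beta, stats::sd(boots), L)
}

## Weighted least squares of by on bx with intercept, weights sy^-2,
## after recoding every variant to a non-negative exposure effect.
## Returns coefficients, covariance pieces and the weighted RSS.
eggerFit <- function(bx, by, sy) {
  s <- ifelse(bx < 0, -1, 1)
  bxo <- bx * s
  byo <- by * s
  if (max(bxo) - min(bxo) < .Machine$double.eps * max(1, max(abs(bxo))))
    stop("collinearity error: no variance in the exposure effects",
         call. = FALSE)
  w <- sy^-2
  X <- cbind(1, bxo)
  xwx <- crossprod(X, w * X)
  coefs <- solve(xwx, crossprod(X, w * byo))
  fitted <- X %*% coefs
  qres <- sum(w * (byo - fitted)^2)
  list(intercept = coefs[1], slope = coefs[2], cov = solve(xwx),
       qres = qres, n = length(bx))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the variant-outcome on the
#' variant-exposure associations with an intercept, weights `sy^-2`.
#' Variants are first recoded so every exposure effect is non-negative
#' (flipping the outcome effect in tandem), which makes the intercept
#' interpretable as the average directional pleiotropic effect: under no
#' unbalanced horizontal pleiotropy the intercept is zero, and under the
#' InSIDE assumption the slope is a consistent causal-effect estimate even
#' when every instrument is pleiotropic. The fixed-effects model holds the
#' residual variance at 1; multiplicative random effects scales both
#' standard errors by `sqrt(max(1, Q' / (L - 2)))` with `Q'` the weighted
#' residual sum of squares.
#'
#' @param h a [HarmonizedSet-class] with at least 3 variants.
#' @param effectsModel `"multiplicative_random"` (default) or `"fixed"`.
#' @return an [EggerResult-class].
#' @seealso [simexEgger()] for the weak-instrument-corrected version.
#' @export
mrEgger <- function(h, effectsModel = c("multiplicative_random", "fixed")) {
  effectsModel <- match.arg(effectsModel)
  stopifnot(is(h, "HarmonizedSet"))
  d <- h@data
  if (nrow(d) < 3L)
    stop("insufficient instruments: MR-Egger needs at least 3 (got ",
         nrow(d), ")", call. = FALSE)
  fit <- eggerFit(d$bx, d$by, d$sy)
  eggerResultFromFit(fit, effectsModel)
}

eggerResultFromFit <- function(fit, effectsModel) {
  phi <- if (effectsModel == "multiplicative_random")
    max(1, fit$qres / (fit$n - 2)) else 1
  seInt <- sqrt(phi * fit$cov[1, 1])
  seSlope <- sqrt(phi * fit$cov[2, 2])
  slope <- newMREstimate("egger", effectsModel, fit$slope, seSlope, fit$n)
  ciInt <- c(fit$intercept - Z95 * seInt, fit$intercept + Z95 * seInt)
  zInt <- if (seInt > 0) fit$intercept / seInt
          else if (fit$intercept == 0) 0 else Inf
  new("EggerResult", slope = slope,
      interceptBeta = fit$intercept, interceptSe = seInt,
      interceptCiLow = ciInt[1], interceptCiHigh = ciInt[2],
      interceptP = twoSidedP(zInt),
      interceptOdds = exp(fit$intercept),
      interceptOddsLow = exp(ciInt[1]), interceptOddsHigh = exp(ciInt[2]),
      effectsModel = effectsModel, nSnps = as.integer(fit$n))
}
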