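#' Weak-instrument attenuation statistics
#'
#' Both IVW and MR-Egger treat the variant-exposure associations as known
#' constants (the no-measurement-error, NOME, assumption). Sampling error
#' in `bx` dilutes the estimates toward the null. Two statistics quantify
#' the expected attenuation:
#'
#' * mean instrument strength `F_bar = mean(bx^2 / sx^2)`; the IVW
#'   estimate is expected to be attenuated by the factor
#'   `F_bar / (F_bar + 1)`, reported as a percentage;
#' * `I2_GX = max(0, (Q_GX - (L - 1)) / Q_GX) * 100`, where `Q_GX` is the
#'   Cochran-type statistic of the variant-exposure associations with
#'   weights `sx^-2`; it approximates the expected relative attenuation of
#'   the MR-Egger slope.
#'
#' Values near 100% indicate negligible attenuation; low values motivate
#' the SIMEX correction of [simexEgger()].
#'
#' @param h a [HarmonizedSet-class] with at least 2 variants.
#' @param qWeights `"sx"` (default): `Q_GX` weighted by `sx^-2`; `"sy"`:
#'   weighted by `sy^-2` instead (the outcome-weighted variant).
#' @return an [AttenuationStats-class].
#' @export
attenuationStats <- function(h, qWeights = c("sx", "sy")) {
  qWeights <- match.arg(qWeights)
  stopifnot(is(h, "HarmonizedSet"))
  d <- h@data
  L <- nrow(d)
  if (L < 2L)
    stop("insufficient instruments: need at least 2", call. = FALSE)
  if (any(d$sx == 0)) {
    # no measurement error at all: no attenuation
    return(new("AttenuationStats", fBar = Inf, ivwDilution = 100,
               i2gx = 100, nSnps = as.integer(L)))
  }
  fBar <- mean(d$bx^2 / d$sx^2)
  w <- if (qWeights == "sx") d$sx^-2 else d$sy^-2
  bxBar <- sum(w * d$bx) / sum(w)
  qGx <- sum(d$sx^-2 * (d$bx - bxBar)^2)
  i2 <- if (qGx > 0) 100 * max(0, (qGx - (L - 1)) / qGx) else 0
  new("AttenuationStats", fBar = fBar,
      ivwDilution = 100 * fBar / (fBar + 1), i2gx = i2,
      nSnps = as.integer(L))
}

quadExtrapolate <- function(lambda, y, at = -1) {
  X <- cbind(1, lambda, lambda^2)
  coefs <- qr.solve(X, y)
  sum(coefs * c(1, at, at^2))
}

#' SIMEX-corrected MR-Egger regression
#'
#' Corrects the weak-instrument (NOME-violation) attenuation of MR-Egger
#' by simulation extrapolation: for each multiplier `lambda` in the grid,
#' additional measurement error `sqrt(lambda) * sx * epsilon` is added to
#' the variant-exposure associations over many replicates, Egger is refit
#' on each pseudo-dataset and the coefficients are averaged. A quadratic
#' in `lambda` is fit to the averaged slope and intercept and extrapolated
#' to `lambda = -1`, the no-measurement-error state. Standard errors use
#' the simulation-extrapolation difference method: the model-based
#' variance minus the between-replicate variance, extrapolated in
#' `lambda` alongside the coefficients (floored at zero). The result is
#' deterministic given `seed`; with vanishing `sx` the correction reduces
#' to the uncorrected fit.
#'
#' @param h a [HarmonizedSet-class] with at least 3 variants.
#' @param lambdaGrid strictly increasing added-error multipliers starting
#'   at 0; at least 3 values are needed for the quadratic extrapolation.
#' @param nReplicates pseudo-datasets per positive `lambda` (default 1000).
#' @param seed mandatory seed.
#' @param effectsModel `"multiplicative_random"` (default) or `"fixed"`,
#'   applied to every Egger refit.
#' @return an [EggerResult-class] (the extrapolated fit).
#' @seealso [mrEgger()], [attenuationStats()]
#' @export
simexEgger <- function(h, lambdaGrid = c(0, 0.5, 1, 1.5, 2),
                       nReplicates = 1000L, seed,
                       effectsModel = c("multiplicative_random", "fixed")) {
  effectsModel <- match.arg(effectsModel)
  stopifnot(is(h, "HarmonizedSet"))
  d <- h@data
  L <- nrow(d)
  if (L < 3L)
    stop("insufficient instruments: MR-Egger needs at least 3", call. = FALSE)
  if (length(lambdaGrid) < 3L)
    stop("configuration error: lambdaGrid needs at least 3 values for ",
         "quadratic extrapolation", call. = FALSE)
  if (lambdaGrid[1] != 0 || any(diff(lambdaGrid) <= 0))
    stop("configuration error: lambdaGrid must be strictly increasing ",
         "and start at 0", call. = FALSE)

  phiOf <- function(fit) if (effectsModel == "multiplicative_random")
    max(1, fit$qres / (fit$n - 2)) else 1

  summarise <- function(lambda) {
    if (lambda == 0) {
      fit <- eggerFit(d$bx, d$by, d$sy)
      phi <- phiOf(fit)
      return(c(int = fit$intercept, slo = fit$slope,
               vInt = phi * fit$cov[1, 1], vSlo = phi * fit$cov[2, 2],
               bInt = 0, bSlo = 0))
    }
    ints <- slos <- vInts <- vSlos <- numeric(nReplicates)
    for (r in seq_len(nReplicates)) {
      bxr <- d$bx + sqrt(lambda) * d$sx * stats::rnorm(L)
      fit <- eggerFit(bxr, d$by, d$sy)
      phi <- phiOf(fit)
      ints[r] <- fit$intercept
      slos[r] <- fit$slope
      vInts[r] <- phi * fit$cov[1, 1]
      vSlos[r] <- phi * fit$cov[2, 2]
    }
    c(int = mean(ints), slo = mean(slos),
      vInt = mean(vInts), vSlo = mean(vSlos),
      bInt = stats::var(ints), bSlo = stats::var(slos))
  }

  sims <- withSeed(seed, vapply(lambdaGrid, summarise, numeric(6)))

  slope <- quadExtrapolate(lambdaGrid, sims["slo", ])
  intercept <- quadExtrapolate(lambdaGrid, sims["int", ])
  varSlope <- max(0, quadExtrapolate(lambdaGrid,
                                     sims["vSlo", ] - sims["bSlo", ]))
  varInt <- max(0, quadExtrapolate(lambdaGrid,
                                   sims["vInt", ] - sims["bInt", ]))

  slopeEst <- newMREstimate("egger_simex", effectsModel, slope,
                            sqrt(varSlope), L)
  seInt <- sqrt(varInt)
  ciInt <- c(intercept - Z95 * seInt, intercept + Z95 * seInt)
  zInt <- if (seInt > 0) intercept / seInt
          else if (intercept == 0) 0 else Inf
  new("EggerResult", slope = slopeEst,
      interceptBeta = intercept, interceptSe = seInt,
      interceptCiLow = ciInt[1], interceptCiHigh = ciInt[2],
      interceptP = twoSidedP(zInt),
      interceptOdds = exp(intercept),
      interceptOddsLow = exp(ciInt[1]), interceptOddsHigh = exp(ciInt[2]),
      effectsModel = effectsModel, nSnps = as.integer(L))
}
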