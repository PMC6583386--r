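## accept an MREstimate, or a numeric c(estimate, se)
asEffect <- function(x, what) {
  if (is(x, "MREstimate")) return(c(beta = x@beta, se = x@se))
  if (is.numeric(x) && length(x) == 2L) {
    if (x[2] < 0) stop(what, ": se must be non-negative", call. = FALSE)
    return(c(beta = unname(x[1]), se = unname(x[2])))
  }
  stop(what, " must be an MREstimate or c(estimate, se)", call. = FALSE)
}

#' Product-of-coefficients mediation analysis
#'
#' Given MR estimates of the exposure-to-mediator effect `a`, the
#' mediator-to-outcome effect `b` and (optionally) the total
#' exposure-to-outcome effect `c`, computes the indirect effect `a * b` —
#' the expected effect of the exposure on the outcome if the mediator
#' fully transmits it — together with its fold-scale odds ratio, and the
#' proportion of the total effect mediated, `a * b / c`, as a percentage.
#'
#' Uncertainty assumes the three estimates come from non-overlapping
#' samples (zero covariances). With `ciMethod = "delta"` the indirect
#' effect's standard error is `sqrt(b^2 se_a^2 + a^2 se_b^2)` and both CIs
#' are normal-approximation intervals; with `"monte_carlo"` (the default,
#' recommended for the proportion, whose ratio form makes the delta
#' interval unstable when `c` is imprecise) the three effects are drawn
#' from independent normals and percentile intervals are taken.
#'
#' @param aEst,bEst,cEst each an [MREstimate-class] or a numeric
#'   `c(estimate, se)`; `cEst` may be `NULL` when only the indirect effect
#'   is wanted.
#' @param ciMethod `"monte_carlo"` (default) or `"delta"`.
#' @param nDraws Monte-Carlo draws (default 100000).
#' @param seed mandatory when `ciMethod = "monte_carlo"`.
#' @return a [MediationResult-class].
#' @examples
#' # expected effect of an exposure acting wholly through its mediator
#' m <- mediationAnalysis(c(-0.26, 0.028), c(-0.14, 0.046),
#'                        cEst = c(0.0841, 0.023), ciMethod = "delta")
#' round(m@expectedOr2fold, 2)  # 1.03
#' @export
mediationAnalysis <- function(aEst, bEst, cEst = NULL,
                              ciMethod = c("monte_carlo", "delta"),
                              nDraws = 100000L, seed = NULL) {
  ciMethod <- match.arg(ciMethod)
  a <- asEffect(aEst, "aEst")
  b <- asEffect(bEst, "bEst")
  cc <- if (is.null(cEst)) c(beta = NA_real_, se = NA_real_)
        else asEffect(cEst, "cEst")
  if (nDraws < 1) stop("configuration error: nDraws must be positive",
                       call. = FALSE)

  ind <- a[["beta"]] * b[["beta"]]
  seIndDelta <- sqrt(b[["beta"]]^2 * a[["se"]]^2 +
                     a[["beta"]]^2 * b[["se"]]^2)
  haveC <- !is.na(cc[["beta"]])
  if (haveC && cc[["beta"]] == 0) {
    warning("proportion mediated undefined: total effect is zero; ",
            "reporting the indirect effect only")
    haveC <- FALSE
  }

  if (ciMethod == "delta") {
    seInd <- seIndDelta
    indCI <- c(ind - Z95 * seInd, ind + Z95 * seInd)
    if (haveC) {
      prop <- 100 * ind / cc[["beta"]]
      seProp <- 100 * sqrt(seIndDelta^2 / cc[["beta"]]^2 +
                           ind^2 * cc[["se"]]^2 / cc[["beta"]]^4)
      propCI <- c(prop - Z95 * seProp, prop + Z95 * seProp)
    }
  } else {
    if (is.null(seed))
      stop("a seed is mandatory for Monte-Carlo intervals", call. = FALSE)
    draws <- withSeed(seed, {
      da <- stats::rnorm(nDraws, a[["beta"]], a[["se"]])
      db <- stats::rnorm(nDraws, b[["beta"]], b[["se"]])
      dc <- if (haveC) stats::rnorm(nDraws, cc[["beta"]], cc[["se"]])
            else rep(NA_real_, nDraws)
      list(ind = da * db, prop = 100 * da * db / dc)
    })
    seInd <- stats::sd(draws$ind)
    indCI <- unname(stats::quantile(draws$ind, c(0.025, 0.975)))
    if (haveC) {
      prop <- 100 * ind / cc[["beta"]]
      propCI <- unname(stats::quantile(draws$prop, c(0.025, 0.975)))
    }
  }
  if (!haveC) prop <- propCI <- c(NA_real_, NA_real_)

  fold <- exp(c(ind, indCI) * log(2))
  new("MediationResult",
      a = a[["beta"]], seA = a[["se"]], b = b[["beta"]], seB = b[["se"]],
      cTotal = cc[["beta"]], seC = cc[["se"]],
      indirect = ind, seIndirect = seInd,
      indirectCiLow = indCI[1], indirectCiHigh = indCI[2],
      expectedOr2fold = fold[1], expectedOr2foldLow = fold[2],
      expectedOr2foldHigh = fold[3],
      proportionMediated = prop[1], proportionCiLow = propCI[1],
      proportionCiHigh = propCI[2], ciMethod = ciMethod)
}
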