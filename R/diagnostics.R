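#' Cochran Q heterogeneity test
#'
#' Tests whether all per-variant ratio estimates are compatible with a
#' single causal effect: `Q = sum(w * (ratio - beta_ivw)^2)` with
#' fixed-effects weights, referred to a chi-square distribution on
#' `L - 1` degrees of freedom. Excess heterogeneity is a signal of
#' horizontal pleiotropy (or other violations of instrument validity).
#'
#' @param est per-variant estimates from [mrRatio()] (at least 2).
#' @return a [QResult-class].
#' @examples
#' est <- data.frame(ratio = c(0.1, 0.2), se = c(0.02, 0.04),
#'                   weight = c(2500, 625))
#' cochranQ(est)  # Q = 5 on 1 df
#' @export
cochranQ <- function(est) {
  if (nrow(est) < 2L)
    stop("insufficient instruments: Cochran Q needs at least 2",
         call. = FALSE)
  q <- cochranQStat(est$ratio, est$weight)
  df <- nrow(est) - 1
  p <- max(stats::pchisq(q, df, lower.tail = FALSE), .Machine$double.xmin)
  new("QResult", q = q, df = df, p = p)
}

#' Influence diagnostics for the fitted MR regression
#'
#' Computes leverage (hat values), studentized deleted residuals and
#' Cook's distance for each variant under the weighted-regression form of
#' the chosen estimator: regression of `by` on `bx` through the origin
#' with weights `sy^-2` for IVW, or with an intercept (after orienting
#' exposure effects non-negative) for MR-Egger. A variant is flagged as
#' potentially influential when its absolute studentized residual exceeds
#' `residThreshold` or its Cook's distance exceeds `cooksThreshold`
#' (default `4 / L`).
#'
#' @param h a [HarmonizedSet-class] with at least 3 variants.
#' @param method `"ivw"` (origin regression) or `"egger"`.
#' @param residThreshold studentized-residual cutoff (default 3).
#' @param cooksThreshold Cook's-distance cutoff (default `4 / L`).
#' @return `data.frame` with one row per variant: `snp`, `leverage`,
#'   `rstudent`, `cooks_d`, `influential`, `rule` (which cutoff fired),
#'   with the method and thresholds stored as attributes.
#' @export
influenceScan <- function(h, method = c("ivw", "egger"),
                          residThreshold = 3, cooksThreshold = NULL) {
  method <- match.arg(method)
  stopifnot(is(h, "HarmonizedSet"))
  d <- h@data
  L <- nrow(d)
  if (L < 3L)
    stop("insufficient instruments: need at least 3", call. = FALSE)
  if (is.null(cooksThreshold)) cooksThreshold <- 4 / L

  w <- d$sy^-2
  if (method == "ivw") {
    fit <- stats::lm(by ~ 0 + bx, data = d, weights = w)
  } else {
    s <- ifelse(d$bx < 0, -1, 1)
    od <- data.frame(bx = d$bx * s, by = d$by * s)
    fit <- stats::lm(by ~ bx, data = od, weights = w)
  }
  lev <- unname(stats::hatvalues(fit))
  rst <- unname(stats::rstudent(fit))
  cks <- unname(stats::cooks.distance(fit))
  # an (all but) exact fit has no meaningful studentization: residuals at
  # rounding level against a near-zero residual scale are not influence
  wrss <- sum(w * stats::resid(fit)^2)
  if (wrss <= 1e-16 * max(1, sum(w * d$by^2))) {
    rst <- rep(0, L)
    cks <- rep(0, L)
  }

  byResid <- !is.na(rst) & is.finite(rst) & abs(rst) > residThreshold
  byCooks <- !is.na(cks) & is.finite(cks) & cks > cooksThreshold
  rule <- ifelse(byResid & byCooks, "residual+cooks",
                 ifelse(byResid, "residual",
                        ifelse(byCooks, "cooks", "")))
  out <- data.frame(snp = d$snp, leverage = lev, rstudent = rst,
                    cooks_d = cks, influential = byResid | byCooks,
                    rule = rule, stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "thresholds") <- c(rstudent = residThreshold,
                               cooks_d = cooksThreshold)
  out
}

looMethodRow <- function(hSub, method, effectsModel, nBoot, seed) {
  tryCatch({
    estimate <- switch(method,
      ivw = mrIvw(mrRatio(hSub), effectsModel),
      egger = eggerSlope(mrEgger(hSub, effectsModel)),
      weighted_median = mrMedian(mrRatio(hSub), nBoot = nBoot, seed = seed),
      stop("unknown method: ", method))
    cbind(as.data.frame(estimate), note = "", stringsAsFactors = FALSE)
  }, error = function(e) {
    data.frame(method = method, effects_model = effectsModel,
               n_snps = NA_integer_, beta = NA_real_, se = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
               or_2fold = NA_real_, or_2fold_low = NA_real_,
               or_2fold_high = NA_real_, note = conditionMessage(e),
               stringsAsFactors = FALSE)
  })
}

#' Leave-one-out sensitivity analysis
#'
#' Re-runs the requested estimators once per variant with that variant
#' excluded, exposing results that hinge on a single instrument. The
#' weighted-median bootstrap uses the same seed in every row so rows
#' differ only by the excluded variant.
#'
#' @param h a [HarmonizedSet-class] with at least 4 variants (so every
#'   reduced set still satisfies the estimators' minimum counts).
#' @param methods subset of `"ivw"`, `"egger"`, `"weighted_median"`.
#' @param effectsModel effects model for IVW and Egger (default
#'   multiplicative random effects).
#' @param nBoot,seed weighted-median bootstrap settings (seed mandatory
#'   when `"weighted_median"` is requested).
#' @return long-format `data.frame`: one row per excluded variant and
#'   method, with the re-estimated effect on both the beta and fold
#'   scales; estimator failures on a reduced set are recorded in `note`
#'   rather than aborting the scan.
#' @export
leaveOneOut <- function(h, methods = c("ivw", "egger", "weighted_median"),
                        effectsModel = "multiplicative_random",
                        nBoot = 1000L, seed = NULL) {
  stopifnot(is(h, "HarmonizedSet"))
  methods <- match.arg(methods, several.ok = TRUE)
  L <- nSnps(h)
  if (L < 4L)
    stop("insufficient instruments: leave-one-out needs at least 4",
         call. = FALSE)
  if ("weighted_median" %in% methods && is.null(seed))
    stop("a seed is mandatory for the weighted-median bootstrap",
         call. = FALSE)
  rows <- lapply(seq_len(L), function(i) {
    hSub <- h[-i]
    res <- do.call(rbind, lapply(methods, looMethodRow, hSub = hSub,
                                 effectsModel = effectsModel,
                                 nBoot = nBoot, seed = seed))
    cbind(excluded_snp = h@data$snp[i], res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
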