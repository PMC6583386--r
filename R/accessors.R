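#' @include AllGenerics.R
NULL

#' @describeIn AssociationTable trait label.
#' @param x,object an `AssociationTable`.
#' @export
setMethod("traitName", "AssociationTable", function(x) x@trait)

#' @describeIn AssociationTable number of variants.
#' @export
setMethod("nSnps", "AssociationTable", function(x) nrow(x@records))

#' @describeIn AssociationTable records as a `data.frame`.
#' @param row.names,optional,... passed on conventions of
#'   [base::as.data.frame()]; ignored.
#' @export
setMethod("as.data.frame", "AssociationTable",
  function(x, row.names = NULL, optional = FALSE, ...) x@records)

setMethod("show", "AssociationTable", function(object) {
  cat(sprintf("AssociationTable: %s (%d variants)\n",
              object@trait, nrow(object@records)))
  print(utils::head(object@records, 6), row.names = FALSE)
  if (nrow(object@records) > 6) cat("...\n")
})

#' @describeIn LDMatrix number of variants.
#' @param x,object an `LDMatrix`.
#' @export
setMethod("nSnps", "LDMatrix", function(x) length(x@snpIds))

#' @describeIn LDMatrix the correlation matrix with identifier dimnames.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "LDMatrix", function(x, ...) {
  m <- x@rho
  dimnames(m) <- list(x@snpIds, x@snpIds)
  m
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d variants\n", length(object@snpIds)))
  print(utils::head(as.matrix(object), c(4, 4)))
  if (length(object@snpIds) > 4) cat("...\n")
})

#' @describeIn HarmonizedSet number of retained variants.
#' @param x,object a `HarmonizedSet`.
#' @export
setMethod("nSnps", "HarmonizedSet", function(x) nrow(x@data))

#' @describeIn HarmonizedSet dropped variants with reasons.
#' @export
setMethod("droppedSnps", "HarmonizedSet", function(x) x@dropped)

#' @describeIn HarmonizedSet retained aligned pairs as a `data.frame`
#'   (columns `snp`, `effect_allele`, `other_allele`, `bx`, `sx`, `by`,
#'   `sy`, `palindromic`).
#' @param row.names,optional,... as in [base::as.data.frame()]; ignored.
#' @export
setMethod("as.data.frame", "HarmonizedSet",
  function(x, row.names = NULL, optional = FALSE, ...) x@data)

#' @describeIn HarmonizedSet subset the retained variants (dropped-variant
#'   record carried through unchanged).
#' @param i index vector over the retained variants.
#' @param j,drop ignored.
#' @export
setMethod("[", "HarmonizedSet", function(x, i, j, ..., drop = FALSE) {
  newHarmonizedSet(x@exposureTrait, x@outcomeTrait,
                   x@data[i, , drop = FALSE], x@dropped)
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet: %s -> %s | %d retained, %d dropped\n",
              object@exposureTrait, object@outcomeTrait,
              nrow(object@data), nrow(object@dropped)))
  print(utils::head(object@data, 6), row.names = FALSE)
  if (nrow(object@dropped)) {
    cat("dropped:\n")
    print(object@dropped, row.names = FALSE)
  }
})

#' @describeIn MREstimate pooled estimate (ln-OR per ln-unit).
#' @param x,object an `MREstimate`.
#' @export
setMethod("mrBeta", "MREstimate", function(x) x@beta)

#' @describeIn MREstimate standard error of the pooled estimate.
#' @export
setMethod("mrSe", "MREstimate", function(x) x@se)

#' @describeIn MREstimate 95% confidence bounds on the pooled estimate.
#' @export
setMethod("mrCI", "MREstimate",
  function(x) c(low = x@ciLow, high = x@ciHigh))

#' @describeIn MREstimate two-sided p-value.
#' @export
setMethod("mrP", "MREstimate", function(x) x@p)

#' @describeIn MREstimate odds ratio per 2-fold increment with CI.
#' @export
setMethod("or2fold", "MREstimate",
  function(x) c(or = x@or2fold, low = x@or2foldLow, high = x@or2foldHigh))

#' @describeIn MREstimate number of instruments.
#' @export
setMethod("nSnps", "MREstimate", function(x) x@nSnps)

#' @describeIn MREstimate one-row `data.frame` (method, effects model,
#'   beta-scale and fold-scale results).
#' @param row.names,optional,... as in [base::as.data.frame()]; ignored.
#' @export
setMethod("as.data.frame", "MREstimate",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(method = x@method, effects_model = x@effectsModel,
               n_snps = x@nSnps, beta = x@beta, se = x@se,
               ci_low = x@ciLow, ci_high = x@ciHigh, p = x@p,
               or_2fold = x@or2fold, or_2fold_low = x@or2foldLow,
               or_2fold_high = x@or2foldHigh)
  })

setMethod("show", "MREstimate", function(object) {
  cat(sprintf(
    "MREstimate [%s, %s] %d SNPs\n  beta = %.4f (SE %.4f), 95%% CI %.4f to %.4f, p = %.3g\n  OR per 2-fold increment: %.2f (%.2f-%.2f)\n",
    object@method, object@effectsModel, object@nSnps,
    object@beta, object@se, object@ciLow, object@ciHigh, object@p,
    object@or2fold, object@or2foldLow, object@or2foldHigh))
})

#' @describeIn EggerResult the causal slope as an [MREstimate-class].
#' @param x,object an `EggerResult`.
#' @export
setMethod("eggerSlope", "EggerResult", function(x) x@slope)

#' @describeIn EggerResult the intercept as a named list (`beta`, `se`,
#'   `ci`, `p`, `odds`, `odds_ci`).
#' @export
setMethod("eggerIntercept", "EggerResult", function(x) {
  list(beta = x@interceptBeta, se = x@interceptSe,
       ci = c(low = x@interceptCiLow, high = x@interceptCiHigh),
       p = x@interceptP, odds = x@interceptOdds,
       odds_ci = c(low = x@interceptOddsLow, high = x@interceptOddsHigh))
})

#' @describeIn EggerResult number of instruments.
#' @export
setMethod("nSnps", "EggerResult", function(x) x@nSnps)

setMethod("show", "EggerResult", function(object) {
  cat(sprintf("EggerResult [%s] %d SNPs\n", object@effectsModel,
              object@nSnps))
  cat(sprintf(
    "  intercept = %.4f (SE %.4f), p = %.3g; odds %.2f (%.2f-%.2f)\n",
    object@interceptBeta, object@interceptSe, object@interceptP,
    object@interceptOdds, object@interceptOddsLow, object@interceptOddsHigh))
  cat(sprintf(
    "  slope beta = %.4f, OR per 2-fold %.2f (%.2f-%.2f), p = %.3g\n",
    object@slope@beta, object@slope@or2fold, object@slope@or2foldLow,
    object@slope@or2foldHigh, object@slope@p))
})

setMethod("show", "QResult", function(object) {
  cat(sprintf("Cochran Q = %.3f on %d df, p = %.3g\n",
              object@q, as.integer(object@df), object@p))
})

#' @describeIn AttenuationStats number of instruments.
#' @param x,object an `AttenuationStats`.
#' @export
setMethod("nSnps", "AttenuationStats", function(x) x@nSnps)

setMethod("show", "AttenuationStats", function(object) {
  cat(sprintf(
    "AttenuationStats (%d SNPs)\n  mean F = %.2f; expected IVW estimate retained: %.1f%%\n  I2(GX) = %.1f%% (expected MR-Egger slope retained under NOME violation)\n",
    object@nSnps, object@fBar, object@ivwDilution, object@i2gx))
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf(
    "MediationResult (%s CI)\n  a = %.4f (SE %.4f), b = %.4f (SE %.4f)\n  indirect a*b = %.4f (SE %.4f), 95%% CI %.4f to %.4f\n  expected OR per 2-fold increment: %.2f (%.2f-%.2f)\n",
    object@ciMethod, object@a, object@seA, object@b, object@seB,
    object@indirect, object@seIndirect,
    object@indirectCiLow, object@indirectCiHigh,
    object@expectedOr2fold, object@expectedOr2foldLow,
    object@expectedOr2foldHigh))
  if (!is.na(object@proportionMediated))
    cat(sprintf("  proportion mediated: %.1f%% (95%% CI %.1f%% to %.1f%%)\n",
                object@proportionMediated, object@proportionCiLow,
                object@proportionCiHigh))
})

#' @describeIn SimulatedStudy exposure-trait summary table.
#' @param x,object a `SimulatedStudy`.
#' @export
setMethod("exposureTable", "SimulatedStudy", function(x) x@exposureTable)

#' @describeIn SimulatedStudy outcome-trait summary table.
#' @export
setMethod("outcomeTable", "SimulatedStudy", function(x) x@outcomeTable)

#' @describeIn SimulatedStudy mediator-trait summary table or `NULL`.
#' @export
setMethod("mediatorTable", "SimulatedStudy", function(x) x@mediatorTable)

#' @describeIn SimulatedStudy generating LD matrix or `NULL`.
#' @export
setMethod("studyLD", "SimulatedStudy", function(x) x@ld)

#' @describeIn SimulatedStudy generating truth (causal effect, per-variant
#'   exposure effects, pleiotropic effects, mode).
#' @export
setMethod("studyTruth", "SimulatedStudy", function(x) x@truth)

#' @describeIn SimulatedStudy number of variants.
#' @export
setMethod("nSnps", "SimulatedStudy", function(x) nSnps(x@exposureTable))

setMethod("show", "SimulatedStudy", function(object) {
  tr <- object@truth
  cat(sprintf(
    "SimulatedStudy: %d variants, theta = %s, pleiotropy = %s%s%s\n",
    nSnps(object@exposureTable),
    format(tr$theta), tr$mode,
    if (!is.null(object@ld)) ", with LD" else "",
    if (!is.null(object@mediatorTable)) ", mediation triplet" else ""))
})
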