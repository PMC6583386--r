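#' @import methods
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' AssociationTable: per-variant summary associations for one trait
#'
#' Container for GWAS summary statistics of a single trait: one row per
#' variant with its effect allele, other allele, optional effect-allele
#' frequency, effect estimate on the natural-log scale (ln-biomarker units
#' for a continuous exposure, ln-odds-ratio for a binary outcome), its
#' standard error and an optional sample size.
#'
#' @slot trait trait label (free text).
#' @slot records `data.frame` with columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `n`. `eaf` and `n` may be `NA`.
#'
#' @seealso [associationTable()], [readAssociationTable()], [harmonize()]
#' @export
setClass("AssociationTable",
  slots = c(trait = "character", records = "data.frame"))

setValidity("AssociationTable", function(object) {
  msgs <- character()
  r <- object@records
  need <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se", "n")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) == 0L) msgs <- c(msgs, "records must be non-empty")
  if (anyDuplicated(tolower(r$snp)))
    msgs <- c(msgs, "duplicate snp identifiers (case-insensitive)")
  if (!all(r$effect_allele %in% VALID_BASES) ||
      !all(r$other_allele %in% VALID_BASES))
    msgs <- c(msgs, "alleles must be single bases A/C/G/T")
  if (any(r$effect_allele == r$other_allele))
    msgs <- c(msgs, "effect_allele must differ from other_allele")
  if (!is.numeric(r$beta) || anyNA(r$beta))
    msgs <- c(msgs, "beta must be numeric and non-missing")
  if (!is.numeric(r$se) || anyNA(r$se) || any(r$se <= 0))
    msgs <- c(msgs, "se must be strictly positive")
  eaf <- r$eaf[!is.na(r$eaf)]
  if (length(eaf) && (any(eaf <= 0) || any(eaf >= 1)))
    msgs <- c(msgs, "eaf must lie in the open interval (0, 1)")
  nn <- r$n[!is.na(r$n)]
  if (length(nn) && any(nn <= 0))
    msgs <- c(msgs, "n must be positive")
  if (length(msgs)) msgs else TRUE
})

#' LDMatrix: pairwise linkage-disequilibrium correlations
#'
#' Square matrix of pairwise LD correlations between instruments, used by
#' [mrIvwCorrelated()] when instruments are not independent.
#'
#' @slot snpIds ordered variant identifiers.
#' @slot rho symmetric positive-semidefinite correlation matrix with unit
#'   diagonal, one row/column per identifier.
#'
#' @seealso [ldMatrix()], [readLDMatrix()]
#' @export
setClass("LDMatrix", slots = c(snpIds = "character", rho = "matrix"))

setValidity("LDMatrix", function(object) {
  msgs <- character()
  rho <- object@rho
  k <- length(object@snpIds)
  if (nrow(rho) != k || ncol(rho) != k)
    return("rho dimension must equal the number of snpIds")
  if (k == 0L) return("at least one variant required")
  if (anyDuplicated(tolower(object@snpIds)))
    msgs <- c(msgs, "duplicate snp identifiers")
  if (max(abs(rho - t(rho))) > 1e-8)
    msgs <- c(msgs, "rho must be symmetric to within 1e-8")
  if (max(abs(diag(rho) - 1)) > 1e-8)
    msgs <- c(msgs, "rho must have unit diagonal")
  if (any(abs(rho) > 1 + 1e-8))
    msgs <- c(msgs, "correlations must lie in [-1, 1]")
  ev <- eigen(0.5 * (rho + t(rho)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    msgs <- c(msgs, "rho must be positive semidefinite to within 1e-8")
  if (length(msgs)) msgs else TRUE
})

#' HarmonizedSet: allele-aligned exposure/outcome pairs
#'
#' Result of [harmonize()]: per-variant exposure effect `bx` with standard
#' error `sx` and outcome effect `by` with standard error `sy`, all coded on
#' the same effect allele, plus a record of every shared variant that was
#' dropped and why.
#'
#' @slot exposureTrait,outcomeTrait trait labels carried from the inputs.
#' @slot data `data.frame` with columns `snp`, `effect_allele`,
#'   `other_allele`, `bx`, `sx`, `by`, `sy`, `palindromic`.
#' @slot dropped `data.frame` with columns `snp`, `reason`.
#' @export
setClass("HarmonizedSet",
  slots = c(exposureTrait = "character", outcomeTrait = "character",
            data = "data.frame", dropped = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  msgs <- character()
  d <- object@data
  need <- c("snp", "effect_allele", "other_allele", "bx", "sx", "by", "sy",
            "palindromic")
  if (!all(need %in% names(d)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (nrow(d) && anyDuplicated(tolower(d$snp)))
    msgs <- c(msgs, "duplicate snp identifiers")
  if (nrow(d) && (any(d$sx <= 0) || any(d$sy <= 0)))
    msgs <- c(msgs, "sx and sy must be strictly positive")
  if (!all(c("snp", "reason") %in% names(object@dropped)))
    msgs <- c(msgs, "dropped must have columns snp, reason")
  if (length(msgs)) msgs else TRUE
})

#' MREstimate: pooled causal-effect estimate
#'
#' A pooled Mendelian randomization estimate on the ln-odds-ratio per
#' ln-unit scale, with its 95% confidence interval, two-sided p-value and
#' the odds-ratio-per-2-fold-increment transform (see [toFoldScale()]).
#'
#' @slot method estimator label (e.g. `"ivw"`, `"weighted_median"`).
#' @slot effectsModel `"fixed"` or `"multiplicative_random"`.
#' @slot beta,se point estimate and standard error (ln-OR per ln-unit).
#' @slot ciLow,ciHigh 95% bounds on `beta`.
#' @slot p two-sided p-value from the standard normal.
#' @slot or2fold,or2foldLow,or2foldHigh odds ratio per 2-fold increment in
#'   the exposure, with its CI (the monotone image of the `beta` CI).
#' @slot nSnps number of instruments used.
#' @export
setClass("MREstimate",
  slots = c(method = "character", effectsModel = "character",
            beta = "numeric", se = "numeric",
            ciLow = "numeric", ciHigh = "numeric", p = "numeric",
            or2fold = "numeric", or2foldLow = "numeric",
            or2foldHigh = "numeric", nSnps = "integer"))

setValidity("MREstimate", function(object) {
  msgs <- character()
  if (object@se < 0) msgs <- c(msgs, "se must be non-negative")
  if (object@ciLow > object@beta + 1e-12 || object@ciHigh < object@beta - 1e-12)
    msgs <- c(msgs, "confidence interval must bracket beta")
  if (abs(object@or2fold - exp(object@beta * log(2))) >
      1e-8 * max(1, abs(object@or2fold)))
    msgs <- c(msgs, "or2fold must equal exp(beta * ln 2)")
  if (length(msgs)) msgs else TRUE
})

#' EggerResult: MR-Egger slope and intercept
#'
#' MR-Egger regression output: the slope is the causal-effect estimate
#' (an [MREstimate-class]); the intercept estimates the average directional
#' pleiotropic effect and is reported both additively (ln-odds per variant)
#' and exponentiated to the odds scale.
#'
#' @slot slope [MREstimate-class] for the causal slope.
#' @slot interceptBeta,interceptSe,interceptCiLow,interceptCiHigh,interceptP
#'   additive-scale intercept estimate, 95% CI and p-value.
#' @slot interceptOdds,interceptOddsLow,interceptOddsHigh exponentiated
#'   intercept and CI (monotone image of the additive CI).
#' @slot effectsModel `"fixed"` or `"multiplicative_random"`.
#' @slot nSnps number of instruments used.
#' @export
setClass("EggerResult",
  slots = c(slope = "MREstimate",
            interceptBeta = "numeric", interceptSe = "numeric",
            interceptCiLow = "numeric", interceptCiHigh = "numeric",
            interceptP = "numeric",
            interceptOdds = "numeric", interceptOddsLow = "numeric",
            interceptOddsHigh = "numeric",
            effectsModel = "character", nSnps = "integer"))

setValidity("EggerResult", function(object) {
  msgs <- character()
  if (abs(object@interceptOdds - exp(object@interceptBeta)) >
      1e-8 * max(1, object@interceptOdds))
    msgs <- c(msgs, "interceptOdds must equal exp(interceptBeta)")
  if (abs(object@interceptOddsLow - exp(object@interceptCiLow)) > 1e-8 ||
      abs(object@interceptOddsHigh - exp(object@interceptCiHigh)) > 1e-8)
    msgs <- c(msgs, "intercept odds CI must be the image of the additive CI")
  if (length(msgs)) msgs else TRUE
})

#' AttenuationStats: weak-instrument (NOME-violation) attenuation
#'
#' Quantifies the expected regression-dilution attenuation of the IVW
#' estimate and of the MR-Egger slope when the no-measurement-error (NOME)
#' assumption on the variant-exposure associations is violated.
#'
#' @slot fBar mean instrument-strength F statistic, `mean(bx^2 / sx^2)`.
#' @slot ivwDilution expected fraction of the IVW estimate retained,
#'   `100 * fBar / (fBar + 1)`, as a percentage (100 = no attenuation).
#' @slot i2gx I-squared(GX): expected fraction of the MR-Egger slope
#'   retained, as a percentage (100 = no attenuation).
#' @slot nSnps number of instruments.
#' @export
setClass("AttenuationStats",
  slots = c(fBar = "numeric", ivwDilution = "numeric", i2gx = "numeric",
            nSnps = "integer"))

setValidity("AttenuationStats", function(object) {
  if (object@ivwDilution < 0 || object@ivwDilution > 100 ||
      object@i2gx < 0 || object@i2gx > 100)
    "attenuation percentages must lie in [0, 100]" else TRUE
})

#' QResult: Cochran heterogeneity test
#'
#' @slot q Cochran Q statistic (weighted sum of squared deviations of the
#'   per-variant ratio estimates around the pooled fixed-effects estimate).
#' @slot df degrees of freedom (instruments minus model dimension).
#' @slot p upper-tail chi-square probability.
#' @export
setClass("QResult", slots = c(q = "numeric", df = "numeric", p = "numeric"))

setValidity("QResult", function(object) {
  msgs <- character()
  if (object@q < 0) msgs <- c(msgs, "q must be non-negative")
  if (object@df < 1) msgs <- c(msgs, "df must be at least 1")
  if (object@p <= 0 || object@p > 1) msgs <- c(msgs, "p must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' MediationResult: product-of-coefficients mediation
#'
#' Indirect effect `a * b` of an exposure on a binary outcome through a
#' mediator, the expected odds ratio per 2-fold exposure increment under
#' full mediation, and the proportion of the total effect `c` mediated.
#'
#' @slot a,seA exposure-to-mediator effect and SE (ln-mediator per ln-unit).
#' @slot b,seB mediator-to-outcome effect and SE (ln-OR per ln-unit).
#' @slot cTotal,seC total exposure-to-outcome effect and SE (ln-OR per
#'   ln-unit); `NA` when no total effect was supplied.
#' @slot indirect,seIndirect product `a * b` and its SE.
#' @slot indirectCiLow,indirectCiHigh 95% CI on the indirect effect.
#' @slot expectedOr2fold,expectedOr2foldLow,expectedOr2foldHigh fold-scale
#'   transform of the indirect effect and its CI.
#' @slot proportionMediated,proportionCiLow,proportionCiHigh percentage of
#'   the total effect mediated, with CI; `NA` when `cTotal` is absent.
#' @slot ciMethod `"delta"` or `"monte_carlo"`.
#' @export
setClass("MediationResult",
  slots = c(a = "numeric", seA = "numeric", b = "numeric", seB = "numeric",
            cTotal = "numeric", seC = "numeric",
            indirect = "numeric", seIndirect = "numeric",
            indirectCiLow = "numeric", indirectCiHigh = "numeric",
            expectedOr2fold = "numeric", expectedOr2foldLow = "numeric",
            expectedOr2foldHigh = "numeric",
            proportionMediated = "numeric", proportionCiLow = "numeric",
            proportionCiHigh = "numeric", ciMethod = "character"))

setValidity("MediationResult", function(object) {
  msgs <- character()
  if (abs(object@indirect - object@a * object@b) >
      1e-12 * max(1, abs(object@indirect)))
    msgs <- c(msgs, "indirect must equal a * b exactly")
  if (abs(object@expectedOr2fold - exp(object@indirect * log(2))) > 1e-8)
    msgs <- c(msgs, "expectedOr2fold must equal exp(indirect * ln 2)")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the synthetic summary-statistics model
#'
#' Describes the generating model for [simulateTwoSample()]: true variant
#' effects on the exposure, a causal effect `theta` of the exposure on the
#' outcome, optional horizontal pleiotropy, sampling noise governed by the
#' effective sample sizes of the two (non-overlapping) study samples, and
#' optional equicorrelated LD between instruments.
#'
#' @slot nSnps number of instruments L (>= 2).
#' @slot theta true causal effect, ln-OR per ln-unit of exposure.
#' @slot gammaMean,gammaSd normal parameters for the true variant-exposure
#'   effects; effects are folded to be positive unless `signedGamma`.
#' @slot signedGamma keep the sign of the drawn exposure effects.
#' @slot pleiotropyMode `"none"`, `"balanced"` (direct effects with mean 0)
#'   or `"directional"` (mean `alphaMean`).
#' @slot alphaMean,alphaSd pleiotropy distribution parameters.
#' @slot nExposure,nOutcome effective sample sizes driving the standard
#'   errors `(2 n maf (1 - maf))^{-1/2}` for standardized traits.
#' @slot outcomeSeScale multiplier on the outcome standard errors,
#'   approximating the precision loss of a case-control outcome.
#' @slot mafRange sampling interval for minor-allele frequencies, within
#'   (0, 0.5].
#' @slot ldBlock length-0 for independent instruments, else a single
#'   within-block correlation applied to the sampling noise of all
#'   instruments (and reported as the true LD matrix).
#' @slot seed integer seed; every draw is reproducible from it.
#' @export
setClass("SimulationConfig",
  slots = c(nSnps = "integer", theta = "numeric",
            gammaMean = "numeric", gammaSd = "numeric",
            signedGamma = "logical", pleiotropyMode = "character",
            alphaMean = "numeric", alphaSd = "numeric",
            nExposure = "numeric", nOutcome = "numeric",
            outcomeSeScale = "numeric", mafRange = "numeric",
            ldBlock = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nSnps < 2L) msgs <- c(msgs, "nSnps must be at least 2")
  if (object@gammaSd < 0 || object@alphaSd < 0)
    msgs <- c(msgs, "standard deviations must be non-negative")
  if (!object@pleiotropyMode %in% c("none", "balanced", "directional"))
    msgs <- c(msgs, "pleiotropyMode must be none, balanced or directional")
  if (object@nExposure <= 0 || object@nOutcome <= 0)
    msgs <- c(msgs, "sample sizes must be positive")
  if (object@outcomeSeScale <= 0)
    msgs <- c(msgs, "outcomeSeScale must be positive")
  if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msgs <- c(msgs, "mafRange must be an interval within (0, 0.5]")
  if (length(object@ldBlock) > 1L ||
      (length(object@ldBlock) == 1L &&
       (object@ldBlock < 0 || object@ldBlock >= 1)))
    msgs <- c(msgs, "ldBlock must be empty or a single correlation in [0, 1)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed is mandatory")
  if (length(msgs)) msgs else TRUE
})

#' SimulatedStudy: synthetic summary tables plus the generating truth
#'
#' @slot exposureTable,outcomeTable [AssociationTable-class] objects sharing
#'   variant identifiers and allele codings.
#' @slot mediatorTable optional [AssociationTable-class] for a mediator
#'   trait (mediation designs), else `NULL`.
#' @slot ld optional [LDMatrix-class] of the generating LD, else `NULL`.
#' @slot truth list recording the generating parameters: `theta`, per-variant
#'   `gamma` and `alpha`, `mode`, and for mediation designs `a`, `b`,
#'   `direct`, `proportion_mediated` and the instrument assignment.
#' @export
setClass("SimulatedStudy",
  slots = c(exposureTable = "AssociationTable",
            outcomeTable = "AssociationTable",
            mediatorTable = "ANY", ld = "ANY", truth = "list"))

setValidity("SimulatedStudy", function(object) {
  msgs <- character()
  if (!is.null(object@mediatorTable) &&
      !is(object@mediatorTable, "AssociationTable"))
    msgs <- c(msgs, "mediatorTable must be NULL or an AssociationTable")
  if (!is.null(object@ld) && !is(object@ld, "LDMatrix"))
    msgs <- c(msgs, "ld must be NULL or an LDMatrix")
  if (!setequal(object@exposureTable@records$snp,
                object@outcomeTable@records$snp))
    msgs <- c(msgs, "exposure and outcome tables must share snp identifiers")
  if (length(msgs)) msgs else TRUE
})
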