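#' @include AllClasses.R
NULL

#' Trait label of an association table
#' @param x an object with a trait label.
#' @return character scalar.
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' Number of variants in an object
#' @param x a summaryMR object.
#' @return integer count of variants (instruments).
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' Dropped variants and the reason each was excluded
#' @param x a [HarmonizedSet-class].
#' @return `data.frame` with columns `snp` and `reason`.
#' @export
setGeneric("droppedSnps", function(x) standardGeneric("droppedSnps"))

#' Point estimate, standard error, CI and p-value accessors
#' @param x an [MREstimate-class] (or, for `mrBeta`/`mrSe`, any object
#'   carrying a pooled estimate).
#' @return numeric scalar (`mrBeta`, `mrSe`, `mrP`) or a named length-2
#'   vector (`mrCI`).
#' @name estimate-accessors
NULL

#' @rdname estimate-accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))
#' @rdname estimate-accessors
#' @export
setGeneric("mrSe", function(x) standardGeneric("mrSe"))
#' @rdname estimate-accessors
#' @export
setGeneric("mrCI", function(x) standardGeneric("mrCI"))
#' @rdname estimate-accessors
#' @export
setGeneric("mrP", function(x) standardGeneric("mrP"))

#' Odds ratio per 2-fold increment, with CI
#' @param x an [MREstimate-class].
#' @return named numeric vector `c(or, low, high)`.
#' @export
setGeneric("or2fold", function(x) standardGeneric("or2fold"))

#' MR-Egger slope and intercept accessors
#' @param x an [EggerResult-class].
#' @return `eggerSlope`: the slope as an [MREstimate-class];
#'   `eggerIntercept`: named list with `beta`, `se`, `ci`, `p`, `odds`,
#'   `odds_ci`.
#' @name egger-accessors
NULL

#' @rdname egger-accessors
#' @export
setGeneric("eggerSlope", function(x) standardGeneric("eggerSlope"))
#' @rdname egger-accessors
#' @export
setGeneric("eggerIntercept", function(x) standardGeneric("eggerIntercept"))

#' Component tables and truth of a simulated study
#' @param x a [SimulatedStudy-class].
#' @return the requested component ([AssociationTable-class],
#'   [LDMatrix-class] or `NULL`, or the truth `list`).
#' @name study-accessors
NULL

#' @rdname study-accessors
#' @export
setGeneric("exposureTable", function(x) standardGeneric("exposureTable"))
#' @rdname study-accessors
#' @export
setGeneric("outcomeTable", function(x) standardGeneric("outcomeTable"))
#' @rdname study-accessors
#' @export
setGeneric("mediatorTable", function(x) standardGeneric("mediatorTable"))
#' @rdname study-accessors
#' @export
setGeneric("studyLD", function(x) standardGeneric("studyLD"))
#' @rdname study-accessors
#' @export
setGeneric("studyTruth", function(x) standardGeneric("studyTruth"))
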