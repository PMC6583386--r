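Z95 <- stats::qnorm(0.975)

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

## Evaluate expr with a private RNG stream; the caller's RNG state is
## untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed))
    stop("a seed is mandatory for stochastic computations", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

twoSidedP <- function(z) 2 * stats::pnorm(-abs(z))

isPalindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Construct an AssociationTable from a data.frame
#'
#' Builds a validated [AssociationTable-class]. Alleles are upper-cased and
#' identifiers kept verbatim (compared case-insensitively downstream);
#' missing optional columns (`eaf`, `n`) are filled with `NA`.
#'
#' @param trait trait label.
#' @param records `data.frame` with columns `snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se` and optionally `eaf`, `n`.
#' @return an [AssociationTable-class].
#' @examples
#' associationTable("CRP", data.frame(
#'   snp = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'   other_allele = c("G", "T"), beta = c(0.12, -0.08), se = c(0.02, 0.03)))
#' @export
associationTable <- function(trait, records) {
  stopifnot(is.character(trait), length(trait) == 1L, is.data.frame(records))
  need <- c("snp", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  r <- data.frame(
    snp = as.character(records$snp),
    effect_allele = toupper(as.character(records$effect_allele)),
    other_allele = toupper(as.character(records$other_allele)),
    eaf = if ("eaf" %in% names(records)) as.numeric(records$eaf)
          else NA_real_,
    beta = as.numeric(records$beta),
    se = as.numeric(records$se),
    n = if ("n" %in% names(records)) as.numeric(records$n) else NA_real_,
    stringsAsFactors = FALSE)
  new("AssociationTable", trait = trait, records = r)
}

#' Construct an LDMatrix
#'
#' @param snpIds ordered variant identifiers.
#' @param rho square correlation matrix in the same order.
#' @return an [LDMatrix-class].
#' @examples
#' ldMatrix(c("rs1", "rs2"), matrix(c(1, 0.6, 0.6, 1), 2))
#' @export
ldMatrix <- function(snpIds, rho) {
  new("LDMatrix", snpIds = as.character(snpIds),
      rho = unname(as.matrix(rho)))
}

## internal constructor used by harmonize() and the simulator
newHarmonizedSet <- function(exposureTrait, outcomeTrait, data, dropped) {
  if (is.null(dropped) || nrow(dropped) == 0L)
    dropped <- data.frame(snp = character(), reason = character(),
                          stringsAsFactors = FALSE)
  new("HarmonizedSet", exposureTrait = exposureTrait,
      outcomeTrait = outcomeTrait, data = data, dropped = dropped)
}

newMREstimate <- function(method, effectsModel, beta, se, nSnps) {
  ci <- c(beta - Z95 * se, beta + Z95 * se)
  fold <- toFoldScale(beta, se)
  z <- if (se > 0) beta / se else if (beta == 0) 0 else sign(beta) * Inf
  new("MREstimate", method = method, effectsModel = effectsModel,
      beta = beta, se = se, ciLow = ci[1], ciHigh = ci[2],
      p = twoSidedP(z),
      or2fold = fold[["or"]], or2foldLow = fold[["low"]],
      or2foldHigh = fold[["high"]], nSnps = as.integer(nSnps))
}
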