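#' Configure the synthetic summary-statistics generator
#'
#' Builds a validated [SimulationConfig-class]. The generating model is
#' the standard two-sample MR data model: each variant j has a true effect
#' `gamma_j` on a standardized exposure and a true effect
#' `theta * gamma_j + alpha_j` on the outcome (ln-OR scale), where
#' `alpha_j` is a horizontal-pleiotropy term drawn independently of
#' `gamma_j` (so the InSIDE condition holds by construction). Observed
#' associations add sampling noise with standard errors
#' `(2 n maf (1 - maf))^{-1/2}` — the standard-error model of a
#' standardized continuous trait — scaled by `outcomeSeScale` on the
#' outcome side to mimic case-control precision.
#'
#' Defaults mirror a biomarker-disease analysis with 18 strong
#' instruments: biomarker associations estimated in tens of thousands of
#' individuals, disease associations in a case-control sample of
#' comparable size.
#'
#' @param nSnps number of instruments (default 18).
#' @param theta true causal effect, ln-OR per ln-unit (default 0).
#' @param gammaMean,gammaSd distribution of true exposure effects
#'   (default 0.1 and 0.05; folded positive unless `signedGamma`).
#' @param signedGamma keep signs of the drawn exposure effects
#'   (default `FALSE`).
#' @param pleiotropyMode `"none"` (default), `"balanced"` or
#'   `"directional"`.
#' @param alphaMean,alphaSd pleiotropy distribution (defaults 0 and 0.02;
#'   `alphaMean` is only used in directional mode).
#' @param nExposure,nOutcome effective sample sizes (defaults 50000 and
#'   80000).
#' @param outcomeSeScale multiplier on outcome SEs (default 2,
#'   approximating a balanced case-control outcome).
#' @param mafRange minor-allele-frequency interval (default 0.1-0.5).
#' @param ldBlock single within-block correlation in `[0, 1)` applied to
#'   the sampling noise of all instruments, or `numeric(0)` (default) for
#'   independent instruments.
#' @param seed mandatory integer seed.
#' @return a [SimulationConfig-class].
#' @seealso [simulateTwoSample()], [simulateMediationTriplet()]
#' @export
simulationConfig <- function(nSnps = 18L, theta = 0, gammaMean = 0.1,
                             gammaSd = 0.05, signedGamma = FALSE,
                             pleiotropyMode = "none", alphaMean = 0,
                             alphaSd = 0.02, nExposure = 50000,
                             nOutcome = 80000, outcomeSeScale = 2,
                             mafRange = c(0.1, 0.5), ldBlock = numeric(0),
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  new("SimulationConfig", nSnps = as.integer(nSnps), theta = theta,
      gammaMean = gammaMean, gammaSd = gammaSd,
      signedGamma = isTRUE(signedGamma), pleiotropyMode = pleiotropyMode,
      alphaMean = alphaMean, alphaSd = alphaSd, nExposure = nExposure,
      nOutcome = nOutcome, outcomeSeScale = outcomeSeScale,
      mafRange = mafRange, ldBlock = as.numeric(ldBlock),
      seed = as.integer(seed))
}

## non-palindromic allele pairs only, so synthetic studies harmonize
## without frequency-based strand inference
ALLELE_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

## equicorrelated standard-normal noise (single block)
equicorNoise <- function(L, r) {
  if (!length(r) || r == 0) return(stats::rnorm(L))
  sqrt(r) * stats::rnorm(1) + sqrt(1 - r) * stats::rnorm(L)
}

drawAlpha <- function(cfg, L) {
  switch(cfg@pleiotropyMode,
         none = rep(0, L),
         balanced = stats::rnorm(L, 0, cfg@alphaSd),
         directional = stats::rnorm(L, cfg@alphaMean, cfg@alphaSd))
}

#' Simulate a two-sample summary-statistics study with known truth
#'
#' Draws minor-allele frequencies, true variant-exposure effects and
#' (optionally) pleiotropic direct effects per the configuration, then
#' observes both sides with independent sampling noise — the exposure and
#' outcome samples are non-overlapping, as the two-sample design assumes.
#' When `ldBlock` is set, the sampling noise of all instruments is
#' equicorrelated within each side and the generating equicorrelation
#' matrix is returned as the study's LD matrix. Output is bit-identical
#' for identical seeds.
#'
#' @param cfg a [SimulationConfig-class].
#' @return a [SimulatedStudy-class]; `studyTruth()` records `theta`, the
#'   per-variant `gamma` and `alpha`, the pleiotropy `mode`, `maf` and the
#'   true standard errors.
#' @examples
#' study <- simulateTwoSample(simulationConfig(theta = 0.2, seed = 7))
#' h <- harmonize(exposureTable(study), outcomeTable(study))
#' mrBeta(mrIvw(mrRatio(h)))  # close to 0.2
#' @export
simulateTwoSample <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  L <- cfg@nSnps
  withSeed(cfg@seed, {
    maf <- stats::runif(L, cfg@mafRange[1], cfg@mafRange[2])
    sx <- (2 * cfg@nExposure * maf * (1 - maf))^-0.5
    sy <- cfg@outcomeSeScale * (2 * cfg@nOutcome * maf * (1 - maf))^-0.5
    gamma <- stats::rnorm(L, cfg@gammaMean, cfg@gammaSd)
    if (!cfg@signedGamma) gamma <- abs(gamma)
    alpha <- drawAlpha(cfg, L)
    bx <- gamma + sx * equicorNoise(L, cfg@ldBlock)
    by <- cfg@theta * gamma + alpha + sy * equicorNoise(L, cfg@ldBlock)

    snp <- sprintf("rs%03d", seq_len(L))
    pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), L, replace = TRUE), ,
                         drop = FALSE]
    base <- data.frame(snp = snp, effect_allele = pair[, 1],
                       other_allele = pair[, 2], eaf = maf,
                       stringsAsFactors = FALSE)
    exposure <- associationTable("exposure",
      cbind(base, beta = bx, se = sx, n = cfg@nExposure))
    outcome <- associationTable("outcome",
      cbind(base, beta = by, se = sy, n = cfg@nOutcome))
    ld <- if (length(cfg@ldBlock) && cfg@ldBlock > 0) {
      rho <- matrix(cfg@ldBlock, L, L); diag(rho) <- 1
      ldMatrix(snp, rho)
    } else NULL
    new("SimulatedStudy", exposureTable = exposure, outcomeTable = outcome,
        mediatorTable = NULL, ld = ld,
        truth = list(theta = cfg@theta, gamma = gamma, alpha = alpha,
                     mode = cfg@pleiotropyMode, maf = maf, sx = sx,
                     sy = sy))
  })
}

#' Simulate an exposure-mediator-outcome summary-statistics triplet
#'
#' Generates three association tables for a product-of-coefficients
#' mediation design: disjoint instrument sets for the exposure and the
#' mediator, a true exposure-to-mediator effect `aTrue`, a true
#' mediator-to-outcome effect `bTrue`, and an optional direct
#' (non-mediated) exposure-to-outcome effect, so the exposure's total
#' outcome effect is `aTrue * bTrue + directEffect`. Each table covers
#' both instrument sets: mediator instruments have zero effect on the
#' exposure, and exposure instruments affect the mediator only through
#' the exposure.
#'
#' @param cfg a [SimulationConfig-class]; `nSnps` instruments are drawn
#'   for the exposure and `nMediatorSnps` for the mediator.
#' @param aTrue true exposure-to-mediator effect (ln-units).
#' @param bTrue true mediator-to-outcome effect (ln-OR per ln-unit).
#' @param directEffect direct exposure-to-outcome effect (default 0, i.e.
#'   full mediation).
#' @param nMediatorSnps mediator instrument count (default `cfg@nSnps`).
#' @return a [SimulatedStudy-class] whose `mediatorTable` is set and whose
#'   truth records `a`, `b`, `direct`, the implied total effect and
#'   proportion mediated (as a percentage), and the instrument
#'   assignments.
#' @export
simulateMediationTriplet <- function(cfg, aTrue, bTrue, directEffect = 0,
                                     nMediatorSnps = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  Le <- cfg@nSnps
  Lm <- if (is.null(nMediatorSnps)) Le else as.integer(nMediatorSnps)
  snpE <- sprintf("rsE%03d", seq_len(Le))
  snpM <- sprintf("rsM%03d", seq_len(Lm))
  if (length(intersect(snpE, snpM)))
    stop("configuration error: exposure and mediator instrument sets ",
         "overlap", call. = FALSE)
  L <- Le + Lm
  total <- aTrue * bTrue + directEffect

  withSeed(cfg@seed, {
    maf <- stats::runif(L, cfg@mafRange[1], cfg@mafRange[2])
    seCont <- (2 * cfg@nExposure * maf * (1 - maf))^-0.5
    seOut <- cfg@outcomeSeScale * (2 * cfg@nOutcome * maf * (1 - maf))^-0.5
    gamma <- stats::rnorm(L, cfg@gammaMean, cfg@gammaSd)
    if (!cfg@signedGamma) gamma <- abs(gamma)
    isE <- seq_len(L) <= Le

    truthExp <- ifelse(isE, gamma, 0)
    truthMed <- ifelse(isE, aTrue * gamma, gamma)
    truthOut <- ifelse(isE, total * gamma, bTrue * gamma)

    snp <- c(snpE, snpM)
    pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), L, replace = TRUE), ,
                         drop = FALSE]
    base <- data.frame(snp = snp, effect_allele = pair[, 1],
                       other_allele = pair[, 2], eaf = maf,
                       stringsAsFactors = FALSE)
    mkTable <- function(trait, mu, se, n) {
      associationTable(trait, cbind(base, beta = mu + se * stats::rnorm(L),
                                    se = se, n = n))
    }
    exposure <- mkTable("exposure", truthExp, seCont, cfg@nExposure)
    mediator <- mkTable("mediator", truthMed, seCont, cfg@nExposure)
    outcome <- mkTable("outcome", truthOut, seOut, cfg@nOutcome)

    new("SimulatedStudy", exposureTable = exposure, outcomeTable = outcome,
        mediatorTable = mediator, ld = NULL,
        truth = list(theta = total, a = aTrue, b = bTrue,
                     direct = directEffect, total = total,
                     proportion_mediated =
                       if (total != 0) 100 * aTrue * bTrue / total
                       else NA_real_,
                     mode = cfg@pleiotropyMode,
                     exposure_instruments = snpE,
                     mediator_instruments = snpM,
                     gamma = gamma, maf = maf))
  })
}
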