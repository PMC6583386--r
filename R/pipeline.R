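#' Write an association table to tab-delimited text
#'
#' @param x an [AssociationTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAssociationTable <- function(x, path) {
  stopifnot(is(x, "AssociationTable"))
  utils::write.table(x@records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an LD matrix to CSV
#'
#' @param x an [LDMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLDMatrix <- function(x, path) {
  stopifnot(is(x, "LDMatrix"))
  utils::write.csv(as.data.frame(as.matrix(x)), path, quote = FALSE)
  invisible(path)
}

defaultAnalysisConfig <- function() {
  list(exposure = NULL, outcome = NULL, dialect = list(), ld = NULL,
       methods = c("ivw", "weighted_median", "egger"),
       effects_models = c("fixed", "multiplicative_random"),
       palindromic_policy = "drop_ambiguous", eaf_ambiguity_band = 0.08,
       n_boot = 1000L, simex = FALSE,
       lambda_grid = c(0, 0.5, 1, 1.5, 2), simex_replicates = 1000L,
       diagnostics = TRUE, loo = TRUE, mediation = NULL, seed = NULL,
       out_dir = NULL, precision = 2L)
}

validateAnalysisConfig <- function(cfg) {
  base <- defaultAnalysisConfig()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("configuration error: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(base, cfg)
  if (is.null(cfg$exposure) || is.null(cfg$outcome))
    stop("configuration error: exposure and outcome paths are mandatory",
         call. = FALSE)
  for (p in c(cfg$exposure, cfg$outcome, cfg$ld))
    if (!file.exists(p))
      stop("configuration error: path does not exist: ", p, call. = FALSE)
  known <- c("ivw", "correlated_ivw", "weighted_median", "egger")
  bad <- setdiff(cfg$methods, known)
  if (length(bad))
    stop("configuration error: unknown method(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if ("correlated_ivw" %in% cfg$methods && is.null(cfg$ld))
    stop("configuration error: correlated_ivw requested without an LD ",
         "matrix", call. = FALSE)
  stochastic <- "weighted_median" %in% cfg$methods || isTRUE(cfg$simex) ||
    (!is.null(cfg$mediation) &&
     !identical(cfg$mediation$ci_method, "delta"))
  if (stochastic && is.null(cfg$seed))
    stop("configuration error: seed is mandatory when any stochastic ",
         "component is enabled", call. = FALSE)
  if (is.null(cfg$out_dir))
    stop("configuration error: out_dir is mandatory", call. = FALSE)
  cfg
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

estimateRecord <- function(e) {
  as.list(as.data.frame(e))
}

#' Run the full two-sample MR analysis from a single configuration
#'
#' Orchestrates harmonization, the requested estimators under the
#' requested effects models, heterogeneity / influence / leave-one-out
#' diagnostics, weak-instrument statistics with optional SIMEX-corrected
#' Egger, and an optional mediation calculation, writing every result to
#' `out_dir` (JSON and flat TSV) together with a manifest recording the
#' configuration and seeds. A failure in any stage is reported with the
#' stage name; outputs already written are preserved.
#'
#' Configuration fields (all optional unless noted): `exposure`, `outcome`
#' (mandatory paths to tab-delimited summary tables), `dialect` (named
#' overrides for [summaryDialect()]), `ld` (CSV path, required for
#' `correlated_ivw`), `methods` (subset of `ivw`, `correlated_ivw`,
#' `weighted_median`, `egger`), `effects_models`, `palindromic_policy`,
#' `eaf_ambiguity_band`, `n_boot`, `simex` (logical), `lambda_grid`,
#' `simex_replicates`, `diagnostics`, `loo` (logicals), `mediation`
#' (list with `a`, `c` as `c(estimate, se)`, `b` likewise or `"ivw"` to
#' use this analysis' IVW estimate, plus `ci_method`, `n_draws`), `seed`
#' (mandatory when any stochastic component is enabled), `out_dir`
#' (mandatory), `precision` (fold-scale decimals in the TSV, default 2).
#'
#' @param config a named list as above, or the path to a JSON file
#'   containing one.
#' @return invisibly, a list with the harmonized set, every estimate,
#'   diagnostics, attenuation statistics, optional SIMEX and mediation
#'   results, and the output paths.
#' @export
runAnalysis <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- validateAnalysisConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(x, name, writer) {
    p <- file.path(cfg$out_dir, name)
    writer(x, p)
    paths[[name]] <<- p
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- list(config = cfg)

  h <- stage("harmonize", {
    dialect <- do.call(summaryDialect, as.list(cfg$dialect))
    exposure <- readAssociationTable(cfg$exposure, dialect = dialect)
    outcome <- readAssociationTable(cfg$outcome, dialect = dialect)
    harmonize(exposure, outcome, cfg$palindromic_policy,
              cfg$eaf_ambiguity_band)
  })
  out$harmonized <- h
  emit(h@data, "harmonized.tsv", writeTsv)
  emit(h@dropped, "harmonize.log", function(x, p) {
    lines <- c(sprintf("retained %d variant(s); dropped %d", nrow(h@data),
                       nrow(x)),
               if (nrow(x)) sprintf("dropped %s: %s", x$snp, x$reason))
    writeLines(lines, p)
  })
  ld <- if (!is.null(cfg$ld))
    stage("read_ld", readLDMatrix(cfg$ld, h@data$snp)) else NULL

  est <- stage("estimate", {
    ratios <- mrRatio(h)
    res <- list()
    for (em in cfg$effects_models) {
      if ("ivw" %in% cfg$methods)
        res[[paste0("ivw_", em)]] <- mrIvw(ratios, em)
      if ("correlated_ivw" %in% cfg$methods)
        res[[paste0("correlated_ivw_", em)]] <- mrIvwCorrelated(h, ld, em)
      if ("egger" %in% cfg$methods)
        res[[paste0("egger_", em)]] <- mrEgger(h, em)
    }
    if ("weighted_median" %in% cfg$methods)
      res$weighted_median <- mrMedian(ratios, nBoot = cfg$n_boot,
                                      seed = cfg$seed)
    res
  })
  out$estimates <- est
  out$ratios <- mrRatio(h)

  tab1 <- do.call(rbind, lapply(names(est), function(nm) {
    e <- est[[nm]]
    if (is(e, "EggerResult")) {
      ic <- eggerIntercept(e)
      rbind(
        data.frame(method = nm, parameter = "intercept_odds",
                   n_snps = e@nSnps,
                   estimate = round(ic$odds, cfg$precision),
                   ci_low = round(ic$odds_ci[["low"]], cfg$precision),
                   ci_high = round(ic$odds_ci[["high"]], cfg$precision),
                   p = signif(ic$p, 2)),
        data.frame(method = nm, parameter = "or_2fold",
                   n_snps = e@nSnps,
                   estimate = round(e@slope@or2fold, cfg$precision),
                   ci_low = round(e@slope@or2foldLow, cfg$precision),
                   ci_high = round(e@slope@or2foldHigh, cfg$precision),
                   p = signif(e@slope@p, 2)))
    } else {
      data.frame(method = nm, parameter = "or_2fold", n_snps = e@nSnps,
                 estimate = round(e@or2fold, cfg$precision),
                 ci_low = round(e@or2foldLow, cfg$precision),
                 ci_high = round(e@or2foldHigh, cfg$precision),
                 p = signif(e@p, 2))
    }
  }))
  emit(tab1, "estimates.tsv", writeTsv)
  emit(lapply(est, function(e) {
    if (is(e, "EggerResult"))
      list(slope = estimateRecord(eggerSlope(e)),
           intercept = eggerIntercept(e))
    else estimateRecord(e)
  }), "estimates.json", writeJson)

  emit(data.frame(snp = h@data$snp, bx = h@data$bx, sx = h@data$sx,
                  by = h@data$by, sy = h@data$sy),
       "scatter.tsv", writeTsv)

  nome <- stage("nome", attenuationStats(h))
  out$nome <- nome
  nomeJson <- list(f_bar = nome@fBar, ivw_dilution = nome@ivwDilution,
                   i2_gx = nome@i2gx, n_snps = nome@nSnps)
  if (isTRUE(cfg$simex)) {
    sx <- stage("simex", simexEgger(h, cfg$lambda_grid,
                                    cfg$simex_replicates, cfg$seed))
    out$simex <- sx
    nomeJson$simex <- list(slope = estimateRecord(eggerSlope(sx)),
                           intercept = eggerIntercept(sx),
                           seed = cfg$seed)
  }
  emit(nomeJson, "nome.json", writeJson)

  if (isTRUE(cfg$diagnostics)) {
    q <- stage("cochran_q", cochranQ(out$ratios))
    out$q <- q
    emit(list(q = q@q, df = q@df, p = q@p), "q.json", writeJson)
    infl <- stage("influence", influenceScan(h, "ivw"))
    out$influence <- infl
    emit(infl, "influence.tsv", writeTsv)
  }
  if (isTRUE(cfg$loo)) {
    loo <- stage("leave_one_out", {
      methods <- intersect(cfg$methods,
                           c("ivw", "egger", "weighted_median"))
      leaveOneOut(h, methods, "multiplicative_random",
                  nBoot = cfg$n_boot, seed = cfg$seed)
    })
    out$loo <- loo
    emit(loo, "leave_one_out.tsv", writeTsv)
  }

  if (!is.null(cfg$mediation)) {
    med <- stage("mediation", {
      m <- cfg$mediation
      bEst <- if (identical(m$b, "ivw")) {
        key <- grep("^ivw_", names(est), value = TRUE)
        if (!length(key))
          stop("mediation b = 'ivw' requires the ivw method")
        est[[key[length(key)]]]
      } else unlist(m$b)
      mediationAnalysis(unlist(m$a), bEst, unlist(m$c),
                        ciMethod = if (is.null(m$ci_method))
                          "monte_carlo" else m$ci_method,
                        nDraws = if (is.null(m$n_draws)) 100000L
                                 else m$n_draws,
                        seed = cfg$seed)
    })
    out$mediation <- med
    emit(list(a = med@a, se_a = med@seA, b = med@b, se_b = med@seB,
              c = med@cTotal, se_c = med@seC, indirect = med@indirect,
              se_indirect = med@seIndirect,
              indirect_ci = c(med@indirectCiLow, med@indirectCiHigh),
              expected_or_2fold = med@expectedOr2fold,
              expected_or_2fold_ci = c(med@expectedOr2foldLow,
                                       med@expectedOr2foldHigh),
              proportion_mediated = med@proportionMediated,
              proportion_ci = c(med@proportionCiLow, med@proportionCiHigh),
              ci_method = med@ciMethod),
         "mediation.json", writeJson)
  }

  manifest <- cfg
  manifest$dialect <- as.list(cfg$dialect)
  emit(manifest, "manifest.json", writeJson)
  out$paths <- paths
  invisible(out)
}
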