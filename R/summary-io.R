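#' Default column-name mapping for summary-statistics files
#'
#' Maps the canonical field names used internally to the column names
#' expected in a tab-delimited summary file. Override individual entries to
#' read files with other layouts.
#'
#' @param ... named overrides, e.g. `snp = "rsid"`, `beta = "Effect"`.
#' @return named character vector mapping canonical names to file columns.
#' @examples
#' summaryDialect(snp = "MarkerName", beta = "Effect", se = "StdErr")
#' @export
summaryDialect <- function(...) {
  d <- c(snp = "snp", effect_allele = "effect_allele",
         other_allele = "other_allele", eaf = "eaf", beta = "beta",
         se = "se", n = "n")
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad))
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    d[names(ov)] <- ov
  }
  d
}

#' Read a GWAS summary-association table
#'
#' Reads a tab-delimited file with a header row, one row per variant, and
#' returns a validated [AssociationTable-class]. Mandatory fields are the
#' variant identifier, effect and other alleles, effect estimate (`beta`,
#' natural-log scale) and its standard error; effect-allele frequency and
#' sample size are optional. Rows that fail validation are reported with
#' their file line numbers.
#'
#' @param path path to a tab-delimited text file.
#' @param trait trait label; defaults to the file name.
#' @param dialect column-name mapping from [summaryDialect()].
#' @return an [AssociationTable-class].
#' @seealso [harmonize()], [summaryDialect()]
#' @export
readAssociationTable <- function(path, trait = NULL,
                                 dialect = summaryDialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(trait)) trait <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se")
  miss <- mandatory[!dialect[mandatory] %in% names(raw)]
  if (length(miss))
    stop("configuration error: column(s) not found in ", basename(path),
         ": ", paste(dialect[miss], collapse = ", "), call. = FALSE)
  line <- seq_len(nrow(raw)) + 1L  # header is line 1

  getNum <- function(field) {
    if (!dialect[[field]] %in% names(raw))
      return(rep(NA_real_, nrow(raw)))
    v <- raw[[dialect[[field]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & v != "" & is.na(out)
    if (any(bad) && field %in% c("beta", "se"))
      stop(sprintf("parse error: non-numeric %s at line(s) %s of %s",
                   field, paste(line[bad], collapse = ", "),
                   basename(path)), call. = FALSE)
    out
  }

  rec <- data.frame(
    snp = raw[[dialect[["snp"]]]],
    effect_allele = toupper(raw[[dialect[["effect_allele"]]]]),
    other_allele = toupper(raw[[dialect[["other_allele"]]]]),
    eaf = getNum("eaf"), beta = getNum("beta"), se = getNum("se"),
    n = getNum("n"), stringsAsFactors = FALSE)

  problems <- character()
  flag <- function(bad, what) {
    if (any(bad))
      problems <<- c(problems, sprintf("%s at line(s) %s", what,
                                       paste(line[bad], collapse = ", ")))
  }
  flag(is.na(rec$beta), "missing beta")
  flag(is.na(rec$se) | rec$se <= 0, "se not strictly positive")
  flag(!rec$effect_allele %in% VALID_BASES |
       !rec$other_allele %in% VALID_BASES,
       "allele not a single base A/C/G/T")
  flag(rec$effect_allele == rec$other_allele, "identical alleles")
  flag(!is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1),
       "eaf outside (0, 1)")
  dup <- duplicated(tolower(rec$snp)) | duplicated(tolower(rec$snp),
                                                   fromLast = TRUE)
  flag(dup, "duplicate snp identifier")
  if (length(problems))
    stop("validation error in ", basename(path), ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  associationTable(trait, rec)
}

#' Read an LD correlation matrix
#'
#' Reads a CSV file whose header row and first column carry variant
#' identifiers, checks it is a correlation matrix (symmetric, unit
#' diagonal, positive semidefinite to tolerance), and reorders it to the
#' requested identifiers. Small numerical asymmetry (at most `1e-6`) is
#' repaired by averaging the matrix with its transpose.
#'
#' @param path path to the CSV file.
#' @param snpIds ordered identifiers the matrix must cover; the returned
#'   matrix follows this order.
#' @param repair if `TRUE`, a matrix that is not positive semidefinite is
#'   repaired by clipping negative eigenvalues at zero and restoring the
#'   unit diagonal.
#' @return an [LDMatrix-class].
#' @export
readLDMatrix <- function(path, snpIds, repair = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- as.matrix(utils::read.csv(path, row.names = 1,
                                   check.names = FALSE))
  if (nrow(raw) != ncol(raw))
    stop("validation error: LD matrix must be square", call. = FALSE)
  ids <- rownames(raw)
  idx <- match(tolower(snpIds), tolower(ids))
  if (anyNA(idx))
    stop("lookup error: identifier(s) missing from LD matrix: ",
         paste(snpIds[is.na(idx)], collapse = ", "), call. = FALSE)
  rho <- raw[idx, idx, drop = FALSE]
  asym <- max(abs(rho - t(rho)))
  if (asym > 1e-6)
    stop("validation error: LD matrix asymmetric beyond 1e-6 (max ",
         format(asym), ")", call. = FALSE)
  rho <- 0.5 * (rho + t(rho))
  if (any(abs(rho) > 1 + 1e-8))
    stop("validation error: entries outside [-1, 1]; not a correlation ",
         "matrix", call. = FALSE)
  if (max(abs(diag(rho) - 1)) > 1e-8)
    stop("validation error: diagonal must be 1", call. = FALSE)
  ev <- eigen(rho, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    if (!repair)
      stop("validation error: LD matrix not positive semidefinite ",
           "(smallest eigenvalue ", format(min(ev$values)),
           "); rerun with repair = TRUE for a nearest-PSD repair",
           call. = FALSE)
    v <- pmax(ev$values, 0)
    rho <- ev$vectors %*% (v * t(ev$vectors))
    d <- sqrt(diag(rho))
    rho <- rho / tcrossprod(d)
    rho <- 0.5 * (rho + t(rho))
    diag(rho) <- 1
  }
  ldMatrix(snpIds, rho)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations to the exposure's effect alleles so that
#' each retained variant's `bx` and `by` refer to the same allele. The
#' outcome effect sign is flipped when its effect allele matches the
#' exposure's other allele; alleles reported on the opposite strand are
#' complemented (A<->T, C<->G) before comparison. Palindromic variants
#' (A/T or C/G pairs), whose strand cannot be resolved from the alleles
#' alone, are handled per `palindromicPolicy`. Variants whose alleles
#' neither match nor complement are dropped with reason
#' `"allele mismatch"`; every exclusion is recorded, never silent.
#'
#' @param exposure,outcome [AssociationTable-class] objects; identifiers
#'   are matched case-insensitively.
#' @param palindromicPolicy one of
#'   * `"drop_ambiguous"` (default): drop a palindromic variant when its
#'     effect-allele frequency is missing in either table or lies within
#'     `eafAmbiguityBand` of 0.5 in either table; otherwise orient it by
#'     frequency;
#'   * `"infer_by_eaf"`: orient by frequency whenever both frequencies are
#'     present (no ambiguity band), dropping only variants with missing
#'     frequency;
#'   * `"keep"`: align palindromic variants by allele labels as if strand
#'     were known.
#' @param eafAmbiguityBand half-width of the frequency interval around 0.5
#'   treated as strand-ambiguous under `"drop_ambiguous"` (default 0.08,
#'   i.e. drop when eaf is in 0.42-0.58).
#' @return a [HarmonizedSet-class].
#' @examples
#' exp <- associationTable("biomarker", data.frame(
#'   snp = c("rs1", "rs2"), effect_allele = c("A", "A"),
#'   other_allele = c("G", "G"), beta = c(0.10, 0.10), se = c(0.01, 0.01)))
#' out <- associationTable("disease", data.frame(
#'   snp = c("rs1", "rs2"), effect_allele = c("G", "T"),
#'   other_allele = c("A", "C"), beta = c(0.05, 0.05), se = c(0.02, 0.02)))
#' as.data.frame(harmonize(exp, out))  # rs1 sign-flipped, rs2 complemented
#' @export
harmonize <- function(exposure, outcome,
                      palindromicPolicy = c("drop_ambiguous",
                                            "infer_by_eaf", "keep"),
                      eafAmbiguityBand = 0.08) {
  palindromicPolicy <- match.arg(palindromicPolicy)
  stopifnot(is(exposure, "AssociationTable"), is(outcome, "AssociationTable"))
  ex <- exposure@records
  oy <- outcome@records
  idx <- match(tolower(ex$snp), tolower(oy$snp))
  shared <- which(!is.na(idx))
  if (!length(shared))
    stop("empty intersection: no shared SNPs between '", exposure@trait,
         "' and '", outcome@trait, "'", call. = FALSE)

  keep <- vector("list", length(shared))
  drop <- vector("list", length(shared))
  for (k in seq_along(shared)) {
    x <- ex[shared[k], ]
    y <- oy[idx[shared[k]], ]
    pal <- unname(isPalindromic(x$effect_allele, x$other_allele))
    dropReason <- NULL
    flip <- NA

    if (pal) {
      yPal <- isPalindromic(y$effect_allele, y$other_allele)
      sameAlleles <- yPal &&
        (setequal(c(y$effect_allele, y$other_allele),
                  c(x$effect_allele, x$other_allele)) ||
         setequal(c(COMPLEMENT[y$effect_allele], COMPLEMENT[y$other_allele]),
                  c(x$effect_allele, x$other_allele)))
      if (!sameAlleles) {
        dropReason <- "allele mismatch"
      } else if (palindromicPolicy == "keep") {
        flip <- y$effect_allele != x$effect_allele
      } else {
        eafMissing <- is.na(x$eaf) || is.na(y$eaf)
        ambiguous <- palindromicPolicy == "drop_ambiguous" &&
          (eafMissing || abs(x$eaf - 0.5) <= eafAmbiguityBand ||
             abs(y$eaf - 0.5) <= eafAmbiguityBand)
        if (eafMissing || ambiguous) {
          dropReason <- "palindromic-ambiguous"
        } else {
          # strand is unresolvable from alleles: orient by frequency
          flip <- sign(x$eaf - 0.5) != sign(y$eaf - 0.5)
        }
      }
    } else {
      yea <- y$effect_allele; yoa <- y$other_allele
      if (yea == x$effect_allele && yoa == x$other_allele) {
        flip <- FALSE
      } else if (yea == x$other_allele && yoa == x$effect_allele) {
        flip <- TRUE
      } else {
        cea <- unname(COMPLEMENT[yea]); coa <- unname(COMPLEMENT[yoa])
        if (cea == x$effect_allele && coa == x$other_allele) {
          flip <- FALSE
        } else if (cea == x$other_allele && coa == x$effect_allele) {
          flip <- TRUE
        } else {
          dropReason <- "allele mismatch"
        }
      }
    }

    if (!is.null(dropReason)) {
      drop[[k]] <- data.frame(snp = x$snp, reason = dropReason,
                              stringsAsFactors = FALSE)
    } else {
      keep[[k]] <- data.frame(
        snp = x$snp, effect_allele = x$effect_allele,
        other_allele = x$other_allele,
        bx = x$beta, sx = x$se,
        by = if (flip) -y$beta else y$beta, sy = y$se,
        palindromic = pal, stringsAsFactors = FALSE)
    }
  }

  data <- do.call(rbind, keep[!vapply(keep, is.null, logical(1))])
  if (is.null(data))
    data <- data.frame(snp = character(), effect_allele = character(),
                       other_allele = character(), bx = numeric(),
                       sx = numeric(), by = numeric(), sy = numeric(),
                       palindromic = logical(), stringsAsFactors = FALSE)
  dropped <- do.call(rbind, drop[!vapply(drop, is.null, logical(1))])
  newHarmonizedSet(exposure@trait, outcome@trait, data, dropped)
}
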