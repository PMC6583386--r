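# in-code fixtures shared across test files

makeTable <- function(trait, snp, ea, oa, beta, se, eaf = NA, n = NA) {
  associationTable(trait, data.frame(
    snp = snp, effect_allele = ea, other_allele = oa,
    beta = beta, se = se, eaf = eaf, n = n, stringsAsFactors = FALSE))
}

# aligned exposure/outcome pair on non-palindromic alleles
makeHarmonized <- function(bx, by, sy, sx = rep(0.005, length(bx)),
                           snp = sprintf("rs%d", seq_along(bx))) {
  ex <- makeTable("exposure", snp, "A", "G", bx, sx)
  oy <- makeTable("outcome", snp, "A", "G", by, sy)
  harmonize(ex, oy)
}

# harmonized set drawn from the generator (strong instruments by default)
simHarmonized <- function(seed, ...) {
  study <- simulateTwoSample(simulationConfig(seed = seed, ...))
  harmonize(exposureTable(study), outcomeTable(study))
}

writeTempTsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writeTempCsv <- function(m, ids) {
  path <- tempfile(fileext = ".csv")
  dimnames(m) <- list(ids, ids)
  write.csv(as.data.frame(m), path, quote = FALSE)
  path
}
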