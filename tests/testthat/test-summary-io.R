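test_that("readAssociationTable reads, validates and maps dialects", {
  df <- data.frame(snp = c("rs1", "rs2"), effect_allele = c("a", "C"),
                   other_allele = c("g", "T"), eaf = c(0.3, 0.6),
                   beta = c(0, -0.08), se = c(0.1, 0.02), n = c(100, 200))
  tab <- readAssociationTable(writeTempTsv(df), trait = "CRP")
  expect_s4_class(tab, "AssociationTable")
  expect_identical(traitName(tab), "CRP")
  expect_identical(nSnps(tab), 2L)
  # alleles upper-cased, zero beta retained
  expect_identical(as.data.frame(tab)$effect_allele, c("A", "C"))
  expect_identical(as.data.frame(tab)$beta[1], 0)

  # custom column names resolved through the dialect
  names(df) <- c("rsid", "EA", "OA", "freq", "Effect", "StdErr", "N")
  tab2 <- readAssociationTable(writeTempTsv(df), trait = "CRP",
    dialect = summaryDialect(snp = "rsid", effect_allele = "EA",
                             other_allele = "OA", eaf = "freq",
                             beta = "Effect", se = "StdErr", n = "N"))
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
})

test_that("readAssociationTable reports the offending row and column", {
  base <- data.frame(snp = c("rs1", "rs2"), effect_allele = c("A", "C"),
                     other_allele = c("G", "T"), beta = c(0.1, 0.2),
                     se = c(0.1, 0.1))
  bad <- base; bad$se[2] <- 0
  expect_error(readAssociationTable(writeTempTsv(bad)),
               "se not strictly positive at line\\(s\\) 3")
  bad <- base; bad$beta <- c("0.1", "x")
  expect_error(readAssociationTable(writeTempTsv(bad)),
               "non-numeric beta at line\\(s\\) 3")
  bad <- base; bad$snp <- c("rs1", "RS1")
  expect_error(readAssociationTable(writeTempTsv(bad)),
               "duplicate snp identifier")
  expect_error(
    readAssociationTable(writeTempTsv(base[, -5])),
    "configuration error.*se")
  bad <- base; bad$other_allele[1] <- "AT"
  expect_error(readAssociationTable(writeTempTsv(bad)),
               "single base")
})

test_that("readLDMatrix validates, reorders and optionally repairs", {
  ids <- c("rs1", "rs2", "rs3", "rs4")
  p <- writeTempCsv(diag(4), ids)
  ld <- readLDMatrix(p, rev(ids))
  expect_s4_class(ld, "LDMatrix")
  expect_equal(unname(as.matrix(ld)), diag(4))
  expect_identical(ld@snpIds, rev(ids))

  m <- matrix(c(1, 0.6, 0.6, 1), 2)
  ld2 <- readLDMatrix(writeTempCsv(m, c("rs1", "rs2")), c("rs1", "rs2"))
  expect_equal(eigen(ld2@rho, only.values = TRUE)$values, c(1.6, 0.4))

  # |rho| > 1 is not a correlation
  m <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(readLDMatrix(writeTempCsv(m, c("rs1", "rs2")),
                            c("rs1", "rs2")),
               "not a correlation")

  # asymmetry beyond tolerance rejected
  m <- matrix(c(1, 0.5, 0.6, 1), 2)
  expect_error(readLDMatrix(writeTempCsv(m, c("rs1", "rs2")),
                            c("rs1", "rs2")), "asymmetric")

  # missing identifier
  expect_error(readLDMatrix(writeTempCsv(diag(2), c("rs1", "rs2")),
                            c("rs1", "rsX")), "rsX")

  # non-PSD: rejected unless repair is requested
  m <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  p <- writeTempCsv(m, c("rs1", "rs2", "rs3"))
  expect_error(readLDMatrix(p, c("rs1", "rs2", "rs3")), "repair = TRUE")
  fixed <- readLDMatrix(p, c("rs1", "rs2", "rs3"), repair = TRUE)
  ev <- eigen(fixed@rho, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(diag(fixed@rho), rep(1, 3))
})

test_that("harmonize aligns alleles, flips signs and complements strands", {
  ex <- makeTable("x", c("rs1", "rs2", "rs4"), c("A", "A", "A"),
                  c("G", "G", "C"), c(0.10, 0.10, 0.10),
                  c(0.01, 0.01, 0.01), eaf = c(0.8, 0.8, 0.3))
  oy <- makeTable("y", c("rs1", "rs2", "rs4"), c("G", "T", "C"),
                  c("A", "C", "A"), c(0.05, 0.05, 0.07),
                  c(0.02, 0.02, 0.02), eaf = c(0.2, 0.79, 0.7))
  h <- harmonize(ex, oy)
  d <- as.data.frame(h)
  # rs1: effect alleles swapped -> sign flip
  expect_equal(d$by[d$snp == "rs1"], -0.05)
  # rs2: T/C is the strand complement of A/G, same orientation
  expect_equal(d$by[d$snp == "rs2"], 0.05)
  # rs4: complement of C/A is G/T, swapped against A/C... C/A vs A/C swap
  expect_equal(d$by[d$snp == "rs4"], -0.07)
  expect_identical(nrow(droppedSnps(h)), 0L)
})

test_that("palindromic policies behave as documented", {
  ex <- makeTable("x", c("rs3", "rs5"), c("A", "A"), c("T", "T"),
                  c(0.1, 0.1), c(0.01, 0.01), eaf = c(0.50, 0.10))
  oy <- makeTable("y", c("rs3", "rs5"), c("A", "A"), c("T", "T"),
                  c(0.05, 0.05), c(0.02, 0.02), eaf = c(0.50, 0.85))
  # default: rs3 ambiguous at eaf 0.5; rs5 informative, frequencies on
  # opposite sides -> orientation flip
  h <- harmonize(ex, oy, eafAmbiguityBand = 0.08)
  expect_identical(droppedSnps(h)$snp, "rs3")
  expect_identical(droppedSnps(h)$reason, "palindromic-ambiguous")
  expect_equal(as.data.frame(h)$by, -0.05)
  expect_true(all(as.data.frame(h)$palindromic))

  # missing frequency is always ambiguous under drop_ambiguous
  exNA <- makeTable("x", "rs6", "C", "G", 0.1, 0.01)
  oyNA <- makeTable("y", "rs6", "C", "G", 0.05, 0.02, eaf = 0.2)
  expect_identical(
    droppedSnps(harmonize(exNA, oyNA))$reason, "palindromic-ambiguous")

  # infer_by_eaf keeps rs3 (no ambiguity band): frequencies equal -> keep
  h2 <- harmonize(ex, oy, "infer_by_eaf")
  expect_identical(nrow(droppedSnps(h2)), 0L)
  # keep aligns by allele labels as-printed
  h3 <- harmonize(ex, oy, "keep")
  expect_equal(as.data.frame(h3)$by, c(0.05, 0.05))
})

test_that("irreconcilable alleles are dropped with a reason, never silently", {
  ex <- makeTable("x", c("rs1", "rs2"), c("A", "A"), c("G", "G"),
                  c(0.1, 0.1), c(0.01, 0.01))
  oy <- makeTable("y", c("rs1", "rs2"), c("A", "A"), c("C", "G"),
                  c(0.05, 0.05), c(0.02, 0.02))
  h <- harmonize(ex, oy)
  expect_identical(droppedSnps(h)$snp, "rs1")
  expect_identical(droppedSnps(h)$reason, "allele mismatch")
  expect_identical(as.data.frame(h)$snp, "rs2")

  ozy <- makeTable("z", "rs9", "A", "G", 0.05, 0.02)
  expect_error(harmonize(ex, ozy), "no shared SNPs")
})

test_that("harmonize is idempotent and sign-coherent, and partitions the
           shared set", {
  set.seed(42)
  for (rep in 1:5) {
    study <- simulateTwoSample(simulationConfig(nSnps = 10,
                                                seed = sample.int(1e6, 1)))
    ex <- exposureTable(study)
    oy <- outcomeTable(study)
    h1 <- harmonize(ex, oy)
    # idempotence: re-harmonizing the aligned pair changes nothing
    oy2 <- associationTable("outcome", within(as.data.frame(h1), {
      beta <- by; se <- sy; eaf <- as.data.frame(ex)$eaf
    })[, c("snp", "effect_allele", "other_allele", "eaf", "beta", "se")])
    h2 <- harmonize(ex, oy2)
    expect_equal(as.data.frame(h2)$by, as.data.frame(h1)$by)

    # sign coherence: flipping alleles, beta and eaf of an input record
    # leaves the harmonized set unchanged
    flipped <- as.data.frame(oy)
    i <- sample.int(nrow(flipped), 1)
    flipped[i, c("effect_allele", "other_allele")] <-
      flipped[i, c("other_allele", "effect_allele")]
    flipped$beta[i] <- -flipped$beta[i]
    flipped$eaf[i] <- 1 - flipped$eaf[i]
    h3 <- harmonize(ex, associationTable("outcome", flipped))
    expect_equal(as.data.frame(h3), as.data.frame(h1))

    # |retained| + |dropped| = |shared|
    shared <- length(intersect(as.data.frame(ex)$snp,
                               as.data.frame(oy)$snp))
    expect_identical(nSnps(h1) + nrow(droppedSnps(h1)), shared)
  }
})
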