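test_that("the generator is reproducible from its seed and validated", {
  cfg <- simulationConfig(nSnps = 12, theta = 0.1, seed = 33)
  s1 <- simulateTwoSample(cfg)
  s2 <- simulateTwoSample(cfg)
  expect_identical(as.data.frame(exposureTable(s1)),
                   as.data.frame(exposureTable(s2)))
  expect_identical(studyTruth(s1), studyTruth(s2))
  s3 <- simulateTwoSample(simulationConfig(nSnps = 12, theta = 0.1,
                                           seed = 34))
  expect_false(identical(as.data.frame(exposureTable(s1)),
                         as.data.frame(exposureTable(s3))))

  expect_error(simulationConfig(), "seed")
  expect_error(simulationConfig(nSnps = 1, seed = 1), "at least 2")
  expect_error(simulationConfig(mafRange = c(0.2, 0.7), seed = 1),
               "mafRange")
  expect_error(simulationConfig(pleiotropyMode = "weird", seed = 1),
               "pleiotropyMode")
  # configuration errors list every violation at once
  err <- tryCatch(simulationConfig(nSnps = 1, nExposure = -1, seed = 1),
                  error = conditionMessage)
  expect_match(err, "at least 2")
  expect_match(err, "positive")
})

test_that("simulated tables follow the generating model", {
  cfg <- simulationConfig(nSnps = 10, theta = 0.2, seed = 91)
  study <- simulateTwoSample(cfg)
  tr <- studyTruth(study)
  ex <- as.data.frame(exposureTable(study))
  oy <- as.data.frame(outcomeTable(study))
  expect_identical(ex$snp, oy$snp)
  expect_identical(ex$effect_allele, oy$effect_allele)
  # the stated standard-error model
  expect_equal(ex$se, (2 * 50000 * tr$maf * (1 - tr$maf))^-0.5)
  expect_equal(oy$se, 2 * (2 * 80000 * tr$maf * (1 - tr$maf))^-0.5)
  expect_true(all(tr$gamma > 0))  # folded positive by default
  expect_true(all(tr$alpha == 0))

  # near-noiseless limit: every ratio equals theta
  quiet <- simulateTwoSample(simulationConfig(
    nSnps = 6, theta = 0.2, nExposure = 1e12, nOutcome = 1e12, seed = 92))
  h <- harmonize(exposureTable(quiet), outcomeTable(quiet))
  expect_equal(mrRatio(h)$ratio, rep(0.2, 6), tolerance = 1e-3)

  # empirical spread of bx around gamma matches the nominal sx
  reps <- 800
  draws <- sapply(seq_len(reps), function(r) {
    s <- simulateTwoSample(simulationConfig(nSnps = 4, theta = 0,
                                            gammaSd = 0, seed = 5000 + r))
    as.data.frame(exposureTable(s))$beta - studyTruth(s)$gamma
  })
  # pool standardized deviations across variants and repetitions
  sxs <- sapply(seq_len(reps), function(r)
    studyTruth(simulateTwoSample(simulationConfig(
      nSnps = 4, theta = 0, gammaSd = 0, seed = 5000 + r)))$sx)
  expect_equal(sd(as.numeric(draws / sxs)), 1, tolerance = 0.05)
})

test_that("block LD induces the advertised equicorrelation", {
  cfg <- simulationConfig(nSnps = 6, theta = 0, ldBlock = 0.5, seed = 94)
  study <- simulateTwoSample(cfg)
  expect_s4_class(studyLD(study), "LDMatrix")
  m <- as.matrix(studyLD(study))
  expect_equal(unname(m[1, 2]), 0.5)
  expect_equal(diag(m), setNames(rep(1, 6), colnames(m)))

  # empirical noise correlation across repetitions approaches ldBlock
  z <- sapply(1:600, function(r) {
    s <- simulateTwoSample(simulationConfig(nSnps = 2, theta = 0,
                                            gammaSd = 0, ldBlock = 0.5,
                                            seed = 9000 + r))
    (as.data.frame(exposureTable(s))$beta - studyTruth(s)$gamma) /
      studyTruth(s)$sx
  })
  expect_equal(cor(z[1, ], z[2, ]), 0.5, tolerance = 0.12)
})

test_that("pleiotropy modes shift the outcome model as configured", {
  bal <- simulateTwoSample(simulationConfig(
    nSnps = 200, pleiotropyMode = "balanced", alphaSd = 0.02, seed = 95))
  expect_equal(mean(studyTruth(bal)$alpha), 0, tolerance = 0.006)
  dir <- simulateTwoSample(simulationConfig(
    nSnps = 200, pleiotropyMode = "directional", alphaMean = 0.02,
    alphaSd = 0.02, seed = 96))
  # within 3 standard errors of the configured mean
  expect_lt(abs(mean(studyTruth(dir)$alpha) - 0.02), 3 * 0.02 / sqrt(200))
})

test_that("mediation triplets encode the product-of-coefficients truth", {
  cfg <- simulationConfig(nSnps = 8, nExposure = 1e14, nOutcome = 1e14,
                          outcomeSeScale = 1, seed = 97)
  # full mediation, near-noiseless: recovered proportion is 100%
  st <- simulateMediationTriplet(cfg, aTrue = -0.26, bTrue = -0.14)
  tr <- studyTruth(st)
  expect_equal(tr$proportion_mediated, 100)
  expect_equal(tr$total, -0.26 * -0.14)
  eSnps <- tr$exposure_instruments
  ex <- as.data.frame(exposureTable(st))
  md <- as.data.frame(mediatorTable(st))
  oy <- as.data.frame(outcomeTable(st))
  i <- match(eSnps, ex$snp)
  # a and the total recovered by the ratio method on exposure instruments
  expect_equal(md$beta[i] / ex$beta[i], rep(-0.26, 8), tolerance = 1e-3)
  expect_equal(oy$beta[i] / ex$beta[i], rep(-0.26 * -0.14, 8),
               tolerance = 1e-3)
  # b recovered on the mediator instruments
  j <- match(tr$mediator_instruments, md$snp)
  expect_equal(oy$beta[j] / md$beta[j], rep(-0.14, 8), tolerance = 1e-3)

  # a configured direct effect dilutes the proportion mediated
  st2 <- simulateMediationTriplet(cfg, aTrue = -0.26, bTrue = -0.14,
                                  directEffect = 0.0841 - 0.0364)
  expect_equal(studyTruth(st2)$total, 0.0841)
  expect_equal(studyTruth(st2)$proportion_mediated, 100 * 0.0364 / 0.0841)

  # null mediator-outcome path: total collapses to the direct effect
  st3 <- simulateMediationTriplet(cfg, aTrue = -0.26, bTrue = 0)
  expect_equal(studyTruth(st3)$total, 0)
})
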