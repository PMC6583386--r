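test_that("Wald ratio estimates divide outcome by exposure effects", {
  cases <- data.frame(bx = c(0.5, -0.5, 0.25), by = c(0.05, 0.05, 0.05),
                      sy = c(0.02, 0.02, 0.01),
                      ratio = c(0.10, -0.10, 0.20), se = c(0.04, 0.04, 0.04))
  h <- makeHarmonized(cases$bx, cases$by, cases$sy)
  est <- mrRatio(h)
  expect_equal(est$ratio, cases$ratio)
  expect_equal(est$se, cases$se)
  expect_equal(est$weight, est$se^-2)

  hz <- makeHarmonized(c(0.5, 0), c(0.05, 0.05), c(0.02, 0.02))
  expect_error(mrRatio(hz), "degenerate instrument.*rs2")
})

test_that("IVW pools ratio estimates by inverse-variance weights", {
  # equal weights: arithmetic mean
  eq <- data.frame(ratio = c(0.1, 0.2), se = c(0.03, 0.03),
                   weight = c(0.03, 0.03)^-2)
  expect_equal(mrBeta(mrIvw(eq, "fixed")), 0.15)

  # hand-computed weighted mean: weights 2500 and 625
  est <- data.frame(ratio = c(0.1, 0.2), se = c(0.02, 0.04),
                    weight = c(2500, 625))
  fe <- mrIvw(est, "fixed")
  expect_equal(mrBeta(fe), 0.12)
  expect_equal(mrSe(fe), 3125^-0.5)
  expect_equal(unname(mrCI(fe)),
               0.12 + c(-1, 1) * qnorm(0.975) * 3125^-0.5)

  # random effects: same point estimate, inflated SE (Q = 5, L - 1 = 1)
  re <- mrIvw(est, "multiplicative_random")
  expect_equal(mrBeta(re), mrBeta(fe))
  expect_equal(mrSe(re), mrSe(fe) * sqrt(5))

  expect_error(mrIvw(est[1, ]), "insufficient instruments")
})

test_that("IVW equals weighted origin regression and metafor on random
           instances", {
  skip_if_not_installed("metafor")
  set.seed(11)
  for (i in 1:100) {
    L <- sample(2:12, 1)
    bx <- runif(L, 0.05, 0.5) * sample(c(-1, 1), L, replace = TRUE)
    by <- rnorm(L, 0.1 * bx, 0.02)
    sy <- runif(L, 0.005, 0.05)
    h <- makeHarmonized(bx, by, sy)
    est <- mrRatio(h)
    ivw <- mrIvw(est, "fixed")
    # oracle 1: weighted least squares through the origin of by on bx
    wls <- lm(by ~ 0 + bx, weights = sy^-2)
    expect_equal(mrBeta(ivw), unname(coef(wls)), tolerance = 1e-10)
    # oracle 2: fixed-effect meta-analysis of the ratio estimates
    rma <- metafor::rma(yi = est$ratio, sei = est$se, method = "FE")
    expect_equal(mrBeta(ivw), as.numeric(rma$beta), tolerance = 1e-10)
    expect_equal(mrSe(ivw), rma$se, tolerance = 1e-10)
  }
})

test_that("correlated IVW reduces to IVW under independence and loses
           precision for near-duplicate instruments", {
  h <- simHarmonized(seed = 5, nSnps = 8, theta = 0.1)
  ld <- ldMatrix(as.data.frame(h)$snp, diag(8))
  est <- mrRatio(h)
  for (em in c("fixed", "multiplicative_random")) {
    a <- mrIvwCorrelated(h, ld, em)
    b <- mrIvw(est, em)
    expect_equal(mrBeta(a), mrBeta(b), tolerance = 1e-10)
    expect_equal(mrSe(a), mrSe(b), tolerance = 1e-10)
  }

  # two identical records in near-perfect LD carry ~one instrument of
  # information: closed-form 2x2 GLS se is s/b * sqrt((1 + rho) / 2)
  h2 <- makeHarmonized(c(0.1, 0.1), c(0.02, 0.02), c(0.05, 0.05))
  ld2 <- ldMatrix(c("rs1", "rs2"), matrix(c(1, 0.99, 0.99, 1), 2))
  g <- mrIvwCorrelated(h2, ld2, "fixed")
  indep <- mrIvw(mrRatio(h2), "fixed")
  expect_gt(mrSe(g), mrSe(indep))
  expect_equal(mrSe(g), 0.05 / 0.1 * sqrt((1 + 0.99) / 2),
               tolerance = 1e-12)

  # numerically singular covariance is a conditioning error
  ld3 <- ldMatrix(c("rs1", "rs2"), matrix(c(1, 1, 1, 1), 2))
  expect_error(mrIvwCorrelated(h2, ld3), "singular")
})

test_that("weighted median interpolates the weighted empirical
           distribution at one half", {
  # equal weights, odd L: the simple median
  eq <- data.frame(ratio = c(0.3, 0.1, 0.2), se = rep(0.05, 3),
                   weight = rep(400, 3))
  expect_equal(mrBeta(mrMedian(eq, seed = 1)), 0.2)

  # hand-applied cumulative-midpoint interpolation, weights 1e4/1e4/100
  est <- data.frame(ratio = c(0.1, 0.2, 0.9), se = c(0.01, 0.01, 0.1),
                    weight = c(1e4, 1e4, 100))
  expect_equal(mrBeta(mrMedian(est, seed = 1)), 0.1505, tolerance = 1e-4)

  # an instrument holding nearly all the weight pins the estimate
  dom <- data.frame(ratio = c(0.1, 0.5, 0.6), se = c(0.001, 0.3, 0.3),
                    weight = c(1e6, 1 / 0.09, 1 / 0.09))
  expect_equal(mrBeta(mrMedian(dom, seed = 1)), 0.1, tolerance = 1e-3)

  expect_error(mrMedian(est[1:2, ], seed = 1), "insufficient instruments")
  expect_error(mrMedian(est, seed = NA), "seed")

  # equal weights equal the simple median for odd L (property)
  set.seed(3)
  for (i in 1:20) {
    L <- sample(c(3, 5, 7, 9), 1)
    r <- rnorm(L)
    est <- data.frame(ratio = r, se = rep(0.1, L), weight = rep(100, L))
    expect_equal(mrBeta(mrMedian(est, nBoot = 2, seed = 1)), median(r))
  }
})

test_that("weighted median bootstrap SE is reproducible and sensible", {
  est <- data.frame(ratio = c(0.1, 0.15, 0.2, 0.4), se = rep(0.05, 4),
                    weight = rep(400, 4))
  m1 <- mrMedian(est, seed = 99)
  m2 <- mrMedian(est, seed = 99)
  expect_identical(mrSe(m1), mrSe(m2))
  expect_gt(mrSe(m1), 0)
})

test_that("MR-Egger fits the weighted regression with intercept", {
  # three collinear points: exact fit, any weights
  h <- makeHarmonized(c(0.2, 0.4, 0.6), c(0.05, 0.07, 0.09),
                      c(0.01, 0.02, 0.03))
  e <- mrEgger(h, "fixed")
  expect_equal(mrBeta(eggerSlope(e)), 0.10, tolerance = 1e-12)
  expect_equal(eggerIntercept(e)$beta, 0.03, tolerance = 1e-12)

  # proportional effects: zero intercept, slope is the proportionality
  h2 <- makeHarmonized(c(1, 2, 3), c(0.1, 0.2, 0.3), rep(0.05, 3))
  e2 <- mrEgger(h2)
  expect_equal(eggerIntercept(e2)$beta, 0, tolerance = 1e-12)
  expect_equal(mrBeta(eggerSlope(e2)), 0.1, tolerance = 1e-12)
  expect_equal(eggerIntercept(e2)$odds, 1, tolerance = 1e-12)

  h3 <- makeHarmonized(c(0.2, 0.4), c(0.05, 0.07), c(0.01, 0.02))
  expect_error(mrEgger(h3), "insufficient instruments")
  h4 <- makeHarmonized(rep(0.2, 3), c(0.05, 0.06, 0.07), rep(0.01, 3))
  expect_error(mrEgger(h4), "collinearity")
})

test_that("MR-Egger matches weighted lm, with SEs floored at the fixed
           model", {
  set.seed(21)
  for (i in 1:25) {
    L <- sample(4:15, 1)
    bx <- runif(L, 0.05, 0.4)
    sy <- runif(L, 0.01, 0.05)
    by <- 0.2 * bx + 0.01 + rnorm(L, 0, sy * 3)  # overdispersed
    h <- makeHarmonized(bx, by, sy)
    fit <- lm(by ~ bx, weights = sy^-2)
    e <- mrEgger(h, "multiplicative_random")
    expect_equal(mrBeta(eggerSlope(e)), unname(coef(fit)[2]),
                 tolerance = 1e-10)
    expect_equal(eggerIntercept(e)$beta, unname(coef(fit)[1]),
                 tolerance = 1e-10)
    disp <- sum(sy^-2 * resid(fit)^2) / (L - 2)
    if (disp >= 1) {
      # multiplicative random effects coincide with lm's variance scaling
      sm <- summary(fit)$coefficients
      expect_equal(mrSe(eggerSlope(e)), sm[2, 2], tolerance = 1e-10)
      expect_equal(eggerIntercept(e)$se, sm[1, 2], tolerance = 1e-10)
    }
    # the floor: random-effects SEs never undercut the fixed model
    ef <- mrEgger(h, "fixed")
    expect_gte(mrSe(eggerSlope(e)), mrSe(eggerSlope(ef)) - 1e-15)
    # identical point estimates across effects models
    expect_equal(mrBeta(eggerSlope(e)), mrBeta(eggerSlope(ef)))
  }
})

test_that("Egger orientation makes the fit invariant to instrument
           sign coding", {
  set.seed(31)
  bx <- runif(6, 0.1, 0.4)
  sy <- runif(6, 0.01, 0.03)
  by <- 0.15 * bx + 0.02 + rnorm(6, 0, 0.01)
  h1 <- makeHarmonized(bx, by, sy)
  flip <- c(1, -1, 1, -1, -1, 1)
  h2 <- makeHarmonized(bx * flip, by * flip, sy)
  e1 <- mrEgger(h1)
  e2 <- mrEgger(h2)
  expect_equal(mrBeta(eggerSlope(e1)), mrBeta(eggerSlope(e2)))
  expect_equal(eggerIntercept(e1)$beta, eggerIntercept(e2)$beta)
})

test_that("fold-scale conversion is exp(beta * ln 2) with monotone CI", {
  expect_equal(toFoldScale(0, 0.1)[["or"]], 1)
  expect_equal(toFoldScale(1, 0)[["or"]], 2)
  expect_equal(round(toFoldScale(0.0364, 0.01)[["or"]], 2), 1.03)
  f <- toFoldScale(-0.2, 0.05)
  expect_equal(unname(f),
               exp((-0.2 + c(0, -1, 1) * qnorm(0.975) * 0.05) * log(2)))
  expect_lt(f[["low"]], f[["or"]])
  expect_error(toFoldScale(0.1, -0.01), "non-negative")
  expect_error(toFoldScale(2000, 1), "overflow")
})

test_that("estimators are scale-equivariant in the exposure units", {
  h <- simHarmonized(seed = 13, nSnps = 9, theta = 0.15)
  d <- as.data.frame(h)
  c0 <- 2.5
  hs <- makeHarmonized(d$bx * c0, d$by, d$sy, sx = d$sx, snp = d$snp)
  expect_equal(mrRatio(hs)$ratio, mrRatio(h)$ratio / c0)
  expect_equal(mrBeta(mrIvw(mrRatio(hs))), mrBeta(mrIvw(mrRatio(h))) / c0)
  expect_equal(mrBeta(mrMedian(mrRatio(hs), seed = 2)),
               mrBeta(mrMedian(mrRatio(h), seed = 2)) / c0)
  expect_equal(mrBeta(eggerSlope(mrEgger(hs))),
               mrBeta(eggerSlope(mrEgger(h))) / c0)
})
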