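test_that("SNR normalisation by the time-activity product", {
  expect_equal(normalizeSnr(15, 1, 1), 15)
  expect_equal(normalizeSnr(15, 100, 3), 15 / sqrt(300), tolerance = 1e-12)
  expect_equal(round(normalizeSnr(15, 100, 3), 3), 0.866)
  expect_equal(normalizeSnr(0, 100, 3), 0)
  expect_error(normalizeSnr(10, 0, 3), "positive")
  expect_error(normalizeSnr(10, 100, -1), "positive")
})

test_that("noise-free power-law data are recovered exactly", {
  p <- c(1, 4, 9, 16, 25)
  fit <- fitPowerLaw(p, 2 * p^(-0.5), parameter = "weight")
  expect_equal(fit@a, 2, tolerance = 1e-6)
  expect_equal(fit@d, 0.5, tolerance = 1e-6)
  expect_equal(fit@rSquared, 1, tolerance = 1e-6)
})

test_that("degenerate and invalid fits are handled", {
  p <- c(50, 70, 90, 110)
  fit <- fitPowerLaw(p, rep(3, 4), parameter = "weight")
  expect_equal(fit@a, 3)
  expect_identical(fit@d, 0)
  expect_identical(fit@rSquared, 0)
  expect_error(fitPowerLaw(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fitPowerLaw(c(1, 2, -3), c(1, 2, 3)), "positive")
  ## log-scale diagnostic fit
  fl <- fitPowerLaw(p, 97.4 * p^(-1.15), scale = "log")
  expect_equal(fl@d, 1.15, tolerance = 1e-8)
})

test_that("model selection maximises R^2 with a weight tie-break", {
  mk <- function(par, r2) {
    f <- fitPowerLaw(c(1, 4, 9), 2 * c(1, 4, 9)^-0.5, parameter = par)
    f@rSquared <- r2
    f
  }
  fits <- list(mk("bmi", 0.85), mk("weight", 0.92), mk("bsa", 0.75),
               mk("circumference", 0.79))
  expect_identical(selectBodyParameter(fits)@parameter, "weight")
  expect_identical(selectBodyParameter(fits[1])@parameter, "bmi")
  tie <- list(mk("bsa", 0.9), mk("weight", 0.9))
  expect_identical(selectBodyParameter(tie)@parameter, "weight")
})

test_that("prescriptions follow the three protocol definitions", {
  m <- methods::new("BodyMetrics", weightKg = 120, heightM = 1.79,
                    bmi = 37.45, bsaM2 = 2.36, circumferenceCm = 138)
  expect_equal(prescribeActivity(fixedProtocol(100), m), 100)
  expect_equal(prescribeActivity(linearProtocol(2), m), 240)
  ## published fit coefficients reproduce ~83 MBq for a 56 kg patient
  fit <- fitPowerLaw(c(1, 4, 9), 2 * c(1, 4, 9)^-0.5, parameter = "weight")
  fit@a <- 97.40; fit@d <- 1.15
  proto <- powerLawProtocol(fit, snrConst = 15, tMin = 3)
  m56 <- methods::new("BodyMetrics", weightKg = 56, heightM = 1.73,
                      bmi = 18.7, bsaM2 = 1.67, circumferenceCm = 72)
  expect_equal(prescribeActivity(proto, m56), 82.98, tolerance = 1e-3)
  ## d = 0 makes the prescription independent of p
  fit0 <- fit; fit0@d <- 0
  p0 <- powerLawProtocol(fit0, snrConst = 15, tMin = 3)
  expect_equal(prescribeActivity(p0, m), prescribeActivity(p0, m56))
})

test_that("the normalisation/prescription round trip is an identity", {
  set.seed(42)
  for (k in 1:100) {
    a <- runif(1, 10, 300); d <- runif(1, 0, 2.5)
    sc <- runif(1, 5, 25); tm <- runif(1, 1, 10); p <- runif(1, 30, 150)
    fit <- fitPowerLaw(c(1, 4, 9), 2 * c(1, 4, 9)^-0.5,
                       parameter = "weight")
    fit@a <- a; fit@d <- d
    proto <- powerLawProtocol(fit, snrConst = sc, tMin = tm)
    m <- methods::new("BodyMetrics", weightKg = p, heightM = 1.7,
                      bmi = p / 1.7^2, bsaM2 = 1.8, circumferenceCm = 100)
    A <- prescribeActivity(proto, m)
    expect_equal(normalizeSnr(sc, A, tm), a * p^(-d), tolerance = 1e-10)
  }
})

test_that("the prescription is monotone in p, quadratic in the target", {
  fit <- fitPowerLaw(c(1, 4, 9), 2 * c(1, 4, 9)^-0.5, parameter = "weight")
  fit@a <- 97.4; fit@d <- 1.15
  mk <- function(w) methods::new("BodyMetrics", weightKg = w, heightM = 1.7,
                                 bmi = w / 2.89, bsaM2 = 1.8,
                                 circumferenceCm = 100)
  A <- vapply(c(50, 70, 90, 120), function(w)
    prescribeActivity(powerLawProtocol(fit, 15, 3), mk(w)), numeric(1))
  expect_true(all(diff(A) > 0))
  A15 <- prescribeActivity(powerLawProtocol(fit, 15, 3), mk(80))
  A30 <- prescribeActivity(powerLawProtocol(fit, 30, 3), mk(80))
  expect_equal(A30 / A15, 4, tolerance = 1e-12)
  A6min <- prescribeActivity(powerLawProtocol(fit, 15, 6), mk(80))
  expect_equal(A6min / A15, 0.5, tolerance = 1e-12)
})
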