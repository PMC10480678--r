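## SNR normalisation, body-size power-law fitting, and the three
## activity-administration protocols.
##
## Unit convention: activities in MBq and times in minutes, both in the
## normalisation SNR_Norm = SNR_L / sqrt(A * t) and in the constant-SNR
## prescription A = (1/t) (SNR_Const/a)^2 p^(2d). This is the only
## convention consistent with the published per-phantom activities.

#' Normalise a liver SNR by the time-activity product
#'
#' `SNR_Norm = SNR_L / sqrt(A_inj * t)` with the activity in MBq and the
#' acquisition time per bed position in minutes; projection counts are
#' Poisson, so reconstructed noise scales approximately with the square
#' root of the time-activity product.
#'
#' @param snrL liver SNR.
#' @param injectedMBq injected activity in MBq.
#' @param tMin acquisition time per bed position in minutes.
#' @return the normalised SNR.
#' @export
#' @examples
#' normalizeSnr(15, 100, 3)  # 15 / sqrt(300) = 0.866
normalizeSnr <- function(snrL, injectedMBq, tMin) {
  if (any(injectedMBq <= 0) || any(tMin <= 0))
    stop("activity and acquisition time must be positive")
  snrL / sqrt(injectedMBq * tMin)
}

#' Fit the body-size power law SNR_Norm = a * p^(-d)
#'
#' Nonlinear least squares on the linear scale, initialised from the
#' ordinary least-squares regression of `log(snrNorm)` on `log(p)`.
#' `R^2 = 1 - SS_res / SS_tot` about the mean of `snrNorm`.  A degenerate
#' input with zero variance in `snrNorm` yields `d = 0`, `a = mean`, and
#' `R^2` reported as 0.
#'
#' @param p body-size parameter values (positive).
#' @param snrNorm normalised SNRs (positive).
#' @param parameter name of the body-size parameter.
#' @param scale `"linear"` (default) fits on the linear scale;
#'   `"log"` returns the log-log regression fit directly.
#' @return a [PowerLawFit-class].
#' @export
#' @examples
#' p <- c(56, 68, 69, 89, 99, 100, 86, 120)
#' fitPowerLaw(p, 97.40 * p^-1.15, parameter = "weight")
fitPowerLaw <- function(p, snrNorm, parameter = "p",
                        scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (length(p) < 3) stop("need at least 3 points to fit the power law")
  if (length(p) != length(snrNorm)) stop("p and snrNorm lengths differ")
  if (any(p <= 0) || any(snrNorm <= 0))
    stop("power-law fit requires positive p and snrNorm")

  ## log-log initialisation (and diagnostic)
  lf <- stats::lm(log(snrNorm) ~ log(p))
  aLog <- exp(unname(stats::coef(lf)[1]))
  dLog <- -unname(stats::coef(lf)[2])

  if (stats::var(snrNorm) < 1e-24) {
    a <- mean(snrNorm); d <- 0; r2 <- 0
    fitted <- rep(a, length(p))
  } else if (scale == "log") {
    a <- aLog; d <- dLog
    fitted <- a * p^(-d)
    r2 <- 1 - sum((snrNorm - fitted)^2) / sum((snrNorm - mean(snrNorm))^2)
  } else {
    df <- data.frame(p = p, y = snrNorm)
    ## Gauss-Newton from the log-log start; an (almost) exact fit makes
    ## nls abort on its relative-offset criterion, so fall back to a
    ## direct quasi-Newton minimisation of the SSE in that case
    fit <- tryCatch(
      stats::nls(y ~ a * p^(-d), data = df,
                 start = list(a = aLog, d = dLog),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      a <- unname(cf["a"]); d <- unname(cf["d"])
    } else {
      sse <- function(par) sum((snrNorm - exp(par[1]) * p^(-par[2]))^2)
      opt <- stats::optim(c(log(aLog), dLog), sse, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14))
      if (opt$convergence != 0 && opt$value > 1e-10 * sum(snrNorm^2))
        stop(sprintf(
          "power-law fit did not converge (start a = %.3g, d = %.3g)",
          aLog, dLog))
      a <- exp(opt$par[1]); d <- opt$par[2]
    }
    fitted <- a * p^(-d)
    r2 <- 1 - sum((snrNorm - fitted)^2) / sum((snrNorm - mean(snrNorm))^2)
  }
  methods::new("PowerLawFit", parameter = parameter, a = a, d = d,
               rSquared = r2,
               data = data.frame(p = p, snrNorm = snrNorm, fitted = fitted),
               logCoef = c(a = aLog, d = dLog))
}

#' Select the body-size parameter with the best fit
#'
#' Returns the candidate fit with the highest coefficient of
#' determination; exact ties are broken in favour of weight (the simplest
#' parameter to use clinically).
#'
#' @param fits list of [PowerLawFit-class] objects (at least 2 for a
#'   meaningful selection; a single fit is returned as-is).
#' @return the selected [PowerLawFit-class].
#' @export
selectBodyParameter <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  if (length(fits) == 1L) return(fits[[1]])
  r2 <- vapply(fits, function(f) f@rSquared, numeric(1))
  best <- which(r2 >= max(r2) - 1e-12)
  if (length(best) > 1L) {
    w <- which(vapply(fits[best], function(f) f@parameter, character(1)) ==
               "weight")
    if (length(w)) best <- best[w[1]]
  }
  fits[[best[1]]]
}

#' Protocol constructors
#'
#' The three activity-administration protocols: a fixed activity
#' (default 100 MBq), an activity linear in body weight (default
#' 2 MBq/kg), and the constant-SNR power-law prescription
#' `A_inj = (1/t) * (SNR_Const/a)^2 * p^(2d)` (defaults SNR_Const = 15,
#' t = 3 min).
#'
#' @param A0_MBq fixed activity in MBq.
#' @param rate_MBq_per_kg weight-scaling rate in MBq/kg.
#' @param fit a [PowerLawFit-class] providing (a, d) and the body-size
#'   parameter.
#' @param snrConst target liver SNR.
#' @param tMin acquisition time per bed position in minutes.
#' @return a [ProtocolSpec-class].
#' @name protocols
NULL

#' @rdname protocols
#' @export
fixedProtocol <- function(A0_MBq = 100) {
  methods::new("ProtocolSpec", kind = "fixed", params = list(A0_MBq = A0_MBq))
}

#' @rdname protocols
#' @export
linearProtocol <- function(rate_MBq_per_kg = 2) {
  methods::new("ProtocolSpec", kind = "linear_per_kg",
               params = list(rate_MBq_per_kg = rate_MBq_per_kg))
}

#' @rdname protocols
#' @export
powerLawProtocol <- function(fit, snrConst = 15, tMin = 3) {
  stopifnot(methods::is(fit, "PowerLawFit"))
  methods::new("ProtocolSpec", kind = "power_law",
               params = list(a = fit@a, d = fit@d,
                             parameter = fit@parameter,
                             snrConst = snrConst, tMin = tMin))
}

## resolve a body-size parameter name from a BodyMetrics object
bodyParameterValue <- function(metrics, parameter) {
  stopifnot(methods::is(metrics, "BodyMetrics"))
  switch(parameter,
         weight = metrics@weightKg,
         bmi = metrics@bmi,
         bsa = metrics@bsaM2,
         circumference = metrics@circumferenceCm,
         stop(sprintf("unknown body-size parameter '%s'", parameter)))
}

#' Prescribe the injected activity for a patient
#'
#' Evaluates a [ProtocolSpec-class] on a patient's [BodyMetrics-class].
#' For the power-law protocol the result is the administered activity 60
#' minutes before imaging; uptake decay is applied downstream when the
#' activity is painted.
#'
#' @param protocol a [ProtocolSpec-class].
#' @param metrics a [BodyMetrics-class].
#' @return injected activity in MBq.
#' @export
#' @examples
#' m <- methods::new("BodyMetrics", weightKg = 120, heightM = 1.79,
#'                   bmi = 37.5, bsaM2 = 2.36, circumferenceCm = 138)
#' prescribeActivity(linearProtocol(2), m)  # 240 MBq
prescribeActivity <- function(protocol, metrics) {
  stopifnot(methods::is(protocol, "ProtocolSpec"))
  pp <- protocol@params
  switch(protocol@kind,
    fixed = pp$A0_MBq,
    linear_per_kg = pp$rate_MBq_per_kg * metrics@weightKg,
    power_law = {
      p <- bodyParameterValue(metrics, pp$parameter)
      (1 / pp$tMin) * (pp$snrConst / pp$a)^2 * p^(2 * pp$d)
    })
}
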