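#' @include AllClasses.R
NULL

#' Fit a Boltzmann sigmoid to a thermal melt curve
#'
#' Least-squares fit of
#' `s(T) = bF + (bU - bF) / (1 + exp((tm - T) / slope))` to a
#' temperature/signal table. Baselines are initialised from the terminal
#' 10 percent of points and `tm` from the half-amplitude crossing; the fit
#' uses Levenberg-Marquardt least squares. When the fitted amplitude is
#' indistinguishable from noise (`|bU - bF| < 3 x residual sd`) the fit is
#' flagged unidentifiable, as for a melt with no visible transition. The
#' fitted `tm` and `slope` are invariant to rescaling all signals by a
#' positive constant.
#'
#' @param curve `data.frame` with columns `temperature` (ascending, degrees
#'   C) and `signal`; at least 6 points.
#' @param ampliThreshold unidentifiability threshold in residual sds
#'   (default 3).
#' @return an [AssayFit-class] with parameters `tm`, `slope`, `baseFolded`,
#'   `baseUnfolded`.
#' @examples
#' m <- simulateMelt(tm = 72.2, slope = 2, baseFolded = -10,
#'                   baseUnfolded = -2, temps = seq(35, 95))
#' fitBoltzmannMelt(m)
#' @export
fitBoltzmannMelt <- function(curve, ampliThreshold = 3) {
  stopifnot(all(c("temperature", "signal") %in% names(curve)))
  tt <- curve$temperature
  ss <- curve$signal
  if (length(tt) < 6)
    stop("melt fit requires at least 6 points", call. = FALSE)
  if (is.unsorted(tt))
    stop("temperatures must be ascending", call. = FALSE)
  nTail <- max(2L, ceiling(0.1 * length(tt)))
  bF0 <- mean(ss[seq_len(nTail)])
  bU0 <- mean(ss[seq.int(length(ss) - nTail + 1L, length(ss))])
  half <- (bF0 + bU0) / 2
  cross <- which.min(abs(ss - half))
  tm0 <- tt[cross]
  slope0 <- max(diff(range(tt)) / 20, 1e-3)
  fit <- try(minpack.lm::nlsLM(
    signal ~ bF + (bU - bF) / (1 + exp((tm - temperature) / slope)),
    data = data.frame(temperature = tt, signal = ss),
    start = list(bF = bF0, bU = bU0, tm = tm0, slope = slope0),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    # degenerate input (e.g. no transition at all): report an
    # unidentifiable fit around the constant model instead of erroring
    res <- ss - mean(ss)
    return(new("AssayFit", method = "boltzmann_melt",
               parameters = c(tm = NA_real_, slope = NA_real_,
                              baseFolded = mean(ss),
                              baseUnfolded = mean(ss)),
               se = c(tm = NA_real_, slope = NA_real_,
                      baseFolded = NA_real_, baseUnfolded = NA_real_),
               fitted = rep(mean(ss), length(ss)), residuals = res,
               data = data.frame(temperature = tt, signal = ss),
               diagnostics = list(converged = FALSE,
                                  residualSd = stats::sd(ss),
                                  unidentifiable = TRUE,
                                  nPoints = length(tt))))
  }
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  resSd <- sqrt(sum(res^2) / max(1, length(res) - 4))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  unident <- abs(cf["bU"] - cf["bF"]) < ampliThreshold * resSd
  params <- c(tm = unname(cf["tm"]), slope = unname(cf["slope"]),
              baseFolded = unname(cf["bF"]), baseUnfolded = unname(cf["bU"]))
  seOut <- c(tm = unname(se["tm"]), slope = unname(se["slope"]),
             baseFolded = unname(se["bF"]), baseUnfolded = unname(se["bU"]))
  new("AssayFit", method = "boltzmann_melt", parameters = params,
      se = seOut, fitted = stats::fitted(fit), residuals = res,
      data = data.frame(temperature = tt, signal = ss),
      diagnostics = list(converged = TRUE, residualSd = resSd,
                         unidentifiable = unname(unident),
                         nPoints = length(tt)))
}

#' Melt hysteresis between heating and cooling traces
#'
#' Fits both traces with the same Boltzmann model and reports
#' `tm(heat) - tm(cool)`.
#'
#' @param heat,cool melt `data.frame`s as for [fitBoltzmannMelt()].
#' @return list with `heat`, `cool` (AssayFits) and `hysteresis` (degrees
#'   C).
#' @export
meltHysteresis <- function(heat, cool) {
  fh <- fitBoltzmannMelt(heat)
  fc <- fitBoltzmannMelt(cool)
  list(heat = fh, cool = fc,
       hysteresis = unname(fh@parameters["tm"] - fc@parameters["tm"]))
}

#' Stoichiometry of inhibition from a residual-activity assay
#'
#' Ordinary least squares of residual activity against serpin:protease
#' ratio, restricted to the linear regime: ratios whose (replicate-mean)
#' residual activity exceeds `activityFloor` (default 0.1), which excludes
#' the post-intercept zero floor. For unreplicated data this reduces to a
#' per-point cut. The SI is the x-intercept `-intercept/slope`; its standard
#' error follows by error propagation from the coefficient covariance. A
#' non-negative slope (no inhibition) is an error. SI is invariant to
#' rescaling all activities by a positive constant.
#'
#' @param assay `data.frame` with columns `ratio` and `residualActivity`
#'   (replicate rows share a ratio).
#' @param activityFloor regression window floor (default 0.1).
#' @return an [AssayFit-class] with parameters `si`, `slope`, `intercept`.
#' @examples
#' a <- simulateInhibitionAssay(si = 1.64)
#' fitSI(a)
#' @export
fitSI <- function(assay, activityFloor = 0.1) {
  stopifnot(all(c("ratio", "residualActivity") %in% names(assay)))
  ratioMean <- tapply(assay$residualActivity, assay$ratio, mean)
  okRatio <- as.numeric(names(ratioMean))[ratioMean > activityFloor]
  use <- assay$ratio %in% okRatio
  if (sum(use) < 3)
    stop("SI fit requires at least 3 points with residual activity > ",
         activityFloor, call. = FALSE)
  d <- assay[use, , drop = FALSE]
  fit <- stats::lm(residualActivity ~ ratio, data = d)
  cf <- stats::coef(fit)
  if (!is.finite(cf["ratio"]) || cf["ratio"] >= 0)
    stop("no inhibition detected (slope >= 0)", call. = FALSE)
  si <- unname(-cf["(Intercept)"] / cf["ratio"])
  # suppressed: summary.lm warns on the (legitimate) noiseless perfect fit
  vc <- suppressWarnings(stats::vcov(fit))
  b0 <- cf["(Intercept)"]; b1 <- cf["ratio"]
  # delta method for -b0/b1
  g <- c(-1 / b1, b0 / b1^2)
  siSe <- sqrt(as.numeric(t(g) %*% vc %*% g))
  res <- stats::residuals(fit)
  new("AssayFit", method = "si_linear",
      parameters = c(si = si, slope = unname(b1), intercept = unname(b0)),
      se = c(si = siSe, slope = sqrt(vc[2, 2]), intercept = sqrt(vc[1, 1])),
      fitted = stats::fitted(fit), residuals = res,
      data = d,
      diagnostics = list(converged = TRUE,
                         residualSd = sqrt(sum(res^2) / max(1, nrow(d) - 2)),
                         nPointsUsed = nrow(d),
                         nPointsExcluded = sum(!use),
                         activityFloor = activityFloor,
                         unidentifiable = FALSE))
}
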