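#' @rdname HillParams
#' @param a,b,c Hill parameters, see [HillParams-class].
#' @export
HillParams <- function(a, b, c)
  new("HillParams", a = unname(a), b = unname(b), c = unname(c))

setMethod("show", "HillParams", function(object) {
  cat(sprintf("HillParams: a = %.4g, b = %.4g, c = %.4g (plateau %.3g)\n",
              object@a, object@b, object@c, 1 - object@a))
})

#' Evaluate the Hill parent-fraction model
#'
#' `PF(t) = 1 - a * t^b / (t^b + c)`; `PF(0) = 1`, asymptote `1 - a`.
#'
#' @param hill a [HillParams-class].
#' @param t times in minutes, `t >= 0`.
#' @return parent fraction per time point.
#' @export
parentFraction <- function(hill, t) {
  stopifnot(is(hill, "HillParams"), all(t >= 0))
  tb <- t^hill@b
  pf <- 1 - hill@a * tb / (tb + hill@c)
  pf[t == 0] <- 1
  pf
}

#' Fit the Hill parent-fraction model to metabolite measurements
#'
#' Bounded least squares of `PF(t) = 1 - a*t^b/(t^b + c)` on measured intact
#' fractions; the anchor `PF(0) = 1` is structural (built into the model),
#' not a data point. Multi-start over the steepness parameter guards against
#' local minima.
#'
#' @param time sample times (minutes, > 0).
#' @param fraction measured parent fractions in `[0, 1]`.
#' @return a [HillParams-class].
#' @examples
#' h <- HillParams(0.95, 2, 25)
#' t <- c(10, 20, 30, 45, 60)
#' fitParentFraction(t, parentFraction(h, t))
#' @export
fitParentFraction <- function(time, fraction) {
  stopifnot(length(time) == length(fraction), length(time) >= 3)
  if (any(fraction < 0 | fraction > 1))
    stop("parent fractions must lie in [0, 1]")
  resid <- function(p) 1 - p[1] * time^p[2] / (time^p[2] + p[3]) - fraction
  lower <- c(0, 1e-6, 1e-6); upper <- c(1, 10, 1e8)
  a0 <- min(max(1 - min(fraction), 1e-3), 1)
  tMid <- stats::median(time)
  fMid <- min(max(fraction[which.min(abs(time - tMid))], 1e-6), 1 - 1e-6)
  best <- NULL
  for (b0 in c(0.5, 1, 1.5, 2, 3, 5)) {
    ## start c so the curve passes through the central sample
    c0 <- tMid^b0 * max(a0 / max(1 - fMid, 1e-6) - 1, 1e-3)
    start <- c(a = a0, b = b0, c = max(c0, 1e-3))
    fit <- try(minpack.lm::nls.lm(start, lower, upper, resid,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 400, ftol = 1e-15,
                                    ptol = 1e-15)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("parent-fraction fit did not converge")
  p <- best$par
  HillParams(p[1], max(p[2], 1e-6), max(p[3], 1e-6))
}

#' Calibrate a continuous blood curve against manual samples
#'
#' The online detector curve is cross-calibrated by a single multiplicative
#' factor `f` minimising `sum((f * C_cont(t_j) - C_manual(t_j))^2)` over the
#' manual sample times, i.e. the closed form `f = sum(x*y) / sum(x^2)`.
#'
#' @param continuous data.frame with `time` (min) and `wholeBlood` (kBq/mL).
#' @param samples a [BloodSamples-class]; samples outside the continuous
#'   curve's span are ignored (at least one must overlap).
#' @return list with `factor`, the calibrated `curve` (data.frame) and the
#'   per-sample `residuals`.
#' @export
calibrateContinuousBlood <- function(continuous, samples) {
  stopifnot(is(samples, "BloodSamples"))
  span <- range(continuous$time)
  inside <- samples@time >= span[1] & samples@time <= span[2]
  if (!any(inside)) stop("no manual sample overlaps the continuous curve")
  x <- stats::approx(continuous$time, continuous$wholeBlood,
                     xout = samples@time[inside])$y
  y <- samples@wholeBlood[inside]
  f <- sum(x * y) / sum(x * x)
  if (!is.finite(f) || f <= 0) stop("calibration factor must be positive")
  list(factor = f,
       curve = data.frame(time = continuous$time,
                          wholeBlood = f * continuous$wholeBlood),
       residuals = f * x - y)
}

## piecewise-linear interpolation: 0 at t <= 0, implicit (0, 0) knot when the
## first sample is later than injection, constant after the last sample
linInterp0 <- function(xt, xv, t) {
  if (xt[1] > 0) { xt <- c(0, xt); xv <- c(0, xv) }
  out <- stats::approx(xt, xv, xout = pmax(t, xt[1]), rule = 2)$y
  out[t <= 0] <- 0
  out
}

#' Build a metabolite-corrected arterial plasma input function
#'
#' Composes the calibrated whole-blood curve with the plasma-to-whole-blood
#' ratio model and the Hill parent fraction:
#' `C_p(t) = C_wb(t) * R(t) * PF(t)`. The ratio model is piecewise linear
#' through the manual samples with constant extrapolation on both sides.
#'
#' @param wholeBlood data.frame with `time` (min) and `wholeBlood` (kBq/mL),
#'   already calibrated.
#' @param samples a [BloodSamples-class] providing the ratio knots.
#' @param hill a [HillParams-class] from [fitParentFraction()].
#' @return an [InputFunction-class] on the whole-blood grid.
#' @export
buildInputFunction <- function(wholeBlood, samples, hill) {
  stopifnot(is(samples, "BloodSamples"), is(hill, "HillParams"))
  t <- wholeBlood$time
  wb <- wholeBlood$wholeBlood
  ratio <- stats::approx(samples@time, samples@plasmaRatio, xout = t,
                         rule = 2)$y
  cp <- wb * ratio * parentFraction(hill, pmax(t, 0))
  cp[t <= 0] <- 0
  wb2 <- wb
  wb2[t <= 0] <- 0
  new("InputFunction", time = t, wholeBlood = wb2, plasma = cp, hill = hill,
      ratioTime = samples@time, ratioValue = samples@plasmaRatio)
}

#' Plasma-to-whole-blood ratio model of an input function
#'
#' @param input an [InputFunction-class].
#' @param t times in minutes.
#' @export
plasmaRatioAt <- function(input, t) {
  stats::approx(input@ratioTime, input@ratioValue, xout = t, rule = 2)$y
}

#' Interpolate an input function
#'
#' Piecewise-linear interpolation between grid samples; 0 at `t <= 0` (with
#' an implicit origin knot when the grid starts after injection) and constant
#' extrapolation after the last sample.
#'
#' @param input an [InputFunction-class].
#' @param t times in minutes, `t >= 0`.
#' @return list with `plasma` and `wholeBlood` at `t`.
#' @export
interpolateInput <- function(input, t) {
  stopifnot(all(t >= 0))
  list(plasma = linInterp0(input@time, input@plasma, t),
       wholeBlood = linInterp0(input@time, input@wholeBlood, t))
}

#' @rdname InputFunction
#' @export
setMethod("plasmaActivity", "InputFunction", function(object) object@plasma)

#' @rdname InputFunction
#' @export
setMethod("wholeBloodActivity", "InputFunction",
          function(object) object@wholeBlood)

#' @rdname InputFunction
#' @export
setMethod("sampleTimes", "InputFunction", function(object) object@time)

setMethod("show", "InputFunction", function(object) {
  cat(sprintf(
    "InputFunction: %d samples over %.1f-%.1f min, peak C_p %.3g kBq/mL\n",
    length(object@time), min(object@time), max(object@time),
    max(object@plasma)))
})
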