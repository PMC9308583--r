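## Carbon-11 decay constant, 1/min (half-life 20.34 min)
LAMBDA_C11 <- log(2) / 20.34

#' Frame weights for weighted least squares
#'
#' Count-statistics weighting for decay-corrected frames:
#' `w_i = dt_i * exp(-lambda * t_mid_i)` with the carbon-11 decay constant,
#' normalized to mean 1 so that weighted residual sums are on the scale of
#' the data. `"uniform"` returns all-ones weights.
#'
#' @param schedule a [FrameSchedule-class].
#' @param mode `"decay"` (default) or `"uniform"`.
#' @return numeric weights, one per frame, mean 1.
#' @export
frameWeights <- function(schedule, mode = c("decay", "uniform")) {
  mode <- match.arg(mode)
  if (mode == "uniform") return(rep(1, nFrames(schedule)))
  w <- frameDuration(schedule) * exp(-LAMBDA_C11 * frameMidpoints(schedule))
  w / mean(w)
}

## Precompute the evaluation grid shared by all forward evaluations of one
## (input, schedule) pair: union of input knots and frame boundaries, input
## curves interpolated onto it, and the indices of the frame boundaries.
makeForwardContext <- function(input, schedule) {
  tend <- scanDuration(schedule)
  if (max(input@time) < tend - 1e-9)
    stop("input function does not span the frame schedule")
  fb <- c(frameStart(schedule), tend)
  tt <- sort(unique(c(0, input@time[input@time > 0 & input@time <= tend], fb)))
  cp <- linInterp0(input@time, input@plasma, tt)
  cwb <- linInterp0(input@time, input@wholeBlood, tt)
  idx <- match(fb, tt)
  list(tt = tt, cp = cp, cwb = cwb, idx = idx,
       dur = frameDuration(schedule),
       wbInt = diff(plExpConvCpp(tt, cwb, 0)$y[idx]))
}

## frame integrals of the tissue curve C_t (excluding blood volume)
tissueFrameIntegrals <- function(ctx, model, K1, k2, k3, k4) {
  if (model == "1T2K") {
    return(K1 * diff(plExpConvCpp(ctx$tt, ctx$cp, k2)$Y[ctx$idx]))
  }
  if (model == "2T3K") {
    a <- k2 + k3
    c0 <- plExpConvCpp(ctx$tt, ctx$cp, 0)
    if (a < 1e-12) return(K1 * diff(c0$Y[ctx$idx]))
    ki <- K1 * k3 / a
    ca <- plExpConvCpp(ctx$tt, ctx$cp, a)
    return(ki * diff(c0$Y[ctx$idx]) + (K1 * k2 / a) * diff(ca$Y[ctx$idx]))
  }
  ## 2T4K: eigenvalues of the two-tissue rate matrix
  s <- k2 + k3 + k4
  disc <- s * s - 4 * k2 * k4
  root <- sqrt(max(disc, 0))
  th1 <- (s + root) / 2
  th2 <- (s - root) / 2
  ## enforce a minimum root separation; the confluent (repeated-root) limit
  ## is approached smoothly so a 1e-7 relative split is exact to ~1e-9
  minSep <- 1e-7 * max(th1, 1e-3)
  if (th1 - th2 < minSep) {
    m <- (th1 + th2) / 2
    th1 <- m + minSep / 2
    th2 <- max(m - minSep / 2, 0)
  }
  a1 <- K1 * (th1 - k3 - k4) / (th1 - th2)
  a2 <- K1 * (k3 + k4 - th2) / (th1 - th2)
  a1 * diff(plExpConvCpp(ctx$tt, ctx$cp, th1)$Y[ctx$idx]) +
    a2 * diff(plExpConvCpp(ctx$tt, ctx$cp, th2)$Y[ctx$idx])
}

forwardFrameAverages <- function(ctx, model, params) {
  K1 <- params[["K1"]]; k2 <- params[["k2"]]
  k3 <- if (model == "1T2K") 0 else params[["k3"]]
  k4 <- if (model == "2T4K") params[["k4"]] else 0
  vB <- params[["vB"]]
  ci <- tissueFrameIntegrals(ctx, model, K1, k2, k3, k4)
  ((1 - vB) * ci + vB * ctx$wbInt) / ctx$dur
}

#' Simulate a tissue time-activity curve from a compartment model
#'
#' Solves the 1T2K, 2T3K or 2T4K model driven by the piecewise-linear
#' plasma input analytically (closed-form exponential convolution per input
#' segment) and returns frame-duration averages of the measured signal
#' `C_pet = (1 - vB) * C_t + vB * C_wb`, not midpoint samples.
#'
#' @param model `"1T2K"`, `"2T3K"` or `"2T4K"`.
#' @param params named numeric with `K1` (mL/cm^3/min), `k2`, `k3`, `k4`
#'   (1/min) and `vB` (unitless); `k3`/`k4` may be omitted where the
#'   topology fixes them to 0.
#' @param input an [InputFunction-class] spanning the schedule.
#' @param schedule a [FrameSchedule-class].
#' @param region,tissueClass labels for the returned [Tac-class].
#' @return a [Tac-class] of frame-averaged activity.
#' @export
modelTissueCurve <- function(model, params, input, schedule,
                             region = "simulated", tissueClass = "WM") {
  model <- match.arg(model, MODEL_NAMES)
  params <- fullParams(params)
  checkParams(model, params)
  ctx <- makeForwardContext(input, schedule)
  Tac(schedule, forwardFrameAverages(ctx, model, params),
      region = region, tissueClass = tissueClass, quiet = TRUE)
}

fullParams <- function(params) {
  full <- c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, vB = 0)
  full[names(params)] <- params
  full
}

checkParams <- function(model, params) {
  if (any(params < 0)) stop("rate constants and vB must be non-negative")
  if (params[["vB"]] >= 1) stop("vB must be below 1")
  if (model == "1T2K" && (params[["k3"]] != 0 || params[["k4"]] != 0))
    stop("1T2K requires k3 = k4 = 0")
  if (model == "2T3K" && params[["k4"]] != 0)
    stop("2T3K requires k4 = 0")
  invisible(TRUE)
}

#' Macroparameters of a compartment model
#'
#' Standard definitions: net influx rate `Ki = K1*k3/(k2+k3)` (irreversible
#' trapping; also reported for 2T4K), total volume of distribution
#' `VT = K1/k2` (1T2K) or `(K1/k2)*(1 + k3/k4)` (2T4K), and binding
#' potential `BPnd = k3/k4` (2T4K). Undefined entries are absent.
#'
#' @param model `"1T2K"`, `"2T3K"` or `"2T4K"`.
#' @param params named numeric kinetic parameters.
#' @return named numeric of the macroparameters defined for the model.
#' @export
macroParameters <- function(model, params) {
  model <- match.arg(model, MODEL_NAMES)
  p <- fullParams(params)
  K1 <- p[["K1"]]; k2 <- p[["k2"]]; k3 <- p[["k3"]]; k4 <- p[["k4"]]
  out <- c()
  if (model == "1T2K") {
    if (k2 <= 0) stop("VT requires k2 > 0")
    out <- c(VT = K1 / k2)
  } else if (model == "2T3K") {
    if (k2 + k3 <= 0) stop("Ki requires k2 + k3 > 0")
    out <- c(Ki = K1 * k3 / (k2 + k3))
  } else {
    if (k2 + k3 <= 0) stop("Ki requires k2 + k3 > 0")
    out <- c(Ki = K1 * k3 / (k2 + k3))
    if (k4 > 0 && k2 > 0)
      out <- c(out, VT = (K1 / k2) * (1 + k3 / k4), BPnd = k3 / k4)
  }
  out
}

## gradient of each macroparameter w.r.t. (K1, k2, k3, k4), for the delta
## method
macroGradients <- function(model, p) {
  K1 <- p[["K1"]]; k2 <- p[["k2"]]; k3 <- p[["k3"]]; k4 <- p[["k4"]]
  g <- list()
  if (model %in% c("2T3K", "2T4K") && k2 + k3 > 0) {
    a <- k2 + k3
    g$Ki <- c(K1 = k3 / a, k2 = -K1 * k3 / a^2, k3 = K1 * k2 / a^2, k4 = 0)
  }
  if (model == "1T2K" && k2 > 0)
    g$VT <- c(K1 = 1 / k2, k2 = -K1 / k2^2, k3 = 0, k4 = 0)
  if (model == "2T4K" && k4 > 0 && k2 > 0) {
    g$VT <- c(K1 = (1 + k3 / k4) / k2, k2 = -K1 * (1 + k3 / k4) / k2^2,
              k3 = K1 / (k2 * k4), k4 = -K1 * k3 / (k2 * k4^2))
    g$BPnd <- c(K1 = 0, k2 = 0, k3 = 1 / k4, k4 = -k3 / k4^2)
  }
  g
}

#' Akaike information criterion for a least-squares fit
#'
#' Classical form `n * log(wrss / n) + 2 * m` with `n` frames, weighted
#' residual sum of squares `wrss` and `m` free parameters. Comparisons are
#' only meaningful between models fitted to the same TAC with identical
#' weights.
#'
#' @param n number of frames.
#' @param wrss weighted residual sum of squares (> 0).
#' @param m number of free parameters (`n > m`).
#' @param smallSample add the second-order small-sample correction
#'   `2m(m+1)/(n-m-1)` (AICc). With 26 frames and up to 5 free parameters
#'   the sample is firmly in AICc territory (`n/m < 40`), so model
#'   preference tables use the corrected value by default while the
#'   classical value is always reported alongside.
#' @return AIC value; `-Inf` with a warning when `wrss == 0`.
#' @export
aicScore <- function(n, wrss, m, smallSample = FALSE) {
  stopifnot(n > m)
  if (wrss <= 0) {
    warning("wrss is zero; returning -Inf")
    return(-Inf)
  }
  n * log(wrss / n) + 2 * m +
    if (smallSample) 2 * m * (m + 1) / (n - m - 1) else 0
}

## deterministic multi-start jitter, isolated from the caller's RNG
multiStartInits <- function(init, nStarts, sd = 0.3) {
  if (nStarts <= 1) return(list(init))
  saved <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(285714L)
  c(list(init), lapply(seq_len(nStarts - 1),
                       function(i) init * exp(stats::rnorm(length(init), 0, sd))))
}

#' Fit a compartment model to a time-activity curve
#'
#' Bounded weighted nonlinear least squares (Levenberg-Marquardt with box
#' bounds, multi-start) of the frame-averaged model prediction against the
#' measured TAC. Percent standard errors come from the scaled inverse
#' Gauss-Newton information matrix `solve(J' W J) * wrss / (n - m)`;
#' macroparameter errors use the first-order delta method.
#'
#' @param tac a [Tac-class].
#' @param input an [InputFunction-class].
#' @param model `"2T3K"` (default), `"1T2K"` or `"2T4K"`.
#' @param vB fix the fractional blood volume at this value (e.g. `0.02`,
#'   the literature mean for white matter), or `NULL` to fit it.
#' @param k1k2Ratio fix the `K1/k2` ratio at this value (the fit is then
#'   reparameterized with `K1` free and `k2 = K1 / ratio`), or `NULL`.
#' @param weights `"decay"` (frame-duration/decay weighting, default) or
#'   `"uniform"`; identical weights must be used for all models compared by
#'   AIC, which holds because weights depend only on the schedule.
#' @param init optional named initial values; defaults
#'   `K1 = 0.1, k2 = 0.1, k3 = 0.05, k4 = 0.01, vB = 0.05`.
#' @param rateBounds bounds for the rate constants (1/min).
#' @param vBBounds bounds for `vB`.
#' @param nStarts number of multi-start fits with jittered initial values;
#'   the lowest weighted residual sum of squares wins.
#' @return a [KineticFit-class].
#' @export
fitCompartmentModel <- function(tac, input, model = c("2T3K", "1T2K", "2T4K"),
                                vB = NULL, k1k2Ratio = NULL,
                                weights = c("decay", "uniform"), init = NULL,
                                rateBounds = c(1e-6, 2), vBBounds = c(0, 0.2),
                                nStarts = 5) {
  model <- match.arg(model)
  sched <- schedule(tac)
  obs <- activity(tac)
  n <- length(obs)
  w <- frameWeights(sched, match.arg(weights))
  sw <- sqrt(w)
  ctx <- makeForwardContext(input, sched)

  defaults <- c(K1 = 0.1, k2 = 0.1, k3 = 0.05, k4 = 0.01, vB = 0.05)
  if (!is.null(init)) defaults[names(init)] <- init
  rateNames <- switch(model, "1T2K" = c("K1", "k2"),
                      "2T3K" = c("K1", "k2", "k3"),
                      "2T4K" = c("K1", "k2", "k3", "k4"))
  freeNames <- rateNames
  if (!is.null(k1k2Ratio)) {
    stopifnot(k1k2Ratio > 0)
    freeNames <- setdiff(freeNames, "k2")
  }
  vBFixed <- !is.null(vB)
  if (!vBFixed) freeNames <- c(freeNames, "vB")
  m <- length(freeNames)
  if (n < m + 1) stop("too few frames for the number of free parameters")

  expand <- function(p) {
    full <- c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, vB = if (vBFixed) vB else 0)
    full[freeNames] <- p
    if (!is.null(k1k2Ratio)) full[["k2"]] <- full[["K1"]] / k1k2Ratio
    full
  }
  residFn <- function(p) sw * (forwardFrameAverages(ctx, model, expand(p)) - obs)

  lower <- ifelse(freeNames == "vB", vBBounds[1], rateBounds[1])
  upper <- ifelse(freeNames == "vB", vBBounds[2], rateBounds[2])
  init0 <- pmin(pmax(defaults[freeNames], lower), upper)

  best <- NULL
  for (start in multiStartInits(init0, nStarts)) {
    start <- pmin(pmax(start, lower), upper)
    fit <- try(minpack.lm::nls.lm(start, lower, upper, residFn,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 300, ptol = 1e-12,
                                    ftol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("compartment fit did not converge for any start")

  est <- expand(best$par)
  wrss <- best$deviance
  pred <- forwardFrameAverages(ctx, model, est)
  r2 <- 1 - sum((obs - pred)^2) / max(sum((obs - mean(obs))^2), .Machine$double.eps)
  aic <- if (wrss > 0) aicScore(n, wrss, m) else -Inf
  aicc <- if (wrss > 0) aicScore(n, wrss, m, smallSample = TRUE) else -Inf

  ## Jacobian of weighted residuals w.r.t. the free parameters
  J <- jacobianFD(residFn, best$par)
  sigma2 <- wrss / max(n - m, 1)
  cov <- tryCatch(solve(crossprod(J)) * sigma2,
                  error = function(e) matrix(Inf, m, m))
  se <- sqrt(pmax(diag(cov), 0))
  sePar <- 100 * se / pmax(abs(best$par), .Machine$double.eps)
  sePar[!is.finite(se)] <- Inf
  names(sePar) <- freeNames

  ## delta-method %SE for macroparameters
  macro <- macroParameters(model, est)
  grads <- macroGradients(model, est)
  seMacro <- numeric(0)
  for (nm in names(macro)) {
    gFull <- grads[[nm]]
    gFree <- vapply(freeNames, function(fn) {
      g <- if (fn %in% names(gFull)) gFull[[fn]] else 0
      if (fn == "K1" && !is.null(k1k2Ratio))
        g <- g + gFull[["k2"]] / k1k2Ratio  # chain rule through k2 = K1/ratio
      g
    }, numeric(1))
    v <- if (all(is.finite(cov))) drop(t(gFree) %*% cov %*% gFree) else Inf
    seMacro[nm] <- if (is.finite(v))
      100 * sqrt(max(v, 0)) / max(abs(macro[[nm]]), .Machine$double.eps)
    else Inf
  }
  names(seMacro) <- names(macro)

  fixedMask <- c(K1 = FALSE, k2 = !is.null(k1k2Ratio),
                 k3 = model == "1T2K", k4 = model != "2T4K", vB = vBFixed)
  new("KineticFit", model = model, estimates = est, fixed = fixedMask,
      macro = macro, sePercent = c(sePar, seMacro), wrss = wrss, r2 = r2,
      aic = aic, aicc = aicc, nFrames = n, converged = best$info %in% 1:4,
      k1k2Ratio = if (is.null(k1k2Ratio)) NA_real_ else k1k2Ratio)
}

## central finite-difference Jacobian
jacobianFD <- function(f, p, relStep = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- relStep * max(abs(p[j]), 1e-4)
    up <- p; up[j] <- p[j] + h
    dn <- p; dn[j] <- p[j] - h
    J[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

#' @rdname KineticFit
#' @export
setMethod("coef", "KineticFit", function(object) object@estimates)

#' @rdname KineticFit
#' @export
setMethod("macroParams", "KineticFit", function(object) object@macro)

#' @rdname KineticFit
#' @param which name of a parameter or macroparameter.
#' @export
setMethod("percentSE", "KineticFit", function(object, which) {
  if (missing(which)) return(object@sePercent)
  if (!which %in% names(object@sePercent))
    stop("no standard error for '", which,
         "' (fixed parameters carry no SE)")
  object@sePercent[[which]]
})

#' @rdname KineticFit
#' @param corrected return the small-sample corrected value (AICc).
#' @export
setMethod("aicValue", "KineticFit", function(object, corrected = FALSE) {
  if (corrected) object@aicc else object@aic
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit %s: wrss %.4g, AIC %.2f, R2 %.4f%s\n",
              object@model, object@wrss, object@aic, object@r2,
              if (object@converged) "" else " (not converged)"))
  fmtSe <- function(se) ifelse(is.finite(se) & se < 1e4,
                               sprintf("%.1f%%", se), "se n/a")
  free <- names(object@fixed)[!object@fixed]
  est <- object@estimates[free]
  cat("  ", paste(sprintf("%s = %.4g (%s)", free, est,
                          fmtSe(object@sePercent[free])),
                  collapse = ", "), "\n")
  if (length(object@macro))
    cat("  ", paste(sprintf("%s = %.4g (%s)", names(object@macro),
                            object@macro,
                            fmtSe(object@sePercent[names(object@macro)])),
                    collapse = ", "), "\n")
})
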