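#' Running (cumulative) integral of a sampled curve
#'
#' Trapezoidal cumulative integral over a monotone grid, with a leading
#' triangle from `(0, 0)` to the first sample when the grid starts after 0.
#' This is the shared integration kernel of all linearized analyses.
#'
#' @param time monotone increasing times (minutes).
#' @param values curve values at `time`.
#' @return numeric running integral at each time point.
#' @examples
#' cumulativeIntegral(c(5, 10), c(1, 1))  # 5, 10
#' @export
cumulativeIntegral <- function(time, values) {
  if (is.unsorted(time, strictly = TRUE)) stop("time grid must be sorted")
  plExpConvCpp(time, values, 0)$y
}

## input-function quantities evaluated at frame midpoints: values and
## running single/double integrals of C_p plus C_wb values and integral
inputAtMidpoints <- function(input, schedule) {
  mids <- frameMidpoints(schedule)
  tt <- sort(unique(c(0, input@time[input@time > 0 & input@time <= max(mids)],
                      mids)))
  cp <- linInterp0(input@time, input@plasma, tt)
  cwb <- linInterp0(input@time, input@wholeBlood, tt)
  convP <- plExpConvCpp(tt, cp, 0)
  convW <- plExpConvCpp(tt, cwb, 0)
  i <- match(mids, tt)
  list(mids = mids, cp = cp[i], cwb = cwb[i], icp = convP$y[i],
       iicp = convP$Y[i], icwb = convW$y[i])
}

## exact frame averages of C_wb, int C_wb, int C_p and int int C_p over the
## schedule, from the piecewise-linear input representation
inputFrameAverages <- function(input, schedule) {
  tend <- scanDuration(schedule)
  if (max(input@time) < tend - 1e-9)
    stop("input function does not span the frame schedule")
  fb <- c(frameStart(schedule), tend)
  tt <- sort(unique(c(0, input@time[input@time > 0 & input@time <= tend], fb)))
  cp <- linInterp0(input@time, input@plasma, tt)
  cwb <- linInterp0(input@time, input@wholeBlood, tt)
  convP <- plExpConvCpp(tt, cp, 0)
  convW <- plExpConvCpp(tt, cwb, 0)
  i <- match(fb, tt)
  dur <- frameDuration(schedule)
  list(cwb = diff(convW$y[i]) / dur, icwb = diff(convW$Y[i]) / dur,
       icp = diff(convP$Y[i]) / dur, iicp = diff(convP$Y2[i]) / dur)
}

## Running integral of a frame-averaged TAC. Whole frames integrate exactly
## (average x duration); within-frame positions use a local linear
## reconstruction whose slope comes from neighbouring frame averages, which
## removes the leading-order bias of treating averages as midpoint samples.
## Returns the integral at frame midpoints and its frame averages.
tacRunningIntegral <- function(act, schedule) {
  dur <- frameDuration(schedule)
  mids <- frameMidpoints(schedule)
  n <- length(act)
  m <- numeric(n)
  if (n >= 2) {
    m[1] <- (act[2] - act[1]) / (mids[2] - mids[1])
    m[n] <- (act[n] - act[n - 1]) / (mids[n] - mids[n - 1])
    if (n > 2)
      m[2:(n - 1)] <- (act[3:n] - act[1:(n - 2)]) / (mids[3:n] - mids[1:(n - 2)])
  }
  atBound <- cumsum(c(0, act * dur))[seq_len(n)]
  list(atMid = atBound + act * dur / 2 - m * dur^2 / 8,
       frameAvg = atBound + act * dur / 2 - m * dur^2 / 12)
}

#' Patlak graphical analysis
#'
#' Ordinary least squares of `C_pet(T)/C_p(T)` on `int_0^T C_p / C_p(T)`
#' over frames with midpoint at or after `tstar`; for an irreversibly
#' trapping tracer the slope estimates the net influx rate Ki.
#'
#' @param tac a [Tac-class].
#' @param input an [InputFunction-class].
#' @param tstar start of the linear phase, minutes (default 20).
#' @return a [GraphicalFit-class] with `estimate` = Ki; fits with fewer than
#'   3 usable frames are flagged `lowConfidence`.
#' @export
patlakFit <- function(tac, input, tstar = 20) {
  iam <- inputAtMidpoints(input, schedule(tac))
  sel <- iam$mids >= tstar
  if (sum(sel) < 2) stop("fewer than 2 frames with midpoint >= tstar")
  if (any(iam$cp[sel] <= 0)) stop("zero plasma activity in Patlak window")
  x <- iam$icp[sel] / iam$cp[sel]
  y <- activity(tac)[sel] / iam$cp[sel]
  fit <- stats::lm(y ~ x)
  new("GraphicalFit", method = "patlak",
      estimate = unname(stats::coef(fit)[2]), estimateName = "Ki",
      intercept = unname(stats::coef(fit)[1]), coefficients = numeric(0),
      tstar = tstar, nPoints = sum(sel),
      r2 = summary(fit)$r.squared, lowConfidence = sum(sel) <= 2)
}

#' Logan graphical analysis
#'
#' Ordinary least squares of `int_0^T C_pet / C_pet(T)` on
#' `int_0^T C_p / C_pet(T)` over frames with midpoint at or after `tstar`;
#' for a reversible tracer the slope estimates the total volume of
#' distribution VT. With irreversible trapping (k4 = 0) no finite VT exists
#' and the slope keeps growing with `tstar`.
#'
#' @inheritParams patlakFit
#' @return a [GraphicalFit-class] with `estimate` = VT.
#' @export
loganFit <- function(tac, input, tstar = 20) {
  sched <- schedule(tac)
  iam <- inputAtMidpoints(input, sched)
  act <- activity(tac)
  sel <- iam$mids >= tstar
  if (sum(sel) < 2) stop("fewer than 2 frames with midpoint >= tstar")
  if (any(act[sel] <= 0)) stop("non-positive tissue activity in Logan window")
  iact <- tacRunningIntegral(act, sched)$atMid
  x <- iam$icp[sel] / act[sel]
  y <- iact[sel] / act[sel]
  fit <- stats::lm(y ~ x)
  new("GraphicalFit", method = "logan",
      estimate = unname(stats::coef(fit)[2]), estimateName = "VT",
      intercept = unname(stats::coef(fit)[1]), coefficients = numeric(0),
      tstar = tstar, nPoints = sum(sel),
      r2 = summary(fit)$r.squared, lowConfidence = sum(sel) <= 2)
}

## MLAIR operates on the frame-averaged form of the operational equation:
## every regressor is the exact frame average of the corresponding
## continuous quantity, and the tissue integral uses the frame-aware
## running integral, so the noiseless estimators are exact to the
## within-frame reconstruction error only.
mlairDesign <- function(tac, input, includeWbIntegral) {
  sched <- schedule(tac)
  ifa <- inputFrameAverages(input, sched)
  act <- activity(tac)
  iact <- tacRunningIntegral(act, sched)$frameAvg
  list(ifa = ifa, act = act, iact = iact,
       cols = if (includeWbIntegral) c("wb", "iwb", "icp", "iicp")
              else c("wb", "icp", "iicp"))
}

mlairSolve <- function(X, y) {
  if (nrow(X) < ncol(X)) stop("fewer frames than MLAIR regressors")
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) stop("rank-deficient MLAIR design matrix")
  rss <- sum(fit$residuals^2)
  r2 <- 1 - rss / max(sum(y^2), .Machine$double.eps)  # uncentered, no intercept
  list(coef = fit$coefficients, r2 = r2)
}

#' MLAIR1: multiple linear analysis for irreversible tracers
#'
#' Double integration of the irreversible two-tissue model with blood volume
#' gives the operational equation
#' `C_pet(T) = P1*C_wb(T) + P2*int C_wb + P3*int C_p + P4*int int C_p +
#' P5*int C_pet`, fitted by multiple linear regression over all frames (no
#' `tstar`). The net influx rate is read as `Ki = -P4/P5`; this apparent Ki
#' absorbs the `(1 - vB)` factor, and `P1` estimates `vB`.
#'
#' @inheritParams patlakFit
#' @param includeWbIntegral include the `int C_wb` regressor. The default
#'   is the 4-term variant (omitting it): the `int C_wb` column is nearly
#'   collinear with the other running integrals late in the scan, which
#'   conditions the design matrix poorly and inflates the Ki variance under
#'   noise, while its physical contribution (`k2+k3` times the blood-volume
#'   fraction) is small for cerebral blood volumes.
#' @return a [GraphicalFit-class] with `estimate` = Ki and the regression
#'   coefficients.
#' @export
mlair1Fit <- function(tac, input, includeWbIntegral = FALSE) {
  d <- mlairDesign(tac, input, includeWbIntegral)
  X <- cbind(wb = d$ifa$cwb, iwb = d$ifa$icwb, icp = d$ifa$icp,
             iicp = d$ifa$iicp, ipet = d$iact)[, c(d$cols, "ipet")]
  s <- mlairSolve(X, d$act)
  ki <- -s$coef[["iicp"]] / s$coef[["ipet"]]
  if (!is.finite(ki)) stop("degenerate MLAIR1 fit")
  new("GraphicalFit", method = "mlair1", estimate = ki, estimateName = "Ki",
      intercept = NA_real_, coefficients = s$coef, tstar = NA_real_,
      nPoints = nrow(X), r2 = s$r2, lowConfidence = FALSE)
}

#' MLAIR2: direct multiple-linear-regression estimate of Ki
#'
#' Rearrangement of the MLAIR operational equation with `int C_pet` as the
#' response: `int C_pet = b1*C_wb(T) + b2*int C_wb + b3*int C_p +
#' b4*int int C_p + b5*C_pet(T)`. Ki is the coefficient `b4` itself (no
#' coefficient ratio), which makes the estimate robust to noise and suited
#' to voxel-level parametric maps.
#'
#' @inheritParams mlair1Fit
#' @return a [GraphicalFit-class] with `estimate` = Ki.
#' @export
mlair2Fit <- function(tac, input, includeWbIntegral = FALSE) {
  d <- mlairDesign(tac, input, includeWbIntegral)
  X <- cbind(wb = d$ifa$cwb, iwb = d$ifa$icwb, icp = d$ifa$icp,
             iicp = d$ifa$iicp, pet = d$act)[, c(d$cols, "pet")]
  s <- mlairSolve(X, d$iact)
  new("GraphicalFit", method = "mlair2", estimate = s$coef[["iicp"]],
      estimateName = "Ki", intercept = NA_real_, coefficients = s$coef,
      tstar = NA_real_, nPoints = nrow(X), r2 = s$r2, lowConfidence = FALSE)
}

setMethod("show", "GraphicalFit", function(object) {
  cat(sprintf("GraphicalFit %s: %s = %.4g (n = %d, R2 = %.4f)%s\n",
              object@method, object@estimateName, object@estimate,
              object@nPoints, object@r2,
              if (object@lowConfidence) " [low confidence]" else ""))
})

#' Standardized uptake value over a time window
#'
#' Duration-weighted mean activity concentration over the interval divided
#' by injected dose per body weight:
#' `SUV = mean(C) / (dose / weight)` in g/cm^3 (kBq/mL over kBq/g).
#'
#' @param tac a [Tac-class].
#' @param interval numeric `c(start, end)` in minutes, e.g. `c(40, 50)`.
#' @param dose net injected dose in MBq.
#' @param weight body weight in kg.
#' @return SUV (g/cm^3) with the interval attached as attribute
#'   `"interval"`. Frames partially covering the interval contribute their
#'   overlapping part, with a warning.
#' @examples
#' sched <- parseFrameSchedule("2x600")
#' suvValue(Tac(sched, c(3, 3)), c(0, 20), dose = 210, weight = 70)  # 1
#' @export
suvValue <- function(tac, interval, dose, weight) {
  stopifnot(length(interval) == 2, interval[1] < interval[2],
            dose > 0, weight > 0)
  sched <- schedule(tac)
  s <- frameStart(sched)
  e <- s + frameDuration(sched)
  if (interval[1] < s[1] - 1e-9 || interval[2] > max(e) + 1e-9)
    stop("interval not covered by the scan")
  overlap <- pmax(pmin(e, interval[2]) - pmax(s, interval[1]), 0)
  used <- overlap > 1e-12
  if (any(abs(overlap[used] - frameDuration(sched)[used]) > 1e-9))
    warning("interval not aligned to frame boundaries; integrating partial frames")
  conc <- sum(activity(tac)[used] * overlap[used]) / sum(overlap[used])
  suv <- conc * weight / dose  # (kBq/mL) / (1000*dose kBq / 1000*weight g)
  attr(suv, "interval") <- interval
  suv
}

#' Voxel-wise parametric map
#'
#' Applies MLAIR2 or SUV independently to every voxel TAC of a volume
#' sharing one frame schedule. Invalid voxels (any non-finite frame) yield
#' `NaN`.
#'
#' @param voxelActivity numeric matrix, voxels in rows, frames in columns.
#' @param schedule the shared [FrameSchedule-class].
#' @param input an [InputFunction-class] (MLAIR2 only).
#' @param method `"mlair2"` or `"suv"`.
#' @param interval,dose,weight SUV arguments, see [suvValue()].
#' @param includeWbIntegral see [mlair1Fit()].
#' @return numeric vector of per-voxel estimates.
#' @export
parametricMap <- function(voxelActivity, schedule, input = NULL,
                          method = c("mlair2", "suv"), interval = c(40, 50),
                          dose = NULL, weight = NULL,
                          includeWbIntegral = FALSE) {
  method <- match.arg(method)
  if (!is.matrix(voxelActivity) || ncol(voxelActivity) != nFrames(schedule))
    stop("voxelActivity must be a voxel x frame matrix matching the schedule")
  ok <- apply(is.finite(voxelActivity), 1, all)
  out <- rep(NaN, nrow(voxelActivity))
  if (method == "suv") {
    for (i in which(ok)) {
      tc <- Tac(schedule, voxelActivity[i, ], quiet = TRUE)
      out[i] <- suppressWarnings(as.numeric(
        suvValue(tc, interval, dose, weight)))
    }
    return(out)
  }
  ## MLAIR2: input-side regressors are shared across voxels
  ifa <- inputFrameAverages(input, schedule)
  base <- cbind(wb = ifa$cwb, iwb = ifa$icwb, icp = ifa$icp, iicp = ifa$iicp)
  if (!includeWbIntegral) base <- base[, c("wb", "icp", "iicp")]
  for (i in which(ok)) {
    act <- voxelActivity[i, ]
    iact <- tacRunningIntegral(act, schedule)$frameAvg
    res <- try(mlairSolve(cbind(base, pet = act), iact), silent = TRUE)
    out[i] <- if (inherits(res, "try-error")) NaN else res$coef[["iicp"]]
  }
  out
}
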