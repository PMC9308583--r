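#' @import methods
NULL

TISSUE_CLASSES <- c("GM", "WM", "lesion", "peri-lesion", "NAWM", "whole-blood")
MODEL_NAMES <- c("1T2K", "2T3K", "2T4K")
LESION_CLASSES <- c("active", "black_hole", "demyelinated",
                    "partially_myelinated", "remyelinated", "excluded")

#' Frame schedule of a dynamic PET acquisition
#'
#' Contiguous, non-overlapping time frames. Times are stored in minutes;
#' frames are half-open intervals `[start, start + duration)`.
#'
#' @slot start numeric, frame start times (minutes).
#' @slot duration numeric, frame durations (minutes), all positive.
#' @export
setClass("FrameSchedule",
         representation(start = "numeric", duration = "numeric"))

setValidity("FrameSchedule", function(object) {
  s <- object@start; d <- object@duration
  if (length(s) != length(d)) return("start and duration lengths differ")
  if (length(s) < 1) return("schedule needs at least one frame")
  if (any(!is.finite(s)) || any(!is.finite(d))) return("non-finite times")
  if (any(d <= 0)) return("frame durations must be positive")
  if (length(s) > 1 &&
      max(abs(s[-1] - (s[-length(s)] + d[-length(d)]))) > 1e-9)
    return("frames must be contiguous and non-overlapping")
  TRUE
})

#' Time-activity curve for one region
#'
#' Decay-corrected activity concentration (kBq/mL) per frame of a
#' [FrameSchedule-class]. Negative values in early low-count frames are
#' retained but flagged via a warning at construction.
#'
#' @slot schedule a [FrameSchedule-class].
#' @slot activity numeric, one value per frame (kBq/mL).
#' @slot region character region label.
#' @slot tissueClass one of GM, WM, lesion, peri-lesion, NAWM, whole-blood.
#' @export
setClass("Tac",
         representation(schedule = "FrameSchedule", activity = "numeric",
                        region = "character", tissueClass = "character"))

setValidity("Tac", function(object) {
  if (length(object@activity) != length(object@schedule@start))
    return("activity length must equal number of frames")
  if (any(!is.finite(object@activity))) return("activity must be finite")
  if (length(object@region) != 1) return("region must be a single string")
  if (!object@tissueClass %in% TISSUE_CLASSES)
    return(paste("tissueClass must be one of:",
                 paste(TISSUE_CLASSES, collapse = ", ")))
  TRUE
})

#' Manual arterial blood samples
#'
#' @slot time numeric sample times (minutes), strictly increasing.
#' @slot wholeBlood numeric whole-blood activity (kBq/mL).
#' @slot plasmaRatio numeric plasma-to-whole-blood activity ratio (> 0).
#' @slot parentFraction numeric fraction of plasma activity that is intact
#'   parent tracer, in `[0, 1]`.
#' @export
setClass("BloodSamples",
         representation(time = "numeric", wholeBlood = "numeric",
                        plasmaRatio = "numeric", parentFraction = "numeric"))

setValidity("BloodSamples", function(object) {
  n <- length(object@time)
  if (any(c(length(object@wholeBlood), length(object@plasmaRatio),
            length(object@parentFraction)) != n))
    return("all fields must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    return("sample times must be strictly increasing")
  if (any(object@plasmaRatio <= 0)) return("plasma ratios must be positive")
  if (any(object@parentFraction < 0 | object@parentFraction > 1))
    return("parent fractions must lie in [0, 1]")
  TRUE
})

#' Hill model of the plasma parent fraction
#'
#' `PF(t) = 1 - a * t^b / (t^b + c)`: equal to 1 at injection, monotonically
#' non-increasing, with asymptote `1 - a`.
#'
#' @slot a unitless amplitude in `[0, 1]` (metabolized fraction at infinity).
#' @slot b unitless steepness (> 0).
#' @slot c scale parameter (minutes^b, > 0).
#' @export
setClass("HillParams", representation(a = "numeric", b = "numeric", c = "numeric"))

setValidity("HillParams", function(object) {
  if (object@a < 0 || object@a > 1) return("a must lie in [0, 1]")
  if (object@b <= 0) return("b must be positive")
  if (object@c <= 0) return("c must be positive")
  TRUE
})

#' Arterial input function
#'
#' Calibrated whole-blood curve and metabolite-corrected parent plasma curve
#' on a shared time grid, plus the Hill parent-fraction model and the
#' plasma-to-whole-blood ratio knots used to build the plasma curve.
#' Both curves are 0 at `t <= 0`; between samples interpolation is
#' piecewise linear with constant extrapolation after the last sample.
#'
#' @slot time numeric grid (minutes).
#' @slot wholeBlood whole-blood activity on the grid (kBq/mL).
#' @slot plasma parent plasma activity on the grid (kBq/mL).
#' @slot hill the fitted [HillParams-class].
#' @slot ratioTime,ratioValue knots of the plasma-to-whole-blood ratio model.
#' @export
setClass("InputFunction",
         representation(time = "numeric", wholeBlood = "numeric",
                        plasma = "numeric", hill = "HillParams",
                        ratioTime = "numeric", ratioValue = "numeric"))

setValidity("InputFunction", function(object) {
  n <- length(object@time)
  if (length(object@wholeBlood) != n || length(object@plasma) != n)
    return("time, wholeBlood and plasma must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    return("time grid must be strictly increasing")
  if (length(object@ratioTime) != length(object@ratioValue))
    return("ratio knots malformed")
  TRUE
})

#' Result of a compartment-model fit
#'
#' @slot model "1T2K", "2T3K" or "2T4K".
#' @slot estimates named numeric `(K1, k2, k3, k4, vB)`; rate constants in
#'   1/min, `K1` in mL/cm^3/min, `vB` unitless.
#' @slot fixed logical mask, `TRUE` where the parameter was held fixed.
#' @slot macro named numeric macroparameters (`Ki`, `VT`, `BPnd` where
#'   defined for the model).
#' @slot sePercent named numeric percent standard errors for free parameters
#'   and macroparameters (`Inf` when not identifiable).
#' @slot wrss weighted residual sum of squares.
#' @slot r2 unweighted coefficient of determination.
#' @slot aic Akaike information criterion `n*log(wrss/n) + 2m`.
#' @slot aicc small-sample corrected AIC (adds `2m(m+1)/(n-m-1)`).
#' @slot nFrames number of frames used.
#' @slot converged logical.
#' @slot k1k2Ratio numeric, the fixed K1/k2 ratio, or NA when k2 was free.
#' @export
setClass("KineticFit",
         representation(model = "character", estimates = "numeric",
                        fixed = "logical", macro = "numeric",
                        sePercent = "numeric", wrss = "numeric",
                        r2 = "numeric", aic = "numeric", aicc = "numeric",
                        nFrames = "numeric",
                        converged = "logical", k1k2Ratio = "numeric"))

#' Result of a linearized (graphical or MLAIR) analysis
#'
#' @slot method "patlak", "logan", "mlair1" or "mlair2".
#' @slot estimate the primary estimate: net influx rate Ki (Patlak, MLAIR) or
#'   total volume of distribution VT (Logan).
#' @slot estimateName "Ki" or "VT".
#' @slot intercept intercept of the Patlak/Logan regression (NA for MLAIR).
#' @slot coefficients regression coefficients P1..P5 / b1..b5 (MLAIR only).
#' @slot tstar linear-phase start time in minutes (NA for MLAIR).
#' @slot nPoints number of frames entering the regression.
#' @slot r2 coefficient of determination of the operational regression.
#' @slot lowConfidence flag set when very few late frames support the fit.
#' @export
setClass("GraphicalFit",
         representation(method = "character", estimate = "numeric",
                        estimateName = "character", intercept = "numeric",
                        coefficients = "numeric", tstar = "numeric",
                        nPoints = "numeric", r2 = "numeric",
                        lowConfidence = "logical"))
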