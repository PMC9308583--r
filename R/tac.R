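#' Construct a time-activity curve
#'
#' @param schedule a [FrameSchedule-class].
#' @param activity numeric activity concentration per frame (kBq/mL),
#'   decay-corrected to injection time.
#' @param region region label.
#' @param tissueClass one of `"GM"`, `"WM"`, `"lesion"`, `"peri-lesion"`,
#'   `"NAWM"`, `"whole-blood"`.
#' @param quiet suppress the warning flagging negative frames.
#' @return a [Tac-class]. Negative values (possible in early low-count
#'   frames after scatter correction) are retained but flagged.
#' @export
Tac <- function(schedule, activity, region = "region", tissueClass = "WM",
                quiet = FALSE) {
  obj <- new("Tac", schedule = schedule, activity = as.numeric(activity),
             region = region, tissueClass = tissueClass)
  if (!quiet && any(activity < 0))
    warning(sprintf("TAC '%s': %d negative frame value(s) retained",
                    region, sum(activity < 0)))
  obj
}

#' @rdname Tac
#' @export
setMethod("activity", "Tac", function(object) object@activity)

#' @rdname Tac
#' @export
setMethod("schedule", "Tac", function(object) object@schedule)

#' @rdname Tac
#' @export
setMethod("regionLabel", "Tac", function(object) object@region)

#' @rdname Tac
#' @export
setMethod("tissueClass", "Tac", function(object) object@tissueClass)

setMethod("show", "Tac", function(object) {
  cat(sprintf("Tac '%s' (%s): %d frames, peak %.3g kBq/mL\n",
              object@region, object@tissueClass, length(object@activity),
              max(object@activity)))
})

#' Construct a set of manual blood samples
#'
#' @param time sample times (minutes).
#' @param wholeBlood whole-blood activity (kBq/mL).
#' @param plasmaRatio plasma-to-whole-blood activity ratio.
#' @param parentFraction intact parent fraction in plasma, in `[0, 1]`.
#' @return a [BloodSamples-class].
#' @export
BloodSamples <- function(time, wholeBlood, plasmaRatio = rep(1, length(time)),
                         parentFraction = rep(1, length(time))) {
  new("BloodSamples", time = as.numeric(time),
      wholeBlood = as.numeric(wholeBlood),
      plasmaRatio = as.numeric(plasmaRatio),
      parentFraction = as.numeric(parentFraction))
}

#' @rdname InputFunction
#' @export
setMethod("sampleTimes", "BloodSamples", function(object) object@time)

setMethod("show", "BloodSamples", function(object) {
  cat(sprintf("BloodSamples: %d samples at %s min\n", length(object@time),
              paste(format(object@time), collapse = ", ")))
})
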