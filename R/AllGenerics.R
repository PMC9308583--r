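#' @rdname Tac
#' @param object,x a package object.
#' @export
setGeneric("activity", function(object) standardGeneric("activity"))

#' @rdname Tac
#' @export
setGeneric("schedule", function(object) standardGeneric("schedule"))

#' @rdname Tac
#' @export
setGeneric("regionLabel", function(object) standardGeneric("regionLabel"))

#' @rdname Tac
#' @export
setGeneric("tissueClass", function(object) standardGeneric("tissueClass"))

#' @rdname FrameSchedule
#' @export
setGeneric("frameStart", function(object) standardGeneric("frameStart"))

#' @rdname FrameSchedule
#' @export
setGeneric("frameDuration", function(object) standardGeneric("frameDuration"))

#' @rdname FrameSchedule
#' @export
setGeneric("frameMidpoints", function(object) standardGeneric("frameMidpoints"))

#' @rdname FrameSchedule
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname InputFunction
#' @export
setGeneric("plasmaActivity", function(object) standardGeneric("plasmaActivity"))

#' @rdname InputFunction
#' @export
setGeneric("wholeBloodActivity",
           function(object) standardGeneric("wholeBloodActivity"))

#' @rdname InputFunction
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname KineticFit
#' @export
setGeneric("macroParams", function(object) standardGeneric("macroParams"))

#' @rdname KineticFit
#' @export
setGeneric("percentSE", function(object, which) standardGeneric("percentSE"))

#' @rdname KineticFit
#' @export
setGeneric("aicValue",
           function(object, corrected = FALSE) standardGeneric("aicValue"))
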