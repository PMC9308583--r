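#' Construct a frame schedule
#'
#' @param start numeric frame start times in minutes.
#' @param duration numeric frame durations in minutes.
#' @return a [FrameSchedule-class].
#' @examples
#' FrameSchedule(c(0, 1), c(1, 1))
#' @export
FrameSchedule <- function(start, duration) {
  new("FrameSchedule", start = as.numeric(start), duration = as.numeric(duration))
}

#' Parse a frame-schedule specification string
#'
#' Parses the compact `"count x seconds"` grammar used to describe dynamic
#' PET reconstructions, e.g. the 26-frame, 60-min protocol
#' `"1x10,10x5,1x10,2x30,3x60,2x150,4x300,3x600"`. Durations in the string
#' are seconds; the returned schedule is in minutes and starts at 0.
#'
#' @param spec character scalar, comma-separated `NxS` tokens.
#' @return a [FrameSchedule-class].
#' @examples
#' sched <- parseFrameSchedule("1x60,1x60")
#' frameMidpoints(sched)  # 0.5, 1.5 min
#' @export
parseFrameSchedule <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  tokens <- strsplit(gsub("[[:space:]]", "", spec), ",", fixed = TRUE)[[1]]
  if (length(tokens) == 0) stop("empty schedule specification")
  parts <- regmatches(tokens, regexec("^([0-9]+)x([0-9.]+)$", tokens))
  bad <- vapply(parts, function(p) length(p) != 3, logical(1))
  if (any(bad))
    stop("malformed schedule token(s): ", paste(tokens[bad], collapse = ", "))
  counts <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  secs <- vapply(parts, function(p) as.numeric(p[3]), numeric(1))
  if (any(counts < 1)) stop("frame counts must be at least 1")
  if (any(secs <= 0)) stop("frame durations must be positive")
  duration <- rep(secs, counts) / 60
  start <- cumsum(c(0, duration[-length(duration)]))
  FrameSchedule(start, duration)
}

#' Serialize a schedule back to the NxS grammar (seconds)
#'
#' @param schedule a [FrameSchedule-class].
#' @return character scalar; `parseFrameSchedule(formatFrameSchedule(x))`
#'   reproduces `x`.
#' @export
formatFrameSchedule <- function(schedule) {
  stopifnot(is(schedule, "FrameSchedule"))
  secs <- round(schedule@duration * 60, 9)
  r <- rle(secs)
  paste(sprintf("%dx%s", r$lengths, format(r$values, trim = TRUE)),
        collapse = ",")
}

#' @rdname FrameSchedule
#' @export
setMethod("frameStart", "FrameSchedule", function(object) object@start)

#' @rdname FrameSchedule
#' @export
setMethod("frameDuration", "FrameSchedule", function(object) object@duration)

#' @rdname FrameSchedule
#' @export
setMethod("nFrames", "FrameSchedule", function(object) length(object@start))

#' @rdname FrameSchedule
#' @export
setMethod("frameMidpoints", "FrameSchedule",
          function(object) object@start + object@duration / 2)

#' @rdname FrameSchedule
#' @export
setMethod("length", "FrameSchedule", function(x) length(x@start))

#' Total scan duration in minutes
#' @param schedule a [FrameSchedule-class].
#' @export
scanDuration <- function(schedule) {
  n <- length(schedule@start)
  schedule@start[n] + schedule@duration[n]
}

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %.2f-%.2f min\n",
              length(object@start), object@start[1], scanDuration(object)))
})
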