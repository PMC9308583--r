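#' Read a time-activity-curve table
#'
#' Expects a delimited text file with columns `frame_start_s`,
#' `frame_duration_s` and one column per region. Leading comment lines
#' beginning with `#` may carry metadata as `# key: value`; recognised keys
#' are `units` (`kBq/mL`, the default, `Bq/mL` or `MBq/mL` — converted to
#' kBq/mL on read), `subject` and `tissue_class_<region>`.
#'
#' @param path file path.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return list of [Tac-class] objects sharing one schedule, with the parsed
#'   metadata attached as attribute `"meta"`.
#' @export
readTacTable <- function(path, sep = ",") {
  lines <- readLines(path)
  headerIdx <- grep("^#", lines)
  meta <- list()
  for (h in lines[headerIdx]) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- if (length(headerIdx)) lines[-headerIdx] else lines
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          check.names = FALSE)
  need <- c("frame_start_s", "frame_duration_s")
  if (!all(need %in% names(df)))
    stop("TAC table must contain columns: ", paste(need, collapse = ", "))
  sched <- FrameSchedule(df$frame_start_s / 60, df$frame_duration_s / 60)
  units <- if (is.null(meta$units)) "kBq/mL" else meta$units
  scale <- switch(units, "kBq/mL" = 1, "Bq/mL" = 1e-3, "MBq/mL" = 1e3,
                  stop("unknown activity units: ", units))
  regions <- setdiff(names(df), need)
  if (length(regions) == 0) stop("TAC table has no region columns")
  tacs <- lapply(regions, function(r) {
    cls <- meta[[paste0("tissue_class_", r)]]
    Tac(sched, df[[r]] * scale, region = r,
        tissueClass = if (is.null(cls)) "WM" else cls, quiet = TRUE)
  })
  names(tacs) <- regions
  attr(tacs, "meta") <- meta
  tacs
}

#' Write a list of TACs to a delimited table
#'
#' Inverse of [readTacTable()]; values are written in kBq/mL with enough
#' digits for a bit-exact round trip of decimal text up to 9 significant
#' digits.
#'
#' @param tacs list of [Tac-class] sharing one schedule.
#' @param path output path.
#' @param subject optional subject id recorded in the header.
#' @param sep field separator.
#' @export
writeTacTable <- function(tacs, path, subject = NULL, sep = ",") {
  if (is(tacs, "Tac")) tacs <- list(tacs)
  sched <- schedule(tacs[[1]])
  for (tc in tacs)
    if (!isTRUE(all.equal(frameStart(schedule(tc)), frameStart(sched))))
      stop("all TACs must share one schedule")
  header <- c("# units: kBq/mL",
              if (!is.null(subject)) paste0("# subject: ", subject),
              vapply(tacs, function(tc)
                sprintf("# tissue_class_%s: %s", regionLabel(tc),
                        tissueClass(tc)), character(1)))
  df <- data.frame(frame_start_s = frameStart(sched) * 60,
                   frame_duration_s = frameDuration(sched) * 60,
                   check.names = FALSE)
  for (tc in tacs) df[[regionLabel(tc)]] <- activity(tc)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read manual blood samples
#'
#' CSV with columns `time_s, whole_blood_kBq_ml` and, for manual samples,
#' `plasma_ratio` and `parent_fraction`.
#'
#' @param path file path.
#' @return a [BloodSamples-class] (4-column file) or a data.frame with
#'   `time` (min) and `wholeBlood` (continuous 2-column file).
#' @export
readBloodTable <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "whole_blood_kBq_ml") %in% names(df)))
    stop("blood table must contain time_s and whole_blood_kBq_ml")
  if (all(c("plasma_ratio", "parent_fraction") %in% names(df)))
    BloodSamples(df$time_s / 60, df$whole_blood_kBq_ml,
                 df$plasma_ratio, df$parent_fraction)
  else
    data.frame(time = df$time_s / 60, wholeBlood = df$whole_blood_kBq_ml)
}

#' Write blood data
#'
#' @param x a [BloodSamples-class] or a data.frame with `time` (min) and
#'   `wholeBlood` columns (continuous curve).
#' @param path output path.
#' @export
writeBloodTable <- function(x, path) {
  if (is(x, "BloodSamples")) {
    df <- data.frame(time_s = x@time * 60, whole_blood_kBq_ml = x@wholeBlood,
                     plasma_ratio = x@plasmaRatio,
                     parent_fraction = x@parentFraction)
  } else {
    df <- data.frame(time_s = x$time * 60, whole_blood_kBq_ml = x$wholeBlood)
  }
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read subject metadata from JSON or YAML
#'
#' Expected keys: `net_injected_dose_MBq`, `body_weight_kg`, `cohort`
#' (`"HC"` or `"MS"`).
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return named list with elements `dose`, `weight`, `cohort`.
#' @export
readSubjectMeta <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  meta <- list(dose = as.numeric(x$net_injected_dose_MBq),
               weight = as.numeric(x$body_weight_kg),
               cohort = as.character(x$cohort))
  if (!isTRUE(meta$dose > 0)) stop("net injected dose must be positive")
  if (!isTRUE(meta$weight > 0)) stop("body weight must be positive")
  if (!meta$cohort %in% c("HC", "MS")) stop("cohort must be HC or MS")
  meta
}

#' Export an input function as CSV
#'
#' Columns: `time_min, C_wb, C_p, parent_fraction, plasma_ratio`.
#'
#' @param input an [InputFunction-class].
#' @param path output path.
#' @export
writeInputFunction <- function(input, path) {
  df <- data.frame(time_min = input@time, C_wb = input@wholeBlood,
                   C_p = input@plasma,
                   parent_fraction = parentFraction(input@hill, input@time),
                   plasma_ratio = plasmaRatioAt(input, input@time))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
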