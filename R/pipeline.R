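#' Pipeline configuration
#'
#' Validated configuration for [runQuantification()]. Unknown keys are
#' rejected before any computation.
#'
#' @param simulate a [cohortSpec()] describing the synthetic study to
#'   generate, or `NULL` when `study` is supplied.
#' @param study a pre-built study object from [simulateStudy()] (or of the
#'   same shape, e.g. assembled from files via the readers), or `NULL`.
#' @param models compartment models to fit per region.
#' @param fixVB fix fractional blood volume at this value for the lesion
#'   pass (`NULL` keeps it free).
#' @param fixK1k2 `"wm"` fixes the lesion-pass K1/k2 ratio to each
#'   subject's whole-brain WM value (two-pass procedure); `NULL` disables.
#' @param tstar Patlak linear-phase start (minutes).
#' @param suvWindows list of SUV intervals in minutes.
#' @param seThreshold percent-SE reliability cutoff.
#' @param fitLesions fit lesion TACs with the compartment model (slow for
#'   large cohorts); lesion statistics otherwise use ground-truth Ki when
#'   available.
#' @param seed integer seed for all stochastic stages.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(simulate = cohortSpec(), study = NULL,
                           models = c("1T2K", "2T3K", "2T4K"),
                           fixVB = NULL, fixK1k2 = "wm", tstar = 20,
                           suvWindows = list(c(40, 50), c(50, 60)),
                           seThreshold = 25, fitLesions = FALSE, seed = 1) {
  cfg <- list(simulate = simulate, study = study, models = models,
              fixVB = fixVB, fixK1k2 = fixK1k2, tstar = tstar,
              suvWindows = suvWindows, seThreshold = seThreshold,
              fitLesions = fitLesions, seed = seed)
  validatePipelineConfig(cfg)
  structure(cfg, class = "pipelineConfig")
}

validatePipelineConfig <- function(cfg) {
  known <- c("simulate", "study", "models", "fixVB", "fixK1k2", "tstar",
             "suvWindows", "seThreshold", "fitLesions", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (is.null(cfg$simulate) && is.null(cfg$study))
    stop("config needs either a simulate spec or a study")
  if (length(cfg$models) == 0) stop("config lists no models")
  bad <- setdiff(cfg$models, MODEL_NAMES)
  if (length(bad)) stop("unknown models: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$fixK1k2) && !identical(cfg$fixK1k2, "wm"))
    stop("fixK1k2 must be \"wm\" or NULL")
  stopifnot(cfg$tstar >= 0, cfg$seThreshold > 0)
  invisible(TRUE)
}

## aggregate (average) the WM TACs of a subject into a whole-brain WM TAC
wholeBrainWmTac <- function(subj) {
  wm <- Filter(function(tc) tissueClass(tc) == "WM", subj$tacs)
  if (!length(wm)) return(NULL)
  acts <- rowMeans(vapply(wm, activity, numeric(nFrames(schedule(wm[[1]])))))
  Tac(schedule(wm[[1]]), acts, region = "wholeBrainWM", tissueClass = "WM",
      quiet = TRUE)
}

#' Run the full quantification workflow
#'
#' Mirrors the study workflow: input construction, compartment fits per
#' region with AIC scoring, reliability filtering, graphical methods
#' (Patlak, MLAIR1, MLAIR2) and SUV, method-comparison regressions per
#' cohort stratum, a GM-versus-WM test on the healthy controls, and lesion
#' classification plus lesion-versus-NAWM statistics. Every input region
#' appears in the output with a status; all stochastic stages consume the
#' config seed.
#'
#' @param config a [pipelineConfig()].
#' @return list of tidy data.frames: `fits`, `preference`, `graphical`,
#'   `suv`, `comparison`, `gmwm`, `lesionClasses`, `lesionStats`, `log`.
#' @export
runQuantification <- function(config) {
  validatePipelineConfig(config)
  study <- if (!is.null(config$study)) config$study
  else simulateStudy(config$simulate, seed = config$seed)

  fits <- list(); logRows <- list(); grRows <- list(); suvRows <- list()
  for (subj in study$subjects) {
    wbWm <- wholeBrainWmTac(subj)
    for (tc in subj$tacs) {
      key <- list(subject = subj$id, region = regionLabel(tc),
                  tissueClass = tissueClass(tc))
      for (model in config$models) {
        fit <- try(fitCompartmentModel(tc, subj$input, model), silent = TRUE)
        if (inherits(fit, "try-error")) {
          logRows[[length(logRows) + 1]] <-
            data.frame(key, model = model, status = "failed")
          next
        }
        primary <- if (model == "2T3K") "Ki" else "VT"
        fits[[length(fits) + 1]] <- data.frame(
          key, model = model, fixMode = "none",
          t(coef(fit)), Ki = unname(fit@macro["Ki"]),
          VT = unname(fit@macro["VT"]),
          sePercent = unname(fit@sePercent[primary]),
          parameter = primary, wrss = fit@wrss, r2 = fit@r2, aic = fit@aic,
          aicc = fit@aicc, row.names = NULL)
        logRows[[length(logRows) + 1]] <- data.frame(
          key, model = model,
          status = if (fit@converged) "fitted" else "not-converged")
      }
      ## simplified methods
      gr <- list(
        patlak = try(patlakFit(tc, subj$input, config$tstar), silent = TRUE),
        mlair1 = try(mlair1Fit(tc, subj$input), silent = TRUE),
        mlair2 = try(mlair2Fit(tc, subj$input), silent = TRUE))
      for (m in names(gr)) {
        if (inherits(gr[[m]], "try-error")) next
        g <- gr[[m]]
        grRows[[length(grRows) + 1]] <- data.frame(
          key, method = m, estimate = g@estimate,
          estimateName = g@estimateName, r2 = g@r2, tstar = g@tstar)
      }
      for (w in config$suvWindows) {
        suvRows[[length(suvRows) + 1]] <- data.frame(
          key, method = sprintf("suv_%d_%d", w[1], w[2]),
          estimate = as.numeric(suppressWarnings(
            suvValue(tc, w, subj$meta$dose, subj$meta$weight))))
      }
    }
  }
  fits <- do.call(rbind, fits)
  graphical <- do.call(rbind, grRows)
  suv <- do.call(rbind, suvRows)
  logDf <- do.call(rbind, logRows)

  ## model preference per tissue-class group (small-sample corrected AIC)
  preference <- if (length(config$models) >= 2)
    modelPreference(data.frame(region = paste(fits$subject, fits$region),
                               model = fits$model, aic = fits$aicc,
                               group = fits$tissueClass))
  else NULL

  ## reliability filtering on the primary macroparameter
  reliable <- filterReliable(fits, config$seThreshold,
                             by = c("model", "parameter"))

  ## method comparison against 2T3K Ki, per stratum
  comparison <- NULL
  ref <- fits[fits$model == "2T3K", ]
  if (nrow(ref)) {
    refKey <- paste(ref$subject, ref$region)
    cohortOf <- stats::setNames(
      vapply(study$subjects, function(s) s$meta$cohort, character(1)),
      vapply(study$subjects, function(s) s$id, character(1)))
    cand <- rbind(graphical[, c("subject", "region", "method", "estimate")],
                  suv[, c("subject", "region", "method", "estimate")])
    rows <- list()
    for (m in unique(cand$method)) {
      cm <- cand[cand$method == m, ]
      idx <- match(paste(cm$subject, cm$region), refKey)
      ok <- !is.na(idx)
      for (g in c("HC", "MS", "all")) {
        sel <- ok & (g == "all" | cohortOf[cm$subject] == g)
        if (sum(sel) < 3) next
        cc <- try(compareMethods(ref$Ki[idx[sel]], cm$estimate[sel], g),
                  silent = TRUE)
        if (!inherits(cc, "try-error"))
          rows[[length(rows) + 1]] <- cbind(method = m, cc)
      }
    }
    comparison <- do.call(rbind, rows)
  }

  ## GM vs WM on healthy controls: per-subject mean 2T3K Ki
  gmwm <- NULL
  if (!is.null(ref) && nrow(ref)) {
    hcIds <- vapply(Filter(function(s) s$meta$cohort == "HC", study$subjects),
                    function(s) s$id, character(1))
    sub <- ref[ref$subject %in% hcIds, ]
    if (nrow(sub)) {
      gmMeans <- tapply(sub$Ki[sub$tissueClass == "GM"],
                        sub$subject[sub$tissueClass == "GM"], mean)
      wmMeans <- tapply(sub$Ki[sub$tissueClass == "WM"],
                        sub$subject[sub$tissueClass == "WM"], mean)
      if (length(gmMeans) >= 3 && length(wmMeans) >= 3) {
        gd <- groupDifference(as.numeric(gmMeans), as.numeric(wmMeans))
        gmwm <- data.frame(gmMean = mean(gmMeans), wmMean = mean(wmMeans),
                           t = gd$t, df = gd$df, p = gd$p,
                           testUsed = gd$testUsed)
      }
    }
  }

  ## lesions: classification + class-wise Mann-Whitney vs contralateral NAWM
  lesionClasses <- NULL; lesionStats <- NULL
  if (!is.null(study$lesionTable) && nrow(study$lesionTable)) {
    lt <- study$lesionTable
    cls <- classifyLesion(lt)
    lesionClasses <- data.frame(lesion_id = lt$lesion_id, class = cls,
                                flagged = attr(cls, "flagged"))
    rows <- list()
    for (cl in unique(as.character(cls))) {
      sel <- as.character(cls) == cl
      if (!any(sel) || !all(c("lesionKi", "nawmKi") %in% names(lt))) next
      mw <- lesionVsNawm(lt$lesionKi[sel], lt$nawmKi[sel])
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, n = sum(sel), lesionKiMean = mean(lt$lesionKi[sel]),
        nawmKiMean = mean(lt$nawmKi[sel]), U = mw$U, p = mw$p)
    }
    lesionStats <- do.call(rbind, rows)
  }

  list(fits = fits, preference = preference, reliability = reliable,
       graphical = graphical, suv = suv, comparison = comparison,
       gmwm = gmwm, lesionClasses = lesionClasses, lesionStats = lesionStats,
       log = logDf,
       provenance = if (is.null(config$study)) study$provenance
       else list(seed = config$seed))
}

#' Patlak start-time sensitivity sweep
#'
#' Recomputes the Patlak Ki of each TAC for a list of linear-phase start
#' times, with the bias against a reference Ki when one is supplied. On
#' noiseless irreversible data the estimate is flat in `tstar`; reversible
#' contamination (k4 > 0) makes it fall with later start times.
#'
#' @param tacs list of [Tac-class].
#' @param input an [InputFunction-class].
#' @param tstars numeric vector of start times (>= 2 values).
#' @param referenceKi optional numeric, one reference Ki per TAC.
#' @return data.frame with `region`, `tstar`, `Ki` and optionally
#'   `biasPercent`.
#' @export
sweepTstar <- function(tacs, input, tstars, referenceKi = NULL) {
  stopifnot(length(tstars) >= 2)
  if (is(tacs, "Tac")) tacs <- list(tacs)
  if (!length(tacs))
    return(data.frame(region = character(0), tstar = numeric(0),
                      Ki = numeric(0)))
  rows <- list()
  for (i in seq_along(tacs)) {
    for (ts in tstars) {
      if (ts >= scanDuration(schedule(tacs[[i]])))
        stop("tstar beyond the scan")
      g <- patlakFit(tacs[[i]], input, ts)
      row <- data.frame(region = regionLabel(tacs[[i]]), tstar = ts,
                        Ki = g@estimate)
      if (!is.null(referenceKi))
        row$biasPercent <- 100 * (g@estimate - referenceKi[i]) / referenceKi[i]
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Write the result tables of a quantification run as CSV files
#'
#' @param results output of [runQuantification()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeResultTables <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x))
      utils::write.csv(x, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(dir)
}
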