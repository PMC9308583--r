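#' Classify an MS lesion by expected myelin density
#'
#' Deterministic rule table over MRI-derived lesion descriptors, applied in
#' priority order:
#' \enumerate{
#'   \item maximum diameter not larger than 3 mm: `excluded`;
#'   \item hyperintense on post-gadolinium T1w: `active`;
#'   \item T1w iso-intense to CSF: `black_hole`;
#'   \item T1w hypointense with a T1w volume smaller than the T2w-FLAIR
#'     volume (beyond the equality tolerance): `partially_myelinated`;
#'   \item T1w hypointense with equal volumes: `demyelinated`;
#'   \item T1w iso-intense to NAWM (with T2w-FLAIR hyperintensity):
#'     `remyelinated`.
#' }
#' Descriptors lacking FLAIR hyperintensity after the size/activity gates are
#' inconsistent; they are flagged (attribute `"flagged"`) and classified by
#' their T1w class, as above.
#'
#' @param lesions data.frame with columns `flair_hyper` (logical),
#'   `t1_class` (`"iso_to_NAWM"`, `"hypointense"`, `"iso_to_CSF"`),
#'   `gd_hyper` (logical), `vol_t1_ml`, `vol_flair_ml`, `max_diam_mm`.
#' @param volumeTol relative tolerance under which the T1w and FLAIR volumes
#'   count as equal: `abs(v1 - v2)/v2 <= volumeTol` (default 0.2).
#' @return factor of lesion classes (levels: active, black_hole,
#'   demyelinated, partially_myelinated, remyelinated, excluded) with a
#'   logical `"flagged"` attribute marking inconsistent descriptors.
#' @export
classifyLesion <- function(lesions, volumeTol = 0.2) {
  need <- c("flair_hyper", "t1_class", "gd_hyper", "vol_t1_ml",
            "vol_flair_ml", "max_diam_mm")
  if (!all(need %in% names(lesions)))
    stop("missing descriptor columns: ",
         paste(setdiff(need, names(lesions)), collapse = ", "))
  stopifnot(all(lesions$vol_t1_ml > 0), all(lesions$vol_flair_ml > 0),
            all(lesions$max_diam_mm > 0))
  n <- nrow(lesions)
  out <- character(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    l <- lesions[i, ]
    out[i] <- if (l$max_diam_mm <= 3) "excluded"
    else if (isTRUE(l$gd_hyper)) "active"
    else {
      if (!isTRUE(l$flair_hyper)) flagged[i] <- TRUE
      switch(as.character(l$t1_class),
             iso_to_CSF = "black_hole",
             hypointense = {
               if (l$vol_t1_ml < (1 - volumeTol) * l$vol_flair_ml)
                 "partially_myelinated" else "demyelinated"
             },
             iso_to_NAWM = "remyelinated",
             stop("unknown t1_class: ", l$t1_class))
    }
  }
  res <- factor(out, levels = LESION_CLASSES)
  attr(res, "flagged") <- flagged
  res
}

#' Filter out unreliable parameter estimates
#'
#' Estimates whose percent standard error exceeds the threshold (the
#' conventional 25%) are deemed unreliable and removed from further
#' analysis; the removed fraction is reported, optionally per group.
#'
#' @param estimates data.frame containing a `sePercent` column.
#' @param threshold percent standard error cutoff (default 25).
#' @param by optional character vector of grouping columns for the removed
#'   fraction bookkeeping (e.g. `c("model", "parameter")`).
#' @return list with `kept` (the filtered data.frame) and `removedFraction`
#'   (a scalar, or a data.frame with one row per group).
#' @export
filterReliable <- function(estimates, threshold = 25, by = NULL) {
  stopifnot("sePercent" %in% names(estimates))
  bad <- estimates$sePercent > threshold
  kept <- estimates[!bad, , drop = FALSE]
  if (is.null(by)) {
    return(list(kept = kept,
                removedFraction = if (nrow(estimates)) mean(bad) else 0))
  }
  agg <- stats::aggregate(bad, by = estimates[by], FUN = mean)
  names(agg)[ncol(agg)] <- "removedFraction"
  list(kept = kept, removedFraction = agg)
}

#' AIC model-preference table
#'
#' For each region the model with the lowest AIC receives one vote; exact
#' ties split the vote equally (with a warning). Preferences are tabulated
#' per region group when a `group` column is present.
#'
#' @param aicTable data.frame with columns `region`, `model`, `aic` and
#'   optionally `group` (e.g. GM regions / WM regions / lesion classes).
#' @return data.frame with columns `group`, `model`, `votes`, `percent`;
#'   votes per group sum to the number of scored regions.
#' @export
modelPreference <- function(aicTable) {
  stopifnot(all(c("region", "model", "aic") %in% names(aicTable)))
  if (!"group" %in% names(aicTable)) aicTable$group <- "all"
  models <- unique(aicTable$model)
  rows <- list()
  for (g in unique(aicTable$group)) {
    sub <- aicTable[aicTable$group == g, ]
    votes <- stats::setNames(numeric(length(models)), models)
    nRegions <- 0
    for (r in unique(sub$region)) {
      rr <- sub[sub$region == r, ]
      if (length(unique(rr$model)) < 2 || any(!is.finite(rr$aic))) {
        message("region '", r, "' skipped in preference table")
        next
      }
      nRegions <- nRegions + 1
      win <- rr$model[rr$aic <= min(rr$aic) + 1e-12]
      if (length(win) > 1)
        warning("AIC tie in region '", r, "'; splitting the vote")
      votes[win] <- votes[win] + 1 / length(win)
    }
    rows[[g]] <- data.frame(group = g, model = models,
                            votes = as.numeric(votes[models]),
                            percent = if (nRegions)
                              100 * as.numeric(votes[models]) / nRegions
                            else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a simplified estimator against a reference
#'
#' Pearson correlation plus ordinary least squares of the candidate
#' estimates on the reference estimates over paired regions — the
#' convention used for validating simplified methods against the 2T3K net
#' influx rate.
#'
#' @param reference numeric reference values (e.g. 2T3K Ki per region).
#' @param candidate numeric candidate values, same regions and order.
#' @param group label for the stratum (`"HC"`, `"MS"`, `"all"`, ...).
#' @return data.frame with `group`, `r`, `slope`, `intercept`, `n`.
#' @export
compareMethods <- function(reference, candidate, group = "all") {
  stopifnot(length(reference) == length(candidate))
  ok <- is.finite(reference) & is.finite(candidate)
  x <- reference[ok]; y <- candidate[ok]
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in comparison input")
  fit <- stats::lm(y ~ x)
  data.frame(group = group, r = stats::cor(x, y),
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]), n = length(x))
}

#' Two-group comparison with normality and variance gates
#'
#' Normality per group is assessed with the Lilliefors-corrected
#' Kolmogorov-Smirnov test (p < 0.05 flags non-normality); equality of
#' variances with Levene's test (centered at the mean, p < 0.05 triggers
#' the Welch correction); otherwise Student's t-test with pooled degrees of
#' freedom `n1 + n2 - 2`.
#'
#' @param x,y numeric samples (n >= 3 each).
#' @return list with `t`, `df`, `p`, `testUsed` (`"student"` or `"welch"`),
#'   `normal` (logical per group), `levene.p`.
#' @export
groupDifference <- function(x, y) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                testUsed = "student", normal = c(TRUE, TRUE), levene.p = NA))
  normal <- vapply(list(x, y), function(v) {
    if (stats::sd(v) == 0) return(TRUE)
    p <- try(nortest::lillie.test(v)$p.value, silent = TRUE)
    if (inherits(p, "try-error")) TRUE else p >= 0.05
  }, logical(1))
  lev <- car::leveneTest(c(x, y),
                         factor(rep(c("x", "y"), c(length(x), length(y)))),
                         center = mean)
  levP <- lev[["Pr(>F)"]][1]
  equalVar <- is.na(levP) || levP >= 0.05
  tt <- stats::t.test(x, y, var.equal = equalVar)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, testUsed = if (equalVar) "student" else "welch",
       normal = normal, levene.p = levP)
}

#' Mann-Whitney U test (lesion versus NAWM)
#'
#' U is the number of (lesion, NAWM) pairs in which the first value is
#' smaller (counting ties as half), i.e. the rank-sum statistic of the
#' first sample. The two-sided p-value uses the exact distribution when
#' `min(n1, n2) <= 8` and the data are tie-free, and the normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param x,y numeric samples (n >= 1 each).
#' @return list with `U`, `p`, `method`.
#' @export
lesionVsNawm <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && min(n1, n2) <= 8) {
    ## exact two-sided p from the null distribution of U
    lo <- min(U, n1 * n2 - U)
    p <- min(2 * stats::pwilcox(lo, n1, n2), 1)
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tieTab <- table(r)
  tieCorr <- sum(tieTab^3 - tieTab) / ((n1 + n2) * (n1 + n2 - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tieCorr))
  if (sigma == 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  list(U = U, p = min(2 * stats::pnorm(-abs(z)), 1), method = "normal")
}
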