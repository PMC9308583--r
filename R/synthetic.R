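## run expr with a private RNG stream, restoring the caller's state
withLocalSeed <- function(seed, expr) {
  saved <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  expr
}

## log-normal draws with a given arithmetic mean and SD
rlnormMeanSd <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

#' Tri-exponential arterial curve model
#'
#' `C(t) = (A1*(t - tau) - A2 - A3)*exp(-l1*(t - tau)) +
#' A2*exp(-l2*(t - tau)) + A3*exp(-l3*(t - tau))` for `t > tau`, 0 before:
#' continuous at the delay `tau`, with a sharp first-pass peak and a slow
#' tail — the standard parametric stand-in for a measured arterial curve.
#'
#' @param params list with `A1` (kBq/mL/min), `A2`, `A3` (kBq/mL),
#'   `l1 > l2 > l3 > 0` (1/min) and delay `tau` (minutes).
#' @param t times in minutes.
#' @return activity concentration per time point (kBq/mL).
#' @export
fengInput <- function(params, t) {
  p <- params
  stopifnot(p$l1 > p$l2, p$l2 > p$l3, p$l3 > 0)
  u <- t - p$tau
  out <- numeric(length(t))
  pos <- u > 0
  up <- u[pos]
  out[pos] <- (p$A1 * up - p$A2 - p$A3) * exp(-p$l1 * up) +
    p$A2 * exp(-p$l2 * up) + p$A3 * exp(-p$l3 * up)
  out
}

#' Default arterial-curve parameters
#'
#' Fixture constants chosen (arbitrarily, within physiological ranges) so
#' the whole-blood curve peaks within the first minute after the delay and
#' retains a measurable tail at 60 min.
#' @export
defaultFengParams <- function() {
  list(A1 = 800, A2 = 40, A3 = 22, l1 = 4, l2 = 0.35, l3 = 0.01, tau = 0.5)
}

#' Default Hill parent-fraction parameters
#'
#' Chosen to reproduce the tracer's fast metabolism: ~19% intact parent at
#' 10 min and a plateau near 5%.
#' @export
defaultHillParams <- function() HillParams(0.95, 1.5, 5.65)

#' Simulate continuous and manual arterial blood data
#'
#' Emulates the acquisition design: a continuous online detector curve
#' (dense 1-s sampling for the first 5 min, 5-s sampling afterwards) and 5
#' manual samples at 10, 20, 30, 45 and 60 min carrying the
#' plasma-to-whole-blood ratio and the intact parent fraction. An
#' intentional miscalibration factor is applied to the continuous curve so
#' that [calibrateContinuousBlood()] has real work to do.
#'
#' @param feng arterial-curve parameters, see [fengInput()].
#' @param hill a [HillParams-class] for the parent fraction.
#' @param ratio plasma-to-whole-blood ratio: scalar or one value per manual
#'   sample.
#' @param detectorNoise multiplicative noise SD of the online detector.
#' @param miscalibration factor applied to the continuous curve
#'   (calibration should recover its inverse).
#' @param pfNoise additive SD on the measured parent fractions.
#' @param seed RNG seed (local to this call).
#' @return list with `continuous` (data.frame `time`, `wholeBlood`),
#'   `samples` (a [BloodSamples-class]) and `truth` (generating values).
#' @export
simulateBloodData <- function(feng = defaultFengParams(),
                              hill = defaultHillParams(), ratio = 1.1,
                              detectorNoise = 0.02, miscalibration = 0.8,
                              pfNoise = 0, seed = NULL) {
  withLocalSeed(seed, {
    ## dense first-pass sampling, coarser afterwards; runs slightly past the
    ## nominal 60 min because the printed frame schedule sums to 3610 s
    grid <- c(seq(0, 5, by = 1 / 60), seq(5 + 1 / 12, 61, by = 1 / 12))
    wbTrue <- fengInput(feng, grid)
    cont <- miscalibration * wbTrue
    if (detectorNoise > 0)
      cont <- cont * (1 + stats::rnorm(length(cont), 0, detectorNoise))
    tManual <- c(10, 20, 30, 45, 60)
    pf <- parentFraction(hill, tManual)
    if (pfNoise > 0)
      pf <- pmin(pmax(pf + stats::rnorm(5, 0, pfNoise), 0), 1)
    samples <- BloodSamples(tManual, fengInput(feng, tManual),
                            plasmaRatio = rep(ratio, length.out = 5),
                            parentFraction = pf)
    list(continuous = data.frame(time = grid, wholeBlood = cont),
         samples = samples,
         truth = list(feng = feng, hill = hill, ratio = ratio,
                      miscalibration = miscalibration))
  })
}

#' Build a synthetic arterial input function end to end
#'
#' Runs the full input-construction pipeline on simulated blood data:
#' detector calibration against the manual samples, Hill fit of the parent
#' fractions, and composition of the metabolite-corrected plasma curve.
#'
#' @param seed RNG seed.
#' @param ... passed to [simulateBloodData()].
#' @return list with `input` (an [InputFunction-class]), `blood`,
#'   `calibration` and `hill`.
#' @export
makeSyntheticInput <- function(seed = NULL, ...) {
  blood <- simulateBloodData(seed = seed, ...)
  cal <- calibrateContinuousBlood(blood$continuous, blood$samples)
  hill <- fitParentFraction(blood$samples@time, blood$samples@parentFraction)
  input <- buildInputFunction(cal$curve, blood$samples, hill)
  list(input = input, blood = blood, calibration = cal, hill = hill)
}

#' Kinetic anchors per tissue class
#'
#' Net-influx-rate distributions (mean, SD of the log-normal draws) per
#' tissue class, with typical delivery (`K1`), washout (`k2`) and blood
#' volume (`vB`) values; lesion classes carry the matching contralateral
#' NAWM anchors. GM/WM values anchor the healthy-cohort Ki distributions
#' (0.064 +/- 0.018 and 0.113 +/- 0.031 mL/cm^3/min); lesion classes are
#' ordered by expected myelin density BH < DM < PM < RM.
#'
#' @return data.frame, one row per tissue class.
#' @export
kineticAnchors <- function() {
  data.frame(
    class = c("GM", "WM", "NAWM", "black_hole", "demyelinated",
              "partially_myelinated", "remyelinated"),
    KiMean = c(0.064, 0.113, 0.105, 0.072, 0.079, 0.085, 0.102),
    KiSd   = c(0.018, 0.031, 0.045, 0.035, 0.038, 0.042, 0.054),
    K1     = c(0.45, 0.25, 0.25, 0.22, 0.22, 0.23, 0.24),
    k2     = c(0.50, 0.12, 0.12, 0.13, 0.13, 0.13, 0.12),
    vB     = c(0.05, 0.02, 0.02, 0.03, 0.03, 0.03, 0.02),
    nawmKiMean = c(NA, NA, NA, 0.094, 0.108, 0.106, 0.118),
    nawmKiSd   = c(NA, NA, NA, 0.039, 0.049, 0.041, 0.050))
}

#' Draw ground-truth kinetic parameters for a tissue class
#'
#' Ki is drawn log-normally from the class anchors; `K1` and `k2` are drawn
#' log-normally (15% CV) around the class-typical values and `k3` is solved
#' from `Ki = K1*k3/(k2 + k3)` so the Ki distribution matches the anchors
#' exactly. `vB` is a truncated normal draw. For a reversible truth model
#' (`"2T4K"`) a small `k4` is added; for `"1T2K"` trapping is removed.
#'
#' @param class tissue class name, see [kineticAnchors()].
#' @param n number of regions.
#' @param truthModel generating topology, default `"2T3K"`.
#' @param seed RNG seed.
#' @return data.frame with columns `K1, k2, k3, k4, vB, Ki`.
#' @export
drawKineticParams <- function(class, n, truthModel = "2T3K", seed = NULL) {
  anchors <- kineticAnchors()
  a <- anchors[anchors$class == class, ]
  if (nrow(a) != 1) stop("unknown tissue class: ", class)
  withLocalSeed(seed, {
    Ki <- rlnormMeanSd(n, a$KiMean, a$KiSd)
    K1 <- rlnormMeanSd(n, a$K1, 0.15 * a$K1)
    k2 <- rlnormMeanSd(n, a$k2, 0.15 * a$k2)
    Ki <- pmin(Ki, 0.8 * K1)  # keep trapping below delivery
    k3 <- Ki * k2 / (K1 - Ki)
    vB <- pmin(pmax(stats::rnorm(n, a$vB, 0.01), 0.001), 0.15)
    k4 <- rep(0, n)
    if (truthModel == "1T2K") {
      k3 <- rep(0, n); Ki <- rep(0, n)
    } else if (truthModel == "2T4K") {
      k4 <- rlnormMeanSd(n, 0.015, 0.005)
    }
    data.frame(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB,
               Ki = K1 * k3 / pmax(k2 + k3, .Machine$double.eps))
  })
}

#' Add frame-dependent noise to a TAC
#'
#' Independent zero-mean Gaussian noise with the standard PET frame-noise
#' structure `sd_i = alpha * sqrt(max(C_i, 0) * exp(lambda*t_mid_i) /
#' dt_i)` (carbon-11 decay constant): shorter frames and later, decayed
#' frames are noisier.
#'
#' @param tac a [Tac-class].
#' @param alpha noise scale (>= 0); 0 returns the TAC unchanged.
#' @param seed RNG seed (local).
#' @return a noisy [Tac-class].
#' @export
addTacNoise <- function(tac, alpha, seed = NULL) {
  stopifnot(alpha >= 0)
  if (alpha == 0) return(tac)
  sched <- schedule(tac)
  sd <- alpha * sqrt(pmax(activity(tac), 0) *
                       exp(LAMBDA_C11 * frameMidpoints(sched)) /
                       frameDuration(sched))
  withLocalSeed(seed, {
    Tac(sched, activity(tac) + stats::rnorm(nFrames(sched), 0, sd),
        region = regionLabel(tac), tissueClass = tissueClass(tac),
        quiet = TRUE)
  })
}

#' Noise scale giving a target frame-wise coefficient of variation
#'
#' Inverts the [addTacNoise()] sd formula so that the median of
#' `sd_i / C_i` over positive frames equals `cv` — e.g. `cv = 0.05` for a
#' "5% noise" simulation.
#'
#' @param tac a noiseless [Tac-class].
#' @param cv target median relative noise.
#' @return alpha for [addTacNoise()].
#' @export
noiseAlphaForCV <- function(tac, cv) {
  sched <- schedule(tac)
  act <- activity(tac)
  pos <- act > 0
  rel <- sqrt(exp(LAMBDA_C11 * frameMidpoints(sched)[pos]) /
                (act[pos] * frameDuration(sched)[pos]))
  cv / stats::median(rel)
}

#' The acquisition frame schedule emulated by the generator
#'
#' 26 frames: 1x10, 10x5, 1x10, 2x30, 3x60, 2x150, 4x300 and 3x600 s.
#' @export
defaultSchedule <- function() {
  parseFrameSchedule("1x10,10x5,1x10,2x30,3x60,2x150,4x300,3x600")
}

#' Simulate a cohort of region TACs with known ground truth
#'
#' Draws per-region kinetic parameters for one tissue class, simulates TACs
#' on the acquisition schedule through the compartment forward model, and
#' adds frame-dependent noise at a target relative level.
#'
#' @param class tissue class, see [kineticAnchors()].
#' @param n number of regions.
#' @param input an [InputFunction-class].
#' @param schedule a [FrameSchedule-class].
#' @param noiseCV target median frame-wise coefficient of variation (0 for
#'   noiseless).
#' @param truthModel generating topology.
#' @param seed RNG seed.
#' @return list with `tacs` (list of [Tac-class]) and `truth` (data.frame).
#' @export
simulateRegionTacs <- function(class, n, input, schedule = defaultSchedule(),
                               noiseCV = 0.05, truthModel = "2T3K",
                               seed = NULL) {
  withLocalSeed(seed, {
    truth <- drawKineticParams(class, n, truthModel)
    tacs <- vector("list", n)
    tissue <- if (class %in% c("GM", "WM", "NAWM"))
      sub("NAWM", "NAWM", class) else "lesion"
    for (i in seq_len(n)) {
      p <- unlist(truth[i, c("K1", "k2", "k3", "k4", "vB")])
      tc <- modelTissueCurve(truthModel, p, input, schedule,
                             region = sprintf("%s_%02d", class, i),
                             tissueClass = if (class == "NAWM") "NAWM"
                             else if (class %in% c("GM", "WM")) class
                             else "lesion")
      if (noiseCV > 0)
        tc <- addTacNoise(tc, noiseAlphaForCV(tc, noiseCV))
      tacs[[i]] <- tc
    }
    truth$region <- vapply(tacs, regionLabel, character(1))
    truth$class <- class
    list(tacs = tacs, truth = truth)
  })
}

#' Simulate a lesion cohort with contralateral NAWM values
#'
#' Draws ground-truth net influx rates for the four myelin-density lesion
#' classes and their contralateral NAWM partners from the class anchors
#' ([kineticAnchors()]); class sizes default to 105 black holes, 111
#' demyelinated, 69 partially myelinated and 7 remyelinated lesions.
#'
#' @param counts named integer vector of lesions per class.
#' @param seed RNG seed.
#' @return data.frame with `class`, `lesionKi`, `nawmKi`.
#' @export
simulateLesionCohort <- function(counts = c(black_hole = 105,
                                            demyelinated = 111,
                                            partially_myelinated = 69,
                                            remyelinated = 7),
                                 seed = NULL) {
  anchors <- kineticAnchors()
  withLocalSeed(seed, {
    rows <- lapply(names(counts), function(cl) {
      a <- anchors[anchors$class == cl, ]
      n <- counts[[cl]]
      data.frame(class = cl,
                 lesionKi = rlnormMeanSd(n, a$KiMean, a$KiSd),
                 nawmKi = rlnormMeanSd(n, a$nawmKiMean, a$nawmKiSd))
    })
    do.call(rbind, rows)
  })
}

#' Simulate subject-level healthy-control Ki values
#'
#' Per-subject whole-brain GM and WM net influx rates drawn from the
#' Table-style anchors (GM 0.064 +/- 0.018, WM 0.113 +/- 0.031
#' mL/cm^3/min).
#'
#' @param n number of subjects (default 6).
#' @param seed RNG seed.
#' @return data.frame with `subject`, `gmKi`, `wmKi`.
#' @export
simulateHcKiCohort <- function(n = 6, seed = NULL) {
  anchors <- kineticAnchors()
  gm <- anchors[anchors$class == "GM", ]
  wm <- anchors[anchors$class == "WM", ]
  withLocalSeed(seed, {
    data.frame(subject = seq_len(n),
               gmKi = stats::rnorm(n, gm$KiMean, gm$KiSd),
               wmKi = stats::rnorm(n, wm$KiMean, wm$KiSd))
  })
}

#' Generate MRI descriptors consistent with a lesion class
#'
#' Inverse of the classification rule table, used to exercise
#' [classifyLesion()] round trips: descriptors generated for a class are
#' classified back into it. Volumes follow the per-class average-volume
#' anchors; no lesion is gadolinium-enhancing (the study conditions include
#' no active lesions).
#'
#' @param classes character vector of target classes.
#' @param seed RNG seed.
#' @return data.frame of descriptors, with a `class` column.
#' @export
simulateLesionDescriptors <- function(classes, seed = NULL) {
  vols <- c(black_hole = 0.17, demyelinated = 0.34,
            partially_myelinated = 0.10, remyelinated = 0.04)
  withLocalSeed(seed, {
    n <- length(classes)
    volFlair <- rlnormMeanSd(n, vols[classes], 0.5 * vols[classes])
    volT1 <- ifelse(classes == "partially_myelinated", 0.5 * volFlair,
                    volFlair * stats::runif(n, 0.95, 1.05))
    data.frame(
      lesion_id = seq_len(n),
      class = classes,
      flair_hyper = TRUE,
      t1_class = c(black_hole = "iso_to_CSF", demyelinated = "hypointense",
                   partially_myelinated = "hypointense",
                   remyelinated = "iso_to_NAWM")[classes],
      gd_hyper = FALSE,
      vol_t1_ml = volT1,
      vol_flair_ml = volFlair,
      max_diam_mm = stats::runif(n, 4, 12))
  })
}

#' Cohort specification for a full synthetic study
#'
#' Defaults mirror the study conditions the generator emulates: 6 healthy
#' controls and 9 MS patients, 26 atlas regions per subject (13 GM + 13
#' WM), lesion class sizes 105/111/69/7 across the MS cohort, net injected
#' dose 203 +/- 46 MBq (HC) and 209 +/- 35 MBq (MS), and 5% frame noise.
#'
#' @param nHC,nMS subject counts.
#' @param regionsGM,regionsWM atlas regions per subject and tissue class.
#' @param lesionCounts named vector of lesions per myelin-density class.
#' @param noiseCV median frame-wise relative noise of the atlas-region TACs
#'   (large VOIs).
#' @param lesionNoiseCV median frame-wise relative noise for lesion TACs;
#'   lesion VOIs are small (average volumes 0.04-0.34 mL), so their default
#'   noise is substantially higher than for atlas regions.
#' @param truthModel generating topology for region kinetics.
#' @return list of class `cohortSpec`.
#' @export
cohortSpec <- function(nHC = 6, nMS = 9, regionsGM = 13, regionsWM = 13,
                       lesionCounts = c(black_hole = 105, demyelinated = 111,
                                        partially_myelinated = 69,
                                        remyelinated = 7),
                       noiseCV = 0.05, lesionNoiseCV = 0.30,
                       truthModel = "2T3K") {
  structure(list(nHC = nHC, nMS = nMS, regionsGM = regionsGM,
                 regionsWM = regionsWM, lesionCounts = lesionCounts,
                 noiseCV = noiseCV, lesionNoiseCV = lesionNoiseCV,
                 truthModel = truthModel),
            class = "cohortSpec")
}

#' Simulate a complete synthetic study
#'
#' For every subject: metadata (dose, weight, cohort), simulated blood data
#' and the input function built from them, GM/WM region TACs with ground
#' truth, and — for MS subjects — lesion descriptors, lesion TACs and
#' contralateral NAWM ground truth, the lesions being distributed across
#' subjects. Fully reproducible from the seed, which is recorded in the
#' provenance element.
#'
#' @param spec a [cohortSpec()].
#' @param seed integer seed.
#' @return list with `subjects` (each a list with `id`, `meta`, `blood`,
#'   `input`, `tacs`, `truth`, and for MS `lesions`), `lesionTable` (pooled
#'   lesion ground truth) and `provenance`.
#' @export
simulateStudy <- function(spec = cohortSpec(), seed = 1) {
  stopifnot(inherits(spec, "cohortSpec"))
  sched <- defaultSchedule()
  nTot <- spec$nHC + spec$nMS
  subjects <- vector("list", nTot)
  ## distribute lesion classes across MS subjects round-robin
  lesionClasses <- rep(names(spec$lesionCounts), spec$lesionCounts)
  lesionOwner <- if (spec$nMS > 0 && length(lesionClasses))
    rep_len(seq_len(spec$nMS), length(lesionClasses)) else integer(0)
  lesionPool <- withLocalSeed(seed + 7L,
                              simulateLesionCohort(spec$lesionCounts))
  descriptors <- simulateLesionDescriptors(lesionPool$class, seed = seed + 11L)

  for (i in seq_len(nTot)) {
    cohort <- if (i <= spec$nHC) "HC" else "MS"
    sseed <- seed * 1000L + i
    meta <- withLocalSeed(sseed, list(
      dose = max(stats::rnorm(1, if (cohort == "HC") 203 else 209,
                              if (cohort == "HC") 46 else 35), 60),
      weight = min(max(stats::rnorm(1, 75, 12), 45), 120),
      cohort = cohort))
    feng <- withLocalSeed(sseed + 1L, {
      p <- defaultFengParams()
      amp <- exp(stats::rnorm(1, 0, 0.15))
      p$A1 <- p$A1 * amp; p$A2 <- p$A2 * amp; p$A3 <- p$A3 * amp
      p$l2 <- p$l2 * exp(stats::rnorm(1, 0, 0.1))
      p
    })
    sys <- makeSyntheticInput(seed = sseed + 2L, feng = feng,
                              miscalibration = withLocalSeed(
                                sseed + 3L, stats::runif(1, 0.7, 0.95)))
    gm <- simulateRegionTacs("GM", spec$regionsGM, sys$input, sched,
                             spec$noiseCV, spec$truthModel, seed = sseed + 4L)
    wm <- simulateRegionTacs("WM", spec$regionsWM, sys$input, sched,
                             spec$noiseCV, spec$truthModel, seed = sseed + 5L)
    subj <- list(id = sprintf("%s%02d", cohort, i), meta = meta,
                 blood = sys$blood, input = sys$input,
                 calibration = sys$calibration,
                 tacs = c(gm$tacs, wm$tacs),
                 truth = rbind(gm$truth, wm$truth))
    if (cohort == "MS") {
      mine <- which(lesionOwner == (i - spec$nHC))
      subj$lesions <- cbind(descriptors[mine, ], lesionPool[mine, -1])
    }
    subjects[[i]] <- subj
  }
  list(subjects = subjects, lesionTable = cbind(descriptors, lesionPool[-1]),
       provenance = list(seed = seed,
                         generator = as.character(
                           utils::packageVersion("myelinpet"))))
}
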