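## Independent stiff-ODE oracle for the compartment forward model: the
## two-tissue system driven by the same piecewise-linear input, integrated
## with deSolve::lsoda including the running integral of the measured
## signal, so frame averages come out of the solver itself.
odeFrameAverages <- function(model, params, input, schedule) {
  p <- c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, vB = 0)
  p[names(params)] <- params
  if (model == "1T2K") p[c("k3", "k4")] <- 0
  if (model == "2T3K") p["k4"] <- 0
  tIn <- sampleTimes(input)
  if (tIn[1] > 0) tIn <- c(0, tIn)
  cpf <- stats::approxfun(tIn, c(if (sampleTimes(input)[1] > 0) 0,
                                 plasmaActivity(input)), rule = 2)
  wbf <- stats::approxfun(tIn, c(if (sampleTimes(input)[1] > 0) 0,
                                 wholeBloodActivity(input)), rule = 2)
  rhs <- function(t, y, parms) {
    dC1 <- p[["K1"]] * cpf(t) - (p[["k2"]] + p[["k3"]]) * y[1] + p[["k4"]] * y[2]
    dC2 <- p[["k3"]] * y[1] - p[["k4"]] * y[2]
    dI <- (1 - p[["vB"]]) * (y[1] + y[2]) + p[["vB"]] * wbf(t)
    list(c(dC1, dC2, dI))
  }
  fb <- c(frameStart(schedule), scanDuration(schedule))
  out <- deSolve::lsoda(c(0, 0, 0), sort(unique(c(0, fb))), rhs, NULL,
                        rtol = 1e-11, atol = 1e-13, hmax = 0.02)
  idx <- match(fb, out[, 1])
  diff(out[idx, 4]) / frameDuration(schedule)
}

## brute-force Mann-Whitney: exact null distribution of U by enumerating
## every assignment of ranks to the first sample
bruteForceMannWhitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  Us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  pLo <- mean(Us <= U)
  pHi <- mean(Us >= U)
  list(U = U, p = min(2 * min(pLo, pHi), 1))
}

## independent restatement of the lesion classification rule table
oracleLesionClass <- function(d, tol = 0.2) {
  if (d$max_diam_mm <= 3) return("excluded")
  if (d$gd_hyper) return("active")
  if (d$t1_class == "iso_to_CSF") return("black_hole")
  if (d$t1_class == "hypointense") {
    if (d$vol_t1_ml < (1 - tol) * d$vol_flair_ml) return("partially_myelinated")
    return("demyelinated")
  }
  "remyelinated"
}
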