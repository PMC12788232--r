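#' Preprocessing configuration
#'
#' Parameters of the raw-EMG-to-envelope chain: a zero-phase 4th-order
#' Butterworth band-pass (20--400 Hz) to remove movement artifact and
#' out-of-band noise, full-wave rectification, a zero-phase 4th-order 20 Hz
#' low-pass producing the linear envelope, amplitude normalization (to the
#' MVC reference by default, or to the channel's task maximum), and linear
#' time normalization of the movement cycle onto `nPoints` samples.
#'
#' Filter orders are nominal design orders: the forward-backward (zero-phase)
#' pass doubles the effective roll-off. For the band-pass the nominal order is
#' the total filter order, i.e. a prototype of order `bandpassOrder/2` applied
#' to both band edges.
#'
#' @param bandpassLow,bandpassHigh band-pass corner frequencies in Hz.
#' @param bandpassOrder nominal band-pass order (even).
#' @param lowpassCutoff envelope low-pass cutoff in Hz.
#' @param lowpassOrder nominal low-pass order.
#' @param nPoints number of normalized-time samples per cycle.
#' @param normalization `"mvc"` (divide by the per-muscle MVC reference) or
#'   `"task_max"` (divide by the channel's maximum over the session).
#' @param samplingRate sampling rate in Hz.
#' @return A validated list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(bandpassLow = 20, bandpassHigh = 400,
                             bandpassOrder = 4, lowpassCutoff = 20,
                             lowpassOrder = 4, nPoints = 100,
                             normalization = c("mvc", "task_max"),
                             samplingRate = 2000) {
  normalization <- match.arg(normalization)
  nyq <- samplingRate / 2
  if (!(bandpassLow > 0 && bandpassLow < bandpassHigh))
    stop("need 0 < bandpassLow < bandpassHigh")
  if (bandpassHigh >= nyq)
    stop(sprintf("bandpassHigh (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 bandpassHigh, nyq))
  if (lowpassCutoff <= 0 || lowpassCutoff >= nyq)
    stop(sprintf("lowpassCutoff (%g Hz) must lie in (0, %g) Hz", lowpassCutoff, nyq))
  if (nPoints < 2) stop("nPoints must be >= 2")
  if (bandpassOrder %% 2 != 0) stop("bandpassOrder must be even")
  structure(list(bandpassLow = bandpassLow, bandpassHigh = bandpassHigh,
                 bandpassOrder = bandpassOrder, lowpassCutoff = lowpassCutoff,
                 lowpassOrder = lowpassOrder, nPoints = as.integer(nPoints),
                 normalization = normalization, samplingRate = samplingRate),
            class = "PreprocessConfig")
}

#' Movement cycle annotation
#'
#' A side-kick cycle within a trial, delimited by its start and end samples,
#' with the five phase stamps a--e (preparation a-b, knee lift b-c, kick c-d,
#' recovery d-e) when available.
#'
#' @param startSample,endSample first and last sample of the cycle (1-based).
#' @param phaseMarks optional numeric vector of 5 non-decreasing sample
#'   indices a--e inside `[startSample, endSample]`.
#' @return A list of class `MovementCycle`.
#' @export
movementCycle <- function(startSample, endSample, phaseMarks = NULL) {
  if (startSample >= endSample) stop("cycle start must precede cycle end")
  if (!is.null(phaseMarks)) {
    if (length(phaseMarks) != 5) stop("phaseMarks must have 5 stamps (a-e)")
    if (any(diff(phaseMarks) < 0)) stop("phaseMarks must be non-decreasing")
    if (phaseMarks[1] < startSample || phaseMarks[5] > endSample)
      stop("phaseMarks must lie within [startSample, endSample]")
  }
  structure(list(startSample = as.integer(startSample),
                 endSample = as.integer(endSample), phaseMarks = phaseMarks),
            class = "MovementCycle")
}

# Zero-phase IIR filtering: reflection padding plus steady-state initial
# conditions around signal::filter, applied forward then backward.
# signal::filtfilt's own edge handling distorts boundaries badly, which would
# bias onset/offset features, hence this implementation. Odd (antisymmetric)
# reflection suits zero-mean raw signals; even (symmetric) reflection suits
# non-negative rectified signals, whose odd mirror would dip below zero and
# drag the boundary envelope towards zero.
zeroPhaseFilter <- function(b, a, x, npad = 3L * max(length(a), length(b)) * 10L,
                            padtype = c("odd", "even")) {
  padtype <- match.arg(padtype)
  n <- length(x)
  if (n <= 3L * max(length(a), length(b)))
    stop("signal too short for the requested filter order")
  k <- min(n - 1L, npad)
  xp <- if (padtype == "odd")
    c(2 * x[1] - x[(k + 1):2], x, 2 * x[n] - x[(n - 1):(n - k)])
  else c(x[(k + 1):2], x, x[(n - 1):(n - k)])
  dc <- sum(b) / sum(a)
  fwd <- function(z)
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], length(b) - 1L),
                              init.y = rep(z[1] * dc, length(a) - 1L)))
  y <- fwd(xp)
  y <- rev(fwd(rev(y)))
  y[(k + 1):(k + n)]
}

asChannelMatrix <- function(signal) {
  if (is.null(dim(signal))) matrix(signal, nrow = 1) else as.matrix(signal)
}

#' Band-pass filter raw EMG
#'
#' Applies the configured zero-phase Butterworth band-pass to each channel,
#' removing the DC component, low-frequency movement artifact and
#' out-of-band high-frequency noise.
#'
#' @param signal numeric matrix (channels x samples) or vector.
#' @param config a [preprocessConfig()].
#' @return Filtered signal, same shape as the input.
#' @export
bandpassFilter <- function(signal, config = preprocessConfig()) {
  nyq <- config$samplingRate / 2
  if (config$bandpassHigh >= nyq)
    stop(sprintf("band-pass upper cutoff %g Hz is not below Nyquist %g Hz",
                 config$bandpassHigh, nyq))
  bw <- signal::butter(config$bandpassOrder / 2,
                       c(config$bandpassLow, config$bandpassHigh) / nyq,
                       type = "pass")
  x <- asChannelMatrix(signal)
  out <- t(apply(x, 1, function(ch) zeroPhaseFilter(bw$b, bw$a, ch)))
  if (is.null(dim(signal))) drop(out) else { dimnames(out) <- dimnames(x); out }
}

#' Full-wave rectification
#'
#' @param signal numeric matrix or vector.
#' @return `abs(signal)`.
#' @export
rectify <- function(signal) abs(signal)

#' Linear envelope by zero-phase low-pass smoothing
#'
#' Smooths the rectified signal with the configured zero-phase Butterworth
#' low-pass. Small negative undershoot from the linear filter is clamped to
#' zero so the envelope stays a valid non-negative activation profile.
#'
#' @inheritParams bandpassFilter
#' @return Smoothed non-negative signal, same shape as the input.
#' @export
lowpassEnvelope <- function(signal, config = preprocessConfig()) {
  nyq <- config$samplingRate / 2
  if (config$lowpassCutoff >= nyq)
    stop(sprintf("low-pass cutoff %g Hz is not below Nyquist %g Hz",
                 config$lowpassCutoff, nyq))
  lw <- signal::butter(config$lowpassOrder, config$lowpassCutoff / nyq,
                       type = "low")
  x <- asChannelMatrix(signal)
  out <- t(apply(x, 1, function(ch)
    zeroPhaseFilter(lw$b, lw$a, ch, padtype = "even")))
  out[out < 0] <- 0
  if (is.null(dim(signal))) drop(out) else { dimnames(out) <- dimnames(x); out }
}

#' Amplitude normalization of envelopes
#'
#' Divides each channel by its reference amplitude: the subject's MVC value
#' for that muscle (`mode = "mvc"`) or the channel's own maximum over the
#' supplied data (`mode = "task_max"`, after which every channel peaks at 1).
#'
#' @param envelope channels x samples envelope matrix with muscle rownames
#'   (or a vector for a single channel).
#' @param reference named numeric vector of per-muscle reference amplitudes
#'   (required for `mode = "mvc"`).
#' @param mode `"mvc"` or `"task_max"`.
#' @return Normalized envelope, same shape.
#' @export
normalizeEnvelope <- function(envelope, reference = NULL,
                              mode = c("mvc", "task_max")) {
  mode <- match.arg(mode)
  x <- asChannelMatrix(envelope)
  labs <- rownames(x) %||% as.character(seq_len(nrow(x)))
  if (mode == "mvc") {
    if (is.null(reference)) stop("mvc normalization requires a reference")
    ref <- if (!is.null(names(reference))) {
      missing <- setdiff(labs, names(reference))
      if (length(missing))
        stop("no MVC reference for muscle(s): ", paste(missing, collapse = ", "))
      reference[labs]
    } else {
      if (length(reference) != nrow(x)) stop("reference length must match channels")
      reference
    }
    bad <- which(!(ref > 0))
    if (length(bad))
      stop("non-positive MVC reference for muscle(s): ",
           paste(labs[bad], collapse = ", "))
  } else {
    ref <- apply(x, 1, max)
    bad <- which(ref <= 0)
    if (length(bad))
      stop("task_max normalization impossible for all-zero channel(s): ",
           paste(labs[bad], collapse = ", "))
  }
  out <- x / ref
  if (is.null(dim(envelope))) drop(out) else out
}

#' Time-normalize a movement cycle onto a fixed grid
#'
#' Linearly interpolates the `[start, end]` segment of each channel onto
#' `nPoints` equally spaced normalized-time samples (0--100% of the cycle),
#' removing cycle-duration variation between trials. Endpoints are preserved
#' exactly.
#'
#' @param envelope channels x samples matrix (or vector).
#' @param cycle a [movementCycle()] within the signal bounds.
#' @param nPoints number of output samples per channel.
#' @return channels x `nPoints` matrix.
#' @export
timeNormalize <- function(envelope, cycle, nPoints = 100) {
  x <- asChannelMatrix(envelope)
  if (cycle$endSample > ncol(x) || cycle$startSample < 1)
    stop("cycle exceeds signal bounds")
  idx <- cycle$startSample:cycle$endSample
  if (length(idx) < 2) stop("degenerate cycle: need at least 2 samples")
  target <- seq(cycle$startSample, cycle$endSample, length.out = nPoints)
  out <- t(apply(x, 1, function(ch)
    stats::approx(idx, ch[idx], xout = target)$y))
  rownames(out) <- rownames(x)
  out
}

#' Average time-normalized trials into an activation matrix
#'
#' Elementwise arithmetic mean of the (already time-normalized) trial
#' matrices, producing the single representative activation profile used as
#' the factorization input.
#'
#' @param trials list of muscles x nPoints matrices with identical dimensions
#'   and muscle labels.
#' @return An [ActivationMatrix-class].
#' @export
averageTrials <- function(trials) {
  if (length(trials) < 1) stop("need at least one trial")
  ref <- trials[[1]]
  for (tr in trials[-1]) {
    if (!identical(dim(tr), dim(ref))) stop("trial shape mismatch")
    if (!identical(rownames(tr), rownames(ref))) stop("trial muscle label mismatch")
  }
  m <- Reduce(`+`, trials) / length(trials)
  m[m < 0] <- 0
  activationMatrix(m, nTrialsAveraged = length(trials))
}

#' Run the full preprocessing chain on one raw trial
#'
#' Band-pass, rectification, low-pass envelope, amplitude normalization and
#' time normalization of the annotated movement cycle, in that order.
#'
#' @param trial a trial object with elements `signal` (channels x samples,
#'   muscle rownames), `samplingRate` and `events` (named list a--e of
#'   second-valued stamps), as produced by [synthesizeTrial()] or
#'   [readTrialCsv()] plus [readEventsJson()].
#' @param config a [preprocessConfig()].
#' @param reference per-muscle MVC amplitudes (for `normalization = "mvc"`).
#' @return muscles x `nPoints` normalized envelope matrix.
#' @export
preprocessTrial <- function(trial, config = preprocessConfig(), reference = NULL) {
  env <- lowpassEnvelope(rectify(bandpassFilter(trial$signal, config)), config)
  env <- normalizeEnvelope(env, reference, mode = config$normalization)
  ev <- unlist(trial$events)
  fs <- trial$samplingRate %||% config$samplingRate
  cyc <- movementCycle(max(1L, round(ev[["a"]] * fs) + 1L),
                       min(ncol(env), round(ev[["e"]] * fs) + 1L))
  timeNormalize(env, cyc, config$nPoints)
}

#' Preprocess a session: 6 trials to one activation matrix
#'
#' @param session a session record (list with `trials` and `mvc`) as stored
#'   in a [StudyDataset-class].
#' @param config a [preprocessConfig()].
#' @return An [ActivationMatrix-class], the trial average.
#' @export
preprocessSession <- function(session, config = preprocessConfig()) {
  ref <- if (config$normalization == "mvc") session$mvc else NULL
  averageTrials(lapply(session$trials, preprocessTrial,
                       config = config, reference = ref))
}
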