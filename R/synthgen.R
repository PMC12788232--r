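#' Default jump-height table (cm) per protocol and time point
#'
#' Mean and SD of the recorded (best-of-three) countermovement jump height for
#' each protocol at 6, 8 and 10 minutes post-intervention. These defaults are
#' the study conditions the generator emulates.
#'
#' @return data.frame with columns `protocol`, `timePoint`, `mean`, `sd`.
#' @export
defaultJumpTable <- function() {
  data.frame(
    protocol  = rep(c("SQG", "RBG", "ESG"), each = 3),
    timePoint = rep(c(6L, 8L, 10L), times = 3),
    mean = c(46.5, 47.8, 46.2,   47.0, 46.2, 45.7,   49.1, 48.9, 47.5),
    sd   = c(3.2, 3.1, 3.3,      2.9, 3.0, 3.1,      2.8, 2.7, 2.9))
}

#' Synthetic-study generator configuration
#'
#' Defines the simulated crossover study: 18 subjects, the three conditioning
#' protocols (ESG/RBG/SQG), six maximal side-kick trials per session recorded
#' over 15 EMG channels at 2000 Hz, and three jumps at each of three
#' post-intervention time points with heights patterned on the default jump
#' table.
#'
#' @param nSubjects number of subjects (default 18).
#' @param nMuscles number of EMG channels (default 15, the full montage).
#' @param nSynergiesTrue number of generative synergies (default 3).
#' @param nTrials side-kick trials per session (default 6).
#' @param noiseSd additive Gaussian noise SD as a fraction of the mean clean
#'   envelope amplitude (default 0.05).
#' @param trialJitter trial-duration jitter as a fraction (default 0.10,
#'   i.e. +/-10%).
#' @param carrierBand Hz pair for the band-limited EMG carrier.
#' @param samplingRate sampling rate in Hz (default 2000).
#' @param trialDuration nominal trial duration in seconds.
#' @param protocolEffectSize multiplicative boost applied to the
#'   protocol-specific muscles (default 0.25, i.e. +25%).
#' @param subjectVariability SD of the log-normal per-subject jitter on the
#'   ground-truth weights.
#' @param jumpTable data.frame as [defaultJumpTable()].
#' @param jumpCorrelation correlation of jump heights across the nine
#'   protocol x time cells induced by the shared subject effect (default 0.5,
#'   matching the repeated-measures correlation assumed by the power
#'   analysis).
#' @param seed global integer seed.
#' @return A validated list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(nSubjects = 18, nMuscles = 15, nSynergiesTrue = 3,
                            nTrials = 6, noiseSd = 0.05, trialJitter = 0.10,
                            carrierBand = c(20, 400), samplingRate = 2000,
                            trialDuration = 1.2, protocolEffectSize = 0.25,
                            subjectVariability = 0.05,
                            jumpTable = defaultJumpTable(),
                            jumpCorrelation = 0.5, seed = 1) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (nSynergiesTrue >= nMuscles) stop("need fewer synergies than muscles")
  if (any(jumpTable$mean <= 0)) stop("configured jump means must be positive")
  if (jumpCorrelation < 0 || jumpCorrelation >= 1) stop("jumpCorrelation must be in [0, 1)")
  structure(list(nSubjects = as.integer(nSubjects), nMuscles = as.integer(nMuscles),
                 nSynergiesTrue = as.integer(nSynergiesTrue),
                 nTrials = as.integer(nTrials), noiseSd = noiseSd,
                 trialJitter = trialJitter, carrierBand = carrierBand,
                 samplingRate = samplingRate, trialDuration = trialDuration,
                 protocolEffectSize = protocolEffectSize,
                 subjectVariability = subjectVariability, jumpTable = jumpTable,
                 jumpCorrelation = jumpCorrelation, seed = as.integer(seed)),
            class = "GeneratorConfig")
}

# Protocol-specific multiplicative weight modifiers. Directions mirror the
# observed between-protocol weight differences: the stimulation-augmented
# squat (ESG) boosts hip/knee extensors (GM, RF, RFR), band-resisted stepping
# (RBG) boosts frontal-plane stabilizers (VL, GMed), and the heavy squat
# (SQG) boosts the knee extensors (RF, RFR). Magnitudes are configuration,
# not empirical claims.
buildProtocolEffects <- function(labels, effectSize) {
  eff <- function(boost) {
    v <- rep(1, length(labels)); names(v) <- labels
    v[intersect(boost, labels)] <- 1 + effectSize
    v
  }
  list(ESG = eff(c("GM", "RF", "RFR")),
       RBG = eff(c("VL", "GMed")),
       SQG = eff(c("RF", "RFR")))
}

#' Conditioning-protocol metadata
#'
#' Descriptive parameters of the three intervention protocols emulated by the
#' generator. The NMES stimulation frequency is reported inconsistently in
#' the source protocol descriptions (75 Hz in the equipment description,
#' 80 Hz in the protocol table); both values are recorded here unresolved.
#'
#' @return Nested list of protocol descriptions.
#' @export
protocolMetadata <- function() {
  list(
    ESG = list(label = "Electrical Stimulation Group",
               exercise = "barbell back squat + synchronized NMES on quadriceps",
               loadIntensity = "70% 1RM",
               nmes = list(frequencyHz = c(75, 80), pulseWidthUs = 400,
                           intensity = "90% of maximal tolerated")),
    RBG = list(label = "Resistance Band Group",
               exercise = "band-resisted lateral steps",
               loadIntensity = "20% body weight", nmes = NULL),
    SQG = list(label = "Squat Group",
               exercise = "heavy barbell back squat",
               loadIntensity = "90% 1RM", nmes = NULL))
}

#' Generate a ground-truth synergy structure
#'
#' Draws a non-negative muscles x synergies weight matrix with unit-norm,
#' well-separated columns (each synergy dominated by a distinct random muscle
#' subset; rejection sampling guarantees all pairwise column cosine
#' similarities stay below `maxCosine`) and unimodal activation coefficients:
#' one Gaussian bump per synergy with distinct centers spread over the
#' normalized 0--100 timeline.
#'
#' @param nMuscles number of muscles.
#' @param nSynergies number of synergies (< `nMuscles`).
#' @param seed integer seed.
#' @param maxCosine separation bound on pairwise weight-column cosines.
#' @param maxAttempts rejection-sampling cap; exceeded separation is an error.
#' @param protocolEffectSize passed to the protocol weight modifiers.
#' @return A [GroundTruth-class].
#' @export
generateGroundTruth <- function(nMuscles = 15, nSynergies = 3, seed = 1,
                                maxCosine = 0.6, maxAttempts = 200,
                                protocolEffectSize = 0.25) {
  if (nSynergies >= nMuscles) stop("nSynergies must be smaller than nMuscles")
  labels <- if (nMuscles == length(muscleRegistry())) muscleRegistry()
            else paste0("M", seq_len(nMuscles))
  withSeed(seed, {
    nDom <- max(2L, round(nMuscles / 3))
    W <- NULL
    for (attempt in seq_len(maxAttempts)) {
      cand <- sapply(seq_len(nSynergies), function(i) {
        w <- stats::runif(nMuscles, 0.02, 0.10)
        dom <- sample.int(nMuscles, nDom)
        w[dom] <- stats::runif(nDom, 0.6, 1)
        w
      })
      cand <- sweep(cand, 2, sqrt(colSums(cand^2)), "/")
      if (all(pairwiseCosines(cand) < maxCosine)) { W <- cand; break }
    }
    if (is.null(W))
      stop(sprintf("could not draw %d weight columns with pairwise cosine < %g in %d attempts",
                   nSynergies, maxCosine, maxAttempts))
    rownames(W) <- labels
    colnames(W) <- paste0("SYN", seq_len(nSynergies))
    grid <- timeGrid(100)
    centers <- seq(20, 80, length.out = nSynergies) +
      stats::runif(nSynergies, -5, 5)
    widths <- stats::runif(nSynergies, 6, 9)
    C <- t(sapply(seq_len(nSynergies), function(i)
      exp(-0.5 * ((grid - centers[i]) / widths[i])^2)))
    rownames(C) <- colnames(W)
    new("GroundTruth", weights = W, coefficients = C,
        protocolEffects = buildProtocolEffects(labels, protocolEffectSize))
  })
}

# Constant-modulus random-FM carrier: unit-amplitude sinusoid whose
# instantaneous frequency performs a reflected random walk well inside the
# carrier band. Its rectified mean is exactly 2/pi regardless of the
# frequency path, so rectification + low-pass smoothing of envelope * carrier
# recovers the envelope (the residual ripple sits at twice the instantaneous
# frequency, far above the smoothing cutoff). Scaled so E[|carrier|] = 1.
fmCarrier <- function(nSamp, samplingRate, carrierBand = c(20, 400)) {
  # keep the frequency path in the flat middle of the analysis band (the
  # physiological sEMG power concentration, ~70-250 Hz for a 20-400 Hz band)
  # so the band-pass stage is transparent to the carrier
  lo <- carrierBand[1] + 0.15 * diff(carrierBand)
  hi <- carrierBand[1] + 0.60 * diff(carrierBand)
  f <- numeric(nSamp)
  f[1] <- stats::runif(1, lo, hi)
  steps <- stats::rnorm(nSamp - 1, 0, 40 / sqrt(samplingRate))
  for (i in 2:nSamp) {
    cand <- f[i - 1] + steps[i - 1]
    if (cand < lo) cand <- 2 * lo - cand
    if (cand > hi) cand <- 2 * hi - cand
    f[i] <- cand
  }
  phase <- stats::runif(1, 0, 2 * pi) + cumsum(2 * pi * f / samplingRate)
  sin(phase) * pi / 2
}

#' Synthesize one raw-like EMG trial
#'
#' Builds the clean activation envelope E = (modified W) C for the requested
#' protocol, upsamples it from the 100-point normalized grid to the trial
#' duration, and multiplies it by a zero-mean band-limited constant-modulus
#' carrier (random-FM sinusoid) scaled so that rectification plus low-pass
#' smoothing recovers E. Additive Gaussian noise is applied at `noiseSd` times the
#' mean clean envelope amplitude. Cycle event stamps a--e are placed with a
#' 5% pad on each side of the trial.
#'
#' @param truth a [GroundTruth-class].
#' @param protocol one of the protocol labels carried by `truth`.
#' @param noiseSd noise fraction (>= 0).
#' @param seed integer seed.
#' @param samplingRate Hz.
#' @param duration trial duration in seconds.
#' @param carrierBand Hz pair for the carrier band.
#' @param subjectWeights optional per-subject weight matrix overriding the
#'   ground-truth weights (same shape).
#' @return A trial object: list with `signal` (muscles x samples, arbitrary
#'   units), `samplingRate`, `protocol`, `events` (named list a--e in
#'   seconds) and `cleanEnvelope` (the muscles x 100 generative envelope).
#' @export
synthesizeTrial <- function(truth, protocol, noiseSd = 0.05, seed = 1,
                            samplingRate = 2000, duration = 1.2,
                            carrierBand = c(20, 400), subjectWeights = NULL) {
  effs <- protocolEffects(truth)
  if (!protocol %in% names(effs))
    stop("unknown protocol '", protocol, "'; allowed: ",
         paste(names(effs), collapse = ", "))
  W <- (subjectWeights %||% trueWeights(truth)) * effs[[protocol]]
  C <- trueCoefficients(truth)
  E100 <- W %*% C
  nSamp <- round(duration * samplingRate)
  pad <- round(0.05 * nSamp)
  aSamp <- pad + 1L
  eSamp <- nSamp - pad
  # envelope over raw samples: cycle region interpolates the 100-point grid,
  # pads hold the boundary values
  cycIdx <- seq(1, 100, length.out = eSamp - aSamp + 1L)
  E <- t(apply(E100, 1, function(row) {
    mid <- stats::approx(seq_len(100), row, xout = cycIdx)$y
    c(rep(row[1], aSamp - 1L), mid, rep(row[100], nSamp - eSamp))
  }))
  sigAmp <- mean(E100)
  withSeed(seed, {
    carrier <- t(replicate(nrow(E),
                           fmCarrier(nSamp, samplingRate, carrierBand)))
    raw <- E * carrier
    if (noiseSd > 0)
      raw <- raw + matrix(stats::rnorm(length(raw), 0, noiseSd * sigAmp),
                          nrow = nrow(raw))
    rownames(raw) <- rownames(W)
    fs <- samplingRate
    cyc <- (eSamp - aSamp) / fs
    a <- (aSamp - 1) / fs
    list(signal = raw, samplingRate = samplingRate, protocol = protocol,
         events = list(a = a, b = a + 0.30 * cyc, c = a + 0.50 * cyc,
                       d = a + 0.75 * cyc, e = (eSamp - 1) / fs),
         cleanEnvelope = E100)
  })
}

#' Simulate jump flight times for a study
#'
#' Draws the recorded (best-of-three) jump height of each subject x protocol
#' x time-point cell from a normal distribution with the configured cell mean
#' and SD, decomposed into a shared standard-normal subject effect (weight
#' `sqrt(rho)`) plus independent cell noise (weight `sqrt(1-rho)`) so that
#' repeated measures correlate at `rho` while keeping the configured marginal
#' moments. The two remaining jumps of each cell are scaled slightly below
#' the best one, and heights are converted to flight times by inverting
#' h = g t^2 / 8 (heights truncated just above zero).
#'
#' @param nSubjects number of subjects.
#' @param jumpTable data.frame as [defaultJumpTable()].
#' @param correlation repeated-measures correlation rho in [0, 1).
#' @param seed integer seed.
#' @param gravity m/s^2.
#' @return data.frame with columns `subject`, `protocol`, `timePoint`,
#'   `jumpIndex`, `height` (cm) and `flightTime` (s).
#' @export
simulateJumps <- function(nSubjects = 18, jumpTable = defaultJumpTable(),
                          correlation = 0.5, seed = 1, gravity = 9.81) {
  if (any(jumpTable$mean <= 0)) stop("configured jump means must be positive")
  withSeed(seed, {
    rows <- vector("list", nSubjects * nrow(jumpTable))
    k <- 0L
    for (s in seq_len(nSubjects)) {
      u <- stats::rnorm(1)
      for (r in seq_len(nrow(jumpTable))) {
        cell <- jumpTable[r, ]
        best <- cell$mean + cell$sd * (sqrt(correlation) * u +
                                       sqrt(1 - correlation) * stats::rnorm(1))
        best <- max(best, 1e-3)
        others <- best * stats::runif(2, 0.93, 0.995)
        h <- c(best, others)[sample.int(3)]
        k <- k + 1L
        rows[[k]] <- data.frame(subject = s, protocol = cell$protocol,
                                timePoint = cell$timePoint, jumpIndex = 1:3,
                                height = h)
      }
    }
    out <- do.call(rbind, rows)
    out$flightTime <- sqrt(8 * (out$height / 100) / gravity)
    out
  })
}

#' Generate a complete synthetic study
#'
#' Builds the full crossover dataset: a seeded ground-truth synergy structure,
#' per-subject log-normally jittered weights, `nTrials` raw-like EMG trials
#' per subject x protocol session (with +/- `trialJitter` duration jitter),
#' per-subject MVC reference amplitudes (set above the subject's maximum
#' clean envelope so normalized activations stay below 1), and jump flight
#' times reproducing the configured height table under h = g t^2 / 8.
#' A single global seed fans out into per-stage child seeds
#' (see [childSeed()]), so subsets rerun in isolation match the full run.
#'
#' @param config a [generatorConfig()].
#' @return A [StudyDataset-class] with the ground truth attached.
#' @export
generateStudy <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "GeneratorConfig"))
  truth <- generateGroundTruth(config$nMuscles, config$nSynergiesTrue,
                               seed = childSeed(config$seed, 1),
                               protocolEffectSize = config$protocolEffectSize)
  jumps <- simulateJumps(config$nSubjects, config$jumpTable,
                         correlation = config$jumpCorrelation,
                         seed = childSeed(config$seed, 2))
  protos <- names(protocolEffects(truth))
  C <- trueCoefficients(truth)
  subjectsList <- lapply(seq_len(config$nSubjects), function(s) {
    Ws <- withSeed(childSeed(config$seed, 3, s),
      trueWeights(truth) *
        matrix(exp(stats::rnorm(length(trueWeights(truth)), 0,
                                config$subjectVariability)),
               nrow = config$nMuscles))
    # MVC reference: comfortably above the largest clean envelope value the
    # subject can produce in any protocol
    maxEnv <- Reduce(pmax, lapply(protos, function(p)
      apply((Ws * protocolEffects(truth)[[p]]) %*% C, 1, max)))
    mvc <- 1.25 * maxEnv
    names(mvc) <- rownames(trueWeights(truth))
    sessions <- lapply(seq_along(protos), function(pi) {
      p <- protos[pi]
      durs <- withSeed(childSeed(config$seed, 4, s, pi),
        config$trialDuration *
          (1 + stats::runif(config$nTrials, -config$trialJitter,
                            config$trialJitter)))
      trials <- lapply(seq_len(config$nTrials), function(j)
        synthesizeTrial(truth, p, noiseSd = config$noiseSd,
                        seed = childSeed(config$seed, 5, s, pi, j),
                        samplingRate = config$samplingRate,
                        duration = durs[j], carrierBand = config$carrierBand,
                        subjectWeights = Ws))
      jp <- jumps[jumps$subject == s & jumps$protocol == p, ]
      list(trials = trials, mvc = mvc,
           jumps = data.frame(timePoint = jp$timePoint, jumpIndex = jp$jumpIndex,
                              flightTime = jp$flightTime))
    })
    names(sessions) <- protos
    list(id = sprintf("S%02d", s), sessions = sessions, subjectWeights = Ws)
  })
  new("StudyDataset", subjectData = subjectsList, truth = truth,
      config = unclass(config))
}
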