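test_that("ground truth has the contracted shape, separation and determinism", {
  gt <- generateGroundTruth(15, 3, seed = 1)
  W <- trueWeights(gt)
  C <- trueCoefficients(gt)
  expect_identical(dim(W), c(15L, 3L))
  expect_identical(dim(C), c(3L, 100L))
  expect_true(all(W >= 0) && all(C >= 0))
  expect_equal(sqrt(colSums(W^2)), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # separation guaranteed by rejection sampling, checked directly per pair
  expect_true(all(synergetics:::pairwiseCosines(W) < 0.8))
  # unimodal bumps with distinct centers
  peaks <- apply(C, 1, which.max)
  expect_true(all(diff(sort(peaks)) > 0))
  expect_identical(serialize(generateGroundTruth(15, 3, seed = 1), NULL),
                   serialize(gt, NULL))
  expect_false(identical(trueWeights(generateGroundTruth(15, 3, seed = 2)), W))
  expect_error(generateGroundTruth(5, 5), "smaller")
  # impossible separation bound triggers an explicit failure
  expect_error(generateGroundTruth(15, 6, seed = 1, maxCosine = 0.01,
                                   maxAttempts = 5), "cosine")
})

test_that("synthesized trials are recoverable by the preprocessing chain", {
  gt <- generateGroundTruth(15, 3, seed = 4)
  cfg <- preprocessConfig(normalization = "task_max")
  tr <- synthesizeTrial(gt, "ESG", noiseSd = 0, seed = 11)
  env <- preprocessTrial(tr, cfg)
  r <- vapply(seq_len(15),
              function(i) cor(env[i, ], tr$cleanEnvelope[i, ]), numeric(1))
  expect_true(all(r > 0.95))
  expect_error(synthesizeTrial(gt, "XXX"), "ESG, RBG, SQG")
})

test_that("a zero-coefficient synergy contributes nothing to the envelope", {
  gt <- generateGroundTruth(15, 3, seed = 5)
  C0 <- trueCoefficients(gt)
  C0[3, ] <- 0
  gtZero <- new("GroundTruth", weights = trueWeights(gt), coefficients = C0,
                protocolEffects = protocolEffects(gt))
  trZero <- synthesizeTrial(gtZero, "SQG", noiseSd = 0, seed = 3)
  expected <- (trueWeights(gt)[, 1:2] * protocolEffects(gt)$SQG) %*%
    trueCoefficients(gt)[1:2, ]
  expect_equal(trZero$cleanEnvelope, expected, ignore_attr = TRUE)
})

test_that("trial sample paths differ by seed but share the expected envelope", {
  gt <- generateGroundTruth(15, 3, seed = 6)
  cfg <- preprocessConfig(normalization = "task_max")
  nTr <- 50
  trials <- lapply(seq_len(nTr), function(s)
    synthesizeTrial(gt, "RBG", noiseSd = 0, seed = s, duration = 0.6))
  expect_false(identical(trials[[1]]$signal, trials[[2]]$signal))
  E <- trials[[1]]$cleanEnvelope
  # raw (un-normalized) envelope chain so amplitudes stay comparable
  envs <- lapply(trials, function(tr) {
    env <- lowpassEnvelope(rectify(bandpassFilter(tr$signal, cfg)), cfg)
    ev <- unlist(tr$events)
    fs <- tr$samplingRate
    timeNormalize(env, movementCycle(round(ev[["a"]] * fs) + 1,
                                     round(ev[["e"]] * fs) + 1), 100)
  })
  # per-channel time-averaged recovered amplitude approaches the ground truth
  # within Monte-Carlo error (3 SE) plus the small deterministic chain
  # attenuation (band-edge gain of the band-pass over the carrier path and
  # envelope smoothing, together bounded by 2%)
  chanMeans <- sapply(envs, rowMeans)        # 15 x nTr
  est <- rowMeans(chanMeans)
  truth <- rowMeans(E)
  se <- apply(chanMeans, 1, sd) / sqrt(nTr)
  expect_true(all(abs(est - truth) < 3 * se + 0.02 * truth))
  # the expectation itself is seed-invariant: two disjoint seed groups agree
  # within their joint Monte-Carlo error
  g1 <- rowMeans(chanMeans[, 1:25]); g2 <- rowMeans(chanMeans[, 26:50])
  seDiff <- sqrt(apply(chanMeans[, 1:25], 1, var) / 25 +
                 apply(chanMeans[, 26:50], 1, var) / 25)
  expect_true(all(abs(g1 - g2) < 4 * seDiff))
})

test_that("generateStudy builds the full crossover design with invariants", {
  ds <- generateStudy(generatorConfig(nSubjects = 2, nTrials = 3,
                                      trialDuration = 0.7, seed = 3))
  expect_s4_class(ds, "StudyDataset")
  expect_identical(nSubjects(ds), 2L)
  for (subj in subjects(ds)) {
    expect_identical(names(subj$sessions), c("ESG", "RBG", "SQG"))
    for (ses in subj$sessions) {
      expect_length(ses$trials, 3L)
      for (tr in ses$trials) {
        expect_identical(nrow(tr$signal), 15L)
        expect_true(all(diff(unlist(tr$events)) > 0))
      }
      expect_true(all(ses$mvc > 0))
      expect_true(all(ses$jumps$flightTime > 0))
      expect_identical(nrow(ses$jumps), 9L)  # 3 time points x 3 jumps
    }
  }
  ds2 <- generateStudy(generatorConfig(nSubjects = 2, nTrials = 3,
                                       trialDuration = 0.7, seed = 3))
  expect_identical(serialize(ds2, NULL), serialize(ds, NULL))
  expect_error(generatorConfig(jumpTable = within(defaultJumpTable(),
                                                  mean[1] <- -1)),
               "positive")
})

test_that("default study dimensions match the emulated design", {
  ds <- generateStudy(generatorConfig(trialDuration = 0.5))
  expect_identical(nSubjects(ds), 18L)
  s1 <- subjects(ds)[[1]]
  expect_length(s1$sessions, 3L)
  expect_length(s1$sessions$ESG$trials, 6L)
  expect_identical(nrow(s1$sessions$ESG$trials[[1]]$signal), 15L)
})

test_that("simulated jump heights reproduce the configured table", {
  j <- simulateJumps(1000, seed = 42)
  # flight time inverts the flight-time formula exactly
  expect_equal(jumpHeight(j$flightTime), j$height, tolerance = 1e-9)
  best <- tapply(j$height, list(j$subject, j$protocol, j$timePoint), max)
  esg6 <- best[, "ESG", "6"]
  se <- sd(esg6) / sqrt(length(esg6))
  expect_lt(abs(mean(esg6) - 49.1), 3 * se)
  # marginal spread close to the configured SD
  expect_equal(sd(esg6), 2.8, tolerance = 0.15)
})

test_that("protocol weight modifiers point in the configured directions", {
  gt <- generateGroundTruth(15, 3, seed = 9, protocolEffectSize = 0.25)
  eff <- protocolEffects(gt)
  boosted <- function(p) names(eff[[p]])[eff[[p]] > 1]
  expect_setequal(boosted("ESG"), c("GM", "RF", "RFR"))
  expect_setequal(boosted("RBG"), c("VL", "GMed"))
  expect_setequal(boosted("SQG"), c("RF", "RFR"))
  eEsg <- synthesizeTrial(gt, "ESG", noiseSd = 0, seed = 1)$cleanEnvelope
  eRbg <- synthesizeTrial(gt, "RBG", noiseSd = 0, seed = 1)$cleanEnvelope
  expect_true(all(rowSums(eEsg)[c("GM", "RF", "RFR")] >
                  rowSums(eRbg)[c("GM", "RF", "RFR")]))
  expect_true(all(rowSums(eRbg)[c("VL", "GMed")] >
                  rowSums(eEsg)[c("VL", "GMed")]))
})
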