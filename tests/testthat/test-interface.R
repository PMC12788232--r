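test_that("trial, events, MVC and jump files round-trip exactly", {
  dir <- withr::local_tempdir()
  gt <- generateGroundTruth(15, 3, seed = 3)
  tr <- synthesizeTrial(gt, "ESG", noiseSd = 0.05, seed = 2, duration = 0.4)
  tf <- file.path(dir, "trial.csv")
  writeTrialCsv(tr, tf)
  back <- readTrialCsv(tf)
  expect_equal(back$signal, tr$signal, tolerance = 1e-12)
  expect_identical(back$samplingRate, 2000)

  ef <- file.path(dir, "ev.json")
  writeEventsJson(tr$events, ef)
  expect_equal(readEventsJson(ef), tr$events, tolerance = 1e-12)

  mvc <- setNames(runif(15, 0.5, 2), muscleRegistry())
  mf <- file.path(dir, "mvc.csv")
  writeMvcCsv(mvc, mf)
  expect_equal(readMvcCsv(mf), mvc, tolerance = 1e-15)

  j <- simulateJumps(3, seed = 5)
  jf <- file.path(dir, "jumps.csv")
  writeJumpsCsv(j, jf)
  back <- readJumpsCsv(jf)
  expect_equal(back$flightTime, j$flightTime, tolerance = 1e-15)
  expect_identical(back$protocol, j$protocol)
})

test_that("malformed input files produce located, named errors", {
  dir <- withr::local_tempdir()
  gt <- generateGroundTruth(15, 3, seed = 3)
  tr <- synthesizeTrial(gt, "ESG", seed = 2, duration = 0.3)
  tf <- file.path(dir, "trial.csv")
  writeTrialCsv(tr, tf)
  # drop one muscle column: error names the absent muscle
  df <- read.csv(tf, check.names = FALSE)
  write.csv(df[, setdiff(names(df), "GMed")], file.path(dir, "bad.csv"),
            row.names = FALSE)
  expect_error(readTrialCsv(file.path(dir, "bad.csv")), "GMed")
  # non-numeric cell is located
  df2 <- df
  df2$GM[3] <- "oops"
  write.csv(df2, file.path(dir, "bad2.csv"), row.names = FALSE, quote = FALSE)
  expect_error(suppressWarnings(readTrialCsv(file.path(dir, "bad2.csv"))),
               "row 3, column 'GM'")
  # events must increase
  jsonlite::write_json(list(a = 0.5, b = 0.6, c = 0.7, d = 0.8, e = 0.1),
                       file.path(dir, "ev.json"), auto_unbox = TRUE)
  expect_error(readEventsJson(file.path(dir, "ev.json")), "increasing")
  # unknown protocol and non-positive flight times
  writeJumpsCsv(data.frame(subject = 1, protocol = "XXX", timePoint = 6,
                           jumpIndex = 1, flightTime = 0.5),
                file.path(dir, "j.csv"))
  expect_error(readJumpsCsv(file.path(dir, "j.csv")), "XXX")
})

test_that("a study written to disk reloads into the same analysis input", {
  dir <- withr::local_tempdir()
  ds <- generateStudy(generatorConfig(nSubjects = 2, nTrials = 2,
                                      trialDuration = 0.5, seed = 11))
  writeStudy(ds, dir)
  back <- loadStudy(dir)
  expect_identical(nSubjects(back), 2L)
  cfg <- preprocessConfig()
  s1 <- subjects(ds)[[1]]$sessions$ESG
  s1b <- subjects(back)[[1]]$sessions$ESG
  expect_equal(as.matrix(preprocessSession(s1b, cfg)),
               as.matrix(preprocessSession(s1, cfg)), tolerance = 1e-9)
})

test_that("pipeline configuration survives a YAML round trip", {
  dir <- withr::local_tempdir()
  cfg <- pipelineConfig(generator = generatorConfig(nSubjects = 5, seed = 4,
                                                    noiseSd = 0.07),
                        preprocess = preprocessConfig(normalization = "task_max"),
                        seed = 99, outDir = file.path(dir, "out"))
  f <- file.path(dir, "config.yaml")
  writePipelineConfig(cfg, f)
  back <- readPipelineConfig(f)
  expect_equal(back$generator, cfg$generator, tolerance = 1e-15)
  expect_equal(back$preprocess, cfg$preprocess)
  expect_identical(back$seed, cfg$seed)
  expect_identical(back$nmf, cfg$nmf)
})

smallPipelineConfig <- function(dir, nSubjects = 4, seed = 21, noiseSd = 0.05,
                                effect = 0.25) {
  pipelineConfig(
    generator = generatorConfig(nSubjects = nSubjects, nTrials = 3,
                                trialDuration = 0.6, noiseSd = noiseSd,
                                protocolEffectSize = effect, seed = seed),
    nmf = list(nRestarts = 4, maxIter = 300, tol = 1e-6, threshold = 0.90,
               maxOrder = 5),
    seed = seed, outDir = dir)
}

test_that("the pipeline is deterministic given the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- runPipeline(smallPipelineConfig(d1, nSubjects = 3))
  r2 <- runPipeline(smallPipelineConfig(d2, nSubjects = 3))
  dataFiles <- setdiff(names(r1$manifest$outputs), "")
  h1 <- unlist(r1$manifest$outputs)
  h2 <- unlist(r2$manifest$outputs)
  expect_identical(unname(h1), unname(h2))
  # manifest carries the decisions in force and the log records them
  expect_identical(r1$manifest$decisions$sstConvention, "uncentered")
  log <- readLines(file.path(d1, "run.log"))
  expect_true(any(grepl("normalization mode", log)))
  expect_true(any(grepl("activation threshold", log)))
})

test_that("injected protocol effects are recovered by the weight comparison", {
  dir <- withr::local_tempdir()
  res <- runPipeline(smallPipelineConfig(dir, nSubjects = 6, seed = 31,
                                         noiseSd = 0.02, effect = 0.4))
  ws <- res$weightStats
  # the ESG-boosted right rectus femoris must surface as ESG > RBG in the
  # synergy where it dominates
  rfr <- ws[ws$muscle == "RFR" & grepl("ESG > RBG", ws$posthoc), ]
  expect_gte(nrow(rfr), 1)
  gmed <- ws[ws$muscle == "GMed" & grepl("RBG > ESG", ws$posthoc), ]
  expect_gte(nrow(gmed), 1)
})

test_that("a null jump configuration rarely yields surviving annotations", {
  # all protocol x time cells share one mean; the familywise rate of any
  # surviving post-hoc annotation across the three time-point families is
  # ~10%, so the count over 50 seeds must stay inside its 99.9% binomial
  # envelope
  tab <- nullJumpTable()
  nAnn <- 0
  for (s in 1:50) {
    j <- simulateJumps(18, tab, seed = s)
    res <- analyzeJumps(j)
    ann <- unlist(lapply(res$byTimePoint, function(r)
      if (is.null(r$posthoc)) "" else r$posthoc$direction))
    if (any(nzchar(ann))) nAnn <- nAnn + 1
  }
  expect_lte(nAnn, qbinom(0.999, 50, 0.10))
})
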