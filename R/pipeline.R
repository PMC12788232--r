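#' Pipeline configuration
#'
#' Bundles all stage configurations for an end-to-end run: the synthetic
#' study generator, the preprocessing chain, the factorization/order
#' selection settings, the temporal-feature threshold and the statistical
#' layer. Serializes losslessly to YAML via [writePipelineConfig()].
#'
#' @param generator a [generatorConfig()].
#' @param preprocess a [preprocessConfig()].
#' @param nmf list with `nRestarts`, `maxIter`, `tol`, `threshold`,
#'   `maxOrder`.
#' @param timing list with `threshold` (activation threshold fraction).
#' @param stats list with `alpha`.
#' @param seed global seed fanning out to all stages.
#' @param outDir output directory for [runPipeline()].
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(generator = generatorConfig(),
                           preprocess = preprocessConfig(),
                           nmf = list(nRestarts = 20, maxIter = 1000,
                                      tol = 1e-6, threshold = 0.90,
                                      maxOrder = 8),
                           timing = list(threshold = 0.20),
                           stats = list(alpha = 0.05),
                           seed = 1, outDir = tempfile("synergetics_run_")) {
  stopifnot(inherits(generator, "GeneratorConfig"),
            inherits(preprocess, "PreprocessConfig"))
  if (nmf$threshold <= 0 || nmf$threshold > 1) stop("nmf$threshold must be in (0, 1]")
  structure(list(generator = generator, preprocess = preprocess, nmf = nmf,
                 timing = timing, stats = stats, seed = as.integer(seed),
                 outDir = outDir),
            class = "PipelineConfig")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipelineConfig()].
#' @param path YAML file path.
#' @return `writePipelineConfig`: the path, invisibly;
#'   `readPipelineConfig`: the reconstructed `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  raw <- list(generator = unclass(config$generator),
              preprocess = unclass(config$preprocess),
              nmf = config$nmf, timing = config$timing, stats = config$stats,
              seed = config$seed, outDir = config$outDir)
  raw$generator$jumpTable <- as.list(raw$generator$jumpTable)
  yaml::write_yaml(raw, path, precision = 17)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  gen <- raw$generator
  gen$jumpTable <- as.data.frame(gen$jumpTable)
  pipelineConfig(
    generator = do.call(generatorConfig, gen),
    preprocess = do.call(preprocessConfig, raw$preprocess),
    nmf = raw$nmf, timing = raw$timing, stats = raw$stats,
    seed = raw$seed, outDir = raw$outDir)
}

# Consensus model order across sessions: the most frequent selected order
# (smallest on ties), so weights are comparable across subjects/protocols.
consensusOrder <- function(orders) {
  tab <- table(orders)
  as.integer(names(tab)[which.max(tab)])
}

#' Analyze jump performance
#'
#' Converts flight times to heights (h = g t^2 / 8), keeps each subject x
#' protocol x time-point cell's best of three jumps, runs the two-way
#' within-subject RM-ANOVA (protocol x time), and per time point the
#' Shapiro-gated protocol comparison with post hocs.
#'
#' @param jumps data.frame in the [simulateJumps()] layout (flight times;
#'   heights are recomputed).
#' @param alpha significance level.
#' @return list with `best` (the best-of-three table), `anova` (two-way
#'   RM-ANOVA), `byTimePoint` (named list of [compareConditions()] results).
#' @export
analyzeJumps <- function(jumps, alpha = 0.05) {
  jumps$height <- jumpHeight(jumps$flightTime)
  cells <- split(jumps, jumps[c("subject", "protocol", "timePoint")], drop = TRUE)
  best <- do.call(rbind, lapply(cells, function(cell)
    data.frame(subject = cell$subject[1], protocol = cell$protocol[1],
               timePoint = cell$timePoint[1],
               height = bestOfJumps(cell$height))))
  rownames(best) <- NULL
  long <- data.frame(subject = best$subject, protocol = best$protocol,
                     time = best$timePoint, value = best$height)
  aov2 <- rmAnova(long, dv = "value", within = c("protocol", "time"))
  byTp <- lapply(split(best, best$timePoint), function(d) {
    mat <- tapply(d$height, list(d$subject, d$protocol), identity)
    compareConditions(mat, alpha = alpha)
  })
  list(best = best, anova = aov2, byTimePoint = byTp)
}

#' Compare synergy muscle weights across protocols
#'
#' For each synergy and muscle, the Shapiro-gated within-subject comparison
#' of the matched weight across protocols, with corrected post hocs.
#'
#' @param weightTable data.frame with columns `subject`, `protocol`,
#'   `synergy`, `muscle`, `weight` (matched synergies).
#' @param alpha significance level.
#' @return data.frame with one row per synergy x muscle: omnibus test name,
#'   statistic, p, effect size, and the concatenated significant post-hoc
#'   annotations.
#' @export
analyzeWeights <- function(weightTable, alpha = 0.05) {
  out <- list()
  for (syn in sort(unique(weightTable$synergy))) {
    for (mus in unique(weightTable$muscle)) {
      d <- weightTable[weightTable$synergy == syn & weightTable$muscle == mus, ]
      mat <- tapply(d$weight, list(d$subject, d$protocol), identity)
      res <- compareConditions(mat, alpha = alpha)
      if (res$parametric) {
        stat <- res$omnibus$F[1]; p <- res$omnibus$p[1]
        es <- res$omnibus$etaPSq[1]; test <- "RM-ANOVA"
      } else {
        stat <- res$omnibus$statistic; p <- res$omnibus$p
        es <- NA_real_; test <- "Friedman"
      }
      ann <- if (!is.null(res$posthoc))
        paste(res$posthoc$direction[nzchar(res$posthoc$direction)],
              collapse = "; ") else ""
      out[[length(out) + 1L]] <- data.frame(
        synergy = syn, muscle = mus, test = test, statistic = stat, p = p,
        effectSize = es, posthoc = ann)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full analysis pipeline
#'
#' End-to-end study reproduction on synthetic (or loaded) data:
#' \enumerate{
#'   \item generate the study from `config$generator` (or load it from
#'     `inputDir`),
#'   \item preprocess each subject x protocol session into an activation
#'     matrix,
#'   \item select the synergy order per session by the VAF criterion, refit
#'     every session at the consensus order, and sort synergies by
#'     coefficient peak time,
#'   \item match each session's synergies to the subject's first-protocol
#'     model so weights are comparable across protocols,
#'   \item extract temporal activation features,
#'   \item run the statistical layer on weights and jump heights,
#'   \item write all result tables, a stats JSON, a log and a run manifest
#'     under `config$outDir`.
#' }
#' Outputs are deterministic given `config$seed`.
#'
#' @param config a [pipelineConfig()].
#' @param inputDir optional directory in the [writeStudy()] layout; when
#'   given, data are loaded instead of generated.
#' @return list with `manifest`, `dataset`, `models`, `weights` (long
#'   weight table), `weightStats`, `features`, `featureSummary`,
#'   `jumpStats`, `vafCurves` and `outDir`.
#' @export
runPipeline <- function(config = pipelineConfig(), inputDir = NULL) {
  t0 <- Sys.time()
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(config$outDir, "run.log")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "", file = logFile,
                               append = TRUE)
  cat("", file = logFile)
  logLine("synergetics %s pipeline run, seed %d",
          as.character(utils::packageVersion("synergetics")), config$seed)
  logLine("normalization mode: %s", config$preprocess$normalization)
  logLine("VAF convention: uncentered SST; selection threshold %.2f",
          config$nmf$threshold)
  logLine("activation threshold: %.2f of curve maximum", config$timing$threshold)

  dataset <- if (is.null(inputDir)) {
    gen <- config$generator; gen$seed <- config$seed
    generateStudy(gen)
  } else loadStudy(inputDir)
  logLine("dataset: %d subjects", nSubjects(dataset))

  # preprocessing + per-session order selection
  sessions <- list()
  for (subj in subjects(dataset)) {
    for (p in names(subj$sessions)) {
      am <- preprocessSession(subj$sessions[[p]], config$preprocess)
      sel <- selectOrder(am, threshold = config$nmf$threshold,
                         maxOrder = config$nmf$maxOrder,
                         nRestarts = config$nmf$nRestarts,
                         maxIter = config$nmf$maxIter, tol = config$nmf$tol,
                         seed = childSeed(config$seed, 11,
                                          match(subj$id, vapply(subjects(dataset),
                                                                `[[`, "", "id")),
                                          match(p, names(subj$sessions))))
      sessions[[paste(subj$id, p, sep = ".")]] <-
        list(subject = subj$id, protocol = p, am = am, model = sel)
    }
  }
  orders <- vapply(sessions, function(s) synergyOrder(s$model), integer(1))
  kStar <- consensusOrder(orders)
  logLine("selected orders: %s; consensus %d",
          paste(orders, collapse = " "), kStar)

  # refit at consensus order where needed, then match within subject
  for (nm in names(sessions)) {
    s <- sessions[[nm]]
    if (synergyOrder(s$model) != kStar)
      sessions[[nm]]$model <- nmfFit(s$am, kStar,
                                     nRestarts = config$nmf$nRestarts,
                                     maxIter = config$nmf$maxIter,
                                     tol = config$nmf$tol,
                                     seed = childSeed(config$seed, 12, which(names(sessions) == nm)))
  }
  weightRows <- list(); featRows <- list(); vafRows <- list(); coefRows <- list()
  bySubject <- split(sessions, vapply(sessions, `[[`, "", "subject"))
  for (sid in names(bySubject)) {
    ses <- bySubject[[sid]]
    refModel <- ses[[1]]$model
    for (s in ses) {
      m <- matchSynergies(refModel, s$model)
      perm <- matchPermutation(m)
      W <- synergyWeights(s$model)[, perm, drop = FALSE]
      C <- synergyCoefficients(s$model)[perm, , drop = FALSE]
      colnames(W) <- rownames(C) <- paste0("SYN", seq_len(kStar))
      for (k in seq_len(kStar)) {
        weightRows[[length(weightRows) + 1L]] <- data.frame(
          subject = sid, protocol = s$protocol, synergy = colnames(W)[k],
          muscle = rownames(W), weight = W[, k])
        featRows[[length(featRows) + 1L]] <- cbind(
          subject = sid, protocol = s$protocol, synergy = colnames(W)[k],
          extractTemporalFeatures(C[k, ], config$timing$threshold))
        coefRows[[length(coefRows) + 1L]] <- data.frame(
          subject = sid, protocol = s$protocol, synergy = colnames(W)[k],
          t(C[k, ]))
      }
      cv <- vafCurve(s$model)
      if (nrow(cv))
        vafRows[[length(vafRows) + 1L]] <- cbind(subject = sid,
                                                 protocol = s$protocol, cv)
    }
  }
  weightTable <- do.call(rbind, weightRows); rownames(weightTable) <- NULL
  features <- do.call(rbind, featRows); rownames(features) <- NULL
  vafCurves <- do.call(rbind, vafRows); rownames(vafCurves) <- NULL

  weightStats <- analyzeWeights(weightTable, alpha = config$stats$alpha)
  featureSummary <- summarizeFeatures(features)
  jumpRows <- do.call(rbind, lapply(subjects(dataset), function(subj)
    do.call(rbind, lapply(names(subj$sessions), function(p)
      cbind(subject = subj$id, protocol = p, subj$sessions[[p]]$jumps)))))
  names(jumpRows)[names(jumpRows) == "flightTime"] <- "flightTime"
  jumpStats <- analyzeJumps(jumpRows, alpha = config$stats$alpha)

  # outputs
  paths <- c(weights = "weights.csv", weightStats = "weight_stats.csv",
             features = "temporal_features.csv",
             featureSummary = "temporal_feature_summary.csv",
             coefficients = "coefficients.csv",
             vafCurves = "vaf_curves.csv", jumps = "jump_heights.csv",
             anova = "jump_anova.csv")
  outPath <- function(p) file.path(config$outDir, p)
  utils::write.csv(weightTable, outPath(paths["weights"]), row.names = FALSE)
  utils::write.csv(weightStats, outPath(paths["weightStats"]), row.names = FALSE)
  utils::write.csv(features, outPath(paths["features"]), row.names = FALSE)
  utils::write.csv(featureSummary, outPath(paths["featureSummary"]), row.names = FALSE)
  utils::write.csv(do.call(rbind, coefRows), outPath(paths["coefficients"]),
                   row.names = FALSE)
  utils::write.csv(vafCurves, outPath(paths["vafCurves"]), row.names = FALSE)
  utils::write.csv(jumpStats$best, outPath(paths["jumps"]), row.names = FALSE)
  utils::write.csv(jumpStats$anova, outPath(paths["anova"]), row.names = FALSE)
  statsJson <- list(
    consensusOrder = kStar,
    jumpAnova = jumpStats$anova,
    jumpPosthocByTimePoint = lapply(jumpStats$byTimePoint, function(r)
      list(parametric = r$parametric,
           posthoc = if (is.null(r$posthoc)) NULL else r$posthoc)),
    weightFindings = weightStats[nzchar(weightStats$posthoc), ])
  jsonlite::write_json(statsJson, outPath("stats.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  files <- c(paths, stats = "stats.json")
  manifest <- list(
    package = "synergetics",
    version = as.character(utils::packageVersion("synergetics")),
    seed = config$seed,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    decisions = list(normalization = config$preprocess$normalization,
                     sstConvention = "uncentered",
                     activationThreshold = config$timing$threshold),
    outputs = as.list(tools::md5sum(vapply(unname(files), outPath, ""))))
  jsonlite::write_json(manifest, outPath("manifest.json"), auto_unbox = TRUE)
  logLine("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  list(manifest = manifest, dataset = dataset,
       models = lapply(sessions, `[[`, "model"), weights = weightTable,
       weightStats = weightStats, features = features,
       featureSummary = featureSummary, jumpStats = jumpStats,
       vafCurves = vafCurves, outDir = config$outDir)
}
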