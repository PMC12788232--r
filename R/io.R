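# File formats: UTF-8 CSV with header row and '.' decimal separator, plus
# small JSON documents. All writers and readers round-trip exactly
# (read(write(x)) == x to full double precision via 17 significant digits).

fmtNum <- function(x) formatC(x, format = "g", digits = 17)

#' Write / read one EMG trial as wide CSV
#'
#' Columns: `time_s` followed by the 15 muscle columns in the registry order
#' (see [muscleRegistry()]). Reading validates the column set and order.
#'
#' @param trial trial object with `signal` (muscles x samples) and
#'   `samplingRate`.
#' @param path file path.
#' @return `writeTrialCsv`: the path, invisibly. `readTrialCsv`: a trial
#'   object (list with `signal`, `samplingRate`; events must be supplied
#'   separately, see [readEventsJson()]).
#' @export
writeTrialCsv <- function(trial, path) {
  sig <- trial$signal
  df <- data.frame(time_s = (seq_len(ncol(sig)) - 1) / trial$samplingRate,
                   t(sig), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrialCsv
#' @param samplingRate expected sampling rate; checked against the time
#'   column when it has at least two samples.
#' @export
readTrialCsv <- function(path, samplingRate = 2000) {
  df <- utils::read.csv(path, check.names = FALSE)
  reg <- muscleRegistry()
  missing <- setdiff(reg, names(df))
  if (length(missing))
    stop("trial CSV ", path, " lacks muscle column(s): ",
         paste(missing, collapse = ", "))
  if (!identical(names(df), c("time_s", reg)))
    stop("trial CSV columns must be time_s followed by the muscle registry order")
  for (cn in names(df)) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric cell in %s at row %d, column '%s'",
                     path, bad[1], cn))
      df[[cn]] <- vn
    }
    if (any(!is.finite(df[[cn]])))
      stop(sprintf("non-numeric cell in %s at row %d, column '%s'",
                   path, which(!is.finite(df[[cn]]))[1], cn))
  }
  fs <- if (nrow(df) >= 2) round(1 / mean(diff(df$time_s))) else samplingRate
  sig <- t(as.matrix(df[, reg]))
  rownames(sig) <- reg
  list(signal = sig, samplingRate = fs)
}

#' Write / read movement-cycle events as JSON
#'
#' A JSON object with the five second-valued stamps `a` through `e`
#' (preparation start to recovery end), strictly increasing.
#'
#' @param events named list or vector with elements a--e (seconds).
#' @param path file path.
#' @return `writeEventsJson`: the path, invisibly; `readEventsJson`: named
#'   list of the five stamps.
#' @export
writeEventsJson <- function(events, path) {
  ev <- as.list(events)[c("a", "b", "c", "d", "e")]
  jsonlite::write_json(ev, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEventsJson
#' @export
readEventsJson <- function(path) {
  ev <- jsonlite::read_json(path)
  need <- c("a", "b", "c", "d", "e")
  if (!all(need %in% names(ev)))
    stop("events JSON must contain stamps a-e")
  ev <- lapply(ev[need], as.numeric)
  if (any(diff(unlist(ev)) <= 0))
    stop("event stamps must be strictly increasing (a < b < c < d < e)")
  ev
}

#' Write / read the MVC reference table
#'
#' CSV with columns `muscle,reference`; muscles validated against the
#' registry, references must be positive.
#'
#' @param mvc named numeric vector of reference amplitudes.
#' @param path file path.
#' @return `writeMvcCsv`: the path, invisibly; `readMvcCsv`: named numeric
#'   vector in registry order.
#' @export
writeMvcCsv <- function(mvc, path) {
  df <- data.frame(muscle = names(mvc), reference = fmtNum(unname(mvc)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMvcCsv
#' @export
readMvcCsv <- function(path) {
  df <- utils::read.csv(path)
  unknown <- setdiff(df$muscle, muscleRegistry())
  if (length(unknown))
    stop("unknown muscle label(s) in ", path, ": ", paste(unknown, collapse = ", "))
  missing <- setdiff(muscleRegistry(), df$muscle)
  if (length(missing))
    stop("MVC table ", path, " lacks muscle(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(df$reference) | df$reference <= 0))
    stop("MVC references must be positive numbers")
  out <- df$reference
  names(out) <- df$muscle
  out[muscleRegistry()]
}

#' Write / read jump flight times
#'
#' CSV with columns `subject, protocol, time_point_min, jump_index,
#' flight_time_s`; protocols validated against [protocolLabels()], time
#' points against [timePoints()], flight times must be positive.
#'
#' @param jumps data.frame as produced by [simulateJumps()] (columns
#'   `subject`, `protocol`, `timePoint`, `jumpIndex`, `flightTime`).
#' @param path file path.
#' @return `writeJumpsCsv`: the path, invisibly; `readJumpsCsv`: a
#'   data.frame in the [simulateJumps()] layout.
#' @export
writeJumpsCsv <- function(jumps, path) {
  df <- data.frame(subject = jumps$subject, protocol = jumps$protocol,
                   time_point_min = jumps$timePoint,
                   jump_index = jumps$jumpIndex,
                   flight_time_s = fmtNum(jumps$flightTime))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMvcCsv
#' @export
readJumpsCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject", "protocol", "time_point_min", "jump_index", "flight_time_s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("jumps CSV ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$protocol), protocolLabels())
  if (length(bad))
    stop("unknown protocol label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$time_point_min), timePoints())
  if (length(bad))
    stop("unknown time point(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(df$flight_time_s) | df$flight_time_s <= 0))
    stop("flight times must be positive")
  data.frame(subject = df$subject, protocol = df$protocol,
             timePoint = df$time_point_min, jumpIndex = df$jump_index,
             flightTime = df$flight_time_s)
}

#' Write a study dataset to a directory tree
#'
#' Lays a [StudyDataset-class] out as the plain-text formats the pipeline
#' reads: per subject/protocol trial CSVs and event JSONs plus an MVC table,
#' and a global jumps CSV.
#'
#' @param dataset a [StudyDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jumpRows <- list()
  for (subj in subjects(dataset)) {
    for (p in names(subj$sessions)) {
      ses <- subj$sessions[[p]]
      sdir <- file.path(dir, subj$id, p)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      for (j in seq_along(ses$trials)) {
        writeTrialCsv(ses$trials[[j]], file.path(sdir, sprintf("trial%02d.csv", j)))
        writeEventsJson(ses$trials[[j]]$events,
                        file.path(sdir, sprintf("trial%02d_events.json", j)))
      }
      writeMvcCsv(ses$mvc, file.path(sdir, "mvc.csv"))
      jr <- ses$jumps
      jumpRows[[length(jumpRows) + 1L]] <-
        data.frame(subject = subj$id, protocol = p, timePoint = jr$timePoint,
                   jumpIndex = jr$jumpIndex, flightTime = jr$flightTime)
    }
  }
  writeJumpsCsv(do.call(rbind, jumpRows), file.path(dir, "jumps.csv"))
  invisible(dir)
}

#' Load a study dataset from a directory tree
#'
#' Inverse of [writeStudy()]: reads the trial CSVs, event JSONs, MVC tables
#' and jump CSV back into a [StudyDataset-class] (without ground truth).
#'
#' @param dir directory written by [writeStudy()] or following its layout.
#' @return A [StudyDataset-class].
#' @export
loadStudy <- function(dir) {
  jumps <- readJumpsCsv(file.path(dir, "jumps.csv"))
  subjDirs <- sort(list.dirs(dir, recursive = FALSE))
  subjectsList <- lapply(subjDirs, function(sd) {
    sid <- basename(sd)
    protos <- intersect(protocolLabels(), basename(list.dirs(sd, recursive = FALSE)))
    if (!length(protos)) stop("no protocol sessions found under ", sd)
    sessions <- lapply(protos, function(p) {
      pdir <- file.path(sd, p)
      trialFiles <- sort(list.files(pdir, pattern = "^trial[0-9]+\\.csv$",
                                    full.names = TRUE))
      if (!length(trialFiles)) stop("missing trial files in ", pdir)
      trials <- lapply(trialFiles, function(tf) {
        tr <- readTrialCsv(tf)
        tr$events <- readEventsJson(sub("\\.csv$", "_events.json", tf))
        tr
      })
      jp <- jumps[jumps$subject == sid & jumps$protocol == p, ]
      list(trials = trials, mvc = readMvcCsv(file.path(pdir, "mvc.csv")),
           jumps = data.frame(timePoint = jp$timePoint,
                              jumpIndex = jp$jumpIndex,
                              flightTime = jp$flightTime))
    })
    names(sessions) <- protos
    list(id = sid, sessions = sessions)
  })
  new("StudyDataset", subjectData = subjectsList, truth = NULL, config = list())
}
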