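#' Temporal activation features of a synergy coefficient curve
#'
#' Computes the standard timing descriptors of one activation coefficient
#' curve on the normalized 0--100% cycle timeline. A sample is "active" when
#' the curve is at or above `threshold` times its maximum (default 20% of
#' peak, a common EMG activation convention). Features:
#' \describe{
#'   \item{duration}{count of active samples (bounded by the number of grid
#'     points, i.e. by 100 on the default grid).}
#'   \item{peak}{normalized time of the curve maximum (first sample on ties).}
#'   \item{onset}{normalized time of the first active sample.}
#'   \item{offset}{normalized time of the last active sample.}
#' }
#' An all-zero curve is flagged inactive: duration 0 and `NA` onset, peak
#' and offset.
#'
#' @param curve non-negative numeric vector (typically 100 points).
#' @param threshold activation threshold as a fraction of the curve maximum,
#'   in (0, 1).
#' @return One-row data.frame with columns `duration`, `peak`, `onset`,
#'   `offset`, `threshold`, `active`.
#' @export
#' @examples
#' g <- seq(0, 100, length.out = 100)
#' extractTemporalFeatures(exp(-0.5 * ((g - 50) / 10)^2))
extractTemporalFeatures <- function(curve, threshold = 0.20) {
  if (any(curve < 0)) stop("curve must be non-negative")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  n <- length(curve)
  grid <- timeGrid(n)
  mx <- max(curve)
  if (mx == 0)
    return(data.frame(duration = 0, peak = NA_real_, onset = NA_real_,
                      offset = NA_real_, threshold = threshold, active = FALSE))
  act <- curve >= threshold * mx
  idx <- which(act)
  data.frame(duration = length(idx),
             peak = grid[which.max(curve)],
             onset = grid[idx[1]],
             offset = grid[idx[length(idx)]],
             threshold = threshold, active = TRUE)
}

#' Temporal features for every synergy of a model
#'
#' @param model a [SynergyModel-class].
#' @param threshold activation threshold fraction.
#' @return data.frame with one row per synergy (column `synergy` plus the
#'   [extractTemporalFeatures()] columns).
#' @export
modelTemporalFeatures <- function(model, threshold = 0.20) {
  C <- synergyCoefficients(model)
  out <- do.call(rbind, lapply(seq_len(nrow(C)), function(i)
    cbind(synergy = rownames(C)[i], extractTemporalFeatures(C[i, ], threshold))))
  rownames(out) <- NULL
  out
}

#' Summarize temporal features per protocol
#'
#' Per-protocol, per-synergy sample mean and SD (n-1 denominator) of each
#' temporal feature across subjects, in the layout of a between-protocol
#' comparison table.
#'
#' @param features data.frame with columns `subject`, `protocol`, `synergy`
#'   and the feature columns `duration`, `peak`, `onset`, `offset`.
#' @return data.frame with columns `synergy`, `feature`, `protocol`, `n`,
#'   `mean`, `sd`.
#' @export
summarizeFeatures <- function(features) {
  needed <- c("subject", "protocol", "synergy", "duration", "peak", "onset",
              "offset")
  if (!all(needed %in% names(features)))
    stop("features must contain columns: ", paste(needed, collapse = ", "))
  if (nrow(features) == 0) stop("empty feature table")
  out <- list()
  for (feat in c("duration", "peak", "onset", "offset")) {
    for (syn in sort(unique(features$synergy))) {
      for (p in sort(unique(features$protocol))) {
        v <- features[features$synergy == syn & features$protocol == p, feat]
        v <- v[!is.na(v)]
        if (length(v) < 2)
          stop(sprintf("group %s/%s has fewer than 2 subjects", syn, p))
        out[[length(out) + 1L]] <- data.frame(
          synergy = syn, feature = feat, protocol = p, n = length(v),
          mean = mean(v), sd = stats::sd(v))
      }
    }
  }
  do.call(rbind, out)
}
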