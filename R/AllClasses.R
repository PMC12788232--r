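#' @include AllGenerics.R
NULL

#' The 15-muscle surface EMG montage
#'
#' Ordered labels of the muscles recorded during the side-kick task:
#' brachioradialis (BR), biceps brachii (BB), triceps brachii (TB), anterior
#' deltoid (AD), external oblique (EO), gluteus maximus (GM), gluteus medius
#' (GMed), biceps femoris (BF), rectus femoris (RF), vastus lateralis (VL),
#' tibialis anterior (TA), medial gastrocnemius (GAS), and the contralateral
#' (right-side) tibialis anterior (TAR), gluteus maximus (GMR) and rectus
#' femoris (RFR). All trial files and activation matrices use this order.
#'
#' @return Character vector of 15 muscle labels.
#' @export
#' @examples
#' muscleRegistry()
muscleRegistry <- function() {
  c("BR", "BB", "TB", "AD", "EO", "GM", "GMed", "BF", "RF", "VL",
    "TA", "GAS", "TAR", "GMR", "RFR")
}

#' Intervention protocol labels
#'
#' The three conditioning protocols compared by the study design: ESG
#' (squat with synchronized neuromuscular electrical stimulation), RBG
#' (band-resisted lateral stepping) and SQG (heavy barbell squat).
#'
#' @return Character vector of the three protocol labels.
#' @export
protocolLabels <- function() c("ESG", "RBG", "SQG")

#' Jump assessment time points (minutes post-intervention)
#' @return Integer vector `c(6, 8, 10)`.
#' @export
timePoints <- function() c(6L, 8L, 10L)

# ---------------------------------------------------------------------------
# VafReport

#' VafReport: variance accounted for by a reconstruction
#'
#' Holds the sum of squared reconstruction errors (SSE), the uncentered total
#' sum of squares (SST, the sum of squared data entries) and the variance
#' accounted for, VAF = 1 - SSE/SST.
#'
#' @slot sse numeric, sum of squared errors (>= 0).
#' @slot sst numeric, total sum of squares (> 0).
#' @slot vaf numeric fraction; equals `1 - sse/sst`.
#' @slot centered logical, whether SST was computed about the grand mean
#'   (the default convention is uncentered).
#' @export
setClass("VafReport",
  representation(sse = "numeric", sst = "numeric", vaf = "numeric",
                 centered = "logical"),
  prototype(centered = FALSE))

setValidity("VafReport", function(object) {
  msg <- character()
  if (length(object@sse) != 1L || object@sse < 0) msg <- c(msg, "sse must be a single non-negative number")
  if (length(object@sst) != 1L || object@sst <= 0) msg <- c(msg, "sst must be a single positive number")
  if (abs(object@vaf - (1 - object@sse / object@sst)) > 1e-12)
    msg <- c(msg, "vaf must equal 1 - sse/sst")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ActivationMatrix

#' ActivationMatrix: the muscle-by-time envelope matrix fed to factorization
#'
#' A non-negative muscles x time matrix of normalized activation envelopes on
#' the normalized movement-cycle grid (default 100 points spanning 0--100% of
#' the cycle), usually the average of several time-normalized trials.
#'
#' @slot values numeric matrix, muscles x time points, all entries >= 0.
#'   Row names are the muscle labels.
#' @slot nTrialsAveraged integer, number of trials averaged into the matrix.
#' @export
setClass("ActivationMatrix",
  representation(values = "matrix", nTrialsAveraged = "integer"),
  prototype(nTrialsAveraged = 1L))

setValidity("ActivationMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (any(!is.finite(v))) msg <- c(msg, "values must be finite")
  else if (any(v < 0)) msg <- c(msg, "values must be non-negative")
  if (ncol(v) < 2L) msg <- c(msg, "need at least 2 time points")
  lab <- rownames(v)
  if (is.null(lab) || anyDuplicated(lab) || any(!nzchar(lab)))
    msg <- c(msg, "rownames(values) must be unique non-empty muscle labels")
  if (object@nTrialsAveraged < 1L) msg <- c(msg, "nTrialsAveraged must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct an ActivationMatrix
#'
#' @param values non-negative numeric matrix, muscles x time points.
#' @param muscleLabels optional character vector of row labels; defaults to
#'   existing rownames.
#' @param nTrialsAveraged number of trials averaged into `values`.
#' @return An [ActivationMatrix-class] object.
#' @export
activationMatrix <- function(values, muscleLabels = rownames(values),
                             nTrialsAveraged = 1L) {
  values <- as.matrix(values)
  if (!is.null(muscleLabels)) rownames(values) <- muscleLabels
  new("ActivationMatrix", values = values,
      nTrialsAveraged = as.integer(nTrialsAveraged))
}

#' @rdname accessors
#' @export
setMethod("muscleLabels", "ActivationMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("nTrialsAveraged", "ActivationMatrix", function(x) x@nTrialsAveraged)

#' @param x an ActivationMatrix.
#' @param ... ignored.
#' @rdname ActivationMatrix-class
#' @export
setMethod("as.matrix", "ActivationMatrix", function(x, ...) x@values)

setMethod("show", "ActivationMatrix", function(object) {
  cat(sprintf("ActivationMatrix: %d muscles x %d time points (average of %d trial%s)\n",
              nrow(object@values), ncol(object@values), object@nTrialsAveraged,
              if (object@nTrialsAveraged == 1L) "" else "s"))
  cat("  muscles:", paste(head(rownames(object@values), 8), collapse = " "),
      if (nrow(object@values) > 8) "..." else "", "\n")
  cat(sprintf("  range: [%.4g, %.4g]\n", min(object@values), max(object@values)))
})

# ---------------------------------------------------------------------------
# SynergyModel

#' SynergyModel: a non-negative factorization of an activation matrix
#'
#' Represents the decomposition D ~ W C of a muscles x time activation matrix
#' into `order` synergies: time-invariant muscle weight vectors (the columns
#' of W, scaled to unit Euclidean norm) and time-varying activation
#' coefficients (the rows of C, which carry the amplitude).
#'
#' @slot weights numeric matrix, muscles x order, non-negative, unit-norm
#'   columns named SYN1..SYNk.
#' @slot coefficients numeric matrix, order x time points, non-negative.
#' @slot order integer, the number of synergies.
#' @slot vaf a [VafReport-class] for the reconstruction.
#' @slot vafCurve data.frame with columns `order` and `vaf`: the VAF attained
#'   at each candidate order during order selection (empty when the model was
#'   fit at a fixed order).
#' @slot restartsUsed integer, number of random restarts evaluated.
#' @slot converged logical, whether the retained run met the relative error
#'   tolerance before the iteration cap.
#' @export
setClass("SynergyModel",
  representation(weights = "matrix", coefficients = "matrix", order = "integer",
                 vaf = "VafReport", vafCurve = "data.frame",
                 restartsUsed = "integer", converged = "logical"))

setValidity("SynergyModel", function(object) {
  msg <- character()
  W <- object@weights; C <- object@coefficients
  if (any(W < 0) || any(C < 0)) msg <- c(msg, "weights and coefficients must be non-negative")
  if (ncol(W) != object@order) msg <- c(msg, "ncol(weights) must equal order")
  if (nrow(C) != object@order) msg <- c(msg, "nrow(coefficients) must equal order")
  nrm <- sqrt(colSums(W^2))
  if (any(nrm > 0 & abs(nrm - 1) > 1e-6))
    msg <- c(msg, "nonzero weight columns must have unit Euclidean norm")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("synergyWeights", "SynergyModel", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("synergyCoefficients", "SynergyModel", function(x) x@coefficients)

#' @rdname accessors
#' @export
setMethod("synergyOrder", "SynergyModel", function(x) x@order)

#' @rdname accessors
#' @export
setMethod("vaf", "SynergyModel", function(x) x@vaf@vaf)

#' @rdname accessors
#' @export
setMethod("vafReport", "SynergyModel", function(x) x@vaf)

#' @rdname accessors
#' @export
setMethod("vafCurve", "SynergyModel", function(x) x@vafCurve)

#' @rdname accessors
#' @export
setMethod("reconstruct", "SynergyModel", function(x) x@weights %*% x@coefficients)

#' @rdname accessors
#' @export
setMethod("vaf", "VafReport", function(x) x@vaf)

setMethod("show", "SynergyModel", function(object) {
  cat(sprintf("SynergyModel: %d synergies over %d muscles x %d time points\n",
              object@order, nrow(object@weights), ncol(object@coefficients)))
  cat(sprintf("  VAF: %.2f%% (SSE %.4g / SST %.4g)%s\n", 100 * object@vaf@vaf,
              object@vaf@sse, object@vaf@sst,
              if (object@converged) "" else "  [not converged]"))
  if (nrow(object@vafCurve))
    cat("  VAF curve:", paste(sprintf("%d:%.3f", object@vafCurve$order,
                                      object@vafCurve$vaf), collapse = " "), "\n")
})

setMethod("show", "VafReport", function(object) {
  cat(sprintf("VafReport: VAF = %.4f (%.2f%%), SSE = %.4g, SST = %.4g (%s)\n",
              object@vaf, 100 * object@vaf, object@sse, object@sst,
              if (object@centered) "centered" else "uncentered"))
})

# ---------------------------------------------------------------------------
# SynergyMatch

#' SynergyMatch: correspondence between two synergy models
#'
#' The permutation mapping the synergies of one model onto a reference model,
#' chosen to maximize the total cosine similarity between matched muscle
#' weight columns.
#'
#' @slot permutation integer vector p; synergy i of the reference is matched
#'   to synergy p[i] of the other model.
#' @slot similarity numeric vector of cosine similarities per matched pair.
#' @export
setClass("SynergyMatch",
  representation(permutation = "integer", similarity = "numeric"))

setValidity("SynergyMatch", function(object) {
  p <- object@permutation
  msg <- character()
  if (!setequal(p, seq_along(p))) msg <- c(msg, "permutation must be a bijection")
  if (length(object@similarity) != length(p)) msg <- c(msg, "one similarity per pair")
  if (any(object@similarity < -1e-9 | object@similarity > 1 + 1e-9))
    msg <- c(msg, "similarities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("matchPermutation", "SynergyMatch", function(x) x@permutation)

#' @rdname accessors
#' @export
setMethod("matchSimilarity", "SynergyMatch", function(x) x@similarity)

setMethod("show", "SynergyMatch", function(object) {
  cat("SynergyMatch:",
      paste(sprintf("%d->%d (%.3f)", seq_along(object@permutation),
                    object@permutation, object@similarity), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# GroundTruth

#' GroundTruth: the generative synergy structure behind synthetic data
#'
#' The known weights and activation coefficients from which synthetic EMG is
#' built, plus per-protocol multiplicative muscle-weight modifiers emulating
#' intervention-specific neuromuscular shifts.
#'
#' @slot weights non-negative muscles x synergies matrix, unit-norm columns.
#' @slot coefficients non-negative synergies x 100 matrix of activation
#'   curves on the normalized-time grid.
#' @slot protocolEffects named list (one element per protocol) of per-muscle
#'   multiplicative weight modifiers.
#' @export
setClass("GroundTruth",
  representation(weights = "matrix", coefficients = "matrix",
                 protocolEffects = "list"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (any(object@weights < 0) || any(object@coefficients < 0))
    msg <- c(msg, "all entries must be non-negative")
  nrm <- sqrt(colSums(object@weights^2))
  if (any(abs(nrm - 1) > 1e-9)) msg <- c(msg, "weight columns must have unit norm (1e-9)")
  if (ncol(object@coefficients) != 100L)
    msg <- c(msg, "coefficients must have exactly 100 columns")
  if (nrow(object@coefficients) != ncol(object@weights))
    msg <- c(msg, "coefficient rows must match weight columns")
  for (eff in object@protocolEffects)
    if (length(eff) != nrow(object@weights) || any(eff < 0))
      msg <- c(msg, "each protocol effect must be a non-negative per-muscle vector")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("trueWeights", "GroundTruth", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("trueCoefficients", "GroundTruth", function(x) x@coefficients)

#' @rdname accessors
#' @export
setMethod("protocolEffects", "GroundTruth", function(x) x@protocolEffects)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d muscles, %d synergies, protocols: %s\n",
              nrow(object@weights), ncol(object@weights),
              paste(names(object@protocolEffects), collapse = " ")))
})

# ---------------------------------------------------------------------------
# StudyDataset

#' StudyDataset: a full synthetic (or loaded) crossover study
#'
#' Container for the complete study: per subject, one session per protocol,
#' each session holding the raw-like EMG trials, cycle event stamps, the MVC
#' reference table and the jump flight times, with the generative ground truth
#' attached when the data are synthetic.
#'
#' @slot subjectData list of subject records. Each record is a list with
#'   `id` and `sessions`, a named list (per protocol) with elements `trials`
#'   (list of trial objects as returned by [synthesizeTrial()]), `mvc`
#'   (named numeric reference amplitudes) and `jumps` (data.frame with
#'   columns `timePoint`, `jumpIndex`, `flightTime`).
#' @slot truth a [GroundTruth-class], or NULL for loaded real data.
#' @slot config the generator configuration list used to build the dataset.
#' @export
setClass("StudyDataset",
  representation(subjectData = "list", truth = "ANY", config = "list"))

setValidity("StudyDataset", function(object) {
  msg <- character()
  for (subj in object@subjectData) {
    if (is.null(subj$id) || is.null(subj$sessions)) {
      msg <- c(msg, "each subject needs id and sessions"); break
    }
    for (ses in subj$sessions) {
      for (tr in ses$trials) {
        if (nrow(tr$signal) != length(muscleRegistry()) &&
            is.null(object@config$nMuscles)) {
          msg <- c(msg, "trials must carry the full muscle montage"); break
        }
        ev <- unlist(tr$events)
        if (any(diff(ev) <= 0)) { msg <- c(msg, "event stamps must be strictly increasing"); break }
      }
      if (!is.null(ses$jumps) && any(ses$jumps$flightTime <= 0))
        msg <- c(msg, "flight times must be positive")
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' @rdname accessors
#' @export
setMethod("subjects", "StudyDataset", function(x) x@subjectData)

#' @rdname accessors
#' @export
setMethod("groundTruth", "StudyDataset", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("nSubjects", "StudyDataset", function(x) length(x@subjectData))

setMethod("show", "StudyDataset", function(object) {
  ns <- length(object@subjectData)
  np <- if (ns) length(object@subjectData[[1]]$sessions) else 0L
  nt <- if (np) length(object@subjectData[[1]]$sessions[[1]]$trials) else 0L
  cat(sprintf("StudyDataset: %d subjects x %d protocols x %d trials%s\n",
              ns, np, nt,
              if (is.null(object@truth)) "" else " (synthetic, ground truth attached)"))
})
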