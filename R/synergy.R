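#' Variance accounted for by a reconstruction
#'
#' VAF = 1 - SSE/SST with SSE the sum of squared differences between the
#' data and its reconstruction and SST, by the convention standard in the
#' muscle-synergy literature, the *uncentered* total sum of squares
#' (the sum of squared data entries). With that convention a zero
#' reconstruction gives VAF = 0 and a perfect one VAF = 1. A centered SST
#' (about the grand mean) is available via `centered = TRUE`.
#'
#' @param D data matrix (or [ActivationMatrix-class]).
#' @param reconstruction matrix of identical shape.
#' @param centered use the centered SST convention.
#' @return A [VafReport-class].
#' @export
#' @examples
#' computeVaf(matrix(2), matrix(1))  # SSE 1, SST 4, VAF 0.75
computeVaf <- function(D, reconstruction, centered = FALSE) {
  D <- if (is(D, "ActivationMatrix")) as.matrix(D) else as.matrix(D)
  R <- as.matrix(reconstruction)
  if (!identical(dim(D), dim(R))) stop("D and reconstruction must have identical shapes")
  sse <- sum((D - R)^2)
  sst <- if (centered) sum((D - mean(D))^2) else sum(D^2)
  if (sst == 0) stop("SST is zero (all-zero data): VAF undefined")
  new("VafReport", sse = sse, sst = sst, vaf = 1 - sse / sst,
      centered = centered)
}

# One multiplicative-update run from a given random init; returns W, C, sse,
# converged. Lee-Seung updates for the squared Frobenius loss with a small
# epsilon guard against zero denominators.
nmfRun <- function(D, k, maxIter, tol) {
  eps <- 1e-12
  m <- nrow(D); n <- ncol(D)
  W <- matrix(stats::runif(m * k, eps, 1), m, k)
  C <- matrix(stats::runif(k * n, eps, 1), k, n)
  errOld <- Inf
  converged <- FALSE
  sst <- sum(D^2)
  for (it in seq_len(maxIter)) {
    C <- C * (crossprod(W, D)) / (crossprod(W) %*% C + eps)
    W <- W * (D %*% t(C)) / (W %*% tcrossprod(C) + eps)
    if (it %% 10 == 0 || it == maxIter) {
      err <- sum((D - W %*% C)^2)
      # exact reconstructions bottom out at machine precision, where the
      # relative-change criterion is meaningless
      if (err < 1e-12 * sst ||
          (is.finite(errOld) && errOld > 0 &&
           abs(errOld - err) / errOld < tol)) { converged <- TRUE; break }
      errOld <- err
    }
  }
  list(W = W, C = C, sse = sum((D - W %*% C)^2), converged = converged)
}

#' Fit a non-negative matrix factorization at a fixed order
#'
#' Decomposes the non-negative activation matrix D into `order` synergies,
#' D ~ W C, by Lee--Seung multiplicative updates minimizing the squared
#' Frobenius reconstruction error. Each of `nRestarts` seeded uniform random
#' initializations is iterated until the relative change in reconstruction
#' error falls below `tol` (checked every 10 iterations) or `maxIter` is
#' reached; the restart with the highest VAF is kept. The result is rescaled
#' to unit-Euclidean-norm weight columns, with the scale carried by the
#' coefficients, and synergies are ordered by ascending coefficient peak time.
#'
#' @param D an [ActivationMatrix-class] or non-negative numeric matrix.
#' @param order number of synergies, between 1 and `min(dim(D))`.
#' @param nRestarts number of random restarts.
#' @param maxIter iteration cap per restart.
#' @param tol relative reconstruction-error tolerance.
#' @param seed integer seed (each restart derives a child seed).
#' @return A [SynergyModel-class].
#' @export
nmfFit <- function(D, order, nRestarts = 20, maxIter = 1000, tol = 1e-6,
                   seed = 1) {
  M <- if (is(D, "ActivationMatrix")) as.matrix(D) else as.matrix(D)
  if (any(M < 0)) stop("D must be non-negative")
  if (order < 1 || order > min(dim(M)))
    stop(sprintf("order must lie in [1, %d]", min(dim(M))))
  if (sum(M^2) == 0) stop("D is all zero; nothing to factorize")
  best <- NULL
  for (r in seq_len(nRestarts)) {
    run <- withSeed(childSeed(seed, order, r), nmfRun(M, order, maxIter, tol))
    if (is.null(best) || run$sse < best$sse) best <- run
  }
  W <- best$W; C <- best$C
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(W, 2, nrm, "/")
  C <- C * nrm
  ord <- order(apply(C, 1, which.max))
  W <- W[, ord, drop = FALSE]
  C <- C[ord, , drop = FALSE]
  colnames(W) <- rownames(C) <- paste0("SYN", seq_len(order))
  rownames(W) <- rownames(M)
  new("SynergyModel", weights = W, coefficients = C, order = as.integer(order),
      vaf = computeVaf(M, W %*% C),
      vafCurve = data.frame(order = integer(), vaf = numeric()),
      restartsUsed = as.integer(nRestarts), converged = best$converged)
}

#' Select the number of synergies by the VAF criterion
#'
#' Fits factorizations of increasing order and returns the model at the
#' smallest order whose best-of-restarts VAF reaches `threshold` (default
#' 0.90, i.e. at least 90% of the signal variance reconstructed). The full
#' VAF-versus-order curve is retained on the returned model for reporting.
#'
#' @inheritParams nmfFit
#' @param threshold VAF fraction required (default 0.90).
#' @param maxOrder largest order tried (default `min(dim(D))`).
#' @return A [SynergyModel-class] with a populated `vafCurve` slot.
#'   If the threshold is unreachable an error of class
#'   `orderSelectionError` is signalled, carrying the curve in its
#'   `vafCurve` field.
#' @export
selectOrder <- function(D, threshold = 0.90, maxOrder = NULL, nRestarts = 20,
                        maxIter = 1000, tol = 1e-6, seed = 1) {
  M <- if (is(D, "ActivationMatrix")) as.matrix(D) else as.matrix(D)
  if (is.null(maxOrder)) maxOrder <- min(dim(M))
  maxOrder <- min(maxOrder, min(dim(M)))
  curve <- data.frame(order = integer(), vaf = numeric())
  for (k in seq_len(maxOrder)) {
    fit <- nmfFit(M, k, nRestarts = nRestarts, maxIter = maxIter, tol = tol,
                  seed = seed)
    curve <- rbind(curve, data.frame(order = k, vaf = vaf(fit)))
    if (vaf(fit) >= threshold) {
      fit@vafCurve <- curve
      return(fit)
    }
  }
  cond <- structure(
    class = c("orderSelectionError", "error", "condition"),
    list(message = sprintf(
           "VAF threshold %.3f not reached by order %d (best %.4f)",
           threshold, maxOrder, max(curve$vaf)),
         call = sys.call(), vafCurve = curve))
  stop(cond)
}

#' Match synergies between two models
#'
#' Finds the bijection between the synergies of two equal-order models that
#' maximizes the total cosine similarity between matched muscle-weight
#' columns (exhaustive search over permutations; orders here are small).
#' Ties are broken in favour of the permutation aligning earlier coefficient
#' peaks.
#'
#' @param reference,other [SynergyModel-class] objects of equal order.
#' @return A [SynergyMatch-class]: synergy i of `reference` corresponds to
#'   synergy `matchPermutation(m)[i]` of `other`.
#' @export
matchSynergies <- function(reference, other) {
  if (synergyOrder(reference) != synergyOrder(other))
    stop("models must have equal orders")
  Wr <- synergyWeights(reference)
  Wo <- synergyWeights(other)
  k <- ncol(Wr)
  S <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    S[i, j] <- cosineSim(Wr[, i], Wo[, j])
  perms <- permuteAll(k)
  tot <- vapply(perms, function(p) sum(S[cbind(seq_len(k), p)]), numeric(1))
  bestIdx <- which(tot > max(tot) - 1e-12)
  if (length(bestIdx) > 1) {
    # tie-break: prefer the assignment matching earlier coefficient peaks
    peaksR <- apply(synergyCoefficients(reference), 1, which.max)
    peaksO <- apply(synergyCoefficients(other), 1, which.max)
    mis <- vapply(perms[bestIdx], function(p) sum(abs(peaksR - peaksO[p])),
                  numeric(1))
    bestIdx <- bestIdx[which.min(mis)]
  } else bestIdx <- bestIdx[1]
  p <- perms[[bestIdx]]
  new("SynergyMatch", permutation = as.integer(p),
      similarity = pmin(1, pmax(0, S[cbind(seq_len(k), p)])))
}

# All permutations of 1..k (k is the synergy count, so small).
permuteAll <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    sub <- permuteAll(k - 1L)
    rest <- setdiff(seq_len(k), i)
    out <- c(out, lapply(sub, function(p) c(i, rest[p])))
  }
  out
}
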