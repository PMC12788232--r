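#' Vertical jump height from flight time
#'
#' Flight-time method: h = g t^2 / 8, returned in centimetres.
#'
#' @param flightTime flight time in seconds (>= 0); vectorized.
#' @param gravity gravitational acceleration in m/s^2.
#' @return Jump height in cm.
#' @export
#' @examples
#' jumpHeight(0.6328)  # ~49.1 cm
jumpHeight <- function(flightTime, gravity = 9.81) {
  if (any(flightTime < 0)) stop("flight time must be non-negative")
  100 * gravity * flightTime^2 / 8
}

#' Best of repeated jumps
#'
#' The recorded value of a jump assessment is the highest of the attempts.
#'
#' @param heights numeric vector of jump heights (>= 1 value).
#' @return The maximum.
#' @export
bestOfJumps <- function(heights) {
  if (length(heights) < 1) stop("need at least one jump")
  max(heights)
}

#' Power of a within-subject repeated-measures ANOVA
#'
#' Power of the F test for a single within factor with `nMeasurements`
#' levels, computed under the G*Power within-factor convention: the test
#' statistic follows a noncentral F with numerator df (m-1) epsilon,
#' denominator df (N-1)(m-1) epsilon and noncentrality
#' lambda = N f^2 m epsilon / (1 - rho), where rho is the correlation among
#' repeated measures and epsilon the nonsphericity correction.
#'
#' @param n number of subjects.
#' @param effectSizeF Cohen's f.
#' @param alpha significance level.
#' @param nMeasurements number of repeated measurements m.
#' @param corr correlation rho among repeated measures.
#' @param epsilon nonsphericity epsilon (1 = sphericity).
#' @return The power (probability of rejection).
#' @export
powerRmAnova <- function(n, effectSizeF = 0.30, alpha = 0.05,
                         nMeasurements = 3, corr = 0.5, epsilon = 1) {
  df1 <- (nMeasurements - 1) * epsilon
  df2 <- (n - 1) * (nMeasurements - 1) * epsilon
  if (df2 < 1) return(0)
  lambda <- n * effectSizeF^2 * nMeasurements * epsilon / (1 - corr)
  crit <- stats::qf(1 - alpha, df1, df2)
  1 - stats::pf(crit, df1, df2, ncp = lambda)
}

#' Minimum sample size for a within-subject RM-ANOVA
#'
#' Smallest number of subjects N for which [powerRmAnova()] reaches the
#' target power.
#'
#' @param effectSizeF Cohen's f.
#' @param alpha significance level.
#' @param power target power (1 - beta).
#' @param nMeasurements number of repeated measurements.
#' @param corr correlation among repeated measures.
#' @param epsilon nonsphericity epsilon.
#' @param nMax search cap; an unreachable target is an error carrying the
#'   power curve.
#' @return Integer minimum N, with the achieved power as attribute `power`.
#' @export
rmAnovaSampleSize <- function(effectSizeF = 0.30, alpha = 0.05, power = 0.80,
                              nMeasurements = 3, corr = 0.5, epsilon = 1,
                              nMax = 10000) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            corr >= 0, corr < 1, nMeasurements >= 2)
  pows <- numeric(0)
  for (n in 2:nMax) {
    p <- powerRmAnova(n, effectSizeF, alpha, nMeasurements, corr, epsilon)
    pows <- c(pows, p)
    if (p >= power) return(structure(as.integer(n), power = p))
  }
  cond <- structure(class = c("powerSearchError", "error", "condition"),
                    list(message = sprintf("power %g unreachable below N = %d",
                                           power, nMax),
                         call = sys.call(), powerCurve = pows))
  stop(cond)
}

# Check a long data.frame forms a complete balanced within-subject design.
checkBalanced <- function(data, subject, factors) {
  cells <- table(data[[subject]], interaction(data[factors], drop = FALSE))
  if (any(cells != 1))
    stop("design must be complete and balanced: one observation per subject per cell (no imputation)")
  invisible(TRUE)
}

#' Two-way within-subject repeated-measures ANOVA
#'
#' Univariate RM-ANOVA for two within-subject factors: the sums of squares
#' are partitioned into subject, the two main effects, their interaction and
#' a separate subject-by-effect error term for each effect. F ratios use each
#' effect's own error term; partial eta squared is
#' SS_effect / (SS_effect + SS_error). No sphericity correction is applied by
#' default (epsilon = 1), matching integer degrees of freedom
#' (a-1), (n-1)(a-1) for main effects and (a-1)(b-1), (n-1)(a-1)(b-1) for
#' the interaction.
#'
#' @param data long data.frame.
#' @param dv name of the outcome column.
#' @param within character vector of one or two within-factor column names.
#' @param subject name of the subject identifier column.
#' @return data.frame with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p`, `etaPSq`, `ssEffect`, `ssError`. A single within factor yields the
#'   one-way RM-ANOVA.
#' @export
rmAnova <- function(data, dv = "value", within = c("protocol", "time"),
                    subject = "subject") {
  stopifnot(length(within) %in% 1:2, all(c(dv, within, subject) %in% names(data)))
  for (col in c(within, subject)) data[[col]] <- factor(data[[col]])
  checkBalanced(data, subject, within)
  if (nlevels(data[[subject]]) < 2) stop("need at least 2 subjects")
  y <- data[[dv]]
  gm <- mean(y)
  n <- nlevels(data[[subject]])
  cellMean <- function(f) tapply(y, f, mean)
  effRows <- list()
  if (length(within) == 1L) {
    A <- data[[within[1]]]; S <- data[[subject]]
    a <- nlevels(A)
    mA <- cellMean(A); mS <- cellMean(S)
    ssA <- n * sum((mA - gm)^2)
    mAS <- tapply(y, list(A, S), mean)
    ssAS <- sum((sweep(sweep(mAS, 1, mA), 2, mS) + gm)^2)
    df1 <- a - 1; df2 <- (n - 1) * (a - 1)
    Fv <- (ssA / df1) / (ssAS / df2)
    effRows[[1]] <- data.frame(effect = within[1], df1 = df1, df2 = df2,
                               F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
                               etaPSq = ssA / (ssA + ssAS),
                               ssEffect = ssA, ssError = ssAS)
  } else {
    A <- data[[within[1]]]; B <- data[[within[2]]]; S <- data[[subject]]
    a <- nlevels(A); b <- nlevels(B)
    mA <- cellMean(A); mB <- cellMean(B); mS <- cellMean(S)
    mAB <- tapply(y, list(A, B), mean)
    mAS <- tapply(y, list(A, S), mean)
    mBS <- tapply(y, list(B, S), mean)
    ssA <- n * b * sum((mA - gm)^2)
    ssB <- n * a * sum((mB - gm)^2)
    ssAB <- n * sum((mAB - outer(mA, mB, `+`) + gm)^2)
    ssAS <- b * sum((sweep(sweep(mAS, 1, mA), 2, mS) + gm)^2)
    ssBS <- a * sum((sweep(sweep(mBS, 1, mB), 2, mS) + gm)^2)
    ssS <- a * b * sum((mS - gm)^2)
    ssTot <- sum((y - gm)^2)
    ssABS <- ssTot - ssA - ssB - ssAB - ssS - ssAS - ssBS
    mk <- function(name, ssE, d1, ssErr, d2) {
      Fv <- (ssE / d1) / (ssErr / d2)
      data.frame(effect = name, df1 = d1, df2 = d2, F = Fv,
                 p = stats::pf(Fv, d1, d2, lower.tail = FALSE),
                 etaPSq = ssE / (ssE + ssErr), ssEffect = ssE, ssError = ssErr)
    }
    effRows <- list(
      mk(within[1], ssA, a - 1, ssAS, (n - 1) * (a - 1)),
      mk(within[2], ssB, b - 1, ssBS, (n - 1) * (b - 1)),
      mk(paste(within, collapse = ":"), ssAB, (a - 1) * (b - 1),
         ssABS, (n - 1) * (a - 1) * (b - 1)))
  }
  out <- do.call(rbind, effRows)
  rownames(out) <- NULL
  out
}

#' Friedman rank test across matched conditions
#'
#' Non-parametric analogue of the one-way RM-ANOVA: ranks each subject's
#' values across conditions (midranks for ties) and computes the
#' tie-corrected Friedman chi-square with k - 1 degrees of freedom. If every
#' subject's values are completely tied the statistic is undefined and is
#' returned flagged (`degenerate = TRUE`, `NA` statistic).
#'
#' @param mat numeric matrix, subjects x conditions (>= 2 each).
#' @return list with `statistic`, `df`, `p`, `method`, `degenerate`.
#' @export
friedmanTest <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  ranks <- t(apply(mat, 1, rank))
  Rj <- colSums(ranks)
  ties <- sum(apply(mat, 1, function(r) {
    tab <- table(r); sum(tab^3 - tab)
  }))
  denom <- n * k * (k + 1) - ties / (k - 1)
  if (denom <= 0)
    return(list(statistic = NA_real_, df = k - 1, p = NA_real_,
                method = "Friedman", degenerate = TRUE))
  stat <- 12 * sum((Rj - n * (k + 1) / 2)^2) / denom
  list(statistic = stat, df = k - 1,
       p = stats::pchisq(stat, k - 1, lower.tail = FALSE),
       method = "Friedman", degenerate = FALSE)
}

# Wilcoxon signed-rank Z on paired data: zero differences dropped (Wilcoxon's
# rule), midranks for ties, normal approximation with tie correction, no
# continuity correction.
wilcoxonZ <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) return(list(z = 0, V = NA_real_, n = 0))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  list(z = (V - mu) / sqrt(sigma2), V = V, n = n)
}

#' Convert a Z statistic to Cohen's d
#'
#' For non-parametric pairwise tests: r = Z / sqrt(n) and
#' d = 2 r / sqrt(1 - r^2).
#'
#' @param z test statistic.
#' @param n number of pairs.
#' @return Cohen's d (same sign as z).
#' @export
cohensDFromZ <- function(z, n) {
  if (n < 2) stop("need n >= 2")
  r <- z / sqrt(n)
  if (abs(r) >= 1) stop("|z|/sqrt(n) >= 1: n too small for this z")
  2 * r / sqrt(1 - r^2)
}

#' Pairwise post-hoc comparisons across matched conditions
#'
#' All k(k-1)/2 pairwise comparisons between the columns of a subjects x
#' conditions matrix. The parametric branch runs paired t tests with
#' Bonferroni correction and reports Cohen's d_z (mean difference over SD of
#' differences); the non-parametric branch runs Wilcoxon signed-rank tests
#' (normal approximation, zeros dropped, midranks) with Holm correction and
#' reports Cohen's d converted from the Z statistic via [cohensDFromZ()].
#'
#' @param mat numeric matrix, subjects x conditions, with column names.
#' @param parametric logical branch switch.
#' @param alpha significance level for the `direction` annotation.
#' @return data.frame with one row per comparison: `conditionA`,
#'   `conditionB`, `test`, `statistic`, `z`, `pRaw`, `pAdjusted`,
#'   `correction`, `effectSize`, `direction` (e.g. `"ESG > RBG"`, or `""`
#'   when not significant after correction).
#' @export
posthocPairwise <- function(mat, parametric = TRUE, alpha = 0.05) {
  mat <- as.matrix(mat)
  k <- ncol(mat)
  if (k < 2) stop("need at least 2 conditions")
  if (nrow(mat) < 2) stop("need at least 2 paired observations")
  labs <- colnames(mat) %||% paste0("C", seq_len(k))
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(ci) {
    i <- pairs[1, ci]; j <- pairs[2, ci]
    x <- mat[, i]; y <- mat[, j]
    if (parametric) {
      tt <- stats::t.test(x, y, paired = TRUE)
      dz <- mean(x - y) / stats::sd(x - y)
      data.frame(conditionA = labs[i], conditionB = labs[j], test = "paired t",
                 statistic = unname(tt$statistic), z = NA_real_,
                 pRaw = tt$p.value, effectSize = dz)
    } else {
      wz <- wilcoxonZ(x, y)
      p <- 2 * stats::pnorm(-abs(wz$z))
      d <- if (wz$n >= 2) cohensDFromZ(wz$z, wz$n) else NA_real_
      data.frame(conditionA = labs[i], conditionB = labs[j],
                 test = "Wilcoxon signed-rank", statistic = wz$V, z = wz$z,
                 pRaw = p, effectSize = d)
    }
  })
  out <- do.call(rbind, rows)
  out$correction <- if (parametric) "bonferroni" else "holm"
  out$pAdjusted <- stats::p.adjust(out$pRaw, method = out$correction[1])
  out$direction <- vapply(seq_len(nrow(out)), function(r) {
    if (is.na(out$pAdjusted[r]) || out$pAdjusted[r] >= alpha) return("")
    mA <- mean(mat[, out$conditionA[r]]); mB <- mean(mat[, out$conditionB[r]])
    if (mA > mB) paste(out$conditionA[r], ">", out$conditionB[r])
    else paste(out$conditionB[r], ">", out$conditionA[r])
  }, character(1))
  out[, c("conditionA", "conditionB", "test", "statistic", "z", "pRaw",
          "pAdjusted", "correction", "effectSize", "direction")]
}

#' Normality gate for the parametric/non-parametric routing
#'
#' Shapiro--Wilk test in every cell of an outcome variable; the variable is
#' routed to the parametric branch iff no cell rejects normality at `alpha`.
#' Cells with fewer than 3 observations are an error; a zero-variance cell is
#' flagged degenerate (and routed non-parametric).
#'
#' @param cells list of numeric vectors (one per design cell).
#' @param alpha significance level of the gate.
#' @return list with `parametric` (logical), `pValues`, `degenerate`.
#' @export
shapiroGate <- function(cells, alpha = 0.05) {
  if (!length(cells)) stop("no cells supplied")
  pv <- vapply(cells, function(v) {
    if (length(v) < 3) stop("Shapiro-Wilk needs at least 3 observations per cell")
    if (stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  degen <- any(is.na(pv))
  list(parametric = !degen && all(pv >= alpha), pValues = pv,
       degenerate = degen)
}

#' Full statistical comparison of matched conditions
#'
#' The per-variable analysis layer: Shapiro--Wilk gate, then either the
#' parametric route (one-way within-subject RM-ANOVA with partial eta
#' squared, paired t post hocs with Bonferroni correction) or the
#' non-parametric route (Friedman test, Wilcoxon signed-rank post hocs with
#' Holm correction and Z-based Cohen's d). Post hocs are run only when the
#' omnibus test is significant at `alpha`.
#'
#' @param mat subjects x conditions matrix with column names.
#' @param alpha significance level.
#' @param forceParametric override the gate (NULL = use the gate).
#' @return list with `parametric`, `gate`, `omnibus`, `posthoc` (NULL when
#'   the omnibus test is not significant).
#' @export
compareConditions <- function(mat, alpha = 0.05, forceParametric = NULL) {
  mat <- as.matrix(mat)
  gate <- shapiroGate(lapply(seq_len(ncol(mat)), function(j) mat[, j]), alpha)
  parametric <- forceParametric %||% gate$parametric
  if (parametric) {
    long <- data.frame(subject = rep(seq_len(nrow(mat)), ncol(mat)),
                       protocol = rep(colnames(mat), each = nrow(mat)),
                       value = as.vector(mat))
    omni <- rmAnova(long, dv = "value", within = "protocol")
    sig <- omni$p[1] < alpha
  } else {
    omni <- friedmanTest(mat)
    sig <- !is.na(omni$p) && omni$p < alpha
  }
  post <- if (sig) posthocPairwise(mat, parametric = parametric, alpha = alpha)
          else NULL
  list(parametric = parametric, gate = gate, omnibus = omni, posthoc = post)
}
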