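# Shared fixtures and independent oracles for the test suite.

# Gaussian activation bump on the normalized 0-100 grid.
gaussBump <- function(center, width = 10, n = 100) {
  g <- seq(0, 100, length.out = n)
  exp(-0.5 * ((g - center) / width)^2)
}

# A small non-negative rank-k test matrix with known factors.
makeLowRank <- function(nMuscles = 10, k = 3, n = 60, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(nMuscles * k), nMuscles, k)
  C <- t(sapply(seq_len(k), function(i)
    gaussBump(runif(1, 20, 80), runif(1, 8, 15), n)))
  list(W = W, C = C, D = W %*% C)
}

# Independent NMF oracle: alternating non-negative least squares built on
# pracma::lsqnonneg (active-set NNLS), a completely different solver family
# from the package's multiplicative updates.
anlsNmf <- function(D, k, maxIter = 30, nRestarts = 3, seed = 1) {
  best <- NULL
  for (r in seq_len(nRestarts)) {
    set.seed(seed * 1000 + r)
    W <- matrix(runif(nrow(D) * k, 0.01, 1), nrow(D), k)
    C <- matrix(0, k, ncol(D))
    sseOld <- Inf
    for (it in seq_len(maxIter)) {
      for (j in seq_len(ncol(D))) C[, j] <- pracma::lsqnonneg(W, D[, j])$x
      for (i in seq_len(nrow(D))) W[i, ] <- pracma::lsqnonneg(t(C), D[i, ])$x
      sse <- sum((D - W %*% C)^2)
      if (is.finite(sseOld) && sseOld - sse < 1e-10 * sseOld) break
      sseOld <- sse
    }
    if (is.null(best) || sse < best$sse)
      best <- list(W = W, C = C, sse = sse)
  }
  best$vaf <- 1 - best$sse / sum(D^2)
  best
}

# RM-ANOVA oracle via stats::aov with within-subject error strata.
aovRmOracle <- function(df) {
  df$subject <- factor(df$subject)
  df$protocol <- factor(df$protocol)
  df$time <- factor(df$time)
  fit <- stats::aov(value ~ protocol * time +
                      Error(subject / (protocol * time)), data = df)
  s <- summary(fit)
  pick <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tab)), fixed = TRUE)
    i <- i[trimws(rownames(tab))[i] == term]
    err <- grep("Residuals", rownames(tab))
    list(F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
         etaPSq = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + tab[err, "Sum Sq"]),
         df1 = tab[i, "Df"], df2 = tab[err, "Df"])
  }
  list(protocol = pick("Error: subject:protocol", "protocol"),
       time = pick("Error: subject:time", "time"),
       interaction = pick("Error: subject:protocol:time", "protocol:time"))
}

# Null jump data: all cells share one mean, subject intercepts at rho = 0.5.
nullJumpTable <- function(mean = 47, sd = 3) {
  tab <- defaultJumpTable()
  tab$mean <- mean
  tab$sd <- sd
  tab
}
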