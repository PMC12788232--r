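test_that("flight-time jump height follows the quadratic law", {
  expect_equal(jumpHeight(0), 0)
  expect_equal(jumpHeight(0.6328), 49.1, tolerance = 0.05 / 49.1)
  expect_equal(jumpHeight(2 * 0.4), 4 * jumpHeight(0.4))
  expect_error(jumpHeight(-0.1), "non-negative")
  expect_equal(bestOfJumps(c(46.0, 48.2, 47.1)), 48.2)
  expect_equal(bestOfJumps(rep(44, 3)), 44)
  expect_equal(bestOfJumps(c(48.2, 46.0, 47.1)), bestOfJumps(c(46.0, 47.1, 48.2)))
  expect_error(bestOfJumps(numeric(0)), "at least one")
})

test_that("RM-ANOVA power matches the noncentral-t oracle for two measurements", {
  # with m = 2 and correlation rho the within test is the paired t test with
  # dz = f * sqrt(m/(1-rho)); power.t.test is an independent noncentral-t route
  for (n in c(10, 20, 54)) {
    mine <- powerRmAnova(n, effectSizeF = 0.25, nMeasurements = 2, corr = 0.5)
    oracle <- stats::power.t.test(n = n, delta = 0.5, sd = 1,
                                  sig.level = 0.05, strict = TRUE,
                                  type = "one.sample")$power
    expect_equal(mine, oracle, tolerance = 1e-6)
  }
  nMine <- rmAnovaSampleSize(effectSizeF = 0.25, power = 0.95,
                             nMeasurements = 2, corr = 0.5)
  nOracle <- 2
  while (stats::power.t.test(n = nOracle, delta = 0.5, sd = 1, strict = TRUE,
                             type = "one.sample")$power < 0.95)
    nOracle <- nOracle + 1
  expect_identical(as.integer(nMine), as.integer(nOracle))
  # monotonicity: a larger effect never needs more subjects
  expect_lte(rmAnovaSampleSize(effectSizeF = 0.60),
             rmAnovaSampleSize(effectSizeF = 0.30))
  err <- tryCatch(rmAnovaSampleSize(effectSizeF = 0.01, nMax = 50),
                  powerSearchError = identity)
  expect_s3_class(err, "powerSearchError")
  expect_true(length(err$powerCurve) > 0)
})

test_that("two-way within-subject ANOVA agrees with the aov error-strata oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    df <- expand.grid(subject = 1:6, protocol = c("A", "B", "C"),
                      time = c("t1", "t2", "t3"))
    subjEff <- rnorm(6, 0, 2)
    df$value <- rnorm(nrow(df)) + subjEff[df$subject] +
      as.integer(df$protocol) * 0.5 * (seed %% 2)
    mine <- rmAnova(df, dv = "value", within = c("protocol", "time"))
    oracle <- aovRmOracle(df)
    for (pair in list(c("protocol", "protocol"), c("time", "time"),
                      c("protocol:time", "interaction"))) {
      row <- mine[mine$effect == pair[1], ]
      orc <- oracle[[pair[2]]]
      expect_equal(row$F, orc$F, tolerance = 1e-6)
      expect_equal(row$p, orc$p, tolerance = 1e-6)
      expect_equal(row$etaPSq, orc$etaPSq, tolerance = 1e-6)
      expect_equal(c(row$df1, row$df2), c(orc$df1, orc$df2),
                   ignore_attr = TRUE)
    }
  }
})

test_that("degrees of freedom and degenerate effects behave as expected", {
  set.seed(2)
  df <- expand.grid(subject = 1:18, protocol = c("ESG", "RBG", "SQG"),
                    time = c(6, 8, 10))
  df$value <- rnorm(nrow(df), 47, 3)
  res <- rmAnova(df, dv = "value", within = c("protocol", "time"))
  expect_equal(res$df1, c(2, 2, 4))
  expect_equal(res$df2, c(34, 34, 68))
  # zero between-condition variation (balanced cancelling subject offsets)
  # gives F = 0 for that effect while the error term stays positive
  df0 <- df
  sgn <- rep(c(1, -1), each = 9)
  df0$value <- rnorm(nrow(df0), 47, 3) +
    sgn[df0$subject] * (df0$protocol == "ESG")
  prot <- tapply(df0$value, df0$protocol, mean)
  df0$value <- df0$value - prot[as.character(df0$protocol)]  # exact zero effect
  res0 <- rmAnova(df0, dv = "value", within = c("protocol", "time"))
  expect_lt(res0$F[res0$effect == "protocol"], 1e-12)
  # incomplete designs are refused
  expect_error(rmAnova(df[-1, ], dv = "value", within = c("protocol", "time")),
               "balanced")
  # one-way layout agrees with aov as well
  d1 <- df[df$time == 6, ]
  mine1 <- rmAnova(d1, dv = "value", within = "protocol")
  fit <- stats::aov(value ~ protocol + Error(factor(subject)),
                    data = transform(d1, protocol = factor(protocol)))
  tab <- summary(fit)[["Error: Within"]][[1]]
  expect_equal(mine1$F, tab["protocol", "F value"], tolerance = 1e-6)
  expect_equal(mine1$p, tab["protocol", "Pr(>F)"], tolerance = 1e-6)
})

test_that("Friedman statistic matches the hand formula and stats oracle", {
  # 3 subjects ranking 3 conditions identically, no ties: chi2 = 6
  m <- rbind(c(1, 2, 3), c(1.5, 2.5, 3.5), c(10, 20, 30))
  expect_equal(friedmanTest(m)$statistic, 6)
  expect_equal(friedmanTest(m)$df, 2)
  # column permutation leaves the statistic unchanged
  expect_equal(friedmanTest(m[, c(3, 1, 2)])$statistic,
               friedmanTest(m)$statistic)
  # oracle equivalence, with and without ties
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(8 * 4), 8)
    if (seed > 3) x <- round(x, 0)  # induce ties
    mine <- friedmanTest(x)
    orc <- stats::friedman.test(x)
    expect_equal(mine$statistic, unname(orc$statistic), tolerance = 1e-9)
    expect_equal(mine$p, orc$p.value, tolerance = 1e-9)
  }
  degen <- friedmanTest(matrix(1, 3, 3))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$statistic))
})

test_that("pairwise post hocs apply the documented corrections", {
  set.seed(9)
  m <- cbind(ESG = rnorm(12, 49, 2), RBG = rnorm(12, 46, 2),
             SQG = rnorm(12, 47, 2))
  par <- posthocPairwise(m, parametric = TRUE)
  expect_identical(nrow(par), 3L)  # k(k-1)/2
  expect_identical(par$correction[1], "bonferroni")
  expect_equal(par$pAdjusted, pmin(1, par$pRaw * 3))
  expect_true(all(par$pAdjusted >= par$pRaw))
  # paired t agrees with stats::t.test
  tt <- t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(par$statistic[1], unname(tt$statistic), tolerance = 1e-9)
  expect_equal(par$pRaw[1], tt$p.value, tolerance = 1e-9)
  expect_match(par$direction[1], "ESG > RBG")

  np <- posthocPairwise(m, parametric = FALSE)
  expect_identical(np$correction[1], "holm")
  # Holm sequence is the step-down ordered multiplication, capped and monotone
  o <- order(np$pRaw)
  holm <- cummax(pmin(1, (3:1) * np$pRaw[o]))
  expect_equal(np$pAdjusted[o], holm)
  # Wilcoxon Z-based p agrees with the normal-approximation oracle
  wt <- stats::wilcox.test(m[, 1], m[, 2], paired = TRUE, exact = FALSE,
                           correct = FALSE)
  expect_equal(np$pRaw[1], wt$p.value, tolerance = 1e-9)
  expect_equal(np$statistic[1], unname(wt$statistic), tolerance = 1e-9)
  expect_error(posthocPairwise(m[, 1, drop = FALSE]), "2 conditions")
})

test_that("zero differences are dropped by the Wilcoxon rule", {
  x <- c(5, 6, 7, 8, 9, 10)
  y <- c(5, 6, 5, 6, 7, 8)  # two zero differences
  wz <- synergetics:::wilcoxonZ(x, y)
  expect_identical(wz$n, 4L)
  wt <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(2 * pnorm(-abs(wz$z)), wt$p.value, tolerance = 1e-9)
})

test_that("Cohen's d from Z follows r = Z/sqrt(n), d = 2r/sqrt(1-r^2)", {
  expect_equal(cohensDFromZ(0, 16), 0)
  expect_equal(cohensDFromZ(2, 16), 2 * 0.5 / sqrt(0.75))
  expect_equal(cohensDFromZ(2, 16), 1.1547005, tolerance = 1e-6)
  expect_equal(cohensDFromZ(-2, 16), -cohensDFromZ(2, 16))
  expect_error(cohensDFromZ(5, 4), "too small")
  expect_error(cohensDFromZ(1, 1), "n >= 2")
})

test_that("the normality gate routes by Shapiro-Wilk across cells", {
  # Gaussian cells: parametric fraction consistent with (1-alpha)^3 per seed
  nPar <- 0
  for (s in 1:100) {
    set.seed(s)
    cells <- replicate(3, rnorm(18), simplify = FALSE)
    nPar <- nPar + shapiroGate(cells)$parametric
  }
  p3 <- 0.95^3
  band <- qbinom(c(0.005, 0.995), 100, p3)
  expect_gte(nPar, band[1])
  expect_lte(nPar, band[2])
  # heavily skewed cells go non-parametric nearly always
  nNp <- 0
  for (s in 1:60) {
    set.seed(s)
    nNp <- nNp + !shapiroGate(replicate(3, exp(rnorm(18, 0, 1.5)),
                                        simplify = FALSE))$parametric
  }
  expect_gte(nNp / 60, 0.95)
  expect_error(shapiroGate(list(c(1, 2))), "at least 3")
  degen <- shapiroGate(list(rep(1, 10), rnorm(10)))
  expect_true(degen$degenerate)
  expect_false(degen$parametric)
})

test_that("compareConditions routes and annotates coherently", {
  set.seed(4)
  m <- cbind(ESG = rnorm(15, 50, 2), RBG = rnorm(15, 46, 2),
             SQG = rnorm(15, 47, 2))
  res <- compareConditions(m)
  expect_true(res$parametric)
  expect_identical(res$omnibus$effect[1], "protocol")
  expect_true(any(grepl("ESG > RBG", res$posthoc$direction)))
  resNp <- compareConditions(m, forceParametric = FALSE)
  expect_identical(resNp$omnibus$method, "Friedman")
})
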