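# Trend smoothing, LOOCV, model comparison and the probe filter.

test_that("exact data are interpolated exactly", {
  f <- fitTrend(c(0, 1, 2), c(1, 0, 1), "quadratic")
  expect_equal(unname(f@coefficients), c(1, -2, 1), tolerance = 1e-10)
  expect_equal(f@sse, 0, tolerance = 1e-20)

  g <- fitTrend(0:3, 0:3, "linear")
  expect_equal(unname(g@coefficients), c(0, 1), tolerance = 1e-12)
  expect_equal(g@sse, 0, tolerance = 1e-20)
})

test_that("polynomial fits match the normal-equations oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- sort(runif(30, 0, 10))
    y <- 1.5 - 0.8 * a + 0.12 * a^2 + rnorm(30, 0, 0.4)
    for (mod in c("linear", "quadratic", "cubic")) {
      d <- c(linear = 1, quadratic = 2, cubic = 3)[[mod]]
      f <- fitTrend(a, y, mod)
      expect_equal(unname(f@coefficients), unname(oracle_polyfit(a, y, d)),
                   tolerance = 1e-8)
      expect_equal(f@sse, sum((y - f@fitted)^2), tolerance = 1e-10)
    }
  }
})

test_that("fits are deterministic and degenerate designs error", {
  a <- sort(runif(20, 25, 90)); y <- rnorm(20)
  f1 <- fitTrend(a, y, "cubic"); f2 <- fitTrend(a, y, "cubic")
  expect_identical(f1@coefficients, f2@coefficients)
  expect_identical(f1@fitted, f2@fitted)

  expect_error(fitTrend(c(1, 2, 3), c(1, 2, 3), "cubic"), "at least 4")
  expect_error(fitTrend(rep(50, 10), rnorm(10), "quadratic"),
               "ages identical")
  expect_error(fitTrend(rep(c(40, 70), 5), rnorm(10), "qbspline"),
               "qbspline")
})

test_that("spline and loess fits track a curved trend", {
  set.seed(4)
  a <- sort(runif(40, 25, 95))
  truth <- sin((a - 25) / 18)
  y <- truth + rnorm(40, 0, 0.1)
  for (mod in c("qbspline", "loess")) {
    f <- fitTrend(a, y, mod)
    expect_gte(f@sse, 0)
    expect_gt(cor(f@fitted, truth), 0.95)
    pr <- predictTrend(f, seq(30, 90, by = 5))
    expect_length(pr, 13)
    expect_error(predictTrend(f, 20), "outside")
  }
})

test_that("LOOCV equals the brute-force refit oracle", {
  # exact linear data: zero error
  expect_equal(loocvError(1:5, 2 * (1:5) + 3, "linear"), 0,
               tolerance = 1e-18)

  for (seed in 1:5) {
    set.seed(seed)
    a <- sort(runif(12, 0, 10))
    y <- 0.3 * a^2 - a + rnorm(12, 0, 0.5)
    expect_equal(loocvError(a, y, "linear"),
                 oracle_loocv(a, y, fit_predict_poly(1)), tolerance = 1e-10)
    expect_equal(loocvError(a, y, "quadratic"),
                 oracle_loocv(a, y, fit_predict_poly(2)), tolerance = 1e-10)
  }

  # qbspline: oracle refits with the same (full-data) basis
  set.seed(9)
  a <- sort(runif(15, 25, 95))
  y <- rnorm(15)
  knots <- unname(quantile(a, c(1 / 3, 2 / 3)))
  B <- splines::bs(a, knots = knots, degree = 2, intercept = TRUE,
                   Boundary.knots = range(a))
  oracle <- mean(vapply(1:15, function(i) {
    cf <- qr.coef(qr(B[-i, , drop = FALSE]), y[-i])
    (y[i] - sum(B[i, ] * cf))^2
  }, numeric(1)))
  expect_equal(loocvError(a, y, "qbspline"), oracle, tolerance = 1e-10)

  # the brute-force 4-point linear case from first principles
  a4 <- c(1, 2, 4, 7); y4 <- c(0.5, 1.1, 2.3, 3.0)
  expect_equal(loocvError(a4, y4, "linear"),
               oracle_loocv(a4, y4, fit_predict_poly(1)), tolerance = 1e-10)
})

test_that("quadratic beats linear by LOOCV on bent data", {
  wins <- vapply(1:20, function(seed) {
    set.seed(seed)
    a <- sort(runif(30, 25, 95))
    y <- 0.001 * (a - 60)^2 + rnorm(30, 0, 0.3)
    loocvError(a, y, "quadratic") < loocvError(a, y, "linear")
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("probe p-values handle the degenerate cases", {
  expect_equal(probePValue(1:10, rep(4, 10)), 1)
  a <- seq(20, 90, length.out = 10)
  expect_equal(probePValue(a, 2 + 0.1 * a - 0.01 * a^2),
               .Machine$double.xmin)
  expect_error(probePValue(1:3, rnorm(3)), "at least 4")
})

test_that("probe p-values match the numeric F-tail oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    a <- sort(runif(n, 25, 95))
    y <- rnorm(n)
    p <- probePValue(a, y)
    # recompute F from explicit fits, integrate the density
    b <- oracle_polyfit(a - 60, y, 2)         # shifted for conditioning
    sse2 <- sum((y - outer(a - 60, 0:2, `^`) %*% b)^2)
    sse0 <- sum((y - mean(y))^2)
    f <- ((sse0 - sse2) / 2) / (sse2 / (n - 3))
    expect_equal(p, oracle_f_tail(f, 2, n - 3), tolerance = 1e-8)
  }
})

test_that("SSE is monotone over nested models on every probe", {
  set.seed(12)
  d <- quad_dataset(15, 25, seed = 12)
  a <- unname(ages(d))
  for (pr in rownames(d)) {
    y <- exprsValues(d)[pr, ]
    sse <- vapply(c("linear", "quadratic", "cubic"), function(mod)
      fitTrend(a, y, mod)@sse, numeric(1))
    sse0 <- sum((y - mean(y))^2)
    expect_lte(sse[["cubic"]], sse[["quadratic"]] + 1e-10)
    expect_lte(sse[["quadratic"]], sse[["linear"]] + 1e-10)
    expect_lte(sse[["linear"]], sse0 + 1e-10)
  }
})

test_that("filterProbes agrees with per-probe p-values and respects alpha", {
  d <- quad_dataset(40, 30, seed = 3)
  flt <- filterProbes(d, alpha = 0.05)
  a <- unname(ages(d))
  pv <- vapply(rownames(d), function(pr)
    probePValue(a, exprsValues(d)[pr, ]), numeric(1))
  expect_equal(flt$fits$p_value, unname(pv), tolerance = 1e-10)
  expect_setequal(flt$significant,
                  rownames(d)[pv < 0.05])
  # coefficient rows match fitTrend on the raw-age scale
  f1 <- fitTrend(a, exprsValues(d)[1, ])
  expect_equal(as.numeric(flt$fits[1, c("beta0", "beta1", "beta2")]),
               unname(f1@coefficients), tolerance = 1e-8)

  expect_identical(filterProbes(d, alpha = 0)$significant, character(0))
})

test_that("null probes are retained at roughly the nominal rate", {
  fr <- vapply(1:5, function(seed) {
    d <- noise_dataset(800, 30, seed = 100 + seed)
    length(filterProbes(d, 0.05)$significant) / 800
  }, numeric(1))
  expect_true(all(fr > 0.02 & fr < 0.09))
  expect_gt(mean(fr), 0.03)
  expect_lt(mean(fr), 0.07)
})

test_that("signal probes are recovered by the filter", {
  sim <- simulateDataset(simulationConfig(nProbes = 600, signalPerBend = 90,
                                          seed = 21))
  flt <- filterProbes(correctSex(sim$dataset))
  sc <- scoreRecovery(sim$truth, numeric(0), flt$significant)
  expect_gte(sc$recall, 0.8)
})

test_that("model comparison ties on exact lines and ranks by mean error", {
  a <- seq(20, 90, length.out = 12)
  m <- rbind(p1 = 1 + 0.5 * a, p2 = 3 - 0.2 * a, p3 = 0.1 * a)
  colnames(m) <- paste0("s", 1:12)
  d <- AgingExperiment(m, a, rep_len(c("female", "male"), 12),
                       normalized = TRUE)
  cmp <- compareModels(d, c("linear", "quadratic", "cubic"))
  expect_equal(unname(cmp@meanErrors), rep(0, 3), tolerance = 1e-16)
  expect_equal(unname(cmp@pairwisePValues["linear", "quadratic"]), 1)

  single <- compareModels(d, "linear")
  expect_identical(single@winner, "linear")
  expect_true(all(is.na(single@pairwisePValues)))

  d2 <- quad_dataset(30, 30, seed = 5, curv = 0.003)
  cmp2 <- compareModels(d2, c("linear", "quadratic"))
  expect_identical(cmp2@winner, "quadratic")
  expect_lt(cmp2@pairwisePValues["linear", "quadratic"], 0.05)
})
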