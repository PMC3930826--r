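# Trend centering, the two k-means metrics, percentile bands, stability.

test_that("centering removes levels and keeps shapes", {
  grid <- c(0, 1, 2)
  fits <- data.frame(probe_id = c("flat", "quad", "quad_shift"),
                     beta0 = c(4, 1, 11), beta1 = c(0, -2, -2),
                     beta2 = c(0, 1, 1))
  tm <- centerTrends(fits, grid)
  expect_equal(unname(tm@trends["flat", ]), c(0, 0, 0))
  # quadratic (1,-2,1): fitted (1,0,1), centered (1/3,-2/3,1/3)
  expect_equal(unname(tm@trends["quad", ]), c(1, -2, 1) / 3,
               tolerance = 1e-12)
  # y(t) + 10 centers to the same row
  expect_equal(tm@trends["quad_shift", ], tm@trends["quad", ],
               tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(tm@trends))), 1e-10)
})

test_that("TrendFit lists center like coefficient tables, within range", {
  set.seed(2)
  a <- sort(runif(20, 25, 95))
  y <- 0.002 * (a - 50)^2 + rnorm(20, 0, 0.1)
  f <- fitTrend(a, y, "quadratic")
  grid <- seq(ceiling(min(a)), floor(max(a)), by = 1)
  tm <- centerTrends(list(pX = f), grid)
  fits <- data.frame(probe_id = "pX", beta0 = f@coefficients[1],
                     beta1 = f@coefficients[2], beta2 = f@coefficients[3])
  tm2 <- centerTrends(fits, grid)
  expect_equal(tm@trends, tm2@trends, tolerance = 1e-9)
  expect_error(centerTrends(list(pX = f), seq(10, 90, 1)), "outside")
})

test_that("mirrored probes are identical under absolute correlation", {
  grid <- 25:95
  x <- sin((grid - 25) / 15)
  rows <- rbind(a = x, b = -x, c = 2 * x + 1, d = -0.5 * x + 3)
  tm <- trend_matrix(rows, grid)
  X <- tm@trends
  r <- abs(cor(X["a", ], X["b", ]))
  expect_equal(r, 1, tolerance = 1e-12)
  # distance 0 between a probe, its mirror, and any affine image (a != 0)
  noise <- trend_matrix(matrix(rnorm(10 * 71), 10, 71), grid)
  tm2 <- trend_matrix(rbind(rows, noise@trends), grid)
  cl <- kmeansTrends(tm2, 2, metric = "abscorrelation", restarts = 10,
                     seed = 1)
  expect_equal(length(unique(cl@assignments[c("a", "b", "c", "d")])), 1L)
})

test_that("euclidean k-means finds the exhaustive optimum on small cases", {
  set.seed(7)
  grid <- seq(30, 80, by = 10)
  centers <- rbind(seq(-1, 1, length.out = 6), seq(1, -1, length.out = 6))
  X <- centers[rep(1:2, each = 5), ] + matrix(rnorm(60, 0, 0.15), 10, 6)
  tm <- trend_matrix(X, grid)
  cl <- kmeansTrends(tm, 2, metric = "euclidean", restarts = 20, seed = 3)
  expect_equal(cl@totalWithin,
               oracle_kmeans_objective(tm@trends, 2), tolerance = 1e-8)
  # the two planted families are recovered exactly
  expect_identical(canonical_partition(unname(cl@assignments)),
                   canonical_partition(rep(1:2, each = 5)))

  # k = 3 against the exhaustive optimum on 9 probes
  set.seed(8)
  X3 <- matrix(rnorm(9 * 4), 9, 4)
  tm3 <- trend_matrix(X3, c(30, 45, 60, 75))
  cl3 <- kmeansTrends(tm3, 3, metric = "euclidean", restarts = 60, seed = 4)
  expect_equal(cl3@totalWithin,
               oracle_kmeans_objective(tm3@trends, 3), tolerance = 1e-8)
})

test_that("euclidean objective matches stats::kmeans on separable data", {
  set.seed(11)
  ctr <- matrix(rnorm(3 * 8, sd = 4), 3, 8)
  X <- ctr[rep(1:3, each = 12), ] + matrix(rnorm(36 * 8, 0, 0.3), 36, 8)
  tm <- trend_matrix(X, seq(20, 90, by = 10))
  cl <- kmeansTrends(tm, 3, metric = "euclidean", restarts = 30, seed = 2)
  km <- kmeans(tm@trends, centers = 3, nstart = 30)
  expect_equal(cl@totalWithin, km$tot.withinss, tolerance = 1e-6)
  expect_identical(canonical_partition(unname(cl@assignments)),
                   canonical_partition(unname(km$cluster)))
})

test_that("abscorrelation distance is affine-invariant per probe", {
  set.seed(5)
  grid <- 25:95
  base <- plogis((grid - 55) / 4)
  fam1 <- outer(runif(6, 0.5, 2) * sample(c(-1, 1), 6, TRUE), base)
  fam2 <- outer(runif(6, 0.5, 2) * sample(c(-1, 1), 6, TRUE),
                sin((grid - 25) / 8))
  tm <- trend_matrix(rbind(fam1, fam2), grid)
  cl <- kmeansTrends(tm, 2, metric = "abscorrelation", restarts = 10,
                     seed = 6)
  expect_identical(canonical_partition(unname(cl@assignments)),
                   canonical_partition(rep(1:2, each = 6)))
})

test_that("percentile bands nest and match order statistics", {
  set.seed(9)
  grid <- seq(30, 80, by = 25)
  X <- matrix(rnorm(100 * 3), 100, 3)
  tm <- trend_matrix(X, grid)
  assign <- setNames(rep(1L, 100), rownames(tm@trends))
  b95 <- percentileBands(tm, assign, 95)[[1]]
  b99 <- percentileBands(tm, assign, 99)[[1]]
  expect_true(all(b99["lower", ] <= b95["lower", ]))
  expect_true(all(b99["upper", ] >= b95["upper", ]))
  # direct order-statistic oracle (type-7 interpolation by hand)
  v <- sort(unname(tm@trends[, 2]))
  h <- (100 - 1) * 0.025
  lo <- v[floor(h) + 1] + (h - floor(h)) * (v[floor(h) + 2] - v[floor(h) + 1])
  expect_equal(unname(b95["lower", 2]), lo, tolerance = 1e-12)

  # identical rows give zero-width bands
  tmc <- trend_matrix(matrix(rep(c(1, 0, -1), each = 5), 5, 3), grid)
  bc <- percentileBands(tmc, setNames(rep(1L, 5), rownames(tmc@trends)), 95)
  expect_equal(bc[[1]]["upper", ], bc[[1]]["lower", ], tolerance = 1e-12)

  tiny <- trend_matrix(matrix(rnorm(6), 2, 3), grid)
  expect_warning(percentileBands(tiny,
                                 setNames(rep(1L, 2), rownames(tiny@trends)),
                                 95), "fewer than 3")
  expect_error(percentileBands(tm, assign, 90), "95 or 99")
})

test_that("stability scan prefers the planted number of families", {
  set.seed(13)
  grid <- seq(25, 95, by = 5)
  shapes <- rbind(plogis((grid - 45) / 3), -plogis((grid - 45) / 3),
                  plogis((grid - 75) / 3), -plogis((grid - 75) / 3))
  X <- shapes[rep(1:4, each = 8), ] + matrix(rnorm(32 * 15, 0, 0.03), 32, 15)
  tm <- trend_matrix(X, grid)
  sc <- stabilityScan(tm, kSequence = c(8, 6, 4), metric = "euclidean",
                      restarts = 15, seed = 1)
  expect_identical(sc$recommendedK, 4)
  k4 <- sc$scan[sc$scan$k == 4, ]
  expect_gte(k4$convergenceFraction, 0.9)
  # within dissimilarity cannot rise as k grows (checked on the scan)
  ord <- order(sc$scan$k)
  expect_true(all(diff(sc$scan$totalWithin[ord]) <= 1e-8))
})
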