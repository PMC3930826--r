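# Reciprocal splitting, bend-age detection, ranges and directions.

# A TrendMatrix of mirrored sigmoid trends bending at `bend` plus a
# single-cluster ClusterResult covering them all (centroid oriented with
# the up family).
mirrored_cluster <- function(bend, grid = 25:95, nPer = 10, noise = 0,
                             seed = 1) {
  set.seed(seed)
  base <- plogis((grid - bend) / 3)
  up <- outer(rep(1, nPer), base)
  down <- -up
  X <- rbind(up, down) + matrix(rnorm(2 * nPer * length(grid), 0, noise),
                                2 * nPer, length(grid))
  rownames(X) <- c(sprintf("up%02d", seq_len(nPer)),
                   sprintf("dn%02d", seq_len(nPer)))
  tm <- trend_matrix(X, grid)
  list(tm = tm, cl = one_cluster(tm))
}

# Wrap every probe of a TrendMatrix into one cluster whose centroid is
# the mean of the rows positively correlated with the first row.
one_cluster <- function(tm) {
  X <- tm@trends
  r <- drop(cor(t(X), X[1, ]))
  ctr <- colMeans(X * ifelse(r < 0, -1, 1))
  methods::new("ClusterResult", k = 1L, metric = "abscorrelation",
               assignments = setNames(rep(1L, nrow(X)), rownames(X)),
               centroids = matrix(ctr, 1), ageGrid = tm@ageGrid,
               withinSS = 0, totalWithin = 0, converged = TRUE,
               nIterations = 1L)
}

test_that("reciprocal subgroups split by correlation sign", {
  grid <- 25:95
  x <- plogis((grid - 50) / 4)
  tm <- trend_matrix(rbind(a = x, b = -x, flat1 = grid * 0 + rnorm(71, 0, 1),
                           flat2 = rnorm(71)), grid)
  cl <- kmeansTrends(tm, 2, metric = "abscorrelation", restarts = 5,
                     seed = 2)
  cid <- unname(cl@assignments["a"])
  expect_identical(cl@assignments[["b"]], cid)
  sub <- splitReciprocal(tm, cl, cid)
  expect_true((("a" %in% sub$A) && ("b" %in% sub$B)) ||
                (("a" %in% sub$B) && ("b" %in% sub$A)))
})

test_that("mirrored families split exactly along the truth", {
  mc <- mirrored_cluster(bend = 55, noise = 0.02, seed = 3)
  sub <- splitReciprocal(mc$tm, mc$cl, 1)
  ups <- grep("^up", rownames(mc$tm@trends), value = TRUE)
  dns <- grep("^dn", rownames(mc$tm@trends), value = TRUE)
  expect_true(setequal(sub$A, ups) || setequal(sub$A, dns))
  expect_identical(length(sub$A), 10L)
  expect_identical(length(sub$B), 10L)
})

test_that("an all-one-sign cluster yields an empty subgroup", {
  set.seed(4)
  grid <- seq(30, 90, by = 2)
  x <- plogis((grid - 60) / 3)
  rows <- outer(runif(6, 0.5, 2), x)      # all positively correlated
  rownames(rows) <- sprintf("u%d", 1:6)
  tm <- trend_matrix(rows, grid)
  sub <- splitReciprocal(tm, one_cluster(tm), 1)
  expect_identical(length(sub$B), 0L)
  expect_identical(length(sub$A), 6L)
})

test_that("a symmetric zero crossing is located exactly", {
  grid <- 25:95
  g <- (grid - 60) / 35                    # strictly increasing, g(60) = 0
  tm <- trend_matrix(rbind(up1 = g, up2 = g, dn1 = -g, dn2 = -g), grid)
  pos <- detectAgePosition(tm, one_cluster(tm), 1)
  expect_equal(pos@age, 60, tolerance = 1e-8)
  expect_identical(pos@method, "intersection")
  expect_identical(pos@nUp, 2L)
  expect_identical(pos@nDown, 2L)
})

test_that("intersection and band-minimum agree on exact mirrored data", {
  mc <- mirrored_cluster(bend = 55, noise = 0.01, seed = 5)
  pos <- detectAgePosition(mc$tm, mc$cl, 1)
  expect_identical(pos@method, "intersection")
  bands <- suppressWarnings(
    percentileBands(mc$tm, mc$cl@assignments, 95))[[1]]
  hw <- (bands["upper", ] - bands["lower", ]) / 2
  bandAge <- mc$tm@ageGrid[which.min(hw)]
  expect_lte(abs(pos@age - bandAge), 1)    # within one grid step
})

test_that("detection is invariant to rescaling and flat clusters error", {
  mc <- mirrored_cluster(bend = 48, noise = 0.02, seed = 6)
  pos1 <- detectAgePosition(mc$tm, mc$cl, 1)
  tm2 <- methods::new("TrendMatrix", ageGrid = mc$tm@ageGrid,
                      trends = mc$tm@trends * 7)
  pos2 <- detectAgePosition(tm2, mc$cl, 1)
  expect_equal(pos2@age, pos1@age, tolerance = 1e-10)

  flat <- trend_matrix(matrix(0, 4, 71), 25:95)
  clFlat <- methods::new("ClusterResult", k = 1L,
                         metric = "abscorrelation",
                         assignments = setNames(rep(1L, 4),
                                                rownames(flat@trends)),
                         centroids = matrix(0, 1, 71), ageGrid = 25:95,
                         withinSS = 0, totalWithin = 0, converged = TRUE,
                         nIterations = 1L)
  expect_error(detectAgePosition(flat, clFlat, 1), "no age-position")
})

test_that("direction calls follow the post-bend change", {
  grid <- 25:95
  up <- (grid - 25) / 70                   # monotone increasing
  tm <- trend_matrix(rbind(mono = up, mirror = -up), grid)
  pos <- methods::new("AgePosition", age = 60, range = NA_real_,
                      clusterId = 1L, method = "intersection",
                      probeIds = c("mono", "mirror"), nUp = 1L, nDown = 1L,
                      directions = c(mono = "up", mirror = "down"))
  dirs <- classifyDirections(pos, tm)
  expect_identical(dirs$directions[["mono"]], "up")
  expect_identical(dirs$directions[["mirror"]], "down")
  expect_identical(dirs$nUp, 1L)

  # 60% down-generated probes recovered exactly at zero noise
  base <- plogis((grid - 55) / 3)
  X <- rbind(outer(rep(1, 4), base), outer(rep(-1, 6), base))
  rownames(X) <- sprintf("p%02d", 1:10)
  tmd <- trend_matrix(X, grid)
  posd <- methods::new("AgePosition", age = 55, range = NA_real_,
                       clusterId = 1L, method = "intersection",
                       probeIds = rownames(X), nUp = 4L, nDown = 6L,
                       directions = setNames(rep("up", 10), rownames(X)))
  dd <- classifyDirections(posd, tmd)
  expect_identical(dd$nDown, 6L)
})

test_that("the across-k range summarizes matched estimates", {
  expect_identical(agebend:::.rangeFromEstimates(c(43, 46, 40)), 3)
  expect_identical(agebend:::.rangeFromEstimates(c(50, 50, 50)), 0)
  expect_identical(agebend:::.rangeFromEstimates(c(60.2, 62.5)), 2)
})

test_that("two-bend synthetic trends yield two matched position groups", {
  set.seed(20)
  grid <- 25:95
  mk <- function(bend, n) {
    s <- plogis((grid - bend) / 3)
    out <- outer(c(rep(1, n / 2), rep(-1, n / 2)), s) +
      matrix(rnorm(n * length(grid), 0, 0.02), n, length(grid))
    out
  }
  X <- rbind(mk(45, 12), mk(75, 12))
  rownames(X) <- sprintf("p%02d", 1:24)
  tm <- trend_matrix(X, grid)
  pos <- findAgePositions(tm, kValues = c(2, 3, 4), restarts = 10, seed = 3)
  expect_identical(length(pos), 2L)
  agesFound <- sort(vapply(pos, function(p) p@age, numeric(1)))
  # sigmoid trends cross where they pass their own grid mean
  expected <- vapply(c(45, 75), function(b) {
    s <- plogis((grid - b) / 3); cs <- s - mean(s)
    i <- max(which(cs < 0)); grid[i] - cs[i] / (cs[i + 1] - cs[i])
  }, numeric(1))
  expect_lt(max(abs(agesFound - sort(expected))), 1.5)
  expect_true(all(vapply(pos, function(p) p@range, numeric(1)) >= 0))
  est <- attr(pos, "estimates")
  expect_true(all(c(2, 3, 4) %in% est$k))
})
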