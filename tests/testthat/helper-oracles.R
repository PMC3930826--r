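# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's own code paths.

# Polynomial least squares by explicit raw-power normal equations.
oracle_polyfit <- function(ages, y, degree) {
  X <- outer(ages, 0:degree, `^`)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Brute-force LOOCV: refit on n-1 points, predict the held-out one.
# `fit_predict(train_x, train_y, new_x)` supplies the model.
oracle_loocv <- function(ages, y, fit_predict) {
  n <- length(ages)
  pred <- vapply(seq_len(n), function(i)
    fit_predict(ages[-i], y[-i], ages[i]), numeric(1))
  mean((y - pred)^2)
}

fit_predict_poly <- function(degree) {
  function(tx, ty, nx) {
    b <- oracle_polyfit(tx, ty, degree)
    sum(b * nx^(0:degree))
  }
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# Hypergeometric upper tail by direct summation of binomial products.
oracle_hyper_p <- function(a, b, c, d) {
  n <- a + b + c + d
  ks <- a:min(a + b, a + c)
  sum(choose(a + c, ks) * choose(b + d, (a + b) - ks)) / choose(n, a + b)
}

# Upper tail of the F(d1, d2) distribution by numeric integration of the
# density written out explicitly.
oracle_f_tail <- function(f, d1, d2) {
  dens <- function(x)
    sqrt(((d1 * x)^d1 * d2^d2) / ((d1 * x + d2)^(d1 + d2))) /
      (x * beta(d1 / 2, d2 / 2))
  stats::integrate(dens, f, Inf, rel.tol = 1e-12)$value
}

# Exhaustive Euclidean k-means optimum: minimal total within-cluster sum
# of squared distances to centroids over all assignments with no empty
# cluster.  Feasible for k^n up to ~10^5.
oracle_kmeans_objective <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  assign <- integer(n)
  for (code in 0:(k^n - 1)) {
    v <- code
    for (i in seq_len(n)) { assign[i] <- v %% k + 1; v <- v %/% k }
    if (length(unique(assign)) < k) next
    tot <- 0
    for (j in seq_len(k)) {
      mem <- X[assign == j, , drop = FALSE]
      ctr <- colMeans(mem)
      tot <- tot + sum(sweep(mem, 2, ctr)^2)
    }
    if (tot < best) best <- tot
  }
  best
}

# ---- fixture builders ------------------------------------------------

# Dataset of pure Gaussian noise.
noise_dataset <- function(nProbes, n, seed, ageMin = 25, ageMax = 95) {
  set.seed(seed)
  age <- sort(runif(n, ageMin, ageMax))
  m <- matrix(rnorm(nProbes * n), nProbes, n,
              dimnames = list(sprintf("p%04d", seq_len(nProbes)),
                              sprintf("s%03d", seq_len(n))))
  AgingExperiment(m, age = age, sex = rep_len(c("female", "male"), n),
                  normalized = TRUE)
}

# Dataset whose probes follow quadratic age trends plus noise.
quad_dataset <- function(nProbes, n, seed, noiseSd = 0.5, curv = 0.002) {
  set.seed(seed)
  age <- sort(runif(n, 25, 95))
  m <- t(vapply(seq_len(nProbes), function(i) {
    a2 <- curv * sample(c(-1, 1), 1)
    a1 <- rnorm(1, 0, 0.01)
    a2 * (age - 60)^2 + a1 * (age - 60) + rnorm(n, 0, noiseSd)
  }, numeric(n)))
  dimnames(m) <- list(sprintf("p%04d", seq_len(nProbes)),
                      sprintf("s%03d", seq_len(n)))
  AgingExperiment(m, age = age, sex = rep_len(c("female", "male"), n),
                  normalized = TRUE)
}

# TrendMatrix built directly from a matrix of (to-be-centered) rows.
trend_matrix <- function(rows, grid) {
  rows <- rows - rowMeans(rows)
  if (is.null(rownames(rows)))
    rownames(rows) <- sprintf("p%03d", seq_len(nrow(rows)))
  methods::new("TrendMatrix", ageGrid = grid, trends = rows)
}

# Canonical partition label for comparing clusterings.
canonical_partition <- function(assign) match(assign, unique(assign))

# Write a tiny expression + metadata TSV pair; returns the paths.
write_fixture_tsv <- function(dir, m, age, sex) {
  exprPath <- file.path(dir, "expr.tsv")
  metaPath <- file.path(dir, "meta.tsv")
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  write.table(df, exprPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = colnames(m), age = age, sex = sex),
              metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expr = exprPath, meta = metaPath)
}
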