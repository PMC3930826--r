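## Per-probe trend smoothing, LOOCV model comparison and the
## quadratic-versus-null probe filter.

.TREND_MODELS <- c("linear", "quadratic", "cubic", "qbspline", "loess")
.POLY_DEGREE <- c(linear = 1L, quadratic = 2L, cubic = 3L)

## Map coefficients of a polynomial in u = (t - m)/s back to powers of t.
## Returns the matrix A with beta_t = A %*% gamma_u.
.polyRescaleMatrix <- function(degree, m, s) {
  A <- matrix(0, degree + 1, degree + 1)
  for (j in 0:degree) {
    ## ((t - m)/s)^j expanded in powers of t
    co <- 1                                    # poly "1", increasing powers
    for (r in seq_len(j)) {
      co <- c(0, co) / s - c(co, 0) * (m / s)  # multiply by (t - m)/s
    }
    A[seq_along(co), j + 1] <- co
  }
  A
}

## Scaled-age polynomial design matrix and its QR pieces.
.polyDesign <- function(ageVec, degree) {
  m <- mean(ageVec)
  s <- stats::sd(ageVec)
  if (s == 0) stop("all ages identical; fit underdetermined")
  u <- (ageVec - m) / s
  X <- outer(u, 0:degree, `^`)
  qrX <- qr(X)
  if (qrX$rank < degree + 1)
    stop("underdetermined system: fewer than ", degree + 1,
         " distinct ages for the ", names(which(.POLY_DEGREE == degree)),
         " model")
  list(X = X, qr = qrX, center = m, scale = s)
}

.checkModel <- function(model) {
  match.arg(model, .TREND_MODELS)
}

## Minimum points to fit at all; exact interpolation is allowed for the
## polynomials (their F test then has no residual df and the p is NA).
.minSamples <- function(model) {
  if (model %in% names(.POLY_DEGREE)) .POLY_DEGREE[[model]] + 1L else 6L
}

.fitLoess <- function(ageVec, values, span) {
  dat <- data.frame(t = ageVec, y = values)
  stats::loess(y ~ t, data = dat, span = span, degree = 2,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
}

.qbsplineBasis <- function(ageVec, knots, boundary) {
  splines::bs(ageVec, knots = knots, degree = 2, intercept = TRUE,
              Boundary.knots = boundary)
}

## p-value of the F test of a degree-d polynomial against intercept-only.
.polyP <- function(sse0, sseD, n, degree) {
  if (n - degree - 1 <= 0) return(NA_real_)
  if (sse0 == 0) return(1)
  if (sseD == 0) return(.Machine$double.xmin)
  f <- ((sse0 - sseD) / degree) / (sseD / (n - degree - 1))
  p <- stats::pf(f, degree, n - degree - 1, lower.tail = FALSE)
  if (p == 0) p <- .Machine$double.xmin
  p
}

#' Fit a smoothing model to one probe
#'
#' Least-squares fit of one of five trend models to per-sample expression
#' values against age: polynomials of degree 1-3 (`"linear"`,
#' `"quadratic"`, `"cubic"`), an unpenalized quadratic B-spline with
#' interior knots at the age terciles (`"qbspline"`), or tri-cube-weighted
#' local quadratic regression (`"loess"`, span configurable).  Ages are
#' centered and scaled internally for conditioning; polynomial
#' coefficients are reported on the raw-age scale.
#'
#' @param ageVec per-sample ages in years.
#' @param values per-sample expression values.
#' @param model one of `"linear"`, `"quadratic"`, `"cubic"`, `"qbspline"`,
#'   `"loess"`.
#' @param options list of model options: `span` for loess (default 0.75);
#'   `knots` to override the qbspline interior knots.
#' @return a [TrendFit].
#' @examples
#' fitTrend(c(0, 1, 2), c(1, 0, 1), "quadratic")  # beta = (1, -2, 1)
#' @export
fitTrend <- function(ageVec, values, model = "quadratic", options = list()) {
  model <- .checkModel(model)
  n <- length(ageVec)
  if (length(values) != n) stop("ages and values must have equal length")
  if (n < .minSamples(model))
    stop("need at least ", .minSamples(model), " samples for ", model)
  rng <- range(ageVec)

  if (model %in% names(.POLY_DEGREE)) {
    d <- .POLY_DEGREE[[model]]
    ds <- .polyDesign(ageVec, d)
    gamma <- qr.coef(ds$qr, values)
    fit <- drop(ds$X %*% gamma)
    sse <- sum((values - fit)^2)
    sse0 <- sum((values - mean(values))^2)
    beta <- drop(.polyRescaleMatrix(d, ds$center, ds$scale) %*% gamma)
    names(beta) <- paste0("beta", 0:d)
    return(methods::new("TrendFit", model = model, coefficients = beta,
                        fitted = fit, sse = sse,
                        pValue = .polyP(sse0, sse, n, d), ageRange = rng,
                        fitData = list(center = ds$center, scale = ds$scale,
                                       gamma = unname(gamma))))
  }

  if (model == "qbspline") {
    knots <- options$knots
    if (is.null(knots))
      knots <- unname(stats::quantile(ageVec, c(1 / 3, 2 / 3)))
    B <- .qbsplineBasis(ageVec, knots, rng)
    qrB <- qr(B)
    if (qrB$rank < ncol(B))
      stop("degenerate design for the qbspline model ",
           "(too few distinct ages)")
    cf <- qr.coef(qrB, values)
    fit <- drop(B %*% cf)
    sse <- sum((values - fit)^2)
    return(methods::new("TrendFit", model = model,
                        coefficients = setNames(numeric(0), character(0)),
                        fitted = fit, sse = sse, pValue = NA_real_,
                        ageRange = rng,
                        fitData = list(knots = knots, boundary = rng,
                                       coef = unname(cf))))
  }

  ## loess
  span <- if (is.null(options$span)) 0.75 else options$span
  lo <- tryCatch(.fitLoess(ageVec, values, span), error = function(e)
    stop("degenerate design for the loess model: ", conditionMessage(e)))
  fit <- stats::fitted(lo)
  sse <- sum((values - fit)^2)
  methods::new("TrendFit", model = "loess",
               coefficients = c(span = span), fitted = fit, sse = sse,
               pValue = NA_real_, ageRange = rng,
               fitData = list(object = lo))
}

#' Evaluate a fitted trend at new ages
#'
#' Predictions are confined to the fitted age range; extrapolation is
#' refused.
#'
#' @param fit a [TrendFit].
#' @param newAges ages (years) at which to evaluate the smoothed trend.
#' @return numeric vector of smoothed values.
#' @export
predictTrend <- function(fit, newAges) {
  eps <- 1e-8
  if (any(newAges < fit@ageRange[1] - eps | newAges > fit@ageRange[2] + eps))
    stop("ages outside the fitted range [", fit@ageRange[1], ", ",
         fit@ageRange[2], "]; no extrapolation")
  if (fit@model %in% names(.POLY_DEGREE)) {
    u <- (newAges - fit@fitData$center) / fit@fitData$scale
    return(drop(outer(u, seq_along(fit@fitData$gamma) - 1, `^`) %*%
                  fit@fitData$gamma))
  }
  if (fit@model == "qbspline") {
    B <- .qbsplineBasis(newAges, fit@fitData$knots, fit@fitData$boundary)
    return(drop(B %*% fit@fitData$coef))
  }
  unname(stats::predict(fit@fitData$object, data.frame(t = newAges)))
}

## Leverages of a linear-in-parameters smoother; errors if any held-out
## refit would be underdetermined (leverage 1).
.leverage <- function(qrX) {
  h <- rowSums(qr.Q(qrX)^2)
  if (any(h > 1 - 1e-8))
    stop("a held-out refit is underdetermined (leverage 1)")
  h
}

.linearDesign <- function(ageVec, model, options) {
  if (model %in% names(.POLY_DEGREE)) {
    .polyDesign(ageVec, .POLY_DEGREE[[model]])$qr
  } else {
    knots <- options$knots
    if (is.null(knots))
      knots <- unname(stats::quantile(ageVec, c(1 / 3, 2 / 3)))
    B <- .qbsplineBasis(ageVec, knots, range(ageVec))
    qrB <- qr(B)
    if (qrB$rank < ncol(B))
      stop("degenerate design for the qbspline model")
    qrB
  }
}

#' Leave-one-out cross-validation error of a trend model
#'
#' Average over samples of the squared prediction error when that sample is
#' held out and the model refit on the rest -- the k-fold equals the
#' dataset resolution.  For the linear-in-parameters models the exact
#' leave-one-out identity (residual over one minus leverage) is used; loess
#' is refit explicitly.
#'
#' @inheritParams fitTrend
#' @return non-negative mean squared leave-one-out prediction error.
#' @export
loocvError <- function(ageVec, values, model = "quadratic",
                       options = list()) {
  model <- .checkModel(model)
  n <- length(ageVec)
  if (n < .minSamples(model) + 1L)
    stop("need at least ", .minSamples(model) + 1L,
         " samples so every held-out refit is admissible for ", model)
  if (model == "loess") {
    span <- if (is.null(options$span)) 0.75 else options$span
    pred <- vapply(seq_len(n), function(i) {
      lo <- .fitLoess(ageVec[-i], values[-i], span)
      stats::predict(lo, data.frame(t = ageVec[i]))
    }, numeric(1))
    return(mean((values - pred)^2))
  }
  qrX <- .linearDesign(ageVec, model, options)
  h <- .leverage(qrX)
  r <- qr.resid(qrX, values)
  mean((r / (1 - h))^2)
}

## Vectorized LOOCV over the rows of a probe matrix (shared age vector).
.loocvMatrix <- function(ageVec, Y, model, options = list()) {
  n <- length(ageVec)
  if (model == "loess") {
    return(apply(Y, 1, function(v) loocvError(ageVec, v, "loess", options)))
  }
  qrX <- .linearDesign(ageVec, model, options)
  h <- .leverage(qrX)
  Q <- qr.Q(qrX)
  R <- t(Y) - Q %*% crossprod(Q, t(Y))      # residuals, samples x probes
  colMeans((R / (1 - h))^2)
}

#' Compare smoothing models by LOOCV over all probes
#'
#' Computes every probe's leave-one-out error under each candidate model,
#' compares each pair of models with a two-sided Wilcoxon signed-rank test
#' on the per-probe errors, and declares the model with the minimal mean
#' error the winner.
#'
#' @param x an [AgingExperiment].
#' @param models character vector of model names (see [fitTrend()]).
#' @param options per-model options passed to the fits.
#' @return a [ModelComparison].
#' @export
compareModels <- function(x, models = c("linear", "quadratic", "cubic"),
                          options = list()) {
  models <- vapply(models, .checkModel, character(1))
  if (anyDuplicated(models)) stop("duplicated model names")
  a <- unname(ages(x))
  Y <- exprsValues(x)
  errs <- matrix(NA_real_, nrow(Y), length(models),
                 dimnames = list(rownames(Y), models))
  for (mod in models) {
    errs[, mod] <- tryCatch(.loocvMatrix(a, Y, mod, options),
      error = function(e) {
        ## attribute per-probe failures when the shared design is fine
        perProbe <- vapply(rownames(Y), function(p) {
          tryCatch({loocvError(a, Y[p, ], mod, options); NA_character_},
                   error = function(e2) conditionMessage(e2))
        }, character(1))
        bad <- which(!is.na(perProbe))[1]
        if (is.na(bad)) stop(conditionMessage(e))
        stop("probe ", rownames(Y)[bad], ": ", perProbe[bad])
      })
  }
  pw <- matrix(NA_real_, length(models), length(models),
               dimnames = list(models, models))
  if (length(models) > 1) {
    for (i in seq_along(models)[-length(models)])
      for (j in (i + 1):length(models)) {
        d <- errs[, i] - errs[, j]
        ## exact fits leave error differences at round-off level; treat
        ## them as ties rather than ranking numerical dust
        d[abs(d) <= 1e-20 * mean(Y^2)] <- 0
        p <- if (all(d == 0)) 1 else
          suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
        pw[i, j] <- pw[j, i] <- p
      }
  }
  mn <- colMeans(errs)
  methods::new("ModelComparison", meanErrors = mn, perProbeErrors = errs,
               pairwisePValues = pw, winner = names(which.min(mn)))
}

#' Age-association p-value of one probe
#'
#' F test of the quadratic age model against the intercept-only null:
#' \eqn{F = ((SSE_0 - SSE_2)/2) / (SSE_2/(n-3))} with an upper-tail
#' F(2, n-3) p-value.  A constant probe returns 1; an exactly quadratic
#' probe (SSE2 = 0, or an underflowing tail) returns the smallest positive
#' representable value.
#'
#' @inheritParams fitTrend
#' @return p-value in (0, 1].
#' @export
probePValue <- function(ageVec, values) {
  n <- length(ageVec)
  if (n < 4) stop("need at least 4 samples")
  if (length(values) != n) stop("ages and values must have equal length")
  ds <- .polyDesign(ageVec, 2L)
  sse2 <- sum(qr.resid(ds$qr, values)^2)
  sse0 <- sum((values - mean(values))^2)
  if (all(values == values[1])) return(1)
  .polyP(sse0, sse2, n, 2L)
}

## Vectorized quadratic filter over the rows of a probe matrix.
.quadFilterTable <- function(ageVec, Y, alpha) {
  n <- length(ageVec)
  if (n < 4) stop("need at least 4 samples")
  ds <- .polyDesign(ageVec, 2L)
  Q <- qr.Q(ds$qr)
  Yt <- t(Y)
  Rm <- Yt - Q %*% crossprod(Q, Yt)          # residuals from quadratic
  sse2 <- colSums(Rm^2)
  sse0 <- colSums((Yt - matrix(colMeans(Yt), n, ncol(Yt), byrow = TRUE))^2)
  f <- ((sse0 - sse2) / 2) / (sse2 / (n - 3))
  p <- stats::pf(f, 2, n - 3, lower.tail = FALSE)
  p[sse2 == 0 | p == 0] <- .Machine$double.xmin
  p[sse0 == 0] <- 1
  ## raw-age-scale coefficients for all probes at once
  Rmat <- qr.R(ds$qr)
  gammas <- backsolve(Rmat, crossprod(Q, Yt))          # 3 x probes, u scale
  A <- .polyRescaleMatrix(2L, ds$center, ds$scale)
  betas <- t(A %*% gammas)
  data.frame(probe_id = rownames(Y), beta0 = betas[, 1], beta1 = betas[, 2],
             beta2 = betas[, 3], sse = sse2, p_value = p,
             significant = p < alpha, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Filter probes by quadratic age association
#'
#' Fits the quadratic age model to every probe and keeps those with an
#' unadjusted p-value strictly below `alpha`.  No multiple-testing
#' correction is applied at this stage: the probe filter is one of two
#' filtering steps (the dataset-level [globalAgeTest()] is the other), and
#' the permutation analysis ([permutationSummary()]) quantifies how many
#' of the retained probes a random ordering would produce.
#'
#' @param x an [AgingExperiment].
#' @param alpha significance threshold in (0, 1), default 0.05.
#' @return a list with elements `significant` (probe ids with p < alpha),
#'   `fits` (per-probe data.frame: probe_id, beta0, beta1, beta2, sse,
#'   p_value, significant), and `alpha`.
#' @export
filterProbes <- function(x, alpha = 0.05) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  tab <- .quadFilterTable(unname(ages(x)), exprsValues(x), alpha)
  list(significant = tab$probe_id[tab$significant], fits = tab,
       alpha = alpha)
}
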