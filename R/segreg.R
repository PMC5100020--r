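#' Ordinary least-squares line through an RM series
#'
#' The one-line null model for the RM-versus-time relationship (a Gaussian
#' identity-link fit).
#'
#' @param series An `rm_series` (or any data frame with `time_h`, `rm`).
#' @return A list with `intercept`, `slope`, their standard errors, `rss`,
#'   `sigma2`, `df`, and `n`.
#' @export
fit_line <- function(series) {
  t <- series$time_h; y <- series$rm
  if (length(t) < 3)
    stop("fit_line: need at least 3 points", call. = FALSE)
  if (length(unique(t)) < 2)
    stop("fit_line: all times identical; design is rank deficient",
         call. = FALSE)
  fit <- stats::lm(y ~ t)
  s <- suppressWarnings(summary(fit))  # exact fits trip a precision warning
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       se_intercept = s$coefficients[1, 2],
       se_slope = s$coefficients[2, 2],
       rss = sum(stats::resid(fit)^2),
       sigma2 = s$sigma^2,
       df = fit$df.residual,
       n = length(t))
}

# RSS of the hinge model y ~ 1 + t + (t - psi)_+ at a fixed breakpoint,
# via QR. Returns Inf when the design is rank deficient (psi outside the
# data or no points on one side).
hinge_rss <- function(t, y, psi) {
  X <- cbind(1, t, pmax(t - psi, 0))
  qr_x <- qr(X)
  if (qr_x$rank < 3L) return(Inf)
  sum(qr.resid(qr_x, y)^2)
}

# Interior interval for admissible breakpoints: (t_min + delta,
# t_max - delta) with delta the smallest positive gap between sorted
# unique times.
psi_bounds <- function(t) {
  ut <- sort(unique(t))
  delta <- min(diff(ut))
  c(ut[1] + delta, ut[length(ut)] - delta)
}

#' Segmented two-line regression with a single breakpoint
#'
#' Minimizes the residual sum of squares of
#' `y = b0 + b1 t + b2 (t - psi)_+` over the coefficients and the
#' breakpoint `psi`. The breakpoint is initialized from a coarse scan over
#' `K` interior quantiles of the observed times and refined by iterative
#' linearization: at each step the model is re-fit with the extra indicator
#' regressor `-(t > psi)` and `psi` is updated by the ratio of that
#' regressor's coefficient to the hinge coefficient, until the update falls
#' below `tol` times the time range. On non-convergence (or whenever it
#' finds a lower RSS) a dense-grid scan followed by golden-section
#' refinement is used instead. Ties in RSS break toward the smaller
#' breakpoint. Slope confidence intervals use the OLS covariance at the
#' final breakpoint with `n - 4` degrees of freedom; the second-segment
#' slope is `b1 + b2` with variance `var(b1) + var(b2) + 2 cov(b1, b2)`.
#'
#' @param series An `rm_series` (columns `time_h`, `rm`).
#' @param psi_init Optional starting breakpoint (hours); default: best of
#'   the coarse quantile grid.
#' @param K Number of interior quantile candidates for the coarse scan.
#' @param conf_level Confidence level for the slope intervals.
#' @param max_iter,tol Iteration controls.
#' @return An object of class `segmented_fit`: `beta0`, `beta1`, `beta2`,
#'   `psi`, `slope1`, `slope2`, `slope1_ci`, `slope2_ci`, `r2`,
#'   `davies_p`, `rss`, `n`, `converged`, `boundary`.
#' @export
fit_segmented <- function(series, psi_init = NULL, K = 10,
                          conf_level = 0.95, max_iter = 50, tol = 1e-6) {
  t <- series$time_h; y <- series$rm
  n <- length(t)
  ut <- unique(t)
  if (n < 5 || length(ut) < 4)
    stop("fit_segmented: need at least 5 points over at least 4 distinct times",
         call. = FALSE)
  bounds <- psi_bounds(t)
  if (bounds[1] >= bounds[2])
    stop("fit_segmented: no admissible interior breakpoint", call. = FALSE)
  rng <- diff(range(t))

  clamp <- function(p) min(max(p, bounds[1]), bounds[2])

  # coarse scan: K evenly spaced interior quantiles of the observed times
  grid <- unique(clamp_v(stats::quantile(t, probs = (1:K) / (K + 1),
                                         names = FALSE, type = 7), bounds))
  grid_rss <- vapply(grid, function(p) hinge_rss(t, y, p), numeric(1))
  if (all(!is.finite(grid_rss)))
    stop("fit_segmented: no admissible breakpoint candidate", call. = FALSE)
  psi <- if (is.null(psi_init)) grid[which.min(grid_rss)] else clamp(psi_init)

  # iterative linearization
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- pmax(t - psi, 0)
    V <- -as.numeric(t > psi)
    fit <- stats::lm(y ~ t + U + V)
    b <- stats::coef(fit)
    if (anyNA(b) || abs(b["U"]) < 1e-12) break
    step <- b["V"] / b["U"]
    psi_new <- clamp(unname(psi + step))
    if (abs(psi_new - psi) < tol * rng) {
      psi <- psi_new
      converged <- TRUE
      break
    }
    psi <- psi_new
  }
  rss_iter <- hinge_rss(t, y, psi)

  # grid + golden-section fallback / safeguard: scan all inter-point
  # intervals and polish the best bracket
  fb <- grid_golden_min(t, y, bounds)
  if (!converged || fb$rss < rss_iter - 1e-10 ||
      (abs(fb$rss - rss_iter) <= 1e-10 && fb$psi < psi - 1e-9)) {
    psi <- fb$psi
    rss_iter <- fb$rss
  }

  boundary <- psi <= bounds[1] + 1e-9 || psi >= bounds[2] - 1e-9
  if (boundary)
    warning("fit_segmented: breakpoint pinned to the admissible boundary",
            call. = FALSE)

  # final OLS at psi-hat; the covariance keeps the linearization's
  # breakpoint-indicator regressor so that slope uncertainty includes the
  # uncertainty in psi
  X <- cbind(`(Intercept)` = 1, t = t, U = pmax(t - psi, 0))
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  df <- n - 4  # three linear coefficients + the breakpoint
  sigma2 <- rss / df
  X4 <- cbind(X, V = -as.numeric(t > psi))
  XtXinv4 <- tryCatch(chol2inv(chol(crossprod(X4))),
                      error = function(e) NULL)
  vc <- if (!is.null(XtXinv4)) (sigma2 * XtXinv4)[1:3, 1:3]
        else sigma2 * chol2inv(chol(crossprod(X)))
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  slope1 <- unname(beta["t"])
  slope2 <- unname(beta["t"] + beta["U"])
  se1 <- sqrt(vc[2, 2])
  se2 <- sqrt(vc[2, 2] + vc[3, 3] + 2 * vc[2, 3])
  tss <- sum((y - mean(y))^2)
  structure(list(
    beta0 = unname(beta[1]), beta1 = slope1, beta2 = unname(beta["U"]),
    psi = psi,
    slope1 = slope1, slope2 = slope2,
    slope1_ci = c(slope1 - tq * se1, slope1 + tq * se1),
    slope2_ci = c(slope2 - tq * se2, slope2 + tq * se2),
    se_slope1 = se1, se_slope2 = se2,
    r2 = 1 - rss / tss, rss = rss, sigma2 = sigma2, n = n, df = df,
    davies_p = davies_test(series, k = K),
    converged = converged, boundary = boundary),
    class = "segmented_fit")
}

clamp_v <- function(p, bounds) pmin(pmax(p, bounds[1]), bounds[2])

# Dense scan of RSS(psi) over every inter-point interval plus Brent polish
# in the best bracket; ties toward smaller psi.
grid_golden_min <- function(t, y, bounds, n_grid = 200) {
  grid <- seq(bounds[1], bounds[2], length.out = n_grid)
  rssv <- vapply(grid, function(p) hinge_rss(t, y, p), numeric(1))
  j <- which.min(rssv)  # which.min takes the first (smallest psi) on ties
  lo <- grid[max(1, j - 1)]; hi <- grid[min(n_grid, j + 1)]
  opt <- stats::optimize(function(p) hinge_rss(t, y, p),
                         interval = c(lo, hi), tol = 1e-10)
  if (opt$objective <= rssv[j]) list(psi = opt$minimum, rss = opt$objective)
  else list(psi = grid[j], rss = rssv[j])
}

#' Davies-type test for a non-constant slope
#'
#' Tests the one-line null against a broken-line alternative when the
#' breakpoint is not identified under the null. For each of `k` evenly
#' spaced interior candidate breakpoints the Wald (t) statistic of the
#' added hinge term `(t - psi)_+` is computed and the maximum absolute
#' statistic `M` over candidates is the test statistic. Three assessments
#' of `M` are available:
#'
#' * `"pivotal"` (default): under the Gaussian one-line null the vector of
#'   candidate statistics is pivotal (invariant to the true intercept,
#'   slope and error variance), so the null distribution of `M` is
#'   simulated exactly by drawing standard-normal responses on the same
#'   design; the p-value is the Monte-Carlo exceedance probability. Exactly
#'   calibrated up to Monte-Carlo error.
#' * `"davies"`: the analytic sup-statistic bound
#'   `p <= 2 P(T > M) + V f_T(M) / 2`, with `V` the total variation of the
#'   candidate statistic sequence and `T` the t distribution with `n - 3`
#'   degrees of freedom (the Gaussian-statistic version of the second term
#'   is the classical `V exp(-M^2/2) / sqrt(8 pi)`). Fast and sensible for
#'   extreme statistics, but the plug-in variation term can be liberal in
#'   small samples.
#' * `"permutation"`: residual permutation under the fitted one-line null.
#'
#' @param series An `rm_series` (columns `time_h`, `rm`).
#' @param k Number of candidate breakpoints (>= 2).
#' @param method `"pivotal"` (default), `"davies"`, or `"permutation"`.
#' @param n_sim Monte-Carlo replicates for the pivotal and permutation
#'   methods.
#' @param mc_seed Seed for the internal Monte-Carlo stream (the caller's
#'   RNG state is left untouched).
#' @return The p-value.
#' @export
davies_test <- function(series, k = 10,
                        method = c("pivotal", "davies", "permutation"),
                        n_sim = 999, mc_seed = 1L) {
  method <- match.arg(method)
  t <- series$time_h; y <- series$rm
  n <- length(t)
  if (n < 6)
    stop("davies_test: need at least 6 points", call. = FALSE)
  if (k < 2)
    stop("davies_test: need at least 2 candidate breakpoints", call. = FALSE)
  bounds <- psi_bounds(t)
  psis <- seq(bounds[1], bounds[2], length.out = k)
  s <- drop(hinge_wald_matrix(t, psis, matrix(y)))
  ok <- is.finite(s) | is.infinite(s)
  s <- s[ok]
  if (length(s) < 2)
    stop("davies_test: too few admissible candidates", call. = FALSE)
  M <- max(abs(s))
  if (method == "davies") {
    V <- sum(abs(diff(s)))
    p <- 2 * stats::pt(-M, df = n - 3) + V * stats::dt(M, df = n - 3) / 2
    return(min(1, p))
  }
  Yb <- local_rng(mc_seed, {
    if (method == "pivotal") {
      matrix(stats::rnorm(n * n_sim), n, n_sim)
    } else {
      null_fit <- stats::lm.fit(cbind(1, t), y)
      idx <- replicate(n_sim, sample.int(n))
      matrix(null_fit$fitted.values, n, n_sim) +
        matrix(null_fit$residuals[idx], n, n_sim)
    }
  })
  Sb <- hinge_wald_matrix(t, psis[ok], Yb)
  Mb <- apply(abs(Sb), 2, max)
  (1 + sum(Mb >= M)) / (1 + n_sim)
}

# Evaluate an expression with a private RNG stream, restoring the caller's.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Wald (t) statistics of the hinge coefficient in y ~ 1 + t + (t - psi)_+,
# for every candidate psi (rows) and every response column of Y.
hinge_wald_matrix <- function(t, psis, Y) {
  n <- length(t)
  out <- matrix(NA_real_, length(psis), ncol(Y))
  for (j in seq_along(psis)) {
    X <- cbind(1, t, pmax(t - psis[j], 0))
    qr_x <- qr(X)
    if (qr_x$rank < 3L) next
    B <- qr.coef(qr_x, Y)
    Res <- qr.resid(qr_x, Y)
    sigma2 <- colSums(Res^2) / (n - 3)
    c33 <- chol2inv(qr.R(qr_x))[3, 3]
    stat <- B[3, ] / sqrt(sigma2 * c33)
    stat[sigma2 <= 0] <- sign(B[3, sigma2 <= 0]) * Inf
    out[j, ] <- stat
  }
  out
}

# scalar convenience used by tests of single candidates
hinge_wald <- function(t, y, psi) {
  drop(hinge_wald_matrix(t, psi, matrix(y)))
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<segmented_fit> y = %.4f + %.4f t  (t < %.3f h), slope %.4f after\n",
    "  slope1 95%% CI [%.4f, %.4f]; slope2 95%% CI [%.4f, %.4f]\n",
    "  R^2 = %.3f, RSS = %.4g, Davies p = %.3g, n = %d%s\n"),
    x$beta0, x$beta1, x$psi, x$slope2,
    x$slope1_ci[1], x$slope1_ci[2], x$slope2_ci[1], x$slope2_ci[2],
    x$r2, x$rss, x$davies_p, x$n,
    if (x$converged) "" else " (grid fallback)"))
  invisible(x)
}
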