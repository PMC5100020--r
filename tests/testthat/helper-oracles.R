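# Independent oracles used across tests. These deliberately avoid the code
# paths they are meant to check.

# mean replicated fraction of a uniform cohort advanced by u, by numeric
# integration of min(f + u, 1) over f ~ U(0, 1)
rm_integration_oracle <- function(u) {
  vapply(u, function(uu) {
    stats::integrate(function(f) pmin(f + uu, 1), 0, 1,
                     rel.tol = 1e-10)$value
  }, numeric(1))
}

# closed-form OLS for y ~ 1 + x via the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / (length(y) - 2)
  vc <- sigma2 * solve(XtX)
  list(intercept = beta[1], slope = beta[2], rss = rss,
       se_intercept = sqrt(vc[1, 1]), se_slope = sqrt(vc[2, 2]))
}

# exhaustive grid search for the one-breakpoint least-squares fit
grid_rss_oracle <- function(t, y, step = 1e-3) {
  ut <- sort(unique(t))
  delta <- min(diff(ut))
  psis <- seq(ut[1] + delta, ut[length(ut)] - delta, by = step)
  best <- Inf
  best_psi <- NA_real_
  for (p in psis) {
    X <- cbind(1, t, pmax(t - p, 0))
    r <- qr.resid(qr(X), y)
    rss <- sum(r^2)
    if (rss < best) {
      best <- rss
      best_psi <- p
    }
  }
  list(psi = best_psi, rss = best)
}

# ideal simulator settings: instantaneous pulse, no noise, no division, no
# residual labeling, no slow/arrested cells, no debris; long G1 and G2/M
# reservoirs keep the unlabeled anchor populations present throughout the
# chase
ideal_config <- function(t_s = 2.7, chase_times = c(0, 1.35, 2.7),
                         n_cells = 1e5, seed = 1L, slow_fraction = 0,
                         slow_factor = 2, t_g1 = 20, t_g2m = 20, ...) {
  sim_config(t_g1 = t_g1, t_s = t_s, t_g2m = t_g2m, pulse_len = 0,
             chase_times = chase_times, n_cells = as.integer(n_cells),
             dapi_cv = 0, label_cv = 0, label_background = 0,
             residual_rate = 0, noncycling_fraction = 0,
             slow_fraction = slow_fraction, slow_factor = slow_factor,
             debris_fraction = 0,
             divide_labeled = FALSE, phase_cv = 0, seed = seed, ...)
}

# RM of every sample of an ideal time course, gated from its 0 h sample
ideal_rm_trajectory <- function(tc) {
  g <- auto_gates(tc$entries[[1]])
  vapply(tc$entries, function(et) {
    st <- gated_stats(et, g, is_t0 = event_meta(et)$time_h == 0)
    relative_movement(st)
  }, numeric(1))
}

# hand-built gate set for synthetic point-mass fixtures
manual_gates <- function(g1 = c(1.9, 2.1), g2m = c(3.9, 4.1),
                         label_threshold = 5, full_label_threshold = 10,
                         debris_floor = 1) {
  structure(list(g1_box = g1, g2m_box = g2m,
                 label_threshold = label_threshold,
                 full_label_threshold = full_label_threshold,
                 debris_floor = debris_floor,
                 g1_mode = mean(g1), g2m_mode = mean(g2m),
                 cv_hat = 0.02, k = 3), class = "gate_set")
}
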