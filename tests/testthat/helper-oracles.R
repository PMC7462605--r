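# independent oracles and fixture builders used across the suite

# analytic isotropic Gaussian utilization distribution built directly on a
# grid (bypasses fit_kde, so closed-form containment results apply exactly
# up to grid discretization)
gaussian_ud <- function(sigma = 1, half = 5, cell = 0.05, center = c(0, 0)) {
  gx <- seq(-half, half, by = cell) + center[1]
  gy <- seq(-half, half, by = cell) + center[2]
  dens <- outer(dnorm(gx, center[1], sigma), dnorm(gy, center[2], sigma))
  dens <- dens / (sum(dens) * cell^2)
  structure(list(x = gx, y = gy, density = dens,
                 isopleth = huntniche:::isopleth_surface(dens, cell),
                 cell_size = cell, bandwidth = c(NA_real_, NA_real_),
                 n = NA_integer_, group_id = "toy"),
            class = "utilization_distribution")
}

# brute-force SRI for one dyad: plain double loop over scan membership lists
bruteforce_sri <- function(scan_members, a, b) {
  pa <- 0; pb <- 0; pab <- 0
  for (m in scan_members) {
    ina <- a %in% m
    inb <- b %in% m
    pa <- pa + ina
    pb <- pb + inb
    pab <- pab + (ina && inb)
  }
  if (pa + pb - pab == 0) NA_real_ else pab / (pa + pb - pab)
}

# scans table from a list of member-id vectors, one scan per 30 min
make_scans <- function(members, start = "2019-03-01 06:00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  do.call(rbind, lapply(seq_along(members), function(i)
    data.frame(scan_id = sprintf("S%03d", i),
               timestamp = t0 + (i - 1) * 1800,
               individual_id = members[[i]])))
}

# dense-grid posterior moments for the 2-category toy model
# (intercept + one predictor): the independent integration oracle
grid_posterior_moments <- function(X, y, df = 3, scale = 2.5,
                                   lim = 8, n = 241) {
  g <- seq(-lim, lim, length.out = n)
  grid <- as.matrix(expand.grid(b1 = g, b2 = g))
  eta <- X %*% t(grid)
  ll <- colSums(eta * (y == 2)) - colSums(log1p(exp(eta)))
  lp <- ll + dt(grid[, 1] / scale, df, log = TRUE) +
    dt(grid[, 2] / scale, df, log = TRUE)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mu <- colSums(w * grid)
  list(mean = mu,
       sd = sqrt(colSums(w * sweep(grid, 2, mu)^2)))
}

# small fast generator config for unit tests
quick_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_days = 60, scans_per_day = 8,
             relocations_per_day = 15, hunt_rate_per_day = 0.5,
             cell_size = 0.2, ...)
}

# the parameter-recovery study design: one full annual cycle, ~500 hunts
recovery_config <- function(seed, true_coefficients =
                              default_true_coefficients()) {
  sim_config(seed = seed, n_days = 365, hunt_rate_per_day = 0.685,
             true_coefficients = true_coefficients)
}

fit_sim <- function(sim, seed, ...) {
  cov <- attr(sim$hunts, "covariates")
  suppressWarnings(fit_categorical(
    cov, cov$prey,
    model_spec(seed = seed,
               reference_group = huntniche:::group_ids(sim$config)[1],
               ...)))
}
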