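# shared fixtures: small scenarios generated in code, memoised per test run

.fixture_env <- new.env(parent = emptyenv())

tiny_config <- function(seed = 42L, ...) {
  scenario_config(seed = seed,
                  n_households_per_site = c(jc = 30L, ttz = 40L),
                  n_migrants = 120L,
                  n_groups_per_site = c(jc = 5L, ttz = 7L),
                  raster_extent = 2500,
                  ...)
}

null_config <- function(seed = 42L, ...) {
  tiny_config(seed = seed, beta_ccfp_logit = 0, beta_ccfp_amount = 0,
              remit_forest_slope = 0, nonremit_drift = 0, ...)
}

tiny_scenario <- function() {
  if (is.null(.fixture_env$tiny))
    .fixture_env$tiny <- suppressWarnings(generate_scenario(tiny_config()))
  .fixture_env$tiny
}

# deterministic small raster pair for buffer tests
toy_raster <- function(n = 20, seed = 5, cell_size = 30) {
  set.seed(seed)
  k0 <- matrix(rbinom(n * n, 1, 0.5), n, n)
  k1 <- matrix(rbinom(n * n, 1, 0.5), n, n)
  e0 <- matrix(runif(n * n, 0, 0.8), n, n)
  e1 <- matrix(runif(n * n, 0, 0.8), n, n)
  raster_pair(k0, k1, e0, e1, cell_size = cell_size)
}

# brute-force weighted change metrics used as the direct-summation oracle
oracle_change <- function(rp, w) {
  idx <- cbind(w$row, w$col)
  k0 <- rp$forest_t0[idx]; k1 <- rp$forest_t1[idx]
  e0 <- rp$evi_t0[idx]; e1 <- rp$evi_t1[idx]
  wt <- w$weight
  df <- sum(wt * k1) / sum(wt) - sum(wt * k0) / sum(wt)
  m1 <- k1 == 1 & !is.na(e1); m0 <- k0 == 1 & !is.na(e0)
  de <- if (sum(wt[m1]) > 0 && sum(wt[m0]) > 0)
    sum(wt[m1] * e1[m1]) / sum(wt[m1]) - sum(wt[m0] * e0[m0]) / sum(wt[m0])
  else NA_real_
  c(delta_forest = df, delta_evi = de)
}

# supersampled circle-overlap weight for one cell
supersample_weight <- function(x0, y0, cs, cx, cy, r, n = 100) {
  off <- (seq_len(n) - 0.5) / n * cs
  px <- rep(x0 + off, each = n); py <- rep(y0 + off, times = n)
  mean((px - cx)^2 + (py - cy)^2 <= r^2)
}

# independent model oracles: hand-rolled IRLS for the weighted logistic fit
# and the closed-form weighted least-squares solution
irls_logit <- function(X, y, w, iters = 60) {
  b <- rep(0, ncol(X))
  for (i in seq_len(iters)) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    W <- w * p * (1 - p)
    z <- eta + (y - p) / (p * (1 - p))
    b <- solve(t(X) %*% (X * W), t(X) %*% (W * z))
  }
  drop(b)
}

wls <- function(X, y, w) drop(solve(t(X) %*% (X * w), t(X) %*% (w * y)))
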