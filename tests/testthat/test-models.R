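model_data <- function() {
  scn <- tiny_scenario()
  m <- scn$migrants
  m$log10_amount <- ifelse(m$remittance_amount > 0,
                           log10(m$remittance_amount), NA)
  m
}

test_that("variance-constrained logistic fit matches the IRLS oracle", {
  m <- model_data()
  f <- sent_remittance ~ payment_k + age + education + (1 | group_id)
  fit <- fit_remit_logit(m, f, zero_variance = TRUE)
  X <- cbind(1, m$payment_k, m$age, m$education)
  b_oracle <- irls_logit(X, m$sent_remittance, m$sampling_weight)
  expect_equal(unname(fit$coefficients$estimate), unname(b_oracle),
               tolerance = 1e-3)
  expect_equal(fit$sigma_u2, 0)
  expect_equal(fit$icc, 0)
})

test_that("variance-constrained linear fit matches closed-form WLS", {
  m <- model_data()
  s <- m[m$sent_remittance == 1, ]
  f <- log10_amount ~ payment_k + education + (1 | group_id)
  fit <- fit_remit_linear(s, f, zero_variance = TRUE)
  X <- cbind(1, s$payment_k, s$education)
  expect_equal(unname(fit$coefficients$estimate),
               unname(wls(X, s$log10_amount, s$sampling_weight)),
               tolerance = 1e-6)
})

test_that("degenerate designs raise informative errors", {
  m <- model_data()
  m$all_zero <- 0
  expect_error(
    fit_remit_logit(m, all_zero ~ payment_k + (1 | group_id)),
    "separation")
  s <- m[m$sent_remittance == 1, ]
  s$dup <- s$payment_k  # perfectly collinear duplicate column
  expect_error(
    fit_remit_linear(s, log10_amount ~ payment_k + dup + (1 | group_id)),
    "rank-deficient")
  expect_error(
    fit_remit_linear(s[1:3, ], log10_amount ~ payment_k + education +
                       migration_years + (1 | group_id)),
    "fewer observations")
})

test_that("mixed fits recover the variance structure and report ICC in [0,1)", {
  m <- model_data()
  s <- m[m$sent_remittance == 1, ]
  fit <- suppressWarnings(fit_remit_linear(
    s, log10_amount ~ payment_k + (1 | group_id)))
  expect_gte(fit$icc, 0); expect_lt(fit$icc, 1)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$df)
  expect_equal(fit$BIC, -2 * fit$logLik + fit$df * log(fit$n))
  g <- glance(fit)
  expect_equal(g$icc, fit$icc)
  expect_equal(nrow(tidy(fit)), 2L)
})

test_that("logistic marginal effect is beta/4 at probability one half", {
  m <- model_data()
  f <- sent_remittance ~ payment_k + (1 | group_id)
  fit <- fit_remit_logit(m, f, zero_variance = TRUE)
  b <- fit$coefficients$estimate
  # choose the payment value that puts the linear predictor at zero
  at0 <- -b[1] / b[2]
  me <- marginal_effects(fit, at = list(payment_k = at0))
  expect_equal(me$effects$estimate[me$effects$term == "payment_k"],
               b[2] / 4, tolerance = 1e-10)
  expect_error(marginal_effects(fit, at = list(nope = 1)), "not model columns")
})

test_that("population-averaged marginal effect matches a Monte-Carlo oracle", {
  m <- model_data()
  f <- sent_remittance ~ payment_k + education + (1 | group_id)
  fit <- suppressWarnings(fit_remit_logit(m, f, nAGQ = 15L))
  me <- marginal_effects(fit)
  beta <- lme4::fixef(fit$model)
  xbar <- colMeans(cbind(1, m$payment_k, m$education))
  eta <- sum(xbar * beta)
  set.seed(99)
  z <- rnorm(4e5, 0, sqrt(fit$sigma_u2))
  p <- plogis(eta + z)
  oracle <- beta["payment_k"] * mean(p * (1 - p))
  expect_equal(unname(me$effects$estimate[me$effects$term == "payment_k"]),
               unname(oracle), tolerance = 5e-3)
  # predictive margins increase with a positive payment coefficient
  expect_true(all(diff(me$margins$margin) > 0))
})

test_that("linear marginal effects equal coefficients; zero beta gives zero", {
  m <- model_data()
  s <- m[m$sent_remittance == 1, ]
  fit <- suppressWarnings(fit_remit_linear(
    s, log10_amount ~ payment_k + education + (1 | group_id)))
  me <- marginal_effects(fit)
  expect_equal(me$effects$estimate,
               fit$coefficients$estimate[-1], tolerance = 1e-12)
})

test_that("planted logistic effect is recovered within 2 s.e. in most replicates", {
  hits <- vapply(1:25, function(s) {
    scn <- generate_scenario(scenario_config(
      seed = 100 + s,
      n_households_per_site = c(jc = 60L, ttz = 80L),
      n_migrants = 240L,
      n_groups_per_site = c(jc = 5L, ttz = 7L),
      raster_extent = 2500), rasters = FALSE)
    m <- scn$migrants
    fit <- try(suppressWarnings(suppressMessages(fit_remit_logit(
      m, sent_remittance ~ payment_k + education + (1 | group_id),
      nAGQ = 1L))), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA)
    cf <- fit$coefficients[fit$coefficients$term == "payment_k", ]
    abs(cf$estimate - 0.104) <= 2 * cf$std.error
  }, TRUE)
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})

test_that("model comparison flags a clearly better nested model", {
  m <- model_data()
  s <- m[m$sent_remittance == 1, ]
  f1 <- log10_amount ~ 1 + (1 | group_id)
  f3 <- log10_amount ~ payment_k + education + (1 | group_id)
  fits <- list(model1 = suppressWarnings(fit_remit_linear(s, f1)),
               model3 = suppressWarnings(fit_remit_linear(s, f3)))
  cmp <- model_compare(fits)
  expect_equal(unname(cmp$delta_AIC[cmp$model == "model3"]), 0)
  # identical fits: zero deltas, nothing favoured
  cmp2 <- model_compare(list(a = fits$model3, b = fits$model3))
  expect_true(all(cmp2$delta_AIC == 0))
  expect_false(any(cmp2$favoured_AIC))
  expect_error(model_compare(list(a = fits$model3,
                                  b = suppressWarnings(
                                    fit_remit_linear(s[-1, ], f3)))),
               "same number")
})

test_that("weighted bootstrap margins are seed-reproducible and weight-scale invariant", {
  scn <- tiny_scenario()
  m <- scn$migrants
  s <- m[m$sent_remittance == 1, ]
  s$log10_amount <- log10(s$remittance_amount)
  f <- log10_amount ~ payment_k + (1 | group_id)
  b1 <- bootstrap_margin_distribution(s, f, family = "linear",
                                      n_reps = 100L, seed = 5L)
  b2 <- bootstrap_margin_distribution(s, f, family = "linear",
                                      n_reps = 100L, seed = 5L)
  expect_identical(b1$draws, b2$draws)
  expect_true(b1$ci[1] < b1$estimate && b1$estimate < b1$ci[2])
  # rescaling all weights leaves the resampling law unchanged
  s2 <- s; s2$sampling_weight <- s$sampling_weight * 10
  b3 <- bootstrap_margin_distribution(s2, f, family = "linear",
                                      n_reps = 100L, seed = 5L)
  expect_equal(b1$draws, b3$draws, tolerance = 1e-6)
  expect_error(bootstrap_margin_distribution(s, f, family = "linear",
                                             n_reps = 50L), ">= 100")
})
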