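single_household <- function() {
  list(
    migrants = tibble::tibble(
      migrant_id = "m1", household_id = "h1", migration_years = 5,
      payment_individual = 2000),
    households = tibble::tibble(
      household_id = "h1", site_id = "jc", ccfp_participant = 1,
      payment_annual = 2000, remittance_received = 1,
      remittance_total = 9772))
}

test_that("hand-computed socioeconomic additionality on one household", {
  d <- single_household()
  # 10^(0.099 * 5 * 2) = 10^0.99 = 9.772 over payments of 2,000 Yuan
  g <- econ_additionality(d$migrants, d$households, beta = 0.099)
  expect_equal(g$numerator, 10^0.99, tolerance = 1e-12)
  expect_equal(g$estimate, 100 * 10^0.99 / 2000, tolerance = 1e-12)
  expect_equal(round(g$estimate, 3), 0.489)
  # degenerate limit: beta = 0 awards 10^0 = 1 per migrant, flagged
  g0 <- econ_additionality(d$migrants, d$households, beta = 0)
  expect_equal(g0$numerator, 1)
  expect_true(g0$degenerate)
})

test_that("hand-computed ecological additionality on one household", {
  d <- single_household()
  A <- pi * 100^2
  g <- ecol_additionality(d$migrants, d$households, beta = 0.099,
                          gamma = 0.011, area = A)
  # L_h = log10(10^0.99) = 0.99; numerator 0.011 * 0.99 * A = 342.1 m2;
  # denominator 2000 / 0.135 = 14814.8 m2 -> 2.31%
  expect_equal(g$forest_area_m2, 0.011 * 0.99 * A, tolerance = 1e-9)
  expect_equal(g$baseline_area_m2, 2000 / 0.135, tolerance = 1e-9)
  expect_equal(round(g$estimate, 2), 2.31)
  expect_equal(ecol_additionality(d$migrants, d$households, beta = 0.099,
                                  gamma = 0, area = A)$estimate, 0)
})

test_that("uncertainty bounds bracket the point estimate and are monotone", {
  d <- single_household()
  g <- econ_additionality(d$migrants, d$households, beta = 0.099,
                          sigma_beta = 0.026)
  expect_lte(g$lower, g$estimate); expect_lte(g$estimate, g$upper)
  e <- ecol_additionality(d$migrants, d$households, beta = 0.099,
                          gamma = 0.011, sigma_beta = 0.026,
                          sigma_gamma = 0.005)
  expect_lte(e$lower, e$estimate); expect_lte(e$estimate, e$upper)
  # additionality increases with beta and gamma on the positive domain
  g2 <- econ_additionality(d$migrants, d$households, beta = 0.12)
  expect_gt(g2$estimate, g$estimate)
  e2 <- ecol_additionality(d$migrants, d$households, beta = 0.099,
                           gamma = 0.02)
  expect_gt(e2$estimate, e$estimate)
})

test_that("payment doubling matches a brute-force recomputation on 10-household toys", {
  set.seed(77)
  for (k in 1:5) {
    hh <- tibble::tibble(
      household_id = sprintf("h%02d", 1:10),
      site_id = sample(c("jc", "ttz"), 10, TRUE),
      ccfp_participant = rbinom(10, 1, 0.7),
      payment_annual = runif(10, 0, 3000) * ccfp_participant,
      remittance_received = rbinom(10, 1, 0.5))
    hh$remittance_total <- hh$remittance_received * runif(10, 1e3, 5e4)
    mg <- tibble::tibble(
      migrant_id = sprintf("m%02d", 1:10), household_id = hh$household_id,
      migration_years = runif(10, 1, 8),
      payment_individual = hh$payment_annual)
    if (sum(hh$payment_annual) == 0) next
    base <- ecol_additionality(mg, hh, beta = 0.05, gamma = 0.011)
    hh2 <- hh; hh2$payment_annual <- hh$payment_annual * 2
    mg2 <- mg; mg2$payment_individual <- mg$payment_individual * 2
    dbl <- ecol_additionality(mg2, hh2, beta = 0.05, gamma = 0.011)
    # brute force: denominator doubles, numerator responds via the exponent
    lam <- c(jc = 0.135, ttz = 0.1875)[hh$site_id]
    part <- hh$ccfp_participant == 1
    Lh2 <- log10(pmax(tapply(10^(0.05 * mg2$migration_years[part] *
                                   mg2$payment_individual[part] / 1000),
                             mg2$household_id[part], sum), 1))
    num2 <- sum(0.011 * Lh2 * pi * 100^2)
    den2 <- sum(hh2$payment_annual / lam)
    expect_equal(dbl$estimate, 100 * num2 / den2, tolerance = 1e-9)
    expect_equal(dbl$baseline_area_m2, 2 * base$baseline_area_m2,
                 tolerance = 1e-9)
  }
})

test_that("extreme predicted-remittance households are excluded by z-score", {
  d <- single_household()
  hh <- dplyr::bind_rows(
    purrr::map_dfr(1:20, function(i)
      dplyr::mutate(d$households, household_id = sprintf("h%02d", i))),
    tibble::tibble(household_id = "hx", site_id = "jc",
                   ccfp_participant = 1, payment_annual = 11000,
                   remittance_received = 1, remittance_total = 1e6))
  mg <- dplyr::bind_rows(
    purrr::map_dfr(1:20, function(i)
      dplyr::mutate(d$migrants, migrant_id = sprintf("m%02d", i),
                    household_id = sprintf("h%02d", i))),
    tibble::tibble(migrant_id = "mx", household_id = "hx",
                   migration_years = 15, payment_individual = 11000))
  g <- econ_additionality(mg, hh, beta = 0.099, z_threshold = 4)
  expect_true("hx" %in% g$excluded)
  g_all <- econ_additionality(mg, hh, beta = 0.099, z_threshold = 1e9)
  expect_gt(g_all$numerator, g$numerator)
})

test_that("errors: zero payments, infinite coefficients, missing totals", {
  d <- single_household()
  hh0 <- dplyr::mutate(d$households, payment_annual = 0, ccfp_participant = 0)
  expect_error(econ_additionality(d$migrants, hh0, beta = 0.1), "zero")
  expect_error(econ_additionality(d$migrants, d$households, beta = Inf),
               "finite")
  expect_error(scale_national(econ = list(estimate = 2, lower = 1, upper = 3),
                              totals = list()), "missing")
})

test_that("national scaling is purely multiplicative", {
  # ecological band of 5.0-15.2% applied to 29.8 Mha enrolled
  ec <- list(estimate = 9.7, lower = 5.0, upper = 15.2)
  s <- scale_national(ecol = ec, totals = list(enrolled_area_mha = 29.8))
  expect_equal(s$lower[s$quantity == "induced_forest"], 1.49)
  expect_equal(s$upper[s$quantity == "induced_forest"], 4.5296)
  # 2% of a US$64 billion investment
  en <- list(estimate = 2.0, lower = 1.4, upper = 3.8)
  s2 <- scale_national(econ = en,
                       totals = list(investment_usd_billion = 64))
  usd <- s2[s2$unit == "USD billion", ]
  expect_equal(usd$point, 1.28)
  expect_true(usd$point > 0.9 && usd$point < 2.4)
  expect_equal(s2$point[s2$unit == "Yuan billion"], 1.28 * 6.22)
  # zero totals give zero scaled output
  s0 <- scale_national(ecol = ec, totals = list(enrolled_area_mha = 0))
  expect_true(all(s0$point == 0))
})
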