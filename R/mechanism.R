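# Forest-dependence mechanism indicators and group comparisons: fuelwood
# share of energy spending, energy-ladder stage, livestock, extraction
# inputs; weighted two-group tests and OLS on log10 remittance amount.

#' Share of fuelwood in household energy spending
#'
#' `fuelwood_value / (fuelwood_value + gas_cost)`, where fuelwood value is
#' typically fuelwood weight times the unit price (0.4 Yuan/kg). NA (with a
#' warning) when both terms are zero.
#'
#' @param fuelwood_value Yuan/year of fuelwood use.
#' @param gas_cost Yuan/year spent on gas.
#' @return numeric vector of shares in \[0, 1\].
#' @export
fuelwood_share <- function(fuelwood_value, gas_cost) {
  if (any(fuelwood_value < 0, na.rm = TRUE) || any(gas_cost < 0, na.rm = TRUE))
    abort_bad_input("fuelwood value and gas cost must be non-negative")
  tot <- fuelwood_value + gas_cost
  out <- ifelse(tot > 0, fuelwood_value / tot, NA_real_)
  if (any(tot == 0, na.rm = TRUE))
    warning("households with zero fuelwood and gas flagged as missing share")
  out
}

#' Energy-ladder stage from the fuelwood share
#'
#' Stage 1: fuelwood/coal is the main source (share above `upper`);
#' stage 2: about half and half (share in \[`lower`, `upper`\]);
#' stage 3: modern fuels dominate (share below `lower`).
#'
#' @param share fuelwood share in \[0, 1\].
#' @param lower,upper stage boundaries (default 0.4 and 0.6).
#' @return integer vector of stages 1-3 (NA propagates).
#' @export
energy_ladder_stage <- function(share, lower = 0.4, upper = 0.6) {
  ifelse(is.na(share), NA_integer_,
         ifelse(share > upper, 1L, ifelse(share >= lower, 2L, 3L)))
}

# weighted mean / variance / Welch t-test helpers
weighted_var <- function(x, w) {
  m <- weighted.mean(x, w)
  sum(w * (x - m)^2) / sum(w) * length(x) / (length(x) - 1)
}

weighted_welch_t <- function(x1, w1, x0, w0) {
  n1 <- sum(w1)^2 / sum(w1^2)  # Kish effective sample sizes
  n0 <- sum(w0)^2 / sum(w0^2)
  m1 <- weighted.mean(x1, w1); m0 <- weighted.mean(x0, w0)
  v1 <- weighted_var(x1, w1); v0 <- weighted_var(x0, w0)
  se <- sqrt(v1 / n1 + v0 / n0)
  t <- (m1 - m0) / se
  df <- (v1 / n1 + v0 / n0)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  list(mean1 = m1, mean0 = m0, difference = m1 - m0, statistic = t,
       df = df, p.value = 2 * pt(-abs(t), df))
}

#' Compare forest-dependence indicators between remittance groups
#'
#' For each continuous indicator: survey-weighted Welch t-test between
#' households receiving remittance (group 1) and those not (group 0), plus
#' a weighted OLS slope of the indicator on log10 remittance amount among
#' receivers. The 3-stage energy-ladder composition is compared by a
#' chi-squared test on weighted counts rescaled to the Kish effective
#' sample size.
#'
#' @param households household table including energy columns (see
#'   [generate_energy_and_flows()]) and `remittance_received`,
#'   `remittance_total`, `sampling_weight`.
#' @param indicators named list mapping indicator column names to an
#'   optional site restriction (`NA` for all sites).
#' @param weighted apply sampling weights (default TRUE).
#' @return list with `indicators` (tibble: mean per group, difference,
#'   t statistic, p, OLS slope and s.e.) and `ladder` (composition
#'   percentages, chi-squared statistic, df, p).
#' @export
mechanism_tests <- function(households,
                            indicators = list(
                              fuelwood_share = NA,
                              fuelwood_share_cook = NA,
                              livestock_jc = "jc",
                              livestock_ttz = "ttz",
                              extraction_cost_k = "ttz"),
                            weighted = TRUE) {
  hh <- households
  if (!all(c("remittance_received", "remittance_total", "sampling_weight")
           %in% names(hh)))
    abort_bad_input("households must carry remittance and weight columns")
  if (!weighted) hh$sampling_weight <- 1
  hh$livestock_jc <- ifelse(hh$site_id == "jc", hh$livestock, NA_real_)
  hh$livestock_ttz <- ifelse(hh$site_id == "ttz", hh$livestock, NA_real_)
  if ("extraction_cost" %in% names(hh))
    hh$extraction_cost_k <- hh$extraction_cost / 1000

  rows <- purrr::map_dfr(names(indicators), function(v) {
    restrict <- indicators[[v]]
    d <- hh
    if (!is.na(restrict)) d <- d[d$site_id == restrict, ]
    d <- d[!is.na(d[[v]]), ]
    d1 <- d[d$remittance_received == 1, ]
    d0 <- d[d$remittance_received == 0, ]
    if (nrow(d1) < 2 || nrow(d0) < 2)
      return(tibble::tibble(indicator = v, mean_remit = NA_real_,
                            mean_noremit = NA_real_, difference = NA_real_,
                            t_statistic = NA_real_, p_value = NA_real_,
                            ols_slope = NA_real_, ols_se = NA_real_))
    tt <- weighted_welch_t(d1[[v]], d1$sampling_weight,
                           d0[[v]], d0$sampling_weight)
    lx <- log10(d1$remittance_total)
    if (length(unique(lx)) > 2) {
      fit <- lm(d1[[v]] ~ lx, weights = d1$sampling_weight)
      sm <- summary(fit)$coefficients
      slope <- sm[2, 1]; se <- sm[2, 2]
    } else { slope <- NA_real_; se <- NA_real_ }
    tibble::tibble(indicator = v, mean_remit = tt$mean1,
                   mean_noremit = tt$mean0, difference = tt$difference,
                   t_statistic = tt$statistic, p_value = tt$p.value,
                   ols_slope = slope, ols_se = se)
  })

  ## energy-ladder composition
  lad <- hh[!is.na(hh$ladder_stage), ]
  tab <- purrr::map_dfr(0:1, function(g) {
    d <- lad[lad$remittance_received == g, ]
    w <- d$sampling_weight
    neff <- sum(w)^2 / sum(w^2)
    shares <- vapply(1:3, function(s)
      sum(w[d$ladder_stage == s]) / sum(w), 0)
    tibble::tibble(group = g, stage = 1:3, share = shares,
                   count = round(shares * neff))
  })
  empty <- tapply(tab$count, tab$stage, sum) == 0
  if (any(empty)) {
    warning("dropping energy-ladder stages empty in both groups: ",
            paste(which(empty), collapse = ", "))
    tab <- tab[!(tab$stage %in% which(empty)), ]
  }
  cmat <- matrix(tab$count, nrow = 2, byrow = TRUE)
  chi <- suppressWarnings(chisq.test(cmat, correct = FALSE))
  list(indicators = rows,
       ladder = list(composition = tab,
                     statistic = unname(chi$statistic),
                     df = unname(chi$parameter),
                     p_value = chi$p.value))
}
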