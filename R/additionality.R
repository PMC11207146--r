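# Additionality estimators: the share of PES-program-stimulated remittance
# in total program payments (socioeconomic additionality) and the share of
# remittance-induced new forest area in the enrolled area baseline
# (ecological additionality), with uncertainty propagated from the two
# estimated coefficients and scaling to program-level totals.

# attributable remittance per individual: 10^(beta * M_i * P_i / 1000),
# with P_i the annual payment in Yuan and M_i the migration period in years
.attributable <- function(beta, M, P_k_year) 10^(beta * M * P_k_year)

#' Socioeconomic additionality of program payments mediated by remittance
#'
#' `G_Econ% = sum_i 10^(beta * M_i * P_i / 1000) / sum_h P_h * 100`, where
#' the sum runs over migrants from participating households (the literal
#' formula, which awards 10^0 = 1 to every non-participant migrant, is
#' available with `participants_only = FALSE`). `beta` is the payment
#' coefficient of the log10-amount model (per 1,000 Yuan); bounds use
#' `beta +- sigma_beta`. Households whose attributable remittance is an
#' extreme outlier (z-score above `z_threshold` among receiving households)
#' are excluded.
#'
#' @param migrants migrant table with `migration_years`,
#'   `payment_individual` (Yuan/year), `household_id`.
#' @param households household table with `payment_annual` (Yuan/year) and
#'   `ccfp_participant`.
#' @param beta,sigma_beta coefficient and s.e. from the amount model.
#' @param z_threshold outlier exclusion threshold (default 10).
#' @param participants_only restrict the numerator to migrants of
#'   participating households (default TRUE).
#' @return list of class `additionality_result` component: `estimate`,
#'   `lower`, `upper` (percent), `numerator`, `denominator`, `excluded`,
#'   `degenerate` flag when `beta = 0`.
#' @export
econ_additionality <- function(migrants, households, beta, sigma_beta = 0,
                               z_threshold = 10, participants_only = TRUE) {
  if (!is.finite(beta)) abort_bad_input("beta must be finite")
  denom <- sum(households$payment_annual)
  if (denom <= 0) abort_bad_input("total program payment is zero")
  part_ids <- households$household_id[households$ccfp_participant == 1]
  m <- migrants
  if (participants_only) m <- m[m$household_id %in% part_ids, ]
  if (nrow(m) == 0) abort_bad_input("no participant migrants")
  Pk <- m$payment_individual / 1000

  calc <- function(b) {
    contrib <- .attributable(b, m$migration_years, Pk)
    hh_pred <- tapply(contrib, m$household_id, sum)
    # exclusion among receiving households by z-score of predicted remittance
    recv <- households$household_id[households$remittance_received == 1]
    zz <- rep(NA_real_, length(hh_pred))
    in_recv <- names(hh_pred) %in% recv
    if (sum(in_recv) > 2 && sd(hh_pred[in_recv]) > 0)
      zz[in_recv] <- (hh_pred[in_recv] - mean(hh_pred[in_recv])) /
        sd(hh_pred[in_recv])
    excl <- names(hh_pred)[!is.na(zz) & zz > z_threshold]
    keep <- !(m$household_id %in% excl)
    list(value = sum(contrib[keep]), excluded = excl)
  }
  point <- calc(beta)
  lo <- calc(beta - sigma_beta); hi <- calc(beta + sigma_beta)
  structure(list(
    estimate = 100 * point$value / denom,
    lower = 100 * lo$value / denom,
    upper = 100 * hi$value / denom,
    numerator = point$value, denominator = denom,
    beta = beta, sigma_beta = sigma_beta,
    excluded = point$excluded,
    degenerate = beta == 0), class = "additionality_component")
}

#' Ecological additionality of program payments mediated by remittance
#'
#' `G_Ecol% = sum_h gamma * L_h * A / sum_h (P_h / lambda_site) * 100`,
#' where `L_h = log10(sum_{i in S_h} 10^(beta * M_i * P_i / 1000))` is the
#' log10 of the household's attributable remittance (`observed_totals =
#' TRUE` instead logs the observed household remittance), `A` the buffer
#' area (m2), and the denominator the area enrolled implied by payments and
#' the per-site payment rate. Bounds multiply the lower (upper) limits of
#' both coefficient estimates.
#'
#' @inheritParams econ_additionality
#' @param gamma,sigma_gamma forest-change-per-log10-remittance slope and
#'   s.e.
#' @param area buffer area A in m2 (default the 100-m disc, pi * 100^2).
#' @param payment_rate_per_site named vector of Yuan/year/m2 rates.
#' @param observed_totals log observed household remittance instead of
#'   attributable remittance.
#' @return `additionality_component` list (percent scale) plus
#'   `forest_area_m2` and `baseline_area_m2`.
#' @export
ecol_additionality <- function(migrants, households, beta, gamma,
                               sigma_beta = 0, sigma_gamma = 0,
                               area = pi * 100^2,
                               payment_rate_per_site = c(jc = 0.135,
                                                         ttz = 0.1875),
                               participants_only = TRUE,
                               observed_totals = FALSE) {
  if (!is.finite(gamma)) abort_bad_input("gamma must be finite")
  if (area <= 0 || any(payment_rate_per_site <= 0))
    abort_bad_input("area and payment rates must be positive")
  lam <- payment_rate_per_site[households$site_id]
  denom <- sum(households$payment_annual / lam)
  if (denom <= 0) abort_bad_input("implied enrolled area is zero")
  part_ids <- households$household_id[households$ccfp_participant == 1]
  m <- migrants
  if (participants_only) m <- m[m$household_id %in% part_ids, ]
  Pk <- m$payment_individual / 1000

  num_fun <- function(b, g) {
    Lh <- if (observed_totals) {
      hh_ids <- sort(unique(m$household_id))
      tot <- households$remittance_total[match(hh_ids,
                                               households$household_id)]
      log10(pmax(tot, 1))
    } else {
      contrib <- tapply(.attributable(b, m$migration_years, Pk),
                        m$household_id, sum)
      log10(pmax(contrib, 1))  # zero attributable remittance -> L_h = 0
    }
    sum(g * Lh * area)
  }
  point <- num_fun(beta, gamma)
  lo <- num_fun(beta - sigma_beta, gamma - sigma_gamma)
  hi <- num_fun(beta + sigma_beta, gamma + sigma_gamma)
  structure(list(
    estimate = 100 * point / denom,
    lower = 100 * lo / denom, upper = 100 * hi / denom,
    forest_area_m2 = point, baseline_area_m2 = denom,
    beta = beta, gamma = gamma, area = area,
    degenerate = gamma == 0), class = "additionality_component")
}

#' @export
print.additionality_component <- function(x, ...) {
  cat(sprintf("additionality: %.3f%% [%.3f%%, %.3f%%]%s\n",
              x$estimate, x$lower, x$upper,
              if (isTRUE(x$degenerate)) " (degenerate: coefficient 0)" else ""))
  invisible(x)
}

#' Scale additionality percentages to program-level totals
#'
#' Applies the estimated socioeconomic additionality to the program's total
#' investment and the ecological additionality to its total enrolled area;
#' purely multiplicative.
#'
#' @param econ,ecol `additionality_component` results (or lists with
#'   `estimate`, `lower`, `upper` in percent); either may be NULL.
#' @param totals list with `investment_usd_billion` and/or
#'   `enrolled_area_mha`.
#' @param yuan_per_usd exchange rate used for reporting (default 6.22).
#' @return tibble: quantity, unit, point, lower, upper.
#' @export
scale_national <- function(econ = NULL, ecol = NULL, totals,
                           yuan_per_usd = 6.22) {
  if (is.null(totals) || (is.null(totals$investment_usd_billion) &&
                          is.null(totals$enrolled_area_mha)))
    abort_bad_input("program totals missing")
  out <- list()
  if (!is.null(econ)) {
    inv <- totals$investment_usd_billion
    if (is.null(inv)) abort_bad_input("investment total missing")
    out$remit_usd <- tibble::tibble(
      quantity = "stimulated_remittance", unit = "USD billion",
      point = econ$estimate / 100 * inv,
      lower = econ$lower / 100 * inv,
      upper = econ$upper / 100 * inv)
    out$remit_yuan <- dplyr::mutate(out$remit_usd,
                                    unit = "Yuan billion",
                                    point = .data$point * yuan_per_usd,
                                    lower = .data$lower * yuan_per_usd,
                                    upper = .data$upper * yuan_per_usd)
  }
  if (!is.null(ecol)) {
    ar <- totals$enrolled_area_mha
    if (is.null(ar)) abort_bad_input("enrolled-area total missing")
    out$forest <- tibble::tibble(
      quantity = "induced_forest", unit = "Mha",
      point = ecol$estimate / 100 * ar,
      lower = ecol$lower / 100 * ar,
      upper = ecol$upper / 100 * ar)
  }
  dplyr::bind_rows(out)
}
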