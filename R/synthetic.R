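# Synthetic study generator: emulates a two-site PES household survey
# (semi-arid "J&C", subtropical "TTZ"), out-migrant roster with remittance,
# resident-group polygons, and two-date forest/EVI rasters whose change is
# positively coupled to household remittance within an effect radius of the
# house location. All planted parameters are recorded in a truth object so
# downstream estimators can be validated by parameter recovery.

#' Scenario configuration for the synthetic study generator
#'
#' Defaults emulate the structure of the motivating two-site survey:
#' 458 migrant households (160 + 298) holding 767 migrants in 63 resident
#' groups (22 + 41), a CCFP participation rate of 0.57, payment rates of
#' 0.135 and 0.1875 Yuan/year/m2, and an overall remittance-sender share
#' near 36\%. Effect sizes are planted on the scales the estimators report:
#' `beta_ccfp_logit` and `beta_ccfp_amount` per 1,000 Yuan of cumulative
#' payment (log-odds and log10-Yuan respectively), `remit_forest_slope` in
#' forest fraction per log10-Yuan of household remittance.
#'
#' @param seed master seed; every sub-stage derives its own stream from it.
#' @param n_households_per_site migrant households per site (J&C, TTZ).
#' @param n_migrants total migrants across both sites (allocated to
#'   households by a truncated Poisson with mean ~1.7, minimum 1).
#' @param n_groups_per_site resident groups per site.
#' @param ccfp_participation_rate probability a household is enrolled.
#' @param payment_rate_per_site Yuan/year/m2 payment rate (J&C, TTZ).
#' @param beta_ccfp_logit planted log-odds of sending remittance per 1,000
#'   Yuan cumulative payment.
#' @param beta_ccfp_amount planted log10-Yuan remitted per 1,000 Yuan.
#' @param remit_forest_slope planted forest-fraction change per log10-Yuan
#'   of household remittance within the effect radius.
#' @param nonremit_drift planted forest-fraction drift around migrant
#'   households with zero remittance (negative: shrinkage/browning).
#' @param effect_radius radius (m) of the remittance effect zone.
#' @param cell_size raster cell size (m).
#' @param raster_extent square raster edge length per site (m).
#' @param forest_frac_t0 initial forest fraction per site.
#' @param sender_intercept,amount_intercept intercepts of the planted
#'   sender (logit) and amount (log10 Yuan) models.
#' @param amount_sd residual SD of log10 remittance amount.
#' @param sigma_group_logit,sigma_group_amount resident-group random
#'   intercept SDs.
#' @param evi_coupling EVI change per unit planted forest-fraction change.
#' @param noise_evi SD of EVI measurement noise.
#' @param energy_coupling fuelwood reduction (log scale) per log10-Yuan of
#'   remittance; 0 decouples energy use from remittance.
#' @param n_destination_cities number of distinct destination cities.
#' @return a validated `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L,
                            n_households_per_site = c(jc = 160L, ttz = 298L),
                            n_migrants = 767L,
                            n_groups_per_site = c(jc = 22L, ttz = 41L),
                            ccfp_participation_rate = 0.57,
                            payment_rate_per_site = c(jc = 0.135, ttz = 0.1875),
                            beta_ccfp_logit = 0.104,
                            beta_ccfp_amount = 0.099,
                            remit_forest_slope = 0.011,
                            nonremit_drift = -0.015,
                            effect_radius = 100,
                            cell_size = 30,
                            raster_extent = 6000,
                            forest_frac_t0 = c(jc = 0.35, ttz = 0.6),
                            sender_intercept = -0.74,
                            amount_intercept = 3.6,
                            amount_sd = 0.45,
                            sigma_group_logit = 0.3,
                            sigma_group_amount = 0.15,
                            evi_coupling = 0.5,
                            noise_evi = 0.02,
                            energy_coupling = 0.25,
                            n_destination_cities = 87L) {
  cfg <- list(seed = as.integer(seed),
              n_households_per_site = as.integer(n_households_per_site),
              n_migrants = as.integer(n_migrants),
              n_groups_per_site = as.integer(n_groups_per_site),
              ccfp_participation_rate = ccfp_participation_rate,
              payment_rate_per_site = payment_rate_per_site,
              beta_ccfp_logit = beta_ccfp_logit,
              beta_ccfp_amount = beta_ccfp_amount,
              remit_forest_slope = remit_forest_slope,
              nonremit_drift = nonremit_drift,
              effect_radius = effect_radius,
              cell_size = cell_size,
              raster_extent = raster_extent,
              forest_frac_t0 = forest_frac_t0,
              sender_intercept = sender_intercept,
              amount_intercept = amount_intercept,
              amount_sd = amount_sd,
              sigma_group_logit = sigma_group_logit,
              sigma_group_amount = sigma_group_amount,
              evi_coupling = evi_coupling,
              noise_evi = noise_evi,
              energy_coupling = energy_coupling,
              n_destination_cities = as.integer(n_destination_cities))
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  if (any(cfg$n_households_per_site <= 0) || any(cfg$n_groups_per_site <= 0) ||
      cfg$n_migrants <= 0)
    abort_bad_input("counts must be positive")
  if (cfg$n_migrants < sum(cfg$n_households_per_site))
    abort_bad_input("n_migrants must be >= number of migrant households (min 1 each)")
  if (any(cfg$n_households_per_site < 3L * cfg$n_groups_per_site))
    abort_bad_input("too few households for the group count (min 3 per group)")
  if (cfg$ccfp_participation_rate < 0 || cfg$ccfp_participation_rate > 1)
    abort_bad_input("ccfp_participation_rate must be in [0,1]")
  if (any(cfg$payment_rate_per_site <= 0) || cfg$effect_radius <= 0 ||
      cfg$cell_size <= 0)
    abort_bad_input("rates, radii and cell size must be strictly positive")
  if (any(cfg$forest_frac_t0 <= 0 | cfg$forest_frac_t0 >= 1))
    abort_bad_input("forest_frac_t0 must be in (0,1)")
  # buffers up to 200 m are analysed by default; reject cramped extents
  if (cfg$raster_extent < 2 * max(cfg$effect_radius, 200))
    abort_bad_input("raster_extent smaller than twice the maximum buffer radius")
  invisible(cfg)
}

site_names <- c("jc", "ttz")

# truncated-Poisson(>=1) counts with total forced to n_total
.alloc_migrants <- function(n_households, n_total, lambda = 1.2) {
  k <- rpois(n_households, lambda)
  k[k == 0] <- 1L
  excess <- sum(k) - n_total
  while (excess > 0) {
    i <- sample(which(k > 1L), 1L)
    k[i] <- k[i] - 1L
    excess <- excess - 1L
  }
  while (excess < 0) {
    i <- sample(seq_along(k), 1L)
    k[i] <- k[i] + 1L
    excess <- excess + 1L
  }
  k
}

zscore <- function(x) (x - mean(x)) / ifelse(sd(x) > 0, sd(x), 1)

#' Generate a complete synthetic study scenario
#'
#' Draws the two-site household and migrant tables, resident-group polygons,
#' per-site raster pairs and the truth object with all planted parameters.
#' Identical seed and configuration give identical output.
#'
#' @param config a [scenario_config()].
#' @param rasters generate the raster pairs (set `FALSE` for table-only
#'   replicates in simulation studies).
#' @return list of class `remiforest_scenario`: `households`, `migrants`,
#'   `destinations`, `groups` (tibble + `polygons` attribute), `rasters`
#'   (named by site), `truth`, `config`.
#' @export
generate_scenario <- function(config = scenario_config(), rasters = TRUE) {
  validate_scenario_config(config)
  cfg <- config

  ## -- groups and household locations ------------------------------------
  set.seed(derive_seed(cfg$seed, 1L))
  margin <- max(cfg$effect_radius, 200) + 100
  groups <- purrr::map_dfr(1:2, function(s) {
    ng <- cfg$n_groups_per_site[s]
    gx <- runif(ng, margin, cfg$raster_extent - margin)
    gy <- runif(ng, margin, cfg$raster_extent - margin)
    tibble::tibble(group_id = sprintf("%s_g%02d", site_names[s], seq_len(ng)),
                   site_id = site_names[s], centre_x = gx, centre_y = gy)
  })

  households <- purrr::map_dfr(1:2, function(s) {
    nh <- cfg$n_households_per_site[s]
    ng <- cfg$n_groups_per_site[s]
    gids <- sprintf("%s_g%02d", site_names[s], seq_len(ng))
    # every group gets at least 3 households, remainder multinomial
    base <- rep(3L, ng)
    extra <- nh - sum(base)
    if (extra < 0) abort_bad_input("too few households for the group count")
    add <- as.integer(stats::rmultinom(1, extra, rep(1, ng)))
    idx <- rep(seq_len(ng), base + add)
    g <- groups[groups$site_id == site_names[s], ]
    x <- pmin(pmax(rnorm(nh, g$centre_x[idx], 200), 60),
              cfg$raster_extent - 60)
    y <- pmin(pmax(rnorm(nh, g$centre_y[idx], 200), 60),
              cfg$raster_extent - 60)
    tibble::tibble(
      household_id = sprintf("%s_h%03d", site_names[s], seq_len(nh)),
      site_id = site_names[s], group_id = gids[idx], x = x, y = y)
  })

  ## -- covariates, participation, payments -------------------------------
  set.seed(derive_seed(cfg$seed, 2L))
  nh <- nrow(households)
  households <- households |>
    dplyr::mutate(
      cropland_mu = rlnorm(nh, log(4), 0.5),
      house_score = sample(1:5, nh, TRUE, prob = c(.1, .25, .3, .25, .1)),
      farmtool_score = sample(1:5, nh, TRUE, prob = c(.15, .3, .3, .15, .1)),
      transport_score = sample(1:5, nh, TRUE, prob = c(.2, .3, .25, .15, .1)),
      head_edu = pmin(pmax(round(rnorm(nh, 7, 3)), 0), 16),
      market_km = rlnorm(nh, log(3), 0.6),
      elevation = ifelse(.data$site_id == "jc", rnorm(nh, 1200, 150),
                         rnorm(nh, 600, 200)),
      slope_deg = pmin(pmax(rnorm(nh, 15, 6), 0), 40),
      ccfp_participant = rbinom(nh, 1, cfg$ccfp_participation_rate),
      enrolled_area = ifelse(.data$ccfp_participant == 1,
                             rlnorm(nh, log(1500), 0.6), 0),
      payment_years = sample(5:12, nh, TRUE),
      payment_rate = unname(cfg$payment_rate_per_site[
        match(.data$site_id, site_names)]),
      payment_annual = .data$enrolled_area * .data$payment_rate,
      cumulative_payment = pmin(.data$payment_annual * .data$payment_years,
                                12000),
      # stratified disproportionate sampling: participants oversampled
      sampling_weight = rlnorm(nh, 0, 0.3) *
        ifelse(.data$ccfp_participant == 1, 0.85, 1.15))
  households$sampling_weight <-
    households$sampling_weight / mean(households$sampling_weight)

  ## -- migrants and planted remittance models ----------------------------
  set.seed(derive_seed(cfg$seed, 3L))
  counts <- .alloc_migrants(nh, cfg$n_migrants)
  households$n_migrants <- counts
  mig_h <- rep(seq_len(nh), counts)
  nm <- cfg$n_migrants
  u_logit <- setNames(rnorm(nrow(groups), 0, cfg$sigma_group_logit),
                      groups$group_id)
  u_amount <- setNames(rnorm(nrow(groups), 0, cfg$sigma_group_amount),
                       groups$group_id)
  migrants <- tibble::tibble(
    migrant_id = sprintf("m%04d", seq_len(nm)),
    household_id = households$household_id[mig_h],
    group_id = households$group_id[mig_h],
    site_id = households$site_id[mig_h],
    gender = rbinom(nm, 1, 0.6),
    age = pmin(pmax(round(rnorm(nm, 30, 8)), 16), 59),
    education = pmin(pmax(round(rnorm(nm, 8, 3)), 0), 16),
    outside_province = rbinom(nm, 1, 0.5),
    migration_years = round(pmin(0.5 + stats::rexp(nm, 1 / 4), 15), 1),
    payment_individual = households$payment_annual[mig_h],
    payment_k = households$cumulative_payment[mig_h] / 1000,
    sampling_weight = households$sampling_weight[mig_h])

  zc <- list(head_edu = zscore(households$head_edu)[mig_h],
             cropland = zscore(households$cropland_mu)[mig_h],
             transport = zscore(households$transport_score)[mig_h],
             market = zscore(households$market_km)[mig_h])
  eta <- cfg$sender_intercept +
    cfg$beta_ccfp_logit * migrants$payment_k +
    0.65 * zc$head_edu - 0.55 * zc$cropland + 0.45 * zc$transport -
    0.45 * zc$market + 0.30 * (migrants$site_id == "ttz") +
    0.10 * zscore(migrants$education) +
    u_logit[migrants$group_id]
  p_send <- plogis(eta)
  migrants$sent_remittance <- rbinom(nm, 1, p_send)
  mu_amt <- cfg$amount_intercept +
    cfg$beta_ccfp_amount * migrants$payment_k +
    0.08 * zscore(migrants$education) +
    u_amount[migrants$group_id]
  log_amt <- mu_amt + rnorm(nm, 0, cfg$amount_sd)
  migrants$remittance_amount <-
    ifelse(migrants$sent_remittance == 1, round(10^log_amt, 2), 0)

  ## -- household aggregates and truth -------------------------------------
  agg <- migrants |>
    dplyr::group_by(.data$household_id) |>
    dplyr::summarise(remittance_total = sum(.data$remittance_amount),
                     .groups = "drop")
  households <- households |>
    dplyr::left_join(agg, by = "household_id") |>
    dplyr::mutate(remittance_received = as.integer(.data$remittance_total > 0))

  g_h <- ifelse(households$remittance_received == 1,
                cfg$nonremit_drift +
                  cfg$remit_forest_slope * log10(households$remittance_total),
                cfg$nonremit_drift)
  truth <- list(
    beta_ccfp_logit = cfg$beta_ccfp_logit,
    beta_ccfp_amount = cfg$beta_ccfp_amount,
    remit_forest_slope = cfg$remit_forest_slope,
    nonremit_drift = cfg$nonremit_drift,
    expected_delta_forest = setNames(g_h, households$household_id),
    planted_contrast = mean(g_h[households$remittance_received == 1]) -
      mean(g_h[households$remittance_received == 0]),
    p_send = setNames(p_send, migrants$migrant_id))

  ## -- group polygons ------------------------------------------------------
  polys <- purrr::map(seq_len(nrow(groups)), function(i) {
    mem <- households[households$group_id == groups$group_id[i], ]
    dilated_hull(mem$x, mem$y, r = 40)
  })
  names(polys) <- groups$group_id
  group_remit <- households |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(group_remittance_total = sum(.data$remittance_total),
                     n_households = dplyr::n(), .groups = "drop")
  groups <- dplyr::left_join(groups, group_remit, by = "group_id")
  attr(groups, "polygons") <- polys

  ## -- energy use and flows ------------------------------------------------
  ef <- generate_energy_and_flows(households, migrants, cfg)
  households <- ef$households
  migrants <- ef$migrants

  rast <- if (rasters) generate_rasters(households, cfg, truth) else NULL

  structure(list(households = households, migrants = migrants,
                 destinations = ef$destinations, groups = groups,
                 rasters = rast, truth = truth, config = cfg),
            class = "remiforest_scenario")
}

#' Generate the two-date forest/EVI raster pair for each site
#'
#' The t0 forest field is a thresholded spatially autocorrelated (smoothed
#' white noise) surface. Between t0 and t1, cells within `effect_radius` of
#' a migrant household transition with probabilities tuned so the expected
#' buffer-level forest-fraction change equals the household's planted effect
#' (`nonremit_drift + remit_forest_slope * log10(remittance)` for receiving
#' households, `nonremit_drift` otherwise); elsewhere gains and losses
#' balance. EVI changes track the planted effect through `evi_coupling`.
#'
#' @param households household table with coordinates and remittance totals.
#' @param config a [scenario_config()].
#' @param truth optional truth list (recomputed when NULL).
#' @return named list of [raster_pair()] objects, one per site.
#' @export
generate_rasters <- function(households, config, truth = NULL) {
  cfg <- config
  ext <- cfg$raster_extent
  if (any(households$x < 0 | households$x > ext |
          households$y < 0 | households$y > ext))
    abort_bad_input("household coordinates outside the raster extent")
  if (is.null(truth)) {
    g_all <- ifelse(households$remittance_received == 1,
                    cfg$nonremit_drift +
                      cfg$remit_forest_slope * log10(households$remittance_total),
                    cfg$nonremit_drift)
    names(g_all) <- households$household_id
  } else g_all <- truth$expected_delta_forest

  set.seed(derive_seed(cfg$seed, 4L))
  out <- list()
  for (s in 1:2) {
    site <- site_names[s]
    hh <- households[households$site_id == site, ]
    n <- as.integer(round(ext / cfg$cell_size))
    f0 <- cfg$forest_frac_t0[s]
    field <- smooth_matrix(matrix(rnorm(n * n), n, n), width = 7L, passes = 3L)
    field <- (field - mean(field)) / sd(field)
    forest0 <- (field > quantile(field, 1 - f0)) * 1L
    evi0 <- matrix(0.12 + rnorm(n * n, 0, 0.03), n, n)
    evi0[forest0 == 1] <- 0.35 + 0.18 * pnorm(field[forest0 == 1]) +
      rnorm(sum(forest0), 0, 0.02)
    evi0 <- pmin(pmax(evi0, -1), 1)

    # planted effect per cell: overlapping household effect zones add, so a
    # household's own buffer carries its full planted effect and neighbour
    # spillover enters as noise, not attenuation bias
    g_cell <- matrix(0, n, n)
    cs <- cfg$cell_size
    r_eff <- cfg$effect_radius
    for (i in seq_len(nrow(hh))) {
      cxy <- c(hh$x[i], hh$y[i])
      c0 <- max(1L, floor((cxy[1] - r_eff) / cs) + 1L)
      c1 <- min(n, ceiling((cxy[1] + r_eff) / cs))
      r0 <- max(1L, floor((cxy[2] - r_eff) / cs) + 1L)
      r1 <- min(n, ceiling((cxy[2] + r_eff) / cs))
      if (c0 > c1 || r0 > r1) next
      cols <- c0:c1; rows <- r0:r1
      xs <- (cols - 0.5) * cs; ys <- (rows - 0.5) * cs
      dmat <- outer(ys - cxy[2], xs - cxy[1],
                    function(a, b) sqrt(a^2 + b^2))
      # include every cell intersecting the effect disc (centre within the
      # radius plus the half cell diagonal), so the buffer-weighted mean of
      # the planted field equals the household's planted effect
      sel <- dmat <= r_eff + cs / sqrt(2)
      block_g <- g_cell[rows, cols]
      block_g[sel] <- block_g[sel] + g_all[[hh$household_id[i]]]
      g_cell[rows, cols] <- block_g
    }

    # planted transitions: per-cell gain/loss probabilities sized so the
    # expected buffer-level forest-fraction change equals the planted effect
    pg <- pmin(pmax(g_cell, 0) / (1 - f0), 1)
    pl <- pmin(pmax(-g_cell, 0) / f0, 1)
    u <- matrix(runif(n * n), n, n)
    forest1 <- forest0
    forest1[forest0 == 0 & u < pg] <- 1L
    forest1[forest0 == 1 & u < pl] <- 0L
    # background churn as a paired swap process: every spontaneous loss is
    # matched by a gain at a nearby non-forest cell, so the expected net
    # change of any buffer is zero (up to boundary leakage) and carries no
    # spatially autocorrelated drift
    churn <- 0.02
    losses <- which(forest1 == 1L & matrix(runif(n * n), n, n) < churn)
    losses <- losses[sample.int(length(losses))]
    off <- as.matrix(expand.grid(dr = -3:3, dc = -3:3))
    off <- off[!(off[, 1] == 0 & off[, 2] == 0), ]
    for (cell in losses) {
      r0i <- ((cell - 1L) %% n) + 1L
      c0i <- ((cell - 1L) %/% n) + 1L
      cand <- off[sample.int(nrow(off)), , drop = FALSE]
      rr <- r0i + cand[, 1]; cc <- c0i + cand[, 2]
      okc <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
      rr <- rr[okc]; cc <- cc[okc]
      free <- which(forest1[cbind(rr, cc)] == 0L)
      if (!length(free)) next  # no local partner: cancel the loss
      forest1[cell] <- 0L
      forest1[rr[free[1]], cc[free[1]]] <- 1L
    }

    evi1 <- evi0 + cfg$evi_coupling * g_cell + rnorm(n * n, 0, cfg$noise_evi)
    evi1[forest0 == 0 & forest1 == 1] <- 0.32 +
      rnorm(sum(forest0 == 0 & forest1 == 1), 0, 0.05)
    evi1[forest1 == 0] <- 0.12 + rnorm(sum(forest1 == 0), 0, 0.03)
    evi1 <- pmin(pmax(evi1, -1), 1)

    out[[site]] <- raster_pair(forest0, forest1, evi0, evi1,
                               cell_size = cs, origin = c(0, 0), site = site)
  }
  out
}

#' Generate energy-use columns and the migrant destination table
#'
#' Fuelwood use (kg/year) is negatively coupled, and gas spending positively
#' coupled, to household remittance on the log10 scale at strength
#' `energy_coupling`; a 3-stage energy-ladder label is derived from the
#' fuelwood share. Each migrant is assigned a destination city whose
#' log10 origin-destination distance lies in \[1.7, 3.2\] (km), with choice
#' probability decaying in distance.
#'
#' @param households,migrants scenario tables.
#' @param config a [scenario_config()].
#' @return list with augmented `households`, `migrants` (destination
#'   columns) and the `destinations` city table.
#' @export
generate_energy_and_flows <- function(households, migrants, config) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, 5L))
  nh <- nrow(households)
  lr <- log10(households$remittance_total + 1)
  fuel_kg <- exp(7.2 - cfg$energy_coupling * lr + rnorm(nh, 0, 0.4))
  gas_cost <- exp(3.6 + 0.35 * cfg$energy_coupling / 0.25 * lr +
                    rnorm(nh, 0, 0.5))
  households$fuelwood_kg <- round(fuel_kg, 1)
  households$fuelwood_value <- round(fuel_kg * 0.4, 2)
  households$gas_cost <- round(gas_cost, 2)
  households$fuelwood_share <-
    fuelwood_share(households$fuelwood_value, households$gas_cost)
  households$fuelwood_share_cook <- pmin(pmax(
    households$fuelwood_share - abs(rnorm(nh, 0.02, 0.02)), 0), 1)
  households$ladder_stage <- energy_ladder_stage(households$fuelwood_share)
  households$livestock <- rbinom(nh, 1, plogis(
    ifelse(households$site_id == "jc", -0.5, 1.3) -
      0.05 * cfg$energy_coupling / 0.25 * lr))
  households$extraction_cost <- ifelse(
    households$site_id == "ttz",
    round(exp(7.4 - 0.3 * cfg$energy_coupling / 0.25 * lr +
                rnorm(nh, 0, 0.5)), 2), NA_real_)

  set.seed(derive_seed(cfg$seed, 6L))
  ncity <- cfg$n_destination_cities
  destinations <- tibble::tibble(
    city_id = sprintf("city%02d", seq_len(ncity)),
    province_id = sprintf("prov%02d", sample(1:28, ncity, TRUE)),
    log10_distance = runif(ncity, 1.7, 3.2)) |>
    dplyr::mutate(distance_km = round(10^.data$log10_distance, 1))
  # gravity-like choice: nearer cities attract more migrants
  pr <- 10^(-0.8 * destinations$log10_distance)
  pick <- sample(seq_len(ncity), nrow(migrants), TRUE, prob = pr)
  migrants$destination_city <- destinations$city_id[pick]
  migrants$distance_km <- destinations$distance_km[pick]
  list(households = households, migrants = migrants,
       destinations = destinations)
}
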