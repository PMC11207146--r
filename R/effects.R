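# Treatment-effect and association estimators: pairwise-bootstrap average
# treatment effects of remittance on buffer forest change with three
# directional hypotheses and their occurrence-of-significance consistency,
# OLS remittance-forest associations at household level, and ring-buffer
# associations at resident-group level with outlier-robust refits.

# fast weighted one-sample t-tests for a matrix of replicate draws
# (columns); weights discount treated households reused across pairs, with
# the Kish effective sample size as the degrees of freedom
.col_t_p <- function(mat, w = NULL) {
  if (is.null(w)) w <- matrix(1, nrow(mat), ncol(mat))
  sw <- colSums(w)
  m <- colSums(w * mat) / sw
  neff <- sw^2 / colSums(w^2)
  v <- colSums(w * sweep(mat, 2, m)^2) / sw * neff / pmax(neff - 1, 1)
  tt <- m / sqrt(v / neff)
  list(mean = m, t = tt, p = 2 * pt(-abs(tt), pmax(neff - 1, 1)))
}

#' Pairwise-bootstrap average treatment effect of remittance on forest change
#'
#' Each replicate draws `ceiling(frac * n_pairs)` matched pairs with
#' replacement and tests three directional hypotheses on the chosen metric:
#' H1 treated-minus-control difference > 0 (paired t-test), H2 treated
#' change > 0, H3 control change <= 0 (reported as the occurrence of a
#' significant negative and of a non-significant result). A replicate
#' counts towards H1/H2 only when p < 0.05 AND the sign agrees. The
#' occurrence percentage over replicates measures consistency.
#'
#' @param match a [match_controls()] result.
#' @param buffer_changes a [radii_sweep()] table covering all matched
#'   households.
#' @param radii radii to evaluate (default all present).
#' @param metrics outcome columns (`delta_forest`, `delta_evi`).
#' @param n_reps bootstrap replicates. @param frac subsample fraction.
#' @param seed RNG seed.
#' @param subsample_mode `"replacement"` (bootstrap to 60\% of the pair
#'   count) or `"without"` (plain 60\% subsample).
#' @return tibble per radius x metric: mean difference, bootstrap s.d.,
#'   mean treated / control change, `occ_h1`, `occ_h2`, `occ_h3_signeg`,
#'   `occ_h3_nonsig`, `occ_h3` percentages.
#' @export
bootstrap_ate <- function(match, buffer_changes, radii = NULL,
                          metrics = c("delta_forest", "delta_evi"),
                          n_reps = 1000L, frac = 0.6, seed = 1L,
                          subsample_mode = c("replacement", "without")) {
  subsample_mode <- match.arg(subsample_mode)
  p <- match$pairs
  if (nrow(p) < 5L) abort_bad_input("need at least 5 matched pairs")
  radii <- radii %||% sort(unique(buffer_changes$radius))
  set.seed(derive_seed(seed, 21L))
  nsub <- ceiling(frac * nrow(p))
  idx <- if (subsample_mode == "replacement")
    matrix(sample.int(nrow(p), nsub * n_reps, TRUE), nsub, n_reps)
  else vapply(seq_len(n_reps), function(b)
    sample.int(nrow(p), nsub, FALSE), integer(nsub))
  purrr::map_dfr(radii, function(r) {
    bc <- buffer_changes[buffer_changes$radius == r, ]
    purrr::map_dfr(metrics, function(metric) {
      vt <- bc[[metric]][match(p$treated_id, bc$household_id)]
      vc <- bc[[metric]][match(p$control_id, bc$household_id)]
      ok <- !is.na(vt) & !is.na(vc)
      vt <- vt[ok]; vc <- vc[ok]
      if (sum(ok) < 5L)
        return(tibble::tibble(radius = r, metric = metric,
                              mean_diff = NA_real_, boot_sd = NA_real_,
                              mean_treated = NA_real_, mean_control = NA_real_,
                              occ_h1 = NA_real_, occ_h2 = NA_real_,
                              occ_h3_signeg = NA_real_,
                              occ_h3_nonsig = NA_real_, occ_h3 = NA_real_,
                              n_pairs = sum(ok)))
      if (sum(ok) == nrow(p)) id2 <- idx
      else {
        # some pairs lack metrics at this radius: draw a fresh index matrix
        set.seed(derive_seed(seed, 23L + as.integer(r)))
        n2 <- ceiling(frac * sum(ok))
        id2 <- matrix(sample.int(sum(ok), n2 * n_reps, TRUE), n2, n_reps)
      }
      dmat <- matrix((vt - vc)[id2], nrow(id2), ncol(id2))
      tmat <- matrix(vt[id2], nrow(id2), ncol(id2))
      cmat <- matrix(vc[id2], nrow(id2), ncol(id2))
      wp <- p$weight[ok]
      wmat <- matrix(wp[id2], nrow(id2), ncol(id2))
      h1 <- .col_t_p(dmat, wmat); h2 <- .col_t_p(tmat, wmat)
      h3 <- .col_t_p(cmat)
      tibble::tibble(
        radius = r, metric = metric,
        mean_diff = mean(h1$mean), boot_sd = sd(h1$mean),
        mean_treated = mean(h2$mean), mean_control = mean(h3$mean),
        occ_h1 = 100 * mean(h1$p < 0.05 & h1$mean > 0),
        occ_h2 = 100 * mean(h2$p < 0.05 & h2$mean > 0),
        occ_h3_signeg = 100 * mean(h3$p < 0.05 & h3$mean < 0),
        occ_h3_nonsig = 100 * mean(h3$p >= 0.05),
        occ_h3 = 100 * mean((h3$p < 0.05 & h3$mean < 0) | h3$p >= 0.05),
        n_pairs = sum(ok))
    })
  })
}

#' Bootstrap OLS association of buffer forest change with remittance
#'
#' Regresses the buffer change metric on log10 remittance (household total
#' or per-migrant average) among receiving households, with the same
#' 60\%-with-replacement pairwise bootstrap; the slope is the effect of a
#' 10-times increase in remittance.
#'
#' @param households household table (`remittance_total`, `n_migrants`).
#' @param buffer_changes [radii_sweep()] output.
#' @param radius buffer radius to analyse.
#' @param metric outcome column.
#' @param level `"household"` (total) or `"per_migrant"` (average).
#' @param n_reps,frac,seed bootstrap settings as in [bootstrap_ate()].
#' @return tibble: slope, slope_se (full sample), boot_mean, boot_sd,
#'   occurrence percentage of p < 0.05, n.
#' @export
remittance_forest_ols <- function(households, buffer_changes, radius = 100,
                                  metric = "delta_forest",
                                  level = c("household", "per_migrant"),
                                  n_reps = 1000L, frac = 0.6, seed = 1L) {
  level <- match.arg(level)
  bc <- buffer_changes[buffer_changes$radius == radius, ]
  d <- households[households$remittance_total > 0, ]
  amt <- if (level == "household") d$remittance_total
  else d$remittance_total / d$n_migrants
  y <- bc[[metric]][match(d$household_id, bc$household_id)]
  ok <- !is.na(y) & amt > 0
  x <- log10(amt[ok]); y <- y[ok]
  if (length(unique(x)) < 3L)
    abort_bad_input("need at least 3 distinct remittance values")
  full <- summary(lm(y ~ x))$coefficients
  set.seed(derive_seed(seed, 22L))
  nsub <- ceiling(frac * length(y))
  draws <- vapply(seq_len(n_reps), function(b) {
    i <- sample.int(length(y), nsub, TRUE)
    if (length(unique(x[i])) < 3L) return(c(NA_real_, NA_real_))
    sm <- summary(lm(y[i] ~ x[i]))$coefficients
    c(sm[2, 1], sm[2, 4])
  }, numeric(2))
  sl <- draws[1, ]; pv <- draws[2, ]
  keep <- !is.na(sl) & !is.na(pv)
  # occurrence follows the directional convention of the hypothesis tests:
  # a replicate counts when p < 0.05 AND the slope is positive; the
  # sign-blind rate is reported alongside
  tibble::tibble(radius = radius, metric = metric, level = level,
                 slope = full[2, 1], slope_se = full[2, 2],
                 boot_mean = mean(sl[keep]), boot_sd = sd(sl[keep]),
                 occurrence = 100 * mean(pv[keep] < 0.05 & sl[keep] > 0),
                 occurrence_any = 100 * mean(pv[keep] < 0.05),
                 n = length(y))
}

#' Group-level association of ring forest change with remittance
#'
#' OLS of the ring-buffer change metric on log10 of the group remittance
#' total, per ring zone (within boundary, 0-100 m, 100-200 m). Outliers are
#' points with |studentised residual| > 3; the regression is refitted
#' without them (the "all points" and "excluding outliers" trend lines).
#'
#' @param groups group table with `group_id`, `group_remittance_total`.
#' @param ring_changes stacked [ring_buffer_change()] rows with `unit_id`
#'   = group id and `label` = zone.
#' @param metric outcome column.
#' @return tibble per zone: slopes/se/p for all points and excluding
#'   outliers, outlier ids, n.
#' @export
group_association <- function(groups, ring_changes, metric = "delta_forest") {
  if (nrow(groups) < 10L) abort_bad_input("need at least 10 groups")
  zones <- unique(ring_changes$label)
  purrr::map_dfr(zones, function(z) {
    rc <- ring_changes[ring_changes$label == z, ]
    d <- dplyr::inner_join(groups, rc, by = c(group_id = "unit_id"))
    d <- d[!is.na(d[[metric]]) & d$group_remittance_total > 0, ]
    x <- log10(d$group_remittance_total); y <- d[[metric]]
    fit <- lm(y ~ x)
    rs <- rstudent(fit)
    out_ids <- d$group_id[abs(rs) > 3]
    keep <- abs(rs) <= 3
    if (!any(keep)) abort_bad_input("all points flagged as outliers")
    fit2 <- lm(y[keep] ~ x[keep])
    s1 <- summary(fit)$coefficients; s2 <- summary(fit2)$coefficients
    tibble::tibble(zone = z, metric = metric, n = length(y),
                   slope_all = s1[2, 1], se_all = s1[2, 2], p_all = s1[2, 4],
                   slope_robust = s2[2, 1], se_robust = s2[2, 2],
                   p_robust = s2[2, 4],
                   n_outliers = length(out_ids),
                   outliers = paste(out_ids, collapse = ";"))
  })
}
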