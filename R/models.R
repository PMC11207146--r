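# Two-level mixed-effects models of remittance: a random-intercept logistic
# model for whether a migrant sends remittance and a random-intercept linear
# model for the log10 amount among senders, both with sampling weights.
# Fitted with lme4 (adaptive Gauss-Hermite quadrature for the logistic
# model); marginal effects are population-averaged over the random
# intercept by Gauss-Hermite integration.

.muffle_weight_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("non-integer", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

.singleton_warning <- function(data, group_var) {
  sizes <- table(data[[group_var]])
  singles <- names(sizes)[sizes == 1]
  if (length(singles))
    warning("groups of size 1 (contribute through the integral only): ",
            paste(singles, collapse = ", "))
}

# boundary/singular fits are converged fits at the variance boundary
.lme4_converged <- function(m) {
  msgs <- m@optinfo$conv$lme4$messages %||% character()
  msgs <- msgs[!grepl("singular|boundary", msgs)]
  length(msgs) == 0
}

.group_var <- function(formula) {
  bars <- lme4::findbars(formula)
  if (length(bars) != 1L)
    abort_bad_input("formula must contain exactly one (1 | group) term")
  deparse(bars[[1]][[3]])
}

.new_remit_fit <- function(model, family, data, formula, weights_col,
                           sigma_u2, resid_var, converged) {
  ll <- as.numeric(logLik(model))
  k <- attr(logLik(model), "df")
  n <- nobs(model)
  icc <- sigma_u2 / (sigma_u2 + resid_var)
  cf <- if (inherits(model, "merMod")) {
    sm <- summary(model)$coefficients
    tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                   std.error = sm[, 2], statistic = sm[, 3])
  } else {
    sm <- summary(model)$coefficients
    tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                   std.error = sm[, 2], statistic = sm[, 3])
  }
  cf$p.value <- 2 * pnorm(-abs(cf$statistic))
  structure(list(model = model, family = family, formula = formula,
                 data = data, weights_col = weights_col,
                 coefficients = cf, sigma_u2 = sigma_u2,
                 resid_var = resid_var, icc = icc,
                 logLik = ll, df = k, AIC = -2 * ll + 2 * k,
                 BIC = -2 * ll + k * log(n), n = n,
                 converged = converged),
            class = "remit_fit")
}

#' @export
print.remit_fit <- function(x, ...) {
  cat(sprintf("<remit_fit> %s mixed model, n = %d, ICC = %.3f%s\n",
              x$family, x$n, x$icc,
              if (!x$converged) " (NOT converged)" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Random-intercept logistic model of sending remittance
#'
#' Fits `Pr(y = 1) = logit^-1(x'beta + u_c)` with resident-group random
#' intercepts `u_c ~ N(0, sigma_u^2)` and sampling weights, by adaptive
#' Gauss-Hermite quadrature (default 15 points; `nAGQ = 1` is the Laplace
#' approximation). The ICC uses the logistic residual variance pi^2 / 3.
#'
#' @param data individual-level data frame.
#' @param formula model formula with exactly one `(1 | group)` term, e.g.
#'   `sent_remittance ~ payment_k + age + (1 | group_id)`.
#' @param weights_col name of the sampling-weight column.
#' @param nAGQ quadrature points (1 = Laplace).
#' @param zero_variance constrain the random-intercept variance to zero
#'   (reduces to a weighted fixed-effects logistic fit).
#' @return object of class `remit_fit`.
#' @export
fit_remit_logit <- function(data, formula, weights_col = "sampling_weight",
                            nAGQ = 15L, zero_variance = FALSE) {
  w <- data[[weights_col]]
  if (is.null(w) || any(w <= 0)) abort_bad_input("weights must exist and be positive")
  resp <- all.vars(formula)[1]
  y <- data[[resp]]
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("complete separation: response '", resp,
         "' takes a single value", call. = FALSE)
  data$.w_ <- w
  if (zero_variance) {
    fx <- lme4::nobars(formula)
    m <- .muffle_weight_warning(
      glm(fx, data = data, family = binomial(), weights = .w_))
    if (!m$converged) stop("separation suspected: weighted logistic fit did not converge",
                           call. = FALSE)
    return(.new_remit_fit(m, "logistic", data, formula, weights_col,
                          sigma_u2 = 0, resid_var = pi^2 / 3,
                          converged = TRUE))
  }
  gv <- .group_var(formula)
  .singleton_warning(data, gv)
  m <- .muffle_weight_warning(
    lme4::glmer(formula, data = data, family = binomial(), weights = .w_,
                nAGQ = nAGQ,
                control = lme4::glmerControl(calc.derivs = FALSE)))
  conv <- .lme4_converged(m)
  s2 <- as.numeric(lme4::VarCorr(m)[[gv]])
  .new_remit_fit(m, "logistic", data, formula, weights_col,
                 sigma_u2 = s2, resid_var = pi^2 / 3, converged = conv)
}

#' Random-intercept linear model of the (log10) remittance amount
#'
#' Fits `y = X beta + Z u + tau` with a resident-group random intercept and
#' sampling weights, on senders only (the response is log10 remittance;
#' zero amounts are excluded upstream, hurdle-style). ML by default so that
#' AIC/BIC comparisons across fixed-effect specifications are valid.
#'
#' @inheritParams fit_remit_logit
#' @param REML use REML instead of ML.
#' @return object of class `remit_fit`.
#' @export
fit_remit_linear <- function(data, formula, weights_col = "sampling_weight",
                             REML = FALSE, zero_variance = FALSE) {
  w <- data[[weights_col]]
  if (is.null(w) || any(w <= 0)) abort_bad_input("weights must exist and be positive")
  fx <- lme4::nobars(formula)
  X <- stats::model.matrix(fx, data)
  if (nrow(X) <= ncol(X) + 1L)
    abort_bad_input("fewer observations than parameters")
  if (qr(X)$rank < ncol(X))
    abort_bad_input("rank-deficient fixed-effect design (collinear columns)")
  data$.w_ <- w
  if (zero_variance) {
    m <- lm(fx, data = data, weights = .w_)
    return(.new_remit_fit(m, "linear", data, formula, weights_col,
                          sigma_u2 = 0,
                          resid_var = summary(m)$sigma^2, converged = TRUE))
  }
  gv <- .group_var(formula)
  .singleton_warning(data, gv)
  m <- lme4::lmer(formula, data = data, weights = .w_, REML = REML)
  conv <- .lme4_converged(m)
  s2 <- as.numeric(lme4::VarCorr(m)[[gv]])
  .new_remit_fit(m, "linear", data, formula, weights_col,
                 sigma_u2 = s2, resid_var = stats::sigma(m)^2,
                 converged = conv)
}

# fixed-effect coefficient vector and covariate means for a remit_fit
.fixef_vec <- function(fit) {
  if (inherits(fit$model, "merMod")) lme4::fixef(fit$model) else coef(fit$model)
}

.design_at <- function(fit, at = NULL) {
  fx <- lme4::nobars(fit$formula)
  mm <- stats::model.matrix(fx, fit$data)
  xbar <- colMeans(mm)
  if (!is.null(at)) {
    bad <- setdiff(names(at), colnames(mm))
    if (length(bad))
      abort_bad_input(paste("'at' names not model columns:",
                            paste(bad, collapse = ", ")))
    xbar[names(at)] <- unlist(at)
  }
  xbar
}

# population-averaged response probability and its derivative factor at a
# linear predictor, integrating the random intercept by Gauss-Hermite
.gh_average <- function(eta, sigma_u, n_nodes = 15L) {
  gq <- statmod::gauss.quad.prob(n_nodes, dist = "normal")
  p <- vapply(seq_along(gq$nodes), function(k)
    plogis(eta + sigma_u * gq$nodes[k]), numeric(length(eta)))
  dens <- vapply(seq_along(gq$nodes), function(k) {
    pk <- plogis(eta + sigma_u * gq$nodes[k]); pk * (1 - pk)
  }, numeric(length(eta)))
  list(p = drop(p %*% gq$weights), dpdeta = drop(dens %*% gq$weights))
}

#' Marginal effects and predictive margins
#'
#' For the logistic model the marginal effect of covariate j is
#' `beta_j * dP/deta` with the response probability population-averaged
#' over the random intercept by Gauss-Hermite integration, evaluated at the
#' covariate means (or at `at`). For the linear model the marginal effect
#' equals the coefficient. Standard errors by the delta method over the
#' fixed effects. Predictive margins are returned over a payment grid.
#'
#' @param fit a `remit_fit`.
#' @param at named list of covariate values overriding the means.
#' @param payment_var name of the payment design column for the margin grid.
#' @param payment_grid grid of payment values (thousand Yuan).
#' @param n_nodes Gauss-Hermite nodes.
#' @return list with `effects` (tibble: term, estimate, std.error) and
#'   `margins` (tibble: payment, margin).
#' @export
marginal_effects <- function(fit, at = NULL, payment_var = "payment_k",
                             payment_grid = seq(0, 12, by = 0.5),
                             n_nodes = 15L) {
  if (!fit$converged) abort_bad_input("fit did not converge")
  beta <- .fixef_vec(fit)
  xbar <- .design_at(fit, at)
  terms <- setdiff(names(beta), "(Intercept)")
  V <- as.matrix(vcov(fit$model))[names(beta), names(beta)]
  if (fit$family == "linear") {
    eff <- tibble::tibble(term = terms, estimate = beta[terms],
                          std.error = sqrt(diag(V))[terms])
    margins <- NULL
    if (payment_var %in% names(beta)) {
      xg <- sapply(payment_grid, function(v) {
        x <- xbar; x[payment_var] <- v; sum(x * beta)
      })
      margins <- tibble::tibble(payment = payment_grid, margin = xg)
    }
    return(list(effects = eff, margins = margins))
  }
  sigma_u <- sqrt(fit$sigma_u2)
  ame_fun <- function(b, j) {
    eta <- sum(xbar * b)
    b[j] * .gh_average(eta, sigma_u, n_nodes)$dpdeta
  }
  eff <- purrr::map_dfr(terms, function(j) {
    est <- ame_fun(beta, j)
    # delta method, numeric gradient over the fixed effects
    grad <- vapply(seq_along(beta), function(k) {
      h <- 1e-6 * max(1, abs(beta[k]))
      bp <- beta; bp[k] <- bp[k] + h
      bm <- beta; bm[k] <- bm[k] - h
      (ame_fun(bp, j) - ame_fun(bm, j)) / (2 * h)
    }, 0)
    tibble::tibble(term = j, estimate = est,
                   std.error = sqrt(drop(t(grad) %*% V %*% grad)))
  })
  margins <- NULL
  if (payment_var %in% names(beta)) {
    mg <- sapply(payment_grid, function(v) {
      x <- xbar; x[payment_var] <- v
      .gh_average(sum(x * beta), sigma_u, n_nodes)$p
    })
    margins <- tibble::tibble(payment = payment_grid, margin = mg)
  }
  list(effects = eff, margins = margins)
}

#' Weighted-bootstrap distribution of a marginal effect
#'
#' Resamples households with replacement with probability proportional to
#' the sampling weight (all migrants of a drawn household enter the
#' replicate), refits the model (Laplace approximation for speed), and
#' collects the marginal effect of `effect_var`. Errors if more than 20\%
#' of replicates fail to converge.
#'
#' @param data individual-level data with `household_id`.
#' @param formula,weights_col as in [fit_remit_logit()].
#' @param family `"logistic"` or `"linear"`.
#' @param effect_var covariate whose marginal effect is tracked.
#' @param n_reps bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @return list with `draws`, `estimate` (mean), `ci` (2.5/97.5
#'   percentiles), `n_failed`.
#' @export
bootstrap_margin_distribution <- function(data, formula,
                                          family = c("logistic", "linear"),
                                          effect_var = "payment_k",
                                          weights_col = "sampling_weight",
                                          n_reps = 200L, seed = 1L) {
  family <- match.arg(family)
  if (n_reps < 100L) abort_bad_input("n_reps must be >= 100")
  hh <- data |>
    dplyr::distinct(.data$household_id, .keep_all = TRUE) |>
    dplyr::select("household_id", dplyr::all_of(weights_col))
  set.seed(derive_seed(seed, 11L))
  draws <- rep(NA_real_, n_reps)
  for (b in seq_len(n_reps)) {
    pick <- sample(hh$household_id, nrow(hh), TRUE, prob = hh[[weights_col]])
    d <- purrr::map_dfr(seq_along(pick), function(i) {
      rows <- data[data$household_id == pick[i], ]
      rows$household_id <- paste0(rows$household_id, "_", i)
      rows
    })
    fitb <- try(suppressWarnings(suppressMessages(
      if (family == "logistic")
        fit_remit_logit(d, formula, weights_col, nAGQ = 1L)
      else fit_remit_linear(d, formula, weights_col))), silent = TRUE)
    if (inherits(fitb, "try-error") || !fitb$converged) next
    me <- try(marginal_effects(fitb, payment_var = effect_var), silent = TRUE)
    if (inherits(me, "try-error")) next
    draws[b] <- me$effects$estimate[me$effects$term == effect_var]
  }
  failed <- sum(is.na(draws))
  if (failed > 0.2 * n_reps)
    stop(sprintf("%d of %d bootstrap replicates failed to converge",
                 failed, n_reps), call. = FALSE)
  ok <- draws[!is.na(draws)]
  list(draws = ok, estimate = mean(ok),
       ci = unname(quantile(ok, c(0.025, 0.975))), n_failed = failed)
}

#' Compare fitted models by AIC/BIC
#'
#' A difference greater than 10 in AIC or BIC flags the lower-valued model
#' as favoured.
#'
#' @param fits named list of `remit_fit` objects on the same response/data.
#' @param delta threshold for favouring a model (default 10).
#' @return tibble: model, df, logLik, AIC, BIC, deltas, favoured flags.
#' @export
model_compare <- function(fits, delta = 10) {
  ns <- vapply(fits, function(f) f$n, 0)
  if (length(unique(ns)) != 1L)
    abort_bad_input("fits must share the same number of observations")
  out <- tibble::tibble(
    model = names(fits) %||% paste0("model", seq_along(fits)),
    df = vapply(fits, function(f) f$df, 0),
    logLik = vapply(fits, function(f) f$logLik, 0),
    AIC = vapply(fits, function(f) f$AIC, 0),
    BIC = vapply(fits, function(f) f$BIC, 0)) |>
    dplyr::mutate(delta_AIC = .data$AIC - min(.data$AIC),
                  delta_BIC = .data$BIC - min(.data$BIC))
  out$favoured_AIC <- out$delta_AIC == 0 &
    sum(out$delta_AIC > delta) == (nrow(out) - 1L) & nrow(out) > 1L
  out$favoured_BIC <- out$delta_BIC == 0 &
    sum(out$delta_BIC > delta) == (nrow(out) - 1L) & nrow(out) > 1L
  out
}

#' @export
tidy.remit_fit <- function(x, ...) x$coefficients

#' @export
glance.remit_fit <- function(x, ...) {
  tibble::tibble(sigma_u2 = x$sigma_u2, icc = x$icc, logLik = x$logLik,
                 AIC = x$AIC, BIC = x$BIC, nobs = x$n,
                 converged = x$converged)
}
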