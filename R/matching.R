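# Propensity-score matching: logistic propensity model, one-to-one
# nearest-score matching of each no-remittance control to a
# remittance-receiving treated household (treated reusable, weighted by the
# inverse of their match multiplicity), balance diagnostics and caliper
# sensitivity.

#' Estimate propensity scores for receiving remittance
#'
#' Logistic regression of the treatment indicator on the covariate block;
#' constant covariates are dropped with a warning. Accuracy is the fraction
#' of households whose thresholded score (>= 0.5) matches the observed
#' treatment.
#'
#' @param households household table.
#' @param covariates character vector of covariate columns.
#' @param treatment name of the 0/1 treatment column.
#' @return list: `scores` tibble (household_id, treatment, score),
#'   `accuracy`, `model`, `dropped`.
#' @export
estimate_propensity <- function(households, covariates,
                                treatment = "remittance_received") {
  miss <- setdiff(c(covariates, treatment, "household_id"), names(households))
  if (length(miss))
    abort_bad_input(paste("missing columns:", paste(miss, collapse = ", ")))
  keep <- covariates[vapply(covariates, function(v) {
    x <- households[[v]]
    if (is.character(x) || is.factor(x)) length(unique(x)) > 1
    else sd(as.numeric(x)) > 0
  }, TRUE)]
  dropped <- setdiff(covariates, keep)
  if (length(dropped))
    warning("dropping constant covariates: ", paste(dropped, collapse = ", "))
  f <- as.formula(paste(treatment, "~", paste(keep, collapse = " + ")))
  m <- glm(f, data = households, family = binomial())
  if (!m$converged || any(abs(coef(m)) > 50, na.rm = TRUE))
    stop("separation in the propensity model; prune the covariate set",
         call. = FALSE)
  sc <- stats::fitted(m)
  tibble_scores <- tibble::tibble(
    household_id = households$household_id,
    treatment = households[[treatment]],
    score = unname(sc))
  acc <- mean((sc >= 0.5) == (households[[treatment]] == 1))
  list(scores = tibble_scores, accuracy = acc, model = m, dropped = dropped)
}

#' One-to-one nearest-score matching with replacement on treated
#'
#' Each control (treatment 0) is matched to the treated household with the
#' nearest propensity score within the caliper; treated households are
#' reusable and receive weight 1 / (times matched). Ties in score distance
#' are broken by the smallest treated household id, so the result does not
#' depend on row order.
#'
#' @param scores tibble from [estimate_propensity()] (household_id,
#'   treatment, score).
#' @param caliper maximum score gap for a valid match (`Inf` for none).
#' @return object of class `match_result`: `pairs` (control_id, treated_id,
#'   gap, weight), `n_matched`, `unmatched`, `caliper`.
#' @export
match_controls <- function(scores, caliper = 0.05) {
  if (caliper <= 0) abort_bad_input("caliper must be positive")
  tr <- scores[scores$treatment == 1, ]
  co <- scores[scores$treatment == 0, ]
  if (nrow(tr) == 0 || nrow(co) == 0)
    abort_bad_input("both treated and control groups must be non-empty")
  tr <- tr[order(tr$household_id), ]
  co <- co[order(co$household_id), ]
  pairs <- purrr::map_dfr(seq_len(nrow(co)), function(i) {
    gaps <- abs(tr$score - co$score[i])
    j <- which(gaps == min(gaps))[1L]  # tr sorted by id -> smallest id wins
    if (gaps[j] > caliper) return(NULL)
    tibble::tibble(control_id = co$household_id[i],
                   treated_id = tr$household_id[j],
                   control_score = co$score[i],
                   treated_score = tr$score[j],
                   gap = gaps[j])
  })
  if (nrow(pairs)) {
    mult <- table(pairs$treated_id)
    pairs$weight <- 1 / as.numeric(mult[pairs$treated_id])
  } else pairs <- tibble::tibble(control_id = character(),
                                 treated_id = character(),
                                 control_score = double(),
                                 treated_score = double(),
                                 gap = double(), weight = double())
  structure(list(pairs = pairs, n_matched = nrow(pairs),
                 unmatched = setdiff(co$household_id, pairs$control_id),
                 caliper = caliper),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs (caliper %g), %d controls unmatched\n",
              x$n_matched, x$caliper, length(x$unmatched)))
  invisible(x)
}

# standardised mean difference (continuous) or proportion difference (binary)
smd <- function(x1, x0, w1 = NULL, w0 = NULL) {
  w1 <- w1 %||% rep(1, length(x1)); w0 <- w0 %||% rep(1, length(x0))
  m1 <- weighted.mean(x1, w1); m0 <- weighted.mean(x0, w0)
  if (all(x1 %in% 0:1) && all(x0 %in% 0:1)) return(abs(m1 - m0))
  sp <- sqrt((weighted_var(x1, w1) + weighted_var(x0, w0)) / 2)
  if (sp == 0) 0 else abs(m1 - m0) / sp
}

#' Balance diagnostics for a matched sample
#'
#' Paired t-test of the signed score gaps (treated minus control) against
#' zero, plus per-covariate absolute standardised mean differences
#' (proportion differences for binary covariates) before and after
#' matching; after-matching treated statistics use the multiplicity
#' weights.
#'
#' @param match a [match_controls()] result.
#' @param households household table with the covariates.
#' @param covariates covariate columns to diagnose.
#' @return list: `score_test` (statistic, p.value), `balance` tibble
#'   (covariate, smd_before, smd_after).
#' @export
balance_check <- function(match, households, covariates) {
  p <- match$pairs
  if (nrow(p) == 0) abort_bad_input("no matched pairs")
  gaps <- p$treated_score - p$control_score
  st <- if (sd(gaps) == 0) list(statistic = 0, p.value = 1)
  else {
    tt <- t.test(gaps)
    list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  rows_t <- households[match(p$treated_id, households$household_id), ]
  rows_c <- households[match(p$control_id, households$household_id), ]
  bal <- purrr::map_dfr(covariates, function(v) {
    before <- smd(households[[v]][households$remittance_received == 1],
                  households[[v]][households$remittance_received == 0])
    after <- smd(rows_t[[v]], rows_c[[v]], w1 = p$weight)
    tibble::tibble(covariate = v, smd_before = before, smd_after = after)
  })
  list(score_test = st, balance = bal)
}

#' Caliper sensitivity sweep
#'
#' Re-runs the matching at each caliper and records the matched sample size
#' and, when buffer change metrics are supplied, the mean treated-control
#' difference in forest change at the requested radius.
#'
#' @param scores propensity score tibble.
#' @param calipers increasing positive caliper grid.
#' @param buffer_changes optional [radii_sweep()] output.
#' @param radius radius at which to evaluate the effect.
#' @return tibble: caliper, n_matched, ate_delta_forest (NA without metrics).
#' @export
caliper_sweep <- function(scores, calipers = seq(0.01, 0.10, by = 0.01),
                          buffer_changes = NULL, radius = 100) {
  if (any(calipers <= 0)) abort_bad_input("calipers must be positive")
  calipers <- sort(calipers)
  purrr::map_dfr(calipers, function(cl) {
    m <- match_controls(scores, caliper = cl)
    ate <- NA_real_
    if (!is.null(buffer_changes) && m$n_matched > 0) {
      bc <- buffer_changes[buffer_changes$radius == radius, ]
      dt <- bc$delta_forest[match(m$pairs$treated_id, bc$household_id)]
      dc <- bc$delta_forest[match(m$pairs$control_id, bc$household_id)]
      ate <- mean(dt - dc, na.rm = TRUE)
    }
    tibble::tibble(caliper = cl, n_matched = m$n_matched,
                   ate_delta_forest = ate)
  })
}
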