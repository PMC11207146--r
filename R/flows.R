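# Migration / remittance flow network between origin sites and destination
# cities: per-destination aggregation, log-scale distance bins and one-way
# ANOVA comparisons of flow attributes across bins.

#' Build the migration/remittance flow table
#'
#' Aggregates migrants by destination city (and by province), recording
#' migrant counts, remittance totals, remittance per migrant (reported with
#' both the sender and the all-migrant denominator), the origin-destination
#' distance and its log-scale bin.
#'
#' @param migrants migrant table with `destination_city`, `distance_km`,
#'   `sent_remittance`, `remittance_amount`.
#' @param destinations destination city table (`city_id`, `province_id`,
#'   `distance_km`).
#' @param bin_edges log10-km bin edges, half-open on the right (default
#'   short 1.7-2.2, medium 2.2-2.7, long 2.7-3.2).
#' @return list: `flows` (per-city tibble), `provinces` (per-province),
#'   `city_remit_share` / `province_remit_share` (percent of destinations
#'   with at least one remittance sender).
#' @export
build_flow_table <- function(migrants, destinations,
                             bin_edges = c(1.7, 2.2, 2.7, 3.2)) {
  if (any(is.na(migrants$destination_city)))
    abort_bad_input("every migrant needs a destination")
  flows <- migrants |>
    dplyr::group_by(city_id = .data$destination_city) |>
    dplyr::summarise(
      n_migrants = dplyr::n(),
      n_senders = sum(.data$sent_remittance),
      remittance_total = sum(.data$remittance_amount),
      .groups = "drop") |>
    dplyr::left_join(destinations, by = "city_id") |>
    dplyr::mutate(
      remittance_per_sender = ifelse(.data$n_senders > 0,
                                     .data$remittance_total / .data$n_senders,
                                     NA_real_),
      remittance_per_migrant = .data$remittance_total / .data$n_migrants,
      log10_distance = log10(.data$distance_km),
      bin = assign_distance_bin(.data$log10_distance, bin_edges),
      flagged = is.na(.data$distance_km) | is.na(.data$bin))
  if (any(flows$flagged))
    warning(sum(flows$flagged),
            " destinations with missing/out-of-range distance flagged")
  provinces <- flows |>
    dplyr::group_by(.data$province_id) |>
    dplyr::summarise(n_migrants = sum(.data$n_migrants),
                     n_senders = sum(.data$n_senders),
                     remittance_total = sum(.data$remittance_total),
                     .groups = "drop")
  list(flows = flows, provinces = provinces,
       city_remit_share = 100 * mean(flows$n_senders > 0),
       province_remit_share = 100 * mean(provinces$n_senders > 0))
}

#' Assign log-distance bins
#'
#' Half-open bins \[lower, upper) on log10 distance; the last bin includes
#' its upper edge. Out-of-range distances get NA (flagged upstream, never
#' silently binned).
#'
#' @param log10_distance numeric vector.
#' @param bin_edges increasing edges; default gives short/medium/long.
#' @return factor with levels `short`, `medium`, `long` (or `bin1`... for
#'   other edge counts).
#' @export
assign_distance_bin <- function(log10_distance,
                                bin_edges = c(1.7, 2.2, 2.7, 3.2)) {
  nb <- length(bin_edges) - 1L
  labels <- if (nb == 3L) c("short", "medium", "long")
  else paste0("bin", seq_len(nb))
  idx <- findInterval(log10_distance, bin_edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > nb] <- NA_integer_
  factor(labels[idx], levels = labels)
}

#' One-way ANOVA of flow attributes across distance bins
#'
#' Tests whether migrant counts, remittance totals and remittance per
#' migrant differ among the short/medium/long distance bins. Rows with a
#' missing bin are excluded; empty bins are dropped with a warning.
#'
#' @param flow_table result of [build_flow_table()] (or its `flows` tibble).
#' @param attributes columns to test.
#' @return tibble: attribute, F statistic, p value, df between/within.
#' @export
distance_bin_tests <- function(flow_table,
                               attributes = c("n_migrants",
                                              "remittance_total",
                                              "remittance_per_sender")) {
  fl <- if (is.data.frame(flow_table)) flow_table else flow_table$flows
  fl <- fl[!is.na(fl$bin), ]
  present <- table(droplevels(fl$bin))
  if (length(present) < 2L) abort_bad_input("need at least 2 non-empty bins")
  if (length(present) < nlevels(fl$bin))
    warning("dropping empty distance bins: ",
            paste(setdiff(levels(fl$bin), names(present)), collapse = ", "))
  fl$bin <- droplevels(fl$bin)
  purrr::map_dfr(attributes, function(a) {
    d <- fl[!is.na(fl[[a]]), ]
    av <- summary(aov(d[[a]] ~ d$bin))[[1]]
    tibble::tibble(attribute = a,
                   statistic = av[1, "F value"],
                   p_value = av[1, "Pr(>F)"],
                   df_between = av[1, "Df"], df_within = av[2, "Df"])
  })
}
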