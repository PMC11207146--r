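# Reading, validation and writing of the dataset bundle: household /
# migrant / destination tables (CSV), resident-group polygons (GeoJSON),
# raster pairs (plain-text bands) and configuration (YAML). Validation is
# total: downstream stages never see an orphan id or a unit-ambiguous area.

MU_TO_M2 <- 666.7  # 1 mu = 666.7 m2

required_household_cols <- c("household_id", "site_id", "group_id", "x", "y",
                             "sampling_weight", "ccfp_participant",
                             "enrolled_area", "cumulative_payment",
                             "remittance_received", "remittance_total",
                             "n_migrants")
required_migrant_cols <- c("migrant_id", "household_id", "gender", "age",
                           "education", "outside_province",
                           "migration_years", "sent_remittance",
                           "remittance_amount")

#' Validate a dataset bundle
#'
#' Enforces schema, referential integrity (every migrant's household and
#' every household's group exist), positivity of sampling weights,
#' consistency of remittance flags and amounts, the minimum migration
#' period of half a year, and normalises areas reported in mu
#' (`enrolled_area_mu` column) to m2.
#'
#' @param households,migrants,groups data frames (groups optional).
#' @return list of validated tibbles (invisibly usable downstream).
#' @export
validate_tables <- function(households, migrants, groups = NULL) {
  if ("enrolled_area_mu" %in% names(households) &&
      !"enrolled_area" %in% names(households))
    households$enrolled_area <- households$enrolled_area_mu * MU_TO_M2
  miss_h <- setdiff(required_household_cols, names(households))
  if (length(miss_h))
    abort_bad_input(paste("households missing columns:",
                          paste(miss_h, collapse = ", ")))
  miss_m <- setdiff(required_migrant_cols, names(migrants))
  if (length(miss_m))
    abort_bad_input(paste("migrants missing columns:",
                          paste(miss_m, collapse = ", ")))
  if (anyDuplicated(households$household_id))
    abort_bad_input("duplicate household ids")
  if (anyDuplicated(migrants$migrant_id))
    abort_bad_input("duplicate migrant ids")
  orphan <- setdiff(migrants$household_id, households$household_id)
  if (length(orphan))
    abort_bad_input(paste("migrants reference absent households:",
                          paste(utils::head(orphan, 5), collapse = ", ")))
  if (!is.null(groups)) {
    og <- setdiff(households$group_id, groups$group_id)
    if (length(og))
      abort_bad_input(paste("households reference absent groups:",
                            paste(utils::head(og, 5), collapse = ", ")))
  }
  bad_w <- which(!(households$sampling_weight > 0))
  if (length(bad_w))
    abort_bad_input(paste("non-positive sampling weights at rows:",
                          paste(utils::head(bad_w, 5), collapse = ", ")))
  bad_r <- which(xor(households$remittance_received == 1,
                     households$remittance_total > 0))
  if (length(bad_r))
    abort_bad_input(paste("remittance flag/total mismatch at rows:",
                          paste(utils::head(bad_r, 5), collapse = ", ")))
  bad_m <- which(xor(migrants$sent_remittance == 1,
                     migrants$remittance_amount > 0))
  if (length(bad_m))
    abort_bad_input(paste("sender flag/amount mismatch at rows:",
                          paste(utils::head(bad_m, 5), collapse = ", ")))
  if (any(migrants$migration_years < 0.5))
    abort_bad_input("migration period below the half-year minimum")
  np <- households$ccfp_participant == 0
  if (any(households$cumulative_payment[np] != 0))
    abort_bad_input("non-participants must have zero cumulative payment")
  list(households = tibble::as_tibble(households),
       migrants = tibble::as_tibble(migrants),
       groups = if (!is.null(groups)) tibble::as_tibble(groups))
}

# ---- GeoJSON polygons --------------------------------------------------

write_groups_geojson <- function(groups, path) {
  polys <- attr(groups, "polygons")
  feats <- purrr::map(seq_len(nrow(groups)), function(i) {
    ring <- polys[[groups$group_id[i]]]
    ring <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(
           group_id = groups$group_id[i], site_id = groups$site_id[i],
           group_remittance_total = groups$group_remittance_total[i],
           n_households = groups$n_households[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(k) as.numeric(ring[k, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_groups_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  tab <- purrr::map_dfr(feats, function(f) tibble::as_tibble(f$properties))
  polys <- purrr::map(feats, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    colnames(ring) <- c("x", "y")
    ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
  })
  names(polys) <- tab$group_id
  attr(tab, "polygons") <- polys
  tab
}

#' Write / load a complete dataset bundle
#'
#' `write_bundle()` serialises a scenario (or equivalent list) to a
#' directory: `households.csv`, `migrants.csv`, `destinations.csv`,
#' `groups.geojson`, `raster_<site>.csv`, `truth.json`, `config.yml`.
#' `load_bundle()` reads it back and re-validates; the round trip is exact
#' up to CSV numeric formatting.
#'
#' @param bundle a `remiforest_scenario` or compatible list.
#' @param dir target/source directory.
#' @return `write_bundle` the directory (invisibly); `load_bundle` the
#'   validated bundle list.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$households, file.path(dir, "households.csv"),
            row.names = FALSE)
  write.csv(bundle$migrants, file.path(dir, "migrants.csv"),
            row.names = FALSE)
  if (!is.null(bundle$destinations))
    write.csv(bundle$destinations, file.path(dir, "destinations.csv"),
              row.names = FALSE)
  if (!is.null(bundle$groups))
    write_groups_geojson(bundle$groups, file.path(dir, "groups.geojson"))
  for (s in names(bundle$rasters))
    write_raster_pair(bundle$rasters[[s]],
                      file.path(dir, sprintf("raster_%s.csv", s)))
  if (!is.null(bundle$truth))
    jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$config))
    yaml::write_yaml(unclass(bundle$config), file.path(dir, "config.yml"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
load_bundle <- function(dir) {
  hh <- read.csv(file.path(dir, "households.csv"))
  mg <- read.csv(file.path(dir, "migrants.csv"))
  gr <- if (file.exists(file.path(dir, "groups.geojson")))
    read_groups_geojson(file.path(dir, "groups.geojson"))
  v <- validate_tables(hh, mg, gr)
  dest_path <- file.path(dir, "destinations.csv")
  dest <- if (file.exists(dest_path)) tibble::as_tibble(read.csv(dest_path))
  rfiles <- list.files(dir, pattern = "^raster_.*\\.csv$", full.names = TRUE)
  rasters <- purrr::map(rfiles, read_raster_pair)
  names(rasters) <- sub("^raster_(.*)\\.csv$", "\\1", basename(rfiles))
  truth <- if (file.exists(file.path(dir, "truth.json")))
    jsonlite::fromJSON(file.path(dir, "truth.json"))
  config <- if (file.exists(file.path(dir, "config.yml")))
    yaml::read_yaml(file.path(dir, "config.yml"))
  list(households = v$households, migrants = v$migrants,
       destinations = dest, groups = v$groups,
       rasters = if (length(rasters)) rasters, truth = truth,
       config = config)
}
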