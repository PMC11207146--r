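# Buffer zonal change metrics: forest-cover and EVI change within circular
# buffers around house points (exact fractional cell weighting) and within
# ring buffers around resident-group polygons (dilation by Euclidean
# distance). The change statistics are differences of weighted proportions /
# weighted forest-EVI means between the survey year (t1) and program start
# (t0).

#' Fractional cell-overlap weights for a circular buffer
#'
#' Each raster cell intersecting the disc (or annulus, if `inner > 0`) of
#' the given radii around `(cx, cy)` receives weight equal to the fraction
#' of its area inside the buffer, computed exactly. Cells with weight below
#' `threshold` are excluded.
#'
#' @param rp a [raster_pair()] (only the grid geometry is used).
#' @param cx,cy buffer centre in site-local metres.
#' @param outer outer radius (m). @param inner inner radius (m), 0 for a disc.
#' @param threshold minimum included fraction (default 0.005, i.e. at least
#'   0.5\% of the cell inside the buffer).
#' @return tibble with `row`, `col`, `weight`; zero rows (with a warning)
#'   when the buffer misses the raster entirely.
#' @export
overlap_weights <- function(rp, cx, cy, outer, inner = 0, threshold = 0.005) {
  if (!(outer > inner && inner >= 0)) abort_bad_input("need outer > inner >= 0")
  if (threshold <= 0 || threshold >= 1) abort_bad_input("threshold must be in (0,1)")
  cs <- rp$cell_size
  ext <- raster_extent(rp)
  d <- dim(rp$forest_t0)
  c0 <- max(1L, floor((cx - outer - ext["xmin"]) / cs) + 1L)
  c1 <- min(d[2], ceiling((cx + outer - ext["xmin"]) / cs))
  r0 <- max(1L, floor((cy - outer - ext["ymin"]) / cs) + 1L)
  r1 <- min(d[1], ceiling((cy + outer - ext["ymin"]) / cs))
  if (c0 > c1 || r0 > r1) {
    warning("buffer lies entirely outside the raster extent")
    return(tibble::tibble(row = integer(), col = integer(), weight = double()))
  }
  cols <- rep(c0:c1, each = r1 - r0 + 1L)
  rows <- rep(r0:r1, times = c1 - c0 + 1L)
  x0 <- ext["xmin"] + (cols - 1L) * cs
  y0 <- ext["ymin"] + (rows - 1L) * cs
  a <- circle_rect_area(x0, x0 + cs, y0, y0 + cs, cx, cy, outer)
  if (inner > 0) a <- a - circle_rect_area(x0, x0 + cs, y0, y0 + cs, cx, cy, inner)
  w <- a / cs^2
  keep <- w >= threshold
  # flag partial raster coverage (buffer extends past an edge)
  if (cx - outer < ext["xmin"] || cx + outer > ext["xmax"] ||
      cy - outer < ext["ymin"] || cy + outer > ext["ymax"])
    warning("buffer extends beyond the raster edge; metrics use included cells only")
  tibble::tibble(row = rows[keep], col = cols[keep], weight = w[keep])
}

# shared core: change metrics from a weight table
.change_from_weights <- function(rp, w, unit_id = NA, label = NA) {
  if (nrow(w) == 0 || sum(w$weight) <= 0) {
    return(tibble::tibble(unit_id = unit_id, label = label,
                          delta_forest = NA_real_, delta_evi = NA_real_,
                          n_cells = 0L, weight_sum = 0, degenerate = TRUE))
  }
  idx <- cbind(w$row, w$col)
  wt <- w$weight
  k0 <- rp$forest_t0[idx]; k1 <- rp$forest_t1[idx]
  e0 <- rp$evi_t0[idx]; e1 <- rp$evi_t1[idx]
  dforest <- sum(wt * k1) / sum(wt) - sum(wt * k0) / sum(wt)
  # forest-EVI means drop cells with missing EVI under forest from both
  # the numerator and denominator of that time point's term
  m1 <- k1 == 1 & !is.na(e1)
  m0 <- k0 == 1 & !is.na(e0)
  den1 <- sum(wt[m1]); den0 <- sum(wt[m0])
  devi <- if (den1 > 0 && den0 > 0)
    sum(wt[m1] * e1[m1]) / den1 - sum(wt[m0] * e0[m0]) / den0
  else NA_real_
  tibble::tibble(unit_id = unit_id, label = label,
                 delta_forest = dforest, delta_evi = devi,
                 n_cells = nrow(w), weight_sum = sum(wt), degenerate = FALSE)
}

#' Forest-cover and EVI change within one circular buffer
#'
#' Delta forest is the difference of area-weighted forest proportions
#' (t1 minus t0); delta EVI the difference of area-weighted mean EVI over
#' forested cells, NA when either time point has no forested weight.
#'
#' @inheritParams overlap_weights
#' @param unit_id identifier copied to the output row.
#' @return one-row tibble: `unit_id`, `label` (radius), `delta_forest`,
#'   `delta_evi`, `n_cells`, `weight_sum`, `degenerate`.
#' @export
buffer_change <- function(rp, cx, cy, outer, inner = 0, threshold = 0.005,
                          unit_id = NA) {
  w <- overlap_weights(rp, cx, cy, outer, inner = inner, threshold = threshold)
  .change_from_weights(rp, w, unit_id = unit_id, label = as.character(outer))
}

#' Buffer change metrics for every household over a series of radii
#'
#' @param rp a [raster_pair()] for one site.
#' @param households data frame with `household_id`, `x`, `y` (same site).
#' @param radii increasing positive radii in metres; default 25 m to 200 m
#'   in 25 m steps.
#' @param threshold inclusion threshold as in [overlap_weights()].
#' @return tibble with one row per household x radius, columns as
#'   [buffer_change()] plus `household_id` and numeric `radius`.
#' @export
radii_sweep <- function(rp, households, radii = seq(25, 200, by = 25),
                        threshold = 0.005) {
  if (any(radii <= 0)) abort_bad_input("radii must be positive")
  if (anyDuplicated(radii)) abort_bad_input("duplicate radii")
  radii <- sort(radii)
  out <- purrr::map_dfr(seq_len(nrow(households)), function(i) {
    hh <- households[i, ]
    purrr::map_dfr(radii, function(r)
      dplyr::mutate(
        buffer_change(rp, hh$x, hh$y, r, threshold = threshold,
                      unit_id = hh$household_id),
        radius = r))
  })
  dplyr::rename(out, household_id = "unit_id")
}

# fraction of each cell within distance (inner, outer] of a convex polygon,
# by midpoint subsampling of the cell (subdiv^2 points); inner = -Inf keeps
# the polygon interior itself (distance 0)
ring_weights <- function(rp, poly, inner, outer, subdiv = 16L, threshold = 0.005) {
  cs <- rp$cell_size
  ext <- raster_extent(rp)
  d <- dim(rp$forest_t0)
  pad <- max(outer, 0)
  c0 <- max(1L, floor((min(poly[, 1]) - pad - ext["xmin"]) / cs) + 1L)
  c1 <- min(d[2], ceiling((max(poly[, 1]) + pad - ext["xmin"]) / cs))
  r0 <- max(1L, floor((min(poly[, 2]) - pad - ext["ymin"]) / cs) + 1L)
  r1 <- min(d[1], ceiling((max(poly[, 2]) + pad - ext["ymin"]) / cs))
  if (c0 > c1 || r0 > r1)
    return(tibble::tibble(row = integer(), col = integer(), weight = double()))
  cols <- rep(c0:c1, each = r1 - r0 + 1L)
  rows <- rep(r0:r1, times = c1 - c0 + 1L)
  off <- (seq_len(subdiv) - 0.5) / subdiv * cs
  frac <- numeric(length(cols))
  base_x <- ext["xmin"] + (cols - 1L) * cs
  base_y <- ext["ymin"] + (rows - 1L) * cs
  grp <- rep(seq_along(cols), each = subdiv)
  for (iy in seq_len(subdiv)) {
    px <- rep(base_x, each = subdiv) + rep(off, times = length(base_x))
    py <- rep(base_y + off[iy], each = subdiv)
    dd <- dist_to_polygon(px, py, poly)
    inside <- if (is.finite(inner)) dd > inner & dd <= outer else dd <= outer
    frac <- frac + rowsum(as.numeric(inside), group = grp)[, 1]
  }
  w <- frac / subdiv^2
  keep <- w >= threshold
  tibble::tibble(row = rows[keep], col = cols[keep], weight = w[keep])
}

#' Ring-buffer change metrics around a resident-group polygon
#'
#' Computes forest-cover and EVI change within the group polygon itself and
#' within rings obtained by Euclidean dilation of the boundary, e.g. 0-100 m
#' and 100-200 m outward. Ring membership of a cell is fractional, from
#' midpoint subsampling of the point-to-polygon distance.
#'
#' @param rp a [raster_pair()].
#' @param poly convex counter-clockwise vertex matrix (columns x, y).
#' @param rings increasing outer distances in metres (default `c(100, 200)`,
#'   giving rings 0-100 and 100-200).
#' @param unit_id identifier copied to the output.
#' @param subdiv per-axis subsampling density per cell.
#' @param threshold inclusion threshold.
#' @return tibble with one row per zone (`within`, `0-100`, ...).
#' @export
ring_buffer_change <- function(rp, poly, rings = c(100, 200), unit_id = NA,
                               subdiv = 16L, threshold = 0.005) {
  if (!is.matrix(poly) || nrow(poly) < 3)
    abort_bad_input("invalid polygon: need a vertex matrix with >= 3 rows")
  if (polygon_area(poly) <= 0) abort_bad_input("invalid polygon: zero area")
  if (any(diff(c(0, rings)) <= 0)) abort_bad_input("rings must be increasing and positive")
  zones <- c(list(c(-Inf, 0)), purrr::map(seq_along(rings), function(i)
    c(if (i == 1) 0 else rings[i - 1], rings[i])))
  labels <- c("within", purrr::map_chr(seq_along(rings), function(i)
    sprintf("%g-%g", if (i == 1) 0 else rings[i - 1], rings[i])))
  purrr::map_dfr(seq_along(zones), function(i) {
    w <- ring_weights(rp, poly, zones[[i]][1], zones[[i]][2],
                      subdiv = subdiv, threshold = threshold)
    .change_from_weights(rp, w, unit_id = unit_id, label = labels[i])
  })
}
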