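# Planar geometry kernel: exact circle/cell overlap areas, convex polygons,
# point-to-polygon distances. All coordinates are site-local metres.

#' Exact area of intersection between a disc and axis-aligned rectangles
#'
#' Computes, in closed form, the area of the intersection of the disc of
#' radius `r` centred at `(cx, cy)` with each rectangle
#' `[x0, x1] x [y0, y1]`. Used as the fractional-overlap weighting kernel
#' for circular buffers; exact up to floating point, no polygonal
#' approximation.
#'
#' @param x0,x1,y0,y1 numeric vectors of rectangle corner coordinates.
#' @param cx,cy disc centre.
#' @param r disc radius (> 0).
#' @return numeric vector of intersection areas.
#' @export
#' @examples
#' circle_rect_area(0, 1, 0, 1, 0.5, 0.5, 10) # cell fully inside: 1
circle_rect_area <- function(x0, x1, y0, y1, cx, cy, r) {
  if (r <= 0) abort_bad_input("radius must be > 0")
  # shift to disc-centred coordinates; inclusion-exclusion over corner areas
  a11 <- .corner_area(x1 - cx, y1 - cy, r)
  a01 <- .corner_area(x0 - cx, y1 - cy, r)
  a10 <- .corner_area(x1 - cx, y0 - cy, r)
  a00 <- .corner_area(x0 - cx, y0 - cy, r)
  pmax(a11 - a01 - a10 + a00, 0)
}

# area of disc (origin, r) intersected with quadrant {X <= x, Y <= y}
.corner_area <- function(x, y, r) {
  # antiderivative of sqrt(r^2 - t^2)
  I <- function(t) {
    t <- pmin(pmax(t, -r), r)
    0.5 * (t * sqrt(pmax(r^2 - t^2, 0)) + r^2 * asin(t / r))
  }
  xc <- pmin(pmax(x, -r), r)
  out <- numeric(length(xc))
  y <- rep_len(y, length(xc))

  hi <- y >= r            # full vertical extent of the disc is below y
  lo <- y <= -r           # region empty
  mid_pos <- !hi & !lo & y >= 0
  mid_neg <- !hi & !lo & y < 0

  if (any(hi)) out[hi] <- 2 * I(xc[hi]) + pi * r^2 / 2
  if (any(mid_pos)) {
    yy <- y[mid_pos]; xx <- xc[mid_pos]
    ty <- sqrt(pmax(r^2 - yy^2, 0))
    # [-r, -ty]: chord 2*sqrt(); [-ty, ty]: y + sqrt(); [ty, r]: 2*sqrt()
    b1 <- pmin(xx, -ty)                       # end of first segment
    seg1 <- ifelse(b1 > -r, 2 * (I(b1) - I(-r)), 0)
    b2 <- pmin(pmax(xx, -ty), ty)
    seg2 <- ifelse(b2 > -ty, yy * (b2 + ty) + (I(b2) - I(-ty)), 0)
    b3 <- pmax(xx, ty)
    seg3 <- ifelse(b3 > ty, 2 * (I(b3) - I(ty)), 0)
    out[mid_pos] <- seg1 + seg2 + seg3
  }
  if (any(mid_neg)) {
    yy <- y[mid_neg]; xx <- xc[mid_neg]
    ty <- sqrt(pmax(r^2 - yy^2, 0))
    b2 <- pmin(pmax(xx, -ty), ty)
    out[mid_neg] <- ifelse(b2 > -ty, yy * (b2 + ty) + (I(b2) - I(-ty)), 0)
  }
  out
}

#' Signed vertex list of a regular polygon approximating a circle
#'
#' Retained as a comparison path and for plotting; the production weighting
#' kernel uses [circle_rect_area()].
#'
#' @param cx,cy centre. @param r radius. @param n vertex count.
#' @return matrix with columns x, y (counter-clockwise).
#' @export
circle_polygon <- function(cx, cy, r, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Polygon area by the shoelace formula
#' @param poly two-column matrix of vertices (closed implicitly).
#' @return non-negative area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# TRUE for points inside or on a convex counter-clockwise polygon
point_in_convex <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(TRUE, length(px))
  for (k in seq_len(n)) {
    j <- if (k == n) 1L else k + 1L
    cross <- (poly[j, 1] - poly[k, 1]) * (py - poly[k, 2]) -
      (poly[j, 2] - poly[k, 2]) * (px - poly[k, 1])
    inside <- inside & cross >= -1e-9
  }
  inside
}

#' Distance from points to a polygon (zero inside)
#'
#' Euclidean distance from each point to the polygon as a set: points inside
#' or on the boundary get 0, outside points the distance to the nearest
#' boundary segment. The polygon must be convex and counter-clockwise.
#'
#' @param px,py point coordinates. @param poly vertex matrix.
#' @return numeric vector of distances.
#' @export
dist_to_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (n < 3) abort_bad_input("polygon needs at least 3 vertices")
  d2 <- rep(Inf, length(px))
  for (k in seq_len(n)) {
    j <- if (k == n) 1L else k + 1L
    ax <- poly[k, 1]; ay <- poly[k, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 > 0) pmin(pmax(((px - ax) * vx + (py - ay) * vy) / len2, 0), 1) else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  d <- sqrt(d2)
  d[point_in_convex(px, py, poly)] <- 0
  d
}

# convex hull of the Minkowski sum of points with a disc of radius r,
# approximated by an m-gon around each point (exact hull of the m-gon union)
dilated_hull <- function(x, y, r = 40, m = 24L) {
  th <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  px <- as.vector(outer(r * cos(th), x, `+`))
  py <- as.vector(outer(r * sin(th), y, `+`))
  h <- grDevices::chull(px, py)
  cbind(x = px[rev(h)], y = py[rev(h)])  # counter-clockwise
}

# smooth a matrix with a separable box filter applied `passes` times;
# approximates Gaussian smoothing with correlation length ~ width * passes
smooth_matrix <- function(m, width = 5L, passes = 3L) {
  k <- rep(1 / width, width)
  pad <- (width - 1L) %/% 2L
  sm1 <- function(v) {
    vp <- c(rev(v[seq_len(pad)]), v, rev(v[(length(v) - pad + 1L):length(v)]))
    as.numeric(stats::filter(vp, k, sides = 2))[(pad + 1L):(pad + length(v))]
  }
  for (p in seq_len(passes)) {
    m <- apply(m, 2, sm1)
    m <- t(apply(m, 1, sm1))
  }
  m
}
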