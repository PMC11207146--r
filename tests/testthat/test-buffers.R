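test_that("hand-computed change metrics on a 2x2 grid", {
  # buffer covering the whole 2x2 grid with equal weights:
  # forest t1 has 2 of 4 cells, t0 has 1 -> delta 0.25
  k1 <- matrix(c(1, 1, 0, 0), 2, 2)
  k0 <- matrix(c(1, 0, 0, 0), 2, 2)
  # t1 forest EVIs {0.6, 0.8}, t0 forest EVI {0.5} -> delta 0.7 - 0.5 = 0.2
  e1 <- matrix(c(0.6, 0.8, NA, NA), 2, 2)
  e0 <- matrix(c(0.5, NA, NA, NA), 2, 2)
  rp <- raster_pair(k0, k1, e0, e1, cell_size = 10)
  bc <- buffer_change(rp, 10, 10, outer = 100)
  expect_equal(bc$delta_forest, 0.25)
  expect_equal(bc$delta_evi, 0.2)
  expect_equal(bc$n_cells, 4L)
})

test_that("metrics equal a direct-summation oracle to 1e-12", {
  set.seed(21)
  for (k in 1:50) {
    rp <- toy_raster(n = 20, seed = k)
    cx <- runif(1, 60, 540); cy <- runif(1, 60, 540)
    r <- runif(1, 40, 150)
    w <- suppressWarnings(overlap_weights(rp, cx, cy, r))
    if (nrow(w) == 0) next
    got <- .subset2(buffer_change(rp, cx, cy, r), "delta_forest")
    ora <- oracle_change(rp, w)
    expect_equal(got, unname(ora["delta_forest"]), tolerance = 1e-12)
    de <- .subset2(buffer_change(rp, cx, cy, r), "delta_evi")
    if (!is.na(de)) expect_equal(de, unname(ora["delta_evi"]), tolerance = 1e-12)
  }
})

test_that("overlap weights: full cells weigh 1, sub-threshold cells drop", {
  rp <- toy_raster(n = 20)
  w <- overlap_weights(rp, 300, 300, 100)
  # cells wholly inside the disc carry exactly weight 1
  expect_true(any(abs(w$weight - 1) < 1e-12))
  expect_true(all(w$weight >= 0.005))
  # a cell overlapping less than 0.5% of its area is excluded: build one by
  # shaving the circle so it just clips a corner of the next cell
  w2 <- suppressWarnings(overlap_weights(rp, 15, 15, outer = 15.5))
  cell2 <- w2[w2$row == 1 & w2$col == 2, ]
  frac <- circle_rect_area(30, 60, 0, 30, 15, 15, 15.5) / 900
  expect_lt(frac, 0.005)
  expect_equal(nrow(cell2), 0L)
})

test_that("weights match a 100x100 supersampling oracle to 1e-3", {
  rp <- toy_raster(n = 20)
  set.seed(9)
  for (k in 1:8) {
    cx <- runif(1, 100, 500); cy <- runif(1, 100, 500); r <- runif(1, 50, 120)
    w <- overlap_weights(rp, cx, cy, r, threshold = 1e-6)
    for (i in sample(nrow(w), min(12, nrow(w)))) {
      x0 <- (w$col[i] - 1) * 30; y0 <- (w$row[i] - 1) * 30
      expect_lt(abs(w$weight[i] -
                      supersample_weight(x0, y0, 30, cx, cy, r)), 1e-3)
    }
  }
})

test_that("radii sweep yields 8 rows per household at default radii", {
  rp <- toy_raster(n = 20)
  hh <- tibble::tibble(household_id = c("a", "b"),
                       x = c(300, 310), y = c(300, 290))
  sw <- radii_sweep(rp, hh)
  expect_equal(nrow(sw), 16L)
  expect_equal(sort(unique(sw$radius)), seq(25, 200, by = 25))
  expect_error(radii_sweep(rp, hh, radii = c(50, 50)), "duplicate")
  expect_error(radii_sweep(rp, hh, radii = c(-10, 50)), "positive")
})

test_that("uniform raster gives equal proportions at all radii and zero ring change", {
  n <- 30
  k <- matrix(1L, n, n); e <- matrix(0.5, n, n)
  rp <- raster_pair(k, k, e, e, cell_size = 30)
  hh <- tibble::tibble(household_id = "a", x = 450, y = 450)
  sw <- radii_sweep(rp, hh)
  expect_true(all(abs(sw$delta_forest) < 1e-12))
  expect_true(all(abs(sw$delta_evi) < 1e-12))
  sq <- cbind(x = c(350, 550, 550, 350), y = c(350, 350, 550, 550))
  rc <- ring_buffer_change(rp, sq, rings = c(100))
  expect_true(all(abs(rc$delta_forest) < 1e-12))
})

test_that("buffers at the raster corner warn and use included cells", {
  rp <- toy_raster(n = 20)
  expect_warning(bc <- buffer_change(rp, 10, 10, 100), "beyond the raster edge")
  expect_false(bc$degenerate)
  expect_warning(overlap_weights(rp, -500, -500, 50), "outside")
})

test_that("delta forest is antisymmetric under swapping the two dates", {
  rp <- toy_raster(n = 20, seed = 3)
  swapped <- raster_pair(rp$forest_t1, rp$forest_t0, rp$evi_t1, rp$evi_t0,
                         cell_size = rp$cell_size)
  a <- buffer_change(rp, 300, 300, 120)
  b <- buffer_change(swapped, 300, 300, 120)
  expect_equal(a$delta_forest, -b$delta_forest, tolerance = 1e-12)
})

test_that("metrics are invariant when raster and centre shift together", {
  rp <- toy_raster(n = 20, seed = 6)
  shift <- c(1234.5, -987.25)
  rp2 <- raster_pair(rp$forest_t0, rp$forest_t1, rp$evi_t0, rp$evi_t1,
                     cell_size = rp$cell_size, origin = shift)
  a <- buffer_change(rp, 300, 300, 110)
  b <- buffer_change(rp2, 300 + shift[1], 300 + shift[2], 110)
  expect_equal(a$delta_forest, b$delta_forest, tolerance = 1e-12)
  expect_equal(a$weight_sum, b$weight_sum, tolerance = 1e-10)
})

test_that("ring weights reproduce the analytic dilation area within 1%", {
  # square 200x200 m dilated by 100 m: ring area = 4*200*100 + pi*100^2
  n <- 40
  k <- matrix(1L, n, n); e <- matrix(0.5, n, n)
  rp <- raster_pair(k, k, e, e, cell_size = 30)
  sq <- cbind(x = c(500, 700, 700, 500), y = c(500, 500, 700, 700))
  w <- remiforest:::ring_weights(rp, sq, inner = 0, outer = 100,
                                 subdiv = 16L, threshold = 1e-9)
  got <- sum(w$weight) * 30^2
  analytic <- 4 * 200 * 100 + pi * 100^2
  expect_lt(abs(got - analytic) / analytic, 0.01)
  # the polygon interior weight matches its own area
  w_in <- remiforest:::ring_weights(rp, sq, inner = -Inf, outer = 0,
                                    subdiv = 16L, threshold = 1e-9)
  expect_lt(abs(sum(w_in$weight) * 900 - 200 * 200) / 4e4, 0.02)
})

test_that("ring zones partition the full dilation weight per cell", {
  rp <- toy_raster(n = 30)
  sq <- cbind(x = c(350, 500, 500, 350), y = c(350, 350, 500, 500))
  w1 <- remiforest:::ring_weights(rp, sq, 0, 100, subdiv = 8L, threshold = 1e-9)
  w2 <- remiforest:::ring_weights(rp, sq, 100, 200, subdiv = 8L, threshold = 1e-9)
  wall <- remiforest:::ring_weights(rp, sq, 0, 200, subdiv = 8L, threshold = 1e-9)
  m <- merge(merge(w1, w2, by = c("row", "col"), all = TRUE),
             wall, by = c("row", "col"), all = TRUE)
  m[is.na(m)] <- 0
  expect_true(all(abs(m$weight.x + m$weight.y - m$weight) < 1e-9))
})

test_that("invalid polygons and ring specs are rejected", {
  rp <- toy_raster(n = 10)
  expect_error(ring_buffer_change(rp, cbind(1, 1), rings = c(100)), "polygon")
  sq <- cbind(x = c(50, 150, 150, 50), y = c(50, 50, 150, 150))
  expect_error(ring_buffer_change(rp, sq, rings = c(200, 100)), "increasing")
})
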