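test_that("utilization distributions are normalized with monotone isopleths", {
  set.seed(7)
  for (rep in 1:3) {
    rel <- data.frame(x_km = rnorm(200, sd = 1 + rep),
                      y_km = rnorm(200, sd = 2))
    ud <- fit_kde(rel, cell_size = 0.25)
    expect_equal(sum(ud$density) * ud$cell_size^2, 1, tolerance = 1e-6)
    expect_true(all(ud$density >= 0))
    expect_true(all(ud$isopleth >= 0 & ud$isopleth <= 100))
    # higher density => smaller-or-equal isopleth label
    ord <- order(ud$density, decreasing = TRUE)
    expect_true(all(diff(ud$isopleth[ord]) >= -1e-12))
  }
})

test_that("kernel fitting rejects degenerate inputs", {
  expect_error(fit_kde(data.frame(x_km = rnorm(10), y_km = rnorm(10))),
               "insufficient relocations")
  expect_error(fit_kde(data.frame(x_km = rep(1, 40), y_km = rnorm(40))),
               "zero variance")
})

test_that("percent-volume regions match brute-force mass accumulation", {
  rel <- data.frame(x_km = c(0, 1.5, -1, 0.5, 2),
                    y_km = c(0, 0.5, 1, -1.5, 1))
  ud <- fit_kde(rel[rep(1:5, 8), ], bandwidth_rule = c(1, 1),
                cell_size = 0.25)
  mass <- as.vector(ud$density) * ud$cell_size^2
  mass <- mass / sum(mass)
  ord <- order(mass, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  for (p in c(30, 50, 80, 95)) {
    # region = cells whose inclusive cumulative mass stays within p
    brute <- rep(FALSE, length(mass))
    brute[ord[cum <= p / 100 + 1e-12]] <- TRUE
    reg <- percent_volume_region(ud, p)
    expect_identical(as.vector(reg$cells), brute,
                     label = sprintf("p = %d region", p))
  }
})

test_that("region area is nondecreasing in the isopleth level", {
  set.seed(11)
  ud <- fit_kde(data.frame(x_km = rnorm(500), y_km = rnorm(500)),
                cell_size = 0.2)
  areas <- vapply(seq(10, 99, by = 1), function(p)
    percent_volume_region(ud, p)$area_km2, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("95% kernel area matches the bivariate-normal closed form", {
  set.seed(3)
  rel <- data.frame(x_km = rnorm(10000), y_km = rnorm(10000))
  ud <- fit_kde(rel, cell_size = 0.1)
  a95 <- percent_volume_region(ud, 95)$area_km2
  # area of the 95% probability disc of a unit isotropic Gaussian
  expect_equal(a95, -2 * log(0.05) * pi, tolerance = 0.1)
  a50 <- percent_volume_region(ud, 50)$area_km2
  expect_equal(a50 / a95, log(0.5) / log(0.05), tolerance = 0.1)
  # doubling all coordinates quadruples the 95% area
  ud2 <- fit_kde(data.frame(x_km = 2 * rel$x_km, y_km = 2 * rel$y_km),
                 cell_size = 0.1)
  expect_equal(percent_volume_region(ud2, 95)$area_km2 / a95, 4,
               tolerance = 0.02)
})

test_that("point usage follows Gaussian containment closed forms", {
  ud <- gaussian_ud(sigma = 1, half = 5, cell = 0.05)
  expect_gte(usage_at(ud, 0, 0), 99)                   # mode
  expect_equal(usage_at(ud, 4.9, 4.9), 0)              # far tail
  expect_equal(usage_at(ud, 50, 50), 0)                # off grid
  # containment p = 1 - exp(-r^2/2) => usage = 100 (1 - p)
  r50 <- sqrt(-2 * log(0.5))
  expect_equal(usage_at(ud, r50, 0), 50, tolerance = 2)
  r80 <- sqrt(-2 * log(0.2))
  expect_equal(usage_at(ud, 0, r80), 20, tolerance = 2)
})

test_that("usage difference is the exact subtraction, other minus hunt", {
  ud_a <- gaussian_ud(sigma = 1, half = 6, cell = 0.1, center = c(0, 0))
  ud_b <- gaussian_ud(sigma = 1, half = 6, cell = 0.1, center = c(0, 0))
  ud_b$x <- ud_b$x + 2  # shift B's grid so usage differs between groups
  uds <- list(A = ud_a, B = ud_b)
  hunts <- data.frame(hunt_id = c("h1", "h2", "h3"),
                      x_km = c(0, 1, 2), y_km = 0,
                      catcher_group = c("A", "A", "B"))
  sc <- usage_difference(hunts, uds)
  expect_equal(sc$usage_difference,
               sc$usage_other_group - sc$usage_hunt_group)
  # at the midpoint both usages agree up to grid-cell tie-breaking
  expect_lt(abs(sc$usage_difference[2]), 0.2)
  # swapping the catcher flips the sign
  hunts2 <- hunts
  hunts2$catcher_group <- c("B", "B", "A")
  sc2 <- usage_difference(hunts2, uds)
  expect_equal(sc2$usage_difference, -sc$usage_difference)
  expect_error(usage_difference(
    data.frame(hunt_id = "x", x_km = 0, y_km = 0, catcher_group = "C"),
    uds), "no utilization distribution")
})

test_that("overlap is total for identical UDs and zero for distant ones", {
  ud <- gaussian_ud(sigma = 1, half = 4, cell = 0.1)
  ov <- overlap_fraction(ud, ud, 95)
  expect_equal(ov$fraction_a_in_b, 1)
  expect_equal(ov$fraction_b_in_a, 1)
  far <- gaussian_ud(sigma = 1, half = 4, cell = 0.1, center = c(100, 0))
  expect_error(overlap_fraction(ud, far), "disjoint")
  near <- gaussian_ud(sigma = 1, half = 4, cell = 0.1)
  near$x <- near$x + 1.5
  ov2 <- overlap_fraction(ud, near, 95)
  expect_true(ov2$fraction_a_in_b > 0 && ov2$fraction_a_in_b < 1)
})

test_that("isopleth outlines enclose exactly the region area", {
  set.seed(21)
  ud <- fit_kde(data.frame(x_km = rnorm(300), y_km = rnorm(300)),
                cell_size = 0.2)
  shoelace <- function(r) {
    n <- nrow(r)
    sum(r[-n, 1] * r[-1, 2] - r[-1, 1] * r[-n, 2]) / 2
  }
  for (p in c(50, 95)) {
    reg <- percent_volume_region(ud, p)
    signed <- sum(vapply(reg$polygons, shoelace, numeric(1)))
    expect_equal(signed, reg$area_km2, tolerance = 1e-9)
    expect_true(all(vapply(reg$polygons, function(r)
      all(r[1, ] == r[nrow(r), ]), TRUE)))
  }
})

test_that("GeoJSON export is well-formed", {
  ud <- gaussian_ud(sigma = 1, half = 4, cell = 0.2)
  ud$group_id <- "Ekalakala"
  path <- tempfile(fileext = ".geojson")
  write_isopleth_geojson(ud, c(50, 95), path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 2)
  expect_equal(gj$features[[1]]$properties$level, 50)
  expect_equal(gj$features[[1]]$properties$group, "Ekalakala")
  expect_equal(gj$features[[2]]$geometry$type, "MultiPolygon")
  expect_gt(gj$features[[2]]$properties$area_km2,
            gj$features[[1]]$properties$area_km2)
})
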