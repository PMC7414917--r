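test_that("Wald width matches direct evaluation of the formula", {
  expect_equal(round(ci_width(0.80, 1524), 4), 0.0402)
  expect_equal(ci_width(1.0, 50), 0)
  expect_equal(ci_width(0.5, 100), 2 * qnorm(0.975) * 0.05, tolerance = 1e-12)
  expect_equal(round(ci_width(0.5, 100), 5), 0.19600)
  expect_error(ci_width(1.2, 10), "\\[0, 1\\]")
  expect_error(ci_width(0.5, 0), "undefined")
  expect_error(ci_width(0.5, 10, 1), "confidence_level")
})

test_that("Wald width is maximal at P = 0.5 and scales as 1/sqrt(N)", {
  p_grid <- seq(0, 1, by = 0.05)
  widths <- ci_width(p_grid, 200)
  expect_equal(p_grid[which.max(widths)], 0.5)
  for (p in c(0.1, 0.5, 0.9)) {
    for (n in c(25, 100, 400)) {
      expect_equal(ci_width(p, n) / ci_width(p, 4 * n), 2)
    }
  }
})

test_that("cell map assigns each corner patient to its own cell", {
  proj <- tibble::tibble(
    x = c(0.1, 0.1, 0.9, 0.9), y = c(0.1, 0.9, 0.1, 0.9),
    survived_12m = c(TRUE, TRUE, FALSE, TRUE)
  )
  map <- build_cell_map(proj, cell_size = 0.5)
  expect_equal(nrow(map), 4)
  expect_equal(map$n, rep(1L, 4))
  lookup <- function(cx, cy) map$rate[map$cell_x == cx & map$cell_y == cy]
  expect_equal(lookup(0, 0), 1)
  expect_equal(lookup(0, 1), 1)
  expect_equal(lookup(1, 0), 0)
  expect_equal(lookup(1, 1), 1)
})

test_that("cell map honours the half-open boundary and conserves patients", {
  proj <- tibble::tibble(x = c(0.5, 0.49999), y = c(0.5, 0.2),
                         survived_12m = c(TRUE, FALSE))
  map <- build_cell_map(proj, cell_size = 0.5)
  expect_equal(map$n[map$cell_x == 1 & map$cell_y == 1], 1L)  # (0.5, 0.5) up
  expect_equal(map$n[map$cell_x == 0 & map$cell_y == 0], 1L)
  expect_equal(sum(map$n), nrow(proj))

  one_cell <- tibble::tibble(x = rep(0.2, 8), y = rep(0.9, 8),
                             survived_12m = rep(TRUE, 8))
  m2 <- build_cell_map(one_cell, cell_size = 0.5)
  expect_equal(m2$rate[m2$n > 0], 1)
  expect_equal(m2$width[m2$n > 0], 0)
  expect_true(all(is.na(m2$rate[m2$n == 0])))  # empty cells undefined, not 0
  expect_error(build_cell_map(one_cell, cell_size = 0.3), "integer")
})

test_that("three equal zones of a 12-point line recover 1.0 / 0.5 / 0.25", {
  proj <- make_projected(y = (1:12 - 1) / 11,
                         survived = c(1, 1, 1, 1, 1, 1, 0, 0, 1, 0, 0, 0) == 1)
  zm <- fit_zones(proj, axis = "y", k = 3)
  expect_equal(tidy(zm)$rate, c(1.0, 0.5, 0.25))
  expect_equal(tidy(zm)$n, rep(4L, 3))
})

test_that("degenerate zoning cases behave: all survive, too few patients", {
  proj <- make_projected(y = runif(30), survived = rep(TRUE, 30))
  for (k in c(2, 3, 5)) {
    zd <- tidy(fit_zones(proj, k = k))
    expect_equal(zd$rate, rep(1, k))
    expect_equal(zd$width, rep(0, k))
  }
  expect_error(fit_zones(make_projected(runif(2), c(TRUE, FALSE)), k = 3),
               "3 zones")
  expect_error(
    fit_zones(make_projected(runif(5), c(TRUE, NA, TRUE, FALSE, TRUE))),
    "survived_12m")
})

test_that("zone populations differ by at most one and conserve totals", {
  set.seed(21)
  for (trial in 1:25) {
    n <- sample(10:400, 1)
    k <- sample(2:6, 1)
    if (n < k) next
    proj <- make_projected(y = runif(n), survived = runif(n) < 0.7)
    zm <- fit_zones(proj, k = k)
    zd <- tidy(zm)
    expect_lte(diff(range(zd$n)), 1)
    expect_equal(sum(zd$n), n)
    expect_equal(sum(zd$survivors), sum(proj$survived_12m))
    # population-weighted zone rates pool back to the overall rate
    expect_equal(sum(zd$n * zd$rate) / n, mean(proj$survived_12m),
                 tolerance = 1e-12)
  }
})

test_that("zone membership agrees with the enumerative nearest-rank oracle", {
  set.seed(33)
  for (trial in 1:30) {
    n <- sample(5:200, 1)
    k <- sample(2:5, 1)
    if (n < k) next
    y <- sample(round(runif(n), 2))  # rounded: forces ties
    zm <- fit_zones(make_projected(y = y, survived = runif(n) < 0.6), k = k)
    expect_equal(zm$membership, oracle_zone_membership(y, k))
  }
})

test_that("ties in coordinates break by stable input order", {
  y <- c(0.5, 0.2, 0.5, 0.5, 0.9, 0.5)
  zm <- fit_zones(make_projected(y = y, survived = rep(TRUE, 6)), k = 3)
  # sorted order: 0.2, then the four 0.5s in input order, then 0.9
  expect_equal(zm$membership, c(1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("zone assignment follows the half-open interval convention", {
  proj <- make_projected(y = (1:9 - 0.5) / 9, survived = rep(c(TRUE, FALSE, TRUE), 3))
  zm <- fit_zones(proj, k = 3)
  zm$cuts <- c(0.3, 0.6)   # fixed cuts make the convention explicit
  expect_equal(assign_zone(zm, 0.92, 0.79)$zone, 3L)
  expect_equal(assign_zone(zm, 0.5, 0.3)$zone, 2L)    # boundary goes up
  expect_equal(assign_zone(zm, 0.5, 0.29999)$zone, 1L)
  expect_equal(assign_zone(zm, 0.5, 0)$zone, 1L)
  expect_equal(assign_zone(zm, 0.5, 1)$zone, 3L)
  expect_error(assign_zone(zm, 1.2, 0.5), "unit square")
  pr <- assign_zone(zm, 0.46, 0.62)
  expect_equal(pr$rate, zm$zones$rate[pr$zone])
  expect_equal(pr$lower, max(0, pr$rate - pr$width / 2))
  expect_equal(pr$upper, min(1, pr$rate + pr$width / 2))
})

test_that("zone model JSON round trip preserves the model and assignments", {
  proj <- make_projected(y = runif(100, 0, 1), survived = runif(100) < 0.7)
  zm <- fit_zones(proj, k = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_zones(zm, path)
  back <- read_zones(path)
  expect_equal(back$cuts, zm$cuts)
  expect_equal(as.data.frame(back$zones), as.data.frame(zm$zones))
  expect_equal(back$z_alpha, zm$z_alpha)
  pts <- cbind(runif(20), runif(20))
  expect_equal(assign_zone(back, pts[, 1], pts[, 2]),
               assign_zone(zm, pts[, 1], pts[, 2]))
})
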