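test_that("threshold_mask applies strict greater-than on valid pixels", {
  m <- value_map(matrix(c(0.60, 0.45, 0.50, 0.70), 2, 2))  # [[0.60,0.50],[0.45,0.70]]
  spec <- threshold_spec(0.52)
  mask <- threshold_mask(m, spec)
  expect_equal(sum(mask), 2L)
  expect_true(mask[1, 1] && mask[2, 2])

  # exactly-equal value is excluded; all-below gives all-false
  expect_false(any(threshold_mask(value_map(matrix(0.52, 2, 2)), spec)))
  expect_false(any(threshold_mask(value_map(matrix(0.1, 2, 2)), spec)))

  # invalid pixels are never flowering
  mv <- value_map(matrix(c(NA, 0.9, 0.9, 0.9), 2, 2))
  expect_equal(sum(threshold_mask(mv, spec)), 3L)

  expect_error(threshold_mask(value_map(matrix(0.5, 2, 2), index = "NDVI"), spec),
               "NDYI")
  expect_error(threshold_spec(1.2), "in \\(-1, 1\\)")
})

test_that("count_flowering_pixels counts mask-true centers inside the plot", {
  m <- value_map(matrix(c(0.60, 0.45, 0.50, 0.70), 2, 2))
  spec <- threshold_spec(0.52)
  expect_equal(count_flowering_pixels(m, rect_plot("P", 0, 1, 0, 1), spec), 2L)
  # plot covering only the below-threshold pixels (0.50 at (0,1), 0.45 at (1,0)):
  # the anti-diagonal half via column 1 row 1 only
  expect_equal(count_flowering_pixels(m, rect_plot("P", 1, 1, 0, 0), spec), 0L)
  expect_equal(count_flowering_pixels(m, rect_plot("P", 0, 0, 1, 1), spec), 0L)

  all_true <- value_map(matrix(0.9, 10, 10))
  expect_equal(count_flowering_pixels(all_true, rect_plot("P", 0, 9, 0, 9), spec),
               100L)
  expect_error(count_flowering_pixels(m, rect_plot("P", 10, 12, 10, 12), spec),
               "outside")
})

test_that("raising the threshold never increases a count (property)", {
  set.seed(13)
  for (rep in 1:20) {
    m <- value_map(matrix(runif(400, -1, 1), 20, 20))
    p <- rect_plot("P", 2, 17, 3, 16)
    th <- sort(runif(5, -0.9, 0.9))
    counts <- vapply(th, function(v)
      count_flowering_pixels(m, p, threshold_spec(v)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("counts are additive over a partition of the plot (property)", {
  set.seed(17)
  m <- value_map(matrix(runif(900), 30, 30))
  spec <- threshold_spec(0.5)
  whole <- plot_geometry("W", cbind(row = c(1.2, 1.2, 27.7, 27.7),
                                    col = c(0.8, 28.4, 28.4, 0.8)))
  # split by a vertical edge at an arbitrary (non-half-integer) column
  split_col <- 13.37
  left <- plot_geometry("L", cbind(row = c(1.2, 1.2, 27.7, 27.7),
                                   col = c(0.8, split_col, split_col, 0.8)))
  right <- plot_geometry("R", cbind(row = c(1.2, 1.2, 27.7, 27.7),
                                    col = c(split_col, 28.4, 28.4, split_col)))
  expect_equal(count_flowering_pixels(m, whole, spec),
               count_flowering_pixels(m, left, spec) +
                 count_flowering_pixels(m, right, spec))

  # same with an edge passing exactly through pixel centers (integer column):
  # the half-open rule assigns on-edge centers to exactly one side
  for (sc in c(14, 14.5)) {
    l2 <- plot_geometry("L", cbind(row = c(1.2, 1.2, 27.7, 27.7),
                                   col = c(0.8, sc, sc, 0.8)))
    r2 <- plot_geometry("R", cbind(row = c(1.2, 1.2, 27.7, 27.7),
                                   col = c(sc, 28.4, 28.4, sc)))
    expect_equal(count_flowering_pixels(m, whole, spec),
                 count_flowering_pixels(m, l2, spec) +
                   count_flowering_pixels(m, r2, spec))
  }
})

test_that("pixel-center containment agrees with an independent point-in-polygon",
{
  skip_if_not_installed("pracma")
  set.seed(23)
  # convex pentagon with non-trivial edges; compare strictly interior points
  vr <- c(2.3, 1.1, 8.6, 12.2, 7.9)
  vc <- c(1.4, 7.7, 11.9, 5.5, 0.7)
  p <- plot_geometry("P", cbind(row = vr, col = vc))
  m <- value_map(matrix(1, 14, 14))
  inside_pkg <- flowerpheno:::.plot_pixel_mask(dim(m$values), p)
  grid <- expand.grid(row = 0:13, col = 0:13)
  ref <- pracma::inpolygon(grid$col, grid$row, vc, vr, boundary = FALSE)
  on_edge <- pracma::inpolygon(grid$col, grid$row, vc, vr, boundary = TRUE) & !ref
  idx <- cbind(grid$row + 1, grid$col + 1)
  expect_equal(inside_pkg[idx][!on_edge], ref[!on_edge])
})

test_that("build_flowering_series assembles sorted per-plot series", {
  maps <- list(value_map(matrix(0.9, 4, 4), date = 199),
               value_map(matrix(0.1, 4, 4), date = 185),
               value_map(matrix(0.9, 4, 4), date = 192))
  plots <- list(rect_plot("P1", 0, 1, 0, 3), rect_plot("P2", 2, 3, 0, 3))
  out <- build_flowering_series(maps, plots, threshold_spec(0.5))
  expect_length(out, 2)
  expect_equal(out[[1]]$t, c(185, 192, 199))  # sorted despite input order
  expect_equal(out[[1]]$count, c(0, 8, 8))
  expect_equal(out[[2]]$plot_id, "P2")

  expect_error(
    build_flowering_series(maps[c(1, 1)], plots, threshold_spec(0.5)),
    "duplicate")
})

test_that("suggest_threshold separates bimodal values and honors quantiles", {
  set.seed(31)
  # bimodal NDYI: flower mode ~0.75, canopy mode ~0.25, equal weight
  x <- c(rnorm(2000, 0.25, 0.05), rnorm(2000, 0.75, 0.05))
  m <- value_map(matrix(x, 40, 100))
  th <- suggest_threshold(m, "otsu")
  expect_gt(th, 0.35)
  expect_lt(th, 0.65)

  # independent oracle: exhaustive minimization of the within-class sum of
  # squares directly on the data.  The objective is nearly flat between
  # well-separated modes, so compare achieved objective values, not argmins.
  wss <- function(e) {
    lo <- x[x < e]; hi <- x[x >= e]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }
  cand <- seq(min(x) + 0.01, max(x) - 0.01, length.out = 400)
  best <- min(vapply(cand, wss, numeric(1)))
  expect_lt(wss(th), best * 1.001)

  # type-1 quantile: q = 0.9 over 1..10 gives exactly 9 (no interpolation)
  m10 <- value_map(matrix(seq(0.1, 1.0, by = 0.1) - 0.05, 2, 5))
  q <- suggest_threshold(m10, "quantile", q = 0.9)
  expect_equal(q, sort(m10$values)[9])

  expect_error(suggest_threshold(value_map(matrix(0.5, 3, 3)), "otsu"),
               "distinct")
})

test_that("otsu matches EBImage on a rescaled histogram", {
  skip_if_not_installed("EBImage")
  set.seed(37)
  x <- c(rnorm(3000, 0.3, 0.06), rnorm(1500, 0.8, 0.04))
  x <- pmin(pmax(x, 0), 1)
  m <- value_map(matrix(x, 45, 100))
  th <- suggest_threshold(m, "otsu")
  eb <- EBImage::otsu(matrix(x, 45, 100), range = range(x), levels = 256)
  # both must land between the modes and achieve near-identical Otsu
  # objectives (the objective is flat in the valley, argmins need not match)
  wss <- function(e) {
    lo <- x[x < e]; hi <- x[x >= e]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }
  for (v in c(th, eb)) {
    expect_gt(v, 0.4)
    expect_lt(v, 0.7)
  }
  expect_lt(abs(wss(th) - wss(eb)) / wss(eb), 0.005)
})
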