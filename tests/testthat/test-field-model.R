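test_that("reflectance_image validates its invariants", {
  img <- const_image(0.2)
  expect_s3_class(img, "reflectance_image")
  expect_equal(dim(img), c(4L, 4L))
  expect_false(any(img$mask))

  bands <- img$bands
  expect_error(reflectance_image(bands[-1], 190), "blue")
  bands_bad <- bands
  bands_bad$nir <- matrix(0.2, 3, 4)
  expect_error(reflectance_image(bands_bad, 190), "same shape")
  expect_error(reflectance_image(bands, -1), "positive Julian")

  # non-finite values are absorbed into the mask
  bands_na <- bands
  bands_na$red[1, 1] <- NA
  expect_true(reflectance_image(bands_na, 190)$mask[1, 1])
})

test_that("raster stack writes and reads back losslessly", {
  img <- const_image(0.2)
  f <- tempfile(fileext = ".tif")
  write_reflectance_stack(img, f)
  back <- read_reflectance_stack(f, setNames(1:5, band_names), date = 190)
  for (b in band_names)
    expect_equal(back$bands[[b]], img$bands[[b]], tolerance = 1e-8)
  expect_false(any(back$mask))
  expect_equal(back$date, 190)

  expect_error(
    read_reflectance_stack(f, setNames(1:4, band_names[-4]), date = 190),
    "rededge")
  expect_error(read_reflectance_stack(tempfile(), setNames(1:5, band_names), 190),
               "not found")
})

test_that("nodata mask round-trips through the sentinel encoding", {
  img <- const_image(0.4)
  img$mask[1, 1] <- TRUE
  f <- tempfile(fileext = ".tif")
  write_reflectance_stack(img, f)
  back <- read_reflectance_stack(f, setNames(1:5, band_names), date = 190)
  expect_identical(which(back$mask), which(img$mask))
  expect_true(all(is.na(back$bands$green[back$mask])) ||
                all(back$bands$green[back$mask] == 0))
})

test_that("out-of-range reflectance is reported but retained", {
  img <- const_image(0.2)
  img$bands$nir[2, 2] <- 1.6  # storable, outside the plausible [-0.1, 1.5]
  f <- tempfile(fileext = ".tif")
  write_reflectance_stack(img, f)
  expect_message(
    back <- read_reflectance_stack(f, setNames(1:5, band_names), date = 190),
    "outside")
  expect_equal(back$bands$nir[2, 2], 1.6, tolerance = 1e-7)
})

test_that("band content is independent of band_map ordering", {
  set.seed(11)
  img <- random_image()
  f <- tempfile(fileext = ".tif")
  write_reflectance_stack(img, f)
  # storage order is canonical; permuted band_map names must still land right
  perm <- sample(5)
  bm <- setNames(perm, band_names[perm])
  back <- read_reflectance_stack(f, bm, date = 190)
  for (b in band_names)
    expect_equal(back$bands[[b]], img$bands[[b]], tolerance = 1e-8)
})

test_that("plot_geometry rejects degenerate and self-intersecting polygons", {
  expect_error(plot_geometry("P1", cbind(c(0, 1), c(0, 1))), "n >= 3")
  expect_error(plot_geometry("P1", cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
  bowtie <- cbind(row = c(0, 3, 0, 2), col = c(0, 3, 3, 0))
  expect_error(plot_geometry("P1", bowtie), "self-intersecting")
  expect_s3_class(rect_plot("P1", 0, 3, 0, 3), "plot_geometry")
})

test_that("GeoJSON polygons round-trip and transform to pixel space", {
  plots <- list(rect_plot("P1", 0, 9, 0, 4, genotype = "lineA"),
                rect_plot("P2", 12, 21, 0, 4))
  f <- tempfile(fileext = ".geojson")
  write_plot_polygons(plots, f)
  back <- load_plot_polygons(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$plot_id, "P1")
  expect_equal(back[[1]]$genotype, "lineA")
  expect_equal(back[[1]]$vertices, plots[[1]]$vertices)

  # duplicate ids are rejected
  dup <- list(rect_plot("P1", 0, 3, 0, 3), rect_plot("P1", 5, 8, 0, 3))
  f2 <- tempfile(fileext = ".geojson")
  write_plot_polygons(dup, f2)
  expect_error(load_plot_polygons(f2), "duplicate")
})

test_that("a 1 m world square on a 1 cm grid becomes a 100-pixel square", {
  # geotransform: origin (500, 900), 0.01 m/px east, -0.01 m/px south
  gt <- c(500, 0.01, 0, 900, 0, -0.01)
  ring <- list(list(c(500, 900), c(501, 900), c(501, 899), c(500, 899),
                    c(500, 900)))
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(plot_id = "W1"),
    geometry = list(type = "Polygon", coordinates = ring))))
  f <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  p <- load_plot_polygons(f, geotransform = gt)[[1]]
  v <- p$vertices
  expect_equal(diff(range(v[, "col"])), 100)
  expect_equal(diff(range(v[, "row"])), 100)
  expect_equal(min(v[, "col"]), -0.5)  # corner at pixel-corner -0.5
  expect_equal(min(v[, "row"]), -0.5)
})

test_that("flowering_series enforces ordering and non-negativity", {
  expect_error(flowering_series("P1", c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(flowering_series("P1", c(1, 2), c(-1, 0)), "non-negative")
  s <- flowering_series("P1", c(180, 187), c(10, 20))
  expect_equal(length(s), 2L)
})

test_that("series tables round-trip exactly", {
  f <- tempfile(fileext = ".csv")
  write_series_table(list(), f)
  expect_identical(read_series_table(f), list())
  expect_equal(nrow(read.csv(f)), 0L)  # header-only file

  series <- list(flowering_series("P1", c(180, 187, 194), c(0, 55, 130)),
                 flowering_series("P2", c(180, 187, 194), c(3, 70, 12)))
  write_series_table(series, f)
  expect_equal(nrow(read.csv(f)), 6L)
  back <- read_series_table(f)
  expect_equal(back, series)

  # duplicated date within one plot is rejected on read
  df <- read.csv(f)
  df$date_julian[2] <- 180
  write.csv(df, f, row.names = FALSE)
  expect_error(read_series_table(f), "duplicated date")
})

test_that("randomized series tables round-trip (property)", {
  set.seed(42)
  for (rep in 1:20) {
    series <- lapply(seq_len(sample(1:6, 1)), function(i)
      random_series(sprintf("P%d", i)))
    f <- tempfile(fileext = ".csv")
    write_series_table(series, f)
    expect_equal(read_series_table(f), series)
    unlink(f)
  }
})

test_that("ground reference readers validate schema and signs", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(plot_id = "P1", date_julian = 190, manual_count = -3),
            f, row.names = FALSE)
  expect_error(read_ground_reference(manual_counts_path = f), ">= 0")
  write.csv(data.frame(plot_id = "P1", wrong = 1), f, row.names = FALSE)
  expect_error(read_ground_reference(manual_counts_path = f), "missing column")

  ref <- ground_reference(
    manual_counts = data.frame(plot_id = "P1", date_julian = 190,
                               manual_count = 12),
    yield = data.frame(plot_id = "P1", yield = 1400))
  f2 <- tempfile(fileext = ".csv")
  write_ground_reference(ref, yield_path = f2)
  expect_equal(read_ground_reference(yield_path = f2)$yield$yield, 1400)
})
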