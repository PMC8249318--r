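# Shared fixtures: tiny images and plots built in code.

band_names <- c("blue", "green", "red", "rededge", "nir")

const_image <- function(value = 0.2, nr = 4, nc = 4, date = 190) {
  reflectance_image(setNames(rep(list(matrix(value, nr, nc)), 5), band_names),
                    date = date)
}

# Image with chosen green/blue (for NDYI) and benign other bands.
gb_image <- function(green, blue, date = 190) {
  stopifnot(identical(dim(green), dim(blue)))
  other <- matrix(0.3, nrow(green), ncol(green))
  reflectance_image(list(blue = blue, green = green, red = other,
                         rededge = other, nir = other), date = date)
}

random_image <- function(nr = 6, nc = 6, date = 190) {
  reflectance_image(setNames(lapply(1:5, function(i)
    matrix(runif(nr * nc, 0.01, 1), nr, nc)), band_names), date = date)
}

# Axis-aligned rectangular plot whose pixel centers are rows r0..r1, cols c0..c1.
rect_plot <- function(id, r0, r1, c0, c1, genotype = NULL) {
  plot_geometry(id, cbind(row = c(r0, r0, r1, r1) - c(0.5, 0.5, -0.5, -0.5),
                          col = c(c0, c1, c1, c0) + c(-0.5, 0.5, 0.5, -0.5)),
                genotype = genotype)
}

# Small index map from a value matrix (all valid unless NA).
value_map <- function(values, index = "NDYI", date = 190) {
  invalid <- is.na(values)
  structure(list(index = index, values = values, invalid = invalid,
                 date = date, pixel_size = NULL),
            class = "index_map")
}

random_series <- function(plot_id = "P1", n = NULL) {
  n <- n %||% sample(2:12, 1)
  t <- cumsum(runif(n, 0.5, 7))
  flowering_series(plot_id, t, round(runif(n, 0, 500)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
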