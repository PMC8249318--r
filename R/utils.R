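# Internal helpers shared across modules.

# Canonical band order used everywhere (storage order in multi-page rasters).
BAND_NAMES <- c("blue", "green", "red", "rededge", "nir")

# Linear storage encoding for rasters written by this package: TIFF integer
# samples hold s = (v + 1) / 4, so reflectance/index values in [-1, 3] are
# representable; stored 0 (v = -1, outside any physical range) is the nodata
# sentinel.  32-bit samples give ~1e-9 resolution.
.encode_sample <- function(v) (v + 1) / 4
.decode_sample <- function(s) {
  v <- 4 * s - 1
  # snap sub-quantum magnitudes to exact zero: truncated-at-zero reflectance
  # must not come back as -1e-9 and flip index validity at the +/-1 bounds
  v[abs(v) < 2e-9] <- 0
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop2 <- function(...) stop(..., call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0

# Deterministic sub-stream seed derivation; keeps results independent of the
# order in which plots/dates are rendered.  All arithmetic stays < 2^31.
.substream_seed <- function(master, a = 0L, b = 0L, c = 0L) {
  s <- (as.numeric(master) %% 1e6) * 1009 + a * 9973 + b * 104729 + c * 7919
  as.integer(s %% 2147483647)
}

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Even-odd point-in-polygon test, vectorized over points.  Uses the standard
# half-open crossing rule ((yi > p) != (yj > p) with strict x < x-intersect),
# so every point is assigned to exactly one polygon of a partition that shares
# edges -- the property the per-plot pixel counts rely on.
# pr, pc: point rows/cols; vr, vc: polygon vertex rows/cols (open ring).
.points_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- vr[i]; yj <- vr[j]
    xi <- vc[i]; xj <- vc[j]
    cross <- (yi > pr) != (yj > pr)
    if (any(cross)) {
      xint <- (xj - xi) * (pr - yi) / (yj - yi) + xi
      inside <- xor(inside, cross & (pc < xint))
    }
    j <- i
  }
  inside
}

# Shoelace area of a polygon given as (row, col) vertices (open ring).
.polygon_area <- function(vr, vc) {
  n <- length(vr)
  j <- c(n, seq_len(n - 1L))
  abs(sum(vc * vr[j] - vc[j] * vr)) / 2
}

# TRUE if any two non-adjacent edges of the ring properly intersect.
.polygon_self_intersects <- function(vr, vc) {
  n <- length(vr)
  if (n < 4L) return(FALSE)
  seg <- cbind(vr, vc, vr[c(2:n, 1L)], vc[c(2:n, 1L)])
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross2(p[3] - p[1], p[4] - p[2], q[1] - p[1], q[2] - p[2])
      d2 <- cross2(p[3] - p[1], p[4] - p[2], q[3] - p[1], q[4] - p[2])
      d3 <- cross2(q[3] - q[1], q[4] - q[2], p[1] - q[1], p[2] - q[2])
      d4 <- cross2(q[3] - q[1], q[4] - q[2], p[3] - q[1], p[4] - q[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv <- function(path, required_cols) {
  if (!file.exists(path)) .stop2("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    .stop2("malformed table ", path, ": missing column(s) ",
           paste(missing, collapse = ", "))
  df
}
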