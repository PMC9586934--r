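#' Grid geometry for an axis-aligned equal-area raster
#'
#' All rasters in this package are plain numeric matrices laid out on a simple
#' projected grid: square pixels of size `px` metres, rows counting downward
#' from the top-left corner at (`x0`, `y0`), pixel-centre registration. The
#' centre of cell (i, j) (1-based row/column) is at
#' `x = x0 + (j - 0.5) * px`, `y = y0 - (i - 0.5) * px`.
#'
#' @param nrow,ncol grid dimensions in pixels.
#' @param px pixel edge length in metres (default 1000, i.e. 1-km cells).
#' @param x0,y0 projected coordinates of the top-left corner.
#' @return an object of class `grid_geom`.
#' @export
grid_geom <- function(nrow, ncol, px = 1000, x0 = 0, y0 = nrow * px) {
  stopifnot(nrow >= 1, ncol >= 1, px > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 px = px, x0 = x0, y0 = y0),
            class = "grid_geom")
}

#' @export
format.grid_geom <- function(x, ...) {
  sprintf("<grid_geom %d x %d, %g m pixels, origin (%g, %g)>",
          x$nrow, x$ncol, x$px, x$x0, x$y0)
}

#' @export
print.grid_geom <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# cell-centre coordinates (internal)
cell_centers_x <- function(g) g$x0 + (seq_len(g$ncol) - 0.5) * g$px
cell_centers_y <- function(g) g$y0 - (seq_len(g$nrow) - 0.5) * g$px

#' The 46 start day-of-years of a year of 8-day composites
#'
#' Satellite 8-day composite products tile the year into 46 fixed periods
#' starting at day-of-year 1, 9, ..., 361 (the final period is 5 or 6 days).
#'
#' @return integer vector of length 46.
#' @export
composite_doys <- function() seq(1L, 361L, by = 8L)

#' A year of 8-day composite layers for one indicator
#'
#' @param indicator name, e.g. `"ET"`, `"GPP"`, `"Ts"`, `"LAI"`.
#' @param year integer year label.
#' @param data numeric array `nrow x ncol x n_layers`; `NA` marks nodata.
#' @param doys composite start day-of-years, one per layer, strictly
#'   increasing with constant step 8.
#' @param geom a [grid_geom()].
#' @param units unit string (e.g. `"mm/8d"`, `"degC"`).
#' @return an object of class `composite_stack`.
#' @export
composite_stack <- function(indicator, year, data, doys = composite_doys(),
                            geom = grid_geom(dim(data)[1], dim(data)[2]),
                            units = "") {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(doys))
  if (length(doys) > 1) {
    d <- diff(doys)
    if (any(d != 8)) stop("composite start DOYs must step by 8")
  }
  stopifnot(dim(data)[1] == geom$nrow, dim(data)[2] == geom$ncol)
  structure(list(indicator = indicator, year = as.integer(year),
                 data = data, doys = as.integer(doys), geom = geom,
                 units = units),
            class = "composite_stack")
}

#' @export
print.composite_stack <- function(x, ...) {
  cat(sprintf("<composite_stack %s year %d: %d x %d x %d layers [%s]>\n",
              x$indicator, x$year, dim(x$data)[1], dim(x$data)[2],
              dim(x$data)[3], x$units))
  invisible(x)
}

#' Derive a reproducible sub-stream seed from a pipeline seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' pipeline seed and a stage key, so stages stay reproducible and independent
#' of each other's consumption of the random stream. The scheme is a simple
#' 31-bit polynomial hash of the key mixed with the seed; collisions across
#' the package's small fixed set of keys are not a concern.
#'
#' @param seed integer pipeline seed.
#' @param key character stage label.
#' @return integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
spawn_seed <- function(seed, key) {
  stopifnot(length(seed) == 1, is.finite(seed), length(key) == 1)
  m <- 2147483629 # prime < 2^31
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m * 69069 + h) %% m)
}
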