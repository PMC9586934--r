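# Crop water productivity: yield per unit of water evapotranspired over the
# growing window, and regional summaries of the resulting rasters.

#' Compute a crop-water-productivity raster
#'
#' CWP [kg/m3] = yield [kg/ha] / (10 * cumulative ET [mm]): one millimetre of
#' water over one hectare is 10 m3, so dividing by 10 * ET converts kg/ha per
#' mm into kg per cubic metre. The cumulative ET must come from the same
#' phenology window as the yield model's ET feature. Pixels where either
#' input is nodata, or where cumulative ET is at or below `eps` (default 1 mm,
#' guarding the division), are nodata; their count is reported.
#'
#' @param yield_raster matrix, kg/ha.
#' @param cum_et matrix, mm over the growing window (same geometry).
#' @param eps minimum usable cumulative ET [mm].
#' @return list of class `cwp_raster`: `values` (matrix, kg/m3),
#'   `n_low_et` (pixels dropped by the `eps` floor), `eps`.
#' @export
compute_cwp <- function(yield_raster, cum_et, eps = 1) {
  stopifnot(identical(dim(yield_raster), dim(cum_et)), eps >= 0)
  low <- !is.na(cum_et) & cum_et <= eps & !is.na(yield_raster)
  v <- yield_raster / (10 * cum_et)
  v[is.na(yield_raster) | is.na(cum_et) | cum_et <= eps] <- NA_real_
  structure(list(values = v, n_low_et = sum(low), eps = eps),
            class = "cwp_raster")
}

#' @export
print.cwp_raster <- function(x, ...) {
  cat(sprintf("<cwp_raster %d x %d, %d valid pixels (%d dropped by ET floor %g mm)>\n",
              nrow(x$values), ncol(x$values), sum(!is.na(x$values)),
              x$n_low_et, x$eps))
  invisible(x)
}

#' Regional mean and SD of a raster
#'
#' Unweighted pixel mean and population SD (divide by n; declared in the
#' output) per region, plus an all-region national row labelled `NA`.
#' Regions with no valid pixel are omitted.
#'
#' @param raster numeric matrix (e.g. a CWP or yield raster), or a
#'   `cwp_raster`.
#' @param region_map integer matrix of region labels (`NA` = outside).
#' @return data.frame with columns `region` (NA for the national row),
#'   `mean`, `sd` (population convention), `n_pixels`.
#' @export
regional_summary <- function(raster, region_map) {
  if (inherits(raster, "cwp_raster")) raster <- raster$values
  stopifnot(identical(dim(raster), dim(region_map)))
  keep <- !is.na(raster) & !is.na(region_map)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  if (!any(keep))
    return(data.frame(region = integer(), mean = numeric(), sd = numeric(),
                      n_pixels = integer()))
  vals <- raster[keep]; ids <- region_map[keep]
  mu <- tapply(vals, ids, mean)
  sdv <- tapply(vals, ids, pop_sd)
  n <- tapply(vals, ids, length)
  out <- data.frame(region = as.integer(names(mu)),
                    mean = as.numeric(mu), sd = as.numeric(sdv),
                    n_pixels = as.integer(n), row.names = NULL)
  national <- data.frame(region = NA_integer_, mean = mean(vals),
                         sd = pop_sd(vals), n_pixels = length(vals))
  rbind(out, national)
}
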