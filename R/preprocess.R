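#' Nearest-neighbour resampling between grids
#'
#' Each target cell takes the value of the source cell whose centre is nearest
#' to the target cell centre (ties broken toward the lower index, as in the
#' usual half-open pixel convention). Nodata (`NA`) propagates. This is the
#' standard "Nearest" resampling used to harmonise 500-m satellite products
#' onto a 1-km analysis grid.
#'
#' @param raster numeric matrix on `src_geom`.
#' @param src_geom,dst_geom [grid_geom()] of the source and target grids.
#' @return numeric matrix on `dst_geom`.
#' @export
resample_nearest <- function(raster, src_geom, dst_geom) {
  stopifnot(nrow(raster) == src_geom$nrow, ncol(raster) == src_geom$ncol)
  sx <- cell_centers_x(src_geom); sy <- cell_centers_y(src_geom)
  dx <- cell_centers_x(dst_geom); dy <- cell_centers_y(dst_geom)
  if (max(dx) < min(sx) - src_geom$px / 2 || min(dx) > max(sx) + src_geom$px / 2 ||
      max(dy) < min(sy) - src_geom$px / 2 || min(dy) > max(sy) + src_geom$px / 2)
    stop("source and target extents are disjoint")
  # nearest source column for each target column (and likewise rows): on a
  # centre-registered regular grid this is the containing cell, with points on
  # a cell boundary assigned to the lower index; clamped to the source extent
  jn <- pmin(pmax(ceiling((dx - src_geom$x0) / src_geom$px), 1), src_geom$ncol)
  im <- pmin(pmax(ceiling((src_geom$y0 - dy) / src_geom$px), 1), src_geom$nrow)
  raster[im, jn, drop = FALSE]
}

#' Mask non-crop pixels out of a composite stack
#'
#' Sets every layer to nodata (`NA`) wherever the crop mask is `FALSE`,
#' emulating masking of the input indicators with a cropland layer.
#'
#' @param stack a [composite_stack()].
#' @param crop_mask logical matrix with the stack's geometry.
#' @return the masked [composite_stack()].
#' @export
mask_cropland <- function(stack, crop_mask) {
  stopifnot(inherits(stack, "composite_stack"))
  if (!identical(dim(crop_mask), dim(stack$data)[1:2]))
    stop("crop mask geometry does not match stack")
  out <- stack
  idx <- which(!crop_mask)
  if (length(idx)) {
    npx <- prod(dim(stack$data)[1:2])
    for (k in seq_len(dim(stack$data)[3]))
      out$data[idx + (k - 1L) * npx] <- NA_real_
  }
  out
}

#' Select the composites falling in a phenology window
#'
#' A composite belongs to the growing window iff its start day-of-year `d`
#' satisfies `start <= d <= end` (inclusive, no fractional weighting).
#'
#' @param start_doy,end_doy window bounds (day-of-year, `start < end`).
#' @param doys composite start day-of-years (default the 46-period ladder).
#' @return integer indices into `doys`.
#' @export
select_window_composites <- function(start_doy, end_doy, doys = composite_doys()) {
  stopifnot(start_doy <= end_doy)
  idx <- which(doys >= start_doy & doys <= end_doy)
  if (!length(idx))
    stop("phenology window [", start_doy, ", ", end_doy,
         "] contains no composite start")
  idx
}

#' Per-pixel phenology map
#'
#' @param year integer year label.
#' @param crop `"maize"` or `"wheat"`.
#' @param start_doy,end_doy integer matrices of window bounds (day-of-year);
#'   `1 <= start < end <= 365` wherever defined.
#' @return object of class `phenology_map`.
#' @export
phenology_map <- function(year, crop, start_doy, end_doy) {
  stopifnot(identical(dim(start_doy), dim(end_doy)))
  ok <- !is.na(start_doy) & !is.na(end_doy)
  if (any(start_doy[ok] >= end_doy[ok]) ||
      any(start_doy[ok] < 1) || any(end_doy[ok] > 365))
    stop("phenology windows must satisfy 1 <= start < end <= 365")
  structure(list(year = as.integer(year), crop = crop,
                 start_doy = start_doy, end_doy = end_doy),
            class = "phenology_map")
}

#' Aggregate a composite stack over per-pixel phenology windows
#'
#' For every pixel, applies `statistic` ("sum" for ET/GPP/Ts, "mean" for LAI)
#' over the composites whose start day-of-year falls inside that pixel's
#' growing window. Missing layers inside the window are tolerated up to
#' `max_missing_frac` of the selected composites: a sum is rescaled by
#' (selected / valid) to a full-window total and a mean uses valid layers
#' only; beyond the tolerance the pixel becomes nodata.
#'
#' @param stack a [composite_stack()].
#' @param phenology a [phenology_map()] for the same year and geometry.
#' @param statistic `"sum"` or `"mean"`.
#' @param max_missing_frac maximum tolerated fraction of nodata composites
#'   within the window (default 0.2).
#' @return numeric matrix (annual windowed raster), `NA` where undefined.
#' @export
window_cumulate <- function(stack, phenology, statistic = c("sum", "mean"),
                            max_missing_frac = 0.2) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(stack, "composite_stack"),
            inherits(phenology, "phenology_map"))
  if (!identical(dim(phenology$start_doy), dim(stack$data)[1:2]))
    stop("phenology geometry does not match stack")
  nr <- dim(stack$data)[1]; nc <- dim(stack$data)[2]
  acc <- matrix(0, nr, nc)       # sum over valid in-window layers
  n_sel <- matrix(0L, nr, nc)    # selected composites per pixel
  n_val <- matrix(0L, nr, nc)    # of which valid (non-nodata)
  for (k in seq_along(stack$doys)) {
    d <- stack$doys[k]
    inwin <- !is.na(phenology$start_doy) & !is.na(phenology$end_doy) &
      phenology$start_doy <= d & phenology$end_doy >= d
    layer <- stack$data[, , k]
    val <- inwin & !is.na(layer)
    n_sel <- n_sel + inwin
    n_val <- n_val + val
    acc[val] <- acc[val] + layer[val]
  }
  out <- matrix(NA_real_, nr, nc)
  ok <- n_sel > 0L & (n_sel - n_val) <= max_missing_frac * n_sel
  if (statistic == "sum") {
    out[ok] <- acc[ok] * (n_sel[ok] / n_val[ok])
  } else {
    out[ok] <- acc[ok] / n_val[ok]
  }
  out
}

#' Zonal mean of an annual raster over counties
#'
#' Unweighted mean over valid crop pixels per county; counties with no valid
#' crop pixel are omitted.
#'
#' @param raster numeric matrix.
#' @param county_map integer matrix of county labels (`NA` = no county).
#' @param crop_mask optional logical matrix restricting the pixels used.
#' @return data.frame with columns `county_id`, `value`, `n_pixels`.
#' @export
zonal_aggregate <- function(raster, county_map, crop_mask = NULL) {
  stopifnot(identical(dim(raster), dim(county_map)))
  keep <- !is.na(raster) & !is.na(county_map)
  if (!is.null(crop_mask)) {
    stopifnot(identical(dim(crop_mask), dim(raster)))
    keep <- keep & crop_mask
  }
  if (!any(keep))
    return(data.frame(county_id = integer(), value = numeric(),
                      n_pixels = integer()))
  ids <- county_map[keep]
  vals <- raster[keep]
  mu <- tapply(vals, ids, mean)
  n <- tapply(vals, ids, length)
  data.frame(county_id = as.integer(names(mu)),
             value = as.numeric(mu),
             n_pixels = as.integer(n),
             row.names = NULL)
}

#' Build the county-year feature table for yield modelling
#'
#' Joins per-county zonal means of the windowed indicator rasters (cumET,
#' cumGPP, cumTs, meanLAI) and the static soil rasters (clay/sand/silt) with
#' the recorded county yields; the result is the model's feature table, one
#' row per (county, year) present in both sources (inner join).
#'
#' @param indicator_rasters named list of lists:
#'   `indicator_rasters[[as.character(year)]]` is a named list with elements
#'   `cumET`, `cumGPP`, `cumTs`, `meanLAI` (annual matrices).
#' @param soil named list with matrices `clay`, `sand`, `silt` (static).
#' @param county_map integer county-label matrix.
#' @param crop_mask named list of logical matrices per year (or one matrix
#'   used for all years).
#' @param yields data.frame with columns `county_id`, `year`, `yield_kg_ha`,
#'   `planting_area_ha`.
#' @return data.frame with one row per county-year and columns
#'   `county_id, year, cumET, cumGPP, cumTs, meanLAI, clay, sand, silt,
#'   yield_kg_ha, planting_area_ha`.
#' @export
build_feature_table <- function(indicator_rasters, soil, county_map,
                                crop_mask, yields) {
  req <- c("county_id", "year", "yield_kg_ha", "planting_area_ha")
  if (!all(req %in% names(yields)))
    stop("yield table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(yields[c("county_id", "year")]))
    stop("duplicate (county_id, year) keys in yield table")
  years <- names(indicator_rasters)
  rows <- lapply(years, function(yr) {
    msk <- if (is.list(crop_mask)) crop_mask[[yr]] else crop_mask
    feats <- indicator_rasters[[yr]]
    stopifnot(all(c("cumET", "cumGPP", "cumTs", "meanLAI") %in% names(feats)))
    tabs <- lapply(c(feats, soil[c("clay", "sand", "silt")]), function(r)
      zonal_aggregate(r, county_map, msk))
    ids <- Reduce(intersect, lapply(tabs, `[[`, "county_id"))
    out <- data.frame(county_id = ids, year = as.integer(yr))
    for (nm in names(tabs)) {
      t <- tabs[[nm]]
      out[[nm]] <- t$value[match(ids, t$county_id)]
    }
    out
  })
  feat <- do.call(rbind, rows)
  out <- merge(feat, yields[req], by = c("county_id", "year"))
  out <- out[order(out$year, out$county_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
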