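# End-to-end convenience wrappers: from a (synthetic) world to windowed
# indicator rasters, the county feature table, a trained model and the full
# validation report.

#' Windowed annual indicator rasters for one year of a world
#'
#' Masks each 8-day stack with the year's crop mask and aggregates it over the
#' per-pixel phenology window: cumulative ET/GPP/Ts, mean LAI.
#'
#' @param world a `synthetic_world`.
#' @param year integer year.
#' @return named list of matrices `cumET`, `cumGPP`, `cumTs`, `meanLAI`.
#' @export
world_annual_rasters <- function(world, year) {
  ykey <- as.character(year)
  st <- world$stacks[[ykey]]
  phen <- world$phenology[[ykey]]
  msk <- world$crop_mask[[ykey]]
  list(
    cumET = window_cumulate(mask_cropland(st$ET, msk), phen, "sum"),
    cumGPP = window_cumulate(mask_cropland(st$GPP, msk), phen, "sum"),
    cumTs = window_cumulate(mask_cropland(st$Ts, msk), phen, "sum"),
    meanLAI = window_cumulate(mask_cropland(st$LAI, msk), phen, "mean"))
}

#' County feature table of a world (all years)
#'
#' @param world a `synthetic_world`.
#' @return feature table from [build_feature_table()].
#' @export
world_feature_table <- function(world) {
  annual <- lapply(world$years, function(y) world_annual_rasters(world, y))
  names(annual) <- as.character(world$years)
  yields <- world$county_yields[c("county_id", "year", "yield_kg_ha",
                                  "planting_area_ha")]
  build_feature_table(annual, world$soil, world$county_map,
                      world$crop_mask, yields)
}

#' Run the full yield/CWP estimation pipeline on a world
#'
#' Screens the county yield records, builds the feature table, splits it with
#' forced extremes, trains the random forest on the chosen indicators,
#' validates on the held-out counties (metrics and Moran's I of county
#' residuals), predicts pixel yield rasters for every year, validates them
#' against the point-scale records, and computes CWP rasters and their
#' regional summary.
#'
#' @param world a `synthetic_world`.
#' @param indicators indicator subset (default all four).
#' @param seed integer pipeline seed (default the world's seed).
#' @param fraction training fraction (default 0.8).
#' @param rules screening rules (default the world's crop, neutral on clean
#'   synthetic tables).
#' @return list: `model`, `features`, `split`, `regional` (test metrics),
#'   `moran_i`, `yield_rasters`, `point` (point-scale metrics), `cwp`
#'   (per-year `cwp_raster`s), `cwp_summary` (pooled regional summary of
#'   year-1), `filter_audit`.
#' @export
run_yield_pipeline <- function(world, indicators = INDICATOR_COLS,
                               seed = world$config$seed, fraction = 0.8,
                               rules = filter_rules(world$config$crop)) {
  features <- world_feature_table(world)
  scr <- filter_yield_records(features, rules)
  split <- split_train_test(scr$table, fraction, seed)
  model <- train_rf(split$train, indicators, seed)
  pred <- predict_table(model, split$test)
  regional <- metrics(pred, split$test$yield_kg_ha,
                      m = length(model$feature_cols))
  adj <- build_adjacency(world$county_map)
  mi <- moran_of_residuals(pred - split$test$yield_kg_ha,
                           split$test$county_id, adj)

  yield_rasters <- list(); cwp <- list()
  for (y in world$years) {
    ykey <- as.character(y)
    annual <- world_annual_rasters(world, y)
    yr_raster <- predict_pixels(model, annual, world$soil,
                                world$crop_mask[[ykey]])
    yield_rasters[[ykey]] <- yr_raster
    cwp[[ykey]] <- compute_cwp(yr_raster, annual$cumET)
  }
  # point records span years; extract each from its year's raster
  pp <- world$point_yields
  pred_pts <- vapply(seq_len(nrow(pp)), function(i) {
    yield_rasters[[as.character(pp$year[i])]][pp$row[i], pp$col[i]]
  }, numeric(1))
  ok <- !is.na(pred_pts)
  if (sum(ok) < 2) stop("too few usable point-validation sites")
  point <- metrics(pred_pts[ok], pp$yield_kg_ha[ok],
                   m = length(model$feature_cols))

  list(model = model, features = scr$table, split = split,
       regional = regional, moran_i = mi,
       yield_rasters = yield_rasters, point = point, cwp = cwp,
       cwp_summary = regional_summary(cwp[[1]], world$county_map),
       filter_audit = scr$audit)
}
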