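# County-yield record screening, random-forest yield regression, the
# indicator-combination search, and pixel-level prediction.

# canonical indicator feature columns, in training order
INDICATOR_COLS <- c("cumET", "cumGPP", "cumTs", "meanLAI")
SOIL_COLS <- c("clay", "sand", "silt")

# biophysically attainable yield ranges [kg/ha] used to screen records
YIELD_BOUNDS <- list(maize = c(500, 15000), wheat = c(500, 13000))

#' Screening rules for recorded county yields
#'
#' Records are excluded when outside the biophysically attainable range
#' (maize: 500-15,000 kg/ha; wheat: 500-13,000 kg/ha), when further than
#' `sd_multiplier` standard deviations from their county's study-period mean,
#' or by the planting-area rule. The printed source of the area rule reads as
#' excluding counties with *more* than the threshold of planting area, which
#' is kept as the literal default (`exclude_above`); the audit trail makes the
#' consequence visible and `exclude_below` is available.
#'
#' @param crop `"maize"` or `"wheat"` (sets the default bounds).
#' @param lower_bound,upper_bound attainable yield range [kg/ha].
#' @param sd_multiplier SD-rule width (default 3).
#' @param area_threshold planting-area threshold [ha] (default 10000).
#' @param area_rule_direction `"exclude_above"` (literal default) or
#'   `"exclude_below"`.
#' @return object of class `filter_rules`.
#' @export
filter_rules <- function(crop = c("maize", "wheat"),
                         lower_bound = NULL, upper_bound = NULL,
                         sd_multiplier = 3, area_threshold = 10000,
                         area_rule_direction = c("exclude_above",
                                                 "exclude_below")) {
  crop <- match.arg(crop)
  b <- YIELD_BOUNDS[[crop]]
  lower_bound <- if (is.null(lower_bound)) b[1] else lower_bound
  upper_bound <- if (is.null(upper_bound)) b[2] else upper_bound
  stopifnot(lower_bound < upper_bound, sd_multiplier > 0, area_threshold > 0)
  structure(list(crop = crop, lower_bound = lower_bound,
                 upper_bound = upper_bound, sd_multiplier = sd_multiplier,
                 area_threshold = area_threshold,
                 area_rule_direction = match.arg(area_rule_direction)),
            class = "filter_rules")
}

#' Screen county yield records for outliers
#'
#' One pass over the original table (county means/SDs are not re-estimated
#' after removals). Each removed row is attributed to the first rule it
#' violates, in the order bounds, SD rule, area rule, so audit counts are
#' unambiguous. The SD rule uses each county's across-year mean and sample SD
#' and is skipped (and flagged) for counties with a single record.
#'
#' @param table data.frame with columns `county_id`, `year`, `yield_kg_ha`,
#'   `planting_area_ha`.
#' @param rules a [filter_rules()].
#' @return list with `table` (surviving rows), and `audit`: a list holding
#'   per-rule removal `counts` (`below_bound`, `above_bound`, `sd_rule`,
#'   `area_rule`), the removed row indices per rule, and
#'   `single_year_counties` where the SD rule could not be applied.
#' @export
filter_yield_records <- function(table, rules = filter_rules()) {
  stopifnot(all(c("county_id", "year", "yield_kg_ha", "planting_area_ha")
                %in% names(table)))
  y <- table$yield_kg_ha
  below <- y < rules$lower_bound
  above <- y > rules$upper_bound

  mu <- tapply(y, table$county_id, mean)
  sdv <- tapply(y, table$county_id, stats::sd)
  nrec <- tapply(y, table$county_id, length)
  key <- as.character(table$county_id)
  single <- names(nrec)[nrec < 2]
  sd_viol <- abs(y - mu[key]) > rules$sd_multiplier * sdv[key]
  sd_viol[is.na(sd_viol)] <- FALSE # single-record counties: rule skipped

  area_viol <- if (rules$area_rule_direction == "exclude_above")
    table$planting_area_ha > rules$area_threshold
  else
    table$planting_area_ha < rules$area_threshold

  cls <- rep(NA_character_, nrow(table))
  cls[area_viol] <- "area_rule"
  cls[sd_viol] <- "sd_rule"
  cls[above] <- "above_bound"
  cls[below] <- "below_bound"
  keep <- is.na(cls)
  counts <- vapply(c("below_bound", "above_bound", "sd_rule", "area_rule"),
                   function(k) sum(cls == k, na.rm = TRUE), integer(1))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out,
       audit = list(counts = counts,
                    removed = split(which(!keep), cls[!keep]),
                    single_year_counties = as.integer(single)))
}

#' Train/test split with forced yield extremes in training
#'
#' Randomly assigns `ceiling(fraction * n)` rows to training, forcing the rows
#' holding the global minimum and maximum yield into the training set (so the
#' forest never extrapolates at validation time). Ties at an extreme force
#' only the first tied row in table order.
#'
#' @param table feature table with a `yield_kg_ha` column.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with data.frames `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(table, fraction = 0.8, seed = 1) {
  n <- nrow(table)
  stopifnot(n >= 5, fraction > 0, fraction < 1,
            "yield_kg_ha" %in% names(table))
  n_train <- ceiling(fraction * n)
  forced <- unique(c(which.min(table$yield_kg_ha),
                     which.max(table$yield_kg_ha)))
  stopifnot(n_train >= length(forced))
  pool <- setdiff(seq_len(n), forced)
  set.seed(spawn_seed(seed, "split"))
  extra <- sort(sample(pool, n_train - length(forced)))
  train_idx <- sort(c(forced, extra))
  list(train = table[train_idx, , drop = FALSE],
       test = table[setdiff(seq_len(n), train_idx), , drop = FALSE])
}

#' Train the random-forest yield model
#'
#' Fits a regression forest of 100 trees with 4 candidate variables per split
#' (capped at the available feature count), bootstrap-resampled per tree; the
#' prediction is the mean over trees. Features are the selected windowed
#' indicators plus the three soil-texture columns, which are always included.
#'
#' @param train feature table with the indicator/soil columns and
#'   `yield_kg_ha`.
#' @param indicators subset of `c("cumET", "cumGPP", "cumTs", "meanLAI")`.
#' @param seed integer seed.
#' @param n_trees,vars_per_split forest size and per-split candidate count
#'   (defaults 100 and 4).
#' @return object of class `yield_rf`: the fitted forest, its feature column
#'   order, indicator set, seed and a training manifest.
#' @export
train_rf <- function(train, indicators = INDICATOR_COLS, seed = 1,
                     n_trees = 100, vars_per_split = 4) {
  stopifnot(nrow(train) > 0, length(indicators) > 0,
            all(indicators %in% INDICATOR_COLS))
  feature_cols <- c(INDICATOR_COLS[INDICATOR_COLS %in% indicators], SOIL_COLS)
  missing_cols <- setdiff(c(feature_cols, "yield_kg_ha"), names(train))
  if (length(missing_cols))
    stop("training table lacks columns: ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(train[feature_cols])
  y <- train$yield_kg_ha
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite feature or yield values in training data")
  mtry <- min(vars_per_split, ncol(x))
  set.seed(spawn_seed(seed, "rf"))
  forest <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                       mtry = mtry)
  structure(list(forest = forest,
                 indicators = INDICATOR_COLS[INDICATOR_COLS %in% indicators],
                 soil_cols = SOIL_COLS,
                 feature_cols = feature_cols,
                 n_trees = n_trees, vars_per_split = mtry, seed = seed,
                 manifest = list(n_rows = nrow(train),
                                 yield_range = range(y),
                                 counties = sort(unique(train$county_id)),
                                 years = sort(unique(train$year)))),
            class = "yield_rf")
}

#' @export
print.yield_rf <- function(x, ...) {
  cat(sprintf("<yield_rf: %d trees, mtry %d, features: %s; %d training rows>\n",
              x$n_trees, x$vars_per_split,
              paste(x$feature_cols, collapse = ", "), x$manifest$n_rows))
  invisible(x)
}

# predict on a feature table using the stored column order (internal)
predict_table <- function(model, table) {
  stopifnot(inherits(model, "yield_rf"))
  missing_cols <- setdiff(model$feature_cols, names(table))
  if (length(missing_cols))
    stop("table lacks model features: ", paste(missing_cols, collapse = ", "))
  as.numeric(stats::predict(model$forest,
                            newdata = as.matrix(table[model$feature_cols])))
}

#' Evaluate every indicator combination on a common train/test split
#'
#' Trains a forest for each of the 15 non-empty subsets of
#' {cumET, cumGPP, cumTs, meanLAI} (soil columns always included) on the same
#' split and reports the test-split accuracy metrics, plus Global Moran's I of
#' the county-mean test residuals when an adjacency structure is supplied.
#'
#' @param table full feature table (all seven features plus `yield_kg_ha`).
#' @param seed integer seed controlling the split and all forests.
#' @param adjacency optional result of [build_adjacency()]; Moran's I is `NA`
#'   when absent or when fewer than 3 test counties are connected.
#' @param fraction training fraction (default 0.8).
#' @return data.frame with one row per combination: `combo`, `n_indicators`,
#'   metrics columns, and `moran_i`.
#' @export
combo_search <- function(table, seed = 1, adjacency = NULL, fraction = 0.8) {
  split <- split_train_test(table, fraction, seed)
  combos <- unlist(lapply(seq_along(INDICATOR_COLS), function(k)
    utils::combn(INDICATOR_COLS, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(combos, function(ind) {
    model <- train_rf(split$train, ind,
                      seed = spawn_seed(seed, paste(ind, collapse = "+")))
    pred <- predict_table(model, split$test)
    met <- metrics(pred, split$test$yield_kg_ha,
                   m = length(model$feature_cols))
    mi <- moran_of_residuals(pred - split$test$yield_kg_ha,
                             split$test$county_id, adjacency)
    cbind(data.frame(combo = paste(ind, collapse = "+"),
                     n_indicators = length(ind)),
          met, data.frame(moran_i = mi))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Moran's I of county-mean residuals on the sub-graph of counties present
# (internal); NA when infeasible rather than an error, since validation splits
# can leave too few connected counties.
moran_of_residuals <- function(residuals, county_id, adjacency) {
  if (is.null(adjacency)) return(NA_real_)
  mu <- tapply(residuals, county_id, mean)
  ids <- as.integer(names(mu))
  sel <- match(ids, adjacency$ids)
  if (anyNA(sel) || length(ids) < 3) return(NA_real_)
  W <- adjacency$W[sel, sel, drop = FALSE]
  S <- sum(W)
  if (S == 0 || stats::var(as.numeric(mu)) == 0) return(NA_real_)
  tryCatch(morans_i(as.numeric(mu), list(ids = ids, W = W, S = S)),
           error = function(e) NA_real_)
}

#' Predict a pixel-level annual yield raster
#'
#' Applies the trained forest to every crop pixel whose features are all
#' valid, using the training feature-column order; everything else is nodata.
#'
#' @param model a [train_rf()] model.
#' @param indicator_rasters named list of annual matrices (`cumET`, `cumGPP`,
#'   `cumTs`, `meanLAI`; only the model's indicators are required).
#' @param soil named list of matrices `clay`, `sand`, `silt`.
#' @param crop_mask logical matrix.
#' @return numeric matrix of predicted yield [kg/ha], `NA` elsewhere.
#' @export
predict_pixels <- function(model, indicator_rasters, soil, crop_mask) {
  stopifnot(inherits(model, "yield_rf"))
  rasters <- c(indicator_rasters, soil)
  missing_cols <- setdiff(model$feature_cols, names(rasters))
  if (length(missing_cols))
    stop("missing feature rasters: ", paste(missing_cols, collapse = ", "))
  dims <- dim(crop_mask)
  feats <- vapply(model$feature_cols, function(nm) {
    r <- rasters[[nm]]
    stopifnot(identical(dim(r), dims))
    as.vector(r)
  }, numeric(prod(dims)))
  ok <- as.vector(crop_mask) & apply(is.finite(feats), 1, all)
  out <- rep(NA_real_, prod(dims))
  if (any(ok)) {
    colnames(feats) <- model$feature_cols
    out[ok] <- as.numeric(stats::predict(model$forest,
                                         newdata = feats[ok, , drop = FALSE]))
  }
  matrix(out, dims[1], dims[2])
}

#' Validate a yield raster against point-scale measurements
#'
#' Extracts the predicted pixel at each measurement site and computes the
#' accuracy metrics against the measured yields. Sites off the grid or on
#' nodata pixels are dropped with a warning. With a single usable site the
#' R-squared values are undefined (`NA`) but RMSE/MBE are still computed.
#'
#' @param yield_raster predicted yield matrix [kg/ha].
#' @param point_yields data.frame with columns `row`, `col`, `yield_kg_ha`
#'   (optionally `year`, `site_id`).
#' @param m number of model variables for the R-squared adjustment.
#' @return one-row data.frame of metrics (see [metrics()]); for a single
#'   site, a one-row data.frame with `rmse`/`mbe` only.
#' @export
point_validate <- function(yield_raster, point_yields, m = 7) {
  stopifnot(all(c("row", "col", "yield_kg_ha") %in% names(point_yields)))
  nr <- nrow(yield_raster); nc <- ncol(yield_raster)
  on_grid <- point_yields$row >= 1 & point_yields$row <= nr &
    point_yields$col >= 1 & point_yields$col <= nc
  pred <- rep(NA_real_, nrow(point_yields))
  pred[on_grid] <- yield_raster[cbind(point_yields$row[on_grid],
                                      point_yields$col[on_grid])]
  usable <- !is.na(pred)
  if (any(!usable))
    warning(sum(!usable), " site(s) off-grid or on nodata pixels dropped")
  if (!any(usable)) stop("no usable validation site")
  M <- pred[usable]; O <- point_yields$yield_kg_ha[usable]
  if (length(M) == 1) {
    return(data.frame(n = 1L, m = m, r2_var_ratio = NA_real_,
                      r2_conventional = NA_real_,
                      rmse = abs(M - O), rrmse = abs(M - O) / O * 100,
                      mbe = M - O))
  }
  metrics(M, O, m = m)
}
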