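# Synthetic-world generator: a toy 1-km landscape with known generative
# ground truth, so every downstream stage (windowed aggregation, yield
# regression, CWP, flux QC, validation) can be exercised and checked against
# the truth without any external data.

#' Configuration of a synthetic world
#'
#' The generative pixel yield is
#' `Y = b0 + b_gpp * cumGPP + b_lai * meanLAI + b_et * cumET
#'      - b_ts2 * (cumTs - t_opt)^2 + b_clay * clay + eps`,
#' with the cumulative/mean features taken over each pixel's phenology window
#' by exactly the same rule as [window_cumulate()], and
#' `eps ~ N(0, noise_sd_pixel)`. County observations are crop-pixel means of
#' the truth plus `N(0, noise_sd_county)` noise. Defaults are chosen so the
#' implied yields sit comfortably inside the attainable range of either crop,
#' with a county-level signal much stronger than the observation noise.
#'
#' @param grid_rows,grid_cols grid size in 1-km pixels (default 60 x 60).
#' @param n_years number of years (default 3).
#' @param counties_rows,counties_cols block partition of the grid into
#'   counties (default 5 x 5 = 25 counties); must divide the grid dims.
#' @param crop `"maize"` or `"wheat"`.
#' @param yield_coefficients named vector `b0, b_gpp, b_lai, b_et, b_ts2,
#'   b_clay, t_opt` of generative weights.
#' @param noise_sd_pixel,noise_sd_county yield noise SDs [kg/ha].
#' @param closure_ratio target mean energy-balance closure ratio of the
#'   synthetic flux towers, in (0, 1.2].
#' @param outlier_spec named integer counts of outlier classes to plant in the
#'   county yield table (`below_bound`, `above_bound`, `sd_rule`,
#'   `area_rule`); all zero by default.
#' @param n_point_sites point-scale yield measurement sites (default 15).
#' @param n_towers synthetic flux towers (default 2).
#' @param seed integer pipeline seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(grid_rows = 60, grid_cols = 60, n_years = 3,
                       counties_rows = 5, counties_cols = 5,
                       crop = c("maize", "wheat"),
                       yield_coefficients = c(b0 = 1500, b_gpp = 5,
                                              b_lai = 400, b_et = 6,
                                              b_ts2 = 0.05, b_clay = 15,
                                              t_opt = 380),
                       noise_sd_pixel = 300, noise_sd_county = 100,
                       closure_ratio = 0.85,
                       outlier_spec = c(below_bound = 0L, above_bound = 0L,
                                        sd_rule = 0L, area_rule = 0L),
                       n_point_sites = 15, n_towers = 2, seed = 1) {
  crop <- match.arg(crop)
  stopifnot(grid_rows >= 1, grid_cols >= 1, n_years >= 1,
            counties_rows >= 1, counties_cols >= 1,
            noise_sd_pixel >= 0, noise_sd_county >= 0,
            closure_ratio > 0, closure_ratio <= 1.2,
            n_point_sites >= 1, n_towers >= 0)
  if (grid_rows %% counties_rows != 0 || grid_cols %% counties_cols != 0)
    stop("grid dimensions must be divisible by the county block partition")
  need <- c("b0", "b_gpp", "b_lai", "b_et", "b_ts2", "b_clay", "t_opt")
  if (!all(need %in% names(yield_coefficients)))
    stop("yield_coefficients must name: ", paste(need, collapse = ", "))
  spec <- c(below_bound = 0L, above_bound = 0L, sd_rule = 0L, area_rule = 0L)
  spec[names(outlier_spec)] <- as.integer(outlier_spec)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 n_years = as.integer(n_years),
                 counties_rows = as.integer(counties_rows),
                 counties_cols = as.integer(counties_cols),
                 crop = crop,
                 composite_doys = composite_doys(),
                 yield_coefficients = yield_coefficients[need],
                 noise_sd_pixel = noise_sd_pixel,
                 noise_sd_county = noise_sd_county,
                 closure_ratio = closure_ratio,
                 outlier_spec = spec,
                 n_point_sites = as.integer(n_point_sites),
                 n_towers = as.integer(n_towers),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# smooth random field in roughly [0, 1]: a standardized low-order polynomial
# trend plus Gaussian-kernel-smoothed noise (internal)
smooth_field <- function(nr, nc, trend_amp = 0.35, noise_amp = 0.12) {
  xs <- if (nc > 1) seq(-1, 1, length.out = nc) else 0
  ys <- if (nr > 1) seq(-1, 1, length.out = nr) else 0
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  a <- stats::rnorm(5)
  tr <- a[1] * X + a[2] * Y + a[3] * X * Y + a[4] * X^2 + a[5] * Y^2
  if (stats::sd(tr) > 0) tr <- tr / stats::sd(tr)
  z <- smooth_noise(nr, nc)
  f <- 0.5 + trend_amp * tr + noise_amp * z
  pmin(pmax(f, 0.01), 0.99)
}

# Gaussian-smoothed unit-variance white noise (internal)
smooth_noise <- function(nr, nc) {
  ksd <- max(1, min(nr, nc) / 10)
  half <- min(ceiling(3 * ksd), floor((min(nr, nc) - 1) / 2))
  w <- stats::dnorm(seq(-half, half), sd = ksd)
  w <- w / sum(w)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (length(w) > 1) {
    z <- apply(z, 2, function(col) stats::filter(col, w, circular = TRUE))
    z <- t(apply(z, 1, function(row) stats::filter(row, w, circular = TRUE)))
  }
  z <- matrix(as.numeric(z), nr, nc)
  if (stats::sd(z) > 0) z / stats::sd(z) else z
}

# seasonal weight of an 8-day composite starting at day-of-year d (internal)
season_bump <- function(d, peak = 200, width = 80, floor = 0.1) {
  floor + (1 - floor) * exp(-((d - peak) / width)^2)
}

#' Generate a synthetic world
#'
#' Builds, reproducibly from `config$seed`: spatially smooth 8-day indicator
#' stacks (ET mm/8d, GPP g C/m2/8d, Ts degC, LAI) for each year; static soil
#' texture rasters summing to 100 percent; a block county partition; yearly
#' crop masks and phenology windows (start DOY in [90, 130], end in
#' [230, 280], smooth in space, never wrapping the calendar year); per-pixel
#' true yields from the generative model of [sim_config()]; county and
#' point-scale yield observations derived from the truth; and daily flux-tower
#' energy-balance series whose corrected, re-cumulated ET matches the ET stack
#' at the tower pixel and whose mean closure ratio is `config$closure_ratio`.
#'
#' Fails (rather than clipping) if the implied yields fall systematically
#' outside the crop's attainable range.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_world`.
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  geom <- grid_geom(nr, nc)
  doys <- config$composite_doys
  years <- seq_len(config$n_years)
  b <- config$yield_coefficients
  bounds <- YIELD_BOUNDS[[config$crop]]

  # county partition: row-major block labels
  br <- nr %/% config$counties_rows; bc <- nc %/% config$counties_cols
  county_map <- outer(ceiling(seq_len(nr) / br) - 1L,
                      ceiling(seq_len(nc) / bc),
                      function(i, j) i * config$counties_cols + j)
  storage.mode(county_map) <- "integer"

  # static soil texture: three positive smooth fields normalised to 100%
  set.seed(spawn_seed(config$seed, "soil"))
  raw <- list(clay = 0.15 + 0.7 * smooth_field(nr, nc),
              sand = 0.15 + 0.7 * smooth_field(nr, nc),
              silt = 0.15 + 0.7 * smooth_field(nr, nc))
  tot <- raw$clay + raw$sand + raw$silt
  soil <- lapply(raw, function(r) r / tot * 100)

  ind_base <- list(ET = function(u) 10 + 20 * u,
                   GPP = function(u) 30 + 50 * u,
                   LAI = function(u) 1 + 4 * u)
  units <- c(ET = "mm/8d", GPP = "gC/m2/8d", Ts = "degC", LAI = "-")

  stacks <- list(); crop_mask <- list(); phenology <- list()
  truth <- list(); county_rows <- list()
  set.seed(spawn_seed(config$seed, "fields"))
  area_frac <- stats::runif(max(county_map), 0.2, 0.6)

  for (yr in years) {
    ykey <- as.character(yr)
    set.seed(spawn_seed(config$seed, paste0("year-", yr)))

    # threshold the mask field within each county so every county keeps crop
    # pixels (the partition arithmetic of the county table stays exact)
    msk_field <- smooth_field(nr, nc, trend_amp = 0.2, noise_amp = 0.25)
    thr <- tapply(as.vector(msk_field), as.vector(county_map),
                  stats::quantile, probs = 0.10)
    mask <- msk_field >= matrix(thr[as.character(county_map)], nr, nc)
    crop_mask[[ykey]] <- mask

    start <- round(90 + 40 * smooth_field(nr, nc))
    end <- round(230 + 50 * smooth_field(nr, nc))
    phen <- phenology_map(yr, config$crop, start, end)
    phenology[[ykey]] <- phen

    ystacks <- list()
    for (ind in c("ET", "GPP", "LAI")) {
      B <- ind_base[[ind]](smooth_field(nr, nc))
      arr <- array(NA_real_, c(nr, nc, length(doys)))
      for (k in seq_along(doys)) {
        w <- season_bump(doys[k])
        arr[, , k] <- B * w * (1 + 0.03 * stats::rnorm(nr * nc))
      }
      ystacks[[ind]] <- composite_stack(ind, yr, arr, doys, geom,
                                        unname(units[ind]))
    }
    uT <- smooth_field(nr, nc)
    arrT <- array(NA_real_, c(nr, nc, length(doys)))
    for (k in seq_along(doys)) {
      w <- exp(-((doys[k] - 200) / 90)^2)
      arrT[, , k] <- 2 + 20 * w + 6 * uT + 0.5 * stats::rnorm(nr * nc)
    }
    ystacks[["Ts"]] <- composite_stack("Ts", yr, arrT, doys, geom,
                                       unname(units["Ts"]))
    stacks[[ykey]] <- ystacks[c("ET", "GPP", "Ts", "LAI")]

    # generative features use the same window rule as the preprocessing stage
    cumET <- window_cumulate(ystacks$ET, phen, "sum")
    cumGPP <- window_cumulate(ystacks$GPP, phen, "sum")
    cumTs <- window_cumulate(ystacks$Ts, phen, "sum")
    meanLAI <- window_cumulate(ystacks$LAI, phen, "mean")

    y <- b["b0"] + b["b_gpp"] * cumGPP + b["b_lai"] * meanLAI +
      b["b_et"] * cumET - b["b_ts2"] * (cumTs - b["t_opt"])^2 +
      b["b_clay"] * soil$clay +
      config$noise_sd_pixel * stats::rnorm(nr * nc)
    frac_out <- mean(y[mask] < bounds[1] | y[mask] > bounds[2])
    if (frac_out > 0.005)
      stop(sprintf(paste("generative configuration places %.1f%% of true",
                         "yields outside the attainable range [%g, %g] kg/ha;",
                         "refusing to clip"),
                   100 * frac_out, bounds[1], bounds[2]))
    ytruth <- y
    ytruth[!mask] <- NA_real_
    truth[[ykey]] <- ytruth

    zt <- zonal_aggregate(ytruth, county_map, mask)
    county_rows[[ykey]] <- data.frame(
      county_id = zt$county_id, year = yr,
      yield_kg_ha = zt$value +
        config$noise_sd_county * stats::rnorm(nrow(zt)),
      planting_area_ha = zt$n_pixels * 100 * area_frac[zt$county_id])
  }

  county_yields <- do.call(rbind, county_rows)
  rownames(county_yields) <- NULL

  # point-scale yield records: the true pixel yield at sampled crop pixels
  set.seed(spawn_seed(config$seed, "points"))
  pts <- lapply(seq_len(config$n_point_sites), function(s) {
    yr <- sample(years, 1)
    ok <- which(crop_mask[[as.character(yr)]] &
                  !is.na(truth[[as.character(yr)]]))
    px <- sample(ok, 1)
    data.frame(site_id = s, row = row(county_map)[px],
               col = col(county_map)[px], year = yr,
               yield_kg_ha = truth[[as.character(yr)]][px])
  })
  point_yields <- do.call(rbind, pts)

  # flux towers: daily energy-balance series consistent with the year-1 ET
  # stack at the tower pixel, with the configured mean closure ratio
  set.seed(spawn_seed(config$seed, "flux"))
  flux <- list()
  if (config$n_towers > 0) {
    ok <- which(crop_mask[["1"]])
    tower_px <- sample(ok, config$n_towers)
    for (t in seq_len(config$n_towers)) {
      px <- tower_px[t]
      loc <- c(row(county_map)[px], col(county_map)[px])
      flux[[t]] <- make_flux_series(paste0("T", t), loc,
                                    stacks[["1"]]$ET, config$closure_ratio)
    }
  }

  structure(list(config = config, geom = geom, years = years,
                 county_map = county_map, soil = soil,
                 crop_mask = crop_mask, phenology = phenology,
                 stacks = stacks, county_yields = county_yields,
                 point_yields = point_yields, flux = flux,
                 truth = list(yield = truth,
                              coefficients = b)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world: %d x %d grid, %d counties, %d years,",
                     " crop %s, %d county-year records>\n"),
              x$geom$nrow, x$geom$ncol, max(x$county_map),
              length(x$years), x$config$crop, nrow(x$county_yields)))
  invisible(x)
}

# daily tower series whose Bowen-corrected, re-cumulated ET reproduces the ET
# stack at the tower pixel (internal)
make_flux_series <- function(tower_id, location, et_stack, closure_ratio,
                             bowen = 0.4, days_in_year = 365) {
  doys <- et_stack$doys
  nominal <- c(diff(doys), days_in_year - doys[length(doys)] + 1L)
  comp <- findInterval(seq_len(days_in_year), doys)
  et8 <- et_stack$data[location[1], location[2], ]
  mm_day <- et8[comp] / nominal[comp]
  lam_cor <- mm_day * LAMBDA_V / 86400
  ecr <- pmin(pmax(closure_ratio * (1 + 0.04 * stats::rnorm(days_in_year)),
                   0.3), 1.3)
  lam <- lam_cor * ecr
  H <- bowen * lam
  rn_g <- (H + lam) / ecr
  Rn <- rn_g / 0.85
  G <- 0.15 * Rn
  list(tower_id = tower_id, location = location,
       data = data.frame(doy = seq_len(days_in_year), Rn = Rn, G = G,
                         H = H, lam_ET = lam))
}

#' Plant known outliers into a county yield table
#'
#' Modifies rows so that each violates exactly one screening rule: yields
#' below/above the attainable bounds, an in-bounds value more than
#' `rules$sd_multiplier` SDs from its county mean, or a planting-area
#' violation. Classes are mutually exclusive per row and every injected row
#' sits in its own county, so the screening audit counts are exact. The
#' intended class is recorded in an `.outlier_class` column (an audit column
#' for test fixtures; the screening functions ignore it).
#'
#' An in-bounds SD outlier under an inclusive county mean/SD is attainable
#' only when the county has enough records (the maximum standardised
#' deviation of one of n values is (n-1)/sqrt(n)); the function errors when
#' the request is infeasible.
#'
#' @param table county yield table (`county_id`, `year`, `yield_kg_ha`,
#'   `planting_area_ha`).
#' @param spec named counts: `below_bound`, `above_bound`, `sd_rule`,
#'   `area_rule`.
#' @param seed integer seed.
#' @param rules the [filter_rules()] the outliers must violate.
#' @return the table with modified rows and an `.outlier_class` column.
#' @export
inject_outliers <- function(table, spec, seed = 1, rules = filter_rules()) {
  full <- c(below_bound = 0L, above_bound = 0L, sd_rule = 0L, area_rule = 0L)
  full[names(spec)] <- as.integer(spec)
  total <- sum(full)
  if (total > nrow(table)) stop("outlier spec larger than the table")
  out <- table
  out$.outlier_class <- NA_character_
  if (total == 0) return(out)

  set.seed(spawn_seed(seed, "outliers"))
  counties <- unique(table$county_id)
  if (total > length(counties))
    stop("need at least one distinct county per planted outlier")
  picked_counties <- sample(counties, total)
  ci <- 0L
  take_row <- function() {
    ci <<- ci + 1L
    rows <- which(table$county_id == picked_counties[ci])
    rows[sample.int(length(rows), 1)]
  }

  for (i in seq_len(full["below_bound"])) {
    r <- take_row()
    out$yield_kg_ha[r] <- stats::runif(1, 0.3, 0.9) * rules$lower_bound
    out$.outlier_class[r] <- "below_bound"
  }
  for (i in seq_len(full["above_bound"])) {
    r <- take_row()
    out$yield_kg_ha[r] <- stats::runif(1, 1.05, 1.3) * rules$upper_bound
    out$.outlier_class[r] <- "above_bound"
  }
  for (i in seq_len(full["sd_rule"])) {
    r <- take_row()
    others <- out$yield_kg_ha[out$county_id == out$county_id[r] &
                                seq_len(nrow(out)) != r]
    v <- plant_sd_outlier(others, rules)
    if (is.na(v))
      stop("cannot plant an in-bounds SD outlier in county ",
           out$county_id[r], " (", length(others) + 1,
           " records; need more years or looser bounds)")
    out$yield_kg_ha[r] <- v
    out$.outlier_class[r] <- "sd_rule"
  }
  for (i in seq_len(full["area_rule"])) {
    r <- take_row()
    out$planting_area_ha[r] <- if (rules$area_rule_direction == "exclude_above")
      1.5 * rules$area_threshold else 0.5 * rules$area_threshold
    out$.outlier_class[r] <- "area_rule"
  }
  out
}

# find an in-bounds value whose inclusive-z exceeds the multiplier (internal)
plant_sd_outlier <- function(others, rules) {
  z_of <- function(v) {
    y <- c(others, v)
    abs(v - mean(y)) / stats::sd(y)
  }
  margin <- 0.01 * (rules$upper_bound - rules$lower_bound)
  cand <- seq(rules$lower_bound + margin, rules$upper_bound - margin,
              length.out = 2001)
  z <- vapply(cand, z_of, numeric(1))
  ok <- which(z > rules$sd_multiplier)
  if (!length(ok)) return(NA_real_)
  # pick the most extreme feasible value for a clear margin
  cand[ok[which.max(z[ok])]]
}
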