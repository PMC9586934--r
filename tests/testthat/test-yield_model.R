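# Record screening, the forced-extremes split, the forest, the combination
# search and pixel-level prediction.

test_that("bound screening removes exactly the out-of-range records", {
  tab <- data.frame(county_id = 1:4, year = 1,
                    yield_kg_ha = c(400, 6000, 15500, 7000),
                    planting_area_ha = 5000)
  res <- filter_yield_records(tab, filter_rules("maize"))
  expect_equal(sort(res$table$yield_kg_ha), c(6000, 7000))
  expect_equal(unname(res$audit$counts[c("below_bound", "above_bound")]),
               c(1L, 1L))
  # single-year counties: SD rule skipped and flagged
  expect_equal(res$audit$single_year_counties, 1:4)
})

test_that("a clean table passes unchanged with an all-zero audit", {
  tab <- clean_yield_table(seed = 6)
  res <- filter_yield_records(tab, filter_rules("maize"))
  expect_equal(res$table[names(tab)], tab, ignore_attr = "row.names")
  expect_true(all(res$audit$counts == 0))
})

test_that("screening is idempotent", {
  tab <- inject_outliers(clean_yield_table(years = 12, seed = 7),
                         c(below_bound = 2, above_bound = 1, sd_rule = 1,
                           area_rule = 2), seed = 3)
  once <- filter_yield_records(tab, filter_rules("maize"))
  twice <- filter_yield_records(once$table, filter_rules("maize"))
  expect_equal(once$table, twice$table)
  expect_true(all(twice$audit$counts == 0))
})

test_that("audit counts equal the planted outlier spec exactly", {
  spec <- c(below_bound = 3, above_bound = 2, sd_rule = 2, area_rule = 3)
  tab <- inject_outliers(clean_yield_table(n_counties = 25, years = 12,
                                           seed = 8),
                         spec, seed = 5)
  res <- filter_yield_records(tab, filter_rules("maize"))
  expect_equal(res$audit$counts[names(spec)], spec,
               ignore_attr = TRUE)
  expect_equal(nrow(res$table), 25 * 12 - sum(spec))
  # and the removed rows are exactly the planted ones
  expect_true(all(is.na(res$table$.outlier_class)))
})

test_that("the planting-area rule direction is configurable", {
  tab <- clean_yield_table(n_counties = 5, years = 2, seed = 9)
  tab$planting_area_ha[3] <- 12000
  lit <- filter_yield_records(tab, filter_rules("maize"))
  expect_equal(unname(lit$audit$counts["area_rule"]), 1L)
  inv <- filter_yield_records(tab, filter_rules(
    "maize", area_rule_direction = "exclude_below"))
  expect_equal(unname(inv$audit$counts["area_rule"]), 9L)
})

test_that("the split forces yield extremes into training and is deterministic", {
  tab <- clean_yield_table(n_counties = 10, years = 1, seed = 10)
  for (s in 1:25) {
    sp <- split_train_test(tab, 0.8, seed = s)
    expect_equal(nrow(sp$train), 8)
    expect_equal(nrow(sp$test), 2)
    expect_true(min(tab$yield_kg_ha) %in% sp$train$yield_kg_ha)
    expect_true(max(tab$yield_kg_ha) %in% sp$train$yield_kg_ha)
    expect_equal(sort(c(sp$train$county_id, sp$test$county_id)),
                 sort(tab$county_id))
  }
  expect_identical(split_train_test(tab, 0.8, 3), split_train_test(tab, 0.8, 3))
  # ties at the minimum: exactly one tied row forced, the first in table order
  tied <- tab
  tied$yield_kg_ha[c(2, 5)] <- 1000
  sp <- split_train_test(tied, 0.6, seed = 2)
  expect_true(2 %in% as.integer(rownames(sp$train)))
  expect_error(split_train_test(tab, 1.2, 1))
})

test_that("a constant target yields constant forest predictions", {
  tab <- clean_yield_table(n_counties = 10, years = 2, seed = 11)
  ft <- cbind(tab, cumET = runif(20, 100, 300), cumGPP = runif(20, 300, 900),
              cumTs = runif(20, 300, 450), meanLAI = runif(20, 1, 4),
              clay = 30, sand = 40, silt = 30)
  ft$yield_kg_ha <- 4200
  # the constant target is deliberately degenerate; the forest warns about it
  model <- suppressWarnings(train_rf(ft, seed = 1))
  pred <- predict_pixels(model,
                         list(cumET = matrix(200, 2, 2),
                              cumGPP = matrix(500, 2, 2),
                              cumTs = matrix(400, 2, 2),
                              meanLAI = matrix(2, 2, 2)),
                         list(clay = matrix(30, 2, 2),
                              sand = matrix(40, 2, 2),
                              silt = matrix(30, 2, 2)),
                         matrix(TRUE, 2, 2))
  expect_equal(as.vector(pred), rep(4200, 4), tolerance = 1e-9)
})

test_that("forest averaging cannot extrapolate beyond the training range", {
  w <- default_world(1)
  ft <- world_feature_table(w)
  sp <- split_train_test(ft, 0.8, 1)
  model <- train_rf(sp$train, seed = 1)
  pred <- cropwater:::predict_table(model, ft)
  expect_true(all(pred >= min(sp$train$yield_kg_ha) - 1e-9))
  expect_true(all(pred <= max(sp$train$yield_kg_ha) + 1e-9))
  expect_error(train_rf(transform(sp$train, cumET = NA_real_), seed = 1),
               "non-finite")
})

test_that("the combination search reports all 15 subsets deterministically", {
  w <- default_world(1)
  ft <- world_feature_table(w)
  adj <- build_adjacency(w$county_map)
  rep1 <- combo_search(ft, seed = 2, adjacency = adj)
  expect_equal(nrow(rep1), 15)
  expect_equal(sum(rep1$n_indicators == 1), 4)
  expect_equal(sum(rep1$n_indicators == 4), 1)
  rep2 <- combo_search(ft, seed = 2, adjacency = adj)
  expect_identical(rep1, rep2)
  expect_true(all(is.finite(rep1$rmse)))
})

test_that("a single informative indicator dominates the combination ranking", {
  cfg <- sim_config(seed = 21, noise_sd_pixel = 50, noise_sd_county = 50,
                    yield_coefficients = c(b0 = 3000, b_gpp = 6, b_lai = 0,
                                           b_et = 0, b_ts2 = 0, b_clay = 0,
                                           t_opt = 380))
  w <- make_world(cfg)
  rep <- combo_search(world_feature_table(w), seed = 1)
  with_gpp <- grepl("cumGPP", rep$combo)
  expect_gt(min(rep$r2_conventional[with_gpp]),
            max(rep$r2_conventional[!with_gpp]))
})

test_that("pixel predictions agree with tabular predictions and honour nodata", {
  w <- make_world(tiny_config(seed = 14))
  ft <- world_feature_table(w)
  model <- train_rf(ft, seed = 3)
  row1 <- ft[1, ]
  const <- function(v) matrix(v, 2, 2)
  pred <- predict_pixels(model,
                         list(cumET = const(row1$cumET),
                              cumGPP = const(row1$cumGPP),
                              cumTs = const(row1$cumTs),
                              meanLAI = const(row1$meanLAI)),
                         list(clay = const(row1$clay), sand = const(row1$sand),
                              silt = const(row1$silt)),
                         matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  tab_pred <- cropwater:::predict_table(model, row1)
  expect_equal(pred[1, 1], tab_pred, tolerance = 1e-9)
  expect_true(is.na(pred[2, 2]))
  # nodata in a feature raster propagates
  holed <- const(row1$cumET); holed[1, 1] <- NA
  pred2 <- predict_pixels(model,
                          list(cumET = holed, cumGPP = const(row1$cumGPP),
                               cumTs = const(row1$cumTs),
                               meanLAI = const(row1$meanLAI)),
                          list(clay = const(row1$clay), sand = const(row1$sand),
                               silt = const(row1$silt)),
                          matrix(TRUE, 2, 2))
  expect_true(is.na(pred2[1, 1]))
  expect_false(anyNA(pred2[2:4]))
  expect_error(predict_pixels(model, list(cumET = holed), list(),
                              matrix(TRUE, 2, 2)), "missing feature")
})

test_that("point validation handles perfect sites, off-grid sites and n = 1", {
  r <- matrix(as.numeric(1:16) * 500, 4, 4)
  pts <- data.frame(row = c(1, 2, 3), col = c(1, 2, 3),
                    yield_kg_ha = c(r[1, 1], r[2, 2], r[3, 3]))
  met <- point_validate(r, pts, m = 1)
  expect_equal(met$rmse, 0)
  expect_equal(met$mbe, 0)
  off <- rbind(pts, data.frame(row = 99, col = 1, yield_kg_ha = 1000))
  expect_warning(met2 <- point_validate(r, off, m = 1), "off-grid")
  expect_equal(met2$n, 3)
  one <- data.frame(row = 2, col = 2, yield_kg_ha = r[2, 2] + 100)
  m1 <- point_validate(r, one)
  expect_true(is.na(m1$r2_conventional))
  expect_equal(m1$rmse, 100)
  expect_equal(m1$mbe, -100)
})

test_that("adding an informative indicator never systematically lowers held-out R2", {
  # noiseless worlds, mean over 10 seeds: every superset combination performs
  # at least as well as its nested subset (small Monte Carlo slack)
  mean_r2 <- NULL
  for (s in 1:10) {
    w <- make_world(sim_config(seed = s, noise_sd_pixel = 0,
                               noise_sd_county = 0))
    rep <- combo_search(world_feature_table(w), seed = s)
    if (is.null(mean_r2)) {
      mean_r2 <- rep[c("combo", "n_indicators")]
      mean_r2$r2 <- 0
    }
    mean_r2$r2 <- mean_r2$r2 + rep$r2_conventional / 10
  }
  combos <- strsplit(mean_r2$combo, "+", fixed = TRUE)
  for (i in seq_along(combos)) {
    for (j in seq_along(combos)) {
      if (length(combos[[j]]) == length(combos[[i]]) + 1 &&
          all(combos[[i]] %in% combos[[j]])) {
        expect_gte(mean_r2$r2[j], mean_r2$r2[i] - 0.02)
      }
    }
  }
  expect_equal(which.max(mean_r2$r2), which(mean_r2$n_indicators == 4))
})
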