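# Synthetic-world generator: determinism, structural invariants, the known
# generative truth, planted outliers, and lossless serialisation.

test_that("configs validate partition arithmetic and coefficient names", {
  expect_error(sim_config(grid_rows = 61), "divisible")
  expect_error(sim_config(yield_coefficients = c(b0 = 1)), "must name")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("identical config and seed give bit-identical worlds", {
  a <- make_world(tiny_config(seed = 9))
  b <- make_world(tiny_config(seed = 9))
  expect_identical(a$stacks, b$stacks)
  expect_identical(a$soil, b$soil)
  expect_identical(a$county_yields, b$county_yields)
  expect_identical(a$point_yields, b$point_yields)
  expect_identical(a$flux, b$flux)
  expect_identical(a$truth, b$truth)
  c <- make_world(tiny_config(seed = 10))
  expect_false(identical(a$county_yields, c$county_yields))
})

test_that("soil fractions lie on the 100% simplex everywhere", {
  w <- make_world(tiny_config(seed = 4))
  tot <- w$soil$clay + w$soil$sand + w$soil$silt
  expect_true(all(abs(tot - 100) <= 0.5))
  expect_true(all(w$soil$clay > 0 & w$soil$sand > 0 & w$soil$silt > 0))
})

test_that("phenology windows are ordered, bounded and never wrap the year", {
  w <- make_world(tiny_config(seed = 6))
  for (y in names(w$phenology)) {
    ph <- w$phenology[[y]]
    expect_true(all(ph$start_doy >= 1 & ph$start_doy <= 130))
    expect_true(all(ph$end_doy >= 230 & ph$end_doy <= 365))
    expect_true(all(ph$start_doy < ph$end_doy))
  }
})

test_that("the default world has the partition-forced county-year count", {
  w <- default_world(1)
  expect_equal(nrow(w$county_yields), 25 * 3)
  expect_equal(sort(unique(w$county_yields$county_id)), 1:25)
  expect_equal(length(w$stacks), 3)
  expect_equal(names(w$stacks[["1"]]), c("ET", "GPP", "Ts", "LAI"))
  expect_equal(dim(w$stacks[["1"]]$ET$data), c(60, 60, 46))
})

test_that("true yields stay inside the attainable range; hot configs fail loudly", {
  w <- default_world(1)
  for (y in names(w$truth$yield)) {
    v <- w$truth$yield[[y]]
    expect_true(all(v[!is.na(v)] > 500 & v[!is.na(v)] < 15000))
  }
  hot <- tiny_config(seed = 1,
                     yield_coefficients = c(b0 = 14000, b_gpp = 5, b_lai = 400,
                                            b_et = 6, b_ts2 = 0.05,
                                            b_clay = 15, t_opt = 380))
  expect_error(make_world(hot), "outside the attainable range")
})

test_that("a constant generative function with zero noise yields constant counties", {
  cfg <- tiny_config(seed = 2, noise_sd_pixel = 0, noise_sd_county = 0,
                     yield_coefficients = c(b0 = 6000, b_gpp = 0, b_lai = 0,
                                            b_et = 0, b_ts2 = 0, b_clay = 0,
                                            t_opt = 380))
  w <- make_world(cfg)
  expect_equal(w$county_yields$yield_kg_ha, rep(6000, nrow(w$county_yields)),
               tolerance = 1e-12)
})

test_that("with zero county noise, county yields equal crop-pixel truth means", {
  cfg <- tiny_config(seed = 5, noise_sd_county = 0)
  w <- make_world(cfg)
  for (y in w$years) {
    zt <- zonal_aggregate(w$truth$yield[[as.character(y)]], w$county_map,
                          w$crop_mask[[as.character(y)]])
    sub <- w$county_yields[w$county_yields$year == y, ]
    expect_equal(sub$yield_kg_ha[match(zt$county_id, sub$county_id)],
                 zt$value, tolerance = 1e-9)
  }
})

test_that("point records carry the true pixel yield of their site and year", {
  w <- make_world(tiny_config(seed = 7))
  for (i in seq_len(nrow(w$point_yields))) {
    p <- w$point_yields[i, ]
    expect_equal(p$yield_kg_ha,
                 w$truth$yield[[as.character(p$year)]][p$row, p$col])
  }
})

test_that("planted outliers each violate exactly their intended rule", {
  rules <- filter_rules("maize")
  tab <- clean_yield_table(n_counties = 25, years = 12, seed = 3)
  spec <- c(below_bound = 2, above_bound = 1, sd_rule = 2, area_rule = 2)
  out <- inject_outliers(tab, spec, seed = 11, rules = rules)
  expect_equal(sum(!is.na(out$.outlier_class)), sum(spec))
  below <- out$yield_kg_ha[out$.outlier_class %in% "below_bound"]
  expect_true(all(below < 500))
  expect_length(below, 2)
  above <- out$yield_kg_ha[out$.outlier_class %in% "above_bound"]
  expect_true(all(above > 15000))
  planted_sd <- which(out$.outlier_class %in% "sd_rule")
  for (r in planted_sd) {
    y <- out$yield_kg_ha[out$county_id == out$county_id[r]]
    v <- out$yield_kg_ha[r]
    expect_gt(abs(v - mean(y)), 3 * sd(y))
    expect_true(v > 500 && v < 15000)
  }
  expect_true(all(out$planting_area_ha[out$.outlier_class %in% "area_rule"]
                  > 10000))
  # empty spec is the identity (plus the audit column)
  same <- inject_outliers(tab, c(), seed = 1, rules = rules)
  expect_identical(same$yield_kg_ha, tab$yield_kg_ha)
  # wheat bound: above-bound outliers exceed 13,000 kg/ha
  wtab <- clean_yield_table(n_counties = 10, years = 3, base = 6000, seed = 4)
  wout <- inject_outliers(wtab, c(above_bound = 1), seed = 2,
                          rules = filter_rules("wheat"))
  expect_gt(wout$yield_kg_ha[!is.na(wout$.outlier_class)], 13000)
  # infeasible requests fail loudly
  expect_error(inject_outliers(tab, c(below_bound = 1000), seed = 1, rules),
               "larger than the table")
  short <- clean_yield_table(n_counties = 5, years = 3, seed = 5)
  expect_error(inject_outliers(short, c(sd_rule = 1), seed = 1, rules = rules),
               "cannot plant an in-bounds SD outlier")
})

test_that("write/read round-trips a world bit-exactly", {
  w <- make_world(tiny_config(seed = 12))
  dir <- withr::local_tempdir()
  manifest <- write_world(w, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # 4 indicators x n_years stacks listed
  roles <- vapply(manifest$files, function(f) f$role, character(1))
  expect_equal(sum(roles == "indicator_stack"), 4 * 2)
  w2 <- read_world(dir)
  expect_identical(w$stacks, w2$stacks)
  expect_identical(w$soil, w2$soil)
  expect_identical(w$county_map, w2$county_map)
  expect_identical(w$crop_mask, w2$crop_mask)
  expect_identical(w$truth$yield, w2$truth$yield)
  expect_equal(w$county_yields, w2$county_yields)
  expect_equal(w$point_yields, w2$point_yields)
  expect_equal(w$flux[[1]]$data, w2$flux[[1]]$data)
})

test_that("ENVI rasters declare 46 bands per stack and a safe nodata sentinel", {
  w <- make_world(tiny_config(seed = 13))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  r <- read_envi(file.path(dir, "stack_ET_year1"))
  expect_equal(dim(r$data)[3], 46)
  expect_equal(r$band_names[1], "doy_1")
  expect_equal(r$nodata, -9999)
  hdr <- readLines(file.path(dir, "stack_ET_year1.hdr"))
  expect_equal(hdr[1], "ENVI")
  expect_true(any(grepl("interleave = bsq", hdr)))
  # nodata collision with valid data is refused
  bad <- matrix(c(1, -9999, 3, 4), 2, 2)
  expect_error(write_envi(bad, tempfile()), "sentinel")
})
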