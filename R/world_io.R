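# On-disk serialisation of a synthetic world: ENVI flat-binary rasters
# (.dat + plain-text .hdr, float64 band-sequential, GDAL-readable), CSV
# tables written at full precision, and a JSON manifest tying it together.

NODATA <- -9999

# --- ENVI raster read/write -------------------------------------------------

#' Write a raster (matrix or band array) as an ENVI flat-binary file
#'
#' Bands are stored band-sequential (BSQ), row-major, little-endian float64
#' (ENVI data type 5), with a plain-text `.hdr` companion carrying the grid
#' geometry, the nodata sentinel and band names. Float64 storage makes
#' write/read round trips bit-exact. `NA` is stored as the nodata sentinel;
#' writing data that already contains the sentinel as a valid value is an
#' error.
#'
#' @param data numeric matrix or 3-d array (`row x col x band`).
#' @param path output path without extension (writes `path.dat`, `path.hdr`).
#' @param geom a [grid_geom()].
#' @param band_names character vector, one per band.
#' @param nodata sentinel value (default -9999).
#' @return `path`, invisibly.
#' @export
write_envi <- function(data, path, geom = NULL, band_names = NULL,
                       nodata = NODATA) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3)
  nr <- dim(data)[1]; nc <- dim(data)[2]; nb <- dim(data)[3]
  if (is.null(geom)) geom <- grid_geom(nr, nc)
  if (is.null(band_names)) band_names <- paste0("band_", seq_len(nb))
  stopifnot(length(band_names) == nb)
  if (any(data == nodata, na.rm = TRUE))
    stop("data contains the nodata sentinel ", nodata, " as a valid value")
  data[is.na(data)] <- nodata
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  for (k in seq_len(nb)) # row-major within each band, as ENVI expects
    writeBin(as.numeric(t(data[, , k])), con, size = 8, endian = "little")
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", nc),
    sprintf("lines = %d", nr),
    sprintf("bands = %d", nb),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("map info = {Arbitrary, 1.0, 1.0, %.10g, %.10g, %.10g, %.10g, units=Meters}",
            geom$x0, geom$y0, geom$px, geom$px),
    sprintf("data ignore value = %.10g", nodata),
    sprintf("band names = {%s}", paste(band_names, collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read an ENVI flat-binary raster written by [write_envi()]
#'
#' @param path path without extension.
#' @return list with `data` (3-d array, `NA` where nodata), `geom`,
#'   `band_names`, `nodata`.
#' @export
read_envi <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  getv <- function(key) {
    ln <- grep(paste0("^", key, " ="), hdr, value = TRUE)
    if (!length(ln)) stop("header lacks field: ", key)
    sub(paste0("^", key, " = "), "", ln[1])
  }
  nc <- as.integer(getv("samples"))
  nr <- as.integer(getv("lines"))
  nb <- as.integer(getv("bands"))
  stopifnot(getv("data type") == "5", getv("interleave") == "bsq",
            getv("byte order") == "0")
  nodata <- as.numeric(getv("data ignore value"))
  map <- strsplit(gsub("[{}]", "", getv("map info")), ",")[[1]]
  geom <- grid_geom(nr, nc, px = as.numeric(map[6]),
                    x0 = as.numeric(map[4]), y0 = as.numeric(map[5]))
  bn <- trimws(strsplit(gsub("[{}]", "", getv("band names")), ",")[[1]])
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = nr * nc * nb, size = 8, endian = "little")
  arr <- array(NA_real_, c(nr, nc, nb))
  for (k in seq_len(nb)) {
    block <- raw[((k - 1) * nr * nc + 1):(k * nr * nc)]
    arr[, , k] <- t(matrix(block, nc, nr)) # undo row-major storage
  }
  arr[arr == nodata] <- NA_real_
  list(data = arr, geom = geom, band_names = bn, nodata = nodata)
}

# --- full-precision CSV -----------------------------------------------------

# write.csv loses precision at the default 15 significant digits; format
# doubles at 17 so text round trips are exact (internal)
write_csv_exact <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                          formatC(out[[nm]], digits = 17, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
}

read_csv_exact <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# --- world serialisation ----------------------------------------------------

#' Write a synthetic world to a directory
#'
#' Rasters go to ENVI flat-binary files (one multi-band file per
#' indicator-year, banded by composite start DOY; soil, county map, crop
#' masks, phenology and truth rasters alongside), tables to CSV at full
#' precision, and `manifest.json` lists every file with its role, the grid
#' geometry, the nodata sentinel and the configuration (including the seed).
#' Reading the directory back with [read_world()] reproduces the world
#' bit-exactly.
#'
#' @param world a [make_world()] result.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- world$geom
  files <- list()
  add <- function(role, name, ...) {
    files[[length(files) + 1]] <<- c(list(role = role, file = name), list(...))
  }

  for (yr in names(world$stacks)) {
    for (ind in names(world$stacks[[yr]])) {
      st <- world$stacks[[yr]][[ind]]
      nm <- sprintf("stack_%s_year%s", ind, yr)
      write_envi(st$data, file.path(dir, nm), g,
                 band_names = paste0("doy_", st$doys))
      add("indicator_stack", nm, indicator = ind, year = as.integer(yr),
          units = st$units)
    }
    write_envi(world$truth$yield[[yr]], file.path(dir, paste0("truth_year", yr)),
               g, "true_yield_kg_ha")
    add("true_yield", paste0("truth_year", yr), year = as.integer(yr))
    msk <- world$crop_mask[[yr]] * 1.0
    write_envi(msk, file.path(dir, paste0("crop_mask_year", yr)), g, "crop_mask")
    add("crop_mask", paste0("crop_mask_year", yr), year = as.integer(yr))
    ph <- world$phenology[[yr]]
    write_envi(array(c(ph$start_doy, ph$end_doy), c(g$nrow, g$ncol, 2)),
               file.path(dir, paste0("phenology_year", yr)), g,
               c("start_doy", "end_doy"))
    add("phenology", paste0("phenology_year", yr), year = as.integer(yr))
  }
  write_envi(array(c(world$soil$clay, world$soil$sand, world$soil$silt),
                   c(g$nrow, g$ncol, 3)),
             file.path(dir, "soil"), g, c("clay", "sand", "silt"))
  add("soil", "soil")
  write_envi(world$county_map + 0.0, file.path(dir, "county_map"), g,
             "county_id")
  add("county_map", "county_map")

  write_csv_exact(world$county_yields, file.path(dir, "county_yields.csv"))
  add("county_yields", "county_yields.csv")
  write_csv_exact(world$point_yields, file.path(dir, "point_yields.csv"))
  add("point_yields", "point_yields.csv")
  for (fx in world$flux) {
    nm <- sprintf("flux_%s.csv", fx$tower_id)
    write_csv_exact(fx$data, file.path(dir, nm))
    add("flux", nm, tower_id = fx$tower_id,
        location = as.integer(fx$location))
  }

  cfg <- unclass(world$config)
  # named atomic vectors serialise to nameless JSON arrays; keep names
  cfg$yield_coefficients <- as.list(cfg$yield_coefficients)
  cfg$outlier_spec <- as.list(cfg$outlier_spec)
  manifest <- list(
    format = "ENVI flat-binary (.dat/.hdr), float64 BSQ + CSV tables",
    coordinate_convention = "(row, col) 1-based, pixel-centre registration",
    nodata = NODATA,
    geometry = unclass(g),
    years = world$years,
    seed = world$config$seed,
    config = cfg,
    truth_coefficients = as.list(world$truth$coefficients),
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a synthetic world written by [write_world()]
#'
#' @param dir directory holding `manifest.json` and the data files.
#' @return a `synthetic_world` equal to the one written.
#' @export
read_world <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  gm <- manifest$geometry
  geom <- grid_geom(gm$nrow, gm$ncol, gm$px, gm$x0, gm$y0)
  cfg <- manifest$config
  config <- sim_config(grid_rows = cfg$grid_rows, grid_cols = cfg$grid_cols,
                       n_years = cfg$n_years,
                       counties_rows = cfg$counties_rows,
                       counties_cols = cfg$counties_cols, crop = cfg$crop,
                       yield_coefficients = unlist(cfg$yield_coefficients),
                       noise_sd_pixel = cfg$noise_sd_pixel,
                       noise_sd_county = cfg$noise_sd_county,
                       closure_ratio = cfg$closure_ratio,
                       outlier_spec = unlist(cfg$outlier_spec),
                       n_point_sites = cfg$n_point_sites,
                       n_towers = cfg$n_towers, seed = cfg$seed)
  files <- manifest$files
  years <- as.integer(manifest$years)

  stacks <- list(); crop_mask <- list(); phenology <- list(); truth <- list()
  soil <- NULL; county_map <- NULL; flux <- list()
  county_yields <- NULL; point_yields <- NULL

  for (i in seq_len(nrow(files))) {
    f <- files[i, ]
    p <- file.path(dir, f$file)
    switch(as.character(f$role),
      indicator_stack = {
        r <- read_envi(p)
        doys <- as.integer(sub("doy_", "", r$band_names))
        ykey <- as.character(f$year)
        if (is.null(stacks[[ykey]])) stacks[[ykey]] <- list()
        stacks[[ykey]][[f$indicator]] <-
          composite_stack(f$indicator, f$year, r$data, doys, r$geom, f$units)
      },
      true_yield = {
        truth[[as.character(f$year)]] <- read_envi(p)$data[, , 1]
      },
      crop_mask = {
        crop_mask[[as.character(f$year)]] <- read_envi(p)$data[, , 1] == 1
      },
      phenology = {
        r <- read_envi(p)$data
        phenology[[as.character(f$year)]] <-
          phenology_map(f$year, cfg$crop, r[, , 1], r[, , 2])
      },
      soil = {
        r <- read_envi(p)$data
        soil <- list(clay = r[, , 1], sand = r[, , 2], silt = r[, , 3])
      },
      county_map = {
        county_map <- read_envi(p)$data[, , 1]
        storage.mode(county_map) <- "integer"
      },
      county_yields = county_yields <- read_csv_exact(p),
      point_yields = point_yields <- read_csv_exact(p),
      flux = {
        flux[[length(flux) + 1]] <- list(tower_id = f$tower_id,
                                         location = unlist(f$location),
                                         data = read_csv_exact(p))
      },
      stop("unknown role in manifest: ", f$role))
  }
  # restore canonical indicator order within each year
  stacks <- lapply(stacks, function(s) s[c("ET", "GPP", "Ts", "LAI")])

  structure(list(config = config, geom = geom, years = years,
                 county_map = county_map, soil = soil,
                 crop_mask = crop_mask, phenology = phenology,
                 stacks = stacks, county_yields = county_yields,
                 point_yields = point_yields, flux = flux,
                 truth = list(yield = truth,
                              coefficients = unlist(manifest$truth_coefficients))),
            class = "synthetic_world")
}
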