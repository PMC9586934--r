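# Shared fixtures: small worlds and hand-built rasters used across tests.

# a small, fast world for structural tests
tiny_config <- function(seed = 1, ...) {
  sim_config(grid_rows = 20, grid_cols = 20, counties_rows = 2,
             counties_cols = 2, n_years = 2, n_point_sites = 6,
             n_towers = 1, seed = seed, ...)
}

# cache the default-config world (expensive enough to share within a file)
default_world <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) cache[[key]] <- make_world(sim_config(seed = seed))
    cache[[key]]
  }
})

# constant composite stack: every layer = value
constant_stack <- function(value, nr = 4, nc = 4, indicator = "ET") {
  doys <- composite_doys()
  composite_stack(indicator, 1L,
                  array(value, c(nr, nc, length(doys))), doys)
}

# uniform phenology map
uniform_phenology <- function(start, end, nr = 4, nc = 4, year = 1L) {
  phenology_map(year, "maize",
                matrix(start, nr, nc), matrix(end, nr, nc))
}

# a clean county yield table: `years` records per county around county means
clean_yield_table <- function(n_counties = 25, years = 3, base = 7000,
                              spread = 800, noise = 80, seed = 1) {
  set.seed(seed)
  mu <- base + runif(n_counties, -spread, spread)
  do.call(rbind, lapply(seq_len(n_counties), function(cid) {
    data.frame(county_id = cid, year = seq_len(years),
               yield_kg_ha = mu[cid] + rnorm(years, 0, noise),
               planting_area_ha = runif(years, 2000, 8000))
  }))
}

# brute-force queen adjacency: all pixel pairs (oracle)
adjacency_oracle <- function(county_map) {
  ids <- sort(unique(as.vector(county_map[!is.na(county_map)])))
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  nr <- nrow(county_map); nc <- ncol(county_map)
  cells <- which(!is.na(county_map), arr.ind = TRUE)
  for (a in seq_len(nrow(cells))) {
    for (b in seq_len(nrow(cells))) {
      if (a == b) next
      di <- abs(cells[a, 1] - cells[b, 1])
      dj <- abs(cells[a, 2] - cells[b, 2])
      la <- county_map[cells[a, 1], cells[a, 2]]
      lb <- county_map[cells[b, 1], cells[b, 2]]
      if (di <= 1 && dj <= 1 && la != lb) {
        W[match(la, ids), match(lb, ids)] <- 1
      }
    }
  }
  list(ids = ids, W = W, S = sum(W))
}

# double-loop Moran's I (oracle)
morans_oracle <- function(x, W, S = sum(W)) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
  n * num / (S * sum((x - xb)^2))
}
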