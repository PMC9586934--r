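# Validation suite: accuracy metrics, spatial autocorrelation of zonal
# residuals, and multiplicative input-perturbation sensitivity analysis.

#' Accuracy metrics for estimated vs observed values
#'
#' Computes, for estimates `M` against observations `O`:
#' \itemize{
#'   \item `rmse`: sqrt(mean((M - O)^2))
#'   \item `rrmse`: RMSE / mean(O) * 100 (percent)
#'   \item `mbe`: mean(M - O) (signed bias)
#'   \item `r2_conventional`: adjusted squared Pearson correlation,
#'     `1 - (1 - r^2) * (n - 1) / (n - m - 1)`
#'   \item `r2_var_ratio`: an adjusted variance-ratio form,
#'     `1 - (1 - sum((M - mean(M))^2) / sum((O - mean(O))^2)) * (n - 1) / (n - m - 1)`,
#'     reported for fidelity with a published formulation; it compares spread
#'     rather than fit and is not used for model selection here.
#' }
#' Adjusted forms are `NA` when `n <= m + 1`; correlation-based R2 is `NA`
#' when either vector is constant.
#'
#' @param M numeric vector of estimates.
#' @param O numeric vector of observations (same length, `n >= 2`).
#' @param m number of model variables used for the adjustment (default 1).
#' @return one-row data.frame: `n, m, r2_var_ratio, r2_conventional, rmse,
#'   rrmse, mbe`.
#' @export
metrics <- function(M, O, m = 1) {
  stopifnot(length(M) == length(O))
  keep <- is.finite(M) & is.finite(O)
  M <- M[keep]; O <- O[keep]
  n <- length(M)
  if (n < 2) stop("need at least 2 paired finite values")
  rmse <- sqrt(mean((M - O)^2))
  rrmse <- if (mean(O) != 0) rmse / mean(O) * 100 else NA_real_
  mbe <- mean(M - O)
  adj <- function(stat) {
    if (is.na(stat) || n <= m + 1) return(NA_real_)
    1 - (1 - stat) * (n - 1) / (n - m - 1)
  }
  sso <- sum((O - mean(O))^2)
  ssm <- sum((M - mean(M))^2)
  r2_var_ratio <- if (sso > 0) adj(ssm / sso) else NA_real_
  r2_conv <- if (sso > 0 && ssm > 0) adj(stats::cor(M, O)^2) else NA_real_
  data.frame(n = n, m = m, r2_var_ratio = r2_var_ratio, r2_conventional = r2_conv,
             rmse = rmse, rrmse = rrmse, mbe = mbe)
}

#' Queen-contiguity adjacency between counties on a labelled raster
#'
#' Two counties are adjacent iff any pair of their pixels touch along an edge
#' or a corner (queen contiguity). Weights are binary and symmetric with a
#' zero diagonal.
#'
#' @param county_map integer matrix of county labels, `NA` = no county.
#' @return list with `ids` (sorted county labels), `W` (binary matrix), and
#'   `S` (sum of all weights). Errors if fewer than two counties are present.
#' @export
build_adjacency <- function(county_map) {
  ids <- sort(unique(as.vector(county_map[!is.na(county_map)])))
  if (length(ids) < 2)
    stop("adjacency requires at least two counties (S would be 0)")
  nr <- nrow(county_map); nc <- ncol(county_map)
  pair_up <- function(a, b) {
    ok <- !is.na(a) & !is.na(b) & a != b
    cbind(a[ok], b[ok])
  }
  pairs <- rbind(
    pair_up(county_map[, -nc], county_map[, -1]),               # east
    pair_up(county_map[-nr, ], county_map[-1, ]),               # south
    pair_up(county_map[-nr, -nc], county_map[-1, -1]),          # south-east
    pair_up(county_map[-nr, -1], county_map[-1, -nc])           # south-west
  )
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(pairs)) {
    i <- match(pairs[, 1], ids); j <- match(pairs[, 2], ids)
    W[cbind(i, j)] <- 1
    W[cbind(j, i)] <- 1
  }
  S <- sum(W)
  if (S == 0) stop("no adjacent county pair found (S = 0)")
  list(ids = ids, W = W, S = S)
}

#' Global Moran's I of zonal values under binary contiguity weights
#'
#' I = n * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#'     (S * sum_i (x_i - xbar)^2),
#' the standard form with squared deviations in the denominator. Applied in
#' this package to county-level yield residuals (estimated minus recorded):
#' values near zero indicate spatially random model errors.
#'
#' @param x numeric vector of zonal values, aligned with `W$ids` (or named by
#'   county id).
#' @param W adjacency from [build_adjacency()] (list with `W`, `S`, `ids`),
#'   or a bare symmetric zero-diagonal weight matrix.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(x, W) {
  if (is.matrix(W)) W <- list(ids = seq_len(nrow(W)), W = W, S = sum(W))
  if (!is.null(names(x)) && !is.null(W$ids))
    x <- x[match(as.character(W$ids), names(x))]
  n <- length(x)
  stopifnot(n == nrow(W$W))
  if (n < 3) stop("Moran's I needs at least 3 zones")
  if (anyNA(x)) stop("missing zonal values")
  d <- x - mean(x)
  denom <- sum(d^2)
  if (denom == 0) stop("Moran's I is undefined for constant values")
  n * as.numeric(t(d) %*% W$W %*% d) / (W$S * denom)
}

#' Multiplicative input-perturbation sensitivity analysis
#'
#' Emulates assessing model robustness to indicator error: each scenario
#' perturbs a subset of the windowed indicators on the *test* features by an
#' independent multiplicative error `v * (1 + u)`, `u ~ Uniform(range)`,
#' drawn per row and per feature; the trained forest is *not* retrained.
#' Metrics are recomputed on the perturbed features and averaged over
#' replicates; deltas are reported against the unperturbed baseline.
#'
#' @param model a trained model from [train_rf()].
#' @param test feature data.frame holding at least the model's feature columns.
#' @param observed numeric vector of observed yields for `test` rows.
#' @param scenarios list of scenarios; each is
#'   `list(name =, indicators = c("cumET", ...), range = c(lo, hi))` with
#'   `-1 <= lo <= hi <= 1`. An empty `indicators` vector is the identity.
#' @param reps replicates per scenario (default 30).
#' @param seed integer seed.
#' @return data.frame, one row per scenario: mean `r2`, `rmse`, `rrmse` over
#'   replicates plus `d_r2`, `d_rmse`, `d_rrmse` deltas vs the baseline, and
#'   the replicate count.
#' @export
sensitivity <- function(model, test, observed, scenarios, reps = 30, seed = 1) {
  stopifnot(inherits(model, "yield_rf"))
  base_pred <- predict_table(model, test)
  mm <- length(model$feature_cols)
  base <- metrics(base_pred, observed, m = mm)
  out <- lapply(seq_along(scenarios), function(si) {
    sc <- scenarios[[si]]
    rng <- sc$range
    if (length(sc$indicators)) {
      stopifnot(length(rng) == 2, rng[1] <= rng[2],
                rng[1] >= -1, rng[2] <= 1)
      if (!all(sc$indicators %in% names(test)))
        stop("scenario targets a feature absent from the test table")
    }
    set.seed(spawn_seed(seed, paste0("sensitivity-", si)))
    reps_m <- vapply(seq_len(reps), function(r) {
      pt <- test
      for (col in sc$indicators) {
        u <- stats::runif(nrow(pt), rng[1], rng[2])
        pt[[col]] <- pt[[col]] * (1 + u)
      }
      pred <- predict_table(model, pt)
      met <- metrics(pred, observed, m = mm)
      c(met$r2_conventional, met$rmse, met$rrmse)
    }, numeric(3))
    mu <- rowMeans(reps_m)
    data.frame(scenario = if (!is.null(sc$name)) sc$name else paste0("s", si),
               r2 = mu[1], rmse = mu[2], rrmse = mu[3],
               d_r2 = mu[1] - base$r2_conventional,
               d_rmse = mu[2] - base$rmse,
               d_rrmse = mu[3] - base$rrmse,
               reps = reps)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
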