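# Eddy-covariance energy-balance quality control.
#
# Daily tower records carry the energy-balance components: net radiation Rn,
# soil heat flux G, sensible heat H and latent heat lambda*ET, all W/m2 daily
# means. Because the measured turbulent fluxes rarely close the energy budget,
# days are screened by their closure ratio and the retained latent heat is
# rescaled with the Bowen-ratio correction, which preserves H/lambdaET while
# forcing closure.

LAMBDA_V <- 2.45e6 # latent heat of vaporisation [J/kg], fixed (no T dependence)

#' Energy balance closure ratio
#'
#' ECR = (H + lambdaET) / (Rn - G). Days with `Rn - G <= 0`
#' (nocturnal-dominated or winter energy budgets, where the correction is
#' unstable) are flagged invalid (`NA`).
#'
#' @param flux data.frame with numeric columns `Rn`, `G`, `H`, `lam_ET`
#'   (W/m2 daily means).
#' @return numeric vector of closure ratios, `NA` where invalid.
#' @export
compute_ecr <- function(flux) {
  stopifnot(all(c("Rn", "G", "H", "lam_ET") %in% names(flux)))
  avail <- flux$Rn - flux$G
  turb <- flux$H + flux$lam_ET
  out <- turb / avail
  out[!is.finite(out) | avail <= 0] <- NA_real_
  out
}

#' Bowen-ratio energy-balance correction of latent heat
#'
#' lambdaET_cor = lambdaET * (Rn - G) / (H + lambdaET), i.e. the available
#' energy is repartitioned into H and lambdaET at the measured Bowen ratio.
#' Days with `H + lambdaET <= 0` are flagged invalid (`NA`).
#'
#' @inheritParams compute_ecr
#' @return numeric vector of corrected latent heat flux (W/m2).
#' @export
bowen_correct <- function(flux) {
  stopifnot(all(c("Rn", "G", "H", "lam_ET") %in% names(flux)))
  turb <- flux$H + flux$lam_ET
  out <- flux$lam_ET * (flux$Rn - flux$G) / turb
  out[!is.finite(out) | turb <= 0] <- NA_real_
  # lambdaET = 0 with valid turbulent flux stays exactly 0
  out[!is.na(out) & flux$lam_ET == 0] <- 0
  out
}

#' Screen a daily flux series by closure ratio and correct latent heat
#'
#' Removes days whose closure ratio is invalid or strictly below `threshold`
#' (a day at exactly the threshold is retained, matching the strict "< 80%
#' not selected" screening rule) and attaches the Bowen-corrected latent heat
#' as column `lam_ET_cor`.
#'
#' @param flux data.frame with columns `date` (integer day-of-year or Date),
#'   `Rn`, `G`, `H`, `lam_ET`.
#' @param threshold minimum closure ratio retained, in (0, 1]; default 0.80.
#' @return the retained rows with added columns `ecr` and `lam_ET_cor`.
#' @export
filter_and_correct <- function(flux, threshold = 0.80) {
  stopifnot(threshold > 0, threshold <= 1)
  ecr <- compute_ecr(flux)
  cor <- bowen_correct(flux)
  keep <- !is.na(ecr) & !is.na(cor) & ecr >= threshold
  out <- flux[keep, , drop = FALSE]
  out$ecr <- ecr[keep]
  out$lam_ET_cor <- cor[keep]
  if (!nrow(out)) warning("no days survive the closure-ratio screen")
  rownames(out) <- NULL
  out
}

#' Convert a daily-mean latent heat flux to evapotranspiration depth
#'
#' mm/day = lambdaET [W/m2] * 86400 [s/day] / lambda_v, with
#' lambda_v = 2.45e6 J/kg (1 kg water / m2 = 1 mm).
#'
#' @param lam_ET numeric, W/m2 daily mean.
#' @return numeric, mm/day.
#' @export
latent_heat_to_mm <- function(lam_ET) lam_ET * 86400 / LAMBDA_V

#' Cumulate a daily ET series to the 8-day composite grid
#'
#' Sums daily ET depths within each composite period. Periods 1-45 span 8
#' days; the final period spans the year's remaining 5 (or 6) days. A period
#' with gaps is scaled to a full-period total by (nominal days / valid days)
#' provided at least `min_frac` of its nominal days are present (default 6 of
#' 8); sparser periods are reported missing.
#'
#' @param daily data.frame with columns `doy` (integer day-of-year) and
#'   `et_mm` (mm/day); one calendar year, missing days simply absent or `NA`.
#' @param doys composite start day-of-years.
#' @param min_frac minimum fraction of a period's days required (default 6/8).
#' @param days_in_year 365 or 366.
#' @return data.frame with columns `doy` (composite start), `et_mm_8d`
#'   (`NA` where insufficient coverage), `n_valid`.
#' @export
cumulate_8day <- function(daily, doys = composite_doys(), min_frac = 6 / 8,
                          days_in_year = 365) {
  stopifnot(all(c("doy", "et_mm") %in% names(daily)),
            all(daily$doy >= 1 & daily$doy <= days_in_year))
  nominal <- c(diff(doys), days_in_year - doys[length(doys)] + 1L)
  ok <- !is.na(daily$et_mm)
  comp <- findInterval(daily$doy, doys)
  sums <- rep(0, length(doys))
  nval <- rep(0L, length(doys))
  for (i in which(ok)) {
    k <- comp[i]
    sums[k] <- sums[k] + daily$et_mm[i]
    nval[k] <- nval[k] + 1L
  }
  need <- ceiling(min_frac * nominal)
  et <- ifelse(nval >= need, sums * nominal / pmax(nval, 1L), NA_real_)
  data.frame(doy = as.integer(doys), et_mm_8d = et, n_valid = nval)
}

#' Pair tower composite ET with the gridded ET product at the tower pixel
#'
#' Extracts the raster pixel containing the tower (a 1 x 1 km cell) from each
#' composite layer and pairs it with the tower's composite total; composites
#' missing on either side are dropped from both.
#'
#' @param tower data.frame from [cumulate_8day()] (`doy`, `et_mm_8d`).
#' @param stack a [composite_stack()] of gridded ET (mm/8d).
#' @param location integer `c(row, col)` of the tower pixel (1-based).
#' @return data.frame with columns `doy`, `tower_ET`, `raster_ET`.
#' @export
pair_with_raster <- function(tower, stack, location) {
  stopifnot(inherits(stack, "composite_stack"), length(location) == 2)
  nr <- dim(stack$data)[1]; nc <- dim(stack$data)[2]
  if (location[1] < 1 || location[1] > nr || location[2] < 1 || location[2] > nc)
    stop("tower location is off the grid")
  rast <- stack$data[location[1], location[2], ]
  m <- match(stack$doys, tower$doy)
  out <- data.frame(doy = stack$doys,
                    tower_ET = tower$et_mm_8d[m],
                    raster_ET = rast)
  out <- out[!is.na(out$tower_ET) & !is.na(out$raster_ET), , drop = FALSE]
  if (!nrow(out)) warning("no overlapping composites between tower and raster")
  rownames(out) <- NULL
  out
}
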