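# Regional carbon-budget components: annual NEE aggregation, riverine
# export, coastal sea uptake, and the headline comparison ratios.

#' Construct an NEE grid from components
#'
#' @param rates Cells x days matrix of daily NEE rates, g C m-2 d-1
#'   (negative = uptake).
#' @param cell_area_km2 Per-cell resolution, km2 (positive); recycled to
#'   the number of cells.
#' @return List of class `"nee_grid"`.
#' @export
#' @examples
#' nee_grid(matrix(-1, 1, 365), 81)
nee_grid <- function(rates, cell_area_km2) {
  rates <- as.matrix(rates)
  area <- rep_len(cell_area_km2, nrow(rates))
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("cell areas must be positive", call. = FALSE)
  }
  if (any(!is.finite(rates))) {
    stop("missing cell-day rates; supply a complete grid or impute ",
         "before aggregation", call. = FALSE)
  }
  structure(list(rates = rates, cell_area_km2 = area,
                 days = seq_len(ncol(rates))),
            class = "nee_grid")
}

#' Aggregate a gridded daily NEE field to an annual total
#'
#' Annual NEE as the sum over days of the sum over cells of
#' `rate x cell area`, in Pg C yr-1 (negative = net terrestrial
#' uptake). Uncertainty follows the package convention: 15% on each
#' daily regional total, combined across days in quadrature.
#'
#' @param grid `"nee_grid"` object.
#' @param relative_daily Relative uncertainty applied to each daily
#'   total (default 0.15).
#' @return `"uncertain"` annual NEE in Pg C yr-1.
#' @export
#' @examples
#' aggregate_nee(nee_grid(matrix(-1, 1, 365), 81))
aggregate_nee <- function(grid, relative_daily = 0.15) {
  stopifnot(inherits(grid, "nee_grid"))
  daily_g <- colSums(grid$rates * (grid$cell_area_km2 * .M2_PER_KM2))
  total <- sum(daily_g) / .G_PER_PG
  delta <- combine_quadrature(abs(daily_g) * relative_daily) / .G_PER_PG
  uncertain(total, delta)
}

#' Sum riverine carbon export records
#'
#' Total dissolved organic plus inorganic C export of the listed rivers.
#' Missing DIC (or DOC) entries are treated as zero with a warning.
#'
#' @param records `data.frame` with columns `river`, `DOC_PgC_yr`,
#'   `DIC_PgC_yr`.
#' @return Total export, Pg C yr-1.
#' @export
#' @examples
#' sum_export(default_export_records())
sum_export <- function(records) {
  if (nrow(records) < 1L) stop("at least one export record is required",
                               call. = FALSE)
  doc <- records$DOC_PgC_yr
  dic <- records$DIC_PgC_yr
  if (anyNA(doc) || anyNA(dic)) {
    warning("missing DOC/DIC entries treated as zero")
    doc[is.na(doc)] <- 0
    dic[is.na(dic)] <- 0
  }
  if (any(doc < 0) || any(dic < 0)) {
    stop("export components must be non-negative", call. = FALSE)
  }
  sum(doc + dic)
}

#' Default riverine export records
#'
#' Per-river DOC/DIC split is an illustrative synthetic decomposition;
#' only the regional total (0.011 Pg C yr-1, the published downstream
#' export of the three rivers) is constrained.
#'
#' @return `data.frame` with columns `river`, `DOC_PgC_yr`, `DIC_PgC_yr`.
#' @export
default_export_records <- function() {
  data.frame(
    river = c("Ob", "Pur", "Taz"),
    DOC_PgC_yr = c(0.0041, 0.0006, 0.0006),
    DIC_PgC_yr = c(0.0049, 0.0004, 0.0004)
  )
}

#' Net C uptake by a coastal sea
#'
#' Mean areal CO2 flux times sea surface area times number of days,
#' converted from mmol CO2 m-2 d-1 to Pg C yr-1; the sign of the rate
#' carries the direction (negative = uptake).
#'
#' @param mean_rate_mmol_m2_d Mean CO2 flux, mmol m-2 d-1.
#' @param surface_area_m2 Sea surface area, m2 (> 0). The default is the
#'   standard geographic surface area of the Kara Sea (9.26e5 km2).
#' @param days Days in the averaging year (1-366; default 365).
#' @return Net annual flux, Pg C yr-1.
#' @export
#' @examples
#' sea_uptake(-7.64) # ~ -0.031
sea_uptake <- function(mean_rate_mmol_m2_d,
                       surface_area_m2 = 9.26e5 * .M2_PER_KM2,
                       days = 365) {
  check_number(mean_rate_mmol_m2_d, "mean_rate_mmol_m2_d")
  check_number(surface_area_m2, "surface_area_m2", lower = 1)
  check_number(days, "days", lower = 1, upper = 366)
  mean_rate_mmol_m2_d * 1e-3 * .C_MOLAR_MASS * days * surface_area_m2 /
    .G_PER_PG
}

#' Headline budget ratios
#'
#' Compares an inland-water emission bracket `[low, high]` with the
#' other regional budget components: percentage of the terrestrial NEE
#' sink returned to the atmosphere, fold difference over riverine
#' export, and fold difference over coastal sea uptake.
#'
#' @param emission_low,emission_high Emission bracket, Pg C yr-1.
#' @param nee Annual NEE, Pg C yr-1 (negative = sink); non-zero.
#' @param export Riverine export, Pg C yr-1 (> 0).
#' @param sea Sea uptake, Pg C yr-1 (negative = uptake); non-zero.
#' @return `data.frame` with columns `comparison`, `low`, `high`.
#' @export
#' @examples
#' budget_ratios(0.076, 0.104, -0.198, 0.011, -0.031)
budget_ratios <- function(emission_low, emission_high, nee, export, sea) {
  check_number(emission_low, "emission_low", lower = 0)
  check_number(emission_high, "emission_high", lower = 0)
  if (emission_high < emission_low) {
    stop("emission_high must be >= emission_low", call. = FALSE)
  }
  if (nee == 0 || export == 0 || sea == 0) {
    stop("budget denominators must be non-zero", call. = FALSE)
  }
  data.frame(
    comparison = c("emission_vs_nee_pct", "emission_vs_export_fold",
                   "emission_vs_sea_fold"),
    low = c(100 * emission_low / abs(nee), emission_low / export,
            emission_low / abs(sea)),
    high = c(100 * emission_high / abs(nee), emission_high / export,
             emission_high / abs(sea))
  )
}
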