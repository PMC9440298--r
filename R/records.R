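#' Validate a unit-record table
#'
#' One row per (spatial unit, ecosystem class, epoch). Required columns:
#' `unit_id`, `ecosystem` (class code), `epoch`, `raw_area` (m2), `ndvi`,
#' `precipitation` (m/yr), `evapotranspiration` (g/m2/yr water flux),
#' `elevation` (m), `npp` (gC/m2/yr), `carbon_pool` (gC/m2),
#' `carbon_turnover` (yr), `infiltration_coeff` (fraction), the soil profile
#' (`bulk_density` g/cm3, `soil_depth` cm, `som_fraction`,
#' `retention_amount` t/ha/yr, plus `pm_*` mineral-proportion columns),
#' `eutrophic` (logical, aquatic only) and the eight `ren_*` renewable
#' emergy flow columns (sej/yr).
#'
#' @param records data.frame to validate.
#' @return `records`, invisibly.
#' @export
validate_records <- function(records) {
  need <- c("unit_id", "ecosystem", "epoch", "raw_area", "ndvi",
            "precipitation", "evapotranspiration", "elevation", "npp",
            "carbon_pool", "carbon_turnover", "infiltration_coeff",
            "bulk_density", "soil_depth", "som_fraction", "retention_amount",
            "eutrophic",
            paste0("ren_", c("solar", "tidal", "geothermal", "wave", "wind",
                             "rain_chem", "runoff_geo", "runoff_chem")))
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("record table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(records$ecosystem %in% es_classes()$code))
    stop("unknown ecosystem class code(s): ",
         paste(setdiff(records$ecosystem, es_classes()$code), collapse = ", "),
         call. = FALSE)
  chk <- function(cond, msg) if (any(!cond)) stop(msg, call. = FALSE)
  chk(records$raw_area >= 0, "raw_area must be >= 0")
  chk(records$ndvi >= -1 & records$ndvi <= 1, "ndvi must lie in [-1, 1]")
  chk(records$precipitation >= 0 & records$evapotranspiration >= 0 &
        records$npp >= 0 & records$carbon_pool >= 0 &
        records$retention_amount >= 0, "all rates must be >= 0")
  chk(records$carbon_turnover > 0, "carbon_turnover must be > 0")
  chk(records$infiltration_coeff >= 0 & records$infiltration_coeff <= 1,
      "infiltration_coeff must lie in [0, 1]")
  chk(records$bulk_density > 0, "bulk_density must be > 0")
  chk(records$soil_depth > 0, "soil_depth must be > 0")
  pm <- grep("^pm_", names(records), value = TRUE)
  if (length(pm))
    chk(as.matrix(records[pm]) >= 0 & as.matrix(records[pm]) <= 1,
        "mineral proportions must lie in [0, 1]")
  ren <- as.matrix(records[grep("^ren_", names(records), value = TRUE)])
  chk(ren >= 0, "renewable flows must be >= 0")
  dup <- duplicated(records[c("unit_id", "ecosystem", "epoch")])
  if (any(dup)) stop("duplicated (unit_id, ecosystem, epoch) rows",
                     call. = FALSE)
  invisible(records)
}

#' Validate a dam table
#'
#' Dams attach to river (A4) records. Columns: `unit_id`, `epoch`,
#' `catchment_area` (m2, >= 0), `rainfall` (m/yr), `deviation_rate` (m/yr)
#' and `position_x` (fraction of river length in \[0, 1\]).
#'
#' @param dams data.frame to validate (may have zero rows).
#' @return `dams`, invisibly.
#' @export
validate_dams <- function(dams) {
  need <- c("unit_id", "epoch", "catchment_area", "rainfall",
            "deviation_rate", "position_x")
  miss <- setdiff(need, names(dams))
  if (length(miss)) stop("dam table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(dams)) {
    if (any(dams$catchment_area < 0)) stop("catchment_area must be >= 0",
                                           call. = FALSE)
    if (any(dams$position_x < 0 | dams$position_x > 1))
      stop("dam position_x must lie in [0, 1]", call. = FALSE)
  }
  invisible(dams)
}

#' Validate a region assignment
#'
#' Maps every unit to exactly one precipitation zone:
#' `north_of_400mm`, `between_400_800mm` or `south_of_800mm`.
#'
#' @param region data.frame with `unit_id`, `zone`.
#' @param unit_ids optionally, the unit ids that must all be covered.
#' @return `region`, invisibly.
#' @export
validate_region <- function(region, unit_ids = NULL) {
  zones <- c("north_of_400mm", "between_400_800mm", "south_of_800mm")
  if (!all(c("unit_id", "zone") %in% names(region)))
    stop("region table needs unit_id and zone columns", call. = FALSE)
  if (!all(region$zone %in% zones))
    stop("zone must be one of: ", paste(zones, collapse = ", "), call. = FALSE)
  if (any(duplicated(region$unit_id)))
    stop("each unit must map to exactly one zone", call. = FALSE)
  if (!is.null(unit_ids) && !all(unit_ids %in% region$unit_id))
    stop("region assignment missing unit(s): ",
         paste(setdiff(unit_ids, region$unit_id), collapse = ", "),
         call. = FALSE)
  invisible(region)
}
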