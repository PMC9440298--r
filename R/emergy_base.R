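# Renewable-flow candidate order fixes tie-breaking: the grouped
# solar+tidal+geothermal term first, then wave, wind, rain chemical,
# runoff geopotential, runoff chemical.
.ren_candidates <- c("grouped", "wave", "wind", "rain_chem",
                     "runoff_geo", "runoff_chem")

# Underlying physical natural factor of each candidate, used later by
# attribution dispatch.
.ren_factors <- c(grouped = "insolation", wave = "wind", wind = "wind",
                  rain_chem = "precipitation", runoff_geo = "elevation",
                  runoff_chem = "precipitation")

#' Vegetation fraction from NDVI
#'
#' The dimidiate-pixel vegetation fraction
#' VF = (NDVI - NDVI_min) / (NDVI_max - NDVI_min), clipped to \[0, 1\].
#' Values falling outside \[0, 1\] before clipping (anomalous NDVI) trigger a
#' warning so the area contract S' <= S is kept without hiding bad inputs.
#'
#' @param ndvi NDVI value(s), dimensionless in \[-1, 1\].
#' @param ndvi_min,ndvi_max support of the NDVI scaling; `ndvi_max` must be
#'   strictly greater than `ndvi_min`.
#' @return vegetation fraction(s) in \[0, 1\].
#' @examples
#' vegetation_fraction(0.5, 0.2, 0.8) # 0.5
#' @export
vegetation_fraction <- function(ndvi, ndvi_min, ndvi_max) {
  if (any(ndvi_max <= ndvi_min))
    stop("degenerate NDVI support: ndvi_max must exceed ndvi_min",
         call. = FALSE)
  vf <- (ndvi - ndvi_min) / (ndvi_max - ndvi_min)
  if (any(vf < 0 | vf > 1))
    warning("vegetation fraction outside [0, 1]; clipping", call. = FALSE)
  pmin(pmax(vf, 0), 1)
}

#' Area correction by vegetation fraction
#'
#' S' = S * VF. Open-water classes conventionally use VF = 1 (no
#' correction); that choice is made by the caller (see
#' [compute_corrected_areas()]), this primitive just multiplies.
#'
#' @param raw_area mapped area S in m2, >= 0.
#' @param vf vegetation fraction in \[0, 1\].
#' @return corrected area S' in m2.
#' @export
correct_area <- function(raw_area, vf) {
  if (any(raw_area < 0)) stop("raw_area must be >= 0", call. = FALSE)
  if (any(vf < 0 | vf > 1)) stop("vf must lie in [0, 1]", call. = FALSE)
  raw_area * vf
}

#' Corrected areas for a record table
#'
#' Computes the vegetation fraction per record and the corrected area
#' S' = S * VF. The NDVI support (min/max) is computed per ecosystem class
#' within each epoch over the given extent by default, or over
#' `ndvi_support = "region"` groups when a `zone` column is present.
#' Open-water classes (lake A2, reservoir/pond A3, river A4) use VF = 1
#' unless `water_vf = "ndvi"`.
#'
#' @param records a unit-record data.frame (see [validate_records()]).
#' @param ndvi_support `"extent"` (default) or `"region"`.
#' @param water_vf `"one"` (default) or `"ndvi"`.
#' @return `records` with columns `vf` and `corrected_area` added.
#' @export
compute_corrected_areas <- function(records, ndvi_support = c("extent", "region"),
                                    water_vf = c("one", "ndvi")) {
  ndvi_support <- match.arg(ndvi_support)
  water_vf <- match.arg(water_vf)
  grp <- paste(records$ecosystem, records$epoch)
  if (ndvi_support == "region") {
    if (is.null(records$zone))
      stop("ndvi_support = \"region\" needs a zone column", call. = FALSE)
    grp <- paste(grp, records$zone)
  }
  lo <- ave(records$ndvi, grp, FUN = min)
  hi <- ave(records$ndvi, grp, FUN = max)
  vf <- numeric(nrow(records))
  degen <- hi <= lo
  # a single record (or constant NDVI) in a group has no usable support;
  # treat as fully vegetated rather than erroring on a degenerate group
  vf[degen] <- 1
  if (any(!degen))
    vf[!degen] <- vegetation_fraction(records$ndvi[!degen], lo[!degen], hi[!degen])
  if (water_vf == "one") vf[records$ecosystem %in% c("A2", "A3", "A4")] <- 1
  records$vf <- vf
  records$corrected_area <- correct_area(records$raw_area, vf)
  records
}

#' Maximum renewable emergy flow
#'
#' The renewable input driving NPP is the largest of six candidate flows:
#' the grouped sum of solar, tidal and geothermal emergy, then wave, wind,
#' rain chemical potential, runoff geopotential and runoff chemical
#' potential. Ties are broken by that fixed listing order. The winner's
#' underlying physical natural factor (insolation, wind, precipitation or
#' elevation) is recorded for attribution dispatch.
#'
#' @param flows named numeric vector or one-row data.frame/list with
#'   `solar`, `tidal`, `geothermal`, `wave`, `wind`, `rain_chem`,
#'   `runoff_geo`, `runoff_chem` (sej/yr, all >= 0).
#' @return list with `value` (sej/yr), `winner` (candidate label) and
#'   `natural_factor`.
#' @examples
#' max_renewable(c(solar = 1, tidal = 1, geothermal = 1, wave = 5, wind = 4,
#'                 rain_chem = 6, runoff_geo = 2, runoff_chem = 1))
#' @export
max_renewable <- function(flows) {
  flows <- as.list(flows)
  need <- c("solar", "tidal", "geothermal", "wave", "wind",
            "rain_chem", "runoff_geo", "runoff_chem")
  miss <- setdiff(need, names(flows))
  if (length(miss)) stop("missing renewable flow(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  v <- vapply(flows[need], as.numeric, numeric(1))
  if (any(!is.finite(v)) || any(v < 0))
    stop("renewable flows must be finite and >= 0", call. = FALSE)
  cand <- c(grouped = unname(v["solar"] + v["tidal"] + v["geothermal"]),
            v[c("wave", "wind", "rain_chem", "runoff_geo", "runoff_chem")])
  cand <- cand[.ren_candidates]
  w <- which.max(cand) # first max wins: listing-order tie-break
  list(value = unname(cand[w]), winner = .ren_candidates[w],
       natural_factor = unname(.ren_factors[.ren_candidates[w]]))
}

#' NPP service for a record table
#'
#' Per record, the NPP service equals the maximum renewable flow MAX(R);
#' over an extent it is the sum of the per-record maxima.
#'
#' @param records unit-record data.frame with `ren_*` flow columns.
#' @return `records` with columns `max_ren`, `ren_winner`, `ren_factor`
#'   added; the extent total is `sum(records$max_ren)`.
#' @export
npp_service <- function(records) {
  cols <- paste0("ren_", c("solar", "tidal", "geothermal", "wave", "wind",
                           "rain_chem", "runoff_geo", "runoff_chem"))
  miss <- setdiff(cols, names(records))
  if (length(miss)) stop("missing renewable flow column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  res <- lapply(seq_len(nrow(records)), function(i) {
    f <- as.list(records[i, cols])
    names(f) <- sub("^ren_", "", names(f))
    max_renewable(f)
  })
  records$max_ren <- vapply(res, `[[`, numeric(1), "value")
  records$ren_winner <- vapply(res, `[[`, character(1), "winner")
  records$ren_factor <- vapply(res, `[[`, character(1), "natural_factor")
  records
}
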