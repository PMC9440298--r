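#' Demo emergy parameter set
#'
#' Returns a complete, internally consistent parameter set for the accounting
#' pipeline. The numeric unit emergy values (UEVs), DALY/PDF damage factors
#' and uptake capacities shipped here are ILLUSTRATIVE ONLY: they are chosen
#' so that service values land in the 1e18--1e23 sej/yr range typical of
#' national-scale emergy tables, not taken from any authoritative source.
#' Users performing real accounting must supply their own tables via
#' [load_params()].
#'
#' The set has five blocks:
#' \describe{
#'   \item{uev}{unit emergy values: `w` rain chemical (sej/g), `r` dam rain
#'     (sej per declared mass unit, see `consts$hg_mass_conv`), `et`
#'     transpired water (sej/g), `sl` soil (sej/J), `om` organic sediment
#'     (sej/J), `rgeo` runoff geopotential (sej/J), `mountain` (sej/g), and
#'     `minerals`, a named vector of per-mineral-species UEVs (sej/g).}
#'   \item{consts}{physical constants and declared unit bridges. Constants
#'     fixed by the method: `runoff_rate` 0.25, `mineral_fraction` 0.95,
#'     `mineral_turnover` 1000 yr, `aq_absorption` 0.78,
#'     `deposition_npp_ratio` 0.3037, `kcal_to_j` 4186, `rho_water` 1000
#'     kg/m3, `gravity` 9.8 m/s2. Declared bridges: `m2_per_ha`,
#'     `cm2_per_m2`, `g_per_kg`, `g_per_t`, `cm3_per_m3`, `wp_bridge` (the
#'     water-purification dimensional bridge), `hg_mass_conv` (dam-rain mass
#'     bridge).}
#'   \item{class_consts}{per-class constants: `k1_litter` litter/biomass
#'     ratio, `kr1` soil g-to-kcal factor, `k2_aq` aquatic g-to-kcal factor
#'     (kcal/g, aquatic classes only), `k2_detritus` detritus carbon
#'     fraction.}
#'   \item{air / water / ghg}{impact-factor tables: `factors` (per pollutant:
#'     DALY, PDF, and turnover/lifetime where applicable) and per-class
#'     uptake/removal/sequestration capacity tables.}
#' }
#'
#' @return A list of class `emergy_params`.
#' @export
demo_params <- function() {
  cls <- es_classes()$code
  air_pollutants <- sort(c("SO2", "fluoride", "NOx", "CO", "O3", "PM10", "PM2.5"))
  metals <- sort(c("Cr", "Ni", "Cu", "Mn", "Zn", "Cd", "Pb"))
  gases <- sort(c("CO2", "CH4", "NOx", "HFC"))

  uptake <- matrix(0, nrow = length(air_pollutants), ncol = length(cls),
                   dimnames = list(air_pollutants, cls))
  # kg/ha/yr; woody > grass > aquatic
  base_uptake <- c(CO = 40, fluoride = 2, NOx = 35, O3 = 25,
                   PM10 = 120, PM2.5 = 60, SO2 = 90)
  class_scale <- c(F1 = 1, F2 = 0.7, G1 = 0.45, G2 = 0.35, G3 = 0.2,
                   A1 = 0.25, A2 = 0.1, A3 = 0.1, A4 = 0.1)
  for (p in air_pollutants) uptake[p, ] <- base_uptake[[p]] * class_scale[cls]

  aqc <- c("A1", "A2", "A3", "A4")
  removal <- matrix(0, nrow = length(metals), ncol = length(aqc),
                    dimnames = list(metals, aqc))
  base_removal <- c(Cd = 0.8, Cr = 6, Cu = 12, Mn = 30, Ni = 5, Pb = 9, Zn = 25) # mg/kg
  aq_scale <- c(A1 = 1, A2 = 0.8, A3 = 0.7, A4 = 0.6)
  for (m in metals) removal[m, ] <- base_removal[[m]] * aq_scale[aqc]

  seq_ghg <- matrix(0, nrow = length(gases), ncol = length(cls),
                    dimnames = list(gases, cls))
  base_seq <- c(CH4 = 0.004, CO2 = 0.55, HFC = 1e-6, NOx = 0.002) # kg/m2/yr
  for (g in gases) seq_ghg[g, ] <- base_seq[[g]] * class_scale[cls]

  structure(list(
    uev = list(
      w = 1.54e5, r = 1.54e8, et = 2.59e5, sl = 7.38e4, om = 7.38e4,
      rgeo = 2.79e4, mountain = 1.0e9,
      minerals = c(clay = 2.0e9, quartz = 1.0e9)
    ),
    consts = list(
      rho_water = 1000, rho_mountain = 2.6, gravity = 9.8,
      kcal_to_j = 4186, runoff_rate = 0.25,
      mineral_fraction = 0.95, mineral_turnover = 1000,
      aq_absorption = 0.78, deposition_npp_ratio = 0.3037,
      m2_per_ha = 1e4, cm2_per_m2 = 1e4, g_per_kg = 1000,
      g_per_t = 1e6, cm3_per_m3 = 1e6,
      wp_bridge = 1, hg_mass_conv = 1,
      kr1 = 4.5 # soil organic matter g -> kcal
    ),
    class_consts = data.frame(
      code = cls,
      k1_litter = c(0.05, 0.08, 0.12, 0.12, 0.12, 0.10, 0.06, 0.06, 0.06),
      k2_detritus = rep(0.45, 9),
      k2_aq = c(rep(NA_real_, 5), 4.0, 3.5, 3.5, 3.2), # kcal/g, aquatic only
      stringsAsFactors = FALSE
    ),
    air = list(
      factors = data.frame(
        pollutant = air_pollutants,
        daly = c(CO = 7.3e-7, fluoride = 8.0e-5, NOx = 8.9e-5, O3 = 3.9e-6,
                 PM10 = 3.8e-4, PM2.5 = 7.0e-4, SO2 = 5.5e-5)[air_pollutants],
        pdf = c(CO = 1e-6, fluoride = 2e-5, NOx = 1.3e-4, O3 = 6e-6,
                PM10 = 8e-5, PM2.5 = 9e-5, SO2 = 1.0e-4)[air_pollutants],
        stringsAsFactors = FALSE
      ),
      uptake = uptake
    ),
    water = list(
      factors = data.frame(
        metal = metals,
        daly = c(Cd = 8.9e-8, Cr = 3.4e-9, Cu = 6.1e-10, Mn = 1.2e-10,
                 Ni = 2.6e-9, Pb = 7.9e-9, Zn = 9.2e-11)[metals],
        pdf = c(Cd = 2.3e-7, Cr = 1.9e-8, Cu = 8.7e-9, Mn = 1.1e-9,
                Ni = 1.4e-8, Pb = 9.6e-9, Zn = 2.2e-9)[metals],
        turnover = c(Cd = 30, Cr = 12, Cu = 15, Mn = 8,
                     Ni = 18, Pb = 40, Zn = 10)[metals],
        stringsAsFactors = FALSE
      ),
      removal = removal
    ),
    ghg = list(
      factors = data.frame(
        gas = gases,
        daly = c(CH4 = 4.4e-6, CO2 = 2.1e-7, HFC = 3.0e-4, NOx = 8.9e-5)[gases],
        pdf = c(CH4 = 1.0e-6, CO2 = 5.0e-8, HFC = 7.0e-5, NOx = 2.0e-5)[gases],
        lifetime = c(CH4 = 12, CO2 = 100, HFC = 52, NOx = 0.3)[gases],
        stringsAsFactors = FALSE
      ),
      sequestration = seq_ghg
    )
  ), class = "emergy_params")
}

# Constants whose values the method itself fixes; applied as defaults when a
# user file omits them. Everything else must be supplied explicitly.
.printed_const_defaults <- function() {
  list(rho_water = 1000, gravity = 9.8, kcal_to_j = 4186,
       runoff_rate = 0.25, mineral_fraction = 0.95, mineral_turnover = 1000,
       aq_absorption = 0.78, deposition_npp_ratio = 0.3037,
       m2_per_ha = 1e4, cm2_per_m2 = 1e4, g_per_kg = 1000,
       g_per_t = 1e6, cm3_per_m3 = 1e6, wp_bridge = 1, hg_mass_conv = 1)
}

#' Validate an emergy parameter set
#'
#' Checks key presence, sign constraints (all UEVs strictly positive, all
#' impact factors non-negative, lifetimes/turnovers strictly positive) and
#' fraction ranges. Called by [load_params()]; exported for direct use.
#'
#' @param params a parameter list as returned by [demo_params()].
#' @return `params`, invisibly, after validation.
#' @export
validate_params <- function(params) {
  req_top <- c("uev", "consts", "class_consts", "air", "water", "ghg")
  miss <- setdiff(req_top, names(params))
  if (length(miss)) stop("parameter set missing key(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  req_uev <- c("w", "r", "et", "sl", "om", "rgeo", "mountain", "minerals")
  miss <- setdiff(req_uev, names(params$uev))
  if (length(miss)) stop("uev block missing key(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  uevs <- c(unlist(params$uev[setdiff(req_uev, "minerals")]),
            params$uev$minerals)
  if (any(!is.finite(uevs)) || any(uevs <= 0))
    stop("all UEVs must be finite and > 0; offending: ",
         paste(names(uevs)[!is.finite(uevs) | uevs <= 0], collapse = ", "),
         call. = FALSE)

  req_const <- c(names(.printed_const_defaults()), "rho_mountain", "kr1")
  miss <- setdiff(req_const, names(params$consts))
  if (length(miss)) stop("consts block missing key(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  cv <- unlist(params$consts[req_const])
  if (any(!is.finite(cv)) || any(cv <= 0))
    stop("all constants must be finite and > 0", call. = FALSE)
  frac <- c("runoff_rate", "mineral_fraction", "aq_absorption",
            "deposition_npp_ratio")
  fv <- unlist(params$consts[frac])
  if (any(fv < 0 | fv > 1))
    stop("constants ", paste(frac[fv < 0 | fv > 1], collapse = ", "),
         " must lie in [0, 1]", call. = FALSE)

  cc <- params$class_consts
  if (!all(es_classes()$code %in% cc$code))
    stop("class_consts must cover all nine ecosystem classes", call. = FALSE)
  if (any(cc$k1_litter < 0 | cc$k1_litter > 1) ||
      any(cc$k2_detritus < 0 | cc$k2_detritus > 1))
    stop("class fractions k1_litter, k2_detritus must lie in [0, 1]",
         call. = FALSE)

  for (blk in c("air", "water", "ghg")) {
    f <- params[[blk]]$factors
    vals <- unlist(f[setdiff(names(f), names(f)[1])])
    if (any(vals < 0)) stop(blk, " impact factors must be >= 0", call. = FALSE)
  }
  if (any(params$water$factors$turnover <= 0))
    stop("water pollutant turnover times must be > 0", call. = FALSE)
  if (any(params$ghg$factors$lifetime <= 0))
    stop("greenhouse-gas lifetimes must be > 0", call. = FALSE)
  invisible(params)
}

#' Read and write parameter sets
#'
#' Parameter sets are exchanged as a single JSON document. [load_params()]
#' applies defaults only for the constants whose values the method itself
#' fixes (runoff rate 0.25, mineral mass fraction 0.95, mineral turnover
#' 1000 yr, aquatic absorption 0.78, deposition/NPP ratio 0.3037, water
#' density, gravity, kcal-to-J and the declared unit bridges); every other
#' key must be present. Round-tripping through [save_params()] then
#' [load_params()] reproduces all values exactly.
#'
#' @param path file path of the JSON parameter document.
#' @return [load_params()]: a validated `emergy_params` list.
#' @export
load_params <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (k in names(.printed_const_defaults()))
    if (is.null(raw$consts[[k]]))
      raw$consts[[k]] <- .printed_const_defaults()[[k]]
  # jsonlite reads named vectors back as lists and may narrow whole
  # numbers to integer; restore double vectors and matrices
  if (!is.null(raw$uev$minerals)) {
    mn <- unlist(raw$uev$minerals)
    raw$uev$minerals <- stats::setNames(as.numeric(mn), names(mn))
  }
  raw$uev[setdiff(names(raw$uev), "minerals")] <-
    lapply(raw$uev[setdiff(names(raw$uev), "minerals")], as.numeric)
  raw$consts <- lapply(raw$consts, as.numeric)
  for (blk in c("air", "water", "ghg")) {
    tabs <- setdiff(names(raw[[blk]]), "factors")
    for (tb in tabs) {
      m <- do.call(rbind, lapply(raw[[blk]][[tb]], unlist))
      storage.mode(m) <- "double"
      raw[[blk]][[tb]] <- m
    }
    f <- raw[[blk]]$factors
    for (cl in names(f)) if (is.numeric(f[[cl]])) f[[cl]] <- as.numeric(f[[cl]])
    raw[[blk]]$factors <- f
  }
  structure(validate_params(raw), class = "emergy_params")
}

#' @rdname load_params
#' @param params a validated parameter set.
#' @export
save_params <- function(params, path) {
  validate_params(params)
  out <- unclass(params)
  out$uev$minerals <- as.list(out$uev$minerals) # keep species names in JSON
  for (blk in c("air", "water", "ghg")) {
    tabs <- setdiff(names(out[[blk]]), "factors")
    for (tb in tabs) {
      m <- out[[blk]][[tb]]
      out[[blk]][[tb]] <- apply(m, 1, function(r) as.list(r), simplify = FALSE)
    }
  }
  # digits = I(17): 17 significant digits round-trip doubles exactly
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Cognition-degree driver
#'
#' The cognition driver tau is the emergy equivalent of per-capita health
#' expenditure: tau = I * EmR / Pop, where I is total health expenditure
#' (currency/yr), EmR the emergy-to-money ratio (sej/currency) and Pop the
#' population. Higher per-capita health spending is read as greater human
#' attention to ecosystem-service improvement.
#'
#' @param health_expenditure total health expenditure, currency/yr (>= 0).
#' @param emergy_money_ratio emergy-to-money ratio, sej per currency unit.
#' @param population capita, must be > 0.
#' @return tau in sej per capita.
#' @examples
#' tau_h(1e9, 1e12, 1e6) # 1e15 sej/cap
#' @export
tau_h <- function(health_expenditure, emergy_money_ratio, population) {
  if (any(population <= 0)) stop("population must be > 0", call. = FALSE)
  if (any(health_expenditure < 0))
    stop("health expenditure must be >= 0", call. = FALSE)
  health_expenditure * emergy_money_ratio / population
}
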