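# Seeded synthetic two-epoch fixtures. The generator emulates the
# statistical structure of the accounting inputs -- nine ecosystem classes
# per spatial unit, two epochs, controlled multiplicative driver deltas --
# not any real geography. Magnitudes are chosen so per-record services land
# in the 1e18--1e23 sej/yr range typical of national emergy tables.

#' Fixture specification
#'
#' @param seed integer; fully determines the output.
#' @param n_units number of spatial units.
#' @param classes ecosystem classes present (default all nine).
#' @param deltas named list of multiplicative epoch-1 changes, each entry a
#'   scalar applied to all classes or a vector named by class code. Known
#'   drivers: `area`, `evapotranspiration`, `precipitation`, `ndvi`, `npp`,
#'   `tau`. All deltas must be > -1.
#' @param jitter relative log-normal jitter applied to baseline values
#'   (identically in both epochs, so planned deltas are exactly
#'   recoverable).
#' @param region_layout fractions of units per precipitation zone, in order
#'   north_of_400mm, between_400_800mm, south_of_800mm; must sum to 1.
#' @param eutrophic_frac fraction of non-river aquatic records flagged
#'   eutrophic.
#' @return a validated `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_units = 6L,
                         classes = es_classes()$code,
                         deltas = list(), jitter = 0.1,
                         region_layout = c(0.3, 0.3, 0.4),
                         eutrophic_frac = 0) {
  stopifnot(length(seed) == 1, n_units >= 1,
            all(classes %in% es_classes()$code),
            jitter >= 0, length(region_layout) == 3,
            abs(sum(region_layout) - 1) < 1e-9,
            eutrophic_frac >= 0, eutrophic_frac <= 1)
  known <- c("area", "evapotranspiration", "precipitation", "ndvi", "npp",
             "tau")
  bad <- setdiff(names(deltas), known)
  if (length(bad)) stop("unknown delta driver(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(unlist(deltas) <= -1))
    stop("deltas must be > -1 (quantities cannot go negative)",
         call. = FALSE)
  structure(list(seed = as.integer(seed), n_units = as.integer(n_units),
                 classes = classes, deltas = deltas, jitter = jitter,
                 region_layout = region_layout,
                 eutrophic_frac = eutrophic_frac),
            class = "fixture_spec")
}

.delta_for <- function(spec, driver, class) {
  d <- spec$deltas[[driver]]
  if (is.null(d)) return(0)
  if (length(d) == 1 && is.null(names(d))) return(unname(d))
  if (class %in% names(d)) unname(d[[class]]) else 0
}

# Renewable emergy flows from physical drivers (sej/yr). Flows scale with
# raw area so every service stays homogeneous of degree 1 in area.
.renewable_flows <- function(class, area, precip, elevation, wind_int,
                             insol_int, params) {
  cn <- params$consts
  rain_chem <- precip * cn$rho_water * cn$g_per_kg * params$uev$w * area
  runoff_chem <- cn$runoff_rate * rain_chem * 0.8
  runoff_geo <- precip * cn$rho_water * cn$runoff_rate * elevation *
    cn$gravity * params$uev$rgeo * area
  wave <- if (class %in% c("A2", "A3")) 0.1 * wind_int * area else 0
  data.frame(ren_solar = insol_int * area, ren_tidal = 0.02 * insol_int * area,
             ren_geothermal = 0.05 * insol_int * area,
             ren_wave = wave, ren_wind = wind_int * area,
             ren_rain_chem = rain_chem, ren_runoff_geo = runoff_geo,
             ren_runoff_chem = runoff_chem)
}

#' Generate a two-epoch synthetic fixture
#'
#' Draws baseline (epoch `t0`) unit records from fixed, realistic ranges,
#' applies the multiplicative jitter once, then produces epoch `t1` by
#' scaling each driver by (1 + its planned delta). Identical seeds give
#' identical output. Rivers receive dams whose catchment scales with the
#' river record's area, so a pure-area delta remains a pure human-driver
#' change.
#'
#' @param spec a [fixture_spec()].
#' @param params parameter set used for derived renewable flows (default
#'   [demo_params()]).
#' @return list: `records` (both epochs), `dams`, `region`, `cognition`,
#'   `areas` (per-zone total and ecosystem areas at baseline, m2),
#'   `params`, `spec`.
#' @export
generate_fixture <- function(spec, params = demo_params()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  zones <- c("north_of_400mm", "between_400_800mm", "south_of_800mm")
  nz <- diff(round(cumsum(c(0, spec$region_layout)) * spec$n_units))
  nz[3] <- spec$n_units - sum(nz[1:2])
  unit_ids <- sprintf("U%02d", seq_len(spec$n_units))
  region <- data.frame(unit_id = unit_ids, zone = rep(zones, nz),
                       stringsAsFactors = FALSE)
  # zone-typical precipitation (m/yr)
  zone_precip <- c(north_of_400mm = 0.3, between_400_800mm = 0.6,
                   south_of_800mm = 1.1)

  jit <- function(n) exp(stats::rnorm(n, 0, spec$jitter))
  rows <- list(); dam_rows <- list()
  for (u in seq_len(spec$n_units)) {
    zn <- region$zone[u]
    for (cl in spec$classes) {
      aq <- is_aquatic(cl)
      base <- list(
        raw_area = (if (aq) 3e7 else 1e8) * jit(1),
        ndvi = min(0.95, (if (cl %in% c("A2", "A3", "A4")) 0.1
                          else if (cl == "A1") 0.4 else 0.65) * jit(1)),
        precipitation = zone_precip[[zn]] * jit(1),
        evapotranspiration = (if (aq) 7e5 else 4.5e5) * jit(1),
        elevation = (if (cl == "A4") 900 else 400) * jit(1),
        npp = (if (aq) 150 else 500) * jit(1),
        carbon_pool = (if (aq) 4e3 else 1.2e4) * jit(1),
        carbon_turnover = 35 * jit(1),
        infiltration_coeff = min(0.9, 0.15 * jit(1)),
        bulk_density = 1.35 * jit(1),
        soil_depth = 60 * jit(1),
        som_fraction = min(0.9, 0.03 * jit(1)),
        retention_amount = 3 * jit(1),
        pm_clay = 0.35, pm_quartz = 0.5,
        wind_int = 1.6e10 * jit(1),
        insol_int = 1.3e10 * jit(1)
      )
      eutro <- aq && cl != "A4" && stats::runif(1) < spec$eutrophic_frac
      n_dams <- if (cl == "A4") 1 + (u %% 2) else 0
      dam_x <- if (n_dams) stats::runif(n_dams) else numeric(0)
      dam_catch_mult <- if (n_dams) 20 * jit(n_dams) else numeric(0)
      dam_dev <- if (n_dams) 0.002 * jit(n_dams) else numeric(0)
      for (ep in c("t0", "t1")) {
        g <- function(drv, val) val * (1 + if (ep == "t1")
          .delta_for(spec, drv, cl) else 0)
        area <- g("area", base$raw_area)
        precip <- g("precipitation", base$precipitation)
        elev <- base$elevation
        rec <- data.frame(
          unit_id = unit_ids[u], ecosystem = cl, epoch = ep,
          raw_area = area,
          ndvi = min(1, g("ndvi", base$ndvi)),
          precipitation = precip,
          evapotranspiration = g("evapotranspiration",
                                 base$evapotranspiration),
          elevation = elev,
          npp = g("npp", base$npp),
          carbon_pool = base$carbon_pool,
          carbon_turnover = base$carbon_turnover,
          infiltration_coeff = base$infiltration_coeff,
          bulk_density = base$bulk_density, soil_depth = base$soil_depth,
          som_fraction = base$som_fraction,
          retention_amount = base$retention_amount,
          pm_clay = base$pm_clay, pm_quartz = base$pm_quartz,
          eutrophic = eutro, stringsAsFactors = FALSE)
        rec <- cbind(rec, .renewable_flows(cl, area, precip, elev,
                                           base$wind_int, base$insol_int,
                                           params))
        rows[[length(rows) + 1]] <- rec
        if (n_dams)
          dam_rows[[length(dam_rows) + 1]] <- data.frame(
            unit_id = unit_ids[u], epoch = ep,
            catchment_area = dam_catch_mult * area,
            rainfall = precip, deviation_rate = dam_dev,
            position_x = dam_x, stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  dams <- if (length(dam_rows)) do.call(rbind, dam_rows) else
    data.frame(unit_id = character(0), epoch = character(0),
               catchment_area = numeric(0), rainfall = numeric(0),
               deviation_rate = numeric(0), position_x = numeric(0))
  rownames(dams) <- NULL

  pop <- 5e6 * spec$n_units
  i0 <- 2500 * pop
  cognition <- data.frame(
    epoch = c("t0", "t1"),
    health_expenditure = c(i0, i0 * (1 + .delta_for(spec, "tau", "F1"))),
    population = pop, emergy_money_ratio = 5.4e11,
    stringsAsFactors = FALSE)

  r0 <- records[records$epoch == "t0", ]
  eco_area <- tapply(r0$raw_area, region$zone[match(r0$unit_id,
                                                    region$unit_id)], sum)
  areas <- data.frame(zone = names(eco_area),
                      ecosystem_area = as.numeric(eco_area),
                      total_area = as.numeric(eco_area) / 0.6,
                      stringsAsFactors = FALSE)

  validate_records(records)
  validate_dams(dams)
  validate_region(region, unit_ids)
  list(records = records, dams = dams, region = region,
       cognition = cognition, areas = areas, params = params, spec = spec)
}

#' Packaged worked examples
#'
#' The tiny hand-computed inputs used throughout the documentation and the
#' regression tests: a bilinear decomposition case with a nonzero
#' interaction residual, the terrestrial and river total cases, and a
#' published national-scale regional driver-contribution table (three
#' precipitation zones over a two-decade comparison) used to regression-test
#' the report stage.
#'
#' @return list: `decomp` (model, baseline, end, expected contributions and
#'   residual), `terrestrial_row`, `river_row` and variants with expected
#'   totals (sej/yr), `region_contribs` (printed per-zone driver
#'   contributions, sej/yr), `printed` (printed summary values: subtotals,
#'   unit-area human-driver contributions).
#' @export
worked_example <- function() {
  decomp <- list(
    model = list(
      value = function(s) s$E * s$S + s$S * s$tau,
      partials = function(s) c(E = s$S, tau = s$S, S = s$E + s$tau)),
    baseline = list(E = 2, tau = 1, S = 10),
    end = list(E = 3, tau = 1, S = 12),
    expected = c(E = 10, tau = 0, S = 6), expected_delta = 2)

  terrestrial_row <- data.frame(
    npp = 5e20, cs = 3e20, sb = 2e20, gr = 1e20, mr = 4e20,
    ap = 1e20, sr = 1e20, cr = 1e20)
  river_base <- data.frame(
    npp = 5e20, cs = 3e20, sba = 2e20, gr = 1e20, mr = 4e20,
    wp = 1e20, ap = 1e20, cr = 1e20, hg = 2e20,
    stringsAsFactors = FALSE)
  path <- system.file("extdata", "region_contributions_demo.csv",
                      package = "emergyes")
  region_contribs <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(
    decomp = decomp,
    terrestrial_row = terrestrial_row, terrestrial_total = 8e20,
    river_case_b = transform(river_base, ren_winner = "rain_chem"),
    river_case_b_total = 10e20,
    river_case_a = transform(river_base, ren_winner = "runoff_geo"),
    river_a1_total = 10e20, river_a2_total = 5e20, river_a3_total = 8e20,
    region_contribs = region_contribs,
    printed = list(
      human_driver = c(north_of_400mm = 4.59e22, between_400_800mm = 2.66e22),
      human_driver_per_area = c(north_of_400mm = 5.00e10,
                                between_400_800mm = 4.31e10),
      ratio_pct = c(north_of_400mm = 32, south_of_800mm = 53),
      rate_pct = list(
        north_of_400mm = c(r = 20, tau = 10, s = 71, delta = -1),
        between_400_800mm = c(r = -1, tau = 9, s = 91, delta = 0),
        south_of_800mm = c(r = 58, tau = 6, s = 34, delta = 2)))
  )
}
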