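# Shared fixture builders. Everything is constructed in code; no binary
# data.

# A minimal valid one-row record table with overridable fields.
make_record <- function(ecosystem = "F1", epoch = "t0", unit_id = "U01", ...) {
  rec <- data.frame(
    unit_id = unit_id, ecosystem = ecosystem, epoch = epoch,
    raw_area = 1e8, ndvi = 0.6, precipitation = 0.8,
    evapotranspiration = 4.5e5, elevation = 500, npp = 500,
    carbon_pool = 1.2e4, carbon_turnover = 35, infiltration_coeff = 0.15,
    bulk_density = 1.35, soil_depth = 60, som_fraction = 0.03,
    retention_amount = 3, pm_clay = 0.35, pm_quartz = 0.5,
    eutrophic = FALSE,
    ren_solar = 1.3e18, ren_tidal = 2.6e16, ren_geothermal = 6.5e16,
    ren_wave = 0, ren_wind = 1.6e18, ren_rain_chem = 1.2e19,
    ren_runoff_geo = 2e18, ren_runoff_chem = 2.4e18,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_flows <- function(grouped = 3, wave = 5, wind = 4, rain_chem = 6,
                       runoff_geo = 2, runoff_chem = 1, scale = 1e20) {
  c(solar = grouped * scale, tidal = 0, geothermal = 0,
    wave = wave * scale, wind = wind * scale, rain_chem = rain_chem * scale,
    runoff_geo = runoff_geo * scale, runoff_chem = runoff_chem * scale)
}

# Serialize a (possibly incomplete) parameter list the way save_params()
# does, but without validation, so default-application can be tested.
unclass_params_for_json <- function(params) {
  out <- unclass(params)
  for (blk in c("air", "water", "ghg")) {
    for (tb in setdiff(names(out[[blk]]), "factors")) {
      m <- out[[blk]][[tb]]
      out[[blk]][[tb]] <- apply(m, 1, as.list, simplify = FALSE)
    }
  }
  out
}

# Run the whole pipeline on a generated fixture; returns ledger, totals and
# per-record attribution.
run_pipeline <- function(spec) {
  fx <- generate_fixture(spec)
  ledger <- compute_services(fx$records, fx$params, fx$cognition, fx$dams)
  totals <- compute_totals(ledger, fx$dams, fx$params)
  res <- suppressMessages(attribute_changes(ledger, totals, c("t0", "t1")))
  list(fixture = fx, ledger = ledger, totals = totals, attribution = res)
}
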