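test_that("carbon sequestration agrees across both algebraic forms", {
  r <- carbon_sequestration(carbon_pool = 500, carbon_turnover = 50,
                            corrected_area = 1e4, npp = 100, em_npp = 1e12)
  expect_identical(r$uev_cs, 1e6) # EmNPP / (S' * NPP)
  expect_identical(r$value, 1e11) # (C/T) * S' * UEV
  expect_equal(r$value, 1e12 * 500 / (50 * 100), tolerance = 1e-12)
  expect_identical(carbon_sequestration(0, 50, 1e4, 100, 1e12)$value, 0)
  expect_error(carbon_sequestration(500, 50, 1e4, 0, 1e12), "NPP")
  # cross-form identity on random inputs
  set.seed(11)
  for (i in 1:20) {
    C <- runif(1, 1, 2e4); Tt <- runif(1, 1, 100); S <- runif(1, 1, 1e9)
    np <- runif(1, 1, 1000); em <- runif(1, 1e15, 1e21)
    r <- carbon_sequestration(C, Tt, S, np, em)
    expect_equal(r$value, em * C / (Tt * np), tolerance = 1e-12)
  }
})

test_that("soil building sums the organic part and the winning mineral", {
  p <- demo_params()
  r <- soil_building("F1", em_npp = 1e12, k1_litter = 0.05,
                     k2_detritus = 0.5, pm = c(clay = 0.3, quartz = 0.6),
                     bulk_density = 1.4, soil_depth = 50,
                     corrected_area = 1e6, params = p)
  expect_identical(r$organic, 2.5e10)
  # independent brute-force max over mineral species
  cn <- p$consts
  term <- function(prop, uev) (prop * 1.4 * 50 * 1e6 * cn$mineral_fraction *
                                 cn$cm2_per_m2 / cn$mineral_turnover) * uev
  terms <- c(clay = term(0.3, p$uev$minerals[["clay"]]),
             quartz = term(0.6, p$uev$minerals[["quartz"]]))
  expect_equal(r$mineral, max(terms), tolerance = 1e-12)
  expect_identical(r$winning_mineral, names(which.max(terms)))
  expect_equal(r$value, r$organic + r$mineral, tolerance = 0)
  z <- soil_building("F1", 1e12, 0, 0.5, c(clay = 0, quartz = 0),
                     1.4, 50, 1e6, p)
  expect_identical(z$value, 0)
  expect_error(soil_building("A2", 1e12, 0.05, 0.5, c(clay = 0.3),
                             1.4, 50, 1e6, p), "does not apply")
})

test_that("sediment building follows the deposition chain and the
           eutrophication exclusion", {
  p <- demo_params()
  p$uev$om <- 1
  expect_equal(p$consts$deposition_npp_ratio * 100, 30.37, tolerance = 1e-12)
  v <- sediment_building("A2", npp = 100, k2_aq = 4, corrected_area = 1,
                         eutrophic = FALSE, params = p)
  expect_equal(v, 30.37 * 0.78 * 4 * 4186, tolerance = 1e-12)
  e <- sediment_building("A2", 100, 4, 1, eutrophic = TRUE, params = p)
  expect_true(is.na(e))
  expect_identical(attr(e, "reason"), "eutrophic water body")
  expect_error(sediment_building("F1", 100, 4, 1, FALSE, p),
               "does not apply")
})

test_that("groundwater recharge is the infiltrated rain-mass emergy", {
  p <- demo_params(); p$uev$w <- 1
  expect_identical(groundwater_recharge(1, 1, 0.1, p), 1e5)
  expect_identical(groundwater_recharge(1, 1, 0, p), 0)
  expect_identical(groundwater_recharge(1, 2, 0.1, p),
                   2 * groundwater_recharge(1, 1, 0.1, p))
  expect_error(groundwater_recharge(1, 1, 1.5, p), "infiltration")
})

test_that("air purification splits into HH and EQ parts", {
  p <- demo_params()
  p$air$factors <- data.frame(pollutant = "SO2", daly = 1e-3, pdf = 0)
  p$air$uptake <- matrix(10, 1, 1, dimnames = list("SO2", "F1"))
  r <- air_purification("F1", corrected_area = 1e4, max_ren = 0,
                        tau = 1e15, params = p)
  expect_identical(r$hh, 1e13) # 10 kg/ha * 1 ha * 1e-3 * 1e15
  expect_identical(r$value, r$hh + r$eq)
  # additivity over pollutants
  p2 <- p
  p2$air$factors <- data.frame(pollutant = c("NOx", "SO2"),
                               daly = c(2e-3, 1e-3), pdf = c(1e-4, 2e-4))
  p2$air$uptake <- matrix(c(5, 10), 2, 1,
                          dimnames = list(c("NOx", "SO2"), "F1"))
  r2 <- air_purification("F1", 1e4, 1e18, 1e15, p2)
  one <- function(m, d, q) {
    pp <- p
    pp$air$factors <- data.frame(pollutant = "x", daly = d, pdf = q)
    pp$air$uptake <- matrix(m, 1, 1, dimnames = list("x", "F1"))
    air_purification("F1", 1e4, 1e18, 1e15, pp)
  }
  a <- one(5, 2e-3, 1e-4); b <- one(10, 1e-3, 2e-4)
  expect_equal(r2$hh, a$hh + b$hh, tolerance = 1e-12)
  expect_equal(r2$eq, a$eq + b$eq, tolerance = 1e-12)
  # zero uptake -> zero service, with a warning for the missing entry
  p3 <- p
  p3$air$uptake <- matrix(0, 1, 1, dimnames = list("SO2", "F2"))
  expect_warning(r3 <- air_purification("F1", 1e4, 1e18, 1e15, p3),
                 "treated as zero")
  expect_identical(r3$value, 0)
})

test_that("water purification scales inversely with metal turnover", {
  p <- demo_params()
  p$water$factors <- data.frame(metal = "Cd", daly = 1e-13, pdf = 0,
                                turnover = 10)
  p$water$removal <- matrix(10, 1, 1, dimnames = list("Cd", "A2"))
  # M*NPP*S'*DALY*tau = 10*10*1e6*1e-13*1e15 = 1e10; / T = 1e9
  r <- water_purification("A2", npp = 10, corrected_area = 1e6, tau = 1e15,
                          em_sp = 0, params = p)
  expect_equal(r$hh, 1e9, tolerance = 1e-12)
  p$water$removal[] <- 0
  expect_identical(water_purification("A2", 10, 1e6, 1e15, 0, p)$value, 0)
  # halving every turnover doubles the service
  p$water$removal[] <- 10
  p$water$factors$turnover <- 5
  expect_equal(water_purification("A2", 10, 1e6, 1e15, 0, p)$hh, 2e9,
               tolerance = 1e-12)
  expect_error(water_purification("F1", 10, 1e6, 1e15, 0, p),
               "does not apply")
})

test_that("soil retention follows the retained-organic-matter chain", {
  p <- demo_params(); p$consts$kr1 <- 4; p$uev$sl <- 1
  # G=2 t/ha/yr, S'=1 ha, rom=0.02 -> 2*1*0.02*1e6*4*4186 = 6.6976e8
  expect_equal(soil_retention("F1", 2, 1e4, 0.02, p), 6.6976e8,
               tolerance = 1e-12)
  expect_identical(soil_retention("F1", 0, 1e4, 0.02, p), 0)
  expect_equal(soil_retention("F1", 2, 2e4, 0.02, p),
               2 * soil_retention("F1", 2, 1e4, 0.02, p), tolerance = 0)
  expect_error(soil_retention("A4", 2, 1e4, 0.02, p), "does not apply")
})

test_that("microclimate regulation is the transpired-water emergy", {
  p <- demo_params(); p$uev$et <- 1e3
  expect_identical(microclimate_regulation(5e5, 1e4, p), 5e12)
  expect_identical(microclimate_regulation(0, 1e4, p), 0)
  p2 <- p; p2$uev$et <- 2e3
  expect_identical(microclimate_regulation(5e5, 1e4, p2), 1e13)
})

test_that("materials transport applies the runoff-geopotential chain on
           rivers only", {
  p <- demo_params(); p$uev$rgeo <- 1
  expect_equal(materials_transport("A4", 1, 1, 100, p), 2.45e5,
               tolerance = 1e-12) # 1*1*1000*0.25*100*9.8
  expect_identical(materials_transport("A4", 1, 1, 0, p), 0)
  expect_identical(p$consts$runoff_rate, 0.25)
  expect_error(materials_transport("F1", 1, 1, 100, p), "does not apply")
})

test_that("hydropower potential sums rain and mountain terms over dams", {
  p <- demo_params(); p$uev$r <- 1
  dam <- data.frame(unit_id = "U01", epoch = "t0", catchment_area = 1e6,
                    rainfall = 1, deviation_rate = 0, position_x = 0.5)
  r <- hydropower_potential("A4", dam, p)
  expect_identical(r$rain, 1e9) # 1e6 * 1 * 1000 * hg_mass_conv(=1) * 1
  expect_identical(hydropower_potential("A4", dam[0, ], p)$value, 0)
  expect_identical(hydropower_potential("A4", NULL, p)$value, 0)
  two <- rbind(dam, dam)
  expect_identical(hydropower_potential("A4", two, p)$value, 2 * r$value)
  expect_error(hydropower_potential("A2", dam, p), "does not apply")
})

test_that("climate regulation divides by gas lifetime", {
  p <- demo_params()
  p$ghg$factors <- data.frame(gas = "CO2", daly = 1e-9, pdf = 0,
                              lifetime = 100)
  p$ghg$sequestration <- matrix(1, 1, 1, dimnames = list("CO2", "F1"))
  # C*DALY*S'*tau = 1 * 1e-9 * 1e6 * 1e15 = 1e12; / LT = 1e10
  r <- climate_regulation("F1", 1e6, 1e15, 0, p)
  expect_equal(r$hh, 1e10, tolerance = 1e-12)
  p$ghg$sequestration[] <- 0
  expect_identical(climate_regulation("F1", 1e6, 1e15, 0, p)$value, 0)
  p$ghg$sequestration[] <- 1
  p$ghg$factors$lifetime <- 200
  expect_equal(climate_regulation("F1", 1e6, 1e15, 0, p)$hh, 5e9,
               tolerance = 1e-12)
})

test_that("the ledger honours the applicability matrix", {
  fx <- generate_fixture(fixture_spec(seed = 5, n_units = 3, jitter = 0))
  led <- compute_services(fx$records, fx$params, fx$cognition, fx$dams)
  m <- service_applicability()
  for (svc in colnames(m)) {
    for (cl in rownames(m)) {
      vals <- led[[svc]][led$ecosystem == cl]
      if (m[cl, svc]) expect_true(all(!is.na(vals)),
                                  label = paste(cl, svc, "present"))
      else expect_true(all(is.na(vals)),
                       label = paste(cl, svc, "absent"))
    }
  }
  # all stored values non-negative
  svc_cols <- colnames(m)
  expect_true(all(unlist(led[svc_cols]) >= 0, na.rm = TRUE))
})

test_that("every service is homogeneous of degree 1 in area", {
  fx <- generate_fixture(fixture_spec(seed = 9, n_units = 2, jitter = 0.05))
  cc <- 3
  recs2 <- fx$records
  recs2$raw_area <- cc * recs2$raw_area
  ren <- grep("^ren_", names(recs2), value = TRUE)
  recs2[ren] <- cc * recs2[ren]
  dams2 <- fx$dams
  dams2$catchment_area <- cc * dams2$catchment_area
  l1 <- compute_services(fx$records, fx$params, fx$cognition, fx$dams)
  l2 <- compute_services(recs2, fx$params, fx$cognition, dams2)
  for (svc in colnames(service_applicability()))
    expect_equal(l2[[svc]], cc * l1[[svc]], tolerance = 1e-10,
                 label = paste("scaled", svc))
})

test_that("eutrophic aquatic records carry no sediment-building service", {
  fx <- generate_fixture(fixture_spec(seed = 4, n_units = 4,
                                      eutrophic_frac = 1))
  led <- compute_services(fx$records, fx$params, fx$cognition, fx$dams)
  nr <- led$ecosystem %in% c("A1", "A2", "A3")
  expect_true(all(is.na(led$sba[nr])))
})
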