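# Eleven ecosystem services as emergy flows (sej/yr). Every function is
# homogeneous of degree 1 in the corrected area (hydropower in catchment
# area). Iteration over pollutants, metals, gases and minerals is in
# lexicographic order so sums are bit-reproducible.

.stop_applicability <- function(service, class) {
  stop(sprintf("service %s does not apply to ecosystem class %s",
               service, class), call. = FALSE)
}

#' Carbon sequestration service
#'
#' The UEV of sequestered carbon is derived from the NPP service:
#' UEV_cs = EmNPP / (S' * NPP), and the service is
#' EmCS = (C / T) * S' * UEV_cs, algebraically equal to
#' EmNPP * C / (T * NPP).
#'
#' @param carbon_pool C, gC/m2.
#' @param carbon_turnover T, yr (> 0).
#' @param corrected_area S', m2.
#' @param npp gC/m2/yr.
#' @param em_npp the record's NPP service MAX(R), sej/yr.
#' @return list with `value` (sej/yr) and `uev_cs` (sej/gC).
#' @export
carbon_sequestration <- function(carbon_pool, carbon_turnover,
                                 corrected_area, npp, em_npp) {
  if (carbon_turnover <= 0) stop("carbon_turnover must be > 0", call. = FALSE)
  if (carbon_pool == 0 || corrected_area == 0)
    return(list(value = 0, uev_cs = NA_real_)) # no pool or no effective area
  if (npp <= 0)
    stop("undefined carbon-sequestration UEV: NPP is zero with a nonzero ",
         "carbon pool", call. = FALSE)
  uev_cs <- em_npp / (corrected_area * npp)
  list(value = (carbon_pool / carbon_turnover) * corrected_area * uev_cs,
       uev_cs = uev_cs)
}

#' Soil building service (terrestrial)
#'
#' Organic part: EmOM = EmNPP * k1 * k2 (litter/biomass ratio times detritus
#' carbon fraction). Mineral part: the maximum over mineral species of
#' (Pm * BD * D * S' * Rmin * cm2_per_m2 / Tmin) * UEV_mineral, with mineral
#' mass fraction Rmin and turnover Tmin from the constants block. Total is
#' organic + mineral.
#'
#' @param class ecosystem class code; must be terrestrial.
#' @param em_npp NPP service, sej/yr.
#' @param k1_litter,k2_detritus class fractions.
#' @param pm named vector of per-species mineral proportions.
#' @param bulk_density g/cm3; @param soil_depth cm; @param corrected_area m2.
#' @param params parameter set (mineral UEVs and constants).
#' @return list with `organic`, `mineral`, `value`, `winning_mineral`.
#' @export
soil_building <- function(class, em_npp, k1_litter, k2_detritus, pm,
                          bulk_density, soil_depth, corrected_area, params) {
  if (!is_terrestrial(class)) .stop_applicability("soil building", class)
  organic <- em_npp * k1_litter * k2_detritus
  cn <- params$consts
  species <- sort(names(params$uev$minerals))
  terms <- vapply(species, function(sp) {
    p <- if (sp %in% names(pm)) pm[[sp]] else 0
    (p * bulk_density * soil_depth * corrected_area *
        cn$mineral_fraction * cn$cm2_per_m2 / cn$mineral_turnover) *
      params$uev$minerals[[sp]]
  }, numeric(1))
  w <- if (length(terms)) which.max(terms) else integer(0)
  mineral <- if (length(terms)) unname(terms[w]) else 0
  list(organic = organic, mineral = mineral, value = organic + mineral,
       winning_mineral = if (length(terms)) species[w] else NA_character_)
}

#' Sediment building service (aquatic, non-eutrophic)
#'
#' Organic deposition OM = k4 * NPP with k4 = deposition/NPP ratio
#' (0.3037); the service is OM * k1_aq * k2_aq * kcal_to_j * S' * UEV_om,
#' with aquatic absorption k1_aq = 0.78 and the per-class g-to-kcal factor
#' k2_aq. Eutrophic records return `NA` with attribute `reason`: the
#' service is excluded from the total when the water body is eutrophic.
#'
#' @param class aquatic class code.
#' @param npp gC/m2/yr; @param k2_aq kcal/g; @param corrected_area m2.
#' @param eutrophic logical flag.
#' @param params parameter set.
#' @return sej/yr, or `NA` when eutrophic.
#' @export
sediment_building <- function(class, npp, k2_aq, corrected_area, eutrophic,
                              params) {
  if (!is_aquatic(class)) .stop_applicability("sediment building", class)
  if (isTRUE(eutrophic))
    return(structure(NA_real_, reason = "eutrophic water body"))
  cn <- params$consts
  om <- cn$deposition_npp_ratio * npp
  om * cn$aq_absorption * k2_aq * cn$kcal_to_j * corrected_area * params$uev$om
}

#' Groundwater recharge service
#'
#' P * S' * rho_water * k * g_per_kg * UEV_w: the emergy of the infiltrated
#' rain mass.
#'
#' @param precipitation m/yr; @param corrected_area m2.
#' @param infiltration_coeff fraction in \[0, 1\].
#' @param params parameter set.
#' @return sej/yr.
#' @export
groundwater_recharge <- function(precipitation, corrected_area,
                                 infiltration_coeff, params) {
  if (infiltration_coeff < 0 || infiltration_coeff > 1)
    stop("infiltration_coeff must lie in [0, 1]", call. = FALSE)
  cn <- params$consts
  precipitation * corrected_area * cn$rho_water * infiltration_coeff *
    cn$g_per_kg * params$uev$w
}

#' Air purification service
#'
#' Human-health part: sum over air pollutants of uptake M (kg/ha/yr) times
#' area (ha) times DALY, scaled by tau. Ecosystem-quality part: sum of
#' M * PDF * MAX(R). The total is HH + EQ. Pollutants missing from the
#' uptake table count as zero uptake (warning).
#'
#' @param class ecosystem class code.
#' @param corrected_area S', m2 (converted to ha internally via the declared
#'   bridge).
#' @param max_ren the record's MAX(R), sej/yr.
#' @param tau cognition driver, sej/cap.
#' @param params parameter set.
#' @return list with `hh`, `eq`, `value`.
#' @export
air_purification <- function(class, corrected_area, max_ren, tau, params) {
  f <- params$air$factors
  f <- f[order(f$pollutant), , drop = FALSE]
  area_ha <- corrected_area / params$consts$m2_per_ha
  hh <- 0; eq <- 0
  for (i in seq_len(nrow(f))) {
    p <- f$pollutant[i]
    m <- if (p %in% rownames(params$air$uptake) &&
             class %in% colnames(params$air$uptake)) {
      params$air$uptake[p, class]
    } else {
      warning("no uptake entry for pollutant ", p, " in class ", class,
              "; treated as zero", call. = FALSE)
      0
    }
    hh <- hh + m * area_ha * f$daly[i]
    eq <- eq + m * f$pdf[i] * max_ren
  }
  hh <- hh * tau
  list(hh = hh, eq = eq, value = hh + eq)
}

#' Water purification service (aquatic)
#'
#' Per heavy metal: HH term M * NPP * S' * DALYp * tau / T and EQ term
#' M * NPP * PDFp * Em_sp / T, where Em_sp is the record's local
#' renewable resource MAX(R) and T the metal's turnover time. The implicit
#' mg/kg x gC/m2/yr dimensional chain is bridged by the declared
#' `wp_bridge` constant.
#'
#' @param class aquatic class code.
#' @param npp gC/m2/yr; @param corrected_area m2; @param tau sej/cap.
#' @param em_sp local renewable resource MAX(R), sej/yr.
#' @param params parameter set.
#' @return list with `hh`, `eq`, `value`.
#' @export
water_purification <- function(class, npp, corrected_area, tau, em_sp,
                               params) {
  if (!is_aquatic(class)) .stop_applicability("water purification", class)
  f <- params$water$factors
  f <- f[order(f$metal), , drop = FALSE]
  if (any(f$turnover <= 0)) stop("metal turnover must be > 0", call. = FALSE)
  br <- params$consts$wp_bridge
  hh <- 0; eq <- 0
  for (i in seq_len(nrow(f))) {
    mt <- f$metal[i]
    m <- if (mt %in% rownames(params$water$removal) &&
             class %in% colnames(params$water$removal)) {
      params$water$removal[mt, class]
    } else {
      warning("no removal entry for metal ", mt, " in class ", class,
              "; treated as zero", call. = FALSE)
      0
    }
    # HH carries the area factor; the EQ term does not (it scales with the
    # local renewable resource Em_sp instead)
    hh <- hh + br * m * npp * corrected_area * f$daly[i] * tau / f$turnover[i]
    eq <- eq + br * m * npp * f$pdf[i] * em_sp / f$turnover[i]
  }
  list(hh = hh, eq = eq, value = hh + eq)
}

#' Soil retention service (terrestrial)
#'
#' G * S'(ha) * rom * g_per_t * kr1 * kcal_to_j * UEV_sl: the emergy of the
#' organic matter in the retained soil mass.
#'
#' @param class terrestrial class code.
#' @param retention_amount G, t/ha/yr.
#' @param corrected_area S', m2 (bridged to ha).
#' @param som_fraction rom, fraction.
#' @param params parameter set.
#' @return sej/yr.
#' @export
soil_retention <- function(class, retention_amount, corrected_area,
                           som_fraction, params) {
  if (!is_terrestrial(class)) .stop_applicability("soil retention", class)
  cn <- params$consts
  retention_amount * (corrected_area / cn$m2_per_ha) * som_fraction *
    cn$g_per_t * cn$kr1 * cn$kcal_to_j * params$uev$sl
}

#' Microclimate regulation service
#'
#' Ee * S' * UEV_et: the emergy of the transpired water flux.
#'
#' @param evapotranspiration Ee, g/m2/yr.
#' @param corrected_area S', m2.
#' @param params parameter set.
#' @return sej/yr.
#' @export
microclimate_regulation <- function(evapotranspiration, corrected_area,
                                    params) {
  evapotranspiration * corrected_area * params$uev$et
}

#' Materials transport service (river only)
#'
#' S' * Ra * rho_water * runoff_rate * h * g * UEV_rgeo: the geopotential
#' emergy of the runoff fraction of rainfall over the reach.
#'
#' @param class class code; must be river (A4).
#' @param corrected_area m2; @param rainfall Ra, m/yr; @param elevation h, m.
#' @param params parameter set.
#' @return sej/yr.
#' @export
materials_transport <- function(class, corrected_area, rainfall, elevation,
                                params) {
  if (!is_river(class)) .stop_applicability("materials transport", class)
  cn <- params$consts
  corrected_area * rainfall * cn$rho_water * cn$runoff_rate * elevation *
    cn$gravity * params$uev$rgeo
}

#' Hydropower potential service (river only, nature's contribution)
#'
#' Sum over dams of a rain term Sdc * Rd * rho_water * hg_mass_conv * UEV_r
#' and a mountain-building term Sdc * rd * cm3_per_m3 * rho_mountain *
#' UEV_mountain. No dams means zero.
#'
#' @param class class code; must be river (A4).
#' @param dams data.frame of the record's dams (may be empty); see
#'   [validate_dams()].
#' @param params parameter set.
#' @return list with `rain`, `mountain`, `value`.
#' @export
hydropower_potential <- function(class, dams, params) {
  if (!is_river(class)) .stop_applicability("hydropower potential", class)
  cn <- params$consts
  if (is.null(dams) || nrow(dams) == 0)
    return(list(rain = 0, mountain = 0, value = 0))
  rain <- sum(dams$catchment_area * dams$rainfall * cn$rho_water *
                cn$hg_mass_conv * params$uev$r)
  mountain <- sum(dams$catchment_area * dams$deviation_rate *
                    cn$cm3_per_m3 * cn$rho_mountain * params$uev$mountain)
  list(rain = rain, mountain = mountain, value = rain + mountain)
}

#' Climate regulation service
#'
#' Per greenhouse gas: HH term C * (DALYg / LT) * S' * tau and EQ term
#' C * (PDFg / LT) * Em_sp, summed over CO2, CH4, NOx and HFC; LT is the
#' gas lifetime.
#'
#' @param class ecosystem class code.
#' @param corrected_area S', m2.
#' @param tau sej/cap; @param em_sp MAX(R), sej/yr.
#' @param params parameter set.
#' @return list with `hh`, `eq`, `value`.
#' @export
climate_regulation <- function(class, corrected_area, tau, em_sp, params) {
  f <- params$ghg$factors
  f <- f[order(f$gas), , drop = FALSE]
  if (any(f$lifetime <= 0)) stop("gas lifetime must be > 0", call. = FALSE)
  hh <- 0; eq <- 0
  for (i in seq_len(nrow(f))) {
    g <- f$gas[i]
    cval <- if (g %in% rownames(params$ghg$sequestration) &&
                class %in% colnames(params$ghg$sequestration)) {
      params$ghg$sequestration[g, class]
    } else {
      warning("no sequestration entry for gas ", g, " in class ", class,
              "; treated as zero", call. = FALSE)
      0
    }
    hh <- hh + cval * (f$daly[i] / f$lifetime[i]) * corrected_area * tau
    eq <- eq + cval * (f$pdf[i] / f$lifetime[i]) * em_sp
  }
  list(hh = hh, eq = eq, value = hh + eq)
}

#' Compute the full service ledger for a record table
#'
#' Runs area correction, the renewable MAX rule and all applicable services
#' per record, honouring the applicability matrix: services a class does not
#' provide are `NA` (absent), never zero. Sub-components (HH/EQ for
#' AP/WP/CR, organic/mineral for SB, rain/mountain for HG) and MAX-rule
#' metadata are kept.
#'
#' @param records validated unit-record table.
#' @param params parameter set.
#' @param cognition data.frame with `epoch`, `health_expenditure`,
#'   `population`, `emergy_money_ratio` (one row per epoch present).
#' @param dams dam table (river records), may be `NULL`.
#' @param ndvi_support,water_vf passed to [compute_corrected_areas()].
#' @return a wide "service ledger" data.frame: record keys, `vf`,
#'   `corrected_area`, `max_ren`, `ren_winner`, `ren_factor`, `tau`, one
#'   column per service (`npp`, `cs`, `sb`, `sba`, `gr`, `ap`, `wp`, `sr`,
#'   `mr`, `mt`, `hg`, `cr`) and sub-component columns (`sb_organic`,
#'   `sb_mineral`, `winning_mineral`, `ap_hh`, `ap_eq`, `wp_hh`, `wp_eq`,
#'   `cr_hh`, `cr_eq`, `hg_rain`, `hg_mountain`).
#' @export
compute_services <- function(records, params, cognition, dams = NULL,
                             ndvi_support = "extent", water_vf = "one") {
  validate_records(records)
  validate_params(params)
  if (!is.null(dams)) validate_dams(dams)
  if (!all(c("epoch", "health_expenditure", "population",
             "emergy_money_ratio") %in% names(cognition)))
    stop("cognition table needs epoch, health_expenditure, population, ",
         "emergy_money_ratio", call. = FALSE)
  if (!all(records$epoch %in% cognition$epoch))
    stop("cognition inputs missing for epoch(s): ",
         paste(setdiff(records$epoch, cognition$epoch), collapse = ", "),
         call. = FALSE)

  recs <- compute_corrected_areas(records, ndvi_support, water_vf)
  recs <- npp_service(recs)
  tau_by_epoch <- stats::setNames(
    tau_h(cognition$health_expenditure, cognition$emergy_money_ratio,
          cognition$population),
    cognition$epoch)
  recs$tau <- unname(tau_by_epoch[as.character(recs$epoch)])

  cc <- params$class_consts
  n <- nrow(recs)
  out <- recs[c("unit_id", "ecosystem", "epoch", "raw_area", "vf",
                "corrected_area", "max_ren", "ren_winner", "ren_factor",
                "tau")]
  svc_cols <- c("npp", "cs", "sb", "sb_organic", "sb_mineral", "sba", "gr",
                "ap", "ap_hh", "ap_eq", "wp", "wp_hh", "wp_eq", "sr", "mr",
                "mt", "hg", "hg_rain", "hg_mountain", "cr", "cr_hh", "cr_eq")
  for (col in svc_cols) out[[col]] <- NA_real_
  out$winning_mineral <- NA_character_

  pm_cols <- grep("^pm_", names(recs), value = TRUE)
  for (i in seq_len(n)) {
    cl <- recs$ecosystem[i]
    k <- match(cl, cc$code)
    sprime <- recs$corrected_area[i]
    emnpp <- recs$max_ren[i]
    tau_i <- recs$tau[i]

    out$npp[i] <- emnpp
    cs <- carbon_sequestration(recs$carbon_pool[i], recs$carbon_turnover[i],
                               sprime, recs$npp[i], emnpp)
    out$cs[i] <- cs$value
    out$gr[i] <- groundwater_recharge(recs$precipitation[i], sprime,
                                      recs$infiltration_coeff[i], params)
    ap <- air_purification(cl, sprime, emnpp, tau_i, params)
    out$ap[i] <- ap$value; out$ap_hh[i] <- ap$hh; out$ap_eq[i] <- ap$eq
    out$mr[i] <- microclimate_regulation(recs$evapotranspiration[i], sprime,
                                         params)
    cr <- climate_regulation(cl, sprime, tau_i, emnpp, params)
    out$cr[i] <- cr$value; out$cr_hh[i] <- cr$hh; out$cr_eq[i] <- cr$eq

    if (is_terrestrial(cl)) {
      pm <- stats::setNames(as.numeric(recs[i, pm_cols]),
                            sub("^pm_", "", pm_cols))
      sb <- soil_building(cl, emnpp, cc$k1_litter[k], cc$k2_detritus[k], pm,
                          recs$bulk_density[i], recs$soil_depth[i], sprime,
                          params)
      out$sb[i] <- sb$value
      out$sb_organic[i] <- sb$organic
      out$sb_mineral[i] <- sb$mineral
      out$winning_mineral[i] <- sb$winning_mineral
      out$sr[i] <- soil_retention(cl, recs$retention_amount[i], sprime,
                                  recs$som_fraction[i], params)
    } else {
      out$sba[i] <- sediment_building(cl, recs$npp[i], cc$k2_aq[k], sprime,
                                      recs$eutrophic[i], params)
      wp <- water_purification(cl, recs$npp[i], sprime, tau_i, emnpp, params)
      out$wp[i] <- wp$value; out$wp_hh[i] <- wp$hh; out$wp_eq[i] <- wp$eq
      if (is_river(cl)) {
        out$mt[i] <- materials_transport(cl, sprime, recs$precipitation[i],
                                         recs$elevation[i], params)
        d <- if (is.null(dams)) NULL else
          dams[dams$unit_id == recs$unit_id[i] & dams$epoch == recs$epoch[i], ,
               drop = FALSE]
        hg <- hydropower_potential(cl, d, params)
        out$hg[i] <- hg$value
        out$hg_rain[i] <- hg$rain
        out$hg_mountain[i] <- hg$mountain
      }
    }
  }
  out
}
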