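# First-order partial-differential attribution. The change in a class's
# total ES between two epochs is decomposed into the contribution of the
# natural driver (the per-area intensity of the winning max-group service),
# the cognition driver tau and the human driver S (area), plus a residual
# that absorbs all higher-order interaction terms.

#' Round half away from zero
#'
#' Report tables print integer percents rounded half away from zero
#' (`round()` in R rounds half to even, which does not reproduce printed
#' tables).
#'
#' @param x numeric; @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' General first-order driver decomposition
#'
#' For a model Y(drivers), the contribution of driver X is the partial
#' derivative of Y at the baseline state times the driver's change:
#' Cr_X = dY/dX|_t0 * (X_t1 - X_t0). The residual is
#' delta = [Y(t1) - Y(t0)] - sum(Cr_X), with Y evaluated exactly at both
#' states, so contributions + delta = dY holds bit-consistently.
#' Elasticities eps_X = dY/dX * X0 / Y0 are reported when defined (they are
#' algebraically redundant with the partial-derivative form, which is always
#' used for the contributions themselves).
#'
#' @param model list with `value(state)` returning Y and `partials(state)`
#'   returning a named vector of dY/dX, for a named-list `state` of drivers.
#' @param baseline,end named lists of driver values at the two epochs.
#' @return list: `contributions` (named), `delta`, `dY`, `elasticities`
#'   (named, `NA` where baseline driver or Y is zero).
#' @examples
#' m <- list(value = function(s) s$E * s$S + s$S * s$tau,
#'           partials = function(s) c(E = s$S, tau = s$S, S = s$E + s$tau))
#' decompose_general(m, list(E = 2, tau = 1, S = 10),
#'                   list(E = 3, tau = 1, S = 12))
#' @export
decompose_general <- function(model, baseline, end) {
  drv <- names(model$partials(baseline))
  stopifnot(all(drv %in% names(baseline)), all(drv %in% names(end)))
  p0 <- model$partials(baseline)
  y0 <- model$value(baseline)
  y1 <- model$value(end)
  dx <- vapply(drv, function(d) end[[d]] - baseline[[d]], numeric(1))
  contrib <- p0[drv] * dx
  dY <- y1 - y0
  delta <- dY - sum(contrib)
  x0 <- vapply(drv, function(d) baseline[[d]], numeric(1))
  eps <- if (y0 != 0) p0[drv] * x0 / y0 else
    rep(NA_real_, length(drv))
  names(eps) <- drv
  list(contributions = contrib, delta = delta, dY = dY, elasticities = eps)
}

#' Per-class attribution model
#'
#' The total ES of one class is modelled as
#' T = (1 + k2) * X * S + (k1 + k4) * S * tau + k3 * S,
#' where X is the per-area intensity of the winning max-group service
#' (the natural driver), S the (corrected) ecosystem area and tau the
#' cognition driver. k1 = AC * DALY and k4 = CS * DALY collect the
#' human-health terms, k2 = AC * PDF the ecosystem-quality terms and
#' k3 = RM the pure-area soil-retention term; all four are constants over
#' the comparison. Partials: dT/dX = (1 + k2) * S, dT/dtau = (k1 + k4) * S,
#' dT/dS = (1 + k2) * X + (k1 + k4) * tau + k3.
#'
#' @param k1k4 combined human-health coefficient (k1 + k4), >= 0.
#' @param k2 ecosystem-quality coefficient, >= 0.
#' @param k3 pure-area coefficient, >= 0.
#' @return a model usable by [decompose_general()], drivers `X`, `tau`, `S`.
#' @export
ecosystem_model <- function(k1k4, k2, k3) {
  stopifnot(k1k4 >= 0, k2 >= 0, k3 >= 0)
  list(
    value = function(s) (1 + k2) * s$X * s$S + k1k4 * s$S * s$tau + k3 * s$S,
    partials = function(s) c(X = (1 + k2) * s$S,
                             tau = k1k4 * s$S,
                             S = (1 + k2) * s$X + k1k4 * s$tau + k3),
    coef = c(k1k4 = k1k4, k2 = k2, k3 = k3)
  )
}

# The winning-service natural factor. MR -> ET; GR -> precipitation;
# CS -> NPP (biomass carbon density recorded as sub-factor); NPP/SB/SBa ->
# the natural factor of the winning renewable flow; HG -> elevation.
.dispatch_factor <- function(winner, ren_factor) {
  switch(winner,
         mr = "evapotranspiration",
         gr = "precipitation",
         cs = "npp",
         hg = "elevation",
         npp = ren_factor, sb = ren_factor, sba = ren_factor,
         stop("unknown max-group winner: ", winner, call. = FALSE))
}

# The R-part of the total at epoch 1 evaluated under the baseline winner,
# river case and dam position (the baseline structure defines the model; a
# winner switch lands in the residual).
.r_part_under <- function(winner, river_case, x_pos, row1) {
  if (identical(winner, "hg"))
    return(list(max_part = row1$hg, hg_add = 0))
  v <- row1[[winner]]
  if (is.na(v)) v <- 0 # winner service absent at t1 (e.g. turned eutrophic)
  hg_add <- 0
  if (!is.na(river_case)) {
    if (river_case == "a2") v <- (1 - x_pos) * v
    if (river_case %in% c("a1", "a2", "b") && !is.na(row1$hg))
      hg_add <- row1$hg
  }
  list(max_part = v, hg_add = hg_add)
}

#' Attribute ES change per (unit, class)
#'
#' For every (unit, ecosystem) pair present at both epochs, estimates the
#' model constants from the baseline ledger (so the model reproduces the
#' baseline total exactly), evaluates the model at both epochs and
#' decomposes the change into natural, cognition and area contributions
#' plus the residual. The baseline max-group winner defines the model; if
#' the winner differs at the end epoch the switch's effect lands in the
#' residual and the pair is flagged.
#'
#' @param ledger wide service ledger (both epochs) from [compute_services()].
#' @param totals per-record totals (both epochs) from [compute_totals()].
#' @param epochs length-2 vector: baseline epoch label, end epoch label.
#' @return data.frame, one row per (unit, ecosystem): contributions `cr_r`,
#'   `cr_tau`, `cr_s`, `delta` (sej/yr), `d_total` (model change),
#'   `d_total_ledger` (ledger change, may diverge; divergence is part of
#'   the model error, reported not hidden), elasticities, rates (rates sum
#'   to 1 exactly via `rate_delta = 1 - sum`), `natural_factor`,
#'   `winner_r`, `winner_switch`.
#' @export
attribute_changes <- function(ledger, totals, epochs) {
  stopifnot(length(epochs) == 2)
  l0 <- ledger[ledger$epoch == epochs[1], ]
  l1 <- ledger[ledger$epoch == epochs[2], ]
  t0 <- totals[totals$epoch == epochs[1], ]
  t1 <- totals[totals$epoch == epochs[2], ]
  key0 <- paste(l0$unit_id, l0$ecosystem)
  key1 <- paste(l1$unit_id, l1$ecosystem)
  miss <- c(setdiff(key0, key1), setdiff(key1, key0))
  if (length(miss))
    stop("(unit, class) pairs present in only one epoch: ",
         paste(miss, collapse = "; "), call. = FALSE)
  ord <- order(key0)
  l0 <- l0[ord, ]; l1 <- l1[match(key0[ord], key1), ]
  kt0 <- paste(t0$unit_id, t0$ecosystem)
  kt1 <- paste(t1$unit_id, t1$ecosystem)
  t0 <- t0[match(key0[ord], kt0), ]
  t1 <- t1[match(key0[ord], kt1), ]

  n <- nrow(l0)
  out <- data.frame(unit_id = l0$unit_id, ecosystem = l0$ecosystem,
                    stringsAsFactors = FALSE)
  num_cols <- c("cr_r", "cr_tau", "cr_s", "delta", "d_total",
                "d_total_ledger", "eps_r", "eps_tau", "eps_s")
  for (cl in num_cols) out[[cl]] <- NA_real_
  out$natural_factor <- out$winner_r <- NA_character_
  out$winner_switch <- FALSE

  for (i in seq_len(n)) {
    r0 <- l0[i, ]; r1 <- l1[i, ]
    w <- t0$winner_r[i]
    S0 <- r0$corrected_area; S1 <- r1$corrected_area
    R0 <- t0$r_component[i] + t0$hg_additive[i]
    rp1 <- .r_part_under(w, t0$river_case[i], t0$x_pos[i], r1)
    R1 <- rp1$max_part + rp1$hg_add
    hh0 <- sum(c(r0$ap_hh, r0$wp_hh, r0$cr_hh), na.rm = TRUE)
    eq0 <- sum(c(r0$ap_eq, r0$wp_eq, r0$cr_eq), na.rm = TRUE)
    sr0 <- if (is.na(r0$sr)) 0 else r0$sr
    a <- if (S0 > 0 && r0$tau > 0) hh0 / (S0 * r0$tau) else 0
    b <- if (R0 > 0) eq0 / R0 else 0
    cc <- if (S0 > 0) sr0 / S0 else 0
    X0 <- if (S0 > 0) R0 / S0 else 0
    X1 <- if (S1 > 0) R1 / S1 else X0
    model <- ecosystem_model(a, b, cc)
    dec <- decompose_general(model,
                             list(X = X0, tau = r0$tau, S = S0),
                             list(X = X1, tau = r1$tau, S = S1))
    out$cr_r[i] <- dec$contributions[["X"]]
    out$cr_tau[i] <- dec$contributions[["tau"]]
    out$cr_s[i] <- dec$contributions[["S"]]
    out$delta[i] <- dec$delta
    out$d_total[i] <- dec$dY
    out$d_total_ledger[i] <- t1$total[i] - t0$total[i]
    out$eps_r[i] <- dec$elasticities[["X"]]
    out$eps_tau[i] <- dec$elasticities[["tau"]]
    out$eps_s[i] <- dec$elasticities[["S"]]
    out$winner_r[i] <- w
    out$natural_factor[i] <- .dispatch_factor(w, r0$ren_factor)
    out$winner_switch[i] <- !identical(w, t1$winner_r[i])
  }
  if (any(out$winner_switch))
    message(sum(out$winner_switch),
            " record(s) switched max-group winner between epochs; ",
            "the switch effect is absorbed by the residual")
  contribution_rates(out)
}

#' Contribution rates
#'
#' rate_X = Cr_X / dT for each driver; the residual rate is defined as
#' 1 - (rate_R + rate_tau + rate_S) so the four rates close to exactly 1.
#' Rows with dT = 0 get `NA` rates and `rates_undefined = TRUE`;
#' contributions are still reported. Rates are fractions and may lie
#' outside \[0, 1\].
#'
#' @param results data.frame with `cr_r`, `cr_tau`, `cr_s`, `delta`,
#'   `d_total`.
#' @return `results` with `rate_r`, `rate_tau`, `rate_s`, `rate_delta`,
#'   `rates_undefined` added (recomputed if present).
#' @export
contribution_rates <- function(results) {
  undef <- results$d_total == 0
  dt <- ifelse(undef, NA_real_, results$d_total)
  results$rate_r <- results$cr_r / dt
  results$rate_tau <- results$cr_tau / dt
  results$rate_s <- results$cr_s / dt
  results$rate_delta <- 1 - (results$rate_r + results$rate_tau +
                               results$rate_s)
  results$rates_undefined <- undef
  results
}

#' Aggregate attribution results
#'
#' Sums driver contributions over classes/units: the aggregate change is
#' the sum of per-class changes, and each aggregate driver change is the
#' sum of per-class changes weighted by their per-class rates (identically,
#' the sum of per-class contributions). Aggregate rates are recomputed from
#' the sums and the residual rate closes them to 1.
#'
#' @param results per-record attribution from [attribute_changes()].
#' @param by `"extent"` (default), `"unit"`, `"class"` or `"region"`.
#' @param region region assignment (for `by = "region"`).
#' @return data.frame, one row per group, with summed contributions,
#'   `d_total`, `d_total_ledger` and rates.
#' @export
aggregate_attribution <- function(results, by = c("extent", "unit", "class",
                                                  "region"), region = NULL) {
  by <- match.arg(by)
  key <- switch(by,
    extent = rep("extent", nrow(results)),
    unit = results$unit_id,
    class = results$ecosystem,
    region = {
      validate_region(region, unique(results$unit_id))
      region$zone[match(results$unit_id, region$unit_id)]
    })
  agg <- function(v) tapply(v, key, sum)
  out <- data.frame(group = names(agg(results$d_total)),
                    cr_r = as.numeric(agg(results$cr_r)),
                    cr_tau = as.numeric(agg(results$cr_tau)),
                    cr_s = as.numeric(agg(results$cr_s)),
                    delta = as.numeric(agg(results$delta)),
                    d_total = as.numeric(agg(results$d_total)),
                    d_total_ledger = as.numeric(agg(results$d_total_ledger)),
                    row.names = NULL, stringsAsFactors = FALSE)
  contribution_rates(out)
}

#' Regional driver-contribution summary table
#'
#' Builds the report table for precipitation-zone regions: per region the
#' driver contributions (sej/yr), their subtotal, the region's share of the
#' extent change (`ratio`), the subtotal per unit of total region area and
#' per unit of region ecosystem area (sej/m2/yr), and the driver
#' contribution rates. Percent columns are rounded half away from zero to
#' integers when `percent_rounding = TRUE`; full precision is kept in the
#' unrounded columns.
#'
#' @param region_contribs data.frame, one row per region: `zone`, `cr_r`,
#'   `cr_tau`, `cr_s`, `delta` (sej/yr).
#' @param areas optional data.frame `zone`, `total_area`, `ecosystem_area`
#'   (m2); zero areas yield `NA` intensities.
#' @param extent_delta denominator of `ratio`; defaults to the sum of the
#'   region subtotals.
#' @param class_contribs optional data.frame `zone`, `ecosystem`, `d_total`
#'   for per-class contribution rates per region.
#' @param percent_rounding round percent columns to integers.
#' @return list with `table` (per-region summary) and `class_rates`
#'   (per-region per-class percent shares of the region subtotal, or
#'   `NULL`).
#' @export
regional_summary <- function(region_contribs, areas = NULL,
                             extent_delta = NULL, class_contribs = NULL,
                             percent_rounding = TRUE) {
  rc <- region_contribs
  stopifnot(all(c("zone", "cr_r", "cr_tau", "cr_s", "delta") %in% names(rc)))
  rc$subtotal <- rc$cr_r + rc$cr_tau + rc$cr_s + rc$delta
  if (is.null(extent_delta)) extent_delta <- sum(rc$subtotal)
  rc$ratio <- rc$subtotal / extent_delta
  pct <- function(x) if (percent_rounding) round_half_away(100 * x) else 100 * x
  rc$ratio_pct <- pct(rc$ratio)
  rc$rate_r_pct <- pct(rc$cr_r / rc$subtotal)
  rc$rate_tau_pct <- pct(rc$cr_tau / rc$subtotal)
  rc$rate_s_pct <- pct(rc$cr_s / rc$subtotal)
  rc$rate_delta_pct <- pct(rc$delta / rc$subtotal)
  rc$intensity_total_area <- NA_real_
  rc$intensity_ecosystem_area <- NA_real_
  if (!is.null(areas)) {
    k <- match(rc$zone, areas$zone)
    tot_a <- areas$total_area[k]
    eco_a <- areas$ecosystem_area[k]
    rc$intensity_total_area <- ifelse(!is.na(tot_a) & tot_a > 0,
                                      rc$subtotal / tot_a, NA_real_)
    rc$intensity_ecosystem_area <- ifelse(!is.na(eco_a) & eco_a > 0,
                                          rc$subtotal / eco_a, NA_real_)
  }
  class_rates <- NULL
  if (!is.null(class_contribs)) {
    cc <- class_contribs
    sub <- rc$subtotal[match(cc$zone, rc$zone)]
    cc$rate_pct <- pct(cc$d_total / sub)
    class_rates <- cc
  }
  list(table = rc, class_rates = class_rates)
}

#' Natural-factor shares per unit
#'
#' For each spatial unit, groups the absolute natural-driver contributions
#' of its classes by their dispatched natural factor and normalises to
#' 100%. The sign of the unit's aggregate natural contribution is reported
#' as improvement (>= 0) or deterioration (< 0). Units whose every class
#' has a zero natural contribution are omitted.
#'
#' @param results per-record attribution from [attribute_changes()].
#' @return data.frame: `unit_id`, `natural_factor`, `share_pct` (summing to
#'   100 within a unit, factors ordered by decreasing share), `direction`.
#' @export
natural_factor_shares <- function(results) {
  out <- NULL
  for (u in unique(results$unit_id)) {
    r <- results[results$unit_id == u, ]
    mass <- tapply(abs(r$cr_r), r$natural_factor, sum)
    tot <- sum(mass)
    if (tot == 0) next
    sh <- 100 * mass / tot
    sh <- sort(sh, decreasing = TRUE)
    out <- rbind(out, data.frame(
      unit_id = u, natural_factor = names(sh), share_pct = as.numeric(sh),
      direction = if (sum(r$cr_r) >= 0) "improvement" else "deterioration",
      row.names = NULL, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(unit_id = character(0), natural_factor = character(0),
                      share_pct = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  out
}
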