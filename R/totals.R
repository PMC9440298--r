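# Double-counting-safe totals. One ecological process can back several
# services (NPP, carbon sequestration, soil building, groundwater recharge
# and microclimate regulation all trace back to the same renewable input),
# so only the largest of that five-member group enters the total; the
# purification/retention/regulation services are additive.

.max5 <- function(vals, members) {
  ok <- !is.na(vals)
  if (!any(ok)) return(list(value = 0, winner = NA_character_))
  w <- which.max(vals[ok]) # first max: listing-order tie-break
  list(value = unname(vals[ok][w]), winner = members[ok][w])
}

.need <- function(row, cols) {
  bad <- cols[vapply(cols, function(cl) is.na(row[[cl]]), logical(1))]
  if (length(bad)) stop("missing required service value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
}

#' Total for a terrestrial ledger row
#'
#' total = max(NPP, CS, SB, GR, MR) + AP + SR + CR. Ties inside the max
#' group are broken by that listing order.
#'
#' @param row one ledger row (list or one-row data.frame) with service
#'   columns `npp`, `cs`, `sb`, `gr`, `mr`, `ap`, `sr`, `cr`.
#' @return list: `total`, `r_component`, `winner_r`, `additive`.
#' @export
total_terrestrial <- function(row) {
  members <- c("npp", "cs", "sb", "gr", "mr")
  .need(row, c(members, "ap", "sr", "cr"))
  m <- .max5(vapply(members, function(cl) row[[cl]], numeric(1)), members)
  additive <- row$ap + row$sr + row$cr
  list(total = m$value + additive, r_component = m$value,
       winner_r = m$winner, additive = additive)
}

#' Total for a non-river aquatic ledger row
#'
#' total = max(NPP, CS, SBa, GR, MR) + WP + AP + CR. A eutrophic record has
#' no sediment-building service (`sba` is `NA`), so SBa simply drops out of
#' the max group.
#'
#' @param row one ledger row with `npp`, `cs`, `sba`, `gr`, `mr`, `wp`,
#'   `ap`, `cr`.
#' @return list: `total`, `r_component`, `winner_r`, `additive`.
#' @export
total_other_aquatic <- function(row) {
  members <- c("npp", "cs", "sba", "gr", "mr")
  .need(row, c(setdiff(members, "sba"), "wp", "ap", "cr"))
  m <- .max5(vapply(members, function(cl) row[[cl]], numeric(1)), members)
  additive <- row$wp + row$ap + row$cr
  list(total = m$value + additive, r_component = m$value,
       winner_r = m$winner, additive = additive)
}

#' Total for a river ledger row
#'
#' Rivers never count materials transport in the total (runoff geopotential
#' already backs the NPP service). The treatment of hydropower depends on
#' whether runoff geopotential is the winning renewable flow (case "a") or
#' not (case "b"), and on the dam position X, the hydropower station's
#' distance from the river head as a fraction of reach length:
#' \itemize{
#'   \item case a, X = 0: max5 + WP + AP + HG + CR
#'   \item case a, X = 1: (1 - X) * max5 + WP + AP + HG + CR
#'   \item case a, 0 < X < 1: max(max5, HG) + WP + AP + CR
#'   \item case b (any X), or no dams: max5 + WP + AP + HG + CR
#' }
#' where max5 = max(NPP, CS, SBa, GR, MR).
#'
#' @param row one ledger row with the aquatic service columns plus `hg` and
#'   `ren_winner`.
#' @param x_pos dam position X in \[0, 1\] (ignored in case b; `NA` allowed
#'   when the river has no dams).
#' @return list: `total`, `r_component`, `winner_r`, `river_case` (one of
#'   "a1", "a2", "a3", "b"), `x_pos`, `additive`, `hg_additive`.
#' @export
total_river <- function(row, x_pos = NA_real_) {
  members <- c("npp", "cs", "sba", "gr", "mr")
  .need(row, c(setdiff(members, "sba"), "wp", "ap", "cr", "hg"))
  m <- .max5(vapply(members, function(cl) row[[cl]], numeric(1)), members)
  additive <- row$wp + row$ap + row$cr
  hg <- row$hg
  case_a <- identical(row$ren_winner, "runoff_geo")
  no_dams <- hg == 0 && (is.na(x_pos))
  if (!case_a || no_dams) {
    return(list(total = m$value + additive + hg, r_component = m$value,
                winner_r = m$winner, river_case = "b", x_pos = x_pos,
                additive = additive, hg_additive = hg))
  }
  if (is.na(x_pos) || x_pos < 0 || x_pos > 1)
    stop("river case a needs dam position X in [0, 1]", call. = FALSE)
  if (x_pos == 0) {
    list(total = m$value + additive + hg, r_component = m$value,
         winner_r = m$winner, river_case = "a1", x_pos = x_pos,
         additive = additive, hg_additive = hg)
  } else if (x_pos == 1) {
    r <- (1 - x_pos) * m$value
    list(total = r + additive + hg, r_component = r, winner_r = m$winner,
         river_case = "a2", x_pos = x_pos, additive = additive,
         hg_additive = hg)
  } else {
    if (hg > m$value) {
      list(total = hg + additive, r_component = hg, winner_r = "hg",
           river_case = "a3", x_pos = x_pos, additive = additive,
           hg_additive = 0)
    } else {
      list(total = m$value + additive, r_component = m$value,
           winner_r = m$winner, river_case = "a3", x_pos = x_pos,
           additive = additive, hg_additive = 0)
    }
  }
}

# Effective dam position for a river record: the emergy-weighted mean of
# per-dam positions (weight = the dam's rain + mountain emergy terms), or an
# error in strict mode when dams disagree.
.dam_position <- function(dams, params, multi_dam) {
  if (is.null(dams) || nrow(dams) == 0) return(NA_real_)
  if (nrow(dams) == 1) return(dams$position_x)
  xs <- unique(dams$position_x)
  if (length(xs) == 1) return(xs)
  if (multi_dam == "strict")
    stop("multiple dams with conflicting positions on one river record",
         call. = FALSE)
  cn <- params$consts
  w <- dams$catchment_area * dams$rainfall * cn$rho_water * cn$hg_mass_conv *
    params$uev$r +
    dams$catchment_area * dams$deviation_rate * cn$cm3_per_m3 *
    cn$rho_mountain * params$uev$mountain
  if (sum(w) == 0) mean(dams$position_x) else sum(w * dams$position_x) / sum(w)
}

#' Per-record totals from a service ledger
#'
#' Applies the class-appropriate summation rule to every ledger row and
#' persists the max-group winner, river case label and dam position, all of
#' which attribution dispatch depends on.
#'
#' @param ledger wide service ledger from [compute_services()].
#' @param dams dam table (for river dam positions), may be `NULL`.
#' @param params parameter set (used to emergy-weight multi-dam positions).
#' @param multi_dam `"weighted"` (default: emergy-weighted mean position) or
#'   `"strict"` (error on conflicting dam positions).
#' @return data.frame: record keys, `total`, `r_component`, `winner_r`,
#'   `river_case`, `x_pos`, `additive`, `hg_additive`.
#' @export
compute_totals <- function(ledger, dams = NULL, params = NULL,
                           multi_dam = c("weighted", "strict")) {
  multi_dam <- match.arg(multi_dam)
  out <- ledger[c("unit_id", "ecosystem", "epoch", "raw_area",
                  "corrected_area", "ren_winner", "ren_factor", "tau")]
  n <- nrow(ledger)
  out$total <- out$r_component <- out$additive <- out$hg_additive <-
    out$x_pos <- NA_real_
  out$winner_r <- out$river_case <- NA_character_
  for (i in seq_len(n)) {
    row <- ledger[i, ]
    cl <- row$ecosystem
    res <- if (is_terrestrial(cl)) {
      c(total_terrestrial(row), list(river_case = NA_character_,
                                     x_pos = NA_real_, hg_additive = 0))
    } else if (!is_river(cl)) {
      c(total_other_aquatic(row), list(river_case = NA_character_,
                                       x_pos = NA_real_, hg_additive = 0))
    } else {
      d <- if (is.null(dams)) NULL else
        dams[dams$unit_id == row$unit_id & dams$epoch == row$epoch, ,
             drop = FALSE]
      total_river(row, .dam_position(d, params, multi_dam))
    }
    out$total[i] <- res$total
    out$r_component[i] <- res$r_component
    out$winner_r[i] <- res$winner_r
    out$river_case[i] <- res$river_case
    out$x_pos[i] <- res$x_pos
    out$additive[i] <- res$additive
    out$hg_additive[i] <- res$hg_additive
  }
  out
}

#' Aggregate totals by group
#'
#' Sums per-record totals by ecosystem class, unit, region or the whole
#' extent, within a single epoch. Aggregation is conservative: the extent
#' total equals the sum over any partition of units.
#'
#' @param totals per-record totals from [compute_totals()] (single epoch).
#' @param by one of `"class"`, `"unit"`, `"region"`, `"extent"`.
#' @param region region assignment table (needed for `by = "region"`).
#' @return data.frame with `group`, `epoch`, `total`.
#' @export
aggregate_totals <- function(totals, by = c("class", "unit", "region",
                                            "extent"), region = NULL) {
  by <- match.arg(by)
  if (length(unique(totals$epoch)) > 1)
    stop("mixed epochs in one aggregation call", call. = FALSE)
  key <- switch(by,
    class = totals$ecosystem,
    unit = totals$unit_id,
    region = {
      validate_region(region, unique(totals$unit_id))
      region$zone[match(totals$unit_id, region$unit_id)]
    },
    extent = rep("extent", nrow(totals)))
  if (nrow(totals) == 0)
    return(data.frame(group = character(0), epoch = character(0),
                      total = numeric(0), stringsAsFactors = FALSE))
  agg <- tapply(totals$total, key, sum)
  data.frame(group = names(agg), epoch = totals$epoch[1],
             total = as.numeric(agg), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Change rate between two epochs
#'
#' (T_t1 - T_t0) / T_t0 per group. Groups with a zero baseline get `NA`
#' with an `undefined` flag rather than a silent value.
#'
#' @param totals_t0,totals_t1 aggregated totals (from [aggregate_totals()])
#'   for the two epochs, matched on `group`.
#' @return data.frame with `group`, `t0`, `t1`, `change_rate`, `undefined`.
#' @export
change_rate <- function(totals_t0, totals_t1) {
  m <- merge(totals_t0[c("group", "total")], totals_t1[c("group", "total")],
             by = "group", suffixes = c("_t0", "_t1"), all = TRUE)
  m$total_t0[is.na(m$total_t0)] <- 0
  m$total_t1[is.na(m$total_t1)] <- 0
  undef <- m$total_t0 == 0
  rate <- ifelse(undef, NA_real_, (m$total_t1 - m$total_t0) / m$total_t0)
  data.frame(group = m$group, t0 = m$total_t0, t1 = m$total_t1,
             change_rate = rate, undefined = undef,
             stringsAsFactors = FALSE)
}
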