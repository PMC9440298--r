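test_that("the general decomposition reproduces the bilinear worked
           example", {
  we <- worked_example()$decomp
  d <- decompose_general(we$model, we$baseline, we$end)
  expect_equal(d$contributions, we$expected, tolerance = 0)
  expect_identical(d$delta, we$expected_delta) # the dE*dS interaction
  # single-driver change: no residual, one contribution
  d1 <- decompose_general(we$model, we$baseline, list(E = 3, tau = 1, S = 10))
  expect_identical(unname(d1$contributions), c(10, 0, 0))
  expect_identical(d1$delta, 0)
  # no change at all
  d0 <- decompose_general(we$model, we$baseline, we$baseline)
  expect_true(all(d0$contributions == 0) && d0$delta == 0)
})

test_that("the per-class model matches its stated partials", {
  m <- ecosystem_model(k1k4 = 1, k2 = 0, k3 = 0)
  s <- list(X = 2, tau = 1, S = 10)
  expect_identical(m$value(s), 2 * 10 + 10 * 1) # reduces to X*S + S*tau
  m2 <- ecosystem_model(k1k4 = 2, k2 = 0, k3 = 4)
  p <- m2$partials(list(X = 3, tau = 1, S = 10))
  expect_identical(unname(p["tau"]), 20) # (k1+k4) * S
  expect_identical(unname(p["S"]), 9)    # (1+k2)*X + (k1+k4)*tau + k3
  expect_error(ecosystem_model(-1, 0, 0))
})

test_that("contribution rates close to exactly one", {
  r <- data.frame(cr_r = 10, cr_tau = 0, cr_s = 6, delta = 2, d_total = 18)
  rr <- contribution_rates(r)
  expect_equal(rr$rate_r, 10 / 18, tolerance = 0)
  expect_equal(rr$rate_s, 6 / 18, tolerance = 0)
  expect_identical(rr$rate_r + rr$rate_tau + rr$rate_s + rr$rate_delta, 1)
  # single nonzero contribution with no residual has rate 1
  one <- contribution_rates(data.frame(cr_r = 0, cr_tau = 5, cr_s = 0,
                                       delta = 0, d_total = 5))
  expect_identical(one$rate_tau, 1)
  # zero total change: undefined, flagged, contributions retained
  z <- contribution_rates(data.frame(cr_r = 1, cr_tau = -1, cr_s = 0,
                                     delta = 0, d_total = 0))
  expect_true(z$rates_undefined)
  expect_true(is.na(z$rate_r))
  expect_identical(z$cr_r, 1)
})

test_that("residuals equal the analytic bilinear interaction remainder", {
  set.seed(13)
  for (i in 1:200) {
    k1k4 <- runif(1, 0, 2); k2 <- runif(1, 0, 1); k3 <- runif(1, 0, 5)
    m <- ecosystem_model(k1k4, k2, k3)
    b <- list(X = runif(1, 0.1, 10), tau = runif(1, 0.1, 10),
              S = runif(1, 0.1, 10))
    e <- list(X = b$X * runif(1, 0.5, 2), tau = b$tau * runif(1, 0.5, 2),
              S = b$S * runif(1, 0.5, 2))
    d <- decompose_general(m, b, e)
    remainder <- (1 + k2) * (e$X - b$X) * (e$S - b$S) +
      k1k4 * (e$tau - b$tau) * (e$S - b$S)
    expect_equal(d$delta, remainder, tolerance = 1e-10)
    r <- contribution_rates(data.frame(
      cr_r = d$contributions[["X"]], cr_tau = d$contributions[["tau"]],
      cr_s = d$contributions[["S"]], delta = d$delta, d_total = d$dY))
    if (!r$rates_undefined)
      expect_equal(r$rate_r + r$rate_tau + r$rate_s + r$rate_delta, 1,
                   tolerance = 1e-12)
  }
})

test_that("a pure cognition change leaves no residual (one-driver limit)", {
  m <- ecosystem_model(1.5, 0.3, 2)
  b <- list(X = 4, tau = 2, S = 7)
  e <- list(X = 4, tau = 5, S = 7)
  d <- decompose_general(m, b, e)
  expect_identical(d$contributions[["X"]], 0)
  expect_identical(d$contributions[["S"]], 0)
  expect_equal(d$delta, 0, tolerance = 1e-12)
  expect_equal(d$contributions[["tau"]], d$dY, tolerance = 1e-12)
})

test_that("attribution is scale invariant in the emergy unit", {
  pl <- run_pipeline(fixture_spec(seed = 31, n_units = 3,
                                  deltas = list(area = 0.1,
                                                evapotranspiration = 0.2,
                                                tau = 0.3)))
  cc <- 1e3
  led2 <- pl$ledger
  emergy_cols <- c(colnames(service_applicability()),
                   "sb_organic", "sb_mineral", "ap_hh", "ap_eq", "wp_hh",
                   "wp_eq", "cr_hh", "cr_eq", "hg_rain", "hg_mountain",
                   "max_ren", "tau")
  for (cl in emergy_cols) led2[[cl]] <- cc * led2[[cl]]
  tot2 <- pl$totals
  for (cl in c("total", "r_component", "additive", "hg_additive", "tau"))
    tot2[[cl]] <- cc * tot2[[cl]]
  r1 <- suppressMessages(attribute_changes(pl$ledger, pl$totals,
                                           c("t0", "t1")))
  r2 <- suppressMessages(attribute_changes(led2, tot2, c("t0", "t1")))
  for (cl in c("cr_r", "cr_tau", "cr_s", "delta", "d_total"))
    expect_equal(r2[[cl]], cc * r1[[cl]], tolerance = 1e-9,
                 label = paste("scaled", cl))
  for (cl in c("rate_r", "rate_tau", "rate_s", "rate_delta"))
    expect_equal(r2[[cl]], r1[[cl]], tolerance = 1e-9,
                 label = paste("invariant", cl))
})

test_that("per-record contributions and residual sum to the model change", {
  pl <- run_pipeline(fixture_spec(seed = 8, n_units = 4,
                                  deltas = list(area = 0.15,
                                                precipitation = -0.1,
                                                npp = 0.2, tau = 0.1)))
  r <- pl$attribution
  expect_equal(r$cr_r + r$cr_tau + r$cr_s + r$delta, r$d_total,
               tolerance = 1e-10)
  ok <- !r$rates_undefined
  expect_equal(r$rate_r[ok] + r$rate_tau[ok] + r$rate_s[ok] +
                 r$rate_delta[ok], rep(1, sum(ok)), tolerance = 1e-12)
  expect_true(all(r$natural_factor %in%
                    c("precipitation", "wind", "elevation", "insolation",
                      "npp", "evapotranspiration")))
})

test_that("aggregation reproduces the weighted-rate identity", {
  # two classes with known changes and natural-driver rates
  res <- data.frame(
    unit_id = "U01", ecosystem = c("F1", "F2"),
    cr_r = c(0.5, 0.1) * c(10e21, 30e21),
    cr_tau = c(0, 0), cr_s = c(5e21, 27e21),
    delta = c(0, 0), d_total = c(10e21, 30e21),
    d_total_ledger = c(10e21, 30e21),
    natural_factor = c("evapotranspiration", "precipitation"),
    stringsAsFactors = FALSE)
  agg <- aggregate_attribution(res, by = "extent")
  expect_identical(agg$cr_r, 8e21) # 10e21*0.5 + 30e21*0.1
  expect_identical(agg$d_total, 4e22)
  # a class with zero change contributes nothing
  res0 <- rbind(res, transform(res[1, ], cr_r = 0, cr_s = 0, d_total = 0,
                               d_total_ledger = 0, ecosystem = "G1"))
  expect_identical(aggregate_attribution(res0, by = "extent")$cr_r, 8e21)
  # a single class keeps its rates under aggregation
  one <- aggregate_attribution(res[1, ], by = "extent")
  expect_equal(one$rate_r, 0.5, tolerance = 1e-12)
})

test_that("natural-factor shares normalise to 100% per unit", {
  res <- data.frame(
    unit_id = c("U01", "U02", "U02"), ecosystem = c("F1", "F1", "G1"),
    cr_r = c(4, 8, 2), natural_factor = c("evapotranspiration",
                                          "evapotranspiration",
                                          "precipitation"),
    stringsAsFactors = FALSE)
  sh <- natural_factor_shares(res)
  u1 <- sh[sh$unit_id == "U01", ]
  expect_identical(u1$share_pct, 100)
  u2 <- sh[sh$unit_id == "U02", ]
  expect_identical(u2$share_pct, c(80, 20)) # ordered by decreasing share
  expect_identical(u2$natural_factor[1], "evapotranspiration")
  expect_true(all(sh$direction == "improvement"))
  expect_equal(sum(u2$share_pct), 100, tolerance = 0)
  # deterioration sign and empty case
  resn <- transform(res, cr_r = -cr_r)
  expect_true(all(natural_factor_shares(resn)$direction == "deterioration"))
  expect_identical(nrow(natural_factor_shares(transform(res, cr_r = 0))), 0L)
})

test_that("regional summary computes shares, intensities and rates", {
  contribs <- data.frame(zone = c("a", "b"), cr_r = c(2, 1),
                         cr_tau = c(1, 1), cr_s = c(6, 2),
                         delta = c(1, 0))
  areas <- data.frame(zone = c("a", "b"), total_area = c(100, 50),
                      ecosystem_area = c(50, 0))
  s <- regional_summary(contribs, areas = areas, percent_rounding = FALSE)
  t <- s$table
  expect_identical(t$subtotal, c(10, 4))
  expect_equal(t$ratio, c(10 / 14, 4 / 14), tolerance = 1e-12)
  expect_equal(t$rate_s_pct, c(60, 50), tolerance = 1e-12)
  expect_identical(t$intensity_total_area, c(0.1, 0.08))
  expect_true(is.na(t$intensity_ecosystem_area[2])) # zero area flagged
  cc <- data.frame(zone = c("a", "a"), ecosystem = c("F1", "A4"),
                   d_total = c(8, 2))
  s2 <- regional_summary(contribs, class_contribs = cc,
                         percent_rounding = FALSE)
  expect_equal(s2$class_rates$rate_pct, c(80, 20), tolerance = 1e-12)
})

test_that("percent rendering rounds half away from zero", {
  expect_identical(round_half_away(c(0.5, 1.5, -0.5, -1.5, 2.4)),
                   c(1, 2, -1, -2, 2))
  expect_identical(round_half_away(1.726, 2), 1.73)
})
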