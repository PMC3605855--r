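make_inc <- function(slope = 10, volume = 0.2, surface = 20, light = 35,
                     noise = 0, n = 7, duration = 2) {
  t <- seq(0, duration, length.out = n)
  chamber_incubation(
    id = "t1", treatment = "400T", season = "summer", light = light,
    duration = duration, volume = volume, surface = surface,
    o2_time = t, o2_conc = 240 + slope * t + noise,
    ph_initial = 8.06, ph_final = 8.05, alk_initial = 2610,
    alk_final = 2600, temperature = 22, salinity = 38)
}

test_that("O2 rate is the regression slope scaled by V/S", {
  expect_equal(o2_rate(make_inc(slope = 10))$rate, 0.1)
  expect_equal(o2_rate(make_inc(slope = 0))$rate, 0)
  # dark convention: negative slope, Rd = -rate positive
  r <- o2_rate(make_inc(slope = -8, light = 0))
  expect_equal(-r$rate, 0.08)
  expect_equal(r$r2, 1)
})

test_that("incubation validation catches bad geometry and series", {
  expect_error(make_inc(n = 2), ">= 3")
  expect_error(chamber_incubation("x", "400T", "summer", 0, 2, 0.2, 20,
                                  c(0, 1, 0.5), c(1, 2, 3), 8, 8, 2600,
                                  2600, 22), "increasing")
  expect_error(chamber_incubation("x", "400T", "summer", 0, 1, 0.2, 20,
                                  c(0, 1, 2), c(1, 2, 3), 8, 8, 2600,
                                  2600, 22), "duration")
  expect_error(make_inc(volume = -1), "volume")
  set.seed(20)
  expect_warning(o2_rate(make_inc(slope = 0.01,
                                  noise = rnorm(7, 0, 5))), "r2")
})

test_that("alkalinity anomaly calcification follows the 2 eq per mol stoichiometry", {
  expect_equal(calcification_rate(2540, 2500, 2, 0.2, 20), 0.1)
  expect_equal(calcification_rate(2500, 2508, 2, 0.2, 20), -0.02)
  expect_equal(calcification_rate(2500, 2500, 2, 0.2, 20), 0)
  expect_error(calcification_rate(2540, 2500, 0, 0.2, 20), "> 0")
})

test_that("carbon flux subtracts the calcification share of the C_T drawdown", {
  # drawdown rate D = (ct_i - ct_f) V / (dt S); organic = D - G
  v <- 0.2; s <- 20; dt <- 2
  d_to_ct <- function(D) D * dt * s / v  # ct drop giving drawdown D
  expect_equal(carbon_rate(2200, 2200 - d_to_ct(0.1), dt, v, s,
                           calcification = 0.1, light = TRUE), 0)
  expect_equal(carbon_rate(2200, 2200 - d_to_ct(0.6), dt, v, s,
                           calcification = 0.1, light = TRUE), 0.5)
  # dark: C_T gain of 0.3 with dark calcification 0.05 -> Rd = 0.35
  expect_equal(carbon_rate(2200, 2200 + d_to_ct(0.3), dt, v, s,
                           calcification = 0.05, light = FALSE), 0.35)
  expect_error(carbon_rate(2200, 2190, dt, v, s,
                           calcification = NULL, light = TRUE),
               "mandatory")
})

test_that("gross production is net plus respiration in a shared currency", {
  expect_equal(gross_rate(0.38, 0.27), 0.65)
  expect_equal(gross_rate(0.5, 0), 0.5)
  expect_equal(gross_rate(-0.27, 0.27), 0)
  expect_error(gross_rate(0.4, 0.2, currency = c("O2", "C")), "mismatch")
  expect_error(gross_rate(0.4, -0.1), ">= 0")
})

test_that("rates are invariant to scaling volume and surface together", {
  tru <- synthetic_truth("summer")
  a <- incubation_fluxes(simulate_incubation(tru, "400T", noise = FALSE,
                                             volume = 0.2, surface = 20))
  b <- incubation_fluxes(simulate_incubation(tru, "400T", noise = FALSE,
                                             volume = 0.4, surface = 40))
  expect_equal(a$Pn_O2, b$Pn_O2, tolerance = 1e-12)
  expect_equal(a$G, b$G, tolerance = 1e-12)
  expect_equal(a$Pn_C, b$Pn_C, tolerance = 1e-10)
})

test_that("noiseless synthetic incubations are inverted exactly, in both currencies", {
  for (season in c("summer", "winter")) {
    tru <- synthetic_truth(season)
    for (tr in c("400T", "700T+3")) {
      light <- simulate_incubation(tru, tr, noise = FALSE)
      dark <- simulate_incubation(tru, tr, irradiance = 0, noise = FALSE)
      truth_l <- attr(light, "truth")
      truth_d <- attr(dark, "truth")
      fl <- incubation_fluxes(light, dark = dark)
      fd <- incubation_fluxes(dark)
      expect_equal(fl$Pn_O2, truth_l$pn_o2, tolerance = 1e-10)
      expect_equal(fl$G, truth_l$G, tolerance = 1e-10)
      # photosynthetic quotient 1: O2 and C currencies agree
      expect_equal(fl$Pn_C, fl$Pn_O2, tolerance = 1e-6)
      expect_equal(fd$Rd_O2, -truth_d$pn_o2, tolerance = 1e-10)
      expect_equal(fd$Gd, truth_d$G, tolerance = 1e-10)
      # Pg = Pn + Rd by construction
      expect_equal(fl$Pg_O2, fl$Pn_O2 + fd$Rd_O2, tolerance = 1e-12)
    }
  }
})
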