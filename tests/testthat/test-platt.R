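E10 <- c(0, 3, 6, 12, 25, 40, 60, 90, 130, 180)

test_that("the model rate matches direct evaluation and its limits", {
  expect_equal(platt_rate(0, 1.5, 0.04, 0.002, 0.3), -0.3)
  expect_equal(platt_rate(0, 0.4, 0.01, 0, 0.1, mode = "calcification"),
               0.1)
  expect_equal(platt_rate(1e9, 1.5, 0.04, 0, 0.3), 1.5 - 0.3)
  expect_equal(platt_rate(50, 1.5, 0.04, 0.002, 0.3),
               oracle_platt(50, 1.5, 0.04, 0.002, 0.3), tolerance = 1e-12)
  expect_error(platt_rate(-1, 1, 0.04), ">= 0")
})

test_that("noiseless data are recovered to high relative accuracy", {
  truth <- c(scale = 1.5, alpha = 0.04, beta = 0.002, offset = 0.3)
  y <- oracle_platt(E10, 1.5, 0.04, 0.002, 0.3)
  f <- fit_platt(E10, y)
  expect_true(f$converged)
  expect_lt(max(abs(f$par - truth) / truth), 1e-6)

  # boundary truth beta = 0
  y0 <- oracle_platt(E10, 1.5, 0.04, 0, 0.3)
  f0 <- fit_platt(E10, y0)
  expect_lt(f0$par[["beta"]], 1e-6)

  # calcification mode with negative dark offset (net dissolution)
  yc <- 0.2 * (1 - exp(-0.008 * E10 / 0.2)) * exp(-0.001 * E10 / 0.2) - 0.01
  fc <- fit_platt(E10, yc, mode = "calcification")
  expect_equal(fc$par[["offset"]], -0.01, tolerance = 1e-6)
})

test_that("fitting validates its inputs", {
  expect_error(fit_platt(c(1, 5, 10, 20, 40), rep(1, 5)), "dark point")
  expect_error(fit_platt(c(0, 5, 10, 20), c(1, 2, 3, 4)), "5 distinct")
  expect_error(fit_platt(E10, rep(0.3, 10)), "degenerate")
})

test_that("a pinned dark offset is honoured", {
  y <- oracle_platt(E10, 1.2, 0.039, 0.001, 0.30)
  f <- fit_platt(E10, y, offset = 0.25)
  expect_equal(f$par[["offset"]], 0.25)
  expect_true(f$offset_fixed)
})

test_that("derived parameters follow the Harrison-Platt closed forms", {
  y <- oracle_platt(E10, 1.5, 0.04, 0.002, 0.3)
  f <- fit_platt(E10, y)
  d <- derive_params(f)
  p <- f$par
  # dense-grid numeric maximum of the gross curve as oracle
  Eg <- seq(0, 5000, by = 0.05)
  gmax_num <- max(oracle_platt(Eg, p[["scale"]], p[["alpha"]],
                               p[["beta"]], 0))
  expect_lt(abs(d$gross_max - gmax_num) / gmax_num, 1e-6)
  expect_equal(d$ek, d$gross_max / p[["alpha"]], tolerance = 1e-12)
  expect_equal(d$net_max, d$gross_max - p[["offset"]], tolerance = 1e-12)
  # modelled net rate at E_c is zero
  expect_lt(abs(platt_rate(d$ec, p[["scale"]], p[["alpha"]], p[["beta"]],
                           p[["offset"]])), 1e-9)
})

test_that("beta = 0 reduces the derived forms to their simple limits", {
  y <- oracle_platt(E10, 1.0, 0.05, 0, 0.1)
  f <- fit_platt(E10, y)
  d <- derive_params(f)
  expect_equal(d$gross_max, f$par[["scale"]], tolerance = 1e-6)
  # closed-form compensation irradiance -(Ps/alpha) ln(1 - Rd/Ps)
  ec_closed <- -(1.0 / 0.05) * log(1 - 0.1 / 1.0)
  expect_lt(abs(d$ec - ec_closed), 1e-9)
})

test_that("E_c is reported missing when respiration exceeds the gross maximum", {
  f <- structure(list(par = c(scale = 0.5, alpha = 0.03, beta = 0.001,
                              offset = 0.6),
                      mode = "photosynthesis", rss = 0, converged = TRUE,
                      offset_fixed = FALSE),
                 class = "platt_fit")
  d <- derive_params(f)
  expect_true(is.na(d$ec))
  expect_match(attr(d$ec, "ec_reason"), "gross maximum")
  # calcification with non-negative dark rate: net curve never crosses 0
  fc <- structure(list(par = c(scale = 0.4, alpha = 0.008, beta = 0,
                               offset = 0.1),
                       mode = "calcification", rss = 0, converged = TRUE,
                       offset_fixed = FALSE),
                  class = "platt_fit")
  expect_true(is.na(derive_params(fc)$ec))
})

test_that("gross maximum rises with the scale parameter and photoinhibition bends the curve", {
  g <- function(ps) derive_params(structure(
    list(par = c(scale = ps, alpha = 0.04, beta = 0.002, offset = 0),
         mode = "photosynthesis", rss = 0, converged = TRUE,
         offset_fixed = FALSE), class = "platt_fit"))$gross_max
  vals <- vapply(c(0.5, 1, 1.5, 2, 3), g, numeric(1))
  expect_true(all(diff(vals) > 0))
  # with beta > 0 the curve has an interior maximum and declines beyond it
  E <- seq(0, 2000, by = 1)
  y <- oracle_platt(E, 0.55, 0.05, 0.004, 0)
  imax <- which.max(y)
  expect_gt(imax, 1)
  expect_lt(imax, length(E))
  expect_true(all(diff(y[imax:length(E)]) < 0))
})

test_that("treatment summaries aggregate per-replicate fits, not pooled ratios", {
  p <- data.frame(ek = c(28, 32), gross_max = c(1.0, 1.4),
                  alpha = c(0.05, 0.035))
  s <- summarize_treatment(p, treatment = "400T", season = "summer")
  expect_equal(s$mean[s$parameter == "ek"], 30)
  expect_equal(s$se[s$parameter == "ek"], 2)
  # mean of per-replicate E_k is not mean(Pg_max)/mean(alpha)
  expect_false(isTRUE(all.equal(30, mean(p$gross_max) / mean(p$alpha))))

  same <- data.frame(alpha = rep(0.04, 4))
  expect_equal(summarize_treatment(same)$se, 0)
  one <- data.frame(alpha = 0.04)
  expect_true(is.na(summarize_treatment(one)$se))
})

test_that("the initial slope is estimated with negligible median bias under noise", {
  set.seed(31)
  bias <- replicate(200, {
    y <- platt_rate(E10, 1.2, 0.039, 0.001, 0.30) +
      rnorm(length(E10), 0, 0.05 * 1.2)
    (fit_platt(E10, y)$par[["alpha"]] - 0.039) / 0.039
  })
  expect_lt(abs(median(bias)), 0.05)
})
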