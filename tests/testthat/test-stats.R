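sim_cells <- function(n = c(5, 5, 5, 4), means = c(0, 0, 0, 0), sd = 1,
                      rdist = rnorm) {
  cells <- expand.grid(pco2 = c("400", "700"), temperature = c("T", "T+3"),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(1:4, function(i)
    data.frame(value = means[i] + rdist(n[i]) * sd,
               pco2 = cells$pco2[i], temperature = cells$temperature[i])))
}

test_that("the Bonferroni divisor gives the published family thresholds", {
  expect_equal(bonferroni_alpha(0.05, 4), 0.0125)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

test_that("Type III F statistics match a brute-force effects-coding oracle", {
  set.seed(51)
  for (i in 1:20) {
    d <- sim_cells(n = sample(4:6, 4, replace = TRUE),
                   means = rnorm(4, 0, 2))
    tab <- two_way_anova(d)
    Fo <- oracle_anova_f(d$value, d$pco2, d$temperature)
    expect_lt(abs(tab$F[tab$effect == "pco2"] - Fo[["A"]]), 1e-9)
    expect_lt(abs(tab$F[tab$effect == "temperature"] - Fo[["B"]]), 1e-9)
    expect_lt(abs(tab$F[tab$effect == "pco2:temperature"] - Fo[["AB"]]),
              1e-9)
    expect_equal(tab$df2[1], nrow(d) - 4)
    expect_true(all(tab$p >= 0 & tab$p <= 1))
  }
})

test_that("degenerate and structured inputs are handled", {
  d <- sim_cells(); d$value <- 1
  tab <- two_way_anova(d)
  expect_true(attr(tab, "degenerate"))
  expect_true(all(is.na(tab$F)))
  # pure pCO2 effect with balanced within-cell deviations: interaction
  # and temperature F are exactly zero
  d2 <- sim_cells(n = c(4, 4, 4, 4), rdist = function(n) rep(0, n))
  d2$value <- ifelse(d2$pco2 == "700", 3, 0) + rep(c(-0.5, 0.5), 8)
  tab2 <- two_way_anova(d2)
  expect_equal(tab2$F[tab2$effect == "pco2:temperature"], 0)
  expect_gt(tab2$F[tab2$effect == "pco2"], 0)
  expect_error(two_way_anova(data.frame(value = 1:4,
                                        pco2 = c("400", "400", "700", "700"),
                                        temperature = "T")),
               "2 levels")
})

test_that("the F statistic is invariant to adding a constant", {
  set.seed(52)
  d <- sim_cells(means = c(1, 2, 0, 1))
  f1 <- two_way_anova(d)$F
  d$value <- d$value + 100
  expect_equal(two_way_anova(d)$F, f1, tolerance = 1e-9)
})

test_that("Tukey-Kramer reduces to classic Tukey HSD for equal n", {
  set.seed(53)
  d <- sim_cells(n = rep(5, 4), means = c(0, 1, 2, 0))
  ph <- tukey_posthoc(d, alpha = 0.05)
  cell <- interaction(factor(d$pco2), factor(d$temperature), sep = ":")
  hsd <- TukeyHSD(aov(d$value ~ cell))$cell
  key <- paste(ph$pairs$a, ph$pairs$b)
  for (i in seq_len(nrow(hsd))) {
    parts <- strsplit(rownames(hsd)[i], "-")[[1]]
    j <- match(TRUE, key %in% paste(parts[1], parts[2]) |
                 key %in% paste(parts[2], parts[1]))
    expect_equal(ph$pairs$p[j], hsd[i, "p adj"], tolerance = 1e-9)
  }
})

test_that("post hoc letters separate an extreme cell and collapse identical ones", {
  set.seed(54)
  d <- sim_cells(n = rep(5, 4), sd = 1)
  d$value[d$pco2 == "700" & d$temperature == "T+3"] <-
    d$value[d$pco2 == "700" & d$temperature == "T+3"] + 10
  ph <- tukey_posthoc(d, alpha = 0.0125)
  lt <- ph$letters
  odd <- lt[["700:T+3"]]
  expect_false(odd %in% lt[names(lt) != "700:T+3"])
  expect_true(length(unique(lt[names(lt) != "700:T+3"])) == 1)

  d0 <- sim_cells(n = rep(5, 4), sd = 1)
  expect_true(all(tukey_posthoc(d0, alpha = 0.0125)$letters == "nd"))
  expect_error(tukey_posthoc(sim_cells(n = c(1, 5, 5, 5))), "n >= 2")
})

test_that("letters are consistent with the pairwise p-values", {
  set.seed(55)
  for (i in 1:25) {
    d <- sim_cells(n = sample(4:5, 4, replace = TRUE),
                   means = rnorm(4, 0, 1.5))
    ph <- tukey_posthoc(d, alpha = 0.05)
    if (all(ph$letters == "nd")) {
      expect_true(all(ph$pairs$p >= 0.05))
      next
    }
    share <- function(a, b) {
      la <- strsplit(ph$letters[[a]], "")[[1]]
      lb <- strsplit(ph$letters[[b]], "")[[1]]
      length(intersect(la, lb)) > 0
    }
    for (j in seq_len(nrow(ph$pairs))) {
      if (share(ph$pairs$a[j], ph$pairs$b[j]))
        expect_gte(ph$pairs$p[j], 0.05)
      else
        expect_lt(ph$pairs$p[j], 0.05)
    }
  }
})

test_that("assumption checks pass clean data and transform log-normal data", {
  set.seed(56)
  ok <- replicate(100, {
    r <- check_assumptions(sim_cells(sd = 1))
    r$shapiro_p >= 0.05 && r$levene_p >= 0.05 && !r$transformed
  })
  expect_gte(mean(ok), 0.9)
  flagged <- replicate(60, {
    check_assumptions(sim_cells(rdist = function(n)
      exp(rnorm(n, 0, 1.2))))$transformed
  })
  expect_gt(mean(flagged), 0.5)
  d <- sim_cells(); d$value <- 2
  expect_error(check_assumptions(d), "degenerate")
  dneg <- sim_cells(rdist = function(n) exp(rnorm(n, 0, 2)))
  dneg$value[1] <- -1
  expect_error(check_assumptions(dneg, transform = "log"), "<= 0")
})

test_that("the family-wise Type I error stays at or below the adjusted level", {
  set.seed(57)
  alpha <- bonferroni_alpha(0.05, 4)
  rej <- replicate(1000, {
    d <- sim_cells(n = c(5, 5, 5, 4))
    two_way_anova(d)$p[1] < alpha
  })
  p_hat <- mean(rej)
  expect_lte(p_hat, alpha + 3 * sqrt(alpha * (1 - alpha) / 1000))
})
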