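#' Ground-truth parameter set for a synthetic seasonal experiment
#'
#' Returns the built-in "true" state of one seasonal run of the 2 x 2
#' (pCO2 x temperature) design: ambient temperature and experimental
#' irradiance for the season, per-treatment Platt parameters for the O2
#' photosynthesis and calcification light responses, per-treatment
#' carbonate baselines (pH_T, A_T), replicate counts, and the measurement
#' noise model. Magnitudes follow the seasonal physiology of a
#' Mediterranean crustose coralline alga: summer rates two- to three-fold
#' winter rates, photoinhibition in winter, the highest summer
#' calcification under elevated pCO2 at ambient temperature, and slight
#' dark dissolution in spring.
#'
#' @param season one of `"summer"`, `"autumn"`, `"winter"`, `"spring"`.
#' @return An object of class `synthetic_truth`: list with `season`,
#'   `temperature` (ambient, degC), `irradiance` (umol photons m-2 s-1),
#'   `photoperiod` (light hours), `salinity`, `treatments` (named list per
#'   treatment with `pco2_level`, `temp_offset`, `n`, `platt`, `calc`,
#'   `ph`, `alk` in umol kg-1), and `noise` (`o2_sigma` umol L-1,
#'   `alk_sigma` ueq L-1, `ph_sigma`, `rate_cv`, `jitter_cv`, `pq`).
#' @export
synthetic_truth <- function(season = c("summer", "autumn", "winter",
                                       "spring")) {
  season <- match.arg(season)
  ambient <- c(summer = 22.0, autumn = 17.7, winter = 13.3, spring = 17.7)
  irr <- c(summer = 35, autumn = 16, winter = 6, spring = 21)
  photoperiod <- c(summer = 14, autumn = 10, winter = 11, spring = 15)

  # platt = (scale, alpha, beta, rd); calc = (scale, alpha, beta, gd)
  tabs <- list(
    summer = list(
      "400T"   = list(platt = c(1.20, 0.039, 0.0010, 0.30),
                      calc = c(0.45, 0.008, 0.0005, 0.20),
                      ph = 8.06, alk = 2538),
      "400T+3" = list(platt = c(1.40, 0.037, 0.0010, 0.32),
                      calc = c(0.52, 0.007, 0.0005, 0.26),
                      ph = 8.01, alk = 2541),
      "700T"   = list(platt = c(1.55, 0.034, 0.0010, 0.32),
                      calc = c(0.62, 0.015, 0.0005, 0.13),
                      ph = 7.87, alk = 2543),
      "700T+3" = list(platt = c(1.25, 0.029, 0.0010, 0.27),
                      calc = c(0.42, 0.007, 0.0005, 0.15),
                      ph = 7.84, alk = 2546)),
    autumn = list(
      "400T"   = list(platt = c(0.85, 0.045, 0.0020, 0.12),
                      calc = c(0.20, 0.007, 0.0010, 0.04),
                      ph = 8.09, alk = 2526),
      "400T+3" = list(platt = c(0.95, 0.047, 0.0020, 0.20),
                      calc = c(0.24, 0.008, 0.0010, 0.05),
                      ph = 8.06, alk = 2533),
      "700T"   = list(platt = c(0.70, 0.040, 0.0020, 0.09),
                      calc = c(0.22, 0.007, 0.0010, 0.03),
                      ph = 7.88, alk = 2521),
      "700T+3" = list(platt = c(0.75, 0.038, 0.0020, 0.15),
                      calc = c(0.25, 0.007, 0.0010, 0.04),
                      ph = 7.86, alk = 2530)),
    winter = list(
      "400T"   = list(platt = c(0.55, 0.050, 0.0040, 0.09),
                      calc = c(0.06, 0.005, 0.0020, 0.010),
                      ph = 8.10, alk = 2540),
      "400T+3" = list(platt = c(0.75, 0.056, 0.0040, 0.11),
                      calc = c(0.14, 0.011, 0.0020, 0.020),
                      ph = 8.06, alk = 2540),
      "700T"   = list(platt = c(0.52, 0.038, 0.0040, 0.06),
                      calc = c(0.11, 0.007, 0.0020, 0.015),
                      ph = 7.87, alk = 2539),
      "700T+3" = list(platt = c(0.57, 0.037, 0.0040, 0.10),
                      calc = c(0.12, 0.005, 0.0020, 0.020),
                      ph = 7.85, alk = 2545)),
    spring = list(
      "400T"   = list(platt = c(0.62, 0.045, 0.0020, 0.14),
                      calc = c(0.14, 0.006, 0.0010, -0.005),
                      ph = 8.09, alk = 2483),
      "400T+3" = list(platt = c(0.60, 0.044, 0.0020, 0.17),
                      calc = c(0.16, 0.007, 0.0010, 0.000),
                      ph = 8.06, alk = 2484),
      "700T"   = list(platt = c(0.58, 0.042, 0.0020, 0.15),
                      calc = c(0.15, 0.006, 0.0010, -0.005),
                      ph = 7.87, alk = 2483),
      "700T+3" = list(platt = c(0.55, 0.040, 0.0020, 0.16),
                      calc = c(0.15, 0.006, 0.0010, 0.000),
                      ph = 7.85, alk = 2487))
  )

  treatments <- lapply(names(tabs[[season]]), function(tr) {
    x <- tabs[[season]][[tr]]
    n <- if (tr == "700T+3" && season %in% c("winter", "spring")) 4L else 5L
    list(pco2_level = if (grepl("^700", tr)) 700 else 400,
         temp_offset = if (grepl("\\+3$", tr)) 3 else 0,
         n = n,
         platt = stats::setNames(x$platt, c("scale", "alpha", "beta",
                                            "offset")),
         calc = stats::setNames(x$calc, c("scale", "alpha", "beta",
                                          "offset")),
         ph = x$ph, alk = x$alk)
  })
  names(treatments) <- names(tabs[[season]])

  out <- list(season = season,
              temperature = unname(ambient[season]),
              irradiance = unname(irr[season]),
              photoperiod = unname(photoperiod[season]),
              salinity = 38,
              treatments = treatments,
              noise = list(o2_sigma = 1, alk_sigma = 3, ph_sigma = 0.005,
                           rate_cv = 0.05, jitter_cv = 0.10, pq = 1))
  class(out) <- "synthetic_truth"
  out
}

truth_rates <- function(tr, E, pq = 1) {
  p <- tr$platt; g <- tr$calc
  pn <- platt_rate(E, p[["scale"]], p[["alpha"]], p[["beta"]],
                   p[["offset"]], "photosynthesis")
  G <- platt_rate(E, g[["scale"]], g[["alpha"]], g[["beta"]],
                  g[["offset"]], "calcification")
  list(pn_o2 = pn, pn_c = pn * pq, G = G)
}

#' Simulate one closed-chamber incubation with known truth
#'
#' Builds a [chamber_incubation()] whose O2 series drifts linearly at the
#' true net metabolic rate (Gaussian measurement noise on top), whose final
#' alkalinity reflects the true calcification rate (2 eq per mole CaCO3),
#' and whose final pH is solved so that the (A_T, C_T) budget closes
#' through the carbonate-chemistry module. At zero noise the flux
#' functions recover the generator's true rates exactly.
#'
#' @param truth a [synthetic_truth()].
#' @param treatment treatment label present in `truth$treatments`.
#' @param irradiance incubation irradiance (0 = dark); defaults to the
#'   seasonal experimental irradiance.
#' @param replicate replicate index used in the incubation id.
#' @param duration,volume,surface chamber settings (defaults 2 h, 0.2 L,
#'   20 cm2).
#' @param n_points number of O2 samples (>= 3).
#' @param noise logical: apply the truth's measurement-noise model?
#' @param o2_start initial O2 concentration (umol L-1).
#' @param density seawater density (kg L-1) linking the per-kg carbonate
#'   system to the volumetric chamber budget.
#' @param seed optional integer seed (set just before drawing noise).
#' @return A `chamber_incubation` with the true rates attached as
#'   attribute `"truth"` (list `pn_o2`, `pn_c`, `G`).
#' @export
simulate_incubation <- function(truth, treatment,
                                irradiance = truth$irradiance,
                                replicate = 1L,
                                duration = 2, volume = 0.2, surface = 20,
                                n_points = 13, noise = TRUE,
                                o2_start = 240, density = 1.028,
                                seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!treatment %in% names(truth$treatments))
    stop("unknown treatment: ", treatment)
  if (n_points < 3) stop("n_points must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  tr <- truth$treatments[[treatment]]
  temp <- truth$temperature + tr$temp_offset
  rt <- truth_rates(tr, irradiance, truth$noise$pq)

  tm <- seq(0, duration, length.out = n_points)
  slope <- rt$pn_o2 * surface / volume
  o2_true <- o2_start + slope * tm
  if (any(o2_true < 0))
    stop("true rate would drive O2 negative within the incubation; ",
         "shorten the run or raise o2_start")
  ns <- truth$noise
  o2 <- o2_true + if (noise) stats::rnorm(n_points, 0, ns$o2_sigma) else 0

  kc <- carb_constants(temp, truth$salinity)
  alk0_L <- tr$alk * density                      # ueq L-1
  ct0_L <- carb_from_ph_alk(tr$ph, tr$alk, constants = kc)$ct * density
  dAL <- 2 * rt$G * duration * surface / volume
  dCT <- (rt$pn_c + rt$G) * duration * surface / volume
  alk1_L <- alk0_L - dAL
  ct1_L <- ct0_L - dCT
  ph1 <- carb_ph_from_alk_ct(alk1_L / density, ct1_L / density,
                             constants = kc)

  jit <- function(x, s) if (noise) x + stats::rnorm(length(x), 0, s) else x
  inc <- chamber_incubation(
    id = sprintf("%s_%s_r%d_%s", truth$season, treatment, replicate,
                 if (irradiance > 0) "light" else "dark"),
    treatment = treatment, season = truth$season, light = irradiance,
    duration = duration, volume = volume, surface = surface,
    o2_time = tm, o2_conc = o2,
    ph_initial = jit(tr$ph, ns$ph_sigma),
    ph_final = jit(ph1, ns$ph_sigma),
    alk_initial = jit(alk0_L, ns$alk_sigma),
    alk_final = jit(alk1_L, ns$alk_sigma),
    temperature = temp, salinity = truth$salinity)
  attr(inc, "truth") <- rt
  inc
}

#' Simulate a replicated irradiance-response experiment
#'
#' Draws per-replicate (per-alga) Platt parameters by multiplicative
#' Gaussian jitter around the treatment truth (biological variability,
#' default CV 10%), then measures each replicate's rate at every
#' irradiance level with additive Gaussian noise proportional to the true
#' scale parameter (default CV 5%).
#'
#' @param truth a [synthetic_truth()].
#' @param treatment treatment label.
#' @param mode `"photosynthesis"` or `"calcification"`.
#' @param e_levels irradiance levels; must include 0 and have >= 5
#'   distinct values.
#' @param n_replicates number of algae (defaults to the treatment's n).
#' @param jitter_cv CV of the between-replicate parameter jitter
#'   (default from the truth's noise model).
#' @param rate_cv CV of the measurement noise relative to the true scale
#'   parameter (default from the truth's noise model).
#' @param seed optional integer seed.
#' @return A data frame with columns `replicate`, `irradiance`, `rate`,
#'   `mode`, `treatment`, `season`; the per-replicate true parameters are
#'   attached as attribute `"truth"` (matrix, one row per replicate).
#' @export
simulate_pe_experiment <- function(truth, treatment,
                                   mode = c("photosynthesis",
                                            "calcification"),
                                   e_levels = c(0, 3, 6, 12, 25, 40, 60,
                                                90, 130, 180),
                                   n_replicates = NULL,
                                   jitter_cv = truth$noise$jitter_cv,
                                   rate_cv = truth$noise$rate_cv,
                                   seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mode <- match.arg(mode)
  if (!0 %in% e_levels) stop("e_levels must include the dark point 0")
  if (length(unique(e_levels)) < 5) stop("need >= 5 distinct e_levels")
  if (!is.null(seed)) set.seed(seed)
  tr <- truth$treatments[[treatment]]
  if (is.null(tr)) stop("unknown treatment: ", treatment)
  if (is.null(n_replicates)) n_replicates <- tr$n
  true_par <- if (mode == "photosynthesis") tr$platt else tr$calc

  reps <- lapply(seq_len(n_replicates), function(r) {
    par_r <- true_par * pmax(1 + stats::rnorm(4, 0, jitter_cv), 0.2)
    mu <- platt_rate(e_levels, par_r[["scale"]], par_r[["alpha"]],
                     par_r[["beta"]], par_r[["offset"]], mode)
    rate <- mu + stats::rnorm(length(e_levels),
                              0, rate_cv * true_par[["scale"]])
    list(par = par_r,
         df = data.frame(replicate = r, irradiance = e_levels, rate = rate,
                         mode = mode, treatment = treatment,
                         season = truth$season, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, lapply(reps, `[[`, "df"))
  attr(out, "truth") <- do.call(rbind, lapply(reps, `[[`, "par"))
  out
}

#' Simulate and write a complete synthetic experiment as CSV
#'
#' Generates light (at the seasonal irradiance) and dark incubations for
#' every replicate of every treatment in the requested seasons, plus
#' photosynthesis and calcification irradiance-response sets for summer
#' and winter, and writes the pipeline's CSV schemas
#' (`incubations.csv`, `o2_series.csv`, `pe_rates.csv`) to `dir`.
#' All randomness flows from `seed`: the same seed writes byte-identical
#' files.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed for the whole dataset.
#' @param seasons seasons to simulate.
#' @param noise logical, apply measurement noise.
#' @param ... passed to [simulate_incubation()] (chamber settings).
#' @return Invisibly, the list of written file paths.
#' @export
write_synthetic_dataset <- function(dir, seed = 1,
                                    seasons = c("summer", "autumn",
                                                "winter", "spring"),
                                    noise = TRUE, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  incs <- list(); o2 <- list(); pe <- list()
  for (season in seasons) {
    tru <- synthetic_truth(season)
    for (tr in names(tru$treatments)) {
      for (r in seq_len(tru$treatments[[tr]]$n)) {
        for (E in c(tru$irradiance, 0)) {
          inc <- simulate_incubation(tru, tr, irradiance = E,
                                     replicate = r, noise = noise, ...)
          incs[[length(incs) + 1]] <- data.frame(
            incubation_id = inc$id, treatment = tr, season = season,
            replicate = r, irradiance = E, duration_h = inc$duration,
            volume_L = inc$volume, surface_cm2 = inc$surface,
            ph_initial = inc$ph_initial, ph_final = inc$ph_final,
            alk_initial_ueq_L = inc$alk_initial,
            alk_final_ueq_L = inc$alk_final,
            temperature_C = inc$temperature, salinity = inc$salinity,
            stringsAsFactors = FALSE)
          o2[[length(o2) + 1]] <- data.frame(
            incubation_id = inc$id, time_h = inc$o2_time,
            o2_umol_L = inc$o2_conc, stringsAsFactors = FALSE)
        }
      }
    }
    if (season %in% c("summer", "winter")) {
      for (tr in names(tru$treatments)) for (md in c("photosynthesis",
                                                     "calcification")) {
        d <- simulate_pe_experiment(tru, tr, mode = md)
        d$replicate_id <- sprintf("%s_%s_r%d", season, tr, d$replicate)
        pe[[length(pe) + 1]] <- d
      }
    }
  }
  paths <- c(incubations = file.path(dir, "incubations.csv"),
             o2_series = file.path(dir, "o2_series.csv"),
             pe_rates = file.path(dir, "pe_rates.csv"))
  utils::write.csv(do.call(rbind, incs), paths["incubations"],
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, o2), paths["o2_series"],
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, pe), paths["pe_rates"],
                   row.names = FALSE)
  invisible(paths)
}
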