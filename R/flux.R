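#' Construct a closed-chamber incubation record
#'
#' Bundles everything measured during one closed-chamber run of a single
#' alga: the O2 time series logged by the oxygen electrode, the bracketing
#' pH/alkalinity water samples, the chamber geometry and the light level.
#'
#' @param id incubation identifier.
#' @param treatment treatment label, one of `"400T"`, `"400T+3"`, `"700T"`,
#'   `"700T+3"`.
#' @param season season label (`"summer"`, `"autumn"`, `"winter"`,
#'   `"spring"`).
#' @param light irradiance during the run (umol photons m-2 s-1; 0 = dark).
#' @param duration incubation duration (h).
#' @param volume chamber volume (L).
#' @param surface thallus surface area (cm2).
#' @param o2_time,o2_conc the O2 series: sampling times (h, strictly
#'   increasing, spanning at most `duration`) and concentrations
#'   (umol L-1); at least 3 points.
#' @param ph_initial,ph_final pH_T of the bracketing samples.
#' @param alk_initial,alk_final total alkalinity of the bracketing samples
#'   (ueq L-1).
#' @param temperature water temperature (degrees C).
#' @param salinity practical salinity.
#' @return An object of class `chamber_incubation` (a list of the above).
#' @export
chamber_incubation <- function(id, treatment, season, light, duration,
                               volume, surface, o2_time, o2_conc,
                               ph_initial, ph_final,
                               alk_initial, alk_final,
                               temperature, salinity = 38) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0 h")
  if (!is.numeric(volume) || volume <= 0) stop("volume must be > 0 L")
  if (!is.numeric(surface) || surface <= 0) stop("surface must be > 0 cm2")
  if (length(o2_time) < 3)
    stop("O2 series needs >= 3 points, got ", length(o2_time))
  if (length(o2_time) != length(o2_conc))
    stop("o2_time and o2_conc lengths differ")
  if (any(diff(o2_time) <= 0)) stop("O2 times must be strictly increasing")
  if (max(o2_time) - min(o2_time) > duration + 1e-9)
    stop("O2 series spans more than the stated duration")
  if (light < 0) stop("light must be >= 0")
  out <- list(id = id, treatment = treatment, season = season,
              light = light, duration = duration, volume = volume,
              surface = surface, o2_time = o2_time, o2_conc = o2_conc,
              ph_initial = ph_initial, ph_final = ph_final,
              alk_initial = alk_initial, alk_final = alk_final,
              temperature = temperature, salinity = salinity)
  class(out) <- "chamber_incubation"
  out
}

#' @export
print.chamber_incubation <- function(x, ...) {
  cat(sprintf("Chamber incubation %s [%s, %s, %s]\n", x$id, x$treatment,
              x$season, if (x$light > 0) sprintf("E = %g", x$light) else "dark"))
  cat(sprintf("  %.2f h, %.3f L, %.1f cm2, %d O2 points, T = %.1f degC\n",
              x$duration, x$volume, x$surface, length(x$o2_time),
              x$temperature))
  invisible(x)
}

#' Net O2 flux of a closed-chamber incubation
#'
#' The O2 flux is the slope of the ordinary least-squares regression of O2
#' concentration on time, scaled to the chamber volume and normalised to
#' the thallus surface area: rate = sO2 * V / S. Positive in the light is
#' net production; in the dark the slope is negative and its magnitude is
#' the dark respiration.
#'
#' @param incubation a [chamber_incubation()].
#' @param r2_threshold regressions with r2 below this are flagged (not
#'   rejected); default 0.8.
#' @return A list with `rate` (signed, umol O2 cm-2 h-1), `slope`
#'   (umol L-1 h-1), `r2`, and logical `low_r2`.
#' @export
o2_rate <- function(incubation, r2_threshold = 0.8) {
  stopifnot(inherits(incubation, "chamber_incubation"))
  t <- incubation$o2_time
  y <- incubation$o2_conc
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  low <- r2 < r2_threshold
  if (low)
    warning(sprintf("O2 regression r2 = %.3f below threshold %.2f (%s)",
                    r2, r2_threshold, incubation$id))
  list(rate = slope * incubation$volume / incubation$surface,
       slope = slope, r2 = r2, low_r2 = low)
}

#' Net calcification by the alkalinity anomaly technique
#'
#' Each mole of CaCO3 precipitated removes 2 equivalents of total
#' alkalinity, so G = dA_T * V / (2 * dt * S) with dA_T = initial - final.
#' A negative G is net dissolution.
#'
#' @param alk_initial,alk_final total alkalinity (ueq L-1).
#' @param duration incubation duration (h).
#' @param volume chamber volume (L).
#' @param surface thallus surface area (cm2).
#' @return Net calcification (umol CaCO3 cm-2 h-1).
#' @examples
#' calcification_rate(2540, 2500, duration = 2, volume = 0.2, surface = 20)
#' @export
calcification_rate <- function(alk_initial, alk_final, duration, volume,
                               surface) {
  if (any(c(duration, volume, surface) <= 0))
    stop("duration, volume and surface must all be > 0")
  (alk_initial - alk_final) * volume / (2 * duration * surface)
}

#' Organic carbon flux from the C_T drawdown, corrected for calcification
#'
#' The C_T change during an incubation mixes organic metabolism
#' (photosynthesis/respiration, 1 mol C per mol C_T) and calcification
#' (1 mol C_T per mol CaCO3). The organic flux is the gross C_T drawdown
#' rate minus the calcification rate. In the light it is returned as net
#' photosynthesis (positive = fixation); in the dark as dark respiration
#' (positive = release).
#'
#' @param ct_initial,ct_final dissolved inorganic carbon of the bracketing
#'   samples (umol L-1), usually from [carb_from_ph_alk()] scaled by the
#'   seawater density.
#' @param duration,volume,surface as in [calcification_rate()].
#' @param calcification the calcification rate G (umol CaCO3 cm-2 h-1) of
#'   the same incubation; the correction is mandatory.
#' @param light logical: was the incubation in the light?
#' @return Pn (light) or Rd (dark), umol C cm-2 h-1.
#' @export
carbon_rate <- function(ct_initial, ct_final, duration, volume, surface,
                        calcification, light) {
  if (missing(calcification) || is.null(calcification) ||
        !is.finite(calcification))
    stop("the calcification correction is mandatory for the carbon flux")
  if (any(c(duration, volume, surface) <= 0))
    stop("duration, volume and surface must all be > 0")
  drawdown <- (ct_initial - ct_final) * volume / (duration * surface)
  organic <- drawdown - calcification
  if (light) organic else -organic
}

#' Gross production from net production and dark respiration
#'
#' Pg = Pn + Rd, in whatever currency (O2 or C) both rates share.
#'
#' @param pn net production (umol cm-2 h-1, signed).
#' @param rd dark respiration (umol cm-2 h-1, >= 0 by convention).
#' @param currency optional currency labels for `pn` and `rd`; if both are
#'   given they must match.
#' @return Pg = pn + rd.
#' @export
gross_rate <- function(pn, rd, currency = NULL) {
  if (!is.null(currency) && length(currency) == 2 &&
        currency[1] != currency[2])
    stop("currency mismatch: ", currency[1], " vs ", currency[2])
  if (any(rd < 0)) stop("rd must be >= 0 (stored as a magnitude)")
  pn + rd
}

#' All metabolic fluxes of one incubation
#'
#' Runs the full flux chain on a single closed-chamber record: O2 slope
#' regression, C_T speciation of the bracketing samples, alkalinity-anomaly
#' calcification, and the calcification-corrected organic carbon flux.
#' Rates follow the sign conventions of the individual functions: light
#' runs report net photosynthesis (Pn), dark runs report respiration (Rd)
#' and dark calcification (Gd) as positive magnitudes (Gd negative = dark
#' dissolution).
#'
#' @param incubation a [chamber_incubation()].
#' @param dark optional matching dark incubation (same alga); when given,
#'   gross production Pg = Pn + Rd is included in both currencies.
#' @param density seawater density (kg L-1) used to convert the per-kg
#'   speciation C_T to the volumetric (per-litre) units of the chamber
#'   budget; default 1.028.
#' @param constants optional [carb_constants()]; defaults to the package
#'   default set at the incubation's temperature and salinity.
#' @param r2_threshold passed to [o2_rate()].
#' @return A one-row data frame: identifiers, `light` flag, `Pn_O2`/`Rd_O2`,
#'   `Pn_C`/`Rd_C`, `G`/`Gd`, optional `Pg_O2`/`Pg_C`, `o2_r2`, `low_r2`.
#' @export
incubation_fluxes <- function(incubation, dark = NULL, density = 1.028,
                              constants = NULL, r2_threshold = 0.8) {
  stopifnot(inherits(incubation, "chamber_incubation"))
  inc <- incubation
  if (is.null(constants))
    constants <- carb_constants(inc$temperature, inc$salinity)
  o2 <- o2_rate(inc, r2_threshold = r2_threshold)
  light <- inc$light > 0

  # bracketing samples: alkalinity is carried volumetrically (ueq L-1);
  # speciation works per kg, so divide by density going in and multiply
  # coming out
  sp <- carb_from_ph_alk(c(inc$ph_initial, inc$ph_final),
                         c(inc$alk_initial, inc$alk_final) / density,
                         constants = constants)
  ct <- sp$ct * density  # umol L-1

  G <- calcification_rate(inc$alk_initial, inc$alk_final, inc$duration,
                          inc$volume, inc$surface)
  organic <- carbon_rate(ct[1], ct[2], inc$duration, inc$volume,
                         inc$surface, calcification = G, light = light)

  out <- data.frame(
    incubation_id = inc$id, treatment = inc$treatment, season = inc$season,
    light = light, irradiance = inc$light,
    Pn_O2 = if (light) o2$rate else NA_real_,
    Rd_O2 = if (light) NA_real_ else -o2$rate,
    Pn_C = if (light) organic else NA_real_,
    Rd_C = if (light) NA_real_ else organic,
    G = if (light) G else NA_real_,
    Gd = if (light) NA_real_ else G,
    o2_r2 = o2$r2, low_r2 = o2$low_r2,
    stringsAsFactors = FALSE
  )
  if (light && !is.null(dark)) {
    dk <- incubation_fluxes(dark, density = density,
                            r2_threshold = r2_threshold)
    out$Pg_O2 <- gross_rate(out$Pn_O2, dk$Rd_O2)
    out$Pg_C <- gross_rate(out$Pn_C, dk$Rd_C)
  }
  out
}
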