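#' Equilibrium constants of the seawater CO2 system
#'
#' Evaluates the thermodynamic constants needed to speciate the CO2 system
#' from a measured (pH_T, A_T) pair: CO2 solubility (K0), the two carbonic
#' acid dissociation constants (K1, K2, total hydrogen-ion scale), boric acid
#' (KB), water (Kw), the stoichiometric solubility products of calcite and
#' aragonite, and the salinity-proportional total borate and calcium
#' concentrations. All constants are evaluated at surface pressure.
#'
#' @param temperature water temperature (degrees C), in \[0, 40\].
#' @param salinity practical salinity, in \[20, 42\].
#' @param k1k2 carbonic-acid constant formulation: `"roy93"` (Roy et al.
#'   1993, the default), `"lueker00"` (Lueker et al. 2000) or `"dm87"`
#'   (Mehrbach refit by Dickson & Millero 1987). All are on the total scale.
#' @return An object of class `carb_constants`: a list with elements `K0`
#'   (mol kg-1 atm-1), `K1`, `K2`, `KB`, `Kw` (mol kg-1 scale as
#'   appropriate), `Ksp_calcite`, `Ksp_aragonite` (mol2 kg-2), `BT`, `CaT`
#'   (mol kg-1), `temperature`, `salinity`, and a `provenance` list naming
#'   each formulation.
#' @references Roy et al. (1993) Mar Chem 44:249; Lueker et al. (2000) Mar
#'   Chem 70:105; Dickson & Millero (1987) Deep-Sea Res 34:1733; Weiss
#'   (1974) Mar Chem 2:203; Dickson (1990) Deep-Sea Res 37:755; Millero
#'   (1995) Geochim Cosmochim Acta 59:661; Mucci (1983) Am J Sci 283:780.
#' @seealso [carb_from_ph_alk()]
#' @examples
#' kc <- carb_constants(22, 38)
#' kc$K1 > kc$K2
#' @export
carb_constants <- function(temperature, salinity,
                           k1k2 = c("roy93", "lueker00", "dm87")) {
  k1k2 <- match.arg(k1k2)
  if (!is.finite(temperature) || temperature < 0 || temperature > 40)
    stop("temperature out of range [0, 40] degC: ", temperature)
  if (!is.finite(salinity) || salinity < 20 || salinity > 42)
    stop("salinity out of range [20, 42]: ", salinity)

  TK <- temperature + 273.15
  S <- salinity

  # Weiss (1974), mol kg-1 atm-1
  K0 <- exp(-60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
              S * (0.023517 - 0.023656 * (TK / 100) +
                     0.0047036 * (TK / 100)^2))

  if (k1k2 == "roy93") {
    K1 <- exp(-2307.1266 / TK + 2.83655 - 1.5529413 * log(TK) +
                (-4.0484 / TK - 0.20760841) * sqrt(S) + 0.08468345 * S -
                0.00654208 * S^1.5 + log(1 - 0.001005 * S))
    K2 <- exp(-3351.6106 / TK - 9.226508 - 0.2005743 * log(TK) +
                (-23.9722 / TK - 0.106901773) * sqrt(S) + 0.1130822 * S -
                0.00846934 * S^1.5 + log(1 - 0.001005 * S))
  } else if (k1k2 == "lueker00") {
    K1 <- 10^-(3633.86 / TK - 61.2172 + 9.6777 * log(TK) -
                 0.011555 * S + 0.0001152 * S^2)
    K2 <- 10^-(471.78 / TK + 25.929 - 3.16967 * log(TK) -
                 0.01781 * S + 0.0001122 * S^2)
  } else {
    K1 <- 10^-(3670.7 / TK - 62.008 + 9.7944 * log(TK) -
                 0.0118 * S + 0.000116 * S^2)
    K2 <- 10^-(1394.7 / TK + 4.777 - 0.0184 * S + 0.000118 * S^2)
  }

  # Dickson (1990), total scale
  KB <- exp((-8966.90 - 2890.53 * sqrt(S) - 77.942 * S +
               1.728 * S^1.5 - 0.0996 * S^2) / TK +
              148.0248 + 137.1942 * sqrt(S) + 1.62142 * S +
              (-24.4344 - 25.085 * sqrt(S) - 0.2474 * S) * log(TK) +
              0.053105 * sqrt(S) * TK)

  # Millero (1995)
  Kw <- exp(148.9802 - 13847.26 / TK - 23.6521 * log(TK) +
              (118.67 / TK - 5.977 + 1.0495 * log(TK)) * sqrt(S) -
              0.01615 * S)

  # Mucci (1983)
  Ksp_calcite <- 10^(-171.9065 - 0.077993 * TK + 2839.319 / TK +
                       71.595 * log10(TK) +
                       (-0.77712 + 0.0028426 * TK + 178.34 / TK) * sqrt(S) -
                       0.07711 * S + 0.0041249 * S^1.5)
  Ksp_aragonite <- 10^(-171.945 - 0.077993 * TK + 2903.293 / TK +
                         71.595 * log10(TK) +
                         (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqrt(S) -
                         0.10018 * S + 0.0059415 * S^1.5)

  out <- list(
    K0 = K0, K1 = K1, K2 = K2, KB = KB, Kw = Kw,
    Ksp_calcite = Ksp_calcite, Ksp_aragonite = Ksp_aragonite,
    BT = 0.0004157 * S / 35,       # Uppstrom (1974)
    CaT = 0.01028 * S / 35,        # Riley & Tongudai via Mucci (1983)
    temperature = temperature, salinity = salinity,
    provenance = list(
      K0 = "Weiss 1974",
      K1K2 = switch(k1k2,
                    roy93 = "Roy et al. 1993 (total scale)",
                    lueker00 = "Lueker et al. 2000 (total scale)",
                    dm87 = "Mehrbach 1973 refit Dickson & Millero 1987 (total scale)"),
      KB = "Dickson 1990 (total scale)",
      Kw = "Millero 1995",
      Ksp = "Mucci 1983",
      BT = "Uppstrom 1974",
      CaT = "0.01028 * S/35",
      pressure = "surface",
      k1k2 = k1k2
    )
  )
  class(out) <- "carb_constants"
  out
}

#' @export
print.carb_constants <- function(x, ...) {
  cat("Seawater CO2-system constants (", x$provenance$K1K2, ")\n", sep = "")
  cat(sprintf("  T = %.2f degC, S = %.2f, surface pressure\n",
              x$temperature, x$salinity))
  for (k in c("K0", "K1", "K2", "KB", "Kw", "Ksp_calcite", "Ksp_aragonite"))
    cat(sprintf("  %-14s %.6e\n", k, x[[k]]))
  invisible(x)
}

# Alkalinity balance used throughout: A_T = [HCO3] + 2[CO3] + [B(OH)4] +
# [OH] - [H]. Phosphate/silicate terms omitted (not measured alongside the
# incubations this package targets).
carb_alk_from_ph_ct <- function(H, CT, kc) {
  denom <- 1 + kc$K1 / H + kc$K1 * kc$K2 / H^2
  CO2 <- CT / denom
  HCO3 <- CO2 * kc$K1 / H
  CO3 <- HCO3 * kc$K2 / H
  HCO3 + 2 * CO3 + kc$BT * kc$KB / (kc$KB + H) + kc$Kw / H - H
}

#' Speciate the seawater CO2 system from pH and total alkalinity
#'
#' Closed-form speciation from the measured pair (pH on the total scale,
#' total alkalinity): the carbonate alkalinity is the total alkalinity minus
#' the borate and water contributions, split into bicarbonate and carbonate
#' via K2/\[H+\]; dissolved CO2 follows from K1 and pCO2 from the solubility
#' K0; saturation states are \[Ca2+\]\[CO3 2-\]/Ksp.
#'
#' @param ph pH on the total hydrogen-ion scale (6.5-9). Vectorised.
#' @param alkalinity total alkalinity (umol kg-1). Vectorised.
#' @param temperature water temperature (degrees C).
#' @param salinity practical salinity (default 38, north-western
#'   Mediterranean surface water).
#' @param constants optional pre-computed [carb_constants()] object; when
#'   supplied, `temperature`/`salinity`/`k1k2` are taken from it.
#' @param k1k2 carbonic-acid constant formulation, see [carb_constants()].
#' @return A data frame of class `carb_state` with one row per input:
#'   `ph_total`, `alkalinity` (umol kg-1), `ct` (umol kg-1), `pco2_uatm`,
#'   `co2`, `hco3`, `co3` (umol kg-1), `omega_calcite`, `omega_aragonite`,
#'   `temperature_C`, `salinity`. The constant provenance is attached as
#'   attribute `"provenance"`.
#' @examples
#' carb_from_ph_alk(8.06, 2538, temperature = 22, salinity = 38)
#' @export
carb_from_ph_alk <- function(ph, alkalinity, temperature, salinity = 38,
                             constants = NULL,
                             k1k2 = c("roy93", "lueker00", "dm87")) {
  if (is.null(constants)) {
    k1k2 <- match.arg(k1k2)
    constants <- carb_constants(temperature, salinity, k1k2 = k1k2)
  }
  stopifnot(inherits(constants, "carb_constants"))
  if (any(!is.finite(ph)) || any(ph < 6.5) || any(ph > 9))
    stop("pH_T out of range [6.5, 9]")
  if (any(!is.finite(alkalinity)) || any(alkalinity <= 0))
    stop("alkalinity must be positive (umol kg-1)")
  n <- max(length(ph), length(alkalinity))
  ph <- rep_len(ph, n)
  alkalinity <- rep_len(alkalinity, n)

  kc <- constants
  H <- 10^(-ph)
  AT <- alkalinity * 1e-6
  borate <- kc$BT * kc$KB / (kc$KB + H)
  OH <- kc$Kw / H
  CA <- AT - borate - OH + H
  if (any(CA <= 0))
    stop("computed carbonate alkalinity <= 0: pH and alkalinity inconsistent")
  HCO3 <- CA / (1 + 2 * kc$K2 / H)
  CO3 <- HCO3 * kc$K2 / H
  CO2 <- HCO3 * H / kc$K1
  out <- data.frame(
    ph_total = ph,
    alkalinity = alkalinity,
    ct = (CO2 + HCO3 + CO3) * 1e6,
    pco2_uatm = CO2 / kc$K0 * 1e6,
    co2 = CO2 * 1e6,
    hco3 = HCO3 * 1e6,
    co3 = CO3 * 1e6,
    omega_calcite = kc$CaT * CO3 / kc$Ksp_calcite,
    omega_aragonite = kc$CaT * CO3 / kc$Ksp_aragonite,
    temperature_C = kc$temperature,
    salinity = kc$salinity
  )
  attr(out, "provenance") <- kc$provenance
  class(out) <- c("carb_state", "data.frame")
  out
}

#' Solve pH from total alkalinity and dissolved inorganic carbon
#'
#' Inverts the alkalinity balance by bisection on pH. Used when propagating
#' a closed-chamber incubation forward in time: metabolic changes are
#' naturally expressed in (A_T, C_T), from which the final pH follows.
#'
#' @param alkalinity total alkalinity (umol kg-1).
#' @param ct dissolved inorganic carbon (umol kg-1).
#' @inheritParams carb_from_ph_alk
#' @param interval pH search interval.
#' @param tol convergence tolerance on pH.
#' @return pH on the total scale (numeric, vectorised over
#'   `alkalinity`/`ct`).
#' @export
carb_ph_from_alk_ct <- function(alkalinity, ct, temperature, salinity = 38,
                                constants = NULL,
                                k1k2 = c("roy93", "lueker00", "dm87"),
                                interval = c(4, 11), tol = 1e-10) {
  if (is.null(constants)) {
    k1k2 <- match.arg(k1k2)
    constants <- carb_constants(temperature, salinity, k1k2 = k1k2)
  }
  n <- max(length(alkalinity), length(ct))
  alkalinity <- rep_len(alkalinity, n)
  ct <- rep_len(ct, n)
  vapply(seq_len(n), function(i) {
    f <- function(ph)
      carb_alk_from_ph_ct(10^(-ph), ct[i] * 1e-6, constants) -
        alkalinity[i] * 1e-6
    stats::uniroot(f, interval = interval, tol = tol)$root
  }, numeric(1))
}

#' Average pH values on the hydrogen-ion scale
#'
#' pH is a logarithmic quantity; replicate pH readings are averaged by
#' converting to \[H+\], taking the arithmetic mean, and converting back.
#' The result is never above the arithmetic mean of the pH values.
#'
#' @param ph numeric vector of pH values (any scale, returned on the same
#'   scale).
#' @return A single pH value.
#' @examples
#' mean_ph(c(8.0, 7.0))  # 7.2596, not 7.5
#' @export
mean_ph <- function(ph) {
  if (length(ph) == 0 || any(!is.finite(ph)))
    stop("mean_ph() needs a non-empty vector of finite pH values")
  -log10(mean(10^(-ph)))
}
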