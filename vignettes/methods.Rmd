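---
title: "Models and numerical choices in lithoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in lithoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lithoflux)
```

lithoflux implements the computational chain of a seasonal closed-chamber
experiment on a calcifying macroalga under crossed pCO2 × temperature
treatments. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not demonstrate.

## Carbonate-system speciation

The experiment measures pH on the total hydrogen-ion scale and total
alkalinity; everything else about the CO2 system is computed. Given
$[\mathrm{H}^+] = 10^{-\mathrm{pH}_T}$, the solver subtracts the borate
and water contributions from total alkalinity,

$$A_C = A_T - \frac{B_T K_B}{K_B + [\mathrm{H}^+]} - \frac{K_w}{[\mathrm{H}^+]} + [\mathrm{H}^+],$$

partitions the carbonate alkalinity $A_C = [\mathrm{HCO_3^-}] +
2[\mathrm{CO_3^{2-}}]$ via $K_2/[\mathrm{H}^+]$, and closes the system
with $[\mathrm{CO_2^*}] = [\mathrm{HCO_3^-}][\mathrm{H}^+]/K_1$,
$p\mathrm{CO_2} = [\mathrm{CO_2^*}]/K_0$ and
$\Omega = [\mathrm{Ca^{2+}}][\mathrm{CO_3^{2-}}]/K_{sp}$. This is a
closed-form computation — no iteration is needed for this input pair; the
package's bisection solver (`carb_ph_from_alk_ct()`) is only used in the
other direction, recovering pH from an $(A_T, C_T)$ budget.

Choices a user should know about:

* **Constant set.** The default is Roy et al. (1993) for $K_1/K_2$, with
  Dickson (1990) $K_B$, Millero (1995) $K_w$, Mucci (1983) solubility
  products, Weiss (1974) $K_0$, Uppström (1974) borate, and
  $\mathrm{Ca_T} = 0.01028\,(S/35)$ mol kg⁻¹ — the default constant suite
  of the CO2-system software generation that the source experiment used.
  We verified that this set reproduces the experiment's printed carbonate
  tables within ~1%, while Lueker et al. (2000) — today's more common
  default, also available via `k1k2 = "lueker00"` — lands 2–5% away on
  pCO2 and Ω for the same inputs. Reproducing a published table requires
  the constants of its era; new analyses are free to choose.
* **Salinity.** The experiment never states salinity; the package default
  is S = 38.0, typical north-western Mediterranean surface water, exposed
  everywhere as an argument.
* **Omissions.** Phosphate and silicate alkalinity are not modelled (they
  were not measured alongside the incubations); the fugacity correction to
  pCO2 (~0.3%) and pH-scale conversion of $K_w$ (sub-0.1 μmol kg⁻¹ effect
  on the balance at pH ≈ 8) are likewise omitted. All are far below the
  ~1% reproduction accuracy this chain can claim given the unreported
  salinity.
* **Units.** Speciation works per kilogram of seawater; chamber budgets
  are volumetric. The two meet through a configurable density (default
  1.028 kg L⁻¹).

Replicate pH values are averaged on the $[\mathrm{H}^+]$ scale
(`mean_ph()`), never arithmetically.

## Chamber fluxes

For a chamber of volume $V$ (L) and thallus area $S$ (cm²) incubated for
$\Delta t$ h:

* O2 flux $= s_{\mathrm{O_2}} V / S$, with $s_{\mathrm{O_2}}$ the OLS
  slope of the whole O2 series (no endpoint-only option and no outlier
  rejection; a fit with $r^2 < 0.8$ is flagged, not dropped, since the
  protocol states no rejection rule).
* Net calcification $G = \Delta A_T \, V / (2 \Delta t \, S)$ — the
  alkalinity anomaly technique, 2 equivalents per mole of CaCO3.
  $\Delta$ is *initial − final* throughout, so consumption is positive;
  negative $G$ is net dissolution.
* Organic carbon flux = C_T drawdown rate − $G$: precipitating one mole
  of CaCO3 removes one mole of C_T, so the calcification correction is
  mandatory (the function refuses to run without it).
* $P_g = P_n + R_d$, with dark respiration stored as a positive
  magnitude. This is the only reading of the gross-production bookkeeping
  consistent with the derived-parameter identity
  $P_n^{max} = P_g^{max} - R_d$.

## Irradiance-response model

Both photosynthesis and calcification light responses use the Platt
saturating-exponential model with photoinhibition plus a dark offset:

$$P_n(E) = P_s\left(1 - e^{-\alpha E / P_s}\right)e^{-\beta E / P_s} - R_d,$$

and $G(E)$ identically with $+G_d$ (dark calcification can be of either
sign, so it is unconstrained; $R_d$ is bounded at 0). $P_s$ is the scale
(gross maximum in the absence of photoinhibition), $\alpha$ the initial
slope, $\beta$ the photoinhibition coefficient.

Derived parameters (Harrison–Platt closed forms):
$P_g^{max} = P_s\,[\alpha/(\alpha+\beta)]\,[\beta/(\alpha+\beta)]^{\beta/\alpha}$,
$P_n^{max} = P_g^{max} - R_d$, $E_k = P_g^{max}/\alpha$. The compensation
irradiance $E_c$ has no usable closed form once $\beta > 0$, so it is
defined as the smallest positive root of the fitted net curve and found
by bracketed root search on $(0, E^*]$, where
$E^* = (P_s/\alpha)\ln\!\big((\alpha+\beta)/\beta\big)$ is the interior
maximum; for $\beta = 0$ the closed form
$-(P_s/\alpha)\ln(1 - R_d/P_s)$ serves as the test oracle. $E_c$ is
reported missing (with a reason) when $R_d \ge P_g^{max}$ and for
calcification fits with $G_d \ge 0$.

Numerical choices in `fit_platt()`:

* bounded Levenberg–Marquardt (minpack.lm) with $P_s > 0$, $\alpha > 0$,
  $\beta \ge 0$;
* deterministic initialisation — $\alpha_0$ from the OLS slope of the 3
  lowest nonzero irradiances, offset from the dark point, $P_s^0$ from
  the observed maximum — with a two-point multi-start over
  $\beta_0 \in \{0, \alpha_0/100\}$ and best-RSS selection, so the fit
  contains no randomness;
* the $[\beta/(\alpha+\beta)]^{\beta/\alpha}$ factor is evaluated as
  $\exp\big((\beta/\alpha)\ln(\beta/(\alpha+\beta))\big)$ with limit 1
  when $\beta < 10^{-12}\alpha$, avoiding 0⁰;
* the dark offset is fitted as a free parameter by default (the model
  statement includes it in the fitted function); `offset =` pins it to a
  measured dark rate instead.

Curves are fitted per alga and parameters aggregated afterwards
(mean ± SE over replicates), matching how such experiments report
treatment values; the treatment mean of $E_k$ is therefore the mean of
per-replicate ratios, deliberately not
$\overline{P_g^{max}}/\overline{\alpha}$.

## Light field

$K_{PAR}$ is minus the OLS slope of $\ln(\mathrm{PAR})$ on depth (the
standard exponential attenuation treatment); an upward PAR gradient
yields a flagged negative estimate rather than an error. Daily mean
irradiance is a trapezoidal time-average over the daylight samples only
(PAR > 0), because the experimental irradiance is a constant applied
during the photoperiod — averaging the night in would halve it.

## Factorial statistics

Each response in each season is analysed independently (specimens are
replaced between seasons, so seasons are not repeated measures):
Shapiro–Wilk on the residuals of the full model and Levene (centred on
cell means) across the four cells; if either fails at α = 0.05 and the
response is strictly positive, the data are log-transformed and flagged.
The two-way ANOVA uses sum-to-zero contrasts and Type III sums of squares
— the decomposition whose F equals the squared t of each 1-df effect in
the full effects-coded regression, appropriate for the mildly unbalanced
cells (n = 4 vs 5) and matching the behaviour of the commercial packages
of the era this pipeline mirrors (Type II by option). Post hoc
comparisons are Tukey–Kramer: studentized-range tests with the pairwise
harmonic-mean n in the standard error, implemented as the practical
approximation of the Spjøtvoll–Støline unequal-n Tukey test. Compact
letters come from a greedy insert–absorb construction, with `nd` when no
pair separates. The family-wise α is Bonferroni-divided by the number of
analyses — a required, explicit input (defaulting to the number of flux
responses analysed per season), since the right divisor is a design
decision, not something the data can supply.

## The synthetic generator, and what the tests show

`synthetic_truth()` fixes, per season and treatment: ambient temperature
(22.0 / 17.7 / 13.3 / 17.7 °C for summer/autumn/winter/spring),
experimental irradiance (35 / 16 / 6 / 21 μmol photons m⁻² s⁻¹),
photoperiod, carbonate baselines per treatment, and true Platt parameters
whose magnitudes echo the published seasonal physiology: summer scale
parameters 2–3× winter, photoinhibition strongest in winter, highest
summer calcification under elevated pCO2 at ambient temperature, slight
dark dissolution in spring, and n = 5 algae per treatment except n = 4
for the warm high-CO2 treatment in winter and spring. Noise defaults are
σ(O2) = 1 μmol L⁻¹, σ(A_T) = 3 μeq L⁻¹, σ(pH) = 0.005, rate noise 5% of
the scale parameter, between-alga parameter jitter CV 10%, photosynthetic
quotient 1. These are fixed study conditions, not tuning knobs.

`simulate_incubation()` closes its own books: the O2 series drifts at the
true net rate, final alkalinity drops by $2 G \Delta t S / V$, and the
final pH is solved so that the $(A_T, C_T)$ budget is exactly consistent
with the carbonate chemistry — so at zero noise every flux function must
invert the generator to machine precision, and the suite asserts that it
does.

What passing tests show: the estimators are unbiased and self-consistent
under Gaussian measurement noise, the fitting is deterministic and
recovers known parameters, and the statistical machinery agrees with
brute-force oracles. What they do not show: robustness to electrode
drift, bubble artefacts, non-Gaussian outliers, within-incubation
nonlinearity (e.g. light fluctuation or O2 supersaturation effects), or
any biology beyond the Platt curve — real chamber data need their own
quality control, for which the r² flags and exclusion logging are entry
points.

A note on one simulation benchmark: with n = 5 replicates, the nominal
coverage of "treatment mean ± 2·SE" is $1 - 2\,t_4(-2) \approx 88\%$, not
95%, because 2 < $t_{0.975,4} = 2.78$. Simulation checks built on that
interval therefore hover near 88–90% per parameter — a property of the
interval at this n, not an estimator defect; the suite's bias checks
(median relative bias of $\alpha$ under 5% noise) are the sharper
diagnostic.

## Problem sizes

The shipped tests run the speciation invariants on 1000 random states,
parameter-recovery simulations at 100–500 seeded replicates, the
family-wise error simulation at 1000 null datasets, and the full-design
ordering check at 50 seeded experiment realisations of one season pair —
sizes chosen so the whole suite exercises every stochastic claim while
completing in well under a minute on a single core.

## Known limitations

* Only the (pH_T, A_T) input pair is supported — the pair this protocol
  measures; no pressure correction, no other pH scales.
* The Spjøtvoll–Støline test is implemented in its Tukey–Kramer form;
  exact Spjøtvoll–Støline critical values differ slightly for strongly
  unbalanced designs (here at most 5 vs 4).
* The carbonate reproduction accuracy is bounded at ~1% by the unreported
  salinity and constant provenance of the source tables.
* `fit_platt()` requires at least five distinct irradiance levels
  including darkness; sparser designs should pin the offset to the
  measured dark rate.
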