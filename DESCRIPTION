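Package: lithoflux
Title: Carbonate Chemistry and Metabolic Fluxes for Closed-Chamber
    Incubations of Coralline Algae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ocean-acidification and warming
    experiments on calcifying macroalgae. Solves the seawater CO2 system
    from measured pH (total scale) and total alkalinity; converts
    closed-chamber incubation records (O2 time series, bracketing
    pH/alkalinity samples) into area-normalised rates of net and gross
    photosynthesis, respiration and net calcification via the alkalinity
    anomaly technique; fits photosynthesis- and calcification-irradiance
    curves with the Platt photoinhibition model plus a dark-offset term
    and derives the photophysiological parameters (maximum rates,
    saturating and compensation irradiances); estimates PAR attenuation
    with depth; and runs the 2 x 2 factorial (pCO2 x temperature)
    statistics with unequal-n Tukey post hoc comparisons and compact
    letter displays. Includes a seeded synthetic-data generator with
    known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    minpack.lm,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
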