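#' Speciate a CSV of discrete seawater samples
#'
#' Reads a CSV with columns `sample_id`, `ph_total`, `alkalinity_umol_kg`,
#' `temperature_C`, `salinity`, appends the speciation columns (`ct`,
#' `pco2_uatm`, `co2`, `hco3`, `co3`, `omega_calcite`,
#' `omega_aragonite`) and optionally writes the result plus a JSON
#' provenance block naming the constant set.
#'
#' @param input path to the input CSV.
#' @param output optional path for the output CSV; a `.provenance.json`
#'   file is written alongside it.
#' @param k1k2 constant formulation, see [carb_constants()].
#' @return The augmented data frame (invisibly when `output` is given).
#' @export
speciate_csv <- function(input, output = NULL,
                         k1k2 = c("roy93", "lueker00", "dm87")) {
  k1k2 <- match.arg(k1k2)
  d <- utils::read.csv(input, stringsAsFactors = FALSE)
  need <- c("sample_id", "ph_total", "alkalinity_umol_kg",
            "temperature_C", "salinity")
  if (!all(need %in% names(d)))
    stop("input is missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  res <- lapply(seq_len(nrow(d)), function(i)
    carb_from_ph_alk(d$ph_total[i], d$alkalinity_umol_kg[i],
                     d$temperature_C[i], d$salinity[i], k1k2 = k1k2))
  prov <- attr(res[[1]], "provenance")
  res <- do.call(rbind, lapply(res, as.data.frame))
  out <- cbind(d, res[c("ct", "pco2_uatm", "co2", "hco3", "co3",
                        "omega_calcite", "omega_aragonite")])
  if (!is.null(output)) {
    utils::write.csv(out, output, row.names = FALSE)
    jsonlite::write_json(prov,
                         paste0(tools::file_path_sans_ext(output),
                                ".provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  attr(out, "provenance") <- prov
  out
}

#' Read incubation records and O2 series from the pipeline CSV schemas
#'
#' `incubations.csv` holds one row per chamber run (see
#' [write_synthetic_dataset()] for the column schema); `o2_series.csv`
#' holds the matching O2 time series keyed by `incubation_id`.
#'
#' @param incubations_csv,o2_csv file paths.
#' @return A list of [chamber_incubation()] objects; rows that fail
#'   validation are dropped with their reasons in attribute `"excluded"`.
#' @export
read_incubations <- function(incubations_csv, o2_csv) {
  inc <- utils::read.csv(incubations_csv, stringsAsFactors = FALSE)
  o2 <- utils::read.csv(o2_csv, stringsAsFactors = FALSE)
  need <- c("incubation_id", "treatment", "season", "replicate",
            "irradiance", "duration_h", "volume_L", "surface_cm2",
            "ph_initial", "ph_final", "alk_initial_ueq_L",
            "alk_final_ueq_L", "temperature_C", "salinity")
  if (!all(need %in% names(inc)))
    stop("incubations.csv is missing columns: ",
         paste(setdiff(need, names(inc)), collapse = ", "))
  if (!all(c("incubation_id", "time_h", "o2_umol_L") %in% names(o2)))
    stop("o2_series.csv must have incubation_id, time_h, o2_umol_L")

  excluded <- character()
  out <- list()
  for (i in seq_len(nrow(inc))) {
    row <- inc[i, ]
    ser <- o2[o2$incubation_id == row$incubation_id, ]
    obj <- tryCatch({
      ord <- order(ser$time_h)
      ci <- chamber_incubation(
        id = row$incubation_id, treatment = row$treatment,
        season = row$season, light = row$irradiance,
        duration = row$duration_h, volume = row$volume_L,
        surface = row$surface_cm2,
        o2_time = ser$time_h[ord], o2_conc = ser$o2_umol_L[ord],
        ph_initial = row$ph_initial, ph_final = row$ph_final,
        alk_initial = row$alk_initial_ueq_L,
        alk_final = row$alk_final_ueq_L,
        temperature = row$temperature_C, salinity = row$salinity)
      ci$replicate <- row$replicate
      ci
    }, error = function(e) {
      excluded[[length(excluded) + 1]] <<-
        sprintf("%s: %s", row$incubation_id, conditionMessage(e))
      NULL
    })
    if (!is.null(obj)) out[[length(out) + 1]] <- obj
  }
  attr(out, "excluded") <- excluded
  out
}

#' Run the full incubation-to-statistics pipeline
#'
#' Orchestrates every stage on a directory of schema CSVs: carbonate
#' speciation of the bracketing samples, per-incubation fluxes (pairing
#' each light run with the dark run of the same alga for gross
#' production), per-replicate irradiance-response fits with derived
#' parameters and treatment summaries (when `pe_rates.csv` is present),
#' and per-season two-way ANOVAs with Tukey-Kramer letters at the
#' Bonferroni-adjusted threshold. A bad incubation record is excluded and
#' logged, not fatal.
#'
#' @param config a named list or path to a YAML file with fields:
#'   `input_dir` (directory holding `incubations.csv`, `o2_series.csv`,
#'   optionally `pe_rates.csv`), `output_dir` (optional: write result
#'   CSVs, a provenance JSON and `log.txt`), `k1k2` (constant set,
#'   default `"roy93"`), `density` (default 1.028), `pin_offset`
#'   (logical: pin the fitted dark offset to the measured dark rate;
#'   default FALSE), `bonferroni_n` (divisor for the family alpha;
#'   default = number of flux responses analysed per season),
#'   `base_alpha` (default 0.05), `r2_threshold` (default 0.8).
#' @return A list: `speciation`, `fluxes`, `curve_params`,
#'   `curve_summary`, `anova`, `letters`, `excluded`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(k1k2 = "roy93", density = 1.028, pin_offset = FALSE,
         bonferroni_n = NULL, base_alpha = 0.05, r2_threshold = 0.8,
         output_dir = NULL),
    config)
  if (is.null(cfg$input_dir)) stop("config needs input_dir")
  pin <- file.path(cfg$input_dir, "incubations.csv")
  po2 <- file.path(cfg$input_dir, "o2_series.csv")
  ppe <- file.path(cfg$input_dir, "pe_rates.csv")
  if (!file.exists(pin) || !file.exists(po2))
    stop("input_dir must contain incubations.csv and o2_series.csv")

  incs <- read_incubations(pin, po2)
  excluded <- attr(incs, "excluded")
  log_lines <- c(sprintf("lithoflux pipeline: %d incubations read, %d excluded",
                         length(incs), length(excluded)), excluded)

  # speciation of initial samples (Table-1-style view of the treatments)
  spec <- do.call(rbind, lapply(incs, function(x) {
    s <- carb_from_ph_alk(x$ph_initial, x$alk_initial / cfg$density,
                          x$temperature, x$salinity, k1k2 = cfg$k1k2)
    cbind(data.frame(incubation_id = x$id, treatment = x$treatment,
                     season = x$season, stringsAsFactors = FALSE),
          as.data.frame(s))
  }))

  # fluxes, pairing light runs with the same alga's dark run
  key <- vapply(incs, function(x)
    sprintf("%s|%s|%s", x$season, x$treatment, x$replicate), character(1))
  is_dark <- vapply(incs, function(x) x$light == 0, logical(1))
  flux <- list()
  for (i in seq_along(incs)) {
    x <- incs[[i]]
    dark <- if (!is_dark[i]) {
      j <- which(key == key[i] & is_dark)
      if (length(j) >= 1) incs[[j[1]]] else NULL
    }
    row <- tryCatch(
      suppressWarnings(
        incubation_fluxes(x, dark = dark, density = cfg$density,
                          r2_threshold = cfg$r2_threshold)),
      error = function(e) {
        log_lines <<- c(log_lines,
                        sprintf("flux failed %s: %s", x$id,
                                conditionMessage(e)))
        NULL
      })
    if (!is.null(row)) {
      row$replicate <- x$replicate
      flux[[length(flux) + 1]] <- row
    }
  }
  flux <- do.call(rbind, lapply(flux, function(d) {
    for (cc in c("Pg_O2", "Pg_C")) if (!cc %in% names(d)) d[[cc]] <- NA_real_
    d
  }))

  # irradiance-response fits
  curve_params <- NULL
  curve_summary <- NULL
  if (file.exists(ppe)) {
    pe <- utils::read.csv(ppe, stringsAsFactors = FALSE)
    grp <- unique(pe[c("season", "treatment", "mode", "replicate")])
    rows <- list()
    for (i in seq_len(nrow(grp))) {
      g <- grp[i, ]
      d <- pe[pe$season == g$season & pe$treatment == g$treatment &
                pe$mode == g$mode & pe$replicate == g$replicate, ]
      res <- tryCatch({
        off <- NULL
        if (isTRUE(cfg$pin_offset)) {
          dk <- d$rate[d$irradiance == 0]
          off <- if (g$mode == "photosynthesis") max(-mean(dk), 0)
                 else mean(dk)
        }
        f <- fit_platt(d$irradiance, d$rate, mode = g$mode, offset = off)
        dp <- derive_params(f)
        data.frame(season = g$season, treatment = g$treatment,
                   mode = g$mode, replicate = g$replicate,
                   scale = f$par[["scale"]], alpha = f$par[["alpha"]],
                   beta = f$par[["beta"]], offset = f$par[["offset"]],
                   gross_max = dp$gross_max, net_max = dp$net_max,
                   ek = dp$ek, ec = as.numeric(dp$ec), rss = f$rss,
                   converged = f$converged, stringsAsFactors = FALSE)
      }, error = function(e) {
        log_lines <<- c(log_lines,
                        sprintf("fit failed %s/%s/%s rep %s: %s", g$season,
                                g$treatment, g$mode, g$replicate,
                                conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1]] <- res
    }
    curve_params <- do.call(rbind, rows)
    if (!is.null(curve_params)) {
      grp2 <- unique(curve_params[c("season", "treatment", "mode")])
      curve_summary <- do.call(rbind, lapply(seq_len(nrow(grp2)),
        function(i) {
          g <- grp2[i, ]
          sub <- curve_params[curve_params$season == g$season &
                                curve_params$treatment == g$treatment &
                                curve_params$mode == g$mode, ]
          s <- summarize_treatment(
            sub[c("scale", "alpha", "beta", "offset", "gross_max",
                  "net_max", "ek", "ec")],
            treatment = g$treatment, season = g$season)
          s$mode <- g$mode
          s
        }))
    }
  }

  # per-season factorial statistics on the flux responses
  responses <- c("Pn_O2", "Rd_O2", "Pg_O2", "Pn_C", "Rd_C", "Pg_C",
                 "G", "Gd")
  nb <- if (is.null(cfg$bonferroni_n)) length(responses) else
    cfg$bonferroni_n
  alpha_adj <- bonferroni_alpha(cfg$base_alpha, nb)
  an_rows <- list(); letter_rows <- list()
  if (!is.null(flux)) {
    flux$pco2 <- ifelse(grepl("^700", flux$treatment), "700", "400")
    flux$temp_level <- ifelse(grepl("\\+3$", flux$treatment), "T+3", "T")
    for (season in unique(flux$season)) for (resp in responses) {
      d <- flux[flux$season == season & is.finite(flux[[resp]]),
                c(resp, "pco2", "temp_level", "treatment")]
      if (nrow(d) < 8) next
      dd <- data.frame(value = d[[resp]], pco2 = d$pco2,
                       temperature = d$temp_level)
      res <- tryCatch(analyze_response(dd, alpha = alpha_adj),
                      error = function(e) {
                        log_lines <<- c(log_lines,
                                        sprintf("stats skipped %s/%s: %s",
                                                season, resp,
                                                conditionMessage(e)))
                        NULL
                      })
      if (is.null(res)) next
      at <- as.data.frame(res$anova)
      at$season <- season; at$response <- resp
      at$transformed <- res$assumptions$transformed
      an_rows[[length(an_rows) + 1]] <- at
      lt <- res$posthoc$letters
      letter_rows[[length(letter_rows) + 1]] <-
        data.frame(season = season, response = resp, cell = names(lt),
                   letters = unname(lt), alpha = alpha_adj,
                   stringsAsFactors = FALSE)
    }
  }
  anova_tab <- if (length(an_rows)) do.call(rbind, an_rows) else NULL
  letters_tab <- if (length(letter_rows)) do.call(rbind, letter_rows) else
    NULL

  provenance <- list(
    package = "lithoflux",
    version = as.character(utils::packageVersion("lithoflux")),
    constants = cfg$k1k2, density = cfg$density,
    pin_offset = cfg$pin_offset, bonferroni_divisor = nb,
    adjusted_alpha = alpha_adj,
    n_incubations = length(incs), n_excluded = length(excluded))

  out <- list(speciation = spec, fluxes = flux,
              curve_params = curve_params, curve_summary = curve_summary,
              anova = anova_tab, letters = letters_tab,
              excluded = excluded, log = log_lines,
              provenance = provenance)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(d, f) if (!is.null(d))
      utils::write.csv(d, file.path(cfg$output_dir, f), row.names = FALSE)
    wr(spec, "speciation.csv")
    wr(flux, "fluxes.csv")
    wr(curve_params, "curve_params.csv")
    wr(curve_summary, "curve_summary.csv")
    wr(anova_tab, "anova.csv")
    wr(letters_tab, "posthoc_letters.csv")
    jsonlite::write_json(provenance,
                         file.path(cfg$output_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(cfg$output_dir, "log.txt"))
  }
  out
}
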