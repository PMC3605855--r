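#' Bonferroni-adjusted significance threshold
#'
#' Divides the family-wise alpha by the number of analyses in the family,
#' e.g. 0.05 / 4 = 0.0125 for four responses analysed per season.
#'
#' @param base_alpha family-wise error rate (default 0.05).
#' @param n_analyses number of analyses in the family, >= 1.
#' @return Adjusted per-test alpha.
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, n_analyses) {
  if (n_analyses < 1) stop("n_analyses must be >= 1")
  base_alpha / n_analyses
}

check_factorial <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("value", "pco2", "temperature") %in% names(data)))
  data$pco2 <- factor(data$pco2)
  data$temperature <- factor(data$temperature)
  if (nlevels(data$pco2) != 2 || nlevels(data$temperature) != 2)
    stop("need exactly 2 levels per factor")
  if (any(table(data$pco2, data$temperature) == 0))
    stop("empty treatment cell")
  data
}

#' ANOVA assumption checks with optional log transform
#'
#' Shapiro-Wilk normality test on the residuals of the full two-way model
#' and Levene's test (centred on cell means) for homogeneity of variance
#' across the four cells. If either fails at `alpha` and all values are
#' positive, a log-transformed copy of the data is returned and flagged;
#' the tests are then re-run on the transformed data.
#'
#' @param data a data frame with columns `value`, `pco2`, `temperature`.
#' @param alpha significance level of the assumption tests (default 0.05).
#' @param transform `"auto"` (log-transform on failure), `"none"`, or
#'   `"log"` (force).
#' @return A list: `data` (possibly transformed), `transformed` (logical),
#'   `shapiro_p`, `levene_p` (after any transform).
#' @export
check_assumptions <- function(data, alpha = 0.05,
                              transform = c("auto", "none", "log")) {
  transform <- match.arg(transform)
  data <- check_factorial(data)
  run_tests <- function(d) {
    fit <- stats::lm(value ~ pco2 * temperature, data = d)
    r <- stats::resid(fit)
    if (stats::sd(r) < 1e-12 * max(1, abs(mean(d$value))))
      stop("degenerate data: no residual variation")
    sw <- stats::shapiro.test(r)$p.value
    lv <- car::leveneTest(value ~ pco2:temperature, data = d,
                          center = mean)[1, "Pr(>F)"]
    c(shapiro = sw, levene = lv)
  }
  p <- run_tests(data)
  transformed <- FALSE
  if (transform == "log") {
    if (any(data$value <= 0))
      stop("log transform requested but data contain values <= 0")
    data$value <- log(data$value)
    transformed <- TRUE
    p <- run_tests(data)
  } else if (transform == "auto" && any(p < alpha) &&
               all(data$value > 0)) {
    data$value <- log(data$value)
    transformed <- TRUE
    p <- run_tests(data)
  }
  list(data = data, transformed = transformed,
       shapiro_p = unname(p["shapiro"]), levene_p = unname(p["levene"]))
}

#' Two-way factorial ANOVA (pCO2 x temperature)
#'
#' Fits the full crossed model with sum-to-zero contrasts and reports the
#' Type III F tests for the pCO2 main effect, the temperature main effect
#' and their interaction — the appropriate decomposition for the slightly
#' unbalanced cells (n = 4 vs 5) that arise when a replicate is lost. Type
#' II is available by option.
#'
#' @param data a data frame with columns `value`, `pco2`, `temperature`.
#' @param type sums-of-squares type, `"III"` (default) or `"II"`.
#' @return An object of class `anova_table`: a data frame with rows
#'   `pco2`, `temperature`, `pco2:temperature` and columns `effect`, `df1`,
#'   `df2`, `F`, `p`, plus attributes `degenerate` and `n`.
#' @export
two_way_anova <- function(data, type = c("III", "II")) {
  type <- match.arg(type)
  data <- check_factorial(data)
  fit <- stats::lm(value ~ pco2 * temperature, data = data,
                   contrasts = list(pco2 = "contr.sum",
                                    temperature = "contr.sum"))
  df2 <- stats::df.residual(fit)
  degenerate <- stats::sigma(fit) < 1e-10 * max(1, abs(mean(data$value)))
  if (degenerate) {
    tab <- data.frame(effect = c("pco2", "temperature", "pco2:temperature"),
                      df1 = 1L, df2 = df2, F = NA_real_, p = NA_real_)
  } else {
    a <- car::Anova(fit, type = if (type == "III") 3 else 2)
    rows <- c("pco2", "temperature", "pco2:temperature")
    tab <- data.frame(effect = rows,
                      df1 = as.integer(a[rows, "Df"]),
                      df2 = df2,
                      F = a[rows, "F value"],
                      p = a[rows, "Pr(>F)"])
  }
  rownames(tab) <- NULL
  attr(tab, "degenerate") <- degenerate
  attr(tab, "n") <- nrow(data)
  class(tab) <- c("anova_table", "data.frame")
  tab
}

#' Tukey-Kramer pairwise comparisons and compact letter display
#'
#' Studentized-range comparisons among the four treatment cells, using the
#' Tukey-Kramer standard error for unequal cell sizes (the harmonic mean of
#' each pair's n), as an implementation of the Spjotvoll/Stoline-style
#' unequal-n Tukey HSD. Treatments are labelled by letters such that any
#' two sharing a letter do not differ at `alpha`; `"nd"` is reported when
#' no pair differs.
#'
#' @param data a data frame with columns `value`, `pco2`, `temperature`.
#' @param alpha comparison-wise significance level, typically the
#'   Bonferroni-adjusted family threshold (e.g. 0.0125).
#' @return A list: `pairs` (data frame of pairwise q statistics and
#'   p-values), `letters` (named character vector per cell, or all `"nd"`),
#'   `alpha`, `mse`, `df`.
#' @export
tukey_posthoc <- function(data, alpha = 0.05) {
  data <- check_factorial(data)
  cell <- interaction(data$pco2, data$temperature, sep = ":", drop = TRUE)
  ns <- table(cell)
  if (any(ns < 2)) stop("every cell needs n >= 2 for the post hoc test")
  k <- nlevels(cell)
  means <- tapply(data$value, cell, mean)
  fit <- stats::lm(data$value ~ cell)
  mse <- stats::sigma(fit)^2
  df <- stats::df.residual(fit)

  cmb <- utils::combn(levels(cell), 2)
  pairs <- data.frame(a = cmb[1, ], b = cmb[2, ])
  pairs$diff <- means[pairs$a] - means[pairs$b]
  se <- sqrt(mse / 2 * (1 / ns[pairs$a] + 1 / ns[pairs$b]))
  pairs$q <- abs(pairs$diff) / se
  pairs$p <- stats::ptukey(pairs$q, nmeans = k, df = df,
                           lower.tail = FALSE)
  rownames(pairs) <- NULL

  sig <- pairs[pairs$p < alpha, , drop = FALSE]
  letters_out <- if (nrow(sig) == 0) {
    stats::setNames(rep("nd", k), levels(cell))
  } else {
    cld_insert_absorb(levels(cell), sig)
  }
  list(pairs = pairs, letters = letters_out, alpha = alpha, mse = mse,
       df = df)
}

# compact letter display, greedy insert-absorb (Piepho-style): start from
# one set of all treatments, split every set that contains a significantly
# different pair, then drop sets contained in others
cld_insert_absorb <- function(groups, sig_pairs) {
  sets <- list(groups)
  for (i in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$a[i]; b <- sig_pairs$b[i]
    nxt <- list()
    for (s in sets) {
      if (a %in% s && b %in% s)
        nxt <- c(nxt, list(setdiff(s, a)), list(setdiff(s, b)))
      else nxt <- c(nxt, list(s))
    }
    # absorb duplicates and subsets
    nxt <- nxt[lengths(nxt) > 0]
    keep <- rep(TRUE, length(nxt))
    for (j in seq_along(nxt)) for (l in seq_along(nxt)) {
      if (j != l && keep[l] && all(nxt[[j]] %in% nxt[[l]]) &&
            (length(nxt[[j]]) < length(nxt[[l]]) || j > l))
        keep[j] <- FALSE
    }
    sets <- nxt[keep]
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, groups)),
                            numeric(1)))]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}

#' Full factorial analysis of one response
#'
#' Convenience wrapper running the whole chain the way each response of a
#' seasonal experiment is analysed: assumption checks (with automatic log
#' transform), two-way ANOVA, and the Tukey-Kramer post hoc with compact
#' letters at the Bonferroni-adjusted alpha.
#'
#' @param data a data frame with columns `value`, `pco2`, `temperature`.
#' @param alpha Bonferroni-adjusted significance threshold used for the
#'   post hoc letters (see [bonferroni_alpha()]).
#' @param type sums-of-squares type for [two_way_anova()].
#' @return A list: `assumptions`, `anova`, `posthoc`, `alpha`.
#' @export
analyze_response <- function(data, alpha = 0.0125, type = "III") {
  chk <- check_assumptions(data)
  an <- two_way_anova(chk$data, type = type)
  ph <- tukey_posthoc(chk$data, alpha = alpha)
  list(assumptions = chk, anova = an, posthoc = ph, alpha = alpha)
}
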