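#' Platt irradiance-response model with photoinhibition and a dark offset
#'
#' The Platt et al. (1980) saturating-exponential model with an exponential
#' photoinhibition term, extended by an additive dark term:
#' photosynthesis Pn(E) = Ps (1 - exp(-alpha E / Ps)) exp(-beta E / Ps) - Rd;
#' calcification  G(E) = Gs (1 - exp(-alpha E / Gs)) exp(-beta E / Gs) + Gd.
#' Ps (or Gs) is the scale parameter — the maximum gross rate in the
#' absence of photoinhibition — alpha the initial slope, beta the
#' photoinhibition coefficient, and the offset the dark respiration Rd
#' (subtracted) or dark calcification Gd (added, may be negative).
#'
#' @param irradiance E (umol photons m-2 s-1), >= 0. Vectorised.
#' @param scale Ps or Gs (umol cm-2 h-1), > 0.
#' @param alpha initial slope (umol cm-2 h-1 per umol photons m-2 s-1), > 0.
#' @param beta photoinhibition coefficient (same units as `alpha`), >= 0.
#' @param offset Rd (photosynthesis) or Gd (calcification).
#' @param mode `"photosynthesis"` or `"calcification"`; decides the sign of
#'   the offset.
#' @return Modelled net rate at each irradiance (umol cm-2 h-1).
#' @examples
#' platt_rate(0, 1.5, 0.04, 0.002, offset = 0.3)   # dark: -Rd
#' @export
platt_rate <- function(irradiance, scale, alpha, beta = 0, offset = 0,
                       mode = c("photosynthesis", "calcification")) {
  mode <- match.arg(mode)
  if (any(irradiance < 0)) stop("irradiance must be >= 0")
  gross <- scale * (1 - exp(-alpha * irradiance / scale)) *
    exp(-beta * irradiance / scale)
  if (mode == "photosynthesis") gross - offset else gross + offset
}

# deterministic initial values: alpha from the OLS slope of the 3 lowest
# nonzero-E points, offset from the dark point, scale from the range
platt_start <- function(E, rate, mode) {
  dark <- rate[E == 0]
  offset0 <- if (mode == "photosynthesis") max(-mean(dark), 1e-3)
             else mean(dark)
  nz <- order(E[E > 0])[1:3]
  Enz <- E[E > 0][nz]
  rnz <- rate[E > 0][nz]
  a0 <- unname(stats::coef(stats::lm(rnz ~ Enz))[2])
  if (!is.finite(a0) || a0 <= 0) a0 <- 1e-3
  s0 <- if (mode == "photosynthesis") max(rate) + offset0
        else max(rate) - offset0
  if (s0 <= 0) s0 <- max(abs(rate), 1e-3)
  list(scale = s0, alpha = a0, offset = offset0)
}

#' Fit the Platt model to a light-response data set
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) with a
#' deterministic multi-start over the photoinhibition coefficient
#' (beta = 0 and beta = alpha0/100): no randomness, same data and options
#' always give the same fit. Constraints: scale > 0, alpha > 0, beta >= 0,
#' and offset >= 0 for photosynthesis (Gd free for calcification).
#'
#' @param irradiance,rate the measured response: at least 5 distinct
#'   irradiance levels including the dark point E = 0.
#' @param mode `"photosynthesis"` or `"calcification"`.
#' @param offset optional fixed dark offset: when supplied the offset is
#'   pinned to this measured value instead of fitted.
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `platt_fit`: list with `par` (named vector
#'   `scale`, `alpha`, `beta`, `offset`), `mode`, `rss`, `converged`,
#'   `offset_fixed`, `data`.
#' @export
fit_platt <- function(irradiance, rate,
                      mode = c("photosynthesis", "calcification"),
                      offset = NULL,
                      control = minpack.lm::nls.lm.control(maxiter = 200)) {
  mode <- match.arg(mode)
  E <- as.numeric(irradiance)
  y <- as.numeric(rate)
  if (length(E) != length(y)) stop("irradiance and rate lengths differ")
  keep <- is.finite(E) & is.finite(y)
  E <- E[keep]; y <- y[keep]
  if (length(unique(E)) < 5 || !any(E == 0))
    stop("need >= 5 distinct irradiance levels including the dark point E = 0")
  if (any(E < 0)) stop("irradiance must be >= 0")
  if (diff(range(y)) == 0)
    stop("degenerate data: all rates identical")

  st <- platt_start(E, y, mode)
  fixed_off <- !is.null(offset)
  sgn <- if (mode == "photosynthesis") -1 else 1

  resid_fn <- function(p) {
    off <- if (fixed_off) offset else p[["offset"]]
    y - platt_rate(E, p[["scale"]], p[["alpha"]], p[["beta"]], off, mode)
  }

  lower <- c(scale = 1e-9, alpha = 1e-12, beta = 0,
             offset = if (mode == "photosynthesis") 0 else -Inf)
  best <- NULL
  for (b0 in c(0, st$alpha / 100)) {
    p0 <- c(scale = st$scale, alpha = st$alpha, beta = b0,
            offset = st$offset)
    if (fixed_off) p0 <- p0[c("scale", "alpha", "beta")]
    lw <- lower[names(p0)]
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lw,
                         control = control),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    conv <- res$info %in% 1:4
    if (is.null(best) || (conv && !best$converged) ||
          (conv == best$converged && rss < best$rss))
      best <- list(par = res$par, rss = rss, converged = conv)
  }
  if (is.null(best))
    stop("Platt fit failed from all starting values")
  par <- best$par
  if (fixed_off) par <- c(par, offset = offset)
  par <- par[c("scale", "alpha", "beta", "offset")]
  out <- list(par = par, mode = mode, rss = best$rss,
              converged = best$converged, offset_fixed = fixed_off,
              data = data.frame(irradiance = E, rate = y))
  class(out) <- "platt_fit"
  out
}

#' @export
print.platt_fit <- function(x, ...) {
  cat(sprintf("Platt %s fit (%s, RSS = %.4g)\n", x$mode,
              if (x$converged) "converged" else "NOT converged", x$rss))
  print(round(x$par, 5))
  invisible(x)
}

#' @export
predict.platt_fit <- function(object, irradiance = object$data$irradiance,
                              ...) {
  p <- object$par
  platt_rate(irradiance, p[["scale"]], p[["alpha"]], p[["beta"]],
             p[["offset"]], object$mode)
}

# gross maximum of the inhibited Platt curve, with the beta -> 0 guard:
# [beta/(alpha+beta)]^(beta/alpha) evaluated in log space, limit 1
platt_gross_max <- function(scale, alpha, beta) {
  if (beta < 1e-12 * alpha) return(scale)
  scale * (alpha / (alpha + beta)) *
    exp((beta / alpha) * log(beta / (alpha + beta)))
}

#' Photophysiological parameters derived from a Platt fit
#'
#' Closed forms following Harrison & Platt: the light-saturated gross
#' maximum Pg_max = Ps \[alpha/(alpha+beta)\] \[beta/(alpha+beta)\]^(beta/alpha)
#' (equal to Ps when beta = 0); the net maximum Pn_max = Pg_max - Rd (for
#' calcification G_max = Gg_max + Gd); the saturating irradiance
#' E_k = Pg_max / alpha; and the compensation irradiance E_c, the smallest
#' positive root of the net curve, found by bracketed root search (for
#' beta = 0 it equals -(Ps/alpha) log(1 - Rd/Ps)). E_c is undefined when
#' the curve never reaches zero (Rd >= Pg_max) and for calcification fits
#' with Gd >= 0 (the net curve is positive everywhere).
#'
#' @param fit a [fit_platt()] result.
#' @return A list: `gross_max`, `net_max`, `ek`, `ec` (NA with an
#'   `ec_reason` attribute when undefined), `mode`.
#' @export
derive_params <- function(fit) {
  stopifnot(inherits(fit, "platt_fit"))
  p <- fit$par
  scale <- p[["scale"]]; alpha <- p[["alpha"]]
  beta <- p[["beta"]]; offset <- p[["offset"]]
  gmax <- platt_gross_max(scale, alpha, beta)
  ek <- gmax / alpha
  if (fit$mode == "photosynthesis") {
    net_max <- gmax - offset
    ec <- platt_ec(scale, alpha, beta, offset)
  } else {
    net_max <- gmax + offset
    ec <- if (offset >= 0) {
      structure(NA_real_, ec_reason = "dark calcification >= 0: net curve never crosses zero")
    } else platt_ec(scale, alpha, beta, -offset)
  }
  list(gross_max = gmax, net_max = net_max, ek = ek, ec = ec,
       mode = fit$mode)
}

# smallest E > 0 with gross(E) = demand; bracket is (0, argmax E], where
# the interior maximum of the inhibited curve sits at (scale/alpha) *
# log((alpha+beta)/beta)
platt_ec <- function(scale, alpha, beta, demand) {
  gmax <- platt_gross_max(scale, alpha, beta)
  if (demand >= gmax)
    return(structure(NA_real_,
                     ec_reason = "dark rate >= light-saturated gross maximum"))
  if (demand <= 0) return(0)
  upper <- if (beta >= 1e-12 * alpha) (scale / alpha) * log((alpha + beta) / beta)
           else {
             u <- gmax / alpha
             while (scale * (1 - exp(-alpha * u / scale)) < demand) u <- 2 * u
             u
           }
  f <- function(E)
    scale * (1 - exp(-alpha * E / scale)) * exp(-beta * E / scale) - demand
  stats::uniroot(f, lower = .Machine$double.eps, upper = upper,
                 tol = 1e-12)$root
}

#' Treatment-level summary of per-replicate curve parameters
#'
#' Curves are fitted per alga and the parameters aggregated afterwards:
#' arithmetic mean and standard error (sd / sqrt(n)) of each parameter over
#' the replicates of one treatment. Note the mean of per-replicate E_k
#' values is deliberately not mean(Pg_max)/mean(alpha).
#'
#' @param params a data frame with one row per replicate and numeric
#'   parameter columns (e.g. built from [fit_platt()] + [derive_params()]
#'   results).
#' @param treatment,season labels attached to the summary.
#' @return A data frame with columns `treatment`, `season`, `parameter`,
#'   `mean`, `se` (NA when n < 2), `n`.
#' @export
summarize_treatment <- function(params, treatment = NA, season = NA) {
  stopifnot(is.data.frame(params))
  num <- vapply(params, is.numeric, logical(1))
  if (!any(num)) stop("no numeric parameter columns to summarise")
  do.call(rbind, lapply(names(params)[num], function(nm) {
    x <- params[[nm]]
    x <- x[is.finite(x)]
    n <- length(x)
    data.frame(treatment = treatment, season = season, parameter = nm,
               mean = if (n) mean(x) else NA_real_,
               se = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
               n = n, stringsAsFactors = FALSE)
  }))
}
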