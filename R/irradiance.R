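#' PAR attenuation coefficient from a depth profile
#'
#' Downwelling PAR decays approximately exponentially with depth (Kirk), so
#' the diffuse attenuation coefficient K_PAR is minus the slope of the OLS
#' regression of log(PAR) on depth.
#'
#' @param depth depths (m), >= 0 and strictly increasing; >= 3 points.
#' @param par PAR at each depth (umol photons m-2 s-1), > 0.
#' @return A list: `kpar` (m-1), `r2`, `n`, and logical `negative_k` (set
#'   when PAR increases with depth — physically suspect, flagged with a
#'   warning rather than rejected).
#' @examples
#' z <- 0:10
#' fit_kpar(z, 400 * exp(-0.14 * z))$kpar
#' @export
fit_kpar <- function(depth, par) {
  if (length(depth) < 3) stop("need >= 3 profile points")
  if (length(depth) != length(par)) stop("depth and par lengths differ")
  if (any(depth < 0) || any(diff(depth) <= 0))
    stop("depths must be >= 0 and strictly increasing")
  if (any(par <= 0)) stop("PAR must be > 0 everywhere in the profile")
  y <- log(par)
  fit <- stats::lm(y ~ depth)
  k <- -unname(stats::coef(fit)[2])
  neg <- k <= 0
  if (neg) warning("PAR increases with depth: negative K_PAR flagged")
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  list(kpar = k, r2 = r2, n = length(depth), negative_k = neg)
}

#' Propagate surface irradiance to depth
#'
#' E(z) = E(0) exp(-K_PAR z).
#'
#' @param e_surface surface PAR (umol photons m-2 s-1), >= 0.
#' @param kpar attenuation coefficient (m-1), >= 0.
#' @param depth depth (m), >= 0.
#' @return PAR at depth.
#' @examples
#' propagate_par(600, 0.14, 25)
#' @export
propagate_par <- function(e_surface, kpar, depth) {
  if (any(e_surface < 0) || any(kpar < 0) || any(depth < 0))
    stop("all arguments must be >= 0")
  e_surface * exp(-kpar * depth)
}

#' Mean PAR over the photoperiod
#'
#' Trapezoidal time-average of a surface (or at-depth) PAR series,
#' restricted to the daylight samples (PAR > 0): the average light level an
#' experiment should apply during its photoperiod.
#'
#' @param time sampling times (h or any consistent unit), increasing.
#' @param par PAR at each time, >= 0.
#' @return Mean PAR over the daylight span; 0 (with a warning) for an
#'   all-dark series.
#' @export
daily_mean_par <- function(time, par) {
  if (length(time) == 0) stop("empty PAR series")
  if (length(time) != length(par)) stop("time and par lengths differ")
  day <- par > 0
  if (!any(day)) {
    warning("all-dark PAR series: daily mean is 0")
    return(0)
  }
  t <- time[day]; p <- par[day]
  if (length(t) == 1) return(p)
  span <- t[length(t)] - t[1]
  if (span <= 0) stop("daylight span is zero")
  sum(diff(t) * (utils::head(p, -1) + utils::tail(p, -1)) / 2) / span
}
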