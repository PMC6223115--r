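#' Drift-diffusion specification for spine-volume dynamics
#'
#' A `drift_diffusion_spec` collects the coefficients of the volume-dependent
#' fluctuation and drift laws of spine-head volume \eqn{V} (\eqn{\mu m^3}),
#' each linear in the spine surface-area proxy \eqn{V^{2/3}}:
#' \deqn{\sigma_{slow}(V) = a V^{2/3} + b,\quad
#'       \sigma_{fast}(V) = e V^{2/3} + f,\quad
#'       \mu(V) = c V^{2/3} + d,}
#' together with the volume range \eqn{[V_{min}, V_{max}]} on which the
#' diffusion lives. The time unit throughout is one imaging interval of 2
#' days: \eqn{\sigma} coefficients are in \eqn{\mu m^3} per square-root
#' interval, \eqn{\mu} in \eqn{\mu m^3} per interval.
#'
#' @param slow_slope,slow_intercept coefficients of the slow (day-scale)
#'   fluctuation SD \eqn{\sigma_{slow}(V)}.
#' @param drift_slope,drift_intercept coefficients of the drift \eqn{\mu(V)}.
#' @param fast_slope,fast_intercept coefficients of the fast (minute-scale)
#'   fluctuation SD \eqn{\sigma_{fast}(V)}, treated as observation noise on
#'   top of the slow dynamics.
#' @param v_min,v_max boundaries of the volume domain (\eqn{\mu m^3}).
#'   `v_min` doubles as the elimination threshold.
#' @param label optional character tag (e.g. `"WT"`).
#'
#' @return An object of class `drift_diffusion_spec`.
#' @seealso [wt_spec()], [ko_spec()], [sigma_slow()], [drift_mu()]
#' @export
drift_diffusion_spec <- function(slow_slope, slow_intercept,
                                 drift_slope = -0.12, drift_intercept = 0.029,
                                 fast_slope = 0.115, fast_intercept = 0.0051,
                                 v_min = 0.01, v_max = 1.0,
                                 label = NULL) {
  stopifnot(is.numeric(slow_slope), is.numeric(slow_intercept),
            is.numeric(drift_slope), is.numeric(drift_intercept),
            is.numeric(fast_slope), is.numeric(fast_intercept))
  if (!(is.numeric(v_min) && is.numeric(v_max) && v_min > 0 && v_min < v_max))
    stop("need 0 < v_min < v_max")
  spec <- structure(
    list(slow_slope = slow_slope, slow_intercept = slow_intercept,
         drift_slope = drift_slope, drift_intercept = drift_intercept,
         fast_slope = fast_slope, fast_intercept = fast_intercept,
         v_min = v_min, v_max = v_max, exponent = 2 / 3,
         label = label),
    class = "drift_diffusion_spec")
  # sigma laws are linear in V^(2/3), so positivity on the domain only needs
  # to be checked at the endpoints
  ends <- c(v_min, v_max)
  # zero sigma is admitted for degenerate (deterministic) dynamics; the
  # Fokker-Planck routines separately require strict positivity
  if (any(sigma_slow(spec, ends) < 0))
    stop("sigma_slow(V) must be non-negative on [v_min, v_max]")
  if (any(sigma_fast(spec, ends) < 0))
    stop("sigma_fast(V) must be non-negative on [v_min, v_max]")
  spec
}

#' @export
print.drift_diffusion_spec <- function(x, ...) {
  lab <- if (is.null(x$label)) "" else paste0(" [", x$label, "]")
  cat("Drift-diffusion spec", lab, " (time unit: one 2-day interval)\n", sep = "")
  cat(sprintf("  sigma_slow(V) = %.4g V^(2/3) + %.4g\n",
              x$slow_slope, x$slow_intercept))
  cat(sprintf("  sigma_fast(V) = %.4g V^(2/3) + %.4g\n",
              x$fast_slope, x$fast_intercept))
  cat(sprintf("  mu(V)         = %.4g V^(2/3) + %.4g\n",
              x$drift_slope, x$drift_intercept))
  cat(sprintf("  domain: [%.4g, %.4g] um^3\n", x$v_min, x$v_max))
  invisible(x)
}

#' Published parameterizations for wild-type and Fmr1 KO neocortex
#'
#' `wt_spec()` and `ko_spec()` return the fitted adult visual-cortex
#' parameterizations: both groups share the fast-fluctuation law
#' \eqn{\sigma_{fast} = 0.115 V^{2/3} + 0.0051} and the drift
#' \eqn{\mu = -0.12 V^{2/3} + 0.029}; they differ only in the slow slope
#' factor (0.198 for wild type, 0.278 for the Fmr1 knockout).
#'
#' @return A [drift_diffusion_spec()].
#' @export
wt_spec <- function() {
  drift_diffusion_spec(slow_slope = 0.198, slow_intercept = 0.0081,
                       label = "WT")
}

#' @rdname wt_spec
#' @export
ko_spec <- function() {
  drift_diffusion_spec(slow_slope = 0.278, slow_intercept = 0.0033,
                       label = "KO")
}

#' Coefficient functions of a drift-diffusion spec
#'
#' Evaluate the slow SD, fast SD, total SD (`sqrt(slow^2 + fast^2)`) or drift
#' of a spec at volumes `v`.
#'
#' @param spec a [drift_diffusion_spec()].
#' @param v volumes (\eqn{\mu m^3}); negative values are clamped to 0 before
#'   taking the 2/3 power.
#' @return Numeric vector of the same length as `v`.
#' @export
sigma_slow <- function(spec, v) {
  spec$slow_slope * pmax(v, 0)^spec$exponent + spec$slow_intercept
}

#' @rdname sigma_slow
#' @export
sigma_fast <- function(spec, v) {
  spec$fast_slope * pmax(v, 0)^spec$exponent + spec$fast_intercept
}

#' @rdname sigma_slow
#' @export
sigma_total <- function(spec, v) {
  sqrt(sigma_slow(spec, v)^2 + sigma_fast(spec, v)^2)
}

#' @rdname sigma_slow
#' @export
drift_mu <- function(spec, v) {
  spec$drift_slope * pmax(v, 0)^spec$exponent + spec$drift_intercept
}

#' Volume at which the drift changes sign
#'
#' For a drift \eqn{\mu(V) = c V^{2/3} + d} with \eqn{c < 0 < d}, the drift
#' vanishes at \eqn{V = (d / -c)^{3/2}}: smaller spines tend to grow, larger
#' spines tend to shrink.
#'
#' @param spec a [drift_diffusion_spec()].
#' @return The zero-crossing volume (\eqn{\mu m^3}).
#' @export
drift_zero_crossing <- function(spec) {
  cc <- spec$drift_slope
  d <- spec$drift_intercept
  if (cc >= 0 || d <= 0)
    stop("drift has no downward zero crossing (need drift_slope < 0 < drift_intercept)")
  (d / -cc)^(3 / 2)
}

#' Expand an anchored fluctuation line into slope-intercept form
#'
#' The slow-fluctuation fits are anchored through the point
#' (`anchor_x`, `anchor_sigma`) in the \eqn{(V^{2/3}, \sigma)} plane, i.e.
#' \eqn{\sigma(V) = slope (V^{2/3} - x_0) + \sigma_0}. This helper returns the
#' equivalent plain intercept \eqn{\sigma_0 - slope \cdot x_0}.
#'
#' @param slope anchored slope.
#' @param anchor_x anchor abscissa, on the \eqn{V^{2/3}} scale (default 0.06,
#'   the surface-area coordinate of the smallest-bin median volume 0.015).
#' @param anchor_sigma anchor ordinate (\eqn{\mu m^3} per sqrt-interval).
#' @return The intercept of the expanded line.
#' @export
anchored_intercept <- function(slope, anchor_x = 0.06, anchor_sigma = 0.02) {
  anchor_sigma - slope * anchor_x
}

#' Read or write a drift-diffusion spec as JSON
#'
#' @param spec a [drift_diffusion_spec()].
#' @param path file path.
#' @return `read_spec_json()` returns a [drift_diffusion_spec()];
#'   `write_spec_json()` returns `path` invisibly.
#' @export
write_spec_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  drift_diffusion_spec(
    slow_slope = x$slow_slope, slow_intercept = x$slow_intercept,
    drift_slope = x$drift_slope, drift_intercept = x$drift_intercept,
    fast_slope = x$fast_slope, fast_intercept = x$fast_intercept,
    v_min = x$v_min, v_max = x$v_max, label = x$label)
}
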