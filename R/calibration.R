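#' Point-spread-function convolved sphere model
#'
#' Describes the expected two-photon image of a GFP-filled spherical spine
#' head: a ball of radius `radius` and homogeneous brightness, blurred by a
#' Gaussian point-spread function with lateral SD `sigma_x` and axial SD
#' `sigma_z`. The defaults correspond to a 0.56 um lateral and 2.1 um axial
#' full-width at half-maximum. `amplitude` is the central intensity the
#' profile would reach for a sphere much larger than the PSF.
#'
#' @param radius sphere radius R (um).
#' @param amplitude central intensity A (arbitrary fluorescence units).
#' @param sigma_x lateral Gaussian SD (um).
#' @param sigma_z axial Gaussian SD (um).
#' @return An object of class `psf_sphere_model` with derived FWHM fields.
#' @export
psf_sphere_model <- function(radius, amplitude = 1,
                             sigma_x = 0.24, sigma_z = 0.91) {
  stopifnot(is.numeric(radius), is.numeric(amplitude),
            is.numeric(sigma_x), is.numeric(sigma_z))
  if (radius <= 0 || amplitude <= 0 || sigma_x <= 0 || sigma_z <= 0)
    stop("radius, amplitude, sigma_x and sigma_z must all be positive")
  k <- 2 * sqrt(2 * log(2))
  structure(list(radius = radius, amplitude = amplitude,
                 sigma_x = sigma_x, sigma_z = sigma_z,
                 fwhm_lateral = k * sigma_x, fwhm_axial = k * sigma_z),
            class = "psf_sphere_model")
}

#' @export
print.psf_sphere_model <- function(x, ...) {
  cat("PSF-convolved sphere model\n")
  cat(sprintf("  radius R   : %.4g um  (volume %.4g um^3)\n",
              x$radius, 4 / 3 * pi * x$radius^3))
  cat(sprintf("  amplitude A: %.4g\n", x$amplitude))
  cat(sprintf("  PSF lateral: sigma %.3g um (FWHM %.3g), axial: sigma %.3g um (FWHM %.3g)\n",
              x$sigma_x, x$fwhm_lateral, x$sigma_z, x$fwhm_axial))
  invisible(x)
}

#' Lateral fluorescence profile of a PSF-blurred sphere
#'
#' Computes the one-dimensional intensity profile F(r) measured across the
#' centre of the z-projected (summed) image of a homogeneous fluorescent ball
#' blurred by the Gaussian PSF,
#' \deqn{F(r) = \frac{A}{(2\pi)^{3/2}\sigma_x^2\sigma_z}
#'   \int\!\!\!\int\!\!\!\int_{x^2+y^2+z^2<R^2} dx\,dy\,dz \int dz'\,
#'   e^{-\left[\frac{(x-r)^2}{2\sigma_x^2}+\frac{y^2}{2\sigma_x^2}
#'       +\frac{(z-z')^2}{2\sigma_z^2}\right]}.}
#' The inner z' integral is a full Gaussian and contributes
#' \eqn{\sqrt{2\pi}\sigma_z} exactly, reducing the expression to a lateral
#' Gaussian blur of the z-projected ball thickness \eqn{2\sqrt{R^2-\rho^2}}.
#' Exploiting circular symmetry reduces that 2-D convolution further to a
#' single radial integral with a Bessel kernel, which is evaluated by
#' adaptive quadrature. The r -> -r symmetry and the agreement of this
#' reduction with direct multi-dimensional integration are exercised in the
#' test suite.
#'
#' @param r lateral offset(s) from the sphere centre (um); may be negative.
#' @param model a [psf_sphere_model()].
#' @param rel_tol relative quadrature tolerance.
#' @return Intensity values, same length as `r`.
#' @export
projected_sphere_profile <- function(r, model, rel_tol = 1e-6) {
  stopifnot(inherits(model, "psf_sphere_model"), all(is.finite(r)))
  A <- model$amplitude
  R <- model$radius
  sx <- model$sigma_x
  vapply(abs(r), function(ri) {
    # exp-scaled Bessel keeps the integrand finite for r >> sigma_x:
    # I0(rho*ri/sx^2) * exp(-(rho^2+ri^2)/(2 sx^2))
    #   = besselI(.., scaled) * exp(-(rho-ri)^2/(2 sx^2))
    integrand <- function(rho) {
      2 * sqrt(pmax(R^2 - rho^2, 0)) *
        besselI(rho * ri / sx^2, 0, expon.scaled = TRUE) *
        exp(-(rho - ri)^2 / (2 * sx^2)) * rho
    }
    val <- tryCatch(
      stats::integrate(integrand, 0, R, rel.tol = rel_tol,
                       subdivisions = 400L)$value,
      error = function(e) NA_real_)
    out <- A / sx^2 * val
    if (!is.finite(out))
      stop(sprintf("profile integration failed at r = %g (R = %g)", ri, R))
    out
  }, numeric(1))
}

#' Fit the PSF-sphere model to a measured intensity profile
#'
#' Least-squares fit of the amplitude A and radius R of
#' [projected_sphere_profile()] to samples of the one-dimensional profile
#' measured across a spine head, with the PSF widths held fixed. Unweighted
#' least squares is used.
#'
#' @param r lateral offsets (um) of the samples.
#' @param intensity measured intensities at `r`.
#' @param sigma_x,sigma_z fixed PSF Gaussian SDs (um).
#' @param start optional named list with starting values `A`, `R`.
#' @return A list with the fitted `model` ([psf_sphere_model()]), the
#'   residual norm `rss`, and the `fit` object.
#' @export
fit_sphere <- function(r, intensity, sigma_x = 0.24, sigma_z = 0.91,
                       start = NULL) {
  stopifnot(length(r) == length(intensity))
  if (length(r) < 5)
    stop("need at least 5 profile samples to fit A and R")
  if (stats::sd(intensity) < 1e-12 * max(abs(intensity), 1))
    stop("flat intensity profile: sphere fit is degenerate")
  peak <- r[which.max(intensity)]
  if (!(any(r < peak) && any(r > peak)))
    stop("profile samples must span both flanks of the peak")
  if (is.null(start)) {
    # half-width at half max as a crude radius seed
    above <- r[intensity >= max(intensity) / 2]
    hwhm <- (max(above) - min(above)) / 2
    start <- list(A = max(intensity), R = max(hwhm, sigma_x / 2))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      intensity ~ projected_sphere_profile(r, psf_sphere_model(R, A, sigma_x, sigma_z)),
      start = list(A = start$A, R = start$R),
      lower = c(A = 1e-12, R = 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("sphere fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  list(model = psf_sphere_model(radius = unname(cf["R"]),
                                amplitude = unname(cf["A"]),
                                sigma_x = sigma_x, sigma_z = sigma_z),
       rss = sum(stats::residuals(fit)^2),
       fit = fit)
}

#' Volume-per-fluorescence conversion coefficient
#'
#' The calibration spine's geometric volume V = 4/3 pi R^3 divided by its
#' total fluorescence gives the conversion coefficient V/F used for all
#' spines in the same field.
#'
#' @param radius fitted calibration-sphere radius (um).
#' @param total_f total fluorescence of the calibration spine.
#' @param spine_id,session optional provenance identifiers.
#' @return An object of class `conversion_coefficient` with fields
#'   `v_over_f` (um^3 per fluorescence unit) and `volume`.
#' @export
conversion_coefficient <- function(radius, total_f, spine_id = NA,
                                   session = NA) {
  stopifnot(radius > 0, total_f > 0)
  v <- 4 / 3 * pi * radius^3
  structure(list(v_over_f = v / total_f, volume = v, radius = radius,
                 source_spine_id = spine_id, session_of_origin = session),
            class = "conversion_coefficient")
}

#' Day-to-day fluorescence normalization factors
#'
#' Per-session multiplicative factors correcting for variation in GFP
#' expression, defined as the ratio of total dendritic-region fluorescence in
#' a session to that in the reference session (so the reference factor is 1).
#' Factors given on another scale are rescaled to the reference session.
#'
#' @param session integer session indices.
#' @param factor positive scale factors, one per session.
#' @param reference_session session whose factor defines the unit scale
#'   (default: the first session given).
#' @return An object of class `daily_normalization`.
#' @export
daily_normalization <- function(session, factor,
                                reference_session = session[1]) {
  stopifnot(length(session) == length(factor), !anyDuplicated(session))
  if (any(factor <= 0)) stop("normalization factors must be positive")
  if (!reference_session %in% session)
    stop("reference_session not among the supplied sessions")
  factor <- factor / factor[match(reference_session, session)]
  structure(list(session = as.integer(session), factor = factor,
                 reference_session = as.integer(reference_session)),
            class = "daily_normalization")
}

#' Convert total fluorescence to spine-head volume
#'
#' Applies the calibration coefficient and (optionally) the session
#' normalization: volume = total_f * v_over_f / session factor. The
#' conversion is linear in `total_f`. Negative background-subtracted
#' fluorescence is clipped to zero and flagged via the `"clipped"` attribute.
#'
#' @param total_f total (background-subtracted) fluorescence value(s).
#' @param coeff a [conversion_coefficient()].
#' @param norm optional [daily_normalization()].
#' @param session session index; required when `norm` is given.
#' @return Volumes (um^3), with attribute `clipped` marking inputs that were
#'   negative before clipping.
#' @export
volume_from_fluorescence <- function(total_f, coeff, norm = NULL,
                                     session = NULL) {
  stopifnot(inherits(coeff, "conversion_coefficient"))
  clipped <- total_f < 0
  if (any(clipped))
    warning(sum(clipped), " negative fluorescence value(s) clipped to 0")
  total_f <- pmax(total_f, 0)
  fct <- 1
  if (!is.null(norm)) {
    stopifnot(inherits(norm, "daily_normalization"))
    if (is.null(session)) stop("session required when a normalization is given")
    i <- match(session, norm$session)
    if (anyNA(i)) stop("session ", session[which(is.na(i))[1]],
                       " has no normalization factor")
    fct <- norm$factor[i]
  }
  structure(total_f * coeff$v_over_f / fct, clipped = clipped)
}

#' Read profile samples or normalization factors from CSV
#'
#' `read_profile_csv()` expects columns `r_um,intensity`;
#' `read_normalization_csv()` expects `dendrite_id,session,factor` and
#' returns a named list of [daily_normalization()] objects, one per dendrite.
#'
#' @param path CSV file path.
#' @param reference_session passed to [daily_normalization()].
#' @return See details.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("r_um", "intensity") %in% names(df)))
  df
}

#' @rdname read_profile_csv
#' @export
read_normalization_csv <- function(path, reference_session = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("dendrite_id", "session", "factor") %in% names(df)))
  lapply(split(df, df$dendrite_id), function(d) {
    ref <- if (is.null(reference_session)) d$session[1] else reference_session
    daily_normalization(d$session, d$factor, ref)
  })
}
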