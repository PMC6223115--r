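# Independent oracles and small constructors shared across the test files.

# Monte-Carlo evaluation of the full PSF-sphere intensity integral
# (triple integral over the ball plus the free z' Gaussian integral),
# independent of the radial-reduction route used by the package.
mc_sphere_profile <- function(r, R, sigma_x, sigma_z, A = 1,
                              n = 1e6, L = 6) {
  # uniform points in the ball via rejection from the bounding cube
  m <- ceiling(n * 6 / pi * 1.1)
  x <- stats::runif(m, -R, R)
  y <- stats::runif(m, -R, R)
  z <- stats::runif(m, -R, R)
  keep <- x^2 + y^2 + z^2 < R^2
  x <- x[keep][1:n]; y <- y[keep][1:n]; z <- z[keep][1:n]
  zp <- stats::runif(n, -R - L * sigma_z, R + L * sigma_z)
  g <- exp(-((x - r)^2 + y^2) / (2 * sigma_x^2) -
             (z - zp)^2 / (2 * sigma_z^2))
  vol_ball <- 4 / 3 * pi * R^3
  len_zp <- 2 * (R + L * sigma_z)
  scale <- A / ((2 * pi)^(3 / 2) * sigma_x^2 * sigma_z) * vol_ball * len_zp
  list(value = scale * mean(g),
       se = scale * stats::sd(g) / sqrt(n))
}

# brute-force enumeration of session pairs in a volume table
brute_force_transitions <- function(tbl, interval = 1L) {
  out <- list()
  key <- paste(tbl$animal_id, tbl$dendrite_id, tbl$spine_id)
  for (k in unique(key)) {
    d <- tbl[key == k, ]
    d <- d[order(d$session), ]
    for (a in seq_len(nrow(d))) for (b in seq_len(nrow(d))) {
      if (d$session[b] - d$session[a] == interval) {
        out[[length(out) + 1L]] <- data.frame(
          v_start = d$volume[a],
          dv = d$volume[b] - d$volume[a],
          event = if (d$eliminated[b]) "elimination" else "change")
      }
    }
  }
  if (!length(out)) return(data.frame(v_start = numeric(), dv = numeric(),
                                      event = character()))
  do.call(rbind, out)
}

# hand-built binned_moments table (bins lying exactly on given curves)
make_moments <- function(rep_volume, sigma, mu = 0, n = 32L) {
  structure(data.frame(rep_volume = rep_volume,
                       v_lo = rep_volume, v_hi = rep_volume,
                       n = n, mu = mu, sigma = sigma,
                       sigma_lo = sigma, sigma_hi = sigma,
                       mu_sem = 0),
            bin_size = n, class = c("binned_moments", "data.frame"))
}

# degenerate dynamics (zero or constant coefficients) for simulator tests
flat_spec <- function(sigma = 0, drift = 0, v_min = 0.01, v_max = 1) {
  drift_diffusion_spec(slow_slope = 0, slow_intercept = sigma,
                       drift_slope = 0, drift_intercept = drift,
                       fast_slope = 0, fast_intercept = 1e-6,
                       v_min = v_min, v_max = v_max)
}

# small WT-like single-group cohort used by several files
small_cohort <- function(n_spines = 120, n_sessions = 5, seed = 1,
                         spec = wt_spec(), ...) {
  generate_cohort(cohort_config(groups = stats::setNames(list(spec), spec$label %||% "WT"),
                                n_spines = n_spines, n_sessions = n_sessions,
                                seed = seed, ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
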