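#' Euler-Maruyama simulation of the spine-volume Langevin equation
#'
#' Simulates the Ito diffusion \eqn{dV = \mu(V)\,dt + \sigma(V)\,dW} with
#' time measured in 2-day intervals (the Brownian motion has unit variance
#' per interval). Coefficients are evaluated at the pre-step volume (Ito
#' convention), on values clamped to \eqn{[V_{min}, V_{max}]} to avoid
#' extrapolating the fluctuation law during a step. Reflecting boundaries are
#' realized by folding (\eqn{V < V_{min} \to 2V_{min} - V}, and analogously
#' at \eqn{V_{max}}, re-applied until inside); an absorbing lower boundary
#' records the first-passage time and freezes the path at `v_min`.
#'
#' @param spec a [drift_diffusion_spec()].
#' @param v0 initial volumes, one per path, inside `[v_min, v_max]`.
#' @param t_end simulated duration in intervals.
#' @param dt time step (fraction of one interval; must be <= 0.05 for
#'   accuracy of the boundary treatment).
#' @param lower lower boundary behaviour.
#' @param sigma which fluctuation law drives the noise: `"slow"` (default;
#'   fast fluctuations are observation noise, not part of the latent state)
#'   or `"total"`.
#' @param seed optional integer seed; the ensemble is bit-reproducible for a
#'   fixed seed.
#' @param keep_paths if `TRUE`, also return the full path matrix
#'   (`n_paths` x `n_steps + 1`).
#' @return A list with `volumes` (final volumes; absorbed paths sit at
#'   `v_min`), `absorbed` (logical), `first_passage` (time in intervals, `NA`
#'   if not absorbed), `t_end`, `dt`, and optionally `paths`.
#' @export
simulate_paths <- function(spec, v0, t_end = 1, dt = 0.005,
                           lower = c("reflecting", "absorbing"),
                           sigma = c("slow", "total"),
                           seed = NULL, keep_paths = FALSE) {
  stopifnot(inherits(spec, "drift_diffusion_spec"), t_end > 0)
  lower <- match.arg(lower)
  sigma <- match.arg(sigma)
  if (dt <= 0 || dt > 0.05)
    stop("dt must be in (0, 0.05] intervals")
  if (any(v0 < spec$v_min | v0 > spec$v_max))
    stop("initial volumes must lie in [v_min, v_max]")
  if (!is.null(seed)) set.seed(seed)
  sig_fun <- if (sigma == "slow") sigma_slow else sigma_total
  n <- length(v0)
  n_steps <- ceiling(t_end / dt - 1e-9)
  v <- as.numeric(v0)
  absorbed <- rep(FALSE, n)
  fpt <- rep(NA_real_, n)
  paths <- if (keep_paths) matrix(NA_real_, n, n_steps + 1L) else NULL
  if (keep_paths) paths[, 1L] <- v
  sqdt <- sqrt(dt)
  for (s in seq_len(n_steps)) {
    idx <- which(!absorbed)
    if (length(idx)) {
      v_old <- v[idx]
      vc <- pmin(pmax(v_old, spec$v_min), spec$v_max)
      sig_i <- sig_fun(spec, vc)
      vn <- v_old + drift_mu(spec, vc) * dt +
        sig_i * sqdt * stats::rnorm(length(idx))
      # fold reflections until inside (upper always reflecting)
      repeat {
        out_hi <- vn > spec$v_max
        if (lower == "reflecting") {
          out_lo <- vn < spec$v_min
          if (!any(out_hi | out_lo)) break
          vn[out_hi] <- 2 * spec$v_max - vn[out_hi]
          vn[out_lo] <- 2 * spec$v_min - vn[out_lo]
        } else {
          if (!any(out_hi)) break
          vn[out_hi] <- 2 * spec$v_max - vn[out_hi]
        }
      }
      if (lower == "absorbing") {
        hit <- vn <= spec$v_min
        # Brownian-bridge correction: a path ending above the boundary may
        # still have crossed it within the step; absorbing with the bridge
        # crossing probability removes the O(sqrt(dt)) discretization bias
        # of endpoint-only checking.
        if (any(!hit)) {
          p_cross <- exp(-2 * pmax(v_old[!hit] - spec$v_min, 0) *
                           (vn[!hit] - spec$v_min) / (sig_i[!hit]^2 * dt))
          hit[!hit] <- stats::runif(sum(!hit)) < p_cross
        }
        if (any(hit)) {
          absorbed[idx[hit]] <- TRUE
          fpt[idx[hit]] <- s * dt
          vn[hit] <- spec$v_min
        }
      }
      v[idx] <- vn
    }
    if (keep_paths) paths[, s + 1L] <- v
  }
  out <- list(volumes = v, absorbed = absorbed, first_passage = fpt,
              t_end = t_end, dt = dt, n_steps = n_steps)
  if (keep_paths) out$paths <- paths
  out
}

#' Monte-Carlo elimination fraction
#'
#' Draws initial volumes from the stationary density (reflecting boundaries),
#' simulates the Langevin dynamics with an absorbing boundary at `v_min`, and
#' returns the fraction of paths absorbed within the horizon, with its
#' binomial standard error. This is the stochastic oracle for the
#' Fokker-Planck first-passage solver.
#'
#' @param spec a [drift_diffusion_spec()].
#' @param t horizon in intervals.
#' @param n_paths number of simulated spines.
#' @param dt Euler-Maruyama step.
#' @param seed optional integer seed (used for both the initial draw and the
#'   dynamics).
#' @param init optional vector of initial volumes (overrides the stationary
#'   draw).
#' @param sigma diffusion law.
#' @return A list with `rate_pct`, `se_pct`, `n_paths`.
#' @export
empirical_elimination <- function(spec, t = 1, n_paths = 1e5, dt = 0.005,
                                  seed = NULL, init = NULL,
                                  sigma = c("slow", "total")) {
  sigma <- match.arg(sigma)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    d <- stationary_density(spec, n_grid = 4001L, sigma = sigma)
    init <- sample_stationary(d, n_paths)
  }
  sim <- simulate_paths(spec, init, t_end = t, dt = dt, lower = "absorbing",
                        sigma = sigma)
  p <- mean(sim$absorbed)
  list(rate_pct = 100 * p,
       se_pct = 100 * sqrt(p * (1 - p) / length(init)),
       n_paths = length(init))
}
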