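#' Configuration for a synthetic spine cohort
#'
#' Describes a simulated longitudinal imaging experiment: one or more groups
#' of spines, each evolving according to its drift-diffusion spec, observed
#' over repeated sessions. Defaults mirror the adult visual-cortex study
#' scale: 754 WT spines on 15 dendrites in 5 mice and 878 KO spines on 20
#' dendrites in 5 mice, imaged every 2 days over 5 sessions.
#'
#' @param groups named list of [drift_diffusion_spec()] objects.
#' @param n_spines,n_dendrites,n_animals per-group counts (recycled).
#' @param n_sessions number of imaging sessions.
#' @param mode `"slow"`: sessions 2 days apart with latent Langevin dynamics
#'   plus fast observation noise; `"fast"`: 10-min spacing (default 7 time
#'   points), latent volume frozen, only fast noise varies; `"fixed"`:
#'   fixed-tissue control, volumes constant across sessions.
#' @param sampling how the latent volume advances between 2-day sessions.
#'   `"interval"` (default): one Gaussian drift-diffusion increment per
#'   session, so the per-interval volume changes follow the fitted laws
#'   exactly (mean \eqn{\mu(V)}, SD \eqn{\sigma_{slow}(V)}) and elimination
#'   is scored at the session endpoint, the resolution at which the laws were
#'   estimated. `"diffusion"`: continuous Euler-Maruyama path with
#'   first-passage absorption at `v_min`; note the restoring drift then
#'   contracts the SD of per-interval increments a few percent below
#'   \eqn{\sigma_{slow}(V)}.
#' @param dt Euler-Maruyama step for the latent dynamics (intervals; used by
#'   `sampling = "diffusion"`).
#' @param seed integer seed; the cohort is reproducible for a fixed seed.
#' @param topup if `TRUE`, eliminated spines are replaced at the next session
#'   by new spines drawn from the stationary density (keeps cohort size
#'   stable); off by default, matching a model without a formation process.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups = list(WT = wt_spec(), KO = ko_spec()),
                          n_spines = c(754, 878),
                          n_dendrites = c(15, 20),
                          n_animals = c(5, 5),
                          n_sessions = 5,
                          mode = c("slow", "fast", "fixed"),
                          sampling = c("interval", "diffusion"),
                          dt = 0.01, seed = NULL, topup = FALSE) {
  mode <- match.arg(mode)
  sampling <- match.arg(sampling)
  ng <- length(groups)
  stopifnot(ng >= 1, !is.null(names(groups)),
            all(vapply(groups, inherits, TRUE, "drift_diffusion_spec")))
  n_spines <- rep_len(n_spines, ng)
  n_dendrites <- rep_len(n_dendrites, ng)
  n_animals <- rep_len(n_animals, ng)
  if (any(c(n_spines, n_dendrites, n_animals, n_sessions) < 1))
    stop("counts must be positive")
  if (mode == "fast" && missing(n_sessions)) n_sessions <- 7
  spacing <- if (mode == "fast") 10 / (48 * 60) else 1  # in 2-day intervals
  structure(list(groups = groups, n_spines = n_spines,
                 n_dendrites = n_dendrites, n_animals = n_animals,
                 n_sessions = as.integer(n_sessions), spacing = spacing,
                 mode = mode, sampling = sampling, dt = dt, seed = seed,
                 topup = topup),
            class = "cohort_config")
}

#' Generate a synthetic longitudinal spine cohort
#'
#' For each spine, an initial latent volume is drawn from its group's
#' stationary density. Between 2-day sessions the latent volume evolves by
#' Euler-Maruyama simulation of the slow Langevin dynamics with an absorbing
#' boundary at `v_min`; absorption marks the spine eliminated at the next
#' session and ends its series. Each observed volume adds independent fast
#' fluctuation noise to the latent volume and is truncated at zero.
#'
#' The per-observation noise SD is \eqn{\sigma_{fast}(V)/\sqrt{2}}: the fast
#' law is defined as the SD of volume *changes* between two closely spaced
#' observations, and the difference of two independent per-observation draws
#' then reproduces exactly that SD. Consequently 2-day observed changes have
#' variance \eqn{\sigma_{slow}^2 + \sigma_{fast}^2}, matching the
#' decomposition used in estimation.
#'
#' In `"fast"` mode the latent volume is frozen (drift and slow noise are
#' negligible over minutes) and only observation noise varies; in `"fixed"`
#' mode (fixed-tissue control) observations are constant.
#'
#' @param config a [cohort_config()].
#' @return A [volume_table()]. Dendrite and animal labels are assigned
#'   round-robin; the latent volumes are recorded in a `latent` column for
#'   validation purposes.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tabs <- lapply(seq_along(config$groups), function(gi) {
    generate_group(names(config$groups)[gi], config$groups[[gi]],
                   config$n_spines[gi], config$n_dendrites[gi],
                   config$n_animals[gi], config)
  })
  volume_table(do.call(rbind, tabs))
}

generate_group <- function(gname, spec, n_sp, n_den, n_an, config) {
  ns <- config$n_sessions
  dendrite <- rep_len(seq_len(n_den), n_sp)
  animal <- rep_len(seq_len(n_an), n_den)[dendrite]
  d <- stationary_density(spec, n_grid = 4001L)
  latent <- matrix(NA_real_, n_sp, ns)
  latent[, 1] <- sample_stationary(d, n_sp)
  alive <- rep(TRUE, n_sp)
  elim_at <- rep(NA_integer_, n_sp)
  if (config$mode == "slow" && ns > 1) {
    for (s in 2:ns) {
      idx <- which(alive)
      if (!length(idx)) break
      if (config$sampling == "interval") {
        v0 <- latent[idx, s - 1]
        vn <- v0 + drift_mu(spec, v0) +
          sigma_slow(spec, v0) * stats::rnorm(length(idx))
        while (any(vn > spec$v_max)) # fold upper reflection
          vn[vn > spec$v_max] <- 2 * spec$v_max - vn[vn > spec$v_max]
        died <- vn <= spec$v_min
        vols <- vn
      } else {
        sim <- simulate_paths(spec, latent[idx, s - 1], t_end = 1,
                              dt = config$dt, lower = "absorbing")
        died <- sim$absorbed
        vols <- sim$volumes
      }
      latent[idx[!died], s] <- vols[!died]
      if (any(died)) {
        elim_at[idx[died]] <- s
        alive[idx[died]] <- FALSE
      }
      if (config$topup && any(died)) {
        # replacements appear as new spines starting at session s
        nrep <- sum(died)
        latent <- rbind(latent, matrix(NA_real_, nrep, ns))
        latent[n_sp + seq_len(nrep), s] <- sample_stationary(d, nrep)
        alive <- c(alive, rep(TRUE, nrep))
        elim_at <- c(elim_at, rep(NA_integer_, nrep))
        dendrite <- c(dendrite, rep_len(seq_len(n_den), nrep))
        animal <- rep_len(seq_len(n_an), n_den)[dendrite]
        n_sp <- n_sp + nrep
      }
    }
  } else if (config$mode %in% c("fast", "fixed") && ns > 1) {
    for (s in 2:ns) latent[, s] <- latent[, 1]
  }
  obs <- latent
  if (config$mode != "fixed") {
    noise <- matrix(stats::rnorm(n_sp * ns), n_sp, ns) *
      sigma_fast(spec, latent) / sqrt(2)
    obs <- pmax(latent + noise, 0)
  }
  rows <- vector("list", n_sp)
  for (i in seq_len(n_sp)) {
    observed <- which(!is.na(latent[i, ]))
    r <- data.frame(animal_id = paste0(gname, "_m", animal[i]),
                    dendrite_id = paste0(gname, "_d", dendrite[i]),
                    spine_id = paste0(gname, "_s", i),
                    group = gname, session = observed,
                    time = (observed - 1) * config$spacing,
                    volume = obs[i, observed],
                    latent = latent[i, observed],
                    eliminated = FALSE, stringsAsFactors = FALSE)
    if (!is.na(elim_at[i])) {
      r <- rbind(r, data.frame(
        animal_id = r$animal_id[1], dendrite_id = r$dendrite_id[1],
        spine_id = r$spine_id[1], group = gname, session = elim_at[i],
        time = (elim_at[i] - 1) * config$spacing,
        volume = NA_real_, latent = NA_real_, eliminated = TRUE))
    }
    rows[[i]] <- r
  }
  do.call(rbind, rows)
}

#' Observed elimination fraction of a cohort
#'
#' Fraction (percent) of at-risk spine-intervals ending in elimination,
#' either pooled or per dendrite (the unit used for group comparisons).
#'
#' @param tbl a [volume_table()].
#' @param per_dendrite if `TRUE`, return one fraction per (group, dendrite).
#' @return A data frame with columns `group`, (`dendrite_id`,)
#'   `eliminations`, `at_risk`, `rate_pct`.
#' @export
cohort_elimination <- function(tbl, per_dendrite = FALSE) {
  tr <- pair_transitions(tbl, interval = 1L)
  key <- if (per_dendrite) list(group = tr$group, dendrite_id = tr$dendrite_id)
         else list(group = tr$group)
  agg <- stats::aggregate(list(eliminations = tr$event == "elimination",
                               at_risk = rep(1L, nrow(tr))),
                          by = key, FUN = sum)
  agg$rate_pct <- 100 * agg$eliminations / agg$at_risk
  agg
}

#' Render a synthetic fluorescence z-stack of spheres
#'
#' Renders Gaussian-blurred homogeneous spheres onto a voxel grid emulating
#' a two-photon stack (default 0.124 um pixels laterally, 0.4 um z steps).
#' The axial blur of each sphere's indicator is applied analytically per
#' voxel column; the lateral blur uses separable discrete Gaussian kernels.
#' Optional Gaussian read noise is added. The z-summed image of an isolated
#' sphere, profiled through its centre and scaled by `z_step`, is consistent
#' with [projected_sphere_profile()] and hence with [fit_sphere()].
#'
#' @param spheres data frame with columns `x`, `y`, `z` (centre, um), `r`
#'   (radius, um) and `amplitude`.
#' @param sigma_x,sigma_z PSF Gaussian SDs (um).
#' @param field_px lateral field size in pixels (nx, ny).
#' @param n_slices number of z slices.
#' @param pixel lateral pixel size (um).
#' @param z_step z slice spacing (um).
#' @param noise_sd SD of additive Gaussian read noise.
#' @param seed optional seed for the noise.
#' @return A 3-D array (nx, ny, n_slices) with attributes `pixel`, `z_step`
#'   and `overlap` (TRUE if any two spheres intersect; overlaps are allowed
#'   but flagged with a warning).
#' @export
generate_zstack <- function(spheres, sigma_x = 0.24, sigma_z = 0.91,
                            field_px = c(64, 64), n_slices = 21,
                            pixel = 0.124, z_step = 0.4,
                            noise_sd = 0, seed = NULL) {
  stopifnot(all(c("x", "y", "z", "r", "amplitude") %in% names(spheres)),
            nrow(spheres) >= 0)
  nx <- field_px[1]; ny <- field_px[2]
  xs <- (seq_len(nx) - 0.5) * pixel
  ys <- (seq_len(ny) - 0.5) * pixel
  zs <- (seq_len(n_slices) - 1) * z_step
  if (nrow(spheres)) {
    inside <- spheres$x - spheres$r >= 0 & spheres$x + spheres$r <= nx * pixel &
      spheres$y - spheres$r >= 0 & spheres$y + spheres$r <= ny * pixel &
      spheres$z - spheres$r >= min(zs) & spheres$z + spheres$r <= max(zs)
    if (!all(inside)) stop("all spheres must lie inside the imaged field")
  }
  overlap <- FALSE
  if (nrow(spheres) > 1) {
    for (i in seq_len(nrow(spheres) - 1)) for (j in (i + 1):nrow(spheres)) {
      dist <- sqrt(sum((spheres[i, c("x", "y", "z")] -
                        spheres[j, c("x", "y", "z")])^2))
      if (dist < spheres$r[i] + spheres$r[j]) overlap <- TRUE
    }
    if (overlap) warning("overlapping spheres in the synthetic field")
  }
  stack <- array(0, dim = c(nx, ny, n_slices))
  kx <- gauss_kernel(sigma_x / pixel)
  for (si in seq_len(nrow(spheres))) {
    x0 <- spheres$x[si]; y0 <- spheres$y[si]; z0 <- spheres$z[si]
    r0 <- spheres$r[si]; a0 <- spheres$amplitude[si]
    d2 <- outer((xs - x0)^2, (ys - y0)^2, `+`)
    ccol <- sqrt(pmax(r0^2 - d2, 0))
    vol <- array(0, dim = c(nx, ny, n_slices))
    for (k in seq_len(n_slices)) {
      dz <- zs[k] - z0
      vol[, , k] <- stats::pnorm((dz + ccol) / sigma_z) -
        stats::pnorm((dz - ccol) / sigma_z)
      vol[, , k][ccol == 0] <- 0
    }
    for (k in seq_len(n_slices)) {
      sl <- conv_sep(vol[, , k], kx)
      stack[, , k] <- stack[, , k] + a0 * sl
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    stack <- stack + array(stats::rnorm(length(stack), 0, noise_sd), dim(stack))
  }
  structure(stack, pixel = pixel, z_step = z_step, overlap = overlap)
}

gauss_kernel <- function(sd_px) {
  half <- max(1L, ceiling(4 * sd_px))
  k <- stats::dnorm(seq(-half, half), 0, sd_px)
  k / sum(k)
}

# separable 2-D convolution with zero padding at the edges
conv_sep <- function(m, k) {
  half <- (length(k) - 1L) / 2L
  cv <- function(x) {
    out <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
    as.numeric(out[(half + 1L):(half + length(x))])
  }
  m <- apply(m, 2, cv)
  t(apply(m, 1, cv))
}

#' Profile a z-stack through the brightest spine
#'
#' Sums the stack over z (scaled by the slice spacing, so intensities match
#' [projected_sphere_profile()]), locates the brightest pixel, and extracts
#' the one-dimensional intensity profile along x through it.
#'
#' @param stack output of [generate_zstack()].
#' @return A data frame with columns `r_um` (offset from the peak) and
#'   `intensity`, suitable for [fit_sphere()].
#' @export
profile_from_zstack <- function(stack) {
  z_step <- attr(stack, "z_step")
  pixel <- attr(stack, "pixel")
  img <- apply(stack, c(1, 2), sum) * z_step
  # a genuine object must stand far above the background spread
  if (max(img) <= 0 || stats::sd(img) < 1e-12 ||
      max(img) - stats::median(img) < 5 * stats::sd(img))
    stop("no fluorescent object found in the stack")
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  prof <- img[, pk[2]]
  data.frame(r_um = (seq_along(prof) - pk[1]) * pixel, intensity = prof)
}

#' Total fluorescence of a stack
#'
#' Sum of all voxel intensities times the voxel footprint, the quantity the
#' V/F conversion coefficient divides.
#'
#' @param stack output of [generate_zstack()].
#' @return Total fluorescence (intensity x um^3).
#' @export
total_fluorescence <- function(stack) {
  sum(stack) * attr(stack, "pixel")^2 * attr(stack, "z_step")
}
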