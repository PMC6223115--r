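#' Full estimation chain on a longitudinal cohort
#'
#' Runs the estimation pipeline on a volume table: pairs 2-day transitions,
#' bins them (32 per bin), decomposes the fast component out of the total
#' fluctuation SD, fits the anchored slow slope per group and a common drift
#' pooled across groups, and assembles a fitted [drift_diffusion_spec()] per
#' group.
#'
#' @param tbl a [volume_table()] at 2-day spacing.
#' @param fast the fast-fluctuation law used in the decomposition: a list
#'   with `slope`/`intercept`, a [drift_diffusion_spec()], or a 10-min-mode
#'   [volume_table()] from which it is fitted (30 per bin).
#' @param bin_size transitions per bin for the 2-day moments.
#' @param anchor_v,anchor_sigma anchor for the slow-slope fit.
#' @param v_min,v_max domain for the assembled specs.
#' @param exclude_sessions optional session indices to drop before pairing
#'   (e.g. a first post-surgery session).
#' @return A list with per-group `moments` (decomposed), `slow_fits`,
#'   `drift_fit` (pooled), `fast` coefficients used, and fitted `specs`.
#' @export
estimate_cohort <- function(tbl, fast, bin_size = 32L,
                            anchor_v = 0.015, anchor_sigma = 0.02,
                            v_min = 0.01, v_max = 1.0,
                            exclude_sessions = NULL) {
  stopifnot(inherits(tbl, "volume_table"))
  if (!is.null(exclude_sessions))
    tbl <- volume_table(tbl[!tbl$session %in% exclude_sessions, ])
  if (inherits(fast, "volume_table")) {
    ftr <- pair_transitions(fast, interval = 1L)
    fast <- fit_fast(bin_moments(ftr, bin_size = 30L))
  } else if (inherits(fast, "drift_diffusion_spec")) {
    fast <- list(slope = fast$fast_slope, intercept = fast$fast_intercept)
  }
  tr <- pair_transitions(tbl, interval = 1L)
  if (!nrow(tr)) stop("estimation stage: no transitions (need >= 2 sessions)")
  groups <- unique(tr$group)
  moments <- list()
  slow_fits <- list()
  for (g in groups) {
    m <- bin_moments(tr[tr$group == g, ], bin_size = bin_size)
    m <- decompose_slow(m, fast)
    moments[[g]] <- m
    slow_fits[[g]] <- fit_anchored_slope(m, anchor_v, anchor_sigma)
  }
  drift_fit <- fit_drift(bin_moments(tr, bin_size = bin_size))
  specs <- lapply(groups, function(g) {
    sl <- slow_fits[[g]]$slope
    drift_diffusion_spec(
      slow_slope = sl,
      slow_intercept = anchored_intercept(sl, anchor_v^(2 / 3), anchor_sigma),
      drift_slope = drift_fit$slope, drift_intercept = drift_fit$intercept,
      fast_slope = fast$slope, fast_intercept = fast$intercept,
      v_min = v_min, v_max = v_max, label = g)
  })
  names(specs) <- groups
  list(moments = moments, slow_fits = slow_fits, drift_fit = drift_fit,
       fast = fast, specs = specs, transitions = tr)
}

#' Model-replication preset
#'
#' Computes the headline model quantities from the published
#' parameterizations alone (no data): stationary densities and mean volumes
#' for WT and Fmr1 KO, model elimination rates per 2-day interval, the drift
#' zero crossing, the expanded anchored intercepts, and the
#' neocortex-to-hippocampus linear-slope attenuation ratio. Optionally writes
#' the table, densities and summary figures to `out_dir`.
#'
#' @param out_dir optional output directory (created if needed).
#' @param n_grid grid resolution for the density and elimination quadrature.
#' @return A list with `table` (data frame of quantities), `densities`
#'   (list of WT/KO [stationary_density()]), and `specs`.
#' @export
run_replication_preset <- function(out_dir = NULL, n_grid = 4001L) {
  specs <- list(WT = wt_spec(), KO = ko_spec())
  dens <- lapply(specs, stationary_density, n_grid = n_grid)
  elim <- vapply(specs, elimination_rate, numeric(1), t = 1,
                 method = "interval", n_grid = n_grid)
  mn <- vapply(dens, stationary_mean, numeric(1))
  tab <- data.frame(
    quantity = c("WT elimination (model, % per 2 d)",
                 "KO elimination (model, % per 2 d)",
                 "WT mean volume (model, um^3)",
                 "KO mean volume (model, um^3)",
                 "drift zero crossing (um^3)",
                 "WT slow intercept (expanded)",
                 "KO slow intercept (expanded)",
                 "linear-slope attenuation ratio (neocortex/hippocampus)"),
    value = c(elim[["WT"]], elim[["KO"]], mn[["WT"]], mn[["KO"]],
              drift_zero_crossing(specs$WT),
              anchored_intercept(specs$WT$slow_slope),
              anchored_intercept(specs$KO$slow_slope),
              0.21 / 0.28))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "replication_table.csv"),
                     row.names = FALSE)
    dd <- rbind(data.frame(group = "WT", v = dens$WT$v,
                           density = dens$WT$density),
                data.frame(group = "KO", v = dens$KO$v,
                           density = dens$KO$density))
    utils::write.csv(dd, file.path(out_dir, "stationary_densities.csv"),
                     row.names = FALSE)
    write_preset_figures(out_dir, specs, dd, tab)
  }
  list(table = tab, densities = dens, specs = specs)
}

write_preset_figures <- function(out_dir, specs, dd, tab) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(invisible(NULL))
  gg <- ggplot2::ggplot(dd, ggplot2::aes(x = v, y = density,
                                         colour = group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "spine-head volume (um^3)", y = "density (1/um^3)",
                  title = "Stationary spine-volume distributions") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "stationary_densities.pdf"), gg,
                  width = 6, height = 4)
  v23 <- seq(0, 1, length.out = 200)
  ln <- rbind(
    data.frame(group = "WT", component = "slow", x = v23,
               sigma = specs$WT$slow_slope * v23 + specs$WT$slow_intercept),
    data.frame(group = "KO", component = "slow", x = v23,
               sigma = specs$KO$slow_slope * v23 + specs$KO$slow_intercept),
    data.frame(group = "both", component = "fast", x = v23,
               sigma = specs$WT$fast_slope * v23 + specs$WT$fast_intercept),
    data.frame(group = "both", component = "drift", x = v23,
               sigma = specs$WT$drift_slope * v23 + specs$WT$drift_intercept))
  gg2 <- ggplot2::ggplot(ln, ggplot2::aes(x = x, y = sigma, colour = group,
                                          linetype = component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "V^(2/3)", y = "um^3 per 2 d",
                  title = "Fluctuation and drift laws") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "model_laws.pdf"), gg2,
                  width = 6, height = 4)
  el <- tab[grepl("elimination", tab$quantity), ]
  el$group <- c("WT", "KO")
  gg3 <- ggplot2::ggplot(el, ggplot2::aes(x = group, y = value)) +
    ggplot2::geom_col(fill = NA, colour = "black", linewidth = 0.6) +
    ggplot2::labs(y = "model elimination (% per 2 d)", x = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "elimination_model.pdf"), gg3,
                  width = 4, height = 4)
  invisible(NULL)
}

#' End-to-end simulate / estimate / predict pipeline
#'
#' Generates a synthetic cohort, runs the estimation chain, derives model
#' predictions from the fitted specs, and performs the group comparisons
#' (anchored-slope interaction, Mann-Whitney U on per-dendrite elimination
#' fractions, Kolmogorov-Smirnov on observed volumes). All stochastic stages
#' are driven by the config seed; re-running the same config reproduces the
#' manifest bit-identically. Each stage failure is re-signalled with a
#' stage tag.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory to persist the cohort CSV, moments CSV,
#'   fitted-spec JSONs and the manifest JSON.
#' @param fast fast law used for the decomposition; default takes each
#'   group's generating fast coefficients (they are shared across groups in
#'   the presets). Alternatively a 10-min [volume_table()].
#' @return A `run_manifest` list: `config`, `cohort`, `estimation`,
#'   `predictions`, `comparisons`, `files`.
#' @export
run_full_pipeline <- function(config, out_dir = NULL, fast = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cohort <- stage("simulate", generate_cohort(config))
  if (is.null(fast)) {
    sp1 <- config$groups[[1]]
    fast <- list(slope = sp1$fast_slope, intercept = sp1$fast_intercept)
  }
  est <- stage("estimate", estimate_cohort(cohort, fast = fast))
  predictions <- stage("predict", {
    lapply(est$specs, function(sp) {
      d <- stationary_density(sp, n_grid = 4001L)
      list(elimination_pct_per_interval =
             elimination_rate(sp, t = 1, method = "interval"),
           mean_volume = stationary_mean(d),
           drift_zero_crossing = tryCatch(drift_zero_crossing(sp),
                                          error = function(e) NA_real_))
    })
  })
  comparisons <- NULL
  if (length(est$specs) >= 2) {
    comparisons <- stage("compare", {
      g <- intersect(names(config$groups), names(est$specs))[1:2]
      slopes <- compare_slopes(est$moments[[g[1]]], est$moments[[g[2]]])
      per_den <- cohort_elimination(cohort, per_dendrite = TRUE)
      mw <- stats::wilcox.test(rate_pct ~ group, data = per_den,
                               exact = FALSE)
      ks <- distribution_comparison(
        cohort$volume[cohort$group == g[1] & !cohort$eliminated],
        cohort$volume[cohort$group == g[2] & !cohort$eliminated])
      list(slope_interaction = slopes[c("t", "p", "slope_a", "slope_b")],
           elimination_mannwhitney = list(statistic = unname(mw$statistic),
                                          p = mw$p.value),
           volume_ks = ks)
    })
  }
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, "cohort.csv")
    write_volume_table(cohort, f1)
    f2 <- vapply(names(est$moments), function(g) {
      fp <- file.path(out_dir, paste0("moments_", g, ".csv"))
      utils::write.csv(as.data.frame(est$moments[[g]]), fp, row.names = FALSE)
      fp
    }, character(1))
    f3 <- vapply(names(est$specs), function(g) {
      fp <- file.path(out_dir, paste0("spec_", g, ".json"))
      write_spec_json(est$specs[[g]], fp)
      fp
    }, character(1))
    manifest <- list(
      seed = config$seed, mode = config$mode,
      n_spines = config$n_spines, n_sessions = config$n_sessions,
      predictions = predictions,
      comparisons = if (is.null(comparisons)) NULL else list(
        slope_t = comparisons$slope_interaction$t,
        slope_p = comparisons$slope_interaction$p,
        mw_p = comparisons$elimination_mannwhitney$p,
        ks_p = comparisons$volume_ks$p.value))
    f4 <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, f4, auto_unbox = TRUE, digits = NA,
                         null = "null")
    files <- c(f1, f2, f3, f4)
  }
  structure(list(config = config, cohort = cohort, estimation = est,
                 predictions = predictions, comparisons = comparisons,
                 files = files),
            class = "run_manifest")
}
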