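#' Longitudinal spine-volume observation table
#'
#' Validates a data frame of longitudinal spine-volume observations with
#' columns `animal_id`, `dendrite_id`, `spine_id`, `group`, `session`
#' (integer index), `time` (in units of one 2-day interval; optional, derived
#' from `session` if absent), `volume` (um^3) and `eliminated` (logical).
#' An `eliminated = TRUE` row marks the session at which a spine was no
#' longer found; its `volume` is `NA` and it terminates that spine's series.
#'
#' @param df a data frame with the columns above.
#' @return The validated table, classed `volume_table`.
#' @export
volume_table <- function(df) {
  req <- c("animal_id", "dendrite_id", "spine_id", "group", "session",
           "volume", "eliminated")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$eliminated <- as.logical(df$eliminated)
  df$session <- as.integer(df$session)
  if (!"time" %in% names(df)) df$time <- as.numeric(df$session - 1L)
  uid <- spine_uid(df)
  ord <- order(uid, df$session)
  df <- df[ord, , drop = FALSE]
  uid <- uid[ord]
  dup <- duplicated(cbind(uid, df$session))
  if (any(dup)) stop("duplicated (spine, session) rows")
  live <- !df$eliminated
  if (any(live & (is.na(df$volume) | df$volume < 0)))
    stop("retained observations must have volume >= 0")
  # eliminated row must be the last row of its spine's series
  elim_uid <- uid[df$eliminated]
  if (length(elim_uid)) {
    last_uid <- uid[!duplicated(uid, fromLast = TRUE)]
    after <- tapply(df$eliminated, uid, function(e) {
      w <- which(e)
      length(w) > 1L || (length(w) == 1L && w < length(e))
    })
    if (any(unlist(after)))
      stop("an eliminated = TRUE row must terminate its spine's series")
  }
  rownames(df) <- NULL
  class(df) <- c("volume_table", "data.frame")
  df
}

spine_uid <- function(df) {
  paste(df$animal_id, df$dendrite_id, df$spine_id, sep = "\r")
}

#' Read / write a volume table as CSV
#'
#' CSV schema: `animal_id,dendrite_id,spine_id,group,session,time,volume,eliminated`.
#'
#' @param path CSV file path.
#' @param tbl a [volume_table()].
#' @return `read_volume_table()` returns a [volume_table()].
#' @export
read_volume_table <- function(path) {
  volume_table(utils::read.csv(path))
}

#' @rdname read_volume_table
#' @export
write_volume_table <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE)
  invisible(path)
}

#' Pair consecutive observations into volume transitions
#'
#' Emits one record per spine per pair of observed sessions separated by
#' `interval`. Pairs whose end observation is an elimination are labelled
#' `event = "elimination"` (no end volume); all other pairs are
#' `event = "change"` with the volume change `dv = v_end - v_start`.
#' Only `"change"` transitions enter moment estimation; eliminations are
#' counted separately for turnover measurement.
#'
#' @param tbl a [volume_table()].
#' @param interval session separation (integer >= 1).
#' @return A data frame with columns `animal_id`, `dendrite_id`, `spine_id`,
#'   `group`, `session_start`, `v_start`, `v_end`, `dv`, `event`.
#' @export
pair_transitions <- function(tbl, interval = 1L) {
  stopifnot(inherits(tbl, "volume_table"))
  interval <- as.integer(interval)
  if (interval < 1L) stop("interval must be >= 1")
  if (nrow(tbl) == 0L)
    return(data.frame(animal_id = character(), dendrite_id = character(),
                      spine_id = character(), group = character(),
                      session_start = integer(), v_start = numeric(),
                      v_end = numeric(), dv = numeric(), event = character()))
  uid <- spine_uid(tbl)
  key <- paste(uid, tbl$session)
  j <- match(paste(uid, tbl$session + interval), key)
  i <- which(!is.na(j))
  j <- j[i]
  out <- data.frame(
    animal_id = tbl$animal_id[i], dendrite_id = tbl$dendrite_id[i],
    spine_id = tbl$spine_id[i], group = tbl$group[i],
    session_start = tbl$session[i],
    v_start = tbl$volume[i], v_end = tbl$volume[j],
    dv = tbl$volume[j] - tbl$volume[i],
    event = ifelse(tbl$eliminated[j], "elimination", "change"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Binned moments of volume changes
#'
#' Sorts `"change"` transitions by starting volume and pools consecutive
#' groups of `bin_size` into bins (pooling spines of similar volume). A final
#' remainder of fewer than `bin_size / 2` transitions is merged into the last
#' full bin, otherwise it forms its own bin. Per bin the estimators are the
#' mean volume change \eqn{\mu_j = \sum \Delta V / N_j} and the SD about it,
#' \eqn{\sigma_j^2 = \sum (\Delta V - \mu_j)^2 / N_j} (population divisor
#' \eqn{N_j}). The representative bin volume is the median of the member
#' starting volumes. 95% confidence limits for \eqn{\sigma_j} use the
#' chi-square pivot \eqn{N_j \hat\sigma_j^2 / \sigma^2};
#' `mu_sem` is the standard error of the bin mean.
#'
#' @param transitions output of [pair_transitions()] (rows with
#'   `event != "change"` are dropped), or any data frame with `v_start` and
#'   `dv` columns.
#' @param bin_size transitions pooled per bin (default 32; use 30 for 10-min
#'   fast-fluctuation series).
#' @return A data frame of class `binned_moments` with one row per bin:
#'   `rep_volume`, `v_lo`, `v_hi`, `n`, `mu`, `sigma`, `sigma_lo`,
#'   `sigma_hi`, `mu_sem`.
#' @export
bin_moments <- function(transitions, bin_size = 32L) {
  if ("event" %in% names(transitions))
    transitions <- transitions[transitions$event == "change", , drop = FALSE]
  stopifnot(all(c("v_start", "dv") %in% names(transitions)))
  n <- nrow(transitions)
  bin_size <- as.integer(bin_size)
  if (n < bin_size)
    stop("need at least one full bin (", bin_size, " transitions); got ", n)
  ord <- order(transitions$v_start)
  v <- transitions$v_start[ord]
  dv <- transitions$dv[ord]
  nb <- n %/% bin_size
  rem <- n - nb * bin_size
  bin <- rep(seq_len(nb), each = bin_size)
  if (rem > 0) bin <- c(bin, rep(if (rem >= bin_size / 2) nb + 1L else nb, rem))
  idx <- split(seq_len(n), bin)
  rows <- lapply(idx, function(k) {
    nj <- length(k)
    mu <- mean(dv[k])
    s2 <- sum((dv[k] - mu)^2) / nj
    s <- sqrt(s2)
    data.frame(rep_volume = stats::median(v[k]),
               v_lo = min(v[k]), v_hi = max(v[k]), n = nj, mu = mu,
               sigma = s,
               sigma_lo = s * sqrt(nj / stats::qchisq(0.975, df = nj)),
               sigma_hi = s * sqrt(nj / stats::qchisq(0.025, df = nj)),
               mu_sem = stats::sd(dv[k]) / sqrt(nj))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, bin_size = bin_size,
            class = c("binned_moments", "data.frame"))
}

#' Fit the fast-fluctuation law to 10-min binned moments
#'
#' Unconstrained least squares of the binned SDs against \eqn{V^{2/3}},
#' giving \eqn{\sigma_{fast}(V) = e V^{2/3} + f}. The fast drift is taken as
#' zero (the minute-scale mean changes are negligible).
#'
#' @param moments a [bin_moments()] table computed from 10-min transitions.
#' @return A list with `slope`, `intercept` and the `fit` object.
#' @export
fit_fast <- function(moments) {
  stopifnot(inherits(moments, "binned_moments"))
  if (nrow(moments) < 2) stop("need at least 2 bins to fit the fast law")
  x <- moments$rep_volume^(2 / 3)
  fit <- stats::lm(moments$sigma ~ x)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]), fit = fit)
}

#' Remove the fast component from total fluctuation moments
#'
#' Applies the variance decomposition \eqn{\sigma^2 = \sigma_{fast}^2 +
#' \sigma_{slow}^2} bin-wise: \eqn{\sigma_{slow,j} =
#' \sqrt{\max(\sigma_j^2 - \sigma_{fast}(V_j)^2, 0)}}, with
#' \eqn{\sigma_{fast}} evaluated at each bin's representative volume. Bins
#' where the subtraction clips at zero are flagged.
#'
#' @param moments a [bin_moments()] table from 2-day transitions.
#' @param fast either a list with `slope` and `intercept` (e.g. from
#'   [fit_fast()]) or a [drift_diffusion_spec()] whose fast law is used.
#' @return The `moments` table with added columns `sigma_fast`, `sigma_slow`
#'   and `clipped`.
#' @export
decompose_slow <- function(moments, fast) {
  stopifnot(inherits(moments, "binned_moments"))
  if (inherits(fast, "drift_diffusion_spec"))
    fast <- list(slope = fast$fast_slope, intercept = fast$fast_intercept)
  sf <- fast$slope * moments$rep_volume^(2 / 3) + fast$intercept
  s2 <- moments$sigma^2 - sf^2
  moments$sigma_fast <- sf
  moments$sigma_slow <- sqrt(pmax(s2, 0))
  moments$clipped <- s2 < 0
  moments
}

#' Anchored slope of the slow-fluctuation line
#'
#' One-parameter least squares for the slope of \eqn{\sigma_{slow}} against
#' \eqn{V^{2/3}}, with the line constrained through the anchor point
#' (`anchor_v^(2/3)`, `anchor_sigma`). The anchor (default V = 0.015 um^3,
#' sigma = 0.02) pins the behaviour of the smallest spines, which dominate
#' turnover.
#'
#' @param slow_moments a [decompose_slow()] table (needs `sigma_slow`).
#' @param anchor_v anchor volume (um^3).
#' @param anchor_sigma anchor SD (um^3 per sqrt-interval).
#' @return A list with `slope`, `ci` (95% confidence interval) and `fit`.
#' @export
fit_anchored_slope <- function(slow_moments, anchor_v = 0.015,
                               anchor_sigma = 0.02) {
  stopifnot("sigma_slow" %in% names(slow_moments))
  if (nrow(slow_moments) < 2) stop("need at least 2 bins for the anchored fit")
  x <- slow_moments$rep_volume^(2 / 3) - anchor_v^(2 / 3)
  y <- slow_moments$sigma_slow - anchor_sigma
  fit <- stats::lm(y ~ x + 0)
  ci <- stats::confint(fit, level = 0.95)
  list(slope = unname(stats::coef(fit)[1]),
       ci = c(lower = ci[1, 1], upper = ci[1, 2]),
       fit = fit)
}

#' Fit the drift law to binned mean changes
#'
#' Unconstrained least squares of the binned mean changes \eqn{\mu_j} against
#' \eqn{V^{2/3}}: \eqn{\mu(V) = c V^{2/3} + d}. Wild-type and knockout
#' transitions are pooled before binning when fitting a common drift.
#'
#' @param moments a [bin_moments()] table.
#' @return A list with `slope`, `intercept` and the `fit` object.
#' @export
fit_drift <- function(moments) {
  stopifnot(inherits(moments, "binned_moments"))
  if (nrow(moments) < 2) stop("need at least 2 bins to fit the drift")
  x <- moments$rep_volume^(2 / 3)
  fit <- stats::lm(moments$mu ~ x)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]), fit = fit)
}

#' Compare anchored slow-fluctuation slopes between two groups
#'
#' Pools the anchored coordinates of both groups (response
#' \eqn{\sigma_{slow} - \sigma_0}, predictor \eqn{V^{2/3} - x_0}) and fits a
#' no-intercept linear model with a group-by-predictor interaction. The
#' interaction term tests the slope difference; its t statistic and two-sided
#' p value are returned.
#'
#' @param slow_a,slow_b [decompose_slow()] tables for the two groups.
#' @param anchor_v,anchor_sigma anchor as in [fit_anchored_slope()].
#' @return A list with `t`, `p`, `slope_a`, `slope_b` and the `fit`.
#' @export
compare_slopes <- function(slow_a, slow_b, anchor_v = 0.015,
                           anchor_sigma = 0.02) {
  stopifnot("sigma_slow" %in% names(slow_a), "sigma_slow" %in% names(slow_b))
  if (nrow(slow_a) < 2 || nrow(slow_b) < 2)
    stop("need at least 2 bins per group")
  df <- rbind(
    data.frame(x = slow_a$rep_volume^(2 / 3) - anchor_v^(2 / 3),
               y = slow_a$sigma_slow - anchor_sigma, g = "A"),
    data.frame(x = slow_b$rep_volume^(2 / 3) - anchor_v^(2 / 3),
               y = slow_b$sigma_slow - anchor_sigma, g = "B"))
  df$xb <- df$x * (df$g == "B")   # slope offset of group B
  fit <- stats::lm(y ~ x + xb + 0, data = df)
  sm <- summary(fit)$coefficients
  if (!"xb" %in% rownames(sm) || anyNA(sm["xb", ]))
    stop("degenerate design: interaction not estimable")
  cf <- stats::coef(fit)
  list(t = unname(sm["xb", "t value"]),
       p = unname(sm["xb", "Pr(>|t|)"]),
       slope_a = unname(cf["x"]),
       slope_b = unname(cf["x"] + cf["xb"]),
       fit = fit)
}
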