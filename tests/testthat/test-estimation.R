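obs_row <- function(spine, session, volume, eliminated = FALSE, group = "WT") {
  data.frame(animal_id = "m1", dendrite_id = "d1", spine_id = spine,
             group = group, session = session, volume = volume,
             eliminated = eliminated)
}

test_that("volume tables enforce the longitudinal schema", {
  ok <- volume_table(rbind(obs_row("s1", 1, 0.1), obs_row("s1", 2, 0.12)))
  expect_s3_class(ok, "volume_table")
  expect_error(volume_table(rbind(obs_row("s1", 1, 0.1),
                                  obs_row("s1", 1, 0.2))), "duplicated")
  expect_error(volume_table(obs_row("s1", 1, -0.5)), "volume")
  expect_error(volume_table(rbind(obs_row("s1", 1, NA, eliminated = TRUE),
                                  obs_row("s1", 2, 0.1))), "terminate")
  rt <- tempfile(fileext = ".csv")
  write_volume_table(ok, rt)
  expect_equal(read_volume_table(rt)$volume, ok$volume)
})

test_that("transition pairing separates volume changes from eliminations", {
  tbl <- volume_table(rbind(obs_row("s1", 1, 0.1), obs_row("s1", 2, 0.12),
                            obs_row("s1", 3, 0.11)))
  tr <- pair_transitions(tbl)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$dv, c(0.02, -0.01))
  expect_true(all(tr$event == "change"))

  tbl2 <- volume_table(rbind(obs_row("s2", 1, 0.05),
                             obs_row("s2", 2, NA, eliminated = TRUE)))
  tr2 <- pair_transitions(tbl2)
  expect_equal(sum(tr2$event == "change"), 0)
  expect_equal(sum(tr2$event == "elimination"), 1)

  # non-adjacent sessions pair only at the matching interval
  tbl3 <- volume_table(rbind(obs_row("s3", 1, 0.1), obs_row("s3", 2, 0.2),
                             obs_row("s3", 4, 0.3)))
  expect_equal(nrow(pair_transitions(tbl3, 1)), 1)
  expect_equal(pair_transitions(tbl3, 2)$v_start, 0.2)
  expect_equal(nrow(pair_transitions(tbl3[0, ], 1)), 0)
})

test_that("transition pairing matches brute-force enumeration on a cohort", {
  tbl <- small_cohort(n_spines = 150, n_sessions = 5, seed = 3)
  for (interval in c(1L, 2L)) {
    tr <- pair_transitions(tbl, interval)
    bf <- brute_force_transitions(tbl, interval)
    expect_equal(nrow(tr), nrow(bf))
    expect_equal(table(tr$event), table(bf$event))
    expect_equal(sort(tr$dv[tr$event == "change"]),
                 sort(bf$dv[bf$event == "change"]))
  }
})

test_that("binned moments use the population divisor and the median volume", {
  # two-element bin: dv = {0, 0.2} gives mu = 0.1, sigma = 0.1 exactly
  m <- bin_moments(data.frame(v_start = c(0.1, 0.2), dv = c(0, 0.2)),
                   bin_size = 2L)
  expect_equal(m$mu, 0.1)
  expect_equal(m$sigma, 0.1)
  expect_equal(m$rep_volume, 0.15)

  # constant changes have zero SD in every bin
  tr <- data.frame(v_start = runif(64), dv = 0.01)
  m2 <- bin_moments(tr, 32L)
  expect_equal(m2$sigma, rep(0, 2))
  expect_equal(m2$mu, rep(0.01, 2))
  expect_equal(m2$n, rep(32L, 2))
})

test_that("last-bin remainders merge below half a bin and split above", {
  tr <- data.frame(v_start = seq_len(70) / 100, dv = 0)
  expect_equal(bin_moments(tr, 32L)$n, c(32L, 38L))
  tr2 <- data.frame(v_start = seq_len(81) / 100, dv = 0)
  expect_equal(bin_moments(tr2, 32L)$n, c(32L, 32L, 17L))
  expect_error(bin_moments(tr[1:10, ], 32L), "full bin")
})

test_that("binned moments are invariant to the order of input transitions", {
  set.seed(11)
  tr <- data.frame(v_start = runif(200), dv = rnorm(200, 0, 0.05))
  m1 <- bin_moments(tr, 32L)
  m2 <- bin_moments(tr[sample(200), ], 32L)
  expect_equal(m1, m2)
})

test_that("sigma confidence intervals cover the true SD at nominal rate", {
  set.seed(21)
  hits <- replicate(200, {
    tr <- data.frame(v_start = runif(320), dv = rnorm(320, 0, 0.05))
    m <- bin_moments(tr, 32L)
    c(covered = sum(m$sigma_lo <= 0.05 & m$sigma_hi >= 0.05),
      bins = nrow(m))
  })
  expect_gte(sum(hits["covered", ]) / sum(hits["bins", ]), 0.9)
})

test_that("fast-law fit recovers line coefficients exactly from clean bins", {
  v <- seq(0.02, 0.6, length.out = 8)
  m <- make_moments(v, 0.115 * v^(2 / 3) + 0.0051)
  ft <- fit_fast(m)
  expect_equal(ft$slope, 0.115, tolerance = 1e-10)
  expect_equal(ft$intercept, 0.0051, tolerance = 1e-10)
  flat <- fit_fast(make_moments(v, rep(0.01, 8)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$intercept, 0.01, tolerance = 1e-12)
  expect_error(fit_fast(make_moments(0.1, 0.01)), "2 bins")
})

test_that("fast/slow decomposition inverts the variance sum", {
  v <- seq(0.02, 0.6, length.out = 6)
  fast <- list(slope = 0.115, intercept = 0.0051)
  sfast <- fast$slope * v^(2 / 3) + fast$intercept
  # sigma equal to the fast law decomposes to zero slow component
  d0 <- decompose_slow(make_moments(v, sfast), fast)
  expect_equal(d0$sigma_slow, rep(0, 6))
  # 3-4-5 triangle
  d1 <- decompose_slow(make_moments(0.1, 0.05), list(slope = 0, intercept = 0.03))
  expect_equal(d1$sigma_slow, 0.04)
  expect_false(d1$clipped)
  # clipping is flagged where fast exceeds total
  d2 <- decompose_slow(make_moments(0.1, 0.01), list(slope = 0, intercept = 0.03))
  expect_equal(d2$sigma_slow, 0)
  expect_true(d2$clipped)
  # exact reconstruction wherever no clipping occurred
  m <- make_moments(v, sqrt((0.2 * v^(2 / 3) + 0.008)^2 + sfast^2))
  dd <- decompose_slow(m, fast)
  expect_equal(sqrt(dd$sigma_slow^2 + dd$sigma_fast^2), m$sigma,
               tolerance = 1e-12)
})

test_that("anchored slope fit is exact on lines through the anchor", {
  v <- seq(0.02, 0.7, length.out = 10)
  x0 <- 0.015^(2 / 3)
  for (a in c(0.198, 0.278)) {
    m <- make_moments(v, a * (v^(2 / 3) - x0) + 0.02)
    m$sigma_slow <- m$sigma
    # exact data make lm's variance summary degenerate; only the point
    # estimate matters here
    ft <- suppressWarnings(fit_anchored_slope(m))
    expect_equal(ft$slope, a, tolerance = 1e-12)
  }
  hor <- make_moments(v, rep(0.02, 10))
  hor$sigma_slow <- hor$sigma
  expect_equal(fit_anchored_slope(hor)$slope, 0, tolerance = 1e-12)
})

test_that("anchored slope is linear in the anchored response", {
  set.seed(5)
  v <- seq(0.02, 0.7, length.out = 10)
  y <- 0.2 * (v^(2 / 3) - 0.015^(2 / 3)) + 0.02 + rnorm(10, 0, 0.004)
  m <- make_moments(v, y); m$sigma_slow <- m$sigma
  s1 <- fit_anchored_slope(m)$slope
  m2 <- m; m2$sigma_slow <- 0.02 + 2 * (m$sigma_slow - 0.02)
  expect_equal(fit_anchored_slope(m2)$slope, 2 * s1, tolerance = 1e-10)
})

test_that("drift fit and its zero crossing match closed forms", {
  v <- seq(0.02, 0.7, length.out = 10)
  m <- make_moments(v, 0.05, mu = -0.12 * v^(2 / 3) + 0.029)
  ft <- fit_drift(m)
  expect_equal(ft$slope, -0.12, tolerance = 1e-10)
  expect_equal(ft$intercept, 0.029, tolerance = 1e-10)
  z <- fit_drift(make_moments(v, 0.05, mu = 0))
  expect_equal(z$slope, 0, tolerance = 1e-12)
  expect_equal(z$intercept, 0, tolerance = 1e-12)

  expect_equal(drift_zero_crossing(
    drift_diffusion_spec(0.2, 0.01, drift_slope = -1, drift_intercept = 1)), 1)
  expect_equal(drift_zero_crossing(
    drift_diffusion_spec(0.2, 0.01, drift_slope = -0.5,
                         drift_intercept = 0.125)), 0.125)
  expect_error(drift_zero_crossing(
    drift_diffusion_spec(0.2, 0.01, drift_slope = 0.1,
                         drift_intercept = 0.029)), "zero crossing")
})

test_that("slope comparison is null on identical groups, sensitive otherwise", {
  set.seed(31)
  v <- seq(0.02, 0.7, length.out = 12)
  mk <- function(a, noise_sd) {
    y <- a * (v^(2 / 3) - 0.015^(2 / 3)) + 0.02 + rnorm(12, 0, noise_sd)
    m <- make_moments(v, y); m$sigma_slow <- m$sigma; m
  }
  same <- mk(0.198, 0.003)
  res0 <- compare_slopes(same, same)
  expect_equal(res0$t, 0, tolerance = 1e-8)
  expect_equal(res0$p, 1, tolerance = 1e-6)

  res1 <- compare_slopes(mk(0.198, 0.003), mk(0.278, 0.003))
  expect_lt(res1$p, 0.05)
  expect_gt(res1$slope_b, res1$slope_a)
  expect_error(compare_slopes(same[1, ], same), "2 bins")
})

test_that("10-minute cohorts recover the fast-fluctuation law", {
  set.seed(41)
  slopes <- replicate(60, {
    cc <- cohort_config(groups = list(WT = wt_spec()), n_spines = 600,
                        n_sessions = 7, mode = "fast",
                        seed = sample.int(1e6, 1))
    tr <- pair_transitions(generate_cohort(cc))
    fit_fast(bin_moments(tr, 30L))$slope
  })
  # binning on noise-carrying observed volumes attenuates the recovered
  # slope ~10% toward zero; recovery lands just below the generating value
  expect_lt(abs(mean(slopes) - 0.115) / 0.115, 0.15)
  expect_lt(mean(slopes), 0.115)
  expect_gt(mean(slopes), 0.09)
})
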