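test_that("sphere profile is even in r and non-increasing away from the centre", {
  m <- psf_sphere_model(radius = 0.5)
  r <- c(0.05, 0.2, 0.4, 0.8)
  expect_equal(projected_sphere_profile(r, m),
               projected_sphere_profile(-r, m), tolerance = 1e-8)
  grid <- seq(0, 1.2, by = 0.06)
  f <- projected_sphere_profile(grid, m)
  expect_true(all(diff(f) <= 1e-10))
  expect_gt(f[1], 0)
})

test_that("radial reduction agrees with direct 2-D quadrature", {
  skip_if_not_installed("pracma")
  m <- psf_sphere_model(radius = 0.5, amplitude = 1.3)
  for (r in c(0, 0.15, 0.45)) {
    direct <- m$amplitude / (2 * pi * m$sigma_x^2) *
      pracma::integral2(function(rho, th) {
        x <- rho * cos(th); y <- rho * sin(th)
        2 * sqrt(pmax(m$radius^2 - rho^2, 0)) *
          exp(-((x - r)^2 + y^2) / (2 * m$sigma_x^2)) * rho
      }, 0, m$radius, 0, 2 * pi, reltol = 1e-9)$Q
    expect_equal(projected_sphere_profile(r, m), direct,
                 tolerance = 1e-4)
  }
})

test_that("profile matches Monte-Carlo integration of the full integral", {
  set.seed(1234)
  mc <- mc_sphere_profile(r = 0.3, R = 0.5, sigma_x = 0.24, sigma_z = 0.91,
                          n = 1e6)
  val <- projected_sphere_profile(0.3, psf_sphere_model(radius = 0.5))
  expect_lt(abs(val - mc$value), 3 * mc$se)
})

test_that("lateral blurring conserves the total flux A * (4/3) pi R^3", {
  for (R in c(0.25, 0.5)) {
    m <- psf_sphere_model(radius = R, amplitude = 2)
    flux <- stats::integrate(function(r) {
      projected_sphere_profile(r, m) * 2 * pi * r
    }, 0, R + 6 * m$sigma_x, rel.tol = 1e-7)$value
    expect_equal(flux, 2 * 4 / 3 * pi * R^3, tolerance = 1e-3)
  }
})

test_that("sphere fit recovers radius and amplitude from noiseless samples", {
  truth <- psf_sphere_model(radius = 0.4, amplitude = 1.7)
  r <- seq(-0.9, 0.9, by = 0.12)
  fit <- fit_sphere(r, projected_sphere_profile(r, truth))
  expect_lt(abs(fit$model$radius - 0.4), 1e-3)
  expect_equal(fit$model$amplitude, 1.7, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-8)
})

test_that("sphere fit is accurate on average under 2% multiplicative noise", {
  set.seed(99)
  truth <- psf_sphere_model(radius = 0.4)
  r <- seq(-0.9, 0.9, by = 0.12)
  clean <- projected_sphere_profile(r, truth)
  radii <- replicate(50, {
    fit_sphere(r, clean * (1 + stats::rnorm(length(r), 0, 0.02)))$model$radius
  })
  expect_lt(abs(mean(radii) - 0.4) / 0.4, 0.02)
})

test_that("sphere fit rejects degenerate inputs", {
  r <- seq(-0.6, 0.6, by = 0.15)
  expect_error(fit_sphere(r, rep(1, length(r))), "flat")
  expect_error(fit_sphere(r[1:4], r[1:4]), "at least 5")
  r_one_sided <- seq(0, 0.8, by = 0.1)
  expect_error(fit_sphere(r_one_sided,
                          projected_sphere_profile(r_one_sided,
                                                   psf_sphere_model(0.4))),
               "flank")
})

test_that("fluorescence-to-volume conversion is linear with the right scale", {
  # calibration sphere of R = 0.5 um has volume 4/3 pi 0.125
  cf <- conversion_coefficient(radius = 0.5, total_f = 1)
  expect_equal(cf$volume, 4 / 3 * pi * 0.125, tolerance = 1e-12)
  expect_equal(as.numeric(volume_from_fluorescence(1, cf)), cf$volume)
  expect_equal(as.numeric(volume_from_fluorescence(0, cf)), 0)
  # homogeneity and additivity
  f <- c(1.5, 2.5)
  v <- as.numeric(volume_from_fluorescence(f, cf))
  expect_equal(as.numeric(volume_from_fluorescence(3 * f, cf)), 3 * v)
  expect_equal(as.numeric(volume_from_fluorescence(sum(f), cf)), sum(v))
})

test_that("session normalization rescales volumes by exact factor ratios", {
  cf <- conversion_coefficient(radius = 0.5, total_f = 10)
  nz <- daily_normalization(session = c(1, 2, 3),
                            factor = c(1, 1.10, 0.55))
  v2 <- as.numeric(volume_from_fluorescence(4, cf, nz, session = 2))
  v3 <- as.numeric(volume_from_fluorescence(4, cf, nz, session = 3))
  expect_equal(v3 / v2, 2, tolerance = 1e-12)
  expect_error(volume_from_fluorescence(4, cf, nz, session = 9), "session")
  expect_error(volume_from_fluorescence(4, cf, nz), "session required")
})

test_that("normalization factors are anchored at the reference session", {
  nz <- daily_normalization(session = c(2, 4, 6), factor = c(2, 3, 4),
                            reference_session = 4)
  expect_equal(nz$factor[nz$session == 4], 1)
  expect_equal(nz$factor, c(2, 3, 4) / 3)
  expect_error(daily_normalization(1:2, c(1, -1)), "positive")
  expect_error(daily_normalization(1:2, c(1, 2), reference_session = 5),
               "reference")
})

test_that("negative background-subtracted fluorescence is clipped and flagged", {
  cf <- conversion_coefficient(radius = 0.5, total_f = 1)
  expect_warning(v <- volume_from_fluorescence(c(-0.2, 1), cf), "clipped")
  expect_equal(as.numeric(v)[1], 0)
  expect_equal(attr(v, "clipped"), c(TRUE, FALSE))
})

test_that("profile and normalization CSV readers validate their schema", {
  p1 <- tempfile(fileext = ".csv")
  truth <- psf_sphere_model(radius = 0.4)
  r <- seq(-0.6, 0.6, by = 0.1)
  utils::write.csv(data.frame(r_um = r,
                              intensity = projected_sphere_profile(r, truth)),
                   p1, row.names = FALSE)
  prof <- read_profile_csv(p1)
  expect_lt(abs(fit_sphere(prof$r_um, prof$intensity)$model$radius - 0.4),
            1e-3)
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(dendrite_id = c("d1", "d1", "d2", "d2"),
                              session = c(1, 2, 1, 2),
                              factor = c(1, 1.1, 2, 2.4)),
                   p2, row.names = FALSE)
  nz <- read_normalization_csv(p2)
  expect_named(nz, c("d1", "d2"))
  expect_equal(nz$d2$factor, c(1, 1.2))
})
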