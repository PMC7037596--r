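test_that("fit_peak recovers exact Gaussian parameters and is idempotent", {
  q <- seq(0.040, 0.054, length.out = 201)
  prof <- synthetic_profile(q, 0.0469, 0.001, 100, b0 = 5, b1 = 20)
  fit <- fit_peak(prof, c(0.043, 0.051))
  expect_true(fit$converged)
  expect_equal(fit$center_q, 0.0469, tolerance = 1e-6)
  expect_equal(fit$sigma_q, 0.001, tolerance = 1e-6)
  expect_equal(fit$area, 100, tolerance = 1e-6)
  # idempotence: refit the fitted model curve
  model <- prof
  model$intensity <- fit$baseline +
    fit$amplitude * exp(-(q - fit$center_q)^2 / (2 * fit$sigma_q^2))
  refit <- fit_peak(model, c(0.043, 0.051))
  expect_equal(refit$center_q, fit$center_q, tolerance = 1e-9)
  expect_equal(refit$sigma_q, fit$sigma_q, tolerance = 1e-9)
  expect_equal(refit$area, fit$area, tolerance = 1e-9)
})

test_that("pseudo-Voigt model fits its own curve and reports the analytic area", {
  q <- seq(0.040, 0.054, length.out = 301)
  s <- 0.0008; A <- 120; mu <- 0.047; eta <- 0.4
  y <- 2 + A * (eta / (1 + ((q - mu) / s)^2) +
                  (1 - eta) * exp(-(q - mu)^2 / (2 * s^2)))
  prof <- synthetic_profile(q, mu, s, 0)
  prof$intensity <- y
  fit <- fit_peak(prof, c(0.043, 0.051), model = "pseudo_voigt")
  expect_true(fit$converged)
  expect_equal(fit$center_q, mu, tolerance = 1e-6)
  expect_equal(fit$area, A * s * (eta * pi + (1 - eta) * sqrt(2 * pi)),
               tolerance = 1e-4)
})

test_that("degenerate windows and flat profiles give flagged nulls or errors", {
  q <- seq(0.040, 0.054, length.out = 101)
  flat <- synthetic_profile(q, 0.0469, 0.001, 0, b0 = 10)
  fit <- fit_peak(flat, c(0.043, 0.051))
  expect_false(is.null(fit))
  expect_true(!fit$converged || fit$amplitude < 1e-6)
  prof <- synthetic_profile(q, 0.0469, 0.001, 100)
  expect_error(fit_peak(prof, c(0.02, 0.03)), "outside")
  expect_error(fit_peak(prof, c(0.0468, 0.0470)), "7 points")
})

test_that("noisy peak centers stay within 0.2 sigma over 100 seeds", {
  q <- seq(0.040, 0.054, length.out = 141)
  sigma_q <- 0.0008
  clean <- synthetic_profile(q, 0.0469, sigma_q, 100 * 0.0469, b0 = 20)
  amp <- max(clean$intensity) - 20
  expect_gt(amp / sqrt(max(clean$intensity)), 15)  # SNR near 20
  err <- vapply(1:100, function(s) {
    noisy <- clean
    noisy$intensity <- withr::with_seed(s, rpois(length(q), clean$intensity))
    fit_peak(noisy, c(0.0435, 0.0505))$center_q - 0.0469
  }, numeric(1))
  expect_lt(quantile(abs(err), 0.95), 0.2 * sigma_q)
})

test_that("collagen D follows from the 5th order alone: d5 x 5", {
  # pure arithmetic on a synthetic 5th-order peak at q = 2*pi/134
  q <- seq(0.040, 0.054, length.out = 201)
  prof <- synthetic_profile(q, 2 * pi / 134, 0.001, 50)
  D <- collagen_D(prof)
  expect_equal(D$d5_nm, 13.40, tolerance = 1e-4)
  expect_equal(D$D_nm, 67.0, tolerance = 1e-3)
})

test_that("rendered D-periods are recovered within 0.2% and orders agree", {
  ph <- make_phantom("MV", overrides = list(D0_nm = 67.67))
  fr <- render_diffraction(ph, 15, 0, geometry = test_geometry())
  D <- collagen_D(fr, D0_guess = 67)
  expect_equal(D$D_nm, 67.67, tolerance = 0.002 * 67.67)
  # n * d_n consistent across visible orders within 0.3%
  tab <- collagen_orders(fr, D0_guess = 67)
  expect_gte(nrow(tab), 5)
  expect_lt((max(tab$n_d_nm) - min(tab$n_d_nm)) / median(tab$n_d_nm), 0.003)
})

test_that("collagen-free frames refuse a D-period", {
  ph <- make_phantom("MV", overrides = list(
    muscle_fraction = list(pm_plateau = 1, ct_plateau = 1)))
  fr <- render_diffraction(ph, 4, 0, geometry = test_geometry())
  expect_error(collagen_D(fr), "5th order")
})

test_that("muscle (1,1) is recovered, flagged relative, and absent in pure CT", {
  ph <- make_phantom("MV", overrides = list(d11_0_nm = 21.5))
  g <- test_geometry()
  fr <- render_diffraction(ph, 4, 0, geometry = g)   # PM: no cross population
  m <- muscle_d11(fr, d11_guess = 21.5)
  expect_equal(m$d11_nm, 21.5, tolerance = 0.005 * 21.5)
  expect_equal(m$provenance$measure, "relative")
  ct <- render_diffraction(cached_phantom("MV"), 15, 0, geometry = g)
  expect_error(muscle_d11(ct), "no muscle")
})

test_that("the (1,1) series shrinks strictly with increasing strain", {
  ph <- cached_phantom("MV")
  g <- test_geometry()
  d <- vapply(seq(0, 0.10, 0.02), function(e)
    muscle_d11(render_diffraction(ph, 4, e, geometry = g),
               d11_guess = ph$d11_0_nm)$d11_nm, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("orientation recovers angle and spread across the tested range", {
  g <- test_geometry()
  for (s0 in c(5, 10, 20, 30)) {
    ph <- make_phantom("MV", overrides = list(
      orientation = list(sigma0_knots = list(x = c(0, 30),
                                             sigma = c(s0, s0)),
                         align_gain = 0, min_factor = 1,
                         cross_amp = 0, cross_sigma_mm = 0.8)))
    fr <- render_diffraction(ph, 15, 0, geometry = g)
    o <- orientation(fr)
    expect_false(o$isotropic)
    expect_lt(valvescan:::.axis_dist(o$angle, 90), 2)
    expect_equal(o$spread, s0, tolerance = 2 / s0)
  }
})

test_that("isotropic rings yield dots and the minor axis is 1/spread", {
  ph <- make_phantom("MV", overrides = list(
    orientation = list(sigma0_knots = list(x = c(0, 30), sigma = c(1e4, 1e4)),
                       align_gain = 0, min_factor = 1,
                       cross_amp = 0, cross_sigma_mm = 0.8)))
  fr <- render_diffraction(ph, 15, 0, geometry = test_geometry())
  o <- orientation(fr)
  expect_true(o$isotropic)
  expect_equal(unname(o$ellipse["b"]), 0.1)
  # minor axes scale as 1/spread by construction: 5 deg vs 20 deg -> 4:1
  b_of <- function(spread) min(1, 5 / spread)
  expect_equal(b_of(5) / b_of(20), 4)
})

test_that("rotating the frame rotates the reported angle", {
  ph <- cached_phantom("MV")
  fr <- render_diffraction(ph, 15, 0, geometry = test_geometry())
  o1 <- orientation(fr)
  rot <- fr
  rot$image <- t(fr$image)[, nrow(fr$image):1]   # 90 degree rotation
  o2 <- orientation(rot)
  expect_lt(valvescan:::.axis_dist(o2$angle, (o1$angle + 90) %% 180), 1)
})

test_that("reduce_frame assembles a complete per-frame record", {
  ph <- cached_phantom("MV")
  fr <- render_diffraction(ph, 9.5, 0.04, geometry = test_geometry())
  row <- reduce_frame(fr, point_id = 3, D0_guess = ph$D0_nm,
                      d11_guess = ph$d11_0_nm)
  expect_equal(row$point_id, 3)
  expect_equal(row$position_mm, 9.5)
  expect_equal(row$eng_strain_pct, 4)
  expect_false(is.na(row$D_nm))
  expect_gt(row$I5_area, 0)
  expect_gt(row$I11_area, 0)
  expect_false(row$isotropic)
})
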