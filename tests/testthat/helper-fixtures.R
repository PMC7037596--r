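# Shared fixtures. All synthetic data is generated in code at test time.

# Compact detector used where full 512^2 fidelity is not the point:
# halving the sample-detector distance halves every arc radius, so orders
# 1..9 of a 67 nm D-period stay on a 256^2 detector.
test_geometry <- function() {
  detector_geometry(distance = 1250, image_shape = c(256L, 256L),
                    beam_center = c(127.5, 127.5))
}

# Phantoms are cheap to build but used everywhere; memoise per preset.
.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(preset = "MV") {
  if (is.null(.phantom_cache[[preset]]))
    .phantom_cache[[preset]] <- make_phantom(preset)
  .phantom_cache[[preset]]
}

# Minimal phantom-shaped object whose regions are purely linear springs
# (no toe: eps_toe = 0 makes sigma = E * eps exactly on the ascending
# branch). Used for the closed-form series-solver cases.
linear_spring_strip <- function(E, area, L0, sigma_ult = NULL) {
  n <- length(E)
  if (is.null(sigma_ult)) sigma_ult <- rep(1e6, n)
  regions <- data.frame(
    region = paste0("R", seq_len(n)),
    x_lo = cumsum(c(0, L0))[seq_len(n)], x_hi = cumsum(L0),
    L0 = L0, area_mm2 = area,
    sigma_table = sigma_ult, sigma_ult = sigma_ult,
    eps_ult = sigma_ult / E,
    E_t = E, k = 1e-6, eps_toe = 0, E = E,
    drop_width = 0.5, residual = 0.5)
  list(regions = regions, sensor_max_g = Inf)
}

# Random phantom jitter: geometry, coupling, thickness and ultimate-stress
# perturbations around the preset, keeping every invariant intact.
jittered_phantom <- function(preset = "MV", seed = 1) {
  withr::with_seed(seed, {
    b <- c(0, 8, 11, 19, 22, 30)
    b[2:5] <- b[2:5] + runif(4, -0.4, 0.4)
    st <- list(PM = 0.011, `PM-CT` = 0.144, CT = 1.491,
               `CT-LL` = 0.024, LL = 0.025)
    if (preset == "TV")
      st <- list(PM = 0.119, `PM-CT` = 0.159, CT = 4.503,
                 `CT-LL` = 0.097, LL = 0.059)
    st <- lapply(st, function(s) s * runif(1, 0.9, 1.1))
    tk <- list(x = b, t = c(2.5, 2.5, 1.0, 1.0, 1.5, 1.5) *
                 runif(1, 0.9, 1.1))
    sc <- list(baseline = 0.02 * runif(1, 0.8, 1.2),
               amp = 0.05 * runif(1, 0.8, 1.2),
               sigma_mm = 1.2 * runif(1, 0.85, 1.2))
    make_phantom(preset, overrides = list(
      region_bounds = b, sigma_table = st, thickness_knots = tk,
      strain_coupling = sc,
      tear_force_N = (if (preset == "TV") 0.45 else 0.30) *
        runif(1, 0.9, 1.1)))
  })
}

# Synthetic radial profile: Gaussian peaks on a linear baseline over a
# uniform q grid, as a radial_profile object.
synthetic_profile <- function(q, centers, sigmas, areas, b0 = 0, b1 = 0) {
  y <- b0 + b1 * q
  for (i in seq_along(centers))
    y <- y + areas[i] / (sigmas[i] * sqrt(2 * pi)) *
      exp(-(q - centers[i])^2 / (2 * sigmas[i]^2))
  structure(list(q = q, intensity = y, r_px = seq_along(q),
                 npix = rep(1L, length(q)), sector = "meridional",
                 half_angle = 15, mask_radius = 0,
                 geometry = NULL, provenance = list()),
            class = "radial_profile")
}
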