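#' Build a synthetic valve-strip phantom
#'
#' Constructs the ground-truth description of a papillary muscle (PM) ->
#' chordae tendinae (CT) -> leaflet (LL) strip: region geometry, relative
#' muscle fraction with a diffuse PM-CT ramp, thickness profile, collagen
#' D-period and muscle (1,1) d-spacing at rest, molecular-strain coupling
#' (a localized gain peaking at the PM-CT junction), azimuthal orientation
#' spread, and a per-region toe/linear/failure constitutive law.
#'
#' Per-region ultimate stresses in the `"MV"` and `"TV"` presets are the
#' published microscopy-derived values for bisected valve pulls. Because a
#' strip under uniaxial pull carries one common force, those per-region
#' stresses are interpreted as (tear force)/(region area): the phantom sets
#' each region's cross-section to `tear_force_N / sigma_table` and gives all
#' regions except the designated weak link (`weak_region`, default the PM-CT
#' transition) a capacity margin so that the weak region tears first while
#' every region's peak recorded stress equals its preset value.
#'
#' @param preset `"MV"`, `"TV"` or `"AV"` (the AV preset is synthetic:
#'   no published values exist for it).
#' @param overrides named list of preset fields to replace (same structure as
#'   the packaged YAML preset files, e.g.
#'   `list(muscle_fraction = list(ct_plateau = 0))`). Values are validated
#'   against the phantom invariants.
#' @return An object of class `tissue_phantom`.
#' @examples
#' ph <- make_phantom("MV")
#' ph$regions$sigma_table  # per-region ultimate stresses, MPa
#' muscle_fraction(ph, c(4, 9.5, 15))
#' @export
make_phantom <- function(preset = c("MV", "TV", "AV"), overrides = list()) {
  preset <- match.arg(preset)
  path <- system.file("extdata", "presets",
                      paste0(tolower(preset), ".yaml"),
                      package = "valvescan")
  if (!nzchar(path)) stop("unknown preset: ", preset)
  cfg <- yaml::read_yaml(path)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("unknown override field(s): ",
                          paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, overrides)
  }
  .phantom_from_config(cfg)
}

.region_names <- c("PM", "PM-CT", "CT", "CT-LL", "LL")

.phantom_from_config <- function(cfg) {
  bounds <- as.numeric(cfg$region_bounds)
  if (length(bounds) != 6L || any(diff(bounds) <= 0))
    stop("region_bounds must be 6 strictly increasing positions (mm)")
  st <- unlist(cfg$sigma_table)[.region_names]
  if (any(is.na(st)) || any(st <= 0))
    stop("sigma_table must give a positive ultimate stress for each region")
  mf <- cfg$muscle_fraction
  if (mf$pm_plateau < 0 || mf$pm_plateau > 1 ||
      mf$ct_plateau < 0 || mf$ct_plateau > 1)
    stop("muscle-fraction plateaus must lie in [0, 1]")
  tk <- cfg$thickness_knots
  if (any(unlist(tk$t) <= 0)) stop("thickness must be positive everywhere")
  if (cfg$tear_force_N <= 0) stop("tear_force_N must be positive")
  if (cfg$capacity_margin < 1) stop("capacity_margin must be >= 1")
  if (!cfg$weak_region %in% .region_names)
    stop("weak_region must be one of ", paste(.region_names, collapse = ", "))

  eps_cap <- unlist(cfg$eps_cap)[.region_names]
  area <- cfg$tear_force_N / st            # mm^2, so that F_tear/A = sigma_table
  sigma_cap <- st * ifelse(.region_names == cfg$weak_region,
                           1, cfg$capacity_margin)

  regions <- data.frame(
    region = .region_names,
    x_lo = bounds[1:5], x_hi = bounds[2:6],
    L0 = diff(bounds),
    area_mm2 = unname(area),
    sigma_table = unname(st),
    sigma_ult = unname(sigma_cap),
    eps_ult = unname(eps_cap),
    stringsAsFactors = FALSE
  )
  # C1-continuous toe construction: exponential toe joins the linear branch
  # with matching slope at eps_toe, reaching sigma_ult at eps_ult.
  toe <- t(vapply(seq_len(5), function(i)
    .solve_toe(regions$sigma_ult[i], regions$eps_ult[i]),
    numeric(4)))
  regions$E_t <- toe[, 1]; regions$k <- toe[, 2]
  regions$eps_toe <- toe[, 3]; regions$E <- toe[, 4]
  regions$drop_width <- cfg$drop_width
  regions$residual <- cfg$residual

  sc <- cfg$strain_coupling
  ph <- structure(list(
    preset = cfg$name,
    synthetic_values = isTRUE(cfg$synthetic),
    region_bounds = bounds,
    regions = regions,
    weak_region = cfg$weak_region,
    tear_force_N = cfg$tear_force_N,
    capacity_margin = cfg$capacity_margin,
    muscle_fraction_params = mf,
    thickness_knots = data.frame(x = unlist(tk$x), t = unlist(tk$t)),
    D0_nm = cfg$D0_nm,
    d11_0_nm = cfg$d11_0_nm,
    d11_gain = cfg$d11_gain,
    strain_coupling = list(baseline = sc$baseline, amp = sc$amp,
                           center = mean(bounds[2:3]), sigma = sc$sigma_mm),
    orientation = cfg$orientation,
    sensor_max_g = cfg$sensor_max_g,
    marker_layout = .marker_layout(bounds)
  ), class = "tissue_phantom")
  ph
}

# Fiducial-marker material positions: one at each region boundary (so every
# region is flanked, including both transitions) plus one mid-region dot.
.marker_layout <- function(bounds) {
  mids <- (bounds[1:5] + bounds[2:6]) / 2
  x <- sort(c(bounds, mids))
  data.frame(marker = seq_along(x), x_mm = x,
             at_boundary = x %in% bounds)
}

# Solve toe parameters (E_t, k, eps_toe, E) for a region whose curve must
# pass (eps_toe, sigma_toe) with slope continuity and reach sigma_ult at
# eps_ult. Shape fractions: eps_toe = 0.4 eps_ult, sigma_toe = 0.15 sigma_ult.
.solve_toe <- function(sigma_ult, eps_ult,
                       toe_strain_frac = 0.4, toe_stress_frac = 0.15) {
  eps_toe <- toe_strain_frac * eps_ult
  sigma_toe <- toe_stress_frac * sigma_ult
  E <- (sigma_ult - sigma_toe) / (eps_ult - eps_toe)
  # with u = exp(k*eps_toe):  sigma_t*u*log(u) - E*eps_toe*(u-1) = 0, u > 1
  h <- function(u) sigma_toe * u * log(u) - E * eps_toe * (u - 1)
  up <- 2
  while (h(up) < 0) up <- up * 2
  u <- uniroot(h, c(1 + 1e-9, up), tol = 1e-14)$root
  k <- log(u) / eps_toe
  c(E_t = E / u, k = k, eps_toe = eps_toe, E = E)
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("tissue_phantom: %s strip, %g mm (%s)\n", x$preset,
              diff(range(x$region_bounds)),
              if (isTRUE(x$synthetic_values)) "synthetic preset values"
              else "preset ultimate stresses from bisected-pull data"))
  cat(sprintf("  weak link: %s | tear force %.3g N | D0 = %.1f nm\n",
              x$weak_region, x$tear_force_N, x$D0_nm))
  print(x$regions[, c("region", "x_lo", "x_hi", "area_mm2",
                      "sigma_table", "eps_ult")], row.names = FALSE)
  invisible(x)
}

#' Ground-truth field accessors
#'
#' Evaluate the phantom's ground-truth fields at material positions `x` (mm,
#' measured from the PM end): relative muscle fraction `f_m(x)` in `[0, 1]`
#' (plateau in PM, linear ramp across the PM-CT transition, zero from pure CT
#' onwards), thickness `t(x)` (mm, piecewise linear), molecular-strain
#' coupling gain `c(x)` (dimensionless Gaussian bump over the PM-CT junction
#' atop a baseline, so local molecular strain is `c(x) * eng_strain`), and
#' azimuthal orientation spread `sigma_chi(x, eng_strain)` (degrees,
#' non-increasing in engineering strain).
#'
#' @param phantom a [tissue_phantom][make_phantom].
#' @param x material position(s), mm.
#' @param eng_strain engineering strain (fraction, e.g. `0.10`).
#' @return numeric vector, one value per `x`.
#' @export
muscle_fraction <- function(phantom, x) {
  .check_x(phantom, x)
  b <- phantom$region_bounds
  p <- phantom$muscle_fraction_params
  ramp <- p$pm_plateau + (p$ct_plateau - p$pm_plateau) *
    (x - b[2]) / (b[3] - b[2])
  out <- ifelse(x <= b[2], p$pm_plateau,
         ifelse(x >= b[3], p$ct_plateau, ramp))
  pmin(pmax(out, 0), 1)
}

#' @rdname muscle_fraction
#' @export
thickness_at <- function(phantom, x) {
  .check_x(phantom, x)
  approx(phantom$thickness_knots$x, phantom$thickness_knots$t,
         xout = x, rule = 2)$y
}

#' @rdname muscle_fraction
#' @export
strain_coupling <- function(phantom, x) {
  .check_x(phantom, x)
  sc <- phantom$strain_coupling
  sc$baseline + sc$amp * exp(-((x - sc$center)^2) / (2 * sc$sigma^2))
}

#' @rdname muscle_fraction
#' @export
orientation_spread <- function(phantom, x, eng_strain = 0) {
  .check_x(phantom, x)
  o <- phantom$orientation
  s0 <- approx(unlist(o$sigma0_knots$x), unlist(o$sigma0_knots$sigma),
               xout = x, rule = 2)$y
  s0 * pmax(o$min_factor, 1 - o$align_gain * eng_strain)
}

# Weight of the 90 degree rotated collagen population near the CT-LL junction
# (relative to the axial population); drives the orientation signature used
# by transition calling.
.cross_population <- function(phantom, x) {
  o <- phantom$orientation
  cc <- mean(phantom$region_bounds[4:5])
  o$cross_amp * exp(-((x - cc)^2) / (2 * o$cross_sigma_mm^2))
}

#' @rdname muscle_fraction
#' @export
region_of <- function(phantom, x) {
  .check_x(phantom, x)
  idx <- findInterval(x, phantom$region_bounds, rightmost.closed = TRUE,
                      all.inside = TRUE)
  .region_names[idx]
}

.check_x <- function(phantom, x) {
  b <- range(phantom$region_bounds)
  if (any(x < b[1] - 1e-9 | x > b[2] + 1e-9))
    stop("position outside the sample extent [", b[1], ", ", b[2], "] mm")
  invisible(TRUE)
}

# --- per-region constitutive law ------------------------------------------

# Stress (MPa) at engineering strain eps (fraction). `reg` may be a single
# region row or the full regions table with `eps` of matching length.
# Branches: exponential toe, linear to sigma_ult, linear drop over
# drop_width to residual*sigma_ult, then a residual plateau.
.region_stress <- function(reg, eps) {
  n <- max(length(eps), nrow(reg))
  eps <- rep_len(eps, n)
  E_t <- rep_len(reg$E_t, n); k <- rep_len(reg$k, n)
  eps_toe <- rep_len(reg$eps_toe, n); E <- rep_len(reg$E, n)
  s_ult <- rep_len(reg$sigma_ult, n); e_ult <- rep_len(reg$eps_ult, n)
  w <- rep_len(reg$drop_width, n); res <- rep_len(reg$residual, n)
  sig_toe <- (E_t / k) * (exp(k * eps_toe) - 1)
  out <- (E_t / k) * (exp(k * pmin(eps, eps_toe)) - 1)
  lin <- eps > eps_toe
  out[lin] <- sig_toe[lin] + E[lin] * (pmin(eps, e_ult)[lin] - eps_toe[lin])
  soft <- eps > e_ult
  out[soft] <- s_ult[soft] - (s_ult * (1 - res) / w)[soft] *
    (pmin(eps - e_ult, w)[soft])
  out
}

# Inverse of the ascending branch: strain at stress sigma (valid for
# 0 <= sigma <= sigma_ult). Vectorized like .region_stress.
.region_strain_at <- function(reg, sigma) {
  n <- max(length(sigma), nrow(reg))
  sigma <- rep_len(sigma, n)
  E_t <- rep_len(reg$E_t, n); k <- rep_len(reg$k, n)
  eps_toe <- rep_len(reg$eps_toe, n); E <- rep_len(reg$E, n)
  sig_toe <- (E_t / k) * (exp(k * eps_toe) - 1)
  ifelse(sigma <= sig_toe,
         log1p(k * sigma / E_t) / k,
         eps_toe + (sigma - sig_toe) / E)
}
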