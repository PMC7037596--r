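#' Equilibrium of the valve strip pulled in series
#'
#' The five regions (PM, PM-CT, CT, CT-LL, LL) act as springs in series: one
#' tensile force `F` runs through the strip, each region carries stress
#' `F / A_i`, and regional strains must absorb the imposed grip displacement,
#' `sum(eps_i * L0_i) = total_displacement`. On the ascending branch the
#' force is found by bracketed root finding (the per-region strain at a given
#' stress is closed-form). Past the weak region's capacity the solver follows
#' that region's softening branch while the intact regions unload
#' elastically; if no softening equilibrium exists at the imposed
#' displacement (snap-back), the state jumps to the residual plateau.
#'
#' @param phantom a [tissue_phantom][make_phantom].
#' @param total_displacement grip displacement, mm (>= 0).
#' @return list with `force_N`, `load_g`, named per-region `strains`
#'   (fractions), `stresses` (MPa), logical `post_failure`, and
#'   `failing_region` (`NA` before failure).
#' @examples
#' ph <- make_phantom("MV")
#' st <- solve_series_pull(ph, 2)
#' max(abs(st$stresses * ph$regions$area_mm2 - st$force_N)) / st$force_N
#' @export
solve_series_pull <- function(phantom, total_displacement) {
  if (total_displacement < 0) stop("displacement must be >= 0")
  reg <- phantom$regions
  caps <- reg$sigma_ult * reg$area_mm2
  w <- which.min(caps)
  F_cap <- caps[w]

  asc_disp <- function(F) {
    sum(.region_strain_at_all(reg, F / reg$area_mm2) * reg$L0)
  }
  D_cap <- asc_disp(F_cap)

  if (total_displacement <= D_cap) {
    F <- if (total_displacement == 0) 0 else
      uniroot(function(f) asc_disp(f) - total_displacement,
              c(0, F_cap), tol = 1e-13)$root
    eps <- .region_strain_at_all(reg, F / reg$area_mm2)
    return(.pull_state(phantom, F, eps, post_failure = FALSE,
                       failing = if (F >= F_cap * (1 - 1e-12)) reg$region[w]
                                 else NA_character_))
  }

  # softening branch of the weak region
  rw <- reg[w, ]
  F_res <- rw$residual * rw$sigma_ult * rw$area_mm2
  soft_eps_w <- function(F) {
    rw$eps_ult + rw$drop_width * (rw$sigma_ult - F / rw$area_mm2) /
      ((1 - rw$residual) * rw$sigma_ult)
  }
  soft_disp <- function(F) {
    eps <- .region_strain_at_all(reg, F / reg$area_mm2)
    eps[w] <- soft_eps_w(F)
    sum(eps * reg$L0)
  }
  g_res <- soft_disp(F_res) - total_displacement
  if (g_res >= 0) {
    F <- uniroot(function(f) soft_disp(f) - total_displacement,
                 c(F_res, F_cap), tol = 1e-13)$root
    eps <- .region_strain_at_all(reg, F / reg$area_mm2)
    eps[w] <- soft_eps_w(F)
  } else {
    # residual plateau: all further displacement goes into the torn region
    F <- F_res
    eps <- .region_strain_at_all(reg, F / reg$area_mm2)
    eps[w] <- (total_displacement - sum(eps[-w] * reg$L0[-w])) / reg$L0[w]
  }
  .pull_state(phantom, F, eps, post_failure = TRUE, failing = reg$region[w])
}

.region_strain_at_all <- function(reg, sigmas) {
  .region_strain_at(reg, sigmas)
}

.pull_state <- function(phantom, F, eps, post_failure, failing) {
  reg <- phantom$regions
  stresses <- .region_stress(reg, eps)
  list(force_N = F,
       load_g = F / (.g0 * 1e-3),
       strains = setNames(eps, reg$region),
       stresses = setNames(stresses, reg$region),
       post_failure = post_failure,
       failing_region = failing)
}

#' Simulate a full displacement-ramp pull
#'
#' Drives the strip at a constant grip rate, solving the series equilibrium
#' at every video frame (default 5 fps), through toe, linear, failure and a
#' short residual tail. Returns the load-displacement trace the strain rig
#' would log, plus the hidden per-region strain ground truth used by the
#' renderer and by tests.
#'
#' @param phantom a [tissue_phantom][make_phantom].
#' @param rate grip displacement rate, mm/s.
#' @param fps sampling/video frame rate, Hz.
#' @param tail_frames residual-plateau frames appended after the torn region
#'   has fully softened.
#' @param max_displacement optional hard stop, mm.
#' @return A `load_trace`: data frame with `time_s`, `displacement_mm`,
#'   `load_g` plus attributes `strain_truth` (frames x regions matrix, as
#'   fractions), `post_failure` (logical per frame) and `phantom` metadata.
#' @export
simulate_pull <- function(phantom, rate = 0.05, fps = 5,
                          tail_frames = 12L, max_displacement = NULL) {
  if (rate <= 0 || fps <= 0) stop("rate and fps must be positive")
  reg <- phantom$regions
  caps <- reg$sigma_ult * reg$area_mm2
  w <- which.min(caps)
  # displacement at which the torn region has fully softened
  eps_end <- reg$eps_ult[w] + reg$drop_width[w]
  F_res <- reg$residual[w] * caps[w]
  eps_others <- .region_strain_at_all(reg, F_res / reg$area_mm2)[-w]
  D_end <- eps_end * reg$L0[w] + sum(eps_others * reg$L0[-w])
  # when the intact regions' elastic recovery exceeds the torn region's
  # softening extension (snap-back), D_end can sit before the capacity
  # displacement; always pull through the peak
  D_cap <- sum(.region_strain_at_all(reg, caps[w] / reg$area_mm2) * reg$L0)
  D_stop <- max(D_end, D_cap) + tail_frames * rate / fps
  if (!is.null(max_displacement)) D_stop <- min(D_stop, max_displacement)

  disp <- seq(0, D_stop, by = rate / fps)
  states <- lapply(disp, function(d) solve_series_pull(phantom, d))
  load_g <- vapply(states, `[[`, numeric(1), "load_g")
  if (any(load_g > phantom$sensor_max_g))
    warning("load exceeds the ", phantom$sensor_max_g, " g sensor range")
  eps <- t(vapply(states, `[[`, numeric(5), "strains"))
  colnames(eps) <- reg$region
  tr <- data.frame(time_s = (seq_along(disp) - 1) / fps,
                   displacement_mm = disp,
                   load_g = load_g)
  attr(tr, "strain_truth") <- eps
  attr(tr, "post_failure") <- vapply(states, `[[`, logical(1), "post_failure")
  attr(tr, "fps") <- fps
  attr(tr, "preset") <- phantom$preset
  class(tr) <- c("load_trace", "data.frame")
  tr
}

#' @export
print.load_trace <- function(x, ...) {
  cat(sprintf("load_trace: %d frames @ %g fps, displacement 0-%.3g mm, peak load %.3g g\n",
              nrow(x), attr(x, "fps"), max(x$displacement_mm), max(x$load_g)))
  invisible(x)
}
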