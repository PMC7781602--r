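# Diffusion Green's-function kernels for ring/line/shell sources and
# quadrature of concentration fields from emitting regions.
#
# Everything in this file has a dimensional public surface; the actual
# quadrature happens in dimensionless "natural" units (D = 1, v = 1,
# Cth = 1) via the nd_* helpers in nd-core.R.

#' Free-space heat kernel
#'
#' Point-source Green's function of the diffusion equation in `m`
#' dimensions: `(4 pi D tau)^(-m/2) exp(-distance^2 / (4 D tau))`.
#'
#' @param m Spatial dimension (1, 2 or 3).
#' @param distance Source-observer distance (m); vectorized.
#' @param tau Elapsed time since emission (s); vectorized.
#' @param D Diffusivity (m^2/s).
#' @return Kernel value (1/m^m).
#' @export
point_propagator <- function(m, distance, tau, D) {
  if (any(tau <= 0)) stop_config("point_propagator requires tau > 0")
  (4 * pi * D * tau)^(-m / 2) * exp(-distance^2 / (4 * D * tau))
}

#' Ring/line/shell source kernel
#'
#' Concentration kernel `G_{n,m}(r; R, tau)` such that
#' `a * rho * dT * dR * G` is the concentration at in-plane radius `r`
#' contributed by the thin shell of cell-radius `R` emitting during `dT`, a
#' time `tau` in the past. The kernel is the angular integral of
#' [point_propagator()] over the source shell times the shell measure (a
#' mirror pair for cells in 1D, `2 pi R` for a ring, `4 pi R^2` for a
#' spherical shell), divided by the channel cross-section for thin
#' environments, and carrying an image factor of 2 when the diffusive
#' environment is semi-infinite (`m > n`). The 2D ring integral is evaluated
#' with the exponentially scaled modified Bessel function so it cannot
#' overflow at small `tau`.
#'
#' @param geom A [relay_geometry()].
#' @param r Observer radius (m).
#' @param R Source shell radius (m); vectorized.
#' @param tau Elapsed time (s); vectorized with `R`.
#' @param D Diffusivity (m^2/s).
#' @param h Medium thickness (m); required when `diff_dim < 3`.
#' @return Kernel values; units such that `a*rho*dT*dR*G` is molecules/m^3.
#' @export
ring_kernel <- function(geom, r, R, tau, D, h = NULL) {
  stopifnot(inherits(geom, "relay_geometry"))
  if (any(tau <= 0)) stop_config("ring_kernel requires tau > 0")
  if (needs_h(geom) && is.null(h))
    stop_config("geometry (%d,%d) requires 'h'", geom$cell_dim, geom$diff_dim)
  n <- max(length(R), length(tau), length(r))
  r <- rep_len(r, n); R <- rep_len(R, n); tau <- rep_len(tau, n)
  fourDt <- 4 * D * tau
  key <- paste(geom$cell_dim, geom$diff_dim)
  switch(key,
    "1 1" = (point_propagator(1, r - R, tau, D) +
             point_propagator(1, r + R, tau, D)) / h^2,
    "1 2" = 2 * (point_propagator(2, r - R, tau, D) +
                 point_propagator(2, r + R, tau, D)) / h,
    "2 2" = (2 * pi * R / h) * (pi * fourDt)^-1 *
            exp(-(r - R)^2 / fourDt) * i0e(2 * r * R / fourDt),
    "2 3" = 2 * (2 * pi * R) * (pi * fourDt)^(-3 / 2) *
            exp(-(r - R)^2 / fourDt) * i0e(2 * r * R / fourDt),
    "3 3" = {
      z <- 2 * r * R / fourDt
      small <- z < 1e-6
      out <- numeric(n)
      if (any(!small)) {
        i <- !small
        out[i] <- 4 * pi * R[i]^2 * (pi * fourDt[i])^(-3 / 2) / (2 * z[i]) *
          (exp(-(r[i] - R[i])^2 / fourDt[i]) - exp(-(r[i] + R[i])^2 / fourDt[i]))
      }
      if (any(small)) {
        i <- small  # sinh(z)/z -> 1 + z^2/6
        out[i] <- 4 * pi * R[i]^2 * (pi * fourDt[i])^(-3 / 2) *
          exp(-(r[i]^2 + R[i]^2) / fourDt[i]) * (1 + z[i]^2 / 6)
      }
      out
    },
    stop_config("unsupported geometry"))
}

#' Concentration created by a continuously emitting colony
#'
#' Time-and-shell quadrature of [ring_kernel()] for a colony of radius `ri`
#' whose cells emit continuously at rate `a` from time 0 ("simple
#' diffusion": no relay). The endpoint singularity of the kernel at small
#' elapsed time is removed exactly by the substitution `u = sqrt(t - T)`.
#'
#' @param r Observer radius (m); vectorized.
#' @param t Time since emission began (s); vectorized with `r`.
#' @param ri Colony radius (m).
#' @param params A [relay_params()].
#' @param geom A [relay_geometry()].
#' @param tol Absolute quadrature tolerance in units of `Cth`.
#' @return Concentration (molecules/m^3).
#' @export
concentration_from_colony <- function(r, t, ri, params, geom, tol = 1e-6) {
  sc <- natural_scales(params, geom)
  n <- max(length(r), length(t))
  r <- rep_len(r, n); t <- rep_len(t, n)
  vapply(seq_len(n), function(i) {
    params$Cth * nd_colony_conc(r[i] / sc$length, t[i] / sc$time,
                                ri / sc$length, geom, tol = tol)
  }, numeric(1))
}

#' Steady-state concentration of a continuously emitting colony
#'
#' Long-time limit of [concentration_from_colony()]. Finite only in 3D
#' diffusive environments; in 1D and 2D environments the concentration grows
#' without bound and `Inf` is returned.
#'
#' @inheritParams concentration_from_colony
#' @return Concentration (molecules/m^3), possibly `Inf`.
#' @export
steady_colony_concentration <- function(r, ri, params, geom, tol = 1e-8) {
  if (geom$diff_dim < 3) return(rep(Inf, length(r)))
  sc <- natural_scales(params, geom)
  vapply(r, function(ri_obs) {
    params$Cth * nd_steady_conc(ri_obs / sc$length, ri / sc$length, geom, tol = tol)
  }, numeric(1))
}

#' Concentration behind a moving activation front
#'
#' Green's-function quadrature of the full relay source history: cells at
#' radius `R` emit from the moment the information front `r_c(T)` passed
#' them (cells inside the initiating colony `ri` emit from time 0), so the
#' shell integral at past time `T` extends to `max(ri, r_c(T))`. Evaluating
#' at `r = r_c(t)` recovers the self-consistency condition that defines the
#' front; evaluating at arbitrary `r` gives the concentration (and hence
#' gradient) field used in the swarming comparison.
#'
#' @param r Observer radius (m); vectorized.
#' @param t Observation time (s), scalar; the front must cover `[0, t]`.
#' @param front A [front_trajectory] (from [propagate_front()]).
#' @param ri Initiating colony radius (m).
#' @inheritParams concentration_from_colony
#' @return Concentration (molecules/m^3).
#' @export
concentration_from_front <- function(r, t, front, ri, params, geom, tol = 1e-6) {
  stopifnot(inherits(front, "front_trajectory"))
  sc <- natural_scales(params, geom)
  tg <- front$time / sc$time
  rg <- front$radius / sc$length
  if (length(t) != 1) stop_config("'t' must be a single time")
  s <- t / sc$time
  if (s > max(tg) + 1e-9 && any(is.finite(rg)))
    stop_config("front does not cover [0, t]: t exceeds the front grid")
  vapply(r / sc$length, function(x) {
    params$Cth * nd_front_conc(x, s, tg, rg, ri / sc$length, geom)
  }, numeric(1))
}
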