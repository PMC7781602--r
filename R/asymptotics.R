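#' Asymptotic relay wave speed
#'
#' Closed-form asymptotic speed of the diffusive relay wave for each
#' supported dimensionality, with Heaviside activation:
#'
#' * cells 1D / diffusion 1D (channel of cross-section `h^2`):
#'   `v = sqrt(a rho D / (h^2 Cth))`
#' * cells 2D / diffusion 2D (film of thickness `h`):
#'   `v = sqrt(a rho D / (h Cth))`
#' * cells 3D / diffusion 3D: `v = sqrt(a rho D / Cth)`
#' * cells 2D / diffusion 3D (half-space): `v = 2 a rho / (pi Cth)`
#' * cells 1D / diffusion 2D (half-plane sheet of thickness `h`):
#'   `v = 2 a rho / (pi h Cth)`
#'
#' In matched dimensions the speed scales as `sqrt(D)` (Luther/Fisher-type
#' scaling); when diffusion has one dimension more than the cells, the speed
#' is independent of the diffusivity altogether.
#'
#' @param params A [relay_params()] object.
#' @param geom A [relay_geometry()] object.
#' @return Wave speed in m/s.
#' @examples
#' p <- relay_params(D = 1e-10, a = 1, rho = 1, Cth = 1 / (25 * 1e-6))
#' wave_speed(p, relay_geometry(2, 2))  # 2e-6 m/s
#' @export
wave_speed <- function(params, geom) {
  stopifnot(inherits(params, "relay_params"), inherits(geom, "relay_geometry"))
  with(params, {
    key <- paste(geom$cell_dim, geom$diff_dim)
    if (needs_h(geom) && is.null(h))
      stop_config("geometry (%d,%d) requires medium thickness 'h'",
                  geom$cell_dim, geom$diff_dim)
    switch(key,
      "1 1" = sqrt(a * rho * D / (h^2 * Cth)),
      "2 2" = sqrt(a * rho * D / (h * Cth)),
      "3 3" = sqrt(a * rho * D / Cth),
      "2 3" = 2 * a * rho / (pi * Cth),
      "1 2" = 2 * a * rho / (pi * h * Cth),
      stop_config("unsupported geometry"))
  })
}

#' Comoving concentration profile, thin (matched-dimension) medium
#'
#' Concentration as a function of the signed distance `r_tilde` from the
#' wave front (negative inside the wave) in the thin-medium limit:
#' linear growth inside the front, exponential decay with length `D/v`
#' beyond it, continuous with continuous first derivative at the front,
#' and exactly `Cth` at `r_tilde = 0`.
#'
#' @param r_tilde Signed distance from the front (m); vectorized.
#' @inheritParams wave_speed
#' @return Concentration (molecules/m^3).
#' @export
profile_thin <- function(r_tilde, params, geom = relay_geometry(2, 2)) {
  if (!geom$matched || geom$diff_dim > 2)
    stop_config("profile_thin applies to matched geometries (1,1) and (2,2)")
  v <- wave_speed(params, geom)
  heff <- if (geom$cell_dim == 1) params$h^2 else params$h
  with(params, {
    amp <- a * rho * D / (heff * v^2)  # == Cth for the self-consistent speed
    ifelse(r_tilde <= 0,
           -a * rho * r_tilde / (heff * v) + amp,
           amp * exp(-r_tilde * v / D))
  })
}

#' Comoving concentration profile, thick (half-space) medium
#'
#' In-plane concentration for cells in 2D under a deep medium, in its two
#' asymptotic limits: square-root growth `2 a rho sqrt(-r_tilde/(pi v D))`
#' well inside the front and an exponentially damped tail
#' `a rho sqrt(D/(pi r_tilde v^3)) exp(-v r_tilde / D)` well beyond it.
#' No closed form exists in the crossover `|r_tilde|` of order `D/v`; values
#' there are returned from the matching limit expression but flagged as
#' unreliable via the `reliable` attribute.
#'
#' @param r_tilde Signed distance from the front (m); vectorized.
#' @inheritParams wave_speed
#' @return Concentration (molecules/m^3) with attribute `reliable`
#'   (logical vector, `FALSE` where `|r_tilde| < D/v`).
#' @export
profile_thick <- function(r_tilde, params) {
  geom <- relay_geometry(2, 3)
  v <- wave_speed(params, geom)
  with(params, {
    inner <- 2 * a * rho * sqrt(pmax(-r_tilde, 0) / (pi * v * D))
    outer <- ifelse(r_tilde > 0,
                    a * rho * sqrt(D / (pi * pmax(r_tilde, .Machine$double.xmin) * v^3)) *
                      exp(-v * r_tilde / D),
                    NA_real_)
    out <- ifelse(r_tilde <= 0, inner, outer)
    attr(out, "reliable") <- abs(r_tilde) > D / v
    out
  })
}
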