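#' Wave initiation time of an emitting colony
#'
#' Time at which the concentration at the edge of a continuously emitting
#' colony of radius `ri` first reaches the activation threshold, computed by
#' Green's-function quadrature with Heaviside activation. In 1D and 2D
#' diffusive environments the wave always initiates (though the time grows
#' explosively for colonies much smaller than `D/v`); in 3D environments a
#' colony whose steady-state edge concentration stays below `Cth` never
#' initiates, which is decided from the steady-state quadrature rather than
#' from any finite time horizon.
#'
#' @param ri Initiating colony radius (m).
#' @inheritParams wave_speed
#' @param t_max Upper bound (s) for the bracketing search; only consulted in
#'   geometries without a steady state, where it guards runaway searches.
#' @return An object of class `initiation_result`: list with `initiated`,
#'   `t_init` (s, `NA` if not initiated), `ri`, `geometry` and `regime`
#'   (`"small_colony"`, `"crossover"`, `"plateau"` or `"below_critical"`).
#' @examples
#' p <- relay_params(D = 1e-10, a = 1, rho = 1, Cth = 1 / (25 * 1e-6))
#' initiation_time(10 * 1e-4, p, relay_geometry(2, 2))
#' @export
initiation_time <- function(ri, params, geom, t_max = Inf) {
  sc <- natural_scales(params, geom)
  b <- ri / sc$length
  s <- nd_initiation_time(b, geom, t_max = t_max / sc$time)
  if (is.na(s)) {
    res <- list(initiated = FALSE, t_init = NA_real_, ri = ri,
                geometry = geom, regime = "below_critical")
  } else {
    regime <- if (b < 1) "small_colony" else if (b >= 20) "plateau" else "crossover"
    res <- list(initiated = TRUE, t_init = s * sc$time, ri = ri,
                geometry = geom, regime = regime)
  }
  structure(res, class = "initiation_result")
}

#' @export
print.initiation_result <- function(x, ...) {
  if (x$initiated)
    cat(sprintf("Wave initiates: t_init = %.6g s (ri = %.4g m, %s regime)\n",
                x$t_init, x$ri, x$regime))
  else
    cat(sprintf("No initiation: colony ri = %.4g m is below the critical size\n", x$ri))
  invisible(x)
}

#' Critical colony size for wave initiation
#'
#' In 3D diffusive environments a continuously emitting colony reaches a
#' finite steady state, so there is a smallest radius whose steady-state
#' edge concentration equals `Cth`; below it no wave ever launches. For
#' cells in 2D under a half-space this critical radius is `D/v`; for cells
#' in 3D it is `sqrt(3) D/v` (the steady state of a uniformly emitting ball
#' is `a rho ri^2 / 3D` at its surface). In 1D and 2D environments the
#' concentration grows without bound and every colony initiates; `NA` is
#' returned.
#'
#' @inheritParams wave_speed
#' @return Critical radius (m), or `NA_real_` when every colony initiates.
#' @export
critical_radius <- function(params, geom) {
  if (geom$diff_dim < 3) return(NA_real_)
  sc <- natural_scales(params, geom)
  f <- function(b) nd_steady_conc(b, b, geom) - 1
  lo <- 0.05; hi <- 5
  while (f(hi) < 0) hi <- hi * 2
  while (f(lo) > 0) lo <- lo / 2
  b <- stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  b * sc$length
}

#' Closed-form limiting initiation times
#'
#' The analytic small- and large-colony limits of the initiation time, used
#' to cross-validate [initiation_time()]:
#'
#' * cells/diffusion 1D: `(pi D / 4 v^2) (D / (v ri))^2` for `ri << D/v`,
#'   plateau `2 D/v^2` for `ri >> D/v`;
#' * cells/diffusion 2D: `~ (ri^2/4D) exp((2D/(v ri))^2)` for small
#'   colonies (order-of-magnitude only: the prefactor is not sharp),
#'   plateau `2 D/v^2`;
#' * cells 1D, diffusion 2D: plateau `4 D / (pi v^2)`; the small-colony
#'   branch shares the exponential form of the (2,2) case and is returned
#'   with the same (order-of-magnitude) prefactor;
#' * cells 2D, diffusion 3D: plateau `4 D / (pi v^2)`; no initiation below
#'   the critical radius `D/v`, so no small-colony branch exists;
#' * cells/diffusion 3D: plateau `2 D/v^2`; near the critical radius
#'   `sqrt(3) D/v` the time diverges as
#'   `(D / 9 pi v^2) (v ri / D)^6 [ (v ri / (sqrt(3) D))^2 - 1 ]^-2`.
#'
#' @inheritParams initiation_time
#' @param regime `"small"` or `"large"` colony limit; `"auto"` picks by
#'   comparing `ri` with `D/v`.
#' @return Limiting time (s), or `NA_real_` outside tabulated regimes.
#' @export
tinit_asymptotic <- function(ri, params, geom, regime = c("auto", "small", "large")) {
  regime <- match.arg(regime)
  sc <- natural_scales(params, geom)
  b <- ri / sc$length
  if (regime == "auto") regime <- if (b < 1) "small" else "large"
  key <- paste(geom$cell_dim, geom$diff_dim)
  s <- switch(key,
    "1 1" = if (regime == "small") (pi / 4) / b^2 else 2,
    "2 2" = if (regime == "small") (b^2 / 4) * exp((2 / b)^2) else 2,
    "1 2" = if (regime == "small") (b^2 / 4) * exp((2 / b)^2) else 4 / pi,
    "2 3" = if (regime == "small") NA_real_ else 4 / pi,
    "3 3" = if (regime == "small") {
      if (b <= sqrt(3)) NA_real_ else (1 / (9 * pi)) * b^6 / ((b / sqrt(3))^2 - 1)^2
    } else 2)
  s * sc$time
}
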