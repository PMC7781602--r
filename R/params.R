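#' Physical parameters of a diffusive signaling relay
#'
#' Bundles the dimensional inputs of the relay model: signaling-molecule
#' diffusivity, per-cell emission rate, cell density, activation threshold,
#' and the optional environment descriptors (medium thickness, decay rate,
#' emission pulse duration, cell size, mean cell spacing). All quantities
#' are in SI units; concentrations are molecules per cubic meter throughout.
#'
#' @param D Diffusivity of the signaling molecule (m^2/s).
#' @param a Maximal per-cell emission rate (molecules/s).
#' @param rho Cell density: 1/m for cells on a line, 1/m^2 in a plane,
#'   1/m^3 in a volume (must match the cell dimension of the geometry the
#'   parameters are used with).
#' @param Cth Activation threshold concentration (molecules/m^3).
#' @param h Thickness of the extracellular medium (m). Required for thin-film
#'   and channel geometries; for a 1D channel the cross-section is `h^2`.
#' @param gamma First-order decay rate of the molecule (1/s); default 0.
#' @param tau Emission pulse duration (s); default `Inf` (continuous).
#' @param H Cell size (m), optional; used only in validity checks.
#' @param d Mean spacing between neighboring cells (m), optional; used only
#'   in validity checks.
#'
#' @return An object of class `relay_params`.
#' @seealso [relay_geometry()], [natural_scales()], [validity_report()]
#' @examples
#' relay_params(D = 1e-10, a = 40, rho = 1 / (50e-6)^2, Cth = 1e12)
#' @export
relay_params <- function(D, a, rho, Cth, h = NULL, gamma = 0, tau = Inf,
                         H = NULL, d = NULL) {
  for (nm in c("D", "a", "rho", "Cth")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val <= 0)
      stop_config("'%s' must be a single positive finite number", nm)
  }
  if (!is.null(h) && (!is.numeric(h) || h <= 0))
    stop_config("'h' must be positive when supplied")
  if (!is.numeric(gamma) || gamma < 0) stop_config("'gamma' must be >= 0")
  if (!is.numeric(tau) || tau <= 0) stop_config("'tau' must be > 0 (Inf for continuous emission)")
  structure(list(D = D, a = a, rho = rho, Cth = Cth, h = h,
                 gamma = gamma, tau = tau, H = H, d = d),
            class = "relay_params")
}

#' @export
print.relay_params <- function(x, ...) {
  cat("Relay model parameters (SI units):\n")
  cat(sprintf("  D     = %.4g m^2/s\n  a     = %.4g molecules/s\n", x$D, x$a))
  cat(sprintf("  rho   = %.4g (1/m^n)\n  Cth   = %.4g molecules/m^3\n", x$rho, x$Cth))
  if (!is.null(x$h)) cat(sprintf("  h     = %.4g m\n", x$h))
  if (x$gamma > 0) cat(sprintf("  gamma = %.4g 1/s\n", x$gamma))
  if (is.finite(x$tau)) cat(sprintf("  tau   = %.4g s\n", x$tau))
  invisible(x)
}

#' System dimensionality of cells and diffusion
#'
#' The relay dynamics are set by the dimension `n` of the cell distribution
#' and the dimension `m` of the diffusive environment. Supported pairs are
#' (1,1), (1,2), (2,2), (2,3) and (3,3). When `m > n` the environment is
#' semi-infinite on one side of the cell plane or line, and all kernels carry
#' the corresponding image factor of two.
#'
#' @param cell_dim Integer dimension of the cell distribution (1, 2 or 3).
#' @param diff_dim Integer dimension of the diffusive environment (>= cell_dim).
#' @return An object of class `relay_geometry`.
#' @examples
#' relay_geometry(2, 3)  # cells in a plane under a deep medium
#' @export
relay_geometry <- function(cell_dim, diff_dim) {
  pairs <- list(c(1, 1), c(1, 2), c(2, 2), c(2, 3), c(3, 3))
  if (!any(vapply(pairs, function(p) p[1] == cell_dim && p[2] == diff_dim, logical(1))))
    stop_config("unsupported geometry pair (%s,%s); supported: (1,1), (1,2), (2,2), (2,3), (3,3)",
                cell_dim, diff_dim)
  structure(list(cell_dim = as.integer(cell_dim), diff_dim = as.integer(diff_dim),
                 matched = cell_dim == diff_dim),
            class = "relay_geometry")
}

#' @export
print.relay_geometry <- function(x, ...) {
  cat(sprintf("Cells in %dD, diffusion in %dD%s\n", x$cell_dim, x$diff_dim,
              if (x$matched) "" else " (semi-infinite environment)"))
  invisible(x)
}

# Does this geometry need a medium thickness h?
needs_h <- function(geom) geom$diff_dim < 3

#' Cellular activation function
#'
#' Emission is `a * f(c)` with `f` either an all-or-none Heaviside switch at
#' the threshold `Cth`, or a graded Hill function
#' `f(c) = c^n / (c^n + Cth^n)` of order `n`. The Heaviside switch is the
#' infinite-order limit of the Hill family.
#'
#' @param kind `"heaviside"` or `"hill"`.
#' @param order Hill order (integer >= 1); ignored for Heaviside.
#' @return An object of class `relay_activation` with an `f(c, Cth)` evaluator.
#' @examples
#' act <- activation("hill", order = 2)
#' act$f(c = 2e12, Cth = 1e12)  # 0.8
#' @export
activation <- function(kind = c("heaviside", "hill"), order = NULL) {
  kind <- match.arg(kind)
  if (kind == "hill") {
    if (is.null(order) || order < 1) stop_config("Hill activation needs 'order' >= 1")
    order <- as.numeric(order)
    f <- function(c, Cth) {
      out <- numeric(length(c))
      pos <- c > 0
      out[pos] <- 1 / (1 + (Cth / c[pos])^order)
      out
    }
  } else {
    f <- function(c, Cth) as.numeric(c >= Cth)
  }
  structure(list(kind = kind, order = order, f = f), class = "relay_activation")
}

#' Natural length and time scales of a relay wave
#'
#' A relay wave with asymptotic speed `v` and molecular diffusivity `D` has
#' intrinsic scales `D/v` (length) and `D/v^2` (time): the width of the
#' concentration boundary layer at the front and the time the front takes to
#' cross it. All dimensionless computations in the package use these units.
#'
#' @inheritParams wave_speed
#' @return A list with elements `length` (m), `time` (s) and `speed` (m/s).
#' @examples
#' p <- relay_params(D = 1e-10, a = 1, rho = 1, Cth = 1 / (25 * 1e-6))
#' natural_scales(p, relay_geometry(2, 2))  # h Cth / (a rho) = 25 s
#' @export
natural_scales <- function(params, geom) {
  v <- wave_speed(params, geom)
  list(length = params$D / v, time = params$D / v^2, speed = v)
}

#' Check the separation-of-scales assumptions of the relay model
#'
#' The continuum relay description assumes well-separated scales: cell
#' spacing and cell size small compared to `D/v`, medium thickness clearly
#' thin or thick relative to `D/v`, decay slow compared to `v^2/D`, and
#' emission pulses long compared to `D/v^2`. This reports each dimensionless
#' metric with a pass/fail flag. The model itself gives no numeric cutoff
#' for "much less/greater than"; the defaults used here (`lower = 0.25`,
#' `upper = 4`) are package conventions and can be changed.
#'
#' @inheritParams wave_speed
#' @param lower Threshold below which a "<<" criterion is considered met.
#' @param upper Threshold above which a ">>" criterion is considered met.
#' @return A data frame with columns `check`, `value`, `requirement`,
#'   `pass` (logical, `NA` when the needed parameter was not supplied).
#' @examples
#' p <- relay_params(D = 1.25e-10, a = 1, rho = 1,
#'                   Cth = pi * 1.73e-6 / 2, d = 50e-6, h = 2e-3)
#' validity_report(p, relay_geometry(2, 3))
#' @export
validity_report <- function(params, geom, lower = 0.25, upper = 4) {
  v <- wave_speed(params, geom)
  D <- params$D
  num <- function(x) if (is.null(x)) NA_real_ else x
  continuum <- num(params$d) * v / (4 * D)
  thin <- num(params$h) * v / D
  cellh <- num(params$H) * v / D
  decay <- params$gamma * D / v^2
  pulse <- if (is.finite(params$tau)) params$tau * v^2 / D else Inf
  thin_req <- if (geom$matched && geom$diff_dim < 3)
    sprintf("< %.3g (thin medium)", lower) else sprintf("> %.3g (thick medium)", upper)
  thin_pass <- if (geom$matched && geom$diff_dim < 3) thin < lower else thin > upper
  if (geom$diff_dim == 3 && geom$cell_dim == 3) { # no thickness in play
    thin <- NA_real_; thin_pass <- NA; thin_req <- "not applicable"
  }
  out <- data.frame(
    check = c("continuum", "thin_medium", "cell_thickness", "decay", "pulse"),
    value = c(continuum, thin, cellh, decay, pulse),
    requirement = c(sprintf("< %.3g", lower), thin_req, sprintf("< %.3g", lower),
                    sprintf("< %.3g", lower), sprintf("> %.3g", upper)),
    pass = c(continuum < lower, thin_pass, cellh < lower, decay < lower, pulse > upper),
    stringsAsFactors = FALSE)
  out
}

#' Convert a concentration in molecules/m^3 to molar units
#'
#' Convenience helper only; all core computations stay in molecules/m^3.
#'
#' @param c_molecules_per_m3 Concentration in molecules/m^3.
#' @return Concentration in mol/L.
#' @export
molecules_per_m3_to_molar <- function(c_molecules_per_m3) {
  c_molecules_per_m3 / 6.02214076e23 / 1000
}
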