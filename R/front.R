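# Self-consistent propagation of the information front r_c(t): the curve
# along which the concentration, generated by the full history of activated
# cells, equals the activation threshold.

new_front_trajectory <- function(time, radius, ri, dt, model, geom, t_init) {
  structure(list(time = time, radius = radius, ri = ri, dt = dt,
                 model = model, geometry = geom, t_init = t_init),
            class = "front_trajectory")
}

#' @export
print.front_trajectory <- function(x, ...) {
  ok <- is.finite(x$radius)
  cat(sprintf("Information front (%s model), %d grid points\n", x$model, length(x$time)))
  if (any(ok))
    cat(sprintf("  t in [%.4g, %.4g] s, r in [%.4g, %.4g] m\n",
                min(x$time[ok]), max(x$time[ok]), min(x$radius[ok]), max(x$radius[ok])))
  invisible(x)
}

#' @export
as.data.frame.front_trajectory <- function(x, ...) {
  data.frame(time = x$time, radius = x$radius)
}

#' Interpolate a front trajectory
#'
#' Linear interpolation between the stored grid points; times before the
#' first grid point return the initiating-colony radius.
#'
#' @param front A `front_trajectory`.
#' @param t Times (s).
#' @return Front radii (m).
#' @export
front_radius <- function(front, t) {
  ok <- is.finite(front$radius)
  if (!any(ok)) return(rep(NA_real_, length(t)))
  if (sum(ok) == 1) {
    out <- rep(front$radius[ok], length(t))
  } else {
    out <- stats::approx(front$time[ok], front$radius[ok], xout = t, rule = 2)$y
  }
  out[t < min(front$time[ok])] <- front$ri
  out
}

#' Propagate the relay information front
#'
#' Self-consistent front propagation with Heaviside activation: starting
#' from the initiation time (concentration at the colony edge reaches
#' threshold), the front radius at each grid time `t_init + k*dt` solves the
#' threshold condition with the concentration generated by all cells the
#' front has already passed (plus the permanently emitting colony). The
#' contribution of the current, not-yet-determined step is handled by a
#' fixed-point iteration initialized from linear extrapolation; root-finding
#' in the radius uses the monotone decay of concentration beyond the source
#' region.
#'
#' @param params A [relay_params()].
#' @param geom A [relay_geometry()].
#' @param ri Initiating colony radius (m).
#' @param t_end End time (s).
#' @param dt Grid step (s); default `D/(10 v^2)`, which converges the front
#'   (halving it moves the final radius by well under 0.5 percent).
#' @return A `front_trajectory` whose first point is `(t_init, ri)`.
#' @examples
#' p <- relay_params(D = 1e-10, a = 1, rho = 1, Cth = 1 / (25 * 1e-6))
#' g <- relay_geometry(2, 2)
#' sc <- natural_scales(p, g)
#' fr <- propagate_front(p, g, ri = 4 * sc$length, t_end = 10 * sc$time)
#' @export
propagate_front <- function(params, geom, ri, t_end, dt = NULL) {
  sc <- natural_scales(params, geom)
  b <- ri / sc$length
  if (is.null(dt)) dt <- sc$time / 10
  dts <- dt / sc$time
  s_end <- t_end / sc$time
  init <- initiation_time(ri, params, geom)
  if (!init$initiated)
    stop_config("wave does not initiate: ri = %.4g m is below the critical radius %.4g m (see initiation_time/critical_radius)",
                ri, critical_radius(params, geom))
  s0 <- init$t_init / sc$time
  if (s_end <= s0)
    return(new_front_trajectory(init$t_init, ri, ri, dt, "relay", geom, init$t_init))
  nd <- nd_propagate_front(b, s0, s_end, dts, geom)
  new_front_trajectory(nd$t * sc$time, nd$r * sc$length, ri, dt, "relay",
                       geom, init$t_init)
}

# Dimensionless front propagation loop. The current step's radius enters
# the threshold condition both as the observer point and as the endpoint of
# the source history; both roles are given the same unknown x, and the
# resulting scalar equation is solved directly (concentration decreases in
# the observer radius faster than the thin current-step source sliver adds
# to it, so the residual is monotone and the root unique).
nd_propagate_front <- function(b, s0, s_end, dts, geom) {
  nstep <- ceiling((s_end - s0) / dts - 1e-9)
  tg <- s0 + dts * (0:nstep)
  rg <- c(b, rep(NA_real_, nstep))
  for (k in seq_len(nstep)) {
    s <- tg[k + 1]
    guess <- if (k >= 2) max(b, 2 * rg[k] - rg[k - 1]) else b + dts
    prev <- rg[k]
    tcur <- tg[seq_len(k + 1)]
    f <- function(x) nd_front_conc(x, s, tcur, c(rg[seq_len(k)], x), b, geom) - 1
    fprev <- f(prev)
    if (fprev <= 0) { root <- prev } else {
      lo <- max(prev, guess - 0.3 * dts); flo <- if (lo > prev) f(lo) else fprev
      if (flo <= 0) {       # root between prev and lo
        root <- stats::uniroot(f, c(prev, lo), f.lower = fprev, f.upper = flo,
                               tol = 2e-6)$root
      } else {
        hi <- guess + 0.3 * dts; fhi <- f(hi)
        nexp <- 0L
        while (fhi > 0 && nexp < 80L) {
          lo <- hi; flo <- fhi; hi <- hi + 2 * dts; fhi <- f(hi); nexp <- nexp + 1L
        }
        if (nexp >= 80L) stop_config("front root not bracketed at step %d", k)
        root <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                               tol = 2e-6)$root
      }
    }
    rg[k + 1] <- root
  }
  list(t = tg, r = rg)
}

#' Information front under simple diffusive signaling
#'
#' Front of the no-relay model: only the cells on the initiating colony
#' emit, and the "front" is the outermost radius at which the accumulated
#' concentration equals the threshold. In 3D diffusive environments this
#' front decelerates toward the finite steady-state level set (and is empty
#' for thresholds above the steady-state maximum); grid times at which no
#' radius `>= ri` has reached threshold get `NA`.
#'
#' @inheritParams propagate_front
#' @param dt Grid step (s); default `D/(10 v^2)`.
#' @return A `front_trajectory` with model `"simple_diffusion"`.
#' @export
simple_diffusion_front <- function(params, geom, ri, t_end, dt = NULL) {
  sc <- natural_scales(params, geom)
  b <- ri / sc$length
  if (is.null(dt)) dt <- sc$time / 10
  tgrid <- seq(dt, t_end, by = dt)
  sgrid <- tgrid / sc$time
  ss <- if (geom$diff_dim == 3) nd_steady_conc(b, b, geom) else Inf
  rad <- rep(NA_real_, length(sgrid))
  if (ss > 1) {
    prev <- b
    for (i in seq_along(sgrid)) {
      s <- sgrid[i]
      f <- function(x) nd_colony_conc(x, s, b, geom) - 1
      if (f(b) < 0) next  # threshold not yet reached anywhere outside colony
      hi <- max(prev, b) + 1
      while (f(hi) > 0) hi <- b + 2 * (hi - b)
      rad[i] <- stats::uniroot(f, c(b, hi), tol = 1e-8)$root
      prev <- rad[i]
    }
  }
  new_front_trajectory(tgrid, rad * sc$length, ri, dt, "simple_diffusion",
                       geom, NA_real_)
}

#' Front speed by least squares
#'
#' Slope of radius versus time over a window, the standard way a wave speed
#' is read off a propagating front.
#'
#' @param front A `front_trajectory`.
#' @param window Length-2 numeric: time window (s) inside the front support.
#' @return Speed (m/s).
#' @export
estimate_speed <- function(front, window) {
  sel <- front$time >= window[1] & front$time <= window[2] & is.finite(front$radius)
  if (sum(sel) < 5) stop_config("speed window contains fewer than 5 front points")
  unname(stats::coef(stats::lm(front$radius[sel] ~ front$time[sel]))[2])
}
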