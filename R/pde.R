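# Direct finite-volume integration of the relay reaction-diffusion
# equation, used as the independent oracle for the Green's-function
# machinery and for graded (Hill) activation where no closed form exists.
#
# Discretization: conservative finite volumes on the radial (and, for the
# half-space geometry, vertical) grid; diffusion is treated implicitly
# (backward Euler, sparse Cholesky factored once since dt is constant), the
# bounded source term explicitly with one corrector pass. The singular
# in-plane cell layer is never discretized: for the half-space it becomes
# the flux boundary condition -D dc/dz|_{z=0} = a rho f(c), i.e. a source
# in the bottom cell row of magnitude a rho f / dz.

new_sim_result <- function(snapshots, front, params, geom, act, grid, mass) {
  structure(list(snapshots = snapshots, front = front, params = params,
                 geometry = geom, activation = act, grid = grid, mass = mass),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Relay PDE simulation: cells %dD / diffusion %dD, %s activation\n",
              x$geometry$cell_dim, x$geometry$diff_dim, x$activation$kind))
  cat(sprintf("  grid: %s; t_end = %.4g s\n",
              paste(names(x$grid), unlist(lapply(x$grid, function(g) format(signif(g, 4)))),
                    sep = "=", collapse = ", "),
              max(x$front$time)))
  invisible(x)
}

# level-set radius of c = 1 (natural units) on a radial profile
.level_set_radius <- function(x, c, thr = 1) {
  above <- which(c >= thr)
  if (!length(above)) return(NA_real_)
  i <- max(above)
  if (i == length(c)) return(x[i])
  # linear interpolation to the crossing
  x[i] + (thr - c[i]) * (x[i + 1] - x[i]) / (c[i + 1] - c[i])
}

# symmetric sparse backward-Euler operator  diag(V (1 + dt*gamma)) + dt*K
.be_operator <- function(ii, jj, ww, V, dt, gamma) {
  n <- length(V)
  K <- Matrix::sparseMatrix(i = c(ii, jj, ii, jj), j = c(jj, ii, ii, jj),
                            x = c(-ww, -ww, ww, ww), dims = c(n, n))
  M <- Matrix::Diagonal(n, V * (1 + dt * gamma)) + dt * K
  Matrix::Cholesky(methods::as(Matrix::forceSymmetric(M), "CsparseMatrix"))
}

#' Simulate a relay wave in a thin medium (matched dimensions)
#'
#' Direct numerical integration of the relay equation in the thin-medium
#' limit (cells and diffusion share their dimensionality; the medium
#' thickness only rescales the source). Cells inside the initiating colony
#' emit from time 0; all other cells emit `a f(c)` with `f` the chosen
#' activation function.
#'
#' @param params A [relay_params()].
#' @param geom [relay_geometry()] (1,1) or (2,2).
#' @param act An [activation()]; default Heaviside.
#' @param ri Initiating colony radius (m); default `4 D/v`.
#' @param t_end End time (s).
#' @param dr,dt Grid and time steps (m, s); defaults `D/(20 v)`, `D/(20 v^2)`.
#' @param r_max Domain size (m); default `1.2 v t_end + 10 D/v`.
#' @param snapshot_times Times (s) at which to store radial profiles.
#' @param relay If `FALSE`, activation is disabled and only the colony
#'   emits (used for oracle comparisons against
#'   [concentration_from_colony()]).
#' @return A `sim_result` with snapshots, the `c = Cth` level-set front,
#'   and a mass-balance table.
#' @export
simulate_thin <- function(params, geom = relay_geometry(2, 2),
                          act = activation("heaviside"), ri = NULL,
                          t_end, dr = NULL, dt = NULL, r_max = NULL,
                          snapshot_times = NULL, relay = TRUE) {
  if (!geom$matched || geom$diff_dim > 2)
    stop_config("simulate_thin handles matched geometries (1,1) and (2,2)")
  sc <- natural_scales(params, geom)
  if (is.null(ri)) ri <- 4 * sc$length
  b <- ri / sc$length
  s_end <- t_end / sc$time
  dx <- if (is.null(dr)) 0.05 else dr / sc$length
  ds <- if (is.null(dt)) 0.05 else dt / sc$time
  xmax <- if (is.null(r_max)) 1.2 * s_end + 10 else r_max / sc$length
  gam <- params$gamma * sc$time
  n_dim <- geom$cell_dim

  nx <- ceiling(xmax / dx)
  xc <- (seq_len(nx) - 0.5) * dx
  xf <- seq_len(nx - 1) * dx
  af <- if (n_dim == 2) xf else rep(1, nx - 1)
  V <- if (n_dim == 2) xc * dx else rep(dx, nx)
  ch <- .be_operator(seq_len(nx - 1), seq_len(nx - 1) + 1, af / dx, V, ds, gam)

  colony <- xc <= b
  src_of <- function(c) {
    f <- if (relay) act$f(c, 1) else numeric(nx)
    f[colony] <- 1
    f
  }
  nstep <- ceiling(s_end / ds)
  snap_s <- if (is.null(snapshot_times)) {
    pretty_s <- seq(s_end / 4, s_end, length.out = 4)
  } else snapshot_times / sc$time
  cvec <- numeric(nx)
  front_t <- numeric(nstep); front_r <- numeric(nstep)
  snaps <- list()
  emitted <- 0
  mass_rows <- list()
  for (k in seq_len(nstep)) {
    f0 <- src_of(cvec)
    c1 <- as.numeric(Matrix::solve(ch, V * (cvec + ds * f0)))
    f1 <- src_of(c1)  # corrector on the updated activation pattern
    cvec <- as.numeric(Matrix::solve(ch, V * (cvec + ds * f1)))
    emitted <- emitted + ds * sum(V * f1)
    s <- k * ds
    front_t[k] <- s
    front_r[k] <- .level_set_radius(xc, cvec)
    if (any(abs(s - snap_s) < ds / 2)) {
      snaps[[length(snaps) + 1]] <- data.frame(
        t = s * sc$time, r = xc * sc$length, c = cvec * params$Cth)
    }
    if (k %% max(1L, nstep %/% 8L) == 0L || k == nstep)
      mass_rows[[length(mass_rows) + 1]] <-
        data.frame(t = s * sc$time, total = sum(V * cvec), emitted = emitted)
  }
  front <- new_front_trajectory(front_t * sc$time, front_r * sc$length, ri,
                                ds * sc$time, if (relay) "relay" else "simple_diffusion",
                                geom, NA_real_)
  new_sim_result(snaps, front, params, geom, act,
                 list(dr = dx * sc$length, dt = ds * sc$time, r_max = xmax * sc$length),
                 do.call(rbind, mass_rows))
}

#' Simulate a relay wave for planar cells under a deep medium
#'
#' Axisymmetric `(r, z)` integration on the half-space `z >= 0` for cells
#' in 2D with 3D diffusion. The cell monolayer enters as the flux boundary
#' condition at `z = 0`: a source `a rho f(c)/dz` in the bottom cell row,
#' with activation evaluated on the bottom-row concentration. The vertical
#' grid is geometrically stretched away from the cell plane.
#'
#' @inheritParams simulate_thin
#' @param dz0 Vertical grid step at the cell plane (m); default `D/(10 v)`.
#' @param z_ratio Geometric stretch factor of the vertical grid.
#' @param z_max Vertical extent (m); default `6 sqrt(D t_end)`.
#' @export
simulate_thick <- function(params, geom = relay_geometry(2, 3),
                           act = activation("heaviside"), ri = NULL,
                           t_end, dr = NULL, dt = NULL, r_max = NULL,
                           dz0 = NULL, z_ratio = 1.15, z_max = NULL,
                           snapshot_times = NULL, relay = TRUE) {
  if (!(geom$cell_dim == 2 && geom$diff_dim == 3))
    stop_config("simulate_thick handles cells in 2D with diffusion in 3D")
  sc <- natural_scales(params, geom)
  if (is.null(ri)) ri <- 4 * sc$length
  b <- ri / sc$length
  s_end <- t_end / sc$time
  dx <- if (is.null(dr)) 0.1 else dr / sc$length
  ds <- if (is.null(dt)) 0.05 else dt / sc$time
  xmax <- if (is.null(r_max)) 1.2 * s_end + 10 else r_max / sc$length
  zmax <- if (is.null(z_max)) max(6 * sqrt(s_end), 10) else z_max / sc$length
  dz1 <- if (is.null(dz0)) 0.1 else dz0 / sc$length
  gam <- params$gamma * sc$time
  arho <- pi / 2  # a rho in units of Cth v: the half-space speed relation

  nx <- ceiling(xmax / dx)
  xc <- (seq_len(nx) - 0.5) * dx
  xf <- seq_len(nx - 1) * dx
  dz <- dz1 * z_ratio^(0:200)
  dz <- dz[cumsum(dz) - dz < zmax]
  nz <- length(dz)
  zf <- cumsum(dz)            # upper faces
  zc <- zf - dz / 2
  idx <- function(i, j) (j - 1L) * nx + i

  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (j in seq_len(nz)) {    # radial faces, layer j
    ii <- c(ii, idx(seq_len(nx - 1), j))
    jj <- c(jj, idx(seq_len(nx - 1) + 1, j))
    ww <- c(ww, xf * dz[j] / dx)
  }
  for (j in seq_len(nz - 1)) { # vertical faces between layers j, j+1
    ii <- c(ii, idx(seq_len(nx), j))
    jj <- c(jj, idx(seq_len(nx), j + 1))
    ww <- c(ww, xc * dx / (zc[j + 1] - zc[j]))
  }
  V <- as.vector(outer(xc * dx, dz))
  ch <- .be_operator(ii, jj, ww, V, ds, gam)

  colony <- xc <= b
  bot <- seq_len(nx)
  row2 <- nx + seq_len(nx)
  # cell-plane concentration: linear extrapolation of the first two cell
  # rows to z = 0 (the bottom cell center sits at dz/2, where the flux
  # boundary layer makes the raw value a biased estimate of c(z=0))
  surf <- function(cfull) {
    pmax(cfull[bot] + (cfull[bot] - cfull[row2]) * zc[1] / (zc[2] - zc[1]), 0)
  }
  src_of <- function(cfull) {
    cb <- surf(cfull)
    f <- if (relay) act$f(cb, 1) else numeric(nx)
    f[colony] <- 1
    s <- numeric(nx * nz)
    s[bot] <- arho * f / dz[1]
    list(s = s, f = f)
  }
  nstep <- ceiling(s_end / ds)
  snap_s <- if (is.null(snapshot_times)) seq(s_end / 4, s_end, length.out = 4)
            else snapshot_times / sc$time
  cvec <- numeric(nx * nz)
  front_t <- numeric(nstep); front_r <- numeric(nstep)
  snaps <- list(); emitted <- 0; mass_rows <- list()
  for (k in seq_len(nstep)) {
    s0 <- src_of(cvec)
    c1 <- as.numeric(Matrix::solve(ch, V * (cvec + ds * s0$s)))
    s1 <- src_of(c1)
    cvec <- as.numeric(Matrix::solve(ch, V * (cvec + ds * s1$s)))
    emitted <- emitted + ds * arho * sum(s1$f * xc) * dx  # per-area rate x area measure
    s <- k * ds
    front_t[k] <- s
    front_r[k] <- .level_set_radius(xc, surf(cvec))
    if (any(abs(s - snap_s) < ds / 2)) {
      snaps[[length(snaps) + 1]] <- data.frame(
        t = s * sc$time, r = rep(xc, nz) * sc$length,
        z = rep(zc, each = nx) * sc$length, c = cvec * params$Cth)
    }
    if (k %% max(1L, nstep %/% 8L) == 0L || k == nstep)
      mass_rows[[length(mass_rows) + 1]] <-
        data.frame(t = s * sc$time, total = sum(V * cvec),
                   emitted = emitted)
  }
  front <- new_front_trajectory(front_t * sc$time, front_r * sc$length, ri,
                                ds * sc$time, if (relay) "relay" else "simple_diffusion",
                                geom, NA_real_)
  new_sim_result(snaps, front, params, geom, act,
                 list(dr = dx * sc$length, dt = ds * sc$time,
                      r_max = xmax * sc$length, nz = nz, z_max = zmax * sc$length),
                 do.call(rbind, mass_rows))
}

#' Wave speed from a simulated front
#'
#' Least-squares slope of the `c = Cth` level-set radius over the last 20
#' percent of `[0, t_measure]`.
#'
#' @param sim A `sim_result`.
#' @param t_measure Measurement time (s); default the simulation end.
#' @return Speed (m/s).
#' @export
measure_wave_speed <- function(sim, t_measure = NULL) {
  if (is.null(t_measure)) t_measure <- max(sim$front$time)
  sel <- is.finite(sim$front$radius) & sim$front$time <= t_measure
  if (!any(sel)) stop_config("front has not formed by t_measure")
  if (max(sim$front$radius[sel]) <= sim$front$ri)
    stop_config("front has not detached from the initiating colony")
  estimate_speed(sim$front, c(0.8, 1) * t_measure)
}
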