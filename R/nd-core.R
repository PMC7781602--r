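# Dimensionless computational core.
#
# All quantities here are expressed in natural units: lengths in D/v, times
# in D/v^2, concentrations in Cth, where v is the asymptotic Heaviside wave
# speed of the geometry at hand. In these units the colony/front
# concentration integrals become parameter-free:
#
#   matched dims (m == n):    c(x, s) = int_0^s  P_n(x, b(T), s - T) dT
#   mismatched (m == n + 1):  c(x, s) = int_0^s  sqrt(pi/(4 (s-T))) * 2/pi *
#                                        pi * ... = sqrt(pi) int_0^sqrt(s) P_n du
#
# with u = sqrt(s - T) and P_n(x, b, sigma) the mass, within cell-radius b,
# of an isotropic n-D Gaussian of per-axis variance 2*sigma centered at
# radius x -- i.e. the shell integral of the heat kernel. The prefactors
# absorb exactly the Eq-of-motion normalizations (a rho / h^p = Cth v^2 / D
# for matched dims, 2 a rho = pi v Cth for mismatched dims).

# --- Gaussian disk/segment/ball mass -----------------------------------

# P_1: mass of a 1D Gaussian (var 2*sigma) centered at x within [-b, b].
.pmass1 <- function(x, b, sigma) {
  s <- sqrt(4 * sigma)
  0.5 * (erf((b - x) / s) + erf((b + x) / s))
}

# P_2: mass of a 2D Gaussian centered at radius x within the disk of
# radius b. Windowed Gauss-Legendre integration of the ring density
# R/(2 sigma) exp(-(R-x)^2/(4 sigma)) I0e(x R/(2 sigma)); the window
# half-width 17*sqrt(sigma) keeps the truncation error below 1e-30 while
# 40 nodes resolve the Gaussian to ~1e-9 (checked against the noncentral
# chi-square CDF).
.pmass2 <- function(x, b, sigma) {
  n <- max(length(x), length(b), length(sigma))
  x <- rep_len(x, n); b <- rep_len(b, n); sigma <- rep_len(sigma, n)
  out <- numeric(n)
  w <- 17 * sqrt(sigma)
  lo <- pmax(0, pmin(b, x - w))
  hi <- pmin(b, x + w)   # ring density is negligible beyond x + w
  ok <- hi > lo & (x - b) < w & sigma > 0
  if (any(ok)) {
    g <- gauss_legendre_01(40)
    k <- length(g$x)
    lw <- hi[ok] - lo[ok]
    R <- outer(g$x, lw) + rep(lo[ok], each = k)
    sg <- rep(sigma[ok], each = k)
    xg <- rep(x[ok], each = k)
    p <- R / (2 * sg) * exp(-(R - xg)^2 / (4 * sg)) * i0e(xg * R / (2 * sg))
    dim(p) <- c(k, sum(ok))
    out[ok] <- colSums(p * g$w) * lw
  }
  out
}

# P_3: mass of a 3D Gaussian centered at radius x within the ball of
# radius b; closed form from the radial shell integral.
.pmass3 <- function(x, b, sigma) {
  n <- max(length(x), length(b), length(sigma))
  x <- rep_len(x, n); b <- rep_len(b, n); sigma <- rep_len(sigma, n)
  s <- sqrt(4 * sigma)
  out <- numeric(n)
  # wide-Gaussian branch: the erf/exp closed form cancels catastrophically
  # when the Gaussian is much wider than both radii; use the ball-volume
  # times density expansion (relative error O((b^2/sigma)^2)).
  wide <- s > 45 * (b + x)
  if (any(wide)) {
    i <- wide
    out[i] <- (4 / 3) * pi * b[i]^3 * (4 * pi * sigma[i])^(-3 / 2) *
      exp(-x[i]^2 / (4 * sigma[i])) *
      (1 + (b[i]^2 / 10) * (x[i]^2 / (4 * sigma[i]^2) - 3 / (2 * sigma[i])))
    x <- x[!i]; b <- b[!i]; sigma <- sigma[!i]; s <- s[!i]
    if (!length(x)) return(pmin(pmax(out, 0), 1))
    sub <- which(!i)
  } else sub <- seq_len(n)
  tmp <- numeric(length(x))
  ctr <- x < 1e-8 * pmax(b, s)  # on-axis limit (chi distribution, 3 dof)
  if (any(ctr)) {
    q <- b[ctr] / sqrt(2 * sigma[ctr])
    tmp[ctr] <- erf(q / sqrt(2)) - sqrt(2 / pi) * q * exp(-q^2 / 2)
  }
  if (any(!ctr)) {
    i <- !ctr; xi <- x[i]; bi <- b[i]; si <- s[i]
    A <- -si^2 / 2 * (exp(-(bi - xi)^2 / si^2) - exp(-xi^2 / si^2)) +
      xi * sqrt(pi) * si / 2 * (erf((bi - xi) / si) + erf(xi / si))
    B <- -si^2 / 2 * (exp(-(bi + xi)^2 / si^2) - exp(-xi^2 / si^2)) -
      xi * sqrt(pi) * si / 2 * (erf((bi + xi) / si) - erf(xi / si))
    tmp[i] <- (A - B) / (xi * sqrt(pi) * si)
  }
  out[sub] <- tmp
  pmin(pmax(out, 0), 1)
}

.pmass <- function(n_dim, x, b, sigma) {
  switch(n_dim, .pmass1(x, b, sigma), .pmass2(x, b, sigma), .pmass3(x, b, sigma))
}

# --- colony (simple-diffusion) concentration ---------------------------

# Dimensionless concentration at radius x, time s, from a colony of radius
# b emitting continuously from time 0. u = sqrt(s - T) substitution.
nd_colony_conc <- function(x, s, b, geom, tol = 1e-6) {
  if (s <= 0 || b <= 0) return(0)
  n_dim <- geom$cell_dim
  if (geom$matched) {
    f <- function(u) 2 * u * .pmass(n_dim, x, b, u^2)
  } else {
    f <- function(u) sqrt(pi) * .pmass(n_dim, x, b, u^2)
  }
  umax <- sqrt(s)
  # long-time tails (log-type growth in 1D/2D environments): integrate the
  # bulk over [0, u0] and the smooth tail in xi = log(u) panels.
  u0 <- min(umax, 10 * max(b, x, 1))
  val <- stats::integrate(f, 0, u0, rel.tol = 1e-8, abs.tol = tol / 10,
                          subdivisions = 500L)$value
  if (umax > u0) {
    val <- val + stats::integrate(function(xi) exp(xi) * f(exp(xi)),
                                  log(u0), log(umax), rel.tol = 1e-8,
                                  abs.tol = tol / 10, subdivisions = 500L)$value
  }
  val
}

# Steady state (m = 3 environments only): s -> Inf limit.
nd_steady_conc <- function(x, b, geom, tol = 1e-8) {
  n_dim <- geom$cell_dim
  pref <- if (geom$matched) function(u) 2 * u else function(u) rep(sqrt(pi), length(u))
  f <- function(u) pref(u) * .pmass(n_dim, x, b, u^2)
  u0 <- 10 * max(b, x, 1)
  stats::integrate(f, 0, u0, rel.tol = 1e-9, abs.tol = tol / 10,
                   subdivisions = 500L)$value +
    stats::integrate(function(w) f(1 / w) / w^2, 0, 1 / u0, rel.tol = 1e-9,
                     abs.tol = tol / 10, subdivisions = 500L)$value
}

# --- concentration from a moving front ---------------------------------

# Shell upper limit max(b, r_c(T)) for a front tabulated on (tg, rg);
# T < tg[1] (before initiation) -> b.
.front_rmax <- function(Tq, tg, rg, b) {
  if (length(tg) == 0 || all(!is.finite(rg))) return(rep(b, length(Tq)))
  r <- stats::approx(tg, rg, xout = Tq, rule = 2)$y
  pmax(b, r)
}

# Dimensionless concentration at (x, s) given the emission history encoded
# by the front grid. Composite Gauss-Legendre in u = sqrt(s - T): one panel
# per front step for the most recent `recent` steps (where the kernel
# varies fastest), geometrically coarsened panels for older history, and a
# kink-respecting split at the initiation time.
nd_front_conc <- function(x, s, tg, rg, b, geom, recent = 40L, nodes = 6L) {
  if (s <= 0) return(0)
  keep <- tg < s - .Machine$double.eps
  tk <- tg[keep]
  u_knots <- sqrt(s - c(tk, 0))          # ascending-in-T; includes T = 0
  u_knots <- sort(unique(c(0, u_knots)))
  # retain the `recent` smallest knots (most recent history), coarsen the rest
  if (length(u_knots) > recent + 2L) {
    head_k <- u_knots[seq_len(recent)]
    u_from <- u_knots[recent]
    u_max <- u_knots[length(u_knots)]
    u_init <- sqrt(max(s - min(tg), 0))   # kink where relay history begins
    tail_k <- u_from * 1.3^(seq_len(ceiling(log(u_max / u_from) / log(1.3))))
    tail_k <- tail_k[tail_k < u_max]
    u_knots <- sort(unique(c(head_k, tail_k, u_init[u_init > u_from], u_max)))
  }
  # sparse histories (few grid steps) must still be integrated accurately:
  # enforce a minimum panel count
  if (length(u_knots) < 25L) {
    u_max <- u_knots[length(u_knots)]
    u_knots <- sort(unique(c(u_knots, seq(0, u_max, length.out = 25L))))
  }
  g <- gauss_legendre_01(nodes)
  widths <- diff(u_knots)
  pos <- widths > 0
  widths <- widths[pos]
  starts <- u_knots[-length(u_knots)][pos]
  u <- as.vector(outer(g$x, widths) + rep(starts, each = nodes))
  wq <- as.vector(outer(g$w, widths))
  Tq <- s - u^2
  Rmax <- .front_rmax(Tq, tg, rg, b)
  n_dim <- geom$cell_dim
  p <- .pmass(n_dim, x, Rmax, u^2)
  if (geom$matched) sum(wq * 2 * u * p) else sum(wq * sqrt(pi) * p)
}

# --- initiation --------------------------------------------------------

# Dimensionless initiation time: first s with c(b, s) = 1 at the colony
# edge. Monotone in s; bracket by doubling from s = 0.01, then uniroot.
# Returns NA (never initiates) when the steady state in a 3D environment
# stays below threshold.
nd_initiation_time <- function(b, geom, t_max = Inf, tol = 1e-8) {
  if (geom$diff_dim == 3) {
    if (nd_steady_conc(b, b, geom) <= 1) return(NA_real_)
  }
  f <- function(s) nd_colony_conc(b, s, b, geom) - 1
  s_hi <- 0.01
  f_hi <- f(s_hi)
  while (f_hi < 0) {
    if (s_hi > t_max) stop_config(
      "no initiation by t_max; enlarge t_max (1D/2D environments always initiate eventually)")
    if (s_hi > 1e25) stop_config("initiation bracketing exceeded 1e25 natural times")
    s_hi <- s_hi * 2
    f_hi <- f(s_hi)
  }
  if (s_hi <= 0.01 + 1e-15) return(stats::uniroot(f, c(1e-8, 0.01), tol = tol)$root)
  stats::uniroot(f, c(s_hi / 2, s_hi), tol = tol * max(1, s_hi))$root
}
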