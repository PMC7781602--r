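# The closed-form kernels and shell masses are checked against independent
# oracles: direct angular quadrature of the heat kernel, the noncentral
# chi-square CDF, and closed-form diffusion solutions.

test_that("point propagator is normalized and takes textbook values", {
  D <- 1e-10
  tau1 <- 1 / (4 * pi * D)  # makes 4 pi D tau = 1
  expect_equal(point_propagator(1, 0, tau1, D), 1, tolerance = 1e-12)
  expect_equal(point_propagator(3, sqrt(4 * D * 2), 2, D),
               exp(-1) * (4 * pi * D * 2)^(-3 / 2), tolerance = 1e-12)
  # conservation in m = 1, 2, 3 by quadrature (O(1) scales so the adaptive
  # integrator sees the Gaussian)
  for (m in 1:3) {
    shell <- c(2, 2 * pi, 4 * pi)[m]
    tot <- stats::integrate(function(x) shell * x^(m - 1) *
                              point_propagator(m, x, 0.3, 1),
                            0, Inf, rel.tol = 1e-10)$value
    expect_equal(tot, 1, tolerance = 1e-8)
  }
  expect_error(point_propagator(2, 1, 0, D), "tau")
})

test_that("ring kernels match direct angular quadrature of the heat kernel", {
  D <- 1e-10; h <- 1e-3
  set.seed(42)
  for (i in 1:5) {
    r <- runif(1, 0, 3e-4); R <- runif(1, 1e-5, 3e-4); tau <- runif(1, 1, 100)
    ang22 <- stats::integrate(function(th) R * point_propagator(
      2, sqrt(r^2 + R^2 - 2 * r * R * cos(th)), tau, D) / h, 0, 2 * pi,
      rel.tol = 1e-10)$value
    expect_equal(ring_kernel(geom_22, r, R, tau, D, h), ang22, tolerance = 1e-7)
    ang23 <- 2 * stats::integrate(function(th) R * point_propagator(
      3, sqrt(r^2 + R^2 - 2 * r * R * cos(th)), tau, D), 0, 2 * pi,
      rel.tol = 1e-10)$value
    expect_equal(ring_kernel(geom_23, r, R, tau, D), ang23, tolerance = 1e-7)
    ang33 <- stats::integrate(function(th) 2 * pi * R^2 * sin(th) * point_propagator(
      3, sqrt(r^2 + R^2 - 2 * r * R * cos(th)), tau, D), 0, pi,
      rel.tol = 1e-10)$value
    expect_equal(ring_kernel(geom_33, r, R, tau, D), ang33, tolerance = 1e-7)
  }
})

test_that("ring-kernel shell integrals satisfy uniform-source reductions", {
  D <- 1e-10; tau <- 20
  # shell integrals: finite upper limit far beyond the diffusion length so
  # the adaptive integrator resolves the micrometer-scale kernel
  Rup <- 2e-4 + 30 * sqrt(4 * D * tau)
  # uniform plane into a half-space: concentration kernel of a 1D problem
  int23 <- stats::integrate(function(R) ring_kernel(geom_23, 2e-4, R, tau, D),
                            0, Rup, rel.tol = 1e-9)$value
  expect_equal(int23, 2 * (4 * pi * D * tau)^(-1 / 2), tolerance = 1e-7)
  # uniform full-space source: unit concentration rate
  int33 <- stats::integrate(function(R) ring_kernel(geom_33, 2e-4, R, tau, D),
                            0, Rup, rel.tol = 1e-9)$value
  expect_equal(int33, 1, tolerance = 1e-7)
  # ring observed at the origin in a thin film collapses to a point kernel
  expect_equal(ring_kernel(geom_22, 0, 1.3e-4, tau, D, 1e-3),
               2 * pi * 1.3e-4 * point_propagator(2, 1.3e-4, tau, D) / 1e-3,
               tolerance = 1e-12)
  # scaled-Bessel evaluation survives extreme arguments without overflow
  expect_true(is.finite(ring_kernel(geom_22, 1e-3, 1e-3, 1e-6, D, 1e-3)))
})

test_that("Gaussian shell masses agree with the noncentral chi-square CDF", {
  set.seed(7)
  for (i in 1:20) {
    x <- runif(1, 0, 8); b <- runif(1, 0, 8); s <- runif(1, 1e-4, 6)
    for (n in 1:3) {
      expect_equal(relaywave:::.pmass(n, x, b, s),
                   pchisq(b^2 / (2 * s), df = n, ncp = x^2 / (2 * s)),
                   tolerance = 1e-6, label = sprintf("pmass n=%d", n))
    }
  }
})

test_that("colony concentrations recover closed-form uniform-source solutions", {
  # 1D channel, observer at the center of a wide colony: c = (a rho/h^2) t
  p <- params_11(); sc <- natural_scales(p, geom_11)
  t <- 2 * sc$time
  expect_equal(concentration_from_colony(0, t, 60 * sc$length, p, geom_11),
               p$a * p$rho * t / p$h^2, tolerance = 1e-6)
  # plane source into half-space: c = 2 a rho sqrt(t/(pi D))
  p3 <- params_23(); sc3 <- natural_scales(p3, geom_23)
  t3 <- 3 * sc3$time
  expect_equal(concentration_from_colony(0, t3, 80 * sc3$length, p3, geom_23),
               2 * p3$a * p3$rho * sqrt(t3 / (pi * p3$D)), tolerance = 1e-5)
  # emitting ball, steady state at its surface: c = a rho ri^2 / (3 D)
  p33 <- params_33(); sc33 <- natural_scales(p33, geom_33)
  ri <- 1.2 * sc33$length
  expect_equal(steady_colony_concentration(ri, ri, p33, geom_33),
               p33$a * p33$rho * ri^2 / (3 * p33$D), tolerance = 1e-6)
  # emitting disk under a half-space, steady state at its rim: 2 a rho ri/(pi D)
  p23 <- params_23(); ri2 <- 1.7 * sc3$length
  expect_equal(steady_colony_concentration(ri2, ri2, p23, geom_23),
               2 * p23$a * p23$rho * ri2 / (pi * p23$D), tolerance = 1e-6)
})

test_that("emitted molecules equal the domain integral of concentration", {
  p <- params_11(); sc <- natural_scales(p, geom_11)
  ri <- 2 * sc$length; t <- 1.5 * sc$time
  xs <- seq(0, ri + 10 * sqrt(4 * p$D * t), length.out = 2000)
  cs <- concentration_from_colony(xs, t, ri, p, geom_11)
  total <- 2 * p$h^2 * sum((cs[-1] + cs[-length(cs)]) / 2 * diff(xs))
  emitted <- p$a * p$rho * 2 * ri * t
  expect_equal(total / emitted, 1, tolerance = 0.005)
})

test_that("Green's-function fields match the PDE oracle with relay disabled", {
  # thin film, cells in 2D
  p <- params_22(); sc <- natural_scales(p, geom_22)
  sim <- simulate_thin(p, geom_22, ri = 4 * sc$length, t_end = 3 * sc$time,
                       relay = FALSE, r_max = 15 * sc$length,
                       dr = 0.025 * sc$length, dt = 0.01 * sc$time)
  snap <- sim$snapshots[[length(sim$snapshots)]]
  sel <- seq(10, nrow(snap), by = 40)
  ref <- concentration_from_colony(snap$r[sel], snap$t[1], 4 * sc$length, p, geom_22)
  keep <- ref > 0.05 * p$Cth
  expect_lt(max(abs(snap$c[sel][keep] / ref[keep] - 1)), 0.01)

  # channel, cells in 1D
  p1 <- params_11(); sim1 <- simulate_thin(p1, geom_11, ri = 4 * sc$length,
                                           t_end = 3 * sc$time, relay = FALSE,
                                           r_max = 15 * sc$length,
                                           dr = 0.025 * sc$length, dt = 0.01 * sc$time)
  s1 <- sim1$snapshots[[length(sim1$snapshots)]]
  ref1 <- concentration_from_colony(s1$r[sel], s1$t[1], 4 * sc$length, p1, geom_11)
  keep1 <- ref1 > 0.05 * p1$Cth
  expect_lt(max(abs(s1$c[sel][keep1] / ref1[keep1] - 1)), 0.01)

  # half-space: compare the extrapolated cell-plane concentration
  p3 <- params_23(); sc3 <- natural_scales(p3, geom_23)
  sim3 <- simulate_thick(p3, geom_23, ri = 4 * sc3$length, t_end = 3 * sc3$time,
                         relay = FALSE, r_max = 15 * sc3$length,
                         dr = 0.05 * sc3$length, dz0 = 0.05 * sc3$length,
                         dt = 0.01 * sc3$time, z_ratio = 1.1)
  s3 <- sim3$snapshots[[length(sim3$snapshots)]]
  zs <- sort(unique(s3$z))
  b1 <- s3[s3$z == zs[1], ]; b2 <- s3[s3$z == zs[2], ]
  csurf <- pmax(b1$c + (b1$c - b2$c) * zs[1] / (zs[2] - zs[1]), 0)
  sel3 <- seq(5, nrow(b1), by = 20)
  ref3 <- concentration_from_colony(b1$r[sel3], s3$t[1], 4 * sc3$length, p3, geom_23)
  keep3 <- ref3 > 0.05 * p3$Cth
  expect_lt(max(abs(csurf[sel3][keep3] / ref3[keep3] - 1)), 0.01)
})

test_that("a zero front reduces the history integral to the colony integral", {
  p <- params_23(); sc <- natural_scales(p, geom_23)
  t <- 4 * sc$time; ri <- 3 * sc$length
  zero_front <- structure(list(time = c(0, t), radius = c(0, 0), ri = ri,
                               dt = t, model = "relay", geometry = geom_23,
                               t_init = 0), class = "front_trajectory")
  r <- c(1, 2.5, 4, 6) * sc$length
  expect_equal(concentration_from_front(r, t, zero_front, ri, p, geom_23),
               concentration_from_colony(r, t, ri, p, geom_23), tolerance = 1e-4)
})

test_that("a converged relay front returns the threshold along itself", {
  p <- params_23(); sc <- natural_scales(p, geom_23)
  fr <- propagate_front(p, geom_23, ri = 4 * sc$length, t_end = 8 * sc$time)
  idx <- round(seq(3, length(fr$time), length.out = 5))
  for (i in idx) {
    cc <- concentration_from_front(fr$radius[i], fr$time[i], fr, 4 * sc$length,
                                   p, geom_23)
    expect_equal(cc / p$Cth, 1, tolerance = 2e-3)
  }
})
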