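test_that("the predicted relay front is convex, the diffusion front concave", {
  fr <- predict_front(swarm_truth$Cth_over_arho, swarm_truth$D, swarm_truth$ri,
                      t_end = 500)
  tq <- seq(fr$t_init + 20, 500, length.out = 12)
  rq <- front_radius(fr, tq)
  d2 <- diff(diff(rq))
  expect_true(all(d2 > -1e-7))  # accelerating (convex) information front
  # and the late slope stays below the asymptotic speed it approaches
  v_late <- (rq[12] - rq[10]) / (tq[12] - tq[10])
  v_asym <- 2 / (pi * swarm_truth$Cth_over_arho)
  expect_lt(v_late, v_asym)
  expect_gt(v_late, 0.5 * v_asym)

  pd <- relay_params(D = swarm_truth$D, a = 1, rho = 1, Cth = 2.91e4)
  fd <- simple_diffusion_front(pd, geom_23, swarm_truth$ri, t_end = 500, dt = 25)
  rd <- front_radius(fd, seq(100, 500, by = 40))
  expect_true(all(diff(diff(rd)) < 1e-7))  # decelerating (concave)
})

test_that("an unreachable threshold keeps the front at the target", {
  expect_error(predict_front(1e12, swarm_truth$D, swarm_truth$ri, t_end = 500),
               "critical")
})

test_that("the matched simple-diffusion threshold behaves monotonically", {
  fr <- predict_front(swarm_truth$Cth_over_arho, swarm_truth$D, swarm_truth$ri,
                      t_end = 500)
  m400 <- match_simple_diffusion_threshold(swarm_truth$Cth_over_arho, swarm_truth$D,
                                           swarm_truth$ri, 400, front = fr)
  m500 <- match_simple_diffusion_threshold(swarm_truth$Cth_over_arho, swarm_truth$D,
                                           swarm_truth$ri, 500, front = fr)
  # the relay front outruns the diffusing field, so the later the match the
  # lower the diffusion threshold has to be to keep up
  expect_lt(as.numeric(m500), as.numeric(m400))
  expect_error(match_simple_diffusion_threshold(swarm_truth$Cth_over_arho,
                                                swarm_truth$D, swarm_truth$ri,
                                                1, front = fr),
               "not left the target")
})

test_that("relay signaling builds far steeper gradients than simple diffusion", {
  fr <- predict_front(swarm_truth$Cth_over_arho, swarm_truth$D, swarm_truth$ri,
                      t_end = 500)
  md <- match_simple_diffusion_threshold(swarm_truth$Cth_over_arho, swarm_truth$D,
                                         swarm_truth$ri, 500, front = fr)
  L <- swarm_truth$D / (2 / (pi * swarm_truth$Cth_over_arho))  # D/v ~ 72 um
  gp <- gradient_profiles(swarm_truth$Cth_over_arho, swarm_truth$D, swarm_truth$ri,
                          as.numeric(md), times = c(300, 500),
                          r_grid = seq(100e-6, 800e-6, length.out = 120),
                          front = fr)
  # at the matching time both fronts sit at the same radius, and inside the
  # wave the relay holds a several-fold steeper gradient than the diffusion
  # model at the same locations
  rel <- gp[gp$t == 500 & gp$model == "relay", ]
  dif <- gp[gp$t == 500 & gp$model == "simple_diffusion", ]
  fp <- rel$front_r[1]
  expect_equal(dif$front_r[1], fp, tolerance = 0.01)
  band <- which(rel$r > swarm_truth$ri + 0.4 * (fp - swarm_truth$ri) & rel$r < fp)
  expect_true(all(abs(rel$dcdr[band]) > 2 * abs(dif$dcdr[band])))
  # the relay gradient decays only modestly inside the wave (well under an
  # order of magnitude over the inner half), unlike the Gaussian collapse
  g_in <- abs(rel$dcdr[rel$r >= swarm_truth$ri + 0.5 * (fp - swarm_truth$ri) &
                         rel$r <= 0.95 * fp])
  expect_lt(max(g_in) / min(g_in), 10)
  # far beyond the fronts (several boundary-layer widths) both gradients
  # are a vanishing fraction of the relay's peak
  for (tt in c(300, 500)) {
    relt <- gp[gp$t == tt & gp$model == "relay", ]
    dift <- gp[gp$t == tt & gp$model == "simple_diffusion", ]
    far <- which(relt$r > max(relt$front_r[1], dift$front_r[1]) + 3.5 * L)
    expect_gt(length(far), 0)
    expect_lt(max(abs(relt$dcdr[far])), 0.05 * max(abs(relt$dcdr)))
    expect_lt(max(abs(dift$dcdr[far])), 0.05 * max(abs(relt$dcdr)))
    # and the relay's gradient at its own front beats the diffusion model's
    # gradient there at every time
    at_front <- which.min(abs(relt$r - relt$front_r[1]))
    expect_gt(abs(relt$dcdr[at_front]), abs(dift$dcdr[at_front]))
  }
})

test_that("the synthetic chemotactic-index map is seeded and honest about its front", {
  s1 <- synth_front_map(swarm_truth$Cth_over_arho, swarm_truth$D, swarm_truth$ri,
                        noise = 0.05, seed = 11)
  s2 <- synth_front_map(swarm_truth$Cth_over_arho, swarm_truth$D, swarm_truth$ri,
                        noise = 0.05, seed = 11)
  expect_identical(s1$map$cos_theta, s2$map$cos_theta)  # determinism
  expect_true(all(abs(s1$map$cos_theta) <= 1))
  # zero noise: extracted front within one radial bin of the truth
  s0 <- synth_front_map(swarm_truth$Cth_over_arho, swarm_truth$D, swarm_truth$ri,
                        noise = 0, seed = 1)
  truth_r <- front_radius(s0$truth, s0$obs$t)
  expect_lt(max(abs(s0$obs$r - truth_r)), 25e-6 + 1e-9)
})

test_that("a noiseless front is refit to its own parameters", {
  s0 <- synth_front_map(swarm_truth$Cth_over_arho, swarm_truth$D, swarm_truth$ri,
                        t_bins = seq(50, 400, by = 50), noise = 0, seed = 1)
  fit <- fit_front(s0$obs, ri = swarm_truth$ri, restarts = 1,
                   control = list(reltol = 1e-6, maxit = 60))
  expect_equal(fit$Cth_over_arho / swarm_truth$Cth_over_arho, 1, tolerance = 0.03)
  expect_equal(fit$D / swarm_truth$D, 1, tolerance = 0.05)
  expect_equal(fit$implied_v, 2 / (pi * fit$Cth_over_arho), tolerance = 1e-12)
})

test_that("a relay fit cannot explain a simple-diffusion front as well as its own model", {
  # truth: diffusion-only signaling from the target
  pd <- relay_params(D = swarm_truth$D, a = 1, rho = 1, Cth = 2.91e4)
  fd <- simple_diffusion_front(pd, geom_23, swarm_truth$ri, t_end = 500, dt = 25)
  tq <- seq(150, 500, by = 50)
  obs <- data.frame(t = tq, r = front_radius(fd, tq))
  fit_rel <- fit_front(obs, ri = swarm_truth$ri, restarts = 0,
                       control = list(reltol = 1e-5, maxit = 40))
  # best single-parameter diffusion fit: threshold matched by least squares
  resid_diff <- stats::optimize(function(ca) {
    pdx <- relay_params(D = swarm_truth$D, a = 1, rho = 1, Cth = ca)
    fx <- simple_diffusion_front(pdx, geom_23, swarm_truth$ri, 500, dt = 25)
    sum((front_radius(fx, tq) - obs$r)^2)
  }, c(1e4, 1e5))$objective
  expect_gt(fit_rel$residual, 3 * resid_diff)
})
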