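test_that("rescaling maps profiles to dimensionless variables and back exactly", {
  p <- fig3_params()
  # printed-scale example: N = 0.05 with a_n mu / lambda = 1000 gives u = 50
  prof <- tibble::tibble(x = c(0, 0.5), N = c(0, 0.05), E = c(0.2, 0), t = 0.2)
  r <- rescale_profile(prof, p)
  expect_equal(r$u, c(0, 50))
  expect_equal(r$tau, c(0.032, 0.032))
  expect_equal(r$X, prof$x * sqrt(p$lambda / p$D))

  # zero maps to zero
  expect_equal(rescale_profile(tibble::tibble(x = 1, N = 0, E = 0, t = 1), p)$u, 0)

  # random valid profiles round-trip to machine precision
  set.seed(9)
  for (i in 1:10) {
    prof <- tibble::tibble(x = sort(runif(20, 0, 10)), N = runif(20, 0, 0.05),
                           E = runif(20, 0, 1), t = runif(1, 0.2, 5))
    back <- unrescale_profile(rescale_profile(prof, p), p)
    expect_equal(back$x, prof$x, tolerance = 1e-12)
    expect_equal(back$N, prof$N, tolerance = 1e-12)
    expect_equal(back$E, prof$E, tolerance = 1e-12)
    expect_equal(back$t, prof$t, tolerance = 1e-12)
  }
})

test_that("the travelling frame keeps the right boundary image positive", {
  p <- fig3_params()
  fr <- moving_frame(p, X0 = 0.5)
  g <- dimensionless_groups(p)
  tau <- 0.8
  X <- 42
  expect_equal(fr$to_frame(X, tau), X - (tau + 0.5) / g$epsilon)
  expect_equal(fr$from_frame(fr$to_frame(X, tau), tau), X)
  # y* = (lambda L / (chi nu) - tau - X0) / epsilon
  expect_equal(fr$y_star(tau),
               (p$lambda * p$L / (p$chi * p$nu) - tau - 0.5) / g$epsilon)
  expect_gt(fr$y_star(2), 0)
})

test_that("zero data stay zero under the leading-order dynamics", {
  p <- fig3_params(L = 1)
  ic <- tibble::tibble(X = c(0, 5, 12), u = 0, w = 0)
  lo <- solve_leading_order(ic, p, tau_out = c(0.05, 0.1), nx = 401)
  expect_equal(max(abs(lo$u0)), 0)
  expect_equal(max(abs(lo$w0)), 0)
})

test_that("with no stalk coupling and no TAF the tip mass decays monotonically", {
  # beta = 0 and a vanishing TAF ramp reduce the leading-order equation to
  # u_tau = u_XX - u_X / eps - u^2 (logistic decay only): total mass must
  # fall at rate integral(u^2)
  p <- continuum_params(D = 1e-8, chi = 0.01, mu = 1e4, lambda = 1, a_e = 0,
                        a_n = 1, nu = 1, L = 2e-3, t0 = 0.05)
  g <- dimensionless_groups(p)
  expect_equal(g$beta, 0)
  XR <- p$L * sqrt(p$lambda / p$D)
  Xg <- seq(0, XR, length.out = 1001)
  ic <- tibble::tibble(X = Xg, u = 2 * exp(-(Xg - 4)^2 / 0.5), w = 0)
  tau_out <- seq(0.05, 0.13, by = 0.02)
  lo <- solve_leading_order(ic, p, tau_out = tau_out, nx = 1001)
  dX <- XR / 1000
  mass <- vapply(tau_out, function(tt) sum(lo$u0[lo$tau == tt]) * dX, numeric(1))
  expect_true(all(diff(mass) < 0))
  # decay rate matches d(mass)/dtau = -integral(u^2) to leading order
  u_mid <- lo$u0[lo$tau == tau_out[3]]
  rate_expect <- -sum(u_mid^2) * dX
  rate_obs <- (mass[4] - mass[2]) / (tau_out[4] - tau_out[2])
  expect_equal(rate_obs, rate_expect, tolerance = 0.05)
})

test_that("leading-order tip solutions stay non-negative from non-negative data", {
  p <- fig3_params(L = 1)
  XR <- sqrt(p$lambda / p$D)
  Xg <- seq(0, XR, length.out = 801)
  set.seed(21)
  for (i in 1:3) {
    c0 <- runif(1, 1, 3); w0 <- runif(1, 0.1, 0.4)
    ic <- tibble::tibble(X = Xg, u = 20 * exp(-(Xg - c0)^2 / (2 * w0^2)),
                         w = 5 * exp(-(Xg - c0 + 0.5)^2 / (2 * w0^2)))
    lo <- solve_leading_order(ic, p, tau_out = c(0.05, 0.15), nx = 801)
    expect_gt(min(lo$u0), -1e-8)
    expect_gt(min(lo$w0), -1e-8)
  }
})

test_that("frame and laboratory coordinates of the solution are consistent", {
  p <- fig3_params(L = 1)
  a <- abm_params(p, Lx = 0.4)
  ens <- simulate_abm_ensemble(a, n = 50, t_out = 0.2, seed = 3)
  lo <- solve_leading_order(ens, p, tau_out = c(0.032, 0.2), nx = 801)
  fr <- attr(lo, "frame")
  expect_equal(lo$y, fr$to_frame(lo$X, lo$tau), tolerance = 1e-12)
  # default offset puts the initial pulse centroid at y = 0
  first <- lo[lo$tau == 0.032, ]
  centroid_y <- sum(first$y * first$u0) / sum(first$u0)
  expect_lt(abs(centroid_y), 0.5)
})
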