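test_that("normalized maximum difference follows its definition", {
  a <- tibble::tibble(x = 0:2, N = c(0, 1, 0), E = 0)
  expect_equal(max_relative_difference(a, a, "N"), 0)

  b <- tibble::tibble(x = 0:2, N = c(0, 0.9, 0.05), E = 0)
  # max |a - b| = 0.1, reference max (b) = 0.9
  expect_equal(max_relative_difference(a, b, "N"), 0.1 / 0.9, tolerance = 1e-12)
  expect_equal(max_relative_difference(a, b, "N", reference = "a"), 0.1,
               tolerance = 1e-12)

  z <- tibble::tibble(x = 0:2, N = 0, E = 0)
  expect_error(max_relative_difference(a, z, "N"), "zero")

  # multi-time wrapper matches per-time calls
  at <- dplyr::bind_rows(dplyr::mutate(a, t = 1), dplyr::mutate(b, t = 2))
  bt <- dplyr::bind_rows(dplyr::mutate(b, t = 1), dplyr::mutate(b, t = 2))
  cmp <- compare_solutions(at, bt, fields = "N")
  expect_equal(cmp$max_rel_diff, c(0.1 / 0.9, 0))
})

test_that("wave-speed estimation is exact for rigid translation", {
  x <- seq(0, 10, length.out = 501)
  set.seed(17)
  for (i in 1:5) {
    c0 <- runif(1, 1, 2); w <- runif(1, 0.2, 0.5); v <- runif(1, 0.5, 2)
    tt <- seq(1, 3, by = 0.5)
    # a pulse with an exactly parabolic cap: three-point interpolation of
    # the peak is then exact whatever the grid phase
    sol <- purrr::map_dfr(tt, function(t) {
      tibble::tibble(x = x, N = pmax(0, 1 - ((x - c0 - v * t) / w)^2), t = t)
    })
    sp <- estimate_wave_speed(sol, "N")
    expect_equal(sp$position, c0 + v * tt, tolerance = 1e-9)
    expect_equal(sp$speed, rep(v, length(tt)), tolerance = 1e-9)
  }

  # bimodal profiles are rejected
  bad <- purrr::map_dfr(1:3, function(t) {
    tibble::tibble(x = x, N = exp(-(x - 2 - 0.1 * t)^2 / 0.1) +
                     0.9 * exp(-(x - 7)^2 / 0.1), t = t)
  })
  expect_error(estimate_wave_speed(bad, "N"), "unimodal")

  # an accelerating pulse sets the acceleration flag
  acc <- purrr::map_dfr(seq(1, 3, by = 0.25), function(t) {
    tibble::tibble(x = x, N = exp(-(x - 0.3 * t^2)^2 / 0.2), t = t)
  })
  expect_true(attr(estimate_wave_speed(acc, "N"), "accelerating"))
})

test_that("leading-edge tracking finds the half-maximum crossing", {
  x <- seq(0, 10, length.out = 1001)
  v <- 1.3
  tt <- 1:4
  sol <- purrr::map_dfr(tt, function(t) {
    tibble::tibble(x = x, N = exp(-(x - 1 - v * t)^2 / (2 * 0.25^2)), t = t)
  })
  edge <- track_leading_edge(sol, "N", level = 0.5)
  # half maximum of a Gaussian sits sqrt(2 log 2) sd beyond the peak
  offset <- sqrt(2 * log(2)) * 0.25
  expect_equal(edge$position, 1 + v * tt + offset, tolerance = 1e-3)
  expect_equal(mean_speed(edge), v, tolerance = 1e-6)
})

test_that("the log-log slope fit recovers exact power laws", {
  tt <- seq(0.05, 0.5, by = 0.05)
  f <- fit_powerlaw_slope(tt, tt^-2, tau_max = 0.5)
  expect_equal(f$slope, -2, tolerance = 1e-12)
  expect_lt(f$max_rel_error, 1e-12)

  f2 <- fit_powerlaw_slope(tt, 3 * tt^0.5, tau_max = 0.5)
  expect_equal(f2$slope, 0.5, tolerance = 1e-12)

  expect_error(fit_powerlaw_slope(tt[1:2], tt[1:2]^-1), "3 points")
  # the window restriction drops late points
  peaks <- c(tt[1:5]^-1, rep(1, 5))
  f3 <- fit_powerlaw_slope(tt, peaks, tau_max = tt[5])
  expect_equal(f3$slope, -1, tolerance = 1e-12)
})

test_that("calibration recovers known parameters from self-generated data", {
  p_true <- continuum_params(D = 1e-3, chi = 0.4, mu = 20, lambda = 0.8,
                             a_e = 0.06, a_n = 1, L = 1, nu = 1, t0 = 0.2)
  xg <- seq(0, 1, length.out = 201)
  ic <- make_pulse_ic(xg, center = 0.25, width = 0.05, mass = 0.03)
  ic$E <- 0.3 * exp(-(xg - 0.15)^2 / 0.005)
  tt <- seq(0.2, 1.4, by = 0.3)
  truth <- solve_st_pde(ic, p_true, times = tt, nx = 201)

  p_start <- p_true
  p_start$lambda <- 0.4; p_start$a_e <- 0.02
  fit <- fit_continuum_params(truth, "st", p_start, nx = 201)
  expect_lt(abs(fit$estimates[["lambda"]] - 0.8) / 0.8, 0.01)
  expect_lt(abs(fit$estimates[["a_e"]] - 0.06) / 0.06, 0.01)

  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$model, "st")

  # refitting at the calibrated parameters reproduces the data
  refit <- solve_fitted(fit)
  expect_lt(max(abs(refit$N - truth$N[truth$t > 0.2])), 1e-4)

  # with multiplicative noise the truth stays inside the reported interval
  set.seed(31)
  noisy <- truth
  noisy$N <- noisy$N * (1 + 0.01 * rnorm(nrow(noisy)))
  noisy$E <- noisy$E * (1 + 0.01 * rnorm(nrow(noisy)))
  noisy$N[noisy$t == 0.2] <- truth$N[truth$t == 0.2]
  noisy$E[noisy$t == 0.2] <- truth$E[truth$t == 0.2]
  fit_n <- fit_continuum_params(noisy, "st", p_start, nx = 201)
  expect_true(fit_n$conf_low[["lambda"]] < 0.8 &&
                0.8 < fit_n$conf_high[["lambda"]])
  expect_true(fit_n$conf_low[["a_e"]] < 0.06 &&
                0.06 < fit_n$conf_high[["a_e"]])
})
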