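test_that("lattice parameters derive from continuum constants and round-trip exactly", {
  p <- fig3_params()
  a <- abm_params(p, Lx = 0.5)
  expect_equal(a$h, 5e-3)
  expect_equal(a$k, 100)
  expect_equal(a$dt, 1 / 160)
  expect_equal(a$Pp, 1e-3)
  # round trip through the defining relations
  mu <- a$Pm / a$dt
  expect_equal(mu * a$h^2 / 4, p$D, tolerance = 1e-15)
  expect_equal(mu * a$k * a$h^2, p$chi, tolerance = 1e-15)
  expect_equal(a$Pp * mu / a$Pm, p$lambda, tolerance = 1e-15)

  # zero branching
  p0 <- continuum_params(D = 1e-3, chi = 0.4, mu = 160, lambda = 0, a_e = 0.04,
                         nu = 1, L = 1)
  expect_equal(abm_params(p0, Lx = 0.5)$Pp, 0)

  # the Fig-3 mapping sits exactly at the bias bound b = 1/4
  expect_equal(max(a$bias), 0.25)
  # a steeper gradient would need b > 1/4: invalid move probabilities
  p_bad <- continuum_params(D = 1e-3, chi = 0.8, mu = 160, lambda = 0.16,
                            a_e = 0.04, nu = 1, L = 1)
  expect_error(abm_params(p_bad, Lx = 0.5), "bias")
})

test_that("one-step movement moments reproduce the D and chi mappings", {
  # single tip in the middle of an otherwise empty lattice
  p <- continuum_params(D = 1e-3, chi = 0.2, mu = 160, lambda = 0, a_e = 0.04,
                        nu = 1, L = 1) # b = 0.125
  a <- abm_params(p, Lx = 0.25, Ly = 0.25)
  mid_r <- a$ny %/% 2L
  mid_c <- a$nx %/% 2L
  set.seed(42)
  ndraw <- 4000
  dx <- integer(ndraw); dy <- integer(ndraw)
  for (i in seq_len(ndraw)) {
    g <- matrix(0L, a$ny, a$nx); g[mid_r, mid_c] <- -1L
    s1 <- abm_step(list(grid = g, t = 0), a)
    pos <- which(s1$grid < 0L, arr.ind = TRUE)
    dx[i] <- pos[1, "col"] - mid_c
    dy[i] <- pos[1, "row"] - mid_r
  }
  b <- a$bias[mid_c]
  # mean x-displacement per step: h (P+x - P-x) = 2 b h = chi nu dt
  se_x <- a$h * sqrt(0.5) / sqrt(ndraw)
  expect_lt(abs(mean(dx) * a$h - p$chi * p$nu * a$dt), 4 * se_x)
  # bias-free y second moment: E[dy^2] = h^2 / 2 = 2 D dt per step
  se_y2 <- a$h^2 * 0.5 / sqrt(ndraw)
  expect_lt(abs(mean(dy^2) * a$h^2 - 2 * p$D * a$dt), 4 * se_y2)
  # direction frequencies: +x with 1/4 + b, -x with 1/4 - b, each y with 1/4
  freq <- c(mean(dx == 1), mean(dx == -1), mean(dy == 1), mean(dy == -1))
  expected <- c(0.25 + b, 0.25 - b, 0.25, 0.25)
  se <- sqrt(expected * (1 - expected) / ndraw)
  expect_true(all(abs(freq - expected) < 4 * se))
})

test_that("anastomosis and trail rules act site by site", {
  p <- fig3_params()
  a <- abm_params(p, Lx = 0.05, Ly = 0.05)

  # two adjacent tips, each walled in by its own trail except towards the
  # other: the only state change possible is a tip-to-tip collision, which
  # removes the moving tip and turns its site into stalk
  set.seed(1)
  g0 <- matrix(0L, a$ny, a$nx)
  g0[, ] <- 0L
  g0[3, 5] <- -1L; g0[4, 5] <- -2L
  for (r in 1:a$ny) for (cc in 1:a$nx) {
    if (abs(r - 3.5) > 1.2 || abs(cc - 5) > 1.2) {
      g0[r, cc] <- if (r <= 3) 1L else 2L # own-trail walls
    }
  }
  g0[3, 4] <- 1L; g0[3, 6] <- 1L; g0[2, 5] <- 1L
  g0[4, 4] <- 2L; g0[4, 6] <- 2L; g0[5, 5] <- 2L
  s <- list(grid = g0, t = 0)
  for (i in 1:200) {
    s2 <- abm_step(s, a)
    expect_lte(sum(s2$grid < 0), sum(s$grid < 0)) # tips never appear
    if (sum(s2$grid < 0) == 1 && sum(s$grid < 0) == 2) {
      # the collision site: the vacated position of the removed tip is stalk
      gone <- which(s$grid < 0 & !(s2$grid < 0))
      expect_true(all(s2$grid[gone] > 0))
      break
    }
    s <- s2
  }
  expect_equal(sum(s2$grid < 0), 1) # a collision happened within 200 sweeps

  # a tip walled in by foreign stalk dies as soon as it moves
  g <- matrix(2L, a$ny, a$nx) # all stalk of sprout 2
  g[3, 5] <- -1L
  s <- list(grid = g, t = 0)
  for (i in 1:20) s <- abm_step(s, a)
  expect_equal(sum(s$grid < 0), 0)

  # a tip surrounded by its own trail only ever aborts: it survives
  g <- matrix(1L, a$ny, a$nx) # all stalk of sprout 1
  g[3, 5] <- -1L
  s <- list(grid = g, t = 0)
  for (i in 1:20) s <- abm_step(s, a)
  expect_equal(sum(s$grid < 0), 1)
})

test_that("column averaging counts occupancy fractions", {
  p <- fig3_params()
  a <- abm_params(p, Lx = 0.02, Ly = 0.02) # 4 x 4 lattice
  expect_equal(a$nx, 4L)
  g <- matrix(0L, 4, 4)
  prof0 <- column_average(list(grid = g, t = 0), a)
  expect_true(all(prof0$N == 0) && all(prof0$E == 0))

  g[, 2] <- -seq_len(4) # one column fully tip-occupied
  expect_equal(column_average(list(grid = g, t = 0), a)$N, c(0, 1, 0, 0))

  g2 <- matrix(0L, 4, 4)
  g2[c(1, 3), 1] <- c(-1L, -2L) # 2 tips in column 1
  g2[2, 3] <- 5L               # 1 stalk in column 3
  prof <- column_average(list(grid = g2, t = 0), a)
  expect_equal(prof$N, c(0.5, 0, 0, 0))
  expect_equal(prof$E, c(0, 0, 0.25, 0))
})

test_that("a lone unbranching tip is conserved and ensembles are reproducible", {
  p <- continuum_params(D = 1e-3, chi = 0.4, mu = 160, lambda = 0, a_e = 0.04,
                        a_n = 0, nu = 1, L = 1)
  a <- abm_params(p, Lx = 0.3, Ly = 0.1, seed_columns = 1L)
  # single tip: no branching, no foreign trails -> tip count conserved
  g <- matrix(0L, a$ny, a$nx); g[a$ny %/% 2, 3] <- -1L
  s <- list(grid = g, t = 0)
  set.seed(3)
  for (i in 1:50) s <- abm_step(s, a)
  expect_equal(sum(s$grid < 0), 1)

  a3 <- abm_params(fig3_params(), Lx = 0.3)
  e1 <- simulate_abm_ensemble(a3, n = 5, t_out = c(0.1, 0.2), seed = 11)
  e2 <- simulate_abm_ensemble(a3, n = 5, t_out = c(0.1, 0.2), seed = 11)
  expect_identical(e1, e2)
  e3 <- simulate_abm_ensemble(a3, n = 5, t_out = c(0.1, 0.2), seed = 12)
  expect_false(identical(e1, e3))
})

test_that("the captioned regime yields a detached unimodal pulse at t0", {
  a <- abm_params(fig3_params(), Lx = 0.4)
  ens <- simulate_abm_ensemble(a, n = 100, t_out = 0.2, seed = 5)
  peak_at <- ens$x[which.max(ens$N)]
  expect_gt(peak_at, 10 * a$h)      # detached from the parent vessel
  expect_lt(ens$N[1], 0.1 * max(ens$N))
  # unimodal up to Monte-Carlo noise: smoothed profile has one maximum
  sm <- stats::filter(ens$N, rep(1 / 5, 5), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_true(is_unimodal(sm))
})

test_that("ensemble means of the lattice model track the coarse-grained PDE", {
  # Mean-field check: pulse position and cell masses follow the P-PDE
  # solution initialised from the t0 ensemble mean. Pm < 1 keeps the
  # per-step drift variance correction (chi nu)^2 dt small relative to D,
  # inside the diffusion limit the D = mu h^2 / 4 mapping assumes.
  p <- fig3_params()
  a <- abm_params(p, Lx = 1.2, Pm = 0.2)
  tt <- c(0.2, 1, 2)
  ens <- simulate_abm_ensemble(a, n = 150, t_out = tt, seed = 7)
  sol <- solve_p_pde(ens[ens$t == 0.2, ], p, times = tt[-1], nx = 1401,
                     rtol = 1e-6, atol = 1e-9)
  dx_pde <- sol$x[2] - sol$x[1]
  for (t in tt[-1]) {
    pa <- ens[ens$t == t, ]
    ps <- sol[sol$t == t, ]
    # pulse positions agree to within half a pulse width
    sd_a <- sqrt(sum(pa$N * (pa$x - sum(pa$N * pa$x) / sum(pa$N))^2) / sum(pa$N))
    expect_lt(abs(peak_position(pa$x, pa$N) - peak_position(ps$x, ps$N)),
              0.5 * sd_a)
    # total tip and stalk masses agree to 15%
    expect_lt(abs(sum(pa$N) * a$h - sum(ps$N) * dx_pde) / (sum(pa$N) * a$h), 0.15)
    expect_lt(abs(sum(pa$E) * a$h - sum(ps$E) * dx_pde) / (sum(pa$E) * a$h), 0.15)
    # stalk profiles agree pointwise to 10% of the maximum
    Ep <- approx(ps$x, ps$E, pa$x, yleft = 0, yright = 0)$y
    expect_lt(max(abs(Ep - pa$E)) / max(pa$E), 0.10)
  }
})
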