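# Shared fixtures and independent reference implementations used as oracles.

fig3_params <- function(L = 10) {
  continuum_params(D = 1e-3, chi = 0.4, mu = 160, lambda = 0.16,
                   a_e = 0.0391, a_n = 1, L = L, nu = 1, t0 = 0.2)
}

fig1_params <- function(nu = 1) {
  continuum_params(D = 5e-4, chi = 0.425, mu = 150, lambda = 0.1,
                   a_e = 0.05, a_n = 1, L = 10, nu = nu, t0 = 0.2)
}

# Brute-force fixed-step explicit (RK4) reference solver for both PDE
# systems on a coarse grid: the same finite-volume upwind semi-discretisation
# as solve_*_pde(scheme = "upwind"), but assembled independently with scalar
# loops over faces. Checks the package's operator assembly and adaptive time
# integration on small instances.
reference_solve <- function(model, ic_N, ic_E, params, xgrid, t_end, dt) {
  nx <- length(xgrid)
  dx <- xgrid[2] - xgrid[1]
  v <- params$chi * params$nu
  Cx <- params$nu * xgrid
  kap <- params$mu / (params$chi * params$nu)
  N <- ic_N; E <- ic_E
  nstep <- round(t_end / dt)
  rk <- function(N, E) {
    J <- numeric(nx + 1) # total flux at faces; no-flux walls
    for (f in 2:nx) {
      J[f] <- v * N[f - 1] - params$D * (N[f] - N[f - 1]) / dx
    }
    mov <- numeric(nx); grad <- numeric(nx)
    for (i in 1:nx) mov[i] <- -(J[i + 1] - J[i]) / dx
    grad[1] <- (N[2] - N[1]) / dx
    grad[nx] <- (N[nx] - N[nx - 1]) / dx
    for (i in 2:(nx - 1)) grad[i] <- (N[i + 1] - N[i - 1]) / (2 * dx)
    react <- params$lambda * N * Cx - params$a_n * params$mu * N^2 -
      params$a_e * params$mu * N * E
    if (model == "st") {
      dN <- mov + react
      dE <- kap * abs(params$D * grad - v * N)
    } else {
      fac <- pmax(1 - params$a_n * N - params$a_e * E, 0)
      dN <- mov * fac + react
      dE <- params$mu * N + params$a_n * params$mu * N^2 + params$a_n * N * mov
    }
    list(dN, dE)
  }
  for (s in seq_len(nstep)) {
    k1 <- rk(N, E)
    k2 <- rk(N + dt / 2 * k1[[1]], E + dt / 2 * k1[[2]])
    k3 <- rk(N + dt / 2 * k2[[1]], E + dt / 2 * k2[[2]])
    k4 <- rk(N + dt * k3[[1]], E + dt * k3[[2]])
    N <- N + dt / 6 * (k1[[1]] + 2 * k2[[1]] + 2 * k3[[1]] + k4[[1]])
    E <- E + dt / 6 * (k1[[2]] + 2 * k2[[2]] + 2 * k3[[2]] + k4[[2]])
  }
  list(N = N, E = E)
}

# Shooting oracle for the similarity boundary-value problem
# U'' + (z/2) U' + U = U^2: by reflection symmetry the bell solution is
# even, so integrate from z = 0 with U'(0) = 0 and bisect on U(0) between a
# value that decays through zero and one that blows up.
shooting_similarity <- function(zmax = 12, n_eval = 2001) {
  rhs <- function(z, y, parms) {
    list(c(y[2], -z / 2 * y[2] - y[1] + y[1]^2))
  }
  shoot <- function(p) {
    sol <- deSolve::ode(c(p, 0), seq(0, zmax, length.out = 401), rhs, NULL,
                        rtol = 1e-12, atol = 1e-14)
    u <- sol[, 2]
    if (any(u < -1e-10)) return(-1)  # undershoot: crossed zero
    if (any(u > 2 * p)) return(1)    # overshoot: blow-up
    sign(u[length(u)])
  }
  lo <- 0.2; hi <- 0.99
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (shoot(mid) <= 0) lo <- mid else hi <- mid
  }
  p <- (lo + hi) / 2
  zs <- seq(0, zmax, length.out = (n_eval + 1) / 2)
  sol <- deSolve::ode(c(p, 0), zs, rhs, NULL, rtol = 1e-12, atol = 1e-14)
  u_half <- pmax(sol[, 2], 0)
  tibble::tibble(z = c(-rev(zs[-1]), zs), U = c(rev(u_half[-1]), u_half))
}
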