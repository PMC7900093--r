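# Method-of-lines machinery shared by the ST-PDE, P-PDE and leading-order
# solvers. Space: finite volumes with central diffusion and a flux-limited
# (van Leer MUSCL) upwind treatment of the chemotactic advection; the
# advection velocity chi * nu > 0 is constant for the linear TAF field.
# Time: deSolve::lsoda with a banded numeric Jacobian (state interleaved as
# N1, E1, N2, E2, ... so the band stays narrow).

# Upwind face values N_{j+1/2} for j = 1..nx-1 (flow in +x).
face_values <- function(N, scheme) {
  nx <- length(N)
  up <- N[-nx]            # donor node j
  if (scheme == "upwind") return(up)
  dN <- N[-1] - N[-nx]    # N_{j+1} - N_j
  if (scheme == "central") return(up + 0.5 * dN)
  # MUSCL with the van Leer limiter, written as the harmonic mean of the
  # adjacent slopes (phi(r) dN = 2 dN_up dN / (dN_up + dN) for same-sign
  # slopes), which is overflow-safe when dN underflows. The first interior
  # face falls back to first order (no upwind-upwind neighbour).
  dN_up <- c(0, dN[-length(dN)]) # N_j - N_{j-1}
  prod_pos <- dN_up * dN > 0
  corr <- ifelse(prod_pos, dN_up * dN / (dN_up + dN), 0)
  corr[1] <- 0
  up + corr
}

# Total flux J = v*N - Dc*dN/dx on interior faces; boundary faces carry the
# imposed flux (0 for no-flux). Returns the divergence term -dJ/dx per node.
flux_divergence <- function(N, v, Dc, dx, scheme, bc) {
  nx <- length(N)
  Jint <- v * face_values(N, scheme) - Dc * (N[-1] - N[-nx]) / dx
  if (bc == "noflux") {
    J <- c(0, Jint, 0)
  } else { # far-field Dirichlet via zero ghost values
    J <- c(v * 0 - Dc * (N[1] - 0) / dx, Jint, v * N[nx] - Dc * (0 - N[nx]) / dx)
  }
  -(J[-1] - J[-(nx + 1)]) / dx
}

central_gradient <- function(N, dx) {
  nx <- length(N)
  c(N[2] - N[1], N[-(1:2)] - N[-((nx - 1):nx)], N[nx] - N[nx - 1]) /
    c(dx, rep(2 * dx, nx - 2), dx)
}

interp_ic <- function(ic, xgrid, col) {
  if (nrow(ic) == 1) return(rep(ic[[col]], length(xgrid)))
  approx(ic$x, ic[[col]], xout = xgrid, yleft = 0, yright = 0)$y
}

solve_mol <- function(ic_N, ic_E, rhs, t0, times, xgrid, rtol, atol, parms) {
  y0 <- as.vector(rbind(ic_N, ic_E))
  t_all <- sort(unique(c(t0, times)))
  sol <- deSolve::ode(
    y = y0, times = t_all, func = rhs, parms = parms,
    method = "lsoda", jactype = "bandint", bandup = 2L, banddown = 5L,
    rtol = rtol, atol = atol, maxsteps = 50000L
  )
  if (attr(sol, "istate")[1] < 0)
    abort("time integrator failed to converge; refine the grid or relax tolerances.")
  keep <- sol[, 1] %in% times
  mat <- sol[keep, -1, drop = FALSE]
  nx <- length(xgrid)
  purrr::map_dfr(seq_len(sum(keep)), function(i) {
    tibble::tibble(
      x = xgrid,
      N = unname(mat[i, seq(1, 2 * nx, by = 2)]),
      E = unname(mat[i, seq(2, 2 * nx, by = 2)]),
      t = sol[keep, 1][i]
    )
  })
}

check_nonneg <- function(sol, tol = 1e-6) {
  mn <- min(sol$N, sol$E)
  if (mn < -tol)
    abort(sprintf("solver produced negative densities beyond tolerance (min = %g).", mn))
  invisible(sol)
}

#' Solve the snail-trail PDE system
#'
#' Integrates the snail-trail model: the tip density obeys
#' `N_t = D N_xx - chi (N C_x)_x + lambda N C - a_n mu N^2 - a_e mu N E`
#' with no-flux boundary conditions, and the stalk density grows with the
#' magnitude of the *net* tip flux, `E_t = kappa |D N_x - chi N C_x|`, with
#' the correction factor `kappa = mu / (chi |C_x|)`. The TAF field is the
#' quasi-steady linear ramp `C(x) = nu x`.
#'
#' @param ic A data frame with columns `x`, `N`, `E` giving the initial tip
#'   and stalk densities at `params$t0` (interpolated onto the solver grid;
#'   zero outside its range).
#' @param params A [continuum_params()] object.
#' @param times Increasing output times, all `>= params$t0`.
#' @param nx Number of grid nodes on `[0, L]`.
#' @param scheme Advection discretisation: flux-limited second-order
#'   `"muscl"` (default), first-order `"upwind"`, or `"central"`.
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @return A `pde_solution` tibble with columns `x`, `N`, `E`, `t` (one
#'   block per output time) and attributes `model`, `params`, `nx`.
#' @export
solve_st_pde <- function(ic, params, times, nx = 2001,
                         scheme = c("muscl", "upwind", "central"),
                         rtol = 1e-8, atol = 1e-10) {
  scheme <- match.arg(scheme)
  stopifnot(all(times >= params$t0 - 1e-12), !is.unsorted(times))
  xgrid <- seq(0, params$L, length.out = nx)
  dx <- xgrid[2] - xgrid[1]
  G <- interp_ic(ic, xgrid, "N"); H <- interp_ic(ic, xgrid, "E")
  if (min(G) < 0 || min(H) < 0) abort("initial densities must be non-negative.")
  v <- params$chi * params$nu
  Cx <- taf_concentration(xgrid, params)
  kap <- kappa(params)
  p <- params
  idxN <- seq(1, 2 * nx, by = 2); idxE <- seq(2, 2 * nx, by = 2)
  rhs <- function(t, y, parms) {
    N <- y[idxN]; E <- y[idxE]
    M <- flux_divergence(N, v, p$D, dx, scheme, "noflux")
    dN <- M + p$lambda * N * Cx - p$a_n * p$mu * N^2 - p$a_e * p$mu * N * E
    net_flux <- p$D * central_gradient(N, dx) - v * N
    dE <- kap * abs(net_flux)
    dy <- numeric(2 * nx); dy[idxN] <- dN; dy[idxE] <- dE
    list(dy)
  }
  out <- solve_mol(G, H, rhs, params$t0, times, xgrid, rtol, atol, NULL)
  check_nonneg(out)
  structure(out, model = "st", params = params, nx = nx, class = c("pde_solution", class(out)))
}

#' Solve the coarse-grained Pillay PDE system
#'
#' Integrates the mean-field system coarse-grained from the lattice model:
#' tip movement terms are multiplied by the volume-exclusion factor
#' `(1 - a_n N - a_e E)`, and the stalk equation gains production from
#' tip-to-tip anastomosis,
#' `E_t = mu N + a_n mu N^2 + a_n N (D N_xx - chi (N C_x)_x)`.
#' The movement factor is clamped at zero inside the tip equation; if
#' `1 - a_n N - a_e E` falls below `-tol_illposed` during integration a
#' warning reports the first violation (the model approaches ill-posedness
#' there).
#'
#' @inheritParams solve_st_pde
#' @param tol_illposed Tolerated undershoot of the well-posedness guard.
#' @return A `pde_solution` tibble (see [solve_st_pde()]).
#' @export
solve_p_pde <- function(ic, params, times, nx = 2001,
                        scheme = c("muscl", "upwind", "central"),
                        rtol = 1e-8, atol = 1e-10, tol_illposed = 1e-6) {
  scheme <- match.arg(scheme)
  stopifnot(all(times >= params$t0 - 1e-12), !is.unsorted(times))
  xgrid <- seq(0, params$L, length.out = nx)
  dx <- xgrid[2] - xgrid[1]
  G <- interp_ic(ic, xgrid, "N"); H <- interp_ic(ic, xgrid, "E")
  if (min(G) < 0 || min(H) < 0) abort("initial densities must be non-negative.")
  guard0 <- 1 - params$a_n * G - params$a_e * H
  if (min(guard0) < -1e-9)
    abort(sprintf("initial condition violates the well-posedness guard a_n G + a_e E <= 1 (min factor %g).",
                  min(guard0)))
  v <- params$chi * params$nu
  Cx <- taf_concentration(xgrid, params)
  p <- params
  idxN <- seq(1, 2 * nx, by = 2); idxE <- seq(2, 2 * nx, by = 2)
  viol <- new.env(); viol$first <- NULL
  rhs <- function(t, y, parms) {
    N <- y[idxN]; E <- y[idxE]
    M <- flux_divergence(N, v, p$D, dx, scheme, "noflux")
    fac <- 1 - p$a_n * N - p$a_e * E
    if (is.null(viol$first) && min(fac) < -tol_illposed) {
      viol$first <- c(t = t, x = xgrid[which.min(fac)], factor = min(fac))
    }
    fac <- pmax(fac, 0)
    dN <- M * fac + p$lambda * N * Cx - p$a_n * p$mu * N^2 - p$a_e * p$mu * N * E
    dE <- p$mu * N + p$a_n * p$mu * N^2 + p$a_n * N * M
    dy <- numeric(2 * nx); dy[idxN] <- dN; dy[idxE] <- dE
    list(dy)
  }
  out <- solve_mol(G, H, rhs, params$t0, times, xgrid, rtol, atol, NULL)
  if (!is.null(viol$first))
    warn(sprintf("well-posedness guard 1 - a_n N - a_e E fell to %g at t = %g, x = %g (clamped).",
                 viol$first["factor"], viol$first["t"], viol$first["x"]))
  check_nonneg(out)
  structure(out, model = "pillay", params = params, nx = nx, class = c("pde_solution", class(out)))
}
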