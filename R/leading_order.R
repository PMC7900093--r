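#' Solve the shared leading-order asymptotic system
#'
#' In the chemotaxis-dominated, rare-branching limit (`epsilon << 1`,
#' `alpha = epsilon^2 Psi << 1`) the ST-PDE and the P-PDE reduce to one and
#' the same leading-order system. In the frame `y = X - (tau + X0)/epsilon`
#' travelling with the chemotactic drift it reads
#' `U0_tau = U0_yy + U0 (Ctilde - U0 - W0)` with far-field Dirichlet
#' conditions `U0 -> 0` as `y -> +/- Inf`, while the stalk variable obeys
#' `w0_tau = beta U0` at fixed laboratory position. The solver integrates
#' the equivalent laboratory-frame form
#' `u0_tau = u0_XX - u0_X / epsilon + u0 (c - u0 - w0)`, `w0_tau = beta u0`,
#' which keeps the stalk accumulation at fixed `X` exact; solutions are
#' reported in both coordinates.
#'
#' @param ic Initial condition: either a data frame with columns `x`, `N`,
#'   `E` in laboratory variables (rescaled internally via
#'   [rescale_profile()]) or one with columns `X`, `u`, `w` already in
#'   dimensionless variables, taken at `tau0 = lambda * t0`.
#' @param params A [continuum_params()] object with `a_n = 1`.
#' @param tau_out Increasing dimensionless output times, all `>= tau0`.
#' @param nx Number of nodes on the rescaled domain `[0, L sqrt(lambda/D)]`.
#' @param X0 Frame offset. Default: chosen so the initial pulse centroid
#'   sits at `y = 0` at `tau0`, subject to the right-boundary image
#'   `y*(tau)` staying positive.
#' @param rtol,atol Integrator tolerances.
#' @param scheme Advection scheme, as in [solve_st_pde()].
#' @return A `leading_order_solution` tibble with columns `X`, `y`, `u0`,
#'   `w0`, `tau`, plus attributes `groups` (the dimensionless groups),
#'   `frame` (the [moving_frame()]), and `params`.
#' @export
solve_leading_order <- function(ic, params, tau_out, nx = 2001, X0 = NULL,
                                rtol = 1e-8, atol = 1e-10,
                                scheme = c("muscl", "upwind", "central")) {
  scheme <- match.arg(scheme)
  groups <- dimensionless_groups(params)
  eps <- groups$epsilon
  tau0 <- params$lambda * params$t0
  stopifnot(all(tau_out >= tau0 - 1e-12), !is.unsorted(tau_out))

  if (all(c("x", "N", "E") %in% names(ic))) {
    ic <- rescale_profile(ic, params)
  }
  stopifnot(all(c("X", "u", "w") %in% names(ic)))

  XR <- params$L * sqrt(params$lambda / params$D)
  Xgrid <- seq(0, XR, length.out = nx)
  dX <- Xgrid[2] - Xgrid[1]
  u0 <- approx(ic$X, ic$u, xout = Xgrid, yleft = 0, yright = 0)$y
  w0 <- approx(ic$X, ic$w, xout = Xgrid, yleft = 0, yright = 0)$y
  if (min(u0) < 0 || min(w0) < 0) abort("initial densities must be non-negative.")
  if (sum(u0) <= 0) {
    centroid <- 0
  } else {
    centroid <- sum(Xgrid * u0) / sum(u0)
  }
  if (is.null(X0)) X0 <- eps * centroid - tau0
  frame <- moving_frame(params, X0)
  if (frame$y_star(max(tau_out)) <= 0)
    abort("right-boundary image y* is not positive over the requested window; adjust X0 or the domain.")

  # TAF in rescaled coordinates, clipped to the physical range [0, 1].
  ctilde <- pmin(pmax(params$nu * sqrt(params$D / params$lambda) * Xgrid, 0), 1)
  beta <- groups$beta
  idxU <- seq(1, 2 * nx, by = 2); idxW <- seq(2, 2 * nx, by = 2)
  rhs <- function(t, y, parms) {
    u <- y[idxU]; w <- y[idxW]
    M <- flux_divergence(u, 1 / eps, 1, dX, scheme, "dirichlet")
    du <- M + u * (ctilde - u - w)
    dy <- numeric(2 * nx); dy[idxU] <- du; dy[idxW] <- beta * u
    list(dy)
  }
  out <- solve_mol(u0, w0, rhs, tau0, tau_out, Xgrid, rtol, atol, NULL)
  names(out) <- c("X", "u0", "w0", "tau")
  # boundary-support check: the far-field truncation must hold
  edge <- max(abs(out$u0[out$X %in% range(Xgrid)]))
  if (edge > 1e-3 * max(out$u0))
    warn("leading-order tip support reached the grid boundary; enlarge the domain.")
  out$y <- frame$to_frame(out$X, out$tau)
  out <- out[, c("X", "y", "u0", "w0", "tau")]
  structure(out, groups = groups, frame = frame, params = params,
            class = c("leading_order_solution", class(out)))
}
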