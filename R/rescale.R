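#' Rescale cell-density profiles to dimensionless comparison variables
#'
#' Transforms a profile `(x, N, E, t)` into the dimensionless variables used
#' by the asymptotic analysis: `u = (a_n mu / lambda) N`,
#' `w = (a_e mu / lambda) E`, `tau = lambda t`, `X = x sqrt(lambda / D)`.
#' The time scale of interest is `1 / lambda` and the length scale is
#' `sqrt(D / lambda)`.
#'
#' @param profile A data frame with columns `x`, `N`, `E` and (optionally)
#'   `t`. Extra columns are dropped.
#' @param params A [continuum_params()] object with `a_n = 1` (the tip
#'   rescaling degenerates when tip-to-tip anastomosis is switched off).
#' @return A tibble with columns `X`, `u`, `w`, `tau`.
#' @seealso [unrescale_profile()] for the exact inverse.
#' @export
rescale_profile <- function(profile, params) {
  stopifnot(all(c("x", "N", "E") %in% names(profile)))
  if (params$a_n != 1) abort("rescaling requires a_n = 1.")
  t <- if ("t" %in% names(profile)) profile$t else params$t0
  tibble::tibble(
    X   = profile$x * sqrt(params$lambda / params$D),
    u   = (params$a_n * params$mu / params$lambda) * profile$N,
    w   = (params$a_e * params$mu / params$lambda) * profile$E,
    tau = params$lambda * t
  )
}

#' Map a dimensionless profile back to laboratory variables
#'
#' Exact inverse of [rescale_profile()].
#'
#' @param profile A data frame with columns `X`, `u`, `w` and optionally
#'   `tau`.
#' @param params A [continuum_params()] object with `a_n = 1`.
#' @return A tibble with columns `x`, `N`, `E`, `t`.
#' @export
unrescale_profile <- function(profile, params) {
  stopifnot(all(c("X", "u", "w") %in% names(profile)))
  if (params$a_n != 1) abort("rescaling requires a_n = 1.")
  tau <- if ("tau" %in% names(profile)) profile$tau else params$lambda * params$t0
  tibble::tibble(
    x = profile$X * sqrt(params$D / params$lambda),
    N = profile$u * params$lambda / (params$a_n * params$mu),
    E = profile$w * params$lambda / (params$a_e * params$mu),
    t = tau / params$lambda
  )
}

#' Travelling frame for the leading-order dynamics
#'
#' The rescaled tip equation contains an `O(1/epsilon)` chemotactic drift;
#' the leading-order reduction removes it by the change of variables
#' `y = X - (tau + X0) / epsilon`, a frame translating with the chemotactic
#' wave. `X0` is an arbitrary offset chosen so that the image of the right
#' boundary, `y* = (lambda L / (chi nu) - tau - X0) / epsilon`, stays
#' strictly positive over the times of interest.
#'
#' @param params A [continuum_params()] object.
#' @param X0 Frame offset (dimensionless). The default 0 places the frame
#'   origin at `X = tau / epsilon`; solvers typically recentre so that the
#'   initial pulse centroid sits at `y = 0`.
#' @return An object of class `moving_frame` with fields `epsilon`, `X0`,
#'   and helper closures `to_frame(X, tau)`, `from_frame(y, tau)`,
#'   `y_star(tau)`.
#' @export
moving_frame <- function(params, X0 = 0) {
  eps <- dimensionless_groups(params, require_beta = FALSE)$epsilon
  lam <- params$lambda
  XR <- params$L * sqrt(lam / params$D) # = lambda L / (chi nu) / epsilon
  structure(
    list(
      epsilon = eps,
      X0 = X0,
      to_frame = function(X, tau) X - (tau + X0) / eps,
      from_frame = function(y, tau) y + (tau + X0) / eps,
      y_star = function(tau) XR - (tau + X0) / eps
    ),
    class = "moving_frame"
  )
}

#' @export
print.moving_frame <- function(x, ...) {
  cat(sprintf("<moving_frame> epsilon = %.4g, X0 = %.4g\n", x$epsilon, x$X0))
  invisible(x)
}
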