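#' Continuum model parameters
#'
#' Bundles the dimensional constants shared by the snail-trail PDE (ST-PDE),
#' the coarse-grained Pillay PDE (P-PDE) and the quasi-steady TAF field.
#' The TAF (tumour angiogenic factor) concentration is taken at quasi-steady
#' state, `C(x) = nu * x`, i.e. a linear ramp from the parent vessel at
#' `x = 0` towards the TAF source.
#'
#' @param D Tip-cell random motility coefficient (length^2 / time).
#' @param chi Chemotactic sensitivity (length^2 / (time * concentration)).
#' @param mu Tip movement rate constant (1 / time).
#' @param lambda Branching rate constant (1 / (time * concentration)).
#' @param a_e Tip-to-sprout anastomosis effectiveness, in `[0, 1]`.
#' @param a_n Tip-to-tip anastomosis switch, 0 or 1.
#' @param L Domain length.
#' @param nu TAF gradient (1 / length). Defaults to `1 / L`, which pins the
#'   TAF boundary data to `C(0) = 0`, `C(L) = 1`. The rescaled comparison
#'   regimes instead use `nu = 1` (see `regime()`), where `nu` is decoupled
#'   from `L`.
#' @param t0 Initial time (> 0). Continuum solutions are started at `t0 > 0`
#'   so that early anastomosis has already brought densities into the
#'   well-posed range `1 - a_n N - a_e E >= 0`.
#' @param gamma TAF time-scale ratio; retained for completeness but fixed at
#'   0 (quasi-steady TAF) in every solver.
#'
#' @return An object of class `continuum_params` (a named list).
#' @examples
#' p <- continuum_params(D = 1e-3, chi = 0.4, mu = 160, lambda = 0.16,
#'                       a_e = 0.0391, nu = 1, L = 10)
#' kappa(p)
#' @export
continuum_params <- function(D, chi, mu, lambda, a_e, a_n = 1, L = 1,
                             nu = 1 / L, t0 = 0.2, gamma = 0) {
  stopifnot(D > 0, chi > 0, mu > 0, lambda >= 0, nu > 0, L > 0, t0 > 0)
  if (!a_n %in% c(0, 1)) abort("`a_n` must be 0 or 1 (tip-to-tip anastomosis switch).")
  if (a_e < 0 || a_e > 1) abort("`a_e` must lie in [0, 1].")
  if (gamma != 0) abort("Only the quasi-steady TAF limit (`gamma = 0`) is supported.")
  structure(
    list(D = D, chi = chi, mu = mu, lambda = lambda, a_e = a_e, a_n = a_n,
         L = L, nu = nu, t0 = t0, gamma = gamma),
    class = "continuum_params"
  )
}

#' @export
print.continuum_params <- function(x, ...) {
  cat("<continuum_params>\n")
  cat(sprintf("  D = %g, chi = %g, mu = %g, lambda = %g\n",
              x$D, x$chi, x$mu, x$lambda))
  cat(sprintf("  a_n = %g, a_e = %g, nu = %g, L = %g, t0 = %g\n",
              x$a_n, x$a_e, x$nu, x$L, x$t0))
  g <- dimensionless_groups(x, require_beta = FALSE)
  cat(sprintf("  epsilon = %.4g, alpha = %.4g, beta = %s, Psi = %.4g\n",
              g$epsilon, g$alpha,
              if (is.na(g$beta)) "NA (a_n = 0)" else sprintf("%.4g", g$beta),
              g$Psi))
  invisible(x)
}

#' Quasi-steady TAF concentration
#'
#' The linear TAF field `C(x) = nu * x`.
#'
#' @param x Positions.
#' @param params A [continuum_params()] object.
#' @return Numeric vector of concentrations.
#' @export
taf_concentration <- function(x, params) {
  params$nu * x
}

#' Snail-trail stalk production correction factor
#'
#' The stalk equation of the ST-PDE converts the *net* tip-cell flux into a
#' *total* path length laid down by tips; `kappa = mu / (chi |dC/dx|)`
#' corrects for the difference. For the linear TAF field the gradient is the
#' constant `nu`, so `kappa` is constant in space.
#'
#' @param params A [continuum_params()] object.
#' @return The scalar correction factor.
#' @export
kappa <- function(params) {
  grad <- abs(params$nu)
  if (grad == 0) abort("kappa is undefined where the TAF gradient vanishes.")
  params$mu / (params$chi * grad)
}

#' Dimensionless groups of the sprouting models
#'
#' Computes `epsilon = sqrt(D * lambda) / (chi * nu)` (ratio of diffusive to
#' chemotactic transport on the branching time scale), `alpha = lambda / mu`
#' (branching per movement event), `beta = a_e * mu / (a_n * lambda)`
#' (tip-to-sprout anastomosis strength at leading order) and
#' `Psi = alpha / epsilon^2`. The asymptotic reduction assumes
#' `epsilon << 1` and `alpha = epsilon^2 * Psi << 1` with `Psi = O(1)`.
#'
#' @param params A [continuum_params()] object.
#' @param require_beta If `TRUE` (default), signal an error when `a_n = 0`
#'   makes `beta` undefined; otherwise return `NA` for `beta`.
#' @return A one-row tibble with columns `epsilon`, `alpha`, `beta`, `Psi`.
#' @examples
#' p <- continuum_params(D = 1e-3, chi = 0.4, mu = 160, lambda = 0.16,
#'                       a_e = 0.0391, nu = 1, L = 10)
#' dimensionless_groups(p) # epsilon = 10^-1.5, alpha = 1e-3, beta = 39.1
#' @export
dimensionless_groups <- function(params, require_beta = TRUE) {
  eps <- sqrt(params$D * params$lambda) / (params$chi * params$nu)
  alpha <- params$lambda / params$mu
  if (params$a_n == 0) {
    if (require_beta) abort("beta is undefined when a_n = 0.")
    beta <- NA_real_
  } else {
    beta <- params$a_e * params$mu / (params$a_n * params$lambda)
  }
  tibble::tibble(epsilon = eps, alpha = alpha, beta = beta,
                 Psi = alpha / eps^2)
}
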