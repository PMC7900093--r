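#' Early-time self-similar tip profile: the nonlinear boundary-value problem
#'
#' For tip-to-sprout anastomosis of moderate strength (`beta ~ O(1)`, and
#' identically for `beta << 1`) the leading-order tip density admits the
#' early-time self-similar form `U0(y, tau) = tau^-1 Utilde(z)` with
#' similarity variable `z = tau^(-1/2) (y - sigma(tau) tau)`. The profile
#' solves the two-point boundary-value problem
#' `Utilde'' + (z/2) Utilde' + Utilde = Utilde^2`, `Utilde(+/-Inf) = 0`,
#' whose nontrivial branch is a bell curve. The solver uses damped Newton
#' iteration on a central-difference collocation with homogeneous Dirichlet
#' ends on a truncated interval, started from a unit-height Gaussian (the
#' trivial branch is detected and rejected).
#'
#' @param zmax Half-width of the truncated similarity interval.
#' @param n Number of grid nodes.
#' @param init Optional initial guess on the grid (default: Gaussian of
#'   unit height).
#' @param tol Newton convergence tolerance on the max update.
#' @return A `similarity_profile` tibble with columns `z`, `U`, and
#'   attributes `A = -1` (amplitude exponent), `case = "order1"`, and
#'   `residual` (max interior ODE residual).
#' @export
solve_similarity_bvp <- function(zmax = 12, n = 4801, init = NULL,
                                 tol = 1e-12) {
  z <- seq(-zmax, zmax, length.out = n)
  dz <- z[2] - z[1]
  U <- if (is.null(init)) exp(-z^2 / 4) else init
  U[c(1, n)] <- 0
  zi <- z[2:(n - 1)]
  for (it in 1:100) {
    Ui <- U[2:(n - 1)]
    Um <- U[1:(n - 2)]; Up <- U[3:n]
    FF <- (Um - 2 * Ui + Up) / dz^2 + (zi / 2) * (Up - Um) / (2 * dz) + Ui - Ui^2
    sub <- rep(1 / dz^2, n - 2) - zi / (4 * dz)
    dia <- rep(-2 / dz^2, n - 2) + 1 - 2 * Ui
    sup <- rep(1 / dz^2, n - 2) + zi / (4 * dz)
    dU <- thomas_solve(sub, dia, sup, -FF)
    step <- 1
    if (max(abs(dU)) > 1) step <- 1 / max(abs(dU)) # damped step far from the root
    U[2:(n - 1)] <- Ui + step * dU
    if (max(abs(dU)) < tol) break
  }
  if (max(U) < 1e-3)
    abort("Newton iteration converged to the trivial branch; restart with a different initial guess.")
  Ui <- U[2:(n - 1)]; Um <- U[1:(n - 2)]; Up <- U[3:n]
  res <- max(abs((Um - 2 * Ui + Up) / dz^2 + (zi / 2) * (Up -Um) / (2 * dz) + Ui - Ui^2))
  structure(tibble::tibble(z = z, U = U),
            A = -1, case = "order1", residual = res,
            class = c("similarity_profile", class(tibble::tibble())))
}

# Tridiagonal (Thomas) solve for the Newton updates.
thomas_solve <- function(sub, dia, sup, rhs) {
  n <- length(dia)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- sup[1] / dia[1]
  dp[1] <- rhs[1] / dia[1]
  for (i in 2:n) {
    m <- dia[i] - sub[i] * cp[i - 1]
    cp[i] <- sup[i] / m
    dp[i] <- (rhs[i] - sub[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Early-time self-similar profile in the strong tip-to-sprout limit
#'
#' When `beta >> 1` tip-to-tip anastomosis drops from the leading-order
#' balance and the similarity equation becomes linear,
#' `Utilde'' + (z/2) Utilde' - A Utilde = 0`, `Utilde(+/-Inf) = 0`, with
#' `U0 = tau^A Utilde(z)`. Decay at both ends together with non-negativity
#' forces `A = -1/2`, and the profile is the Gaussian
#' `Utilde(z) = C1 exp(-z^2 / 4)`.
#'
#' @param z Similarity variable value(s).
#' @param C1 Non-negative amplitude.
#' @return `C1 * exp(-z^2/4)` evaluated at `z`.
#' @export
similarity_gaussian <- function(z, C1 = 1) {
  stopifnot(C1 >= 0)
  C1 * exp(-z^2 / 4)
}

#' Gaussian similarity profile as a profile object
#'
#' Convenience wrapper returning the `beta >> 1` Gaussian in the same form
#' as [solve_similarity_bvp()], with exponent `A = -1/2`.
#'
#' @inheritParams solve_similarity_bvp
#' @param C1 Gaussian amplitude.
#' @return A `similarity_profile` tibble with attributes `A = -1/2`,
#'   `case = "large_beta"`.
#' @export
similarity_profile_gaussian <- function(C1 = 1, zmax = 12, n = 4801) {
  z <- seq(-zmax, zmax, length.out = n)
  structure(tibble::tibble(z = z, U = similarity_gaussian(z, C1)),
            A = -1 / 2, case = "large_beta", residual = 0,
            class = c("similarity_profile", class(tibble::tibble())))
}

#' Map a self-similar profile to laboratory (rescaled) coordinates
#'
#' Transforms a similarity profile into curves over the rescaled spatial
#' variable `X` at given times, using
#' `X = z sqrt(tau) + phi(tau) tau + X0 / epsilon` with wave speed
#' `phi(tau) = 1/epsilon + sigma(tau)`, and amplitude scaling `tau^A`.
#'
#' @param profile A `similarity_profile` (see [solve_similarity_bvp()]).
#' @param tau Vector of output times (dimensionless).
#' @param phi Wave speed `phi(tau)`: a scalar, or a vector matching `tau`.
#' @param X0 Frame offset.
#' @param epsilon The small parameter of the asymptotic reduction.
#' @param domain Optional length-2 numeric; if supplied, mapped `X` values
#'   falling entirely outside it raise an error.
#' @param anchor Optional one-point amplitude normalisation: a list
#'   `list(tau = ..., max = ...)` scaling the profile so that the mapped
#'   curve at `anchor$tau` has maximum `anchor$max` (used to pin the
#'   self-similar curve to the full-model amplitude at the earliest output).
#' @return A tibble with columns `X`, `z`, `u`, `tau`.
#' @export
similarity_to_lab <- function(profile, tau, phi, X0, epsilon,
                              domain = NULL, anchor = NULL) {
  A <- attr(profile, "A")
  phi <- rep_len(phi, length(tau))
  scale <- 1
  if (!is.null(anchor)) {
    scale <- anchor$max / (anchor$tau^A * max(profile$U))
  }
  out <- purrr::map2_dfr(tau, phi, function(tt, ph) {
    X <- profile$z * sqrt(tt) + ph * tt + X0 / epsilon
    tibble::tibble(X = X, z = profile$z, u = scale * tt^A * profile$U, tau = tt)
  })
  if (!is.null(domain)) {
    inside <- out$X >= domain[1] & out$X <= domain[2]
    if (!any(inside)) abort("mapped similarity curve falls entirely outside the configured domain.")
  }
  out
}
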