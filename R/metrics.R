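# Shared helper: interpolate profile `b` onto the grid of `a` at one time.
interp_onto <- function(xa, xb, vb) {
  if (length(xb) == length(xa) && all(abs(xb - xa) < 1e-12)) return(vb)
  approx(xb, vb, xout = xa, yleft = 0, yright = 0)$y
}

#' Normalized maximum pointwise difference between two profiles
#'
#' The headline comparison statistic: the largest pointwise difference over
#' the spatial domain between two single-time density profiles, normalized
#' by the maximum density of the reference profile at that time. By package
#' convention the reference is the second (coarse-grained) profile; set
#' `reference = "a"` to switch.
#'
#' @param a,b Data frames with columns `x` and the chosen field, each at a
#'   single time (`b` is interpolated onto `a`'s grid if needed).
#' @param field `"N"` (tips) or `"E"` (stalks).
#' @param reference Which profile's maximum normalizes the difference.
#' @return The scalar normalized difference (dimensionless, >= 0).
#' @export
max_relative_difference <- function(a, b, field = c("N", "E"),
                                    reference = c("b", "a")) {
  field <- match.arg(field)
  reference <- match.arg(reference)
  vb <- interp_onto(a$x, b$x, b[[field]])
  va <- a[[field]]
  ref_max <- if (reference == "b") max(b[[field]]) else max(va)
  if (ref_max <= 0) {
    if (max(abs(va - vb)) == 0) return(0) # both fields identically zero
    abort("reference profile maximum is zero; difference is undefined.")
  }
  max(abs(va - vb)) / ref_max
}

#' Per-time normalized difference curves between two solutions
#'
#' Applies [max_relative_difference()] at every shared output time of two
#' multi-time solutions (times are matched to within `t_tol`).
#'
#' @param a,b `pde_solution`-style tibbles with columns `x`, `N`, `E`, `t`.
#' @param fields Which density fields to compare.
#' @param reference As in [max_relative_difference()].
#' @param t_tol Absolute tolerance for matching output times.
#' @return A tibble with columns `t`, `field`, `max_rel_diff`.
#' @export
compare_solutions <- function(a, b, fields = c("N", "E"), reference = "b",
                              t_tol = 1e-8) {
  ta <- sort(unique(a$t))
  tb <- sort(unique(b$t))
  shared <- ta[vapply(ta, function(t) any(abs(tb - t) < t_tol), logical(1))]
  if (length(shared) == 0) abort("solutions share no output times.")
  purrr::map_dfr(shared, function(t) {
    pa <- a[abs(a$t - t) < t_tol, ]
    pb <- b[abs(b$t - tb[which.min(abs(tb - t))]) < t_tol, ]
    purrr::map_dfr(fields, function(f) {
      tibble::tibble(t = t, field = f,
                     max_rel_diff = max_relative_difference(pa, pb, f, reference))
    })
  })
}

# Parabolic (three-point) refinement of the argmax of a sampled pulse.
peak_position <- function(x, v) {
  i <- which.max(v)
  if (i == 1 || i == length(v)) return(x[i])
  num <- v[i - 1] - v[i + 1]
  den <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (den == 0) return(x[i])
  x[i] + 0.5 * num / den * (x[i + 1] - x[i])
}

is_unimodal <- function(v, frac = 0.5) {
  thr <- frac * max(v)
  n <- length(v)
  loc <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1
  sum(v[loc] > thr) <= 1
}

#' Pulse-peak wave speed series
#'
#' Tracks the pulse position (parabolic interpolation of the argmax over
#' three nodes) across output times and differentiates it with centered
#' finite differences (one-sided at the ends). Also flags whether the wave
#' accelerates (speed non-decreasing over the window).
#'
#' @param sol A multi-time solution tibble with columns `x`, `t` and the
#'   chosen field (at least 3 output times; unimodal pulses).
#' @param field Density field to track.
#' @return A tibble with columns `t`, `position`, `speed` and attribute
#'   `accelerating` (logical).
#' @export
estimate_wave_speed <- function(sol, field = "N") {
  tt <- sort(unique(sol$t))
  if (length(tt) < 3) abort("need at least 3 output times to estimate speeds.")
  pos <- vapply(tt, function(t) {
    p <- sol[sol$t == t, ]
    if (!is_unimodal(p[[field]])) abort(sprintf("profile at t = %g is not unimodal.", t))
    peak_position(p$x, p[[field]])
  }, numeric(1))
  n <- length(tt)
  speed <- numeric(n)
  speed[1] <- (pos[2] - pos[1]) / (tt[2] - tt[1])
  speed[n] <- (pos[n] - pos[n - 1]) / (tt[n] - tt[n - 1])
  if (n > 2) speed[2:(n - 1)] <- (pos[3:n] - pos[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  out <- tibble::tibble(t = tt, position = pos, speed = speed)
  attr(out, "accelerating") <- all(diff(speed) > -1e-10)
  out
}

#' Half-maximum leading-edge positions
#'
#' For each output time, returns the rightmost position at which the
#' density crosses `level * max(density)` (linear interpolation between the
#' bracketing nodes). Used for leading-edge speed comparisons, where the
#' front location is better defined than the peak for noisy ensemble data.
#'
#' @param sol A multi-time solution tibble.
#' @param field Density field.
#' @param level Fraction of the per-time maximum defining the edge.
#' @return A tibble with columns `t`, `position`.
#' @export
track_leading_edge <- function(sol, field = "N", level = 0.5) {
  tt <- sort(unique(sol$t))
  pos <- vapply(tt, function(t) {
    p <- sol[sol$t == t, ]
    v <- p[[field]]; x <- p$x
    thr <- level * max(v)
    above <- which(v >= thr)
    i <- max(above)
    if (i == length(v)) return(x[i])
    x[i] + (x[i + 1] - x[i]) * (thr - v[i]) / (v[i + 1] - v[i])
  }, numeric(1))
  tibble::tibble(t = tt, position = pos)
}

#' Mean propagation speed from a position series
#'
#' Ordinary least-squares slope of position against time; robust to
#' Monte-Carlo jitter in ensemble-derived edge positions.
#'
#' @param positions A tibble with columns `t`, `position` (e.g. from
#'   [track_leading_edge()]).
#' @return The scalar speed.
#' @export
mean_speed <- function(positions) {
  unname(coef(lm(position ~ t, data = positions))[2])
}

#' Least-squares power-law decay exponent
#'
#' Fits `log(peak) ~ log(t)` by ordinary least squares over the window
#' `t <= tau_max` and reports the slope together with the maximum relative
#' deviation of the fitted line from the data on the log scale (the "fit
#' error" used to judge how long a pure power law describes the early-time
#' amplitude decay).
#'
#' @param times Positive times.
#' @param peaks Positive peak densities at those times.
#' @param tau_max Right end of the fitting window.
#' @return A list with elements `slope`, `intercept`, `max_rel_error`, `n`.
#' @export
fit_powerlaw_slope <- function(times, peaks, tau_max = max(times)) {
  stopifnot(all(times > 0), all(peaks > 0))
  keep <- times <= tau_max + 1e-12
  if (sum(keep) < 3) abort("need at least 3 points in the fitting window.")
  lt <- log(times[keep]); lp <- log(peaks[keep])
  fit <- lm(lp ~ lt)
  err <- max(abs(fitted(fit) - lp) / abs(lp))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       max_rel_error = err, n = sum(keep))
}

#' Calibrate branching and anastomosis parameters against ensemble data
#'
#' Nonlinear least-squares estimation of `(lambda, a_e)` for either
#' continuum model from column-averaged lattice ensemble data, holding
#' `D, chi, mu, a_n` fixed. The earliest profile in `data` initialises the
#' PDE; the remaining output times contribute stacked tip and stalk
#' residuals (equal weights) on the data grid. Confidence intervals come
#' from the linearised (Gauss-Newton) covariance at the optimum.
#'
#' @param data Ensemble tibble with columns `x`, `N`, `E`, `t`.
#' @param model `"st"` (snail-trail) or `"pillay"` (coarse-grained).
#' @param params A [continuum_params()] object supplying the fixed
#'   constants and domain; its `lambda` and `a_e` entries seed the search
#'   unless `start` is given.
#' @param start Optional named vector `c(lambda = ..., a_e = ...)`.
#' @param nx PDE grid size used inside the objective.
#' @param conf_level Confidence level for the reported intervals.
#' @param ... Passed to the PDE solver (e.g. `rtol`, `scheme`).
#' @return A `sprout_fit` object; see [tidy.sprout_fit()] and
#'   [glance.sprout_fit()].
#' @export
fit_continuum_params <- function(data, model = c("st", "pillay"), params,
                                 start = NULL, nx = 401, conf_level = 0.95,
                                 ...) {
  model <- match.arg(model)
  tt <- sort(unique(data$t))
  if (length(tt) < 2) abort("need at least two output times (IC + data).")
  ic <- data[data$t == tt[1], ]
  fit_times <- tt[-1]
  obs <- data[data$t != tt[1], ]
  xdat <- sort(unique(obs$x))
  if (is.null(start)) start <- c(lambda = params$lambda, a_e = params$a_e)
  solver <- if (model == "st") solve_st_pde else solve_p_pde

  resid_fun <- function(par) {
    p <- params
    p$lambda <- par[["lambda"]]; p$a_e <- min(max(par[["a_e"]], 0), 1)
    p$t0 <- tt[1]
    sol <- suppressWarnings(solver(ic, p, fit_times, nx = nx, ...))
    unlist(lapply(fit_times, function(t) {
      ps <- sol[sol$t == t, ]
      po <- obs[obs$t == t, ]
      c(interp_onto(po$x, ps$x, ps$N) - po$N,
        interp_onto(po$x, ps$x, ps$E) - po$E)
    }), use.names = FALSE)
  }

  res <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    lower = c(lambda = 1e-6, a_e = 0),
    upper = c(lambda = Inf, a_e = 1),
    # epsfcn keeps the finite-difference Jacobian steps well above the PDE
    # integration error; the default (machine epsilon) stalls the search.
    control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-10,
                                         epsfcn = 1e-6)
  )
  if (res$info %in% c(0, 5))
    abort(sprintf("calibration did not converge (nls.lm info = %d).", res$info))
  est <- coef(res)
  if (est[["a_e"]] >= 1 - 1e-10 || est[["a_e"]] <= 0)
    warn("fitted a_e sits on the boundary of [0, 1].")
  np <- length(est)
  dof <- length(res$fvec) - np
  sigma2 <- res$deviance / dof
  covm <- tryCatch(sigma2 * solve(res$hessian), error = function(e) matrix(NA, np, np))
  se <- sqrt(diag(covm))
  tq <- qt(1 - (1 - conf_level) / 2, dof)
  structure(
    list(estimates = est, std_error = setNames(se, names(est)),
         conf_low = est - tq * se, conf_high = est + tq * se,
         conf_level = conf_level, model = model, params = params,
         deviance = res$deviance, df_residual = dof,
         n_times = length(fit_times), nls = res, ic = ic,
         fit_times = fit_times, nx = nx),
    class = "sprout_fit"
  )
}

#' @export
print.sprout_fit <- function(x, ...) {
  cat(sprintf("<sprout_fit> model = %s, %d output times, deviance = %.4g\n",
              x$model, x$n_times, x$deviance))
  print(tidy(x))
  invisible(x)
}

#' Tidy a calibration fit
#'
#' @param x A `sprout_fit` from [fit_continuum_params()].
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.sprout_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$std_error),
    conf.low = unname(x$conf_low),
    conf.high = unname(x$conf_high)
  )
}

#' One-row summary of a calibration fit
#'
#' @param x A `sprout_fit` from [fit_continuum_params()].
#' @param ... Unused.
#' @return A one-row tibble with `model`, `deviance`, `df.residual`,
#'   `n_times`, `converged`.
#' @export
glance.sprout_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    deviance = x$deviance,
    df.residual = x$df_residual,
    n_times = x$n_times,
    converged = !x$nls$info %in% c(0, 5)
  )
}

#' Refit the continuum model at the calibrated parameters
#'
#' Solves the calibrated PDE from the fit's initial condition at the fit's
#' output times (plus any extra times requested).
#'
#' @param fit A `sprout_fit`.
#' @param times Output times; default the fit window.
#' @param nx Grid size; default the fit's.
#' @param ... Passed to the solver.
#' @return A `pde_solution` tibble.
#' @export
solve_fitted <- function(fit, times = NULL, nx = NULL, ...) {
  p <- fit$params
  p$lambda <- fit$estimates[["lambda"]]
  p$a_e <- fit$estimates[["a_e"]]
  p$t0 <- unique(fit$ic$t)[1]
  solver <- if (fit$model == "st") solve_st_pde else solve_p_pde
  if (is.null(times)) times <- fit$fit_times
  if (is.null(nx)) nx <- fit$nx
  solver(fit$ic, p, times, nx = nx, ...)
}
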