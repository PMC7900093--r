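#' Deterministic Gaussian pulse initial condition
#'
#' Lattice-free stand-in for an ensemble-derived initial profile: a
#' Gaussian tip pulse with prescribed centroid, width and integral, and
#' zero stalk density. Signals an error if the pulse is so concentrated
#' that its peak violates the well-posedness guard `a_n N <= 1`.
#'
#' @param x Grid node positions (uniform, increasing).
#' @param center Pulse centroid (inside the grid).
#' @param width Gaussian standard deviation.
#' @param mass Integral of the tip density.
#' @param a_n Tip-to-tip switch used in the guard check.
#' @return A tibble with columns `x`, `N`, `E`.
#' @export
make_pulse_ic <- function(x, center, width, mass = 1, a_n = 1) {
  stopifnot(width > 0, mass >= 0)
  if (center < min(x) || center > max(x))
    abort("pulse center must lie inside the grid.")
  peak <- mass / (width * sqrt(2 * pi))
  if (a_n * peak > 1)
    abort(sprintf("pulse too concentrated: peak density %.3g violates the guard a_n N <= 1.", peak))
  tibble::tibble(x = x, N = mass * stats::dnorm(x, center, width), E = 0)
}

#' Registry of the captioned comparison regimes
#'
#' Returns the configuration for one of the five standard experiment
#' families, each pinned to the parameter set of its published comparison:
#' `"fig1"` (dimensional ST-vs-P comparison on `x` in `[0, 10]`),
#' `"fig2"` (leading-order vs full ST-PDE, rescaled variables),
#' `"fig3"` (long-time rescaled ST-vs-P comparison, wave speeds, decay
#' slope), `"fig4"` (self-similar overlay, same parameters as `"fig3"`),
#' and `"fig5"` (high-branching ensemble calibration). For regimes whose
#' caption prints the dimensionless groups, the derived
#' `(epsilon, alpha, beta)` are checked against the printed values at load
#' time (relative tolerance 1e-6).
#'
#' @param name Regime name.
#' @return A list with elements `name`, `params`, `t_out`, plus per-regime
#'   extras (`abm_Lx`, `nx`, `n_realisations` defaults, `abm_lambda`,
#'   `t_dense`, `caption_groups`).
#' @export
regime <- function(name = c("fig1", "fig2", "fig3", "fig4", "fig5")) {
  name <- match.arg(name)
  cfg <- switch(
    name,
    fig1 = list(
      # PDEs use nu = 1 (epsilon = 0.0166; with nu = 1/L the regime would sit
      # at epsilon = 0.166, where the two models are visibly distinguishable).
      # The lattice bias bound b <= 1/4 admits no matched walk at nu = 1, so
      # the initial data come from the lattice model driven by the steepest
      # admissible TAF ramp, nu_lattice = 1/L.
      params = continuum_params(D = 5e-4, chi = 0.425, mu = 150, lambda = 0.1,
                                a_e = 0.05, a_n = 1, L = 10, nu = 1, t0 = 0.2),
      abm_nu = 0.1,
      t_out = seq(0.2, 19.4, by = 1.2),
      abm_Lx = 0.4, nx = 2001, n_realisations = 200
    ),
    fig2 = list(
      params = continuum_params(D = 1e-3, chi = 0.4, mu = 160, lambda = 0.16,
                                a_e = 0.0391, a_n = 1, L = 1, nu = 1, t0 = 0.2),
      t_out = seq(0.2, 2, by = 0.2),
      abm_Lx = 0.4, nx = 1401, n_realisations = 200,
      caption_groups = c(epsilon = 10^-1.5, alpha = 1e-3, beta = 39.1)
    ),
    fig3 = list(
      params = continuum_params(D = 1e-3, chi = 0.4, mu = 160, lambda = 0.16,
                                a_e = 0.0391, a_n = 1, L = 10, nu = 1, t0 = 0.2),
      t_out = seq(0.2, 19.4, by = 1.6),
      t_dense = seq(0.2, 2.5, by = 0.1),
      abm_Lx = 0.4, nx = 4001, n_realisations = 200,
      caption_groups = c(epsilon = 10^-1.5, alpha = 1e-3, beta = 39.1)
    ),
    fig4 = list(
      params = continuum_params(D = 1e-3, chi = 0.4, mu = 160, lambda = 0.16,
                                a_e = 0.0391, a_n = 1, L = 10, nu = 1, t0 = 0.2),
      t_out = seq(0.2, 5, by = 0.4),
      abm_Lx = 0.4, nx = 4001, n_realisations = 200,
      caption_groups = c(epsilon = 10^-1.5, alpha = 1e-3, beta = 39.1)
    ),
    fig5 = list(
      params = continuum_params(D = 1e-3, chi = 0.4, mu = 160, lambda = 1,
                                a_e = 0.04, a_n = 1, L = 1, nu = 1, t0 = 0.2),
      t_out = seq(0.2, 2, by = 0.2),
      abm_lambda = 8, # branching probability per step Pp = lambda/mu = 5e-2
      abm_Lx = 1, nx = 401, n_realisations = 200
    )
  )
  cfg$name <- name
  if (!is.null(cfg$caption_groups)) {
    g <- dimensionless_groups(cfg$params)
    got <- c(epsilon = g$epsilon, alpha = g$alpha, beta = g$beta)
    rel <- abs(got - cfg$caption_groups) / abs(cfg$caption_groups)
    if (any(rel > 1e-6))
      abort(sprintf("regime '%s': derived dimensionless groups disagree with the captioned values.", name))
  }
  cfg
}

# ABM ensemble for a regime config: truncated lattice near the parent
# vessel (mass cannot reach beyond abm_Lx over the simulated window).
regime_ensemble <- function(cfg, t_out, n, seed) {
  p_abm <- cfg$params
  if (!is.null(cfg$abm_lambda)) p_abm$lambda <- cfg$abm_lambda
  if (!is.null(cfg$abm_nu)) p_abm$nu <- cfg$abm_nu
  abm <- abm_params(p_abm, Lx = cfg$abm_Lx, Ly = 1)
  simulate_abm_ensemble(abm, n = n, t_out = t_out, seed = seed)
}

#' Run one captioned comparison regime end to end
#'
#' Executes the full pipeline for a [regime()] configuration: lattice
#' ensemble generation (or a deterministic pulse fixture), continuum
#' solves, and the regime's comparison metrics. Fully deterministic given
#' `seed`.
#'
#' @param cfg A [regime()] configuration (or a regime name).
#' @param seed Integer seed for the ensemble stream.
#' @param n_realisations Ensemble size; default from the config.
#' @param nx PDE grid size; default from the config.
#' @param fixture_ic If `TRUE`, replace the lattice ensemble initial
#'   condition with a deterministic Gaussian pulse (useful for fast,
#'   noise-free checks). Ignored for `"fig5"`, whose calibration targets
#'   are the ensemble data themselves.
#' @param rtol,atol Integrator tolerances passed to the solvers.
#' @return A named list report; components depend on the regime (PDE
#'   solutions, comparison tibbles, speed series, slope fits, calibration
#'   fits).
#' @export
run_regime <- function(cfg, seed = 1L, n_realisations = NULL, nx = NULL,
                       fixture_ic = FALSE, rtol = 1e-8, atol = 1e-10) {
  if (is.character(cfg)) cfg <- regime(cfg)
  n <- n_realisations %||% cfg$n_realisations
  nx <- nx %||% cfg$nx
  p <- cfg$params

  make_ic <- function() {
    if (fixture_ic) {
      xg <- seq(0, min(cfg$abm_Lx, p$L), length.out = 801)
      drift <- p$chi * p$nu * p$t0
      make_pulse_ic(xg, center = drift, width = max(drift / 2, 4 * sqrt(p$D * p$t0)),
                    mass = 0.5 * drift)
    } else {
      ens <- regime_ensemble(cfg, t_out = p$t0, n = n, seed = seed)
      ens[ens$t == p$t0, ]
    }
  }

  switch(
    cfg$name,
    fig1 = {
      ic <- make_ic()
      st <- solve_st_pde(ic, p, cfg$t_out, nx = nx, rtol = rtol, atol = atol)
      pp <- solve_p_pde(ic, p, cfg$t_out, nx = nx, rtol = rtol, atol = atol)
      list(name = "fig1", params = p, ic = ic, st = st, pillay = pp,
           comparison = compare_solutions(st, pp, reference = "b"))
    },
    fig2 = {
      ic <- make_ic()
      st <- solve_st_pde(ic, p, cfg$t_out, nx = nx, rtol = rtol, atol = atol)
      lo <- solve_leading_order(ic, p, tau_out = p$lambda * cfg$t_out,
                                nx = nx, rtol = rtol, atol = atol)
      st_resc <- rescale_profile(st, p)
      st_cmp <- tibble::tibble(x = st_resc$X, N = st_resc$u, E = st_resc$w,
                               t = round(st_resc$tau, 10))
      lo_cmp <- tibble::tibble(x = lo$X, N = lo$u0, E = lo$w0,
                               t = round(lo$tau, 10))
      # The reduction holds in the domain interior only: once the front
      # reaches the no-flux wall at the TAF source, the full model grows an
      # O(epsilon) boundary layer (brush border) that the far-field
      # leading-order problem cannot carry, so the comparison excludes a
      # 10*epsilon margin at the right wall.
      eps <- dimensionless_groups(p)$epsilon
      XR <- p$L * sqrt(p$lambda / p$D)
      interior <- function(d) d[d$x < XR - 10 * eps, ]
      list(name = "fig2", params = p, ic = ic, st = st, leading_order = lo,
           comparison = compare_solutions(interior(lo_cmp), interior(st_cmp),
                                          reference = "b"))
    },
    fig3 = ,
    fig4 = {
      ic <- make_ic()
      t_all <- sort(unique(c(cfg$t_out, cfg$t_dense)))
      st <- solve_st_pde(ic, p, t_all, nx = nx, rtol = rtol, atol = atol)
      pp <- solve_p_pde(ic, p, t_all, nx = nx, rtol = rtol, atol = atol)
      keep <- function(sol) sol[sol$t %in% cfg$t_out, ]
      comparison <- compare_solutions(keep(st), keep(pp), reference = "b")
      sp_st <- estimate_wave_speed(keep(st))
      sp_pp <- estimate_wave_speed(keep(pp))
      speed_rel <- mean(abs(sp_pp$speed - sp_st$speed) / sp_st$speed)
      out <- list(name = cfg$name, params = p, ic = ic, st = st, pillay = pp,
                  comparison = comparison, speed_st = sp_st, speed_pillay = sp_pp,
                  speed_rel_diff = speed_rel)
      if (!is.null(cfg$t_dense)) {
        peaks <- dplyr::summarise(dplyr::group_by(pp[pp$t %in% cfg$t_dense, ], .data$t),
                                  peak = max(.data$N), .groups = "drop")
        tau <- p$lambda * peaks$t
        out$slope_fit <- fit_powerlaw_slope(tau, peaks$peak, tau_max = 0.4)
      }
      if (cfg$name == "fig4") {
        bvp <- solve_similarity_bvp()
        g <- dimensionless_groups(p)
        st_resc <- rescale_profile(st, p)
        st_sp <- estimate_wave_speed(
          tibble::tibble(x = st_resc$X, N = st_resc$u, t = st_resc$tau))
        phi <- mean(st_sp$speed)
        frame0 <- moving_frame(p, 0)
        # anchor at the earliest output: match the full-model amplitude
        tau0 <- p$lambda * min(cfg$t_out)
        u_max0 <- max(st_resc$u[abs(st_resc$tau - tau0) < 1e-10])
        # offset chosen so the mapped peak coincides with the full-model
        # peak at the earliest output
        X_peak0 <- st_sp$position[1]
        X0 <- g$epsilon * (X_peak0 - phi * tau0)
        overlay <- similarity_to_lab(bvp, tau = p$lambda * cfg$t_out, phi = phi,
                                     X0 = X0, epsilon = g$epsilon,
                                     anchor = list(tau = tau0, max = u_max0))
        mism <- purrr::map_dbl(p$lambda * cfg$t_out, function(tt) {
          ov <- overlay[overlay$tau == tt, ]
          stt <- st_resc[abs(st_resc$tau - tt) < 1e-10, ]
          u_ov <- approx(ov$X, ov$u, xout = stt$X, yleft = 0, yright = 0)$y
          max(abs(u_ov - stt$u)) / max(stt$u)
        })
        out$similarity <- bvp
        out$phi <- phi
        out$X0 <- X0
        out$overlay <- overlay
        out$similarity_mismatch <- tibble::tibble(tau = p$lambda * cfg$t_out,
                                                  rel_diff = mism)
      }
      out
    },
    fig5 = {
      abm_data <- regime_ensemble(cfg, t_out = cfg$t_out, n = n, seed = seed)
      fit_st <- fit_continuum_params(abm_data, "st", p, nx = nx, rtol = 1e-6, atol = 1e-8)
      fit_pp <- fit_continuum_params(abm_data, "pillay", p, nx = nx, rtol = 1e-6, atol = 1e-8)
      st <- solve_fitted(fit_st, times = cfg$t_out, nx = nx, rtol = rtol, atol = atol)
      pp <- solve_fitted(fit_pp, times = cfg$t_out, nx = nx, rtol = rtol, atol = atol)
      comparison <- compare_solutions(st, pp, reference = "b")
      # Tip pulses have a proper half-maximum front; for stalks the frozen
      # initial wake dominates the per-time maximum, so the advancing front
      # is tracked on the newly deposited stalk E - E(t0).
      edge_speeds <- function(sol) {
        t0s <- min(sol$t)
        ic_E <- sol[sol$t == t0s, ]
        new_stalk <- dplyr::mutate(
          dplyr::group_by(sol, .data$t),
          E = pmax(.data$E - approx(ic_E$x, ic_E$E, xout = .data$x,
                                    yleft = 0, yright = 0)$y, 0))
        new_stalk <- dplyr::ungroup(new_stalk)
        c(N = mean_speed(track_leading_edge(sol, "N")),
          E = mean_speed(track_leading_edge(new_stalk[new_stalk$t > t0s, ], "E")))
      }
      v_abm <- edge_speeds(abm_data)
      v_st <- edge_speeds(st)
      v_pp <- edge_speeds(pp)
      edge_rel <- c(abs(v_st - v_abm) / v_abm, abs(v_pp - v_abm) / v_abm)
      names(edge_rel) <- c("st_N", "st_E", "pillay_N", "pillay_E")
      list(name = "fig5", params = p, abm = abm_data,
           fit_st = fit_st, fit_pillay = fit_pp, st = st, pillay = pp,
           comparison = comparison,
           edge_speed_abm = v_abm, edge_speed_st = v_st, edge_speed_pillay = v_pp,
           edge_speed_rel_diff = edge_rel)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
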