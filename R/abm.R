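#' Derive lattice model parameters from continuum constants
#'
#' The biased-random-walk lattice model and the continuum systems are linked
#' by the mapping `D = mu h^2 / 4`, `chi = mu k h^2` with `mu = Pm / dt`.
#' Given continuum parameters, a lattice spacing and a per-step movement
#' probability, this returns the lattice parameters that reproduce them:
#' `dt = Pm / mu`, `k = chi / (mu h^2)`, `Pp = (lambda / mu) * Pm`.
#'
#' Tip cells move to the four nearest neighbours with probabilities
#' `1/4 + b` (up-gradient in x), `1/4 - b` (down-gradient) and `1/4` in each
#' y direction, where `b = (k/4) (C(x+h) - C(x-h))`; for the linear TAF
#' field `b = k nu h / 2`, constant in space. Validity requires
#' `0 <= b <= 1/4` everywhere. Each sprout carries an identity: a tip
#' moving onto a tip-occupied site is removed when tip-to-tip anastomosis
#' is active (`a_n = 1`); a tip moving onto a stalk site of a *different*
#' sprout fuses with that vessel and is removed (tip-to-sprout
#' anastomosis), while re-entering its own trail is a blocked move. The
#' continuum `a_e` is the fitted effectiveness of these fusion events, not
#' a lattice probability. Vacated sites always become stalk.
#'
#' @param params A [continuum_params()] object.
#' @param lattice_spacing Lattice parameter `h`. Default `sqrt(4 D / mu)`,
#'   the value forced by the diffusion mapping when `Pm = 1`.
#' @param Pm Per-step movement probability, in `(0, 1]`.
#' @param Lx,Ly Simulated lattice extent. `Lx` may be smaller than the
#'   continuum domain `L` when the cell mass provably stays near the parent
#'   vessel over the simulated window (columns beyond `Lx` are empty).
#' @param seed_columns Integer vector of 1-based column indices seeded fully
#'   with tip cells at `t = 0`. Default: the column at `x = 0`.
#' @param self_fuse If `TRUE`, a tip re-entering its own sprout's trail also
#'   fuses (is removed) instead of aborting the move; by default
#'   anastomosis only occurs with other vessels.
#' @param branch_new_sprout If `TRUE`, a branched tip starts a sprout of its
#'   own (so it can later fuse with its parent vessel); by default it
#'   inherits the parent's identity, since at birth it is surrounded by the
#'   parent's trail and a new branch remains part of the same vascular tree
#'   until it fuses with another vessel.
#' @return An object of class `abm_params`.
#' @examples
#' p <- continuum_params(D = 1e-3, chi = 0.4, mu = 160, lambda = 0.16,
#'                       a_e = 0.0391, nu = 1, L = 10)
#' abm_params(p, Lx = 0.5) # k = 100, dt = 1/160, Pp = 1e-3
#' @export
abm_params <- function(params, lattice_spacing = sqrt(4 * params$D / params$mu),
                       Pm = 1, Lx = params$L, Ly = 1,
                       seed_columns = 1L, self_fuse = FALSE,
                       branch_new_sprout = FALSE) {
  h <- lattice_spacing
  stopifnot(h > 0, Pm > 0, Pm <= 1, Lx > 0, Ly > 0)
  mu <- params$mu
  dt <- Pm / mu
  k <- params$chi / (mu * h^2)
  Pp <- params$lambda / mu * Pm
  if (Pp > 1) abort("branch probability per step Pp = lambda/mu * Pm exceeds 1.")
  nx <- max(2L, as.integer(round(Lx / h)))
  ny <- max(2L, as.integer(round(Ly / h)))
  x_sites <- (seq_len(nx) - 1) * h
  b <- (k / 4) * (taf_concentration(x_sites + h, params) -
                    taf_concentration(x_sites - h, params))
  if (any(b < 0) || any(b > 0.25 + 1e-12))
    abort(sprintf("invalid movement bias: b must lie in [0, 1/4], got range [%g, %g].",
                  min(b), max(b)))
  structure(
    list(h = h, k = k, Pm = Pm, Pp = Pp, dt = dt,
         mu = mu, lambda = params$lambda, nu = params$nu,
         a_n_flag = as.integer(params$a_n),
         nx = nx, ny = ny, Lx = Lx, Ly = Ly,
         x_sites = x_sites, bias = pmin(b, 0.25),
         seed_columns = as.integer(seed_columns),
         self_fuse = as.integer(self_fuse),
         branch_new_sprout = as.integer(branch_new_sprout)),
    class = "abm_params"
  )
}

#' @export
print.abm_params <- function(x, ...) {
  cat("<abm_params>\n")
  cat(sprintf("  h = %g, k = %g, Pm = %g, Pp = %g, dt = %g\n",
              x$h, x$k, x$Pm, x$Pp, x$dt))
  cat(sprintf("  lattice %d x %d (nx x ny), a_n_flag = %d, bias range [%g, %g]\n",
              x$nx, x$ny, x$a_n_flag, min(x$bias), max(x$bias)))
  invisible(x)
}

# Fresh lattice with the configured seed columns fully tip-occupied; each
# seeded tip starts its own sprout (negative codes are tips, positive are
# stalk, magnitudes are sprout ids).
new_abm_grid <- function(abm) {
  grid <- matrix(0L, abm$ny, abm$nx)
  nseed <- abm$ny * length(abm$seed_columns)
  grid[, abm$seed_columns] <- -seq_len(nseed)
  grid
}

branch_probs <- function(abm) {
  pmin(1, abm$Pp * pmax(0, abm$nu * abm$x_sites))
}

#' Advance a lattice state by one update sweep
#'
#' Low-level single-step interface, mainly useful for inspecting the update
#' rules on hand-built lattices.
#' Each tip, visited in a freshly shuffled order, attempts a biased move
#' (vacated site becomes stalk of the tip's sprout; moving onto a foreign
#' stalk removes the tip by tip-to-sprout anastomosis, onto its own trail
#' aborts, onto a tip removes it only when tip-to-tip anastomosis is
#' active) and then branches with probability `Pp * C(x)`, placing a tip of
#' a new sprout on a uniformly chosen vacant neighbour.
#'
#' @param state A list with elements `grid` (integer matrix ny x nx; 0
#'   vacant, negative tip, positive stalk, magnitude = sprout id) and `t`.
#' @param abm An [abm_params()] object matching the grid dimensions.
#' @return The updated state (time advanced by `dt`).
#' @export
abm_step <- function(state, abm) {
  stopifnot(nrow(state$grid) == abm$ny, ncol(state$grid) == abm$nx)
  res <- cpp_abm_run(state$grid, abm$bias, branch_probs(abm), abm$Pm,
                     abm$a_n_flag, abm$self_fuse, abm$branch_new_sprout, 1L)
  list(grid = res$grid, t = state$t + abm$dt, n_tips = res$n_tips)
}

#' Column-average a lattice state into 1-D density profiles
#'
#' For each lattice column the tip density `N` and stalk density `E` are the
#' occupancy fractions (count / sites per column); grid positions are the
#' column x-coordinates.
#'
#' @param state A list with elements `grid` and `t` (see [abm_step()]).
#' @param abm The matching [abm_params()] object.
#' @return A tibble with columns `x`, `N`, `E`, `t`.
#' @export
column_average <- function(state, abm) {
  g <- state$grid
  tibble::tibble(
    x = abm$x_sites,
    N = colMeans(g < 0L),
    E = colMeans(g > 0L),
    t = state$t
  )
}

#' Simulate one realisation of the lattice sprouting model
#'
#' Runs the biased random walk with branching and anastomosis from the
#' seeded initial state and records column-averaged profiles at the
#' requested output times (rounded to whole steps of `dt`).
#'
#' @param abm An [abm_params()] object.
#' @param t_out Increasing vector of output times (> 0).
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called
#'   first so the realisation is reproducible.
#' @return A tibble with columns `x`, `N`, `E`, `t` (one block per output
#'   time).
#' @export
simulate_abm <- function(abm, t_out, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  steps <- as.integer(round(t_out / abm$dt))
  stopifnot(all(steps >= 1), !is.unsorted(steps, strictly = TRUE))
  res <- cpp_abm_run(new_abm_grid(abm), abm$bias, branch_probs(abm), abm$Pm,
                     abm$a_n_flag, abm$self_fuse, abm$branch_new_sprout, steps)
  # outputs are labelled with the requested times (each within dt/2 of the
  # realised step time)
  purrr::map2_dfr(res$profiles, t_out, function(m, t) {
    tibble::tibble(x = abm$x_sites, N = m[, 1], E = m[, 2], t = t)
  })
}

#' Ensemble-averaged lattice simulation
#'
#' Repeats [simulate_abm()] over independent realisations drawn from a
#' single seeded RNG stream and averages the column-averaged profiles,
#' emulating the ensemble means used to initialise and calibrate the
#' continuum models. Deterministic given `seed` and `n`.
#'
#' @param abm An [abm_params()] object.
#' @param n Number of realisations (>= 1).
#' @param t_out Increasing vector of output times.
#' @param seed Integer seed for the ensemble stream.
#' @return A tibble with columns `x`, `N`, `E`, `t`, carrying attributes
#'   `n_realisations` and `seed`.
#' @export
simulate_abm_ensemble <- function(abm, n, t_out, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  steps <- as.integer(round(t_out / abm$dt))
  stopifnot(all(steps >= 1), !is.unsorted(steps, strictly = TRUE))
  pb <- branch_probs(abm)
  acc <- vector("list", length(steps))
  for (r in seq_len(n)) {
    res <- cpp_abm_run(new_abm_grid(abm), abm$bias, pb, abm$Pm,
                       abm$a_n_flag, abm$self_fuse, abm$branch_new_sprout, steps)
    for (i in seq_along(steps)) {
      acc[[i]] <- if (r == 1) res$profiles[[i]] else acc[[i]] + res$profiles[[i]]
    }
  }
  out <- purrr::map2_dfr(acc, t_out, function(m, t) {
    tibble::tibble(x = abm$x_sites, N = m[, 1] / n, E = m[, 2] / n, t = t)
  })
  attr(out, "n_realisations") <- n
  attr(out, "seed") <- seed
  out
}
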