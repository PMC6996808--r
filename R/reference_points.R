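#' Per-species reference-fishing parameterisation
#'
#' For reference-point analyses each species is fished by its own logistic
#' gear with unit-normalised catchability (L50 at the species' maturity
#' length, steepness `10 / Lmat`), so a fishing-mortality vector `F` is
#' applied simply as effort `F` on the corresponding gears and `F_i` equals
#' the fishing mortality on species `i`'s most-selected class.
#'
#' @param params [CommunityParams-class].
#' @return A copy of `params` whose gears are the `n_s` single-species
#'   logistic gears.
#' @export
reference_params <- function(params) {
  sp <- params@species
  gears <- data.frame(
    gear = paste0("F_", sp$species), species = sp$species,
    fun = "logistic", p1 = 10 / sp$Lmat, p2 = sp$Lmat,
    stringsAsFactors = FALSE)
  Q <- calc_catchability(params@grid, sp, gears)
  params@Q <- Q
  params@gear_names <- dimnames(Q)[[3]]
  params
}

#' Long-term yield under a fishing-mortality vector
#'
#' Runs the model for `years` from `N0` with constant per-species fishing
#' mortality (through the [reference_params()] gears) and returns each
#' species' mean annual catch weight over the final `avg_years` years.
#'
#' @param ref_params Output of [reference_params()].
#' @param N0 Initial state (typically the burn-in state, computed once and
#'   reused across evaluations).
#' @param F_vec Fishing mortality per species (1/yr).
#' @param years Run length (default 50).
#' @param avg_years Averaging window at the end of the run (default 10).
#' @return Named vector of long-term annual yields (g/yr).
#' @export
long_term_yield <- function(ref_params, N0, F_vec, years = 50, avg_years = 10) {
  n_s <- ref_params@n_s
  stopifnot(length(F_vec) == n_s, avg_years <= years)
  out <- run_community(ref_params, N0, years,
                       effort = matrix(F_vec, years, n_s, byrow = TRUE))
  spy <- ref_params@steps_per_year
  keep <- seq_len(avg_years * spy) + (years - avg_years) * spy
  annual <- vapply(seq_len(n_s), function(i)
    sum(out@Catch[, i, , keep]) / avg_years, numeric(1))
  stats::setNames(annual, ref_params@species$species)
}

#' Single-species FMSY
#'
#' Finds the fishing mortality maximising the long-term yield of one
#' species while the other species' F is held fixed: a coarse grid sweep
#' followed by golden-section refinement between the best grid point's
#' neighbours. With ties or a non-concave profile the smallest maximiser is
#' taken and a warning emitted.
#'
#' @param params [CommunityParams-class] (converted internally with
#'   [reference_params()] unless `ref = TRUE`).
#' @param species_index Which species to optimise.
#' @param F_other Fixed fishing mortalities for all species (entry
#'   `species_index` is ignored); default all zero.
#' @param F_grid Candidate F values (default `seq(0, 2, by = 0.25)`).
#' @param years,avg_years Passed to [long_term_yield()].
#' @param tol Golden-section tolerance on F (1/yr, default 0.005).
#' @param N0 Optional precomputed initial state.
#' @param ref Set TRUE if `params` already came from [reference_params()].
#' @return List with `F_MSY`, `yield`, `grid_yields`.
#' @export
calc_FMSY <- function(params, species_index, F_other = NULL,
                      F_grid = seq(0, 2, by = 0.25), years = 50,
                      avg_years = 10, tol = 0.005, N0 = NULL, ref = FALSE) {
  if (any(!is.finite(F_grid) | F_grid < 0)) stop("`F_grid` must be finite and nonnegative")
  F_grid <- sort(unique(F_grid))
  rp <- if (ref) params else reference_params(params)
  if (is.null(N0)) N0 <- get_N0(rp)
  if (is.null(F_other)) F_other <- numeric(rp@n_s)
  f_of <- function(F_i) {
    Fv <- F_other
    Fv[species_index] <- F_i
    long_term_yield(rp, N0, Fv, years, avg_years)[species_index]
  }
  ys <- vapply(F_grid, f_of, numeric(1))
  best <- which(ys >= max(ys) - .Machine$double.eps * max(1, max(ys)))
  if (length(best) > 1) {
    warning("yield profile has tied maxima; returning the smallest")
  }
  b <- best[1]
  lo <- F_grid[max(1, b - 1L)]
  hi <- F_grid[min(length(F_grid), b + 1L)]
  gs <- golden_section(f_of, lo, hi, tol = tol)
  if (gs$fx >= ys[b]) {
    list(F_MSY = gs$x, yield = gs$fx,
         grid_yields = stats::setNames(ys, F_grid))
  } else {
    list(F_MSY = F_grid[b], yield = ys[b],
         grid_yields = stats::setNames(ys, F_grid))
  }
}

# golden-section search for a maximum on [lo, hi]
golden_section <- function(f, lo, hi, tol = 0.005) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
  }
  x <- (lo + hi) / 2
  list(x = x, fx = f(x))
}

#' Multispecies Nash equilibrium of fishing mortalities
#'
#' Best-response iteration: cycle over species, replacing each `F_i` by its
#' FMSY given the other species' current values, until no component moves
#' by more than `tol` in a full sweep. At the returned vector no species'
#' long-term yield can be improved by changing only its own F (within
#' tolerance).
#'
#' @param params [CommunityParams-class].
#' @param F_init Starting F vector (default 0.5 for every species).
#' @param tol Convergence tolerance on the sweep (1/yr, default 0.01).
#' @param max_iter Maximum sweeps (default 50).
#' @param F_grid,years,avg_years,gs_tol Passed to [calc_FMSY()].
#' @return List with `F_Nash` (named vector), `converged`, `sweeps`,
#'   `history` (matrix of iterates).
#' @export
calc_nash <- function(params, F_init = NULL, tol = 0.01, max_iter = 50,
                      F_grid = seq(0, 2, by = 0.25), years = 50,
                      avg_years = 10, gs_tol = 0.005) {
  rp <- reference_params(params)
  N0 <- get_N0(rp)
  n_s <- rp@n_s
  Fv <- if (is.null(F_init)) rep(0.5, n_s) else rep_len(F_init, n_s)
  if (any(Fv < 0)) stop("`F_init` must be nonnegative")
  history <- matrix(Fv, 1, n_s)
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < max_iter) {
    sweeps <- sweeps + 1L
    F_old <- Fv
    for (i in seq_len(n_s)) {
      Fv[i] <- calc_FMSY(rp, i, F_other = Fv, F_grid = F_grid, years = years,
                         avg_years = avg_years, tol = gs_tol, N0 = N0,
                         ref = TRUE)$F_MSY
    }
    history <- rbind(history, Fv)
    if (max(abs(Fv - F_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("Nash best-response iteration did not converge in ",
                          max_iter, " sweeps")
  list(F_Nash = stats::setNames(Fv, rp@species$species),
       converged = converged, sweeps = sweeps, history = history)
}

#' Collapse flags against an unfished reference
#'
#' A stock is flagged collapsed when its SSB falls below `frac` (default
#' 10\%) of its unfished SSB.
#'
#' @param ssb Named vector of SSB under the scenario (g).
#' @param ssb_unfished SSB of the unfished reference (g), same order.
#' @param frac Collapse threshold as a fraction of unfished SSB.
#' @return Logical vector.
#' @export
collapse_flags <- function(ssb, ssb_unfished, frac = 0.1) {
  if (length(ssb) != length(ssb_unfished)) {
    stop("`ssb` and `ssb_unfished` must have equal length")
  }
  ssb < frac * ssb_unfished
}

#' Enumerate a full-factorial effort grid
#'
#' @param effort_levels Effort levels each fleet can take.
#' @param n_fleets Number of fleets.
#' @return Data frame with one row per scenario, one column per fleet.
#' @export
enumerate_scenarios <- function(effort_levels, n_fleets) {
  if (any(effort_levels < 0)) stop("effort levels must be nonnegative")
  grid <- expand.grid(rep(list(effort_levels), n_fleets))
  names(grid) <- paste0("fleet", seq_len(n_fleets))
  grid
}

#' Mixed-fishery scenario grid
#'
#' Runs every combination of per-fleet effort levels (each held constant
#' for `years` years) from a common initial state, and counts the stocks
#' whose SSB ends below `frac` of its unfished level. Unfished SSB comes
#' from a zero-effort run of the same length; collapse is evaluated on the
#' mean SSB over the final simulated year.
#'
#' @param params [CommunityParams-class] whose gears are the fleets.
#' @param effort_levels Levels each fleet can take (default
#'   `c(0, 0.5, 1, 1.5, 2)`).
#' @param years Horizon per scenario (default 50).
#' @param N0 Common initial state (default: [get_N0()] burn-in).
#' @param frac Collapse threshold (default 0.1).
#' @return List with `scenarios` (data frame: one row per scenario, fleet
#'   efforts, `n_collapsed`), `ssb` (scenarios x species matrix of final
#'   mean SSB), `ssb_unfished`, `collapsed` (logical matrix).
#' @export
run_scenario_grid <- function(params, effort_levels = c(0, 0.5, 1, 1.5, 2),
                              years = 50, N0 = NULL, frac = 0.1) {
  if (years < 1) stop("`years` must be >= 1")
  H <- dim(params@Q)[3]
  grid <- enumerate_scenarios(effort_levels, H)
  names(grid) <- params@gear_names
  if (is.null(N0)) N0 <- get_N0(params)
  spy <- params@steps_per_year

  final_ssb <- function(effort_row) {
    out <- run_community(params, N0, years,
                         effort = matrix(effort_row, years, H, byrow = TRUE))
    ssb <- get_SSB(out, params)
    colMeans(ssb[(years - 1L) * spy + seq_len(spy), , drop = FALSE])
  }

  ssb_unfished <- final_ssb(rep(0, H))
  ssb <- vapply(seq_len(nrow(grid)), function(r) final_ssb(as.numeric(grid[r, ])),
                numeric(params@n_s))
  ssb <- matrix(ssb, nrow = nrow(grid), ncol = params@n_s, byrow = TRUE,
                dimnames = list(NULL, params@species$species))
  collapsed <- ssb < matrix(frac * ssb_unfished, nrow(ssb), ncol(ssb),
                            byrow = TRUE)
  grid$n_collapsed <- rowSums(collapsed)
  list(scenarios = grid, ssb = ssb, ssb_unfished = ssb_unfished,
       collapsed = collapsed)
}
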