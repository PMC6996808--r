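#' Simulation output container
#'
#' Per-step time series from a model run. Step `t` corresponds to time
#' `t * dt` years after the initial state.
#'
#' @slot N `n_l x n_s x steps` numbers at the end of each step.
#' @slot Catch `n_l x n_s x H x steps` catch weight (g) taken in each step.
#' @slot M2 `n_l x n_s x steps` predation mortality rate (1/yr) applied in
#'   each step.
#' @slot R `years x n_s` recruit numbers entering at the first step of each
#'   year.
#' @slot N0 `n_l x n_s` initial state.
#' @slot effort `years x H` effort matrix used.
#' @slot dt time step (years).
#' @slot gear_names gear labels.
#' @export
setClass("SimOutput", representation(
  N = "array", Catch = "array", M2 = "array", R = "matrix",
  N0 = "matrix", effort = "matrix", dt = "numeric", gear_names = "character"
))

setMethod("show", "SimOutput", function(object) {
  cat("SimOutput:", dim(object@N)[3], "steps,", dim(object@N)[2], "species,",
      dim(object@Catch)[3], "gear(s)\n")
})

#' Stock-recruitment functions
#'
#' Number of recruits produced from a spawning stock biomass (g):
#' \describe{
#'   \item{hockey-stick}{`a * min(SSB, b)` - linear up to the breakpoint
#'     `b`, plateau `a * b` beyond.}
#'   \item{Ricker}{`a * SSB * exp(-b * SSB)` (overcompensatory).}
#'   \item{Beverton-Holt}{`a * SSB / (1 + b * SSB)` (asymptote `a / b`).}
#'   \item{linear}{`a * SSB`.}
#'   \item{constant}{`a`, independent of SSB.}
#' }
#'
#' @param SSB Spawning stock biomass (g), scalar or vector.
#' @param fun Family name (see [rec_fun_names()]).
#' @param a,b Parameters (nonnegative; `b` unused for linear/constant).
#' @return Recruit numbers, same length as `SSB`.
#' @examples
#' recruitment(5, "hockey-stick", a = 2, b = 10)   # 10
#' recruitment(50, "hockey-stick", a = 2, b = 10)  # plateau 20
#' @export
recruitment <- function(SSB, fun, a, b = 0) {
  if (any(!is.finite(SSB) | SSB < 0)) stop("`SSB` must be nonnegative")
  fun <- match_rec_fun(fun)
  switch(fun,
    `hockey-stick` = a * pmin(SSB, b),
    Ricker = a * SSB * exp(-b * SSB),
    `Beverton-Holt` = a * SSB / (1 + b * SSB),
    linear = a * SSB,
    constant = rep_len(a, length(SSB))
  )
}

# recruits for every species from an SSB vector
recruits_all <- function(ssb, species) {
  vapply(seq_len(nrow(species)), function(i)
    recruitment(ssb[i], species$rec_fun[i], species$a[i], species$b[i]),
    numeric(1))
}

#' Predation mortality
#'
#' Each predator cell (species `m`, class `n`) demands a ration
#' `I[n, m] * N[n, m]` grams per step (the weight it must grow divided by
#' its conversion efficiency). The ration is apportioned across suitable
#' prey biomass and the "other food" pool in proportion to availability, so
#' the per-capita predation mortality of prey cell (`i`, `j`) is
#' `M2[j, i] = (1/dt) * sum_{m,n} I[n,m] N[n,m] suit[m,n,i,j] / A[n,m]`,
#' where `A[n,m] = other + sum_{i',j'} suit[m,n,i',j'] N[j',i'] w[j',i']` is
#' the food available to that predator cell. Predator cells with no
#' available food contribute nothing.
#'
#' @param N `n_l x n_s` matrix of numbers.
#' @param params A [CommunityParams-class] object.
#' @return `n_l x n_s` matrix of predation mortality rates (1/yr).
#' @export
calc_M2 <- function(N, params) {
  b_prey <- as.vector(N * params@w)
  avail <- params@pred$other + as.vector(params@suit_flat %*% b_prey)
  demand <- as.vector(params@intake) * as.vector(N)   # g per step per pred cell
  rate <- ifelse(avail > 0, demand / avail, 0)
  m2 <- as.vector(crossprod(params@suit_flat, rate)) / params@dt
  matrix(m2, params@grid$n_l, params@n_s)
}

#' Fishing mortality from effort
#'
#' `F[j, i] = sum_k e_k * Q[j, i, k]` (1/yr). With unit-normalised
#' catchability, effort `e` equals the fishing mortality on each targeted
#' species' most-selected length class.
#'
#' @param Q `n_l x n_s x H` catchability array.
#' @param effort_row Effort per gear (length `H`, nonnegative).
#' @param by_gear If `TRUE`, return the `n_l x n_s x H` per-gear
#'   decomposition instead of the summed matrix.
#' @return `n_l x n_s` matrix (or per-gear array).
#' @export
calc_F <- function(Q, effort_row, by_gear = FALSE) {
  H <- dim(Q)[3]
  if (length(effort_row) != H) {
    stop("`effort_row` must have one entry per gear (", H, ")")
  }
  if (any(!is.finite(effort_row) | effort_row < 0)) {
    stop("effort must be nonnegative")
  }
  Fg <- sweep(Q, 3, effort_row, "*")
  if (by_gear) Fg else {
    out <- Fg[, , 1]
    if (H > 1) for (k in 2:H) out <- out + Fg[, , k]
    matrix(out, dim(Q)[1], dim(Q)[2])
  }
}

#' One mortality phase
#'
#' Applies total mortality `Z = M1 + M2 + F` over one step:
#' `N'' = N' * exp(-Z dt)`. Deaths are partitioned by the Baranov shares
#' `F_k / Z` (catch of gear `k`) and `(M1 + M2) / Z` (natural), which sum
#' exactly to the total deaths. Catch is also returned in weight using the
#' class midpoint weights.
#'
#' @param N `n_l x n_s` numbers before mortality.
#' @param M1,M2 Background and predation mortality matrices (1/yr).
#' @param F_gear `n_l x n_s x H` per-gear fishing mortality (from
#'   `calc_F(..., by_gear = TRUE)`), or an `n_l x n_s` matrix for a single
#'   aggregate gear.
#' @param dt Step length (years).
#' @param w `n_l x n_s` class weights (g); required for catch in weight.
#' @return List with `N` (after mortality), `catch_n` and `catch_w`
#'   (`n_l x n_s x H` catch in numbers and grams), `natural_n` (natural
#'   deaths in numbers).
#' @export
mortality_step <- function(N, M1, M2, F_gear, dt, w = NULL) {
  if (length(dim(F_gear)) == 2L) F_gear <- array(F_gear, c(dim(F_gear), 1L))
  if (any(M1 < 0) || any(M2 < 0) || any(F_gear < 0)) {
    stop("mortality rates must be nonnegative")
  }
  H <- dim(F_gear)[3]
  Ftot <- matrix(0, nrow(N), ncol(N))
  for (k in seq_len(H)) Ftot <- Ftot + F_gear[, , k]
  Z <- M1 + M2 + Ftot
  N2 <- N * exp(-Z * dt)
  deaths <- N - N2
  frac <- ifelse(Z > 0, deaths / Z, 0)    # deaths per unit rate
  catch_n <- array(0, c(dim(N), H))
  for (k in seq_len(H)) catch_n[, , k] <- F_gear[, , k] * frac
  natural_n <- (M1 + M2) * frac
  catch_w <- if (is.null(w)) catch_n * NA_real_ else
    sweep(catch_n, c(1, 2), w, "*")
  list(N = N2, catch_n = catch_n, catch_w = catch_w, natural_n = natural_n)
}

#' One growth phase
#'
#' Moves the proportion `phi[j, i]` of survivors from class `j` to class
#' `j + 1`: `N_j <- N_j (1 - phi_j) + N_{j-1} phi_{j-1}` (no inflow to the
#' first class). Numbers are conserved whenever the top occupied class has
#' `phi = 0`.
#'
#' @param N `n_l x n_s` numbers after mortality.
#' @param phi `n_l x n_s` growth proportions in `[0, 1]`.
#' @return Updated `n_l x n_s` matrix.
#' @export
growth_step <- function(N, phi) {
  if (any(phi < 0 | phi > 1)) stop("`phi` must lie in [0, 1]")
  n_l <- nrow(N)
  out <- N * (1 - phi)
  if (n_l > 1) {
    out[-1, ] <- out[-1, , drop = FALSE] +
      N[-n_l, , drop = FALSE] * phi[-n_l, , drop = FALSE]
  }
  out
}

#' Spawning stock biomass of a state
#'
#' `SSB_i = sum_j N[j, i] w[j, i] mature[j, i]` (grams).
#'
#' @param N `n_l x n_s` numbers.
#' @param params [CommunityParams-class].
#' @return Named vector of length `n_s`.
#' @export
state_ssb <- function(N, params) {
  stats::setNames(colSums(N * params@w * params@mature),
                  params@species$species)
}

#' Run the community model
#'
#' Advances the state year by year. At the start of each year SSB is
#' computed from the current state and sets that year's recruitment, which
#' enters the first length class in the year's first step; every step then
#' applies the mortality phase (background + predation + fishing under the
#' year's effort row) followed by the growth phase.
#'
#' @param params [CommunityParams-class].
#' @param N0 Initial `n_l x n_s` state (e.g. from [get_N0()]).
#' @param years Number of years to simulate.
#' @param effort `years x H` effort matrix (piecewise-constant within a
#'   year), or a single scalar/row recycled to all years; default no
#'   fishing.
#' @return A [SimOutput-class] object.
#' @examples
#' fx <- generate_fixture(n_species = 3, seed = 1, n_l = 16)
#' p <- community_params(fx$species, gears = fx$gears, tau = fx$tau,
#'                       pred = fx$pred, n_l = 16)
#' run_community(p, get_N0(p, burn_years = 2), years = 2,
#'               effort = matrix(0.25, 2, dim(p@Q)[3]))
#' @export
run_community <- function(params, N0, years, effort = NULL) {
  n_l <- params@grid$n_l
  n_s <- params@n_s
  H <- dim(params@Q)[3]
  years <- as.integer(years)
  if (years < 0) stop("`years` must be >= 0")
  if (is.null(effort)) effort <- matrix(0, max(years, 1L), H)
  if (is.null(dim(effort))) {
    effort <- matrix(effort, max(years, 1L), H, byrow = length(effort) == H)
  }
  effort <- as.matrix(effort)
  if (years > 0 && nrow(effort) != years) {
    stop("`effort` must have one row per year (", years, " year(s), got ",
         nrow(effort), " row(s))")
  }
  if (ncol(effort) != H) {
    stop("`effort` must have one column per gear (", H, " gear(s), got ",
         ncol(effort), " column(s))")
  }
  if (any(!is.finite(effort) | effort < 0)) stop("effort must be nonnegative")
  N0 <- as.matrix(N0)
  if (!identical(dim(N0), c(n_l, n_s))) {
    stop("`N0` must be n_l x n_s (", n_l, " x ", n_s, ")")
  }
  if (any(!is.finite(N0) | N0 < 0)) stop("`N0` must be finite and nonnegative")

  spy <- params@steps_per_year
  n_steps <- years * spy
  N_series <- array(0, c(n_l, n_s, n_steps))
  Catch_series <- array(0, c(n_l, n_s, H, n_steps))
  M2_series <- array(0, c(n_l, n_s, n_steps))
  R_series <- matrix(0, years, n_s, dimnames = list(NULL, params@species$species))

  N <- N0
  t <- 0L
  for (yr in seq_len(years)) {
    R <- recruits_all(state_ssb(N, params), params@species)
    R_series[yr, ] <- R
    Fg <- calc_F(params@Q, effort[yr, ], by_gear = TRUE)
    for (s in seq_len(spy)) {
      if (s == 1L) N[1L, ] <- N[1L, ] + R
      M2 <- calc_M2(N, params)
      mort <- mortality_step(N, params@M1, M2, Fg, params@dt, params@w)
      N <- growth_step(mort$N, params@phi)
      t <- t + 1L
      N_series[, , t] <- N
      Catch_series[, , , t] <- mort$catch_w
      M2_series[, , t] <- M2
    }
  }
  methods::new("SimOutput",
    N = N_series, Catch = Catch_series, M2 = M2_series, R = R_series,
    N0 = N0, effort = effort[seq_len(years), , drop = FALSE],
    dt = params@dt, gear_names = params@gear_names)
}

#' Unfished steady-state numbers per species
#'
#' Analytic fixed point of the mortality + growth update for one species
#' under background mortality only (no predation, no fishing), fed by a
#' constant annual recruitment spread evenly over the year's steps:
#' `N_j = inflow_j / (1 - s_j (1 - phi_j))` with per-step survival
#' `s_j = exp(-M1_j dt)` and `inflow_j = s_{j-1} phi_{j-1} N_{j-1}`
#' (`inflow_1` is the per-step recruitment). Classes with neither mortality
#' nor growth outflow have no finite steady state; they are filled with a
#' nominal 20-year standing stock of their inflow.
#'
#' @param params [CommunityParams-class].
#' @param R_annual Annual recruitment per species (numbers, length `n_s`).
#' @param extra_mortality Optional additional mortality field (`n_l x n_s`,
#'   1/yr), e.g. a predation-mortality estimate, added to M1.
#' @return `n_l x n_s` matrix of numbers.
#' @export
steady_state_numbers <- function(params, R_annual, extra_mortality = NULL) {
  n_l <- params@grid$n_l
  n_s <- params@n_s
  spy <- params@steps_per_year
  M <- params@M1
  if (!is.null(extra_mortality)) M <- M + extra_mortality
  N <- matrix(0, n_l, n_s)
  for (i in seq_len(n_s)) {
    s <- exp(-M[, i] * params@dt)
    phi <- params@phi[, i]
    occ <- which(params@grid$lower_bounds < params@species$Linf[i])
    inflow <- R_annual[i] / spy
    for (j in occ) {
      denom <- 1 - s[j] * (1 - phi[j])
      N[j, i] <- if (denom > 1e-9) inflow / denom else inflow * 20 * spy
      inflow <- N[j, i] * s[j] * phi[j]
    }
  }
  N
}

#' Unfished spawners per recruit
#'
#' Spawning stock biomass (g) produced per annual recruit at the
#' background-mortality steady state of [steady_state_numbers()]. Useful
#' for scaling recruitment parameters of synthetic communities.
#'
#' @param params [CommunityParams-class].
#' @return Named vector of length `n_s` (g per recruit per year).
#' @export
spawners_per_recruit <- function(params) {
  N <- steady_state_numbers(params, rep(1, params@n_s))
  state_ssb(N, params)
}

#' Initialise the community
#'
#' Builds an unfished quasi-equilibrium seed in three deterministic stages:
#' (1) the background-mortality steady state of [steady_state_numbers()] at
#' each species' recruitment plateau; (2) a damped fixed-point iteration
#' folding the implied predation mortality back into the steady-state
#' solve; (3) Aitken-accelerated iteration of the unfished decade map (run
#' ten years, extrapolate cell-wise) until the per-species SSB drift per
#' decade falls below `seed_tol`. `burn_years` of plain unfished simulation
#' are then appended (the default 10 matches the conventional burn-in).
#'
#' @param params [CommunityParams-class].
#' @param burn_years Years of unfished burn-in after seeding (default 10);
#'   0 returns the seed state itself.
#' @param seed_tol Target relative SSB drift per decade of the seed
#'   (default 0.005).
#' @param seed_cycles Maximum acceleration cycles (default 12).
#' @return `n_l x n_s` matrix of numbers.
#' @export
get_N0 <- function(params, burn_years = 10L, seed_tol = 0.005,
                   seed_cycles = 12L) {
  burn_years <- as.integer(burn_years)
  if (is.na(burn_years) || burn_years < 0) stop("`burn_years` must be >= 0")
  sp <- params@species
  # recruitment plateau (or a representative level) per species
  r0 <- vapply(seq_len(params@n_s), function(i) {
    switch(sp$rec_fun[i],
      `hockey-stick` = sp$a[i] * sp$b[i],
      Ricker = if (sp$b[i] > 0) sp$a[i] / (sp$b[i] * exp(1)) else sp$a[i],
      `Beverton-Holt` = if (sp$b[i] > 0) sp$a[i] / sp$b[i] else sp$a[i],
      linear = sp$a[i] * params@w_inf[i] * 1e3,
      constant = sp$a[i])
  }, numeric(1))
  N <- steady_state_numbers(params, r0)
  for (it in 1:25) {
    N <- 0.5 * N + 0.5 * steady_state_numbers(params, r0, calc_M2(N, params))
  }
  decade <- function(N) {
    out <- run_community(params, N, years = 10,
                         effort = matrix(0, 10, dim(params@Q)[3]))
    out@N[, , dim(out@N)[3]]
  }
  for (cycle in seq_len(seed_cycles)) {
    N1 <- decade(N)
    N2 <- decade(N1)
    s1 <- state_ssb(N1, params)
    drift <- max(abs(state_ssb(N2, params) - s1) / pmax(s1, 1e-12))
    if (drift < seed_tol) {
      N <- N2
      break
    }
    # cell-wise Aitken extrapolation of the decade map
    d1 <- N1 - N
    d2 <- N2 - N1
    r <- ifelse(abs(d1) > 1e-9, d2 / d1, 0)
    r[!is.finite(r)] <- 0
    r <- pmin(pmax(r, 0), 0.95)
    N <- pmax(N2 + d2 * r / (1 - r), 0)
  }
  if (burn_years > 0L) {
    out <- run_community(params, N, years = burn_years,
                         effort = matrix(0, burn_years, dim(params@Q)[3]))
    N <- out@N[, , dim(out@N)[3]]
  }
  N
}
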