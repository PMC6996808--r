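#' @import methods
NULL

#' Assembled community model parameters
#'
#' Everything the simulation engine needs, assembled once from raw inputs by
#' [community_params()]: the length grid, growth transition proportions,
#' maturity ogive, background mortality, the predation suitability tensor
#' (plus a flattened copy used by the fast predation-mortality kernel), the
#' catchability array and per-class weights.
#'
#' @slot grid `length_grid` shared by all species.
#' @slot species validated species table (data frame).
#' @slot n_s number of species.
#' @slot dt time step (years); `steps_per_year * dt == 1`.
#' @slot steps_per_year integer steps per year.
#' @slot phi `n_l x n_s` proportion leaving each class per step via growth.
#' @slot mature `n_l x n_s` maturity ogive in `[0, 1]`.
#' @slot M1 `n_l x n_s` background mortality (1/yr).
#' @slot tau `n_s x n_s` predator-prey interaction matrix.
#' @slot suit 4-d suitability array `(pred species, pred class, prey species,
#'   prey class)` in `[0, 1]`.
#' @slot suit_flat `(n_l*n_s) x (n_l*n_s)` flattened suitability, predator
#'   cells in rows, prey cells in columns, cell index `(i-1)*n_l + j`.
#' @slot Q `n_l x n_s x H` catchability (F per unit effort).
#' @slot gear_names names of the `H` gears.
#' @slot pred species-independent predation parameters (`pred_params`).
#' @slot w `n_l x n_s` weight (g) of an individual at the class midpoint.
#' @slot w_inf asymptotic weight per species (g).
#' @slot intake `n_l x n_s` per-capita food ration per time step (g),
#'   derived from the growth requirement and conversion efficiency.
#' @export
setClass("CommunityParams", representation(
  grid = "list",
  species = "data.frame",
  n_s = "integer",
  dt = "numeric",
  steps_per_year = "integer",
  phi = "matrix",
  mature = "matrix",
  M1 = "matrix",
  tau = "matrix",
  suit = "array",
  suit_flat = "matrix",
  Q = "array",
  gear_names = "character",
  pred = "list",
  w = "matrix",
  w_inf = "numeric",
  intake = "matrix"
))

setValidity("CommunityParams", function(object) {
  msgs <- character()
  n_l <- object@grid$n_l
  n_s <- object@n_s
  if (any(object@phi < 0 | object@phi > 1)) msgs <- c(msgs, "phi outside [0,1]")
  if (any(object@mature < 0 | object@mature > 1)) msgs <- c(msgs, "mature outside [0,1]")
  if (any(object@M1 < 0)) msgs <- c(msgs, "M1 negative")
  if (any(object@Q < 0)) msgs <- c(msgs, "Q negative")
  if (abs(object@dt * object@steps_per_year - 1) > 1e-8) {
    msgs <- c(msgs, "dt * steps_per_year != 1")
  }
  if (!identical(dim(object@suit), c(n_s, n_l, n_s, n_l))) {
    msgs <- c(msgs, "suit has wrong dimensions")
  }
  if (length(msgs) == 0) TRUE else msgs
})

setMethod("show", "CommunityParams", function(object) {
  cat("CommunityParams:", object@n_s, "species,",
      object@grid$n_l, "length classes,",
      dim(object@Q)[3], "gear(s), dt =", object@dt, "yr\n")
})

#' Growth transition proportions per time step
#'
#' Under von Bertalanffy growth `dL/dt = k (Linf - L)`, the time for species
#' `i` to traverse class `j` is
#' `t_ji = (1/k_i) * log((Linf_i - lower_j) / (Linf_i - upper_j))`.
#' The proportion of individuals leaving class `j` per step is
#' `phi_ji = dt / t_ji`, capped at 1 (a warning is emitted if the cap binds).
#' Classes the species cannot traverse (upper bound at or beyond `Linf_i`)
#' get `phi = 0`: fish accumulate in the last reachable class.
#'
#' @param grid A `length_grid`.
#' @param species Validated species table.
#' @param phi_min The model time step `dt` in years (default 0.1, i.e. 10
#'   steps per year).
#' @return A list with `phi` (`n_l x n_s` matrix) and `dt`.
#' @examples
#' g <- build_length_grid(bounds = c(40, 50, 60))
#' sp <- data.frame(Linf = 100, Lmat = 50, W_a = 0.01, W_b = 3, k = 0.5,
#'                  rec_fun = "constant", a = 1, b = 0)
#' calc_phi(g, validate_species_table(sp), phi_min = 0.1)$phi
#' @export
calc_phi <- function(grid, species, phi_min = 0.1) {
  if (!is.finite(phi_min) || phi_min <= 0 || phi_min > 1) {
    stop("`phi_min` (the time step, years) must lie in (0, 1]")
  }
  dt <- phi_min
  n_l <- grid$n_l
  n_s <- nrow(species)
  if (any(species$Linf <= grid$upper_bounds[1])) {
    bad <- species$species[species$Linf <= grid$upper_bounds[1]]
    stop("Linf of species ", paste(bad, collapse = ", "),
         " does not exceed the first class upper bound; the grid cannot ",
         "resolve their growth")
  }
  phi <- matrix(0, n_l, n_s)
  for (i in seq_len(n_s)) {
    Linf <- species$Linf[i]
    traversable <- grid$upper_bounds < Linf
    tt <- (1 / species$k[i]) *
      log((Linf - grid$lower_bounds[traversable]) /
            (Linf - grid$upper_bounds[traversable]))
    phi[traversable, i] <- dt / tt
  }
  if (any(phi > 1)) {
    warning("some growth proportions exceeded 1 and were capped; ",
            "consider a smaller time step or wider classes")
    phi[phi > 1] <- 1
  }
  list(phi = phi, dt = dt)
}

#' Maturity ogive
#'
#' Logistic proportion mature at the class midpoint,
#' `1 / (1 + exp(-kappa_i * (L_j - Lmat_i)))`.
#'
#' @inheritParams calc_phi
#' @return `n_l x n_s` matrix in `[0, 1]`, non-decreasing in length.
#' @export
calc_maturity <- function(grid, species) {
  outer(grid$midpoints, seq_len(nrow(species)), function(L, i) {
    1 / (1 + exp(-species$kappa[i] * (L - species$Lmat[i])))
  })
}

#' Background (residual natural) mortality
#'
#' Mortality not attributable to modelled predation or fishing, per year.
#' Three families:
#' \describe{
#'   \item{`std_RNM`}{(default) constant rate `Nmort` for classes with
#'     midpoint at or below `prop * Linf_i`, zero above: residual mortality
#'     acts on the sizes the modelled predators do not reach.}
#'   \item{`constant`}{`Nmort` in every class.}
#'   \item{`linear`}{declines linearly in midpoint length from `Nmort` at
#'     length zero to zero at `Linf_i`.}
#' }
#'
#' @inheritParams calc_phi
#' @param fun One of `"std_RNM"`, `"constant"`, `"linear"`; recycled across
#'   species if length 1.
#' @param Nmort Baseline rate (1/yr), recycled; default 0.8.
#' @param prop For `std_RNM`: fraction of `Linf` above which the rate is
#'   zero (default 0.75).
#' @return `n_l x n_s` nonnegative matrix (1/yr).
#' @export
calc_M1 <- function(grid, species, fun = "std_RNM", Nmort = 0.8, prop = 0.75) {
  n_s <- nrow(species)
  fun <- rep_len(as.character(fun), n_s)
  Nmort <- rep_len(Nmort, n_s)
  prop <- rep_len(prop, n_s)
  ok <- fun %in% c("std_RNM", "constant", "linear")
  if (any(!ok)) stop("unknown M1 function: ", paste(unique(fun[!ok]), collapse = ", "))
  if (any(!is.finite(Nmort) | Nmort < 0)) stop("`Nmort` must be >= 0")
  M1 <- matrix(0, grid$n_l, n_s)
  for (i in seq_len(n_s)) {
    L <- grid$midpoints
    M1[, i] <- switch(fun[i],
      constant = Nmort[i],
      linear = pmax(0, Nmort[i] * (1 - L / species$Linf[i])),
      std_RNM = ifelse(L <= prop[i] * species$Linf[i], Nmort[i], 0)
    )
  }
  M1
}

#' Predation suitability tensor
#'
#' How suitable prey cell (species `i`, class `j`) is to predator cell
#' (species `m`, class `n`): the interaction matrix entry `tau[m, i]` times a
#' log-normal size-preference kernel in the predator/prey weight ratio,
#' peaking at the preferred mass ratio `mu`:
#' `exp(-(log(w_pred / w_prey) - log(mu))^2 / (2 sigma^2))`.
#' A predator cannot eat prey at or above its own weight (kernel truncated
#' to zero there).
#'
#' @inheritParams calc_phi
#' @param tau Validated `n_s x n_s` interaction matrix.
#' @param pred `pred_params`.
#' @return 4-d array `(pred species m, pred class n, prey species i, prey
#'   class j)` with values in `[0, 1]`.
#' @export
calc_suitability <- function(grid, species, tau, pred) {
  n_l <- grid$n_l
  n_s <- nrow(species)
  w <- vapply(seq_len(n_s), function(i)
    class_weights(grid, species$W_a[i], species$W_b[i]), numeric(n_l))
  wv <- as.vector(w)                       # cell index (i-1)*n_l + j
  lr <- outer(log(wv), log(wv), "-")       # log(w_pred / w_prey), pred in rows
  kern <- exp(-(lr - log(pred$mu))^2 / (2 * pred$sigma^2))
  kern[outer(wv, wv, "<=")] <- 0           # prey weight >= predator weight
  tau_cells <- tau[rep(seq_len(n_s), each = n_l), rep(seq_len(n_s), each = n_l)]
  flat <- tau_cells * kern
  # reorder flat [(i,j) cells] into (m, n, i, j)
  suit <- aperm(array(flat, c(n_l, n_s, n_l, n_s)), c(2, 1, 4, 3))
  suit
}

#' Gear catchability array
#'
#' Builds the `n_l x n_s x H` catchability array `Q` (fishing mortality per
#' unit effort) from per-gear, per-species selectivity curves evaluated at
#' class midpoints:
#' \describe{
#'   \item{logistic}{`1 / (1 + exp(-eta * (L - L50)))`; parameters `p1 =
#'     eta` (steepness, 1/cm), `p2 = L50` (cm).}
#'   \item{log_gaussian}{`exp(-(log L - log Lmode)^2 / (2 sd^2))`;
#'     parameters `p1 = Lmode` (cm), `p2 = sd` (log-scale width).}
#'   \item{knife_edge}{0 below the edge length, 1 at or above; parameter
#'     `p1 = edge` (cm, e.g. a minimum landing size).}
#' }
#' Each species-gear curve is rescaled to unit maximum over the classes the
#' species can occupy (lower bound below `Linf`), so one unit of gear effort
#' produces F = 1 per year on the most-selected class of each targeted
#' species. Species absent from a gear's definition have zero catchability
#' for that gear.
#'
#' @inheritParams calc_phi
#' @param gears Data frame with columns `gear`, `species`, `fun` (one of the
#'   three family names), `p1`, `p2` (`p2` ignored by `knife_edge`); one row
#'   per gear-species combination the gear catches.
#' @param rescale Rescale each species-gear curve to unit maximum
#'   (default TRUE). Raw user-supplied arrays bypass this function entirely.
#' @return `n_l x n_s x H` array; gear names in `dimnames`.
#' @export
calc_catchability <- function(grid, species, gears, rescale = TRUE) {
  gears <- as.data.frame(gears, stringsAsFactors = FALSE)
  required <- c("gear", "species", "fun", "p1")
  if (!all(required %in% names(gears))) {
    stop("`gears` needs columns gear, species, fun, p1 (and usually p2)")
  }
  if (is.null(gears$p2)) gears$p2 <- NA_real_
  gear_names <- unique(gears$gear)
  H <- length(gear_names)
  n_l <- grid$n_l
  n_s <- nrow(species)
  Q <- array(0, c(n_l, n_s, H),
             dimnames = list(NULL, species$species, gear_names))
  L <- grid$midpoints
  for (r in seq_len(nrow(gears))) {
    i <- match(gears$species[r], species$species)
    if (is.na(i)) stop("gear ", gears$gear[r], " targets unknown species ",
                       gears$species[r])
    k <- match(gears$gear[r], gear_names)
    p1 <- gears$p1[r]; p2 <- gears$p2[r]
    q <- switch(gears$fun[r],
      logistic = {
        if (!is.finite(p1) || p1 <= 0 || !is.finite(p2) || p2 <= 0) {
          stop("logistic selectivity needs positive eta (p1) and L50 (p2)")
        }
        1 / (1 + exp(-p1 * (L - p2)))
      },
      log_gaussian = {
        if (!is.finite(p1) || p1 <= 0 || !is.finite(p2) || p2 <= 0) {
          stop("log_gaussian selectivity needs positive Lmode (p1) and sd (p2)")
        }
        exp(-(log(L) - log(p1))^2 / (2 * p2^2))
      },
      knife_edge = {
        if (!is.finite(p1) || p1 < 0) stop("knife_edge needs a nonnegative edge length (p1)")
        as.numeric(L >= p1)
      },
      stop("unknown catchability function: ", gears$fun[r])
    )
    # classes the species can never occupy carry no fish and no F
    reachable <- grid$lower_bounds < species$Linf[i]
    q[!reachable] <- 0
    if (rescale) {
      peak <- max(q)
      if (peak > 0) q <- q / peak
    }
    Q[, i, k] <- q
  }
  if (any(apply(Q, 3, max) == 0)) {
    warning("some gear(s) have zero catchability on every species")
  }
  Q
}

#' Assemble a community model
#'
#' Validates all raw inputs and precomputes every time-invariant structure
#' used by the simulation engine.
#'
#' @param species Species table (see [validate_species_table()]).
#' @param gears Gear definitions (see [calc_catchability()]), or `NULL` for
#'   an unfished community (a single all-zero gear is created).
#' @param tau Predator-prey interaction matrix; default all ones.
#' @param pred `pred_params` (preferred mass ratio, kernel width, growth
#'   efficiency, other food).
#' @param n_l Number of length classes (default 32); ignored if `bounds`
#'   given.
#' @param bounds Optional explicit class boundaries.
#' @param phi_min Time step in years (default 0.1).
#' @param M1_fun,Nmort,M1_prop Background mortality family and parameters
#'   (see [calc_M1()]).
#' @param Q Optional raw catchability array (`n_l x n_s x H`), accepted
#'   verbatim in place of `gears`.
#' @return A [CommunityParams-class] object.
#' @examples
#' fx <- generate_fixture(n_species = 4, seed = 1)
#' params <- community_params(fx$species, gears = fx$gears, tau = fx$tau,
#'                            pred = fx$pred)
#' params
#' @export
community_params <- function(species, gears = NULL, tau = NULL,
                             pred = pred_params(), n_l = 32L, bounds = NULL,
                             phi_min = 0.1, M1_fun = "std_RNM", Nmort = 0.8,
                             M1_prop = 0.75, Q = NULL) {
  species <- validate_species_table(species)
  n_s <- nrow(species)
  grid <- build_length_grid(n_l = n_l, max_Linf = max(species$Linf),
                            bounds = bounds)
  n_l <- grid$n_l
  if (is.null(tau)) tau <- matrix(1, n_s, n_s)
  tau <- validate_tau(tau, n_s)
  if (!inherits(pred, "pred_params")) {
    pred <- do.call(pred_params, as.list(pred))
  }

  ph <- calc_phi(grid, species, phi_min)
  steps_per_year <- as.integer(round(1 / ph$dt))
  mature <- calc_maturity(grid, species)
  # per-species M1 columns in the table override the model-level settings
  m1_fun <- rep_len(M1_fun, n_s)
  m1_rate <- rep_len(Nmort, n_s)
  m1_prop <- rep_len(M1_prop, n_s)
  if (!is.null(species$M1_fun)) {
    pick <- !is.na(species$M1_fun)
    m1_fun[pick] <- species$M1_fun[pick]
  }
  if (!is.null(species$M1_Nmort)) {
    pick <- !is.na(species$M1_Nmort)
    m1_rate[pick] <- species$M1_Nmort[pick]
  }
  if (!is.null(species$M1_prop)) {
    pick <- !is.na(species$M1_prop)
    m1_prop[pick] <- species$M1_prop[pick]
  }
  M1 <- calc_M1(grid, species, fun = m1_fun, Nmort = m1_rate, prop = m1_prop)
  suit <- calc_suitability(grid, species, tau, pred)

  if (!is.null(Q)) {
    Q <- array(as.numeric(Q), dim = dim(Q), dimnames = dimnames(Q))
    if (length(dim(Q)) != 3L || !identical(as.integer(dim(Q)[1:2]), c(n_l, n_s))) {
      stop("raw `Q` must be n_l x n_s x H (got ", paste(dim(Q), collapse = " x "), ")")
    }
    if (any(Q < 0)) stop("raw `Q` must be nonnegative")
    gear_names <- dimnames(Q)[[3]]
    if (is.null(gear_names)) gear_names <- paste0("gear", seq_len(dim(Q)[3]))
  } else if (!is.null(gears)) {
    Q <- calc_catchability(grid, species, gears)
    gear_names <- dimnames(Q)[[3]]
  } else {
    Q <- array(0, c(n_l, n_s, 1L))
    gear_names <- "none"
  }

  w <- vapply(seq_len(n_s), function(i)
    class_weights(grid, species$W_a[i], species$W_b[i]), numeric(n_l))
  w_inf <- species$W_a * species$Linf^species$W_b

  # per-capita ration per step: weight gained growing out of the class,
  # divided by a conversion efficiency falling linearly (in weight) from g0
  # at weight zero to zero at the asymptotic weight
  grow_w <- matrix(0, n_l, n_s)
  if (n_l > 1) {
    grow_w[-n_l, ] <- ph$phi[-n_l, ] * (w[-1, , drop = FALSE] - w[-n_l, , drop = FALSE])
  }
  g_eff <- pred$g0 * (1 - sweep(w, 2, w_inf, "/"))
  intake <- ifelse(g_eff > 0, grow_w / g_eff, 0)
  intake[intake < 0] <- 0

  # flattened suitability: predator cells in rows, prey cells in columns
  suit_flat <- matrix(aperm(suit, c(2, 1, 4, 3)), n_l * n_s, n_l * n_s)

  methods::new("CommunityParams",
    grid = unclass(grid), species = species, n_s = n_s,
    dt = ph$dt, steps_per_year = steps_per_year, phi = ph$phi,
    mature = mature, M1 = M1, tau = tau, suit = suit, suit_flat = suit_flat,
    Q = Q, gear_names = gear_names, pred = unclass(pred),
    w = w, w_inf = w_inf, intake = intake)
}
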