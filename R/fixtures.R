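# Synthetic community generator. Magnitudes mimic a temperate shelf sea
# (North-Sea-like), but every number is synthetic: nothing here is a
# calibrated or published parameter set.

#' Generate a synthetic multispecies community
#'
#' Draws a reproducible, North-Sea-like parameter set: `n_species` species
#' with log-uniform asymptotic lengths, near-cubic length-weight relations,
#' growth rate inversely related to `Linf`, hockey-stick recruitment scaled
#' so smaller species produce more recruits, a sparse predator-prey matrix
#' with larger species as predators, and four idealised fleets (Industrial,
#' Otter, Beam, Pelagic) that partition the species by guild so each
#' species is caught by exactly one fleet. Optionally adds a Recreational
#' fleet with knife-edge retention at a minimum landing size (fish below
#' the landing size are not selected at all, i.e. discards survive).
#'
#' @param n_species Number of species (default 21).
#' @param seed Integer seed; the same seed reproduces the fixture exactly.
#' @param Linf_range Range of asymptotic lengths (cm), drawn log-uniformly.
#' @param n_l Number of length classes the fixture is intended for (only
#'   recorded in the manifest; default 32).
#' @param recreational Add the Recreational knife-edge fleet (default
#'   FALSE).
#' @param other Other-food biomass (g); default scales with community size.
#' @return List with `species` (data frame), `tau`, `gears` (data frame for
#'   [calc_catchability()]), `pred` (`pred_params`), and a `manifest`
#'   describing provenance (synthetic) and settings.
#' @examples
#' fx <- generate_fixture(seed = 1)
#' nrow(fx$species)   # 21
#' @export
generate_fixture <- function(n_species = 21L, seed = 1L,
                             Linf_range = c(15, 150), n_l = 32L,
                             recreational = FALSE, other = NULL) {
  n_species <- as.integer(n_species)
  if (is.na(n_species) || n_species < 1L) stop("`n_species` must be >= 1")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  Linf <- sort(exp(stats::runif(n_species, log(Linf_range[1]), log(Linf_range[2]))))
  Lmat <- Linf * stats::runif(n_species, 0.45, 0.65)
  k <- 3.2 * Linf^-0.57 * exp(stats::rnorm(n_species, 0, 0.1))
  W_a <- 0.01 * exp(stats::rnorm(n_species, 0, 0.2))
  W_b <- stats::runif(n_species, 2.9, 3.1)
  w_inf <- W_a * Linf^W_b

  # hockey-stick recruitment: plateau recruits scale inversely with adult
  # weight; breakpoint at a small fraction of a nominal virgin biomass
  R0 <- 1e10 / w_inf
  b <- 0.05 * R0 * w_inf            # breakpoint SSB (g)
  a <- R0 / b                       # slope; plateau a*b = R0

  species <- data.frame(
    species = sprintf("sp%02d", seq_len(n_species)),
    Linf = Linf, Lmat = Lmat, W_a = W_a, W_b = W_b, k = k,
    rec_fun = "hockey-stick", a = a, b = b,
    # background mortality anchored to growth via the M ~ 1.5k life-history
    # invariant, so slow-growing large species have low M and every length
    # class is mortal (an unfished equilibrium exists)
    M1_fun = "constant", M1_Nmort = pmin(1.5 * k, 1.2), M1_prop = NA_real_,
    stringsAsFactors = FALSE)

  # sparse interaction matrix: predators must be at least twice the prey's
  # asymptotic weight; link strength thins with taxonomic distance
  tau <- matrix(0, n_species, n_species,
                dimnames = list(species$species, species$species))
  for (m in seq_len(n_species)) {
    for (i in seq_len(n_species)) {
      if (w_inf[m] >= 2 * w_inf[i] && stats::runif(1) < 0.6) {
        tau[m, i] <- round(stats::runif(1, 0.3, 1), 2)
      }
    }
  }

  # idealised fleets: partition by guild (size + a drawn habit)
  guild <- character(n_species)
  pelagic_flag <- stats::runif(n_species) < 0.4
  guild[Linf < 40] <- "Industrial"
  guild[Linf >= 40 & pelagic_flag] <- "Pelagic"
  guild[Linf >= 40 & !pelagic_flag & Linf < 90] <- "Beam"
  guild[Linf >= 90 & !pelagic_flag] <- "Otter"
  # with enough species, every fleet must catch at least one
  if (n_species >= 4L) {
    for (g in c("Industrial", "Otter", "Beam", "Pelagic")) {
      if (!any(guild == g)) {
        movable <- which(tabulate(factor(guild))[factor(guild)] > 1)
        if (length(movable) == 0) movable <- seq_len(n_species)
        guild[movable[which.max(stats::runif(length(movable)))]] <- g
      }
    }
  }
  eta <- stats::runif(n_species, 0.2, 0.5)
  L50 <- 0.55 * Linf
  gears <- data.frame(
    gear = guild, species = species$species,
    fun = "logistic", p1 = eta, p2 = L50,
    stringsAsFactors = FALSE)
  gears <- gears[order(match(gears$gear,
                             c("Industrial", "Otter", "Beam", "Pelagic"))), ]
  rownames(gears) <- NULL

  if (recreational) {
    # knife-edge retention at the minimum landing size for the larger
    # species; sub-MLS fish are never selected (discards survive)
    targets <- which(Linf >= stats::quantile(Linf, 0.6))
    mls <- 0.9 * Lmat[targets]
    gears <- rbind(gears, data.frame(
      gear = "Recreational", species = species$species[targets],
      fun = "knife_edge", p1 = mls, p2 = NA_real_,
      stringsAsFactors = FALSE))
  }

  if (is.null(other)) other <- n_species * 1e9
  pred <- pred_params(mu = 30, sigma = 1, g0 = 0.5, other = other)

  manifest <- list(
    provenance = "synthetic (generated, not calibrated to any survey)",
    seed = seed, n_species = n_species, n_l = n_l,
    Linf_range = Linf_range, recreational = recreational,
    fleets = unique(gears$gear))

  list(species = species, tau = tau, gears = gears, pred = pred,
       manifest = manifest)
}

#' Case-study effort schedules
#'
#' Ready-made effort schedules for three standard exercises:
#' \describe{
#'   \item{case 1}{constant effort 0.25 on every gear for 50 years.}
#'   \item{case 2}{the five effort levels `c(0, 0.5, 1, 1.5, 2)` whose full
#'     factorial over four fleets gives 625 scenarios (returned as the
#'     level vector; see [run_scenario_grid()]).}
#'   \item{case 3}{20 years of dynamic effort for the four idealised
#'     fleets (smooth, deterministic trajectories bounded by [0, 1]) plus a
#'     Recreational column ramping linearly from 0.1 in the first year to
#'     0.15 in the final year.}
#' }
#'
#' @param case 1, 2 or 3.
#' @param n_gears Number of gears (cases 1 and 3).
#' @param years Schedule length in years (default 50 for case 1, 20 for
#'   case 3).
#' @return Case 1 and 3: a `years x gears` effort matrix. Case 2: the
#'   numeric level vector.
#' @export
make_case_study_efforts <- function(case, n_gears = 4L, years = NULL) {
  if (!case %in% 1:3) stop("unknown case id: ", case)
  if (case == 1) {
    if (is.null(years)) years <- 50L
    return(matrix(0.25, years, n_gears,
                  dimnames = list(NULL, paste0("gear", seq_len(n_gears)))))
  }
  if (case == 2) return(c(0, 0.5, 1, 1.5, 2))
  if (is.null(years)) years <- 20L
  yr <- seq_len(years)
  base <- cbind(
    Industrial = 0.3 + 0.2 * sin(2 * pi * yr / years),
    Otter = pmax(0, 0.8 - 0.03 * yr),
    Beam = 0.2 + 0.4 * (yr > years / 2),
    Pelagic = 0.5 + 0.3 * cos(2 * pi * yr / (years / 2))
  )
  base <- base[, seq_len(min(n_gears, 4L)), drop = FALSE]
  if (n_gears > 4L) {
    extra <- matrix(0.25, years, n_gears - 4L,
                    dimnames = list(NULL, paste0("gear", 5:n_gears)))
    base <- cbind(base, extra)
  }
  recreational <- 0.1 + (0.15 - 0.1) * (yr - 1) / (years - 1)
  cbind(base, Recreational = recreational)
}
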