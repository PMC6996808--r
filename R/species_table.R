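#' Validate a species life-history table
#'
#' The species table is a data frame with one row per species and columns:
#' \describe{
#'   \item{species}{species name (optional; generated if absent)}
#'   \item{Linf}{asymptotic length (cm)}
#'   \item{Lmat}{length at 50\% maturity (cm)}
#'   \item{W_a, W_b}{length-weight coefficients, `w = W_a * L^W_b` (g)}
#'   \item{k}{von Bertalanffy growth rate (1/yr)}
#'   \item{rec_fun}{recruitment family: one of `"hockey-stick"`, `"Ricker"`,
#'     `"Beverton-Holt"`, `"linear"`, `"constant"`}
#'   \item{a, b}{recruitment parameters (b unused for linear/constant)}
#'   \item{kappa}{optional maturity-ogive steepness (1/cm); defaults to
#'     `10 / Lmat`}
#'   \item{M1_fun, M1_Nmort, M1_prop}{optional per-species background
#'     mortality family and parameters (see [calc_M1()]); NA entries fall
#'     back to the model-level settings}
#' }
#'
#' @param species A data frame as described above.
#' @return The validated data frame with defaults filled in
#'   (invisibly identical content, `kappa` and `species` completed).
#' @export
validate_species_table <- function(species) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  required <- c("Linf", "Lmat", "W_a", "W_b", "k", "rec_fun", "a")
  missing_cols <- setdiff(required, names(species))
  if (length(missing_cols) > 0) {
    stop("species table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  n_s <- nrow(species)
  if (n_s < 1L) stop("species table has no rows")
  if (is.null(species$species)) species$species <- paste0("sp", seq_len(n_s))
  if (is.null(species$b)) species$b <- 0
  species$b[is.na(species$b)] <- 0
  if (is.null(species$kappa)) species$kappa <- NA_real_
  species$kappa <- ifelse(is.na(species$kappa), 10 / species$Lmat, species$kappa)
  # optional per-species M1 columns keep stable types through CSV round trips
  if (!is.null(species$M1_fun)) species$M1_fun <- as.character(species$M1_fun)
  if (!is.null(species$M1_Nmort)) species$M1_Nmort <- as.numeric(species$M1_Nmort)
  if (!is.null(species$M1_prop)) species$M1_prop <- as.numeric(species$M1_prop)

  with(species, {
    if (any(!is.finite(Linf) | Linf <= 0)) stop("`Linf` must be positive")
    if (any(!is.finite(Lmat) | Lmat <= 0)) stop("`Lmat` must be positive")
    if (any(Linf <= Lmat)) stop("`Linf` must exceed `Lmat` for every species")
    if (any(!is.finite(k) | k <= 0)) stop("`k` must be positive")
    if (any(!is.finite(W_a) | W_a <= 0)) stop("`W_a` must be positive")
    if (any(!is.finite(W_b) | W_b <= 0)) stop("`W_b` must be positive")
    if (any(kappa <= 0)) stop("`kappa` must be positive")
  })
  species$rec_fun <- match_rec_fun(species$rec_fun)
  if (any(!is.finite(species$a) | species$a < 0)) {
    stop("recruitment parameter `a` must be nonnegative")
  }
  if (any(!is.finite(species$b) | species$b < 0)) {
    stop("recruitment parameter `b` must be nonnegative")
  }
  species
}

#' Recruitment families available to `recruitment()`
#' @return Character vector of the five family names.
#' @export
rec_fun_names <- function() {
  c("hockey-stick", "Ricker", "Beverton-Holt", "linear", "constant")
}

# Normalise user spellings ("ricker", "beverton_holt", ...) to canonical names.
match_rec_fun <- function(x) {
  canon <- rec_fun_names()
  key <- tolower(gsub("[^a-z]", "", tolower(x)))
  lookup <- stats::setNames(canon, tolower(gsub("[^a-z]", "", tolower(canon))))
  out <- lookup[key]
  if (any(is.na(out))) {
    stop("unknown recruitment function: ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (choose from ", paste(canon, collapse = ", "), ")")
  }
  unname(out)
}

#' Validate a predator-prey interaction matrix
#'
#' `tau[m, i]` scales predation of predator species `m` on prey species `i`;
#' entries lie in `[0, 1]` and default to all ones (every predator may eat
#' every prey, subject to the size-preference kernel).
#'
#' @param tau Square numeric matrix, `n_s` x `n_s`.
#' @param n_s Expected number of species.
#' @return The validated matrix.
#' @export
validate_tau <- function(tau, n_s) {
  tau <- as.matrix(tau)
  if (nrow(tau) != n_s || ncol(tau) != n_s) {
    stop("`tau` must be a ", n_s, " x ", n_s, " matrix")
  }
  if (any(!is.finite(tau)) || any(tau < 0) || any(tau > 1)) {
    stop("`tau` entries must lie in [0, 1]")
  }
  tau
}

#' Species-independent predation parameters
#'
#' @param mu Preferred predator-prey mass ratio (dimensionless, > 1).
#' @param sigma Width of the log-scale size-preference kernel (> 0).
#' @param g0 Theoretical growth (gross conversion) efficiency of a fish of
#'   length zero, in (0, 1).
#' @param other Biomass of "other food" available to predators (grams);
#'   dilutes predation on the modelled species.
#' @return A list with class `pred_params`.
#' @export
pred_params <- function(mu = 30, sigma = 1, g0 = 0.5, other = 0) {
  if (!is.finite(mu) || mu <= 1) stop("`mu` must be > 1")
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  if (!is.finite(g0) || g0 <= 0 || g0 >= 1) stop("`g0` must lie in (0, 1)")
  if (!is.finite(other) || other < 0) stop("`other` must be >= 0")
  structure(list(mu = mu, sigma = sigma, g0 = g0, other = other),
            class = "pred_params")
}
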