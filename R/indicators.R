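#' Species biomass and spawning stock biomass series
#'
#' Biomass is `sum_j N w` per species; SSB additionally weights by the
#' maturity ogive. Both in grams, one row per time step.
#'
#' @param output A [SimOutput-class].
#' @param params The [CommunityParams-class] used for the run.
#' @param annual Average within years to an annual series (default FALSE:
#'   per time step).
#' @return `steps x n_s` (or `years x n_s`) matrix, species in columns.
#' @export
get_biomass <- function(output, params, annual = FALSE) {
  series_by_species(output, params, weight = params@w, annual = annual)
}

#' @rdname get_biomass
#' @export
get_SSB <- function(output, params, annual = FALSE) {
  series_by_species(output, params, weight = params@w * params@mature,
                    annual = annual)
}

series_by_species <- function(output, params, weight, annual) {
  n_steps <- dim(output@N)[3]
  out <- t(vapply(seq_len(n_steps), function(t)
    colSums(output@N[, , t] * weight), numeric(params@n_s)))
  colnames(out) <- params@species$species
  if (annual) out <- annualise(out, round(1 / output@dt))
  out
}

annualise <- function(mat, steps_per_year) {
  yr <- (seq_len(nrow(mat)) - 1L) %/% steps_per_year
  apply(mat, 2, function(col) tapply(col, yr, mean))
}

# community biomass by length class: steps x n_l
biomass_by_class <- function(output, params) {
  n_steps <- dim(output@N)[3]
  t(vapply(seq_len(n_steps), function(t)
    rowSums(output@N[, , t] * params@w), numeric(params@grid$n_l)))
}

#' Large Fish Indicator
#'
#' Proportion of community biomass in length classes with midpoint above a
#' threshold (40 cm by convention).
#'
#' @inheritParams get_biomass
#' @param threshold Length threshold in cm; must lie within the grid span.
#' @return Numeric vector (one value per step, or per year if `annual`).
#' @export
get_LFI <- function(output, params, threshold = 40, annual = FALSE) {
  g <- params@grid
  if (threshold < g$lower_bounds[1] || threshold > g$upper_bounds[g$n_l]) {
    stop("`threshold` (", threshold, " cm) lies outside the length grid")
  }
  bc <- biomass_by_class(output, params)
  tot <- rowSums(bc)
  lfi <- ifelse(tot > 0, rowSums(bc[, g$midpoints > threshold, drop = FALSE]) / tot, NA_real_)
  if (annual) lfi <- as.vector(annualise(cbind(lfi), round(1 / output@dt)))
  lfi
}

#' Mean Maximum Length
#'
#' Biomass-weighted mean of the species' asymptotic lengths:
#' `sum_i B_i Linf_i / sum_i B_i`.
#'
#' @inheritParams get_biomass
#' @return Numeric vector in cm.
#' @export
get_MML <- function(output, params, annual = FALSE) {
  B <- get_biomass(output, params)
  mml <- as.vector(B %*% params@species$Linf) / rowSums(B)
  if (annual) mml <- as.vector(annualise(cbind(mml), round(1 / output@dt)))
  mml
}

#' Typical Length
#'
#' Biomass-weighted geometric mean length of the community over length
#' classes: `exp(sum B log L / sum B)` with `L` the class midpoints.
#'
#' @inheritParams get_biomass
#' @return Numeric vector in cm.
#' @export
get_TyL <- function(output, params, annual = FALSE) {
  bc <- biomass_by_class(output, params)
  tyl <- exp(as.vector(bc %*% log(params@grid$midpoints)) / rowSums(bc))
  if (annual) tyl <- as.vector(annualise(cbind(tyl), round(1 / output@dt)))
  tyl
}

#' Length Quantiles
#'
#' The length below which a fraction `prob` of community biomass lies,
#' interpolated linearly within a length class (biomass treated as uniform
#' across each class).
#'
#' @inheritParams get_biomass
#' @param prob Quantile probability in (0, 1].
#' @return Numeric vector in cm.
#' @export
get_LQ <- function(output, params, prob = 0.5, annual = FALSE) {
  if (!is.finite(prob) || prob <= 0 || prob > 1) stop("`prob` must lie in (0, 1]")
  g <- params@grid
  bc <- biomass_by_class(output, params)
  lq <- apply(bc, 1, function(b) {
    tot <- sum(b)
    if (tot == 0) return(NA_real_)
    target <- prob * tot
    cum <- cumsum(b)
    j <- which(cum >= target * (1 - 1e-12))[1]
    below <- if (j > 1) cum[j - 1] else 0
    g$lower_bounds[j] + (g$upper_bounds[j] - g$lower_bounds[j]) *
      (target - below) / b[j]
  })
  if (annual) lq <- as.vector(annualise(cbind(lq), round(1 / output@dt)))
  lq
}

#' Catch per gear and catch per unit effort
#'
#' `get_CPG` sums catch weight over species and length classes per gear and
#' step. `get_CPUE` divides by the effort in force during the step's year;
#' it is undefined (NA) wherever effort is zero.
#'
#' @inheritParams get_biomass
#' @return `steps x H` matrix (grams, or grams per unit effort), gears in
#'   columns.
#' @export
get_CPG <- function(output, params, annual = FALSE) {
  n_steps <- dim(output@Catch)[4]
  H <- dim(output@Catch)[3]
  out <- t(vapply(seq_len(n_steps), function(t)
    apply(output@Catch[, , , t, drop = FALSE], 3, sum), numeric(H)))
  colnames(out) <- output@gear_names
  if (annual) out <- annualise(out, round(1 / output@dt))
  out
}

#' @rdname get_CPG
#' @export
get_CPUE <- function(output, params, annual = FALSE) {
  cpg <- get_CPG(output, params, annual = FALSE)
  spy <- round(1 / output@dt)
  yr_of_step <- (seq_len(nrow(cpg)) - 1L) %/% spy + 1L
  eff <- output@effort[yr_of_step, , drop = FALSE]
  cpue <- ifelse(eff > 0, cpg / eff, NA_real_)
  colnames(cpue) <- output@gear_names
  if (annual) cpue <- annualise(cpue, spy)
  cpue
}

#' Tidy indicator export
#'
#' Evaluates a standard set of indicators and returns them in long format
#' (`time`, `indicator`, `parameter`, `value`), suitable for CSV export.
#' Time is in years from the start of the run.
#'
#' @inheritParams get_biomass
#' @param lfi_threshold LFI threshold (cm).
#' @param lq_probs Quantile probabilities for LQ.
#' @return A long-format data frame.
#' @export
indicator_table <- function(output, params, lfi_threshold = 40,
                            lq_probs = c(0.1, 0.5, 0.9), annual = FALSE) {
  step_time <- if (annual) {
    seq_len(dim(output@N)[3] / round(1 / output@dt))
  } else {
    seq_len(dim(output@N)[3]) * output@dt
  }
  rows <- list(
    data.frame(time = step_time, indicator = "MML", parameter = NA_real_,
               value = get_MML(output, params, annual = annual)),
    data.frame(time = step_time, indicator = "TyL", parameter = NA_real_,
               value = get_TyL(output, params, annual = annual)),
    data.frame(time = step_time, indicator = "LFI", parameter = lfi_threshold,
               value = get_LFI(output, params, lfi_threshold, annual = annual))
  )
  for (p in lq_probs) {
    rows[[length(rows) + 1L]] <-
      data.frame(time = step_time, indicator = "LQ", parameter = p,
                 value = get_LQ(output, params, p, annual = annual))
  }
  do.call(rbind, rows)
}
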