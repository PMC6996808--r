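# Small communities assembled in code for the tests.

# n_s species with spread-out life histories on a small grid; predation on
# unless tau given. Every species gets its own logistic gear via
# reference_params() when needed. Constant background mortality (M ~ 1.5k)
# keeps every class mortal so an unfished equilibrium exists.
toy_species <- function(n_s = 2) {
  Linf <- seq(60, 140, length.out = n_s)
  k <- 2.5 * Linf^-0.5
  data.frame(
    species = paste0("sp", seq_len(n_s)),
    Linf = Linf,
    Lmat = 0.5 * Linf,
    W_a = 0.01, W_b = 3,
    k = k,
    rec_fun = "hockey-stick",
    a = 1, b = 3e8,
    M1_fun = "constant", M1_Nmort = 1.5 * k,
    M1_prop = NA_real_,
    stringsAsFactors = FALSE)
}

toy_params <- function(n_s = 2, n_l = 8, tau = NULL, other = 2e9, ...) {
  sp <- toy_species(n_s)
  # scale the hockey-stick slope to the stock's spawners-per-recruit so the
  # unfished stock is viable but heavy fishing drives recruitment down
  p0 <- community_params(sp, tau = tau, pred = pred_params(other = other),
                         n_l = n_l, ...)
  sp$a <- 6 / spawners_per_recruit(p0)
  community_params(sp, tau = tau, pred = pred_params(other = other),
                   n_l = n_l, ...)
}

# a community with gears attached (one logistic gear per species)
toy_fished_params <- function(n_s = 2, n_l = 8, tau = NULL, other = 2e9) {
  reference_params(toy_params(n_s = n_s, n_l = n_l, tau = tau, other = other))
}

# a nonnegative random state matching params' dimensions
random_state <- function(params, scale = 1000) {
  matrix(stats::runif(params@grid$n_l * params@n_s, 0, scale),
         params@grid$n_l, params@n_s)
}

# brute-force quadruple-sum predation mortality (independent oracle for
# calc_M2): loops the definition directly over the 4-d suitability array
brute_force_M2 <- function(N, params) {
  n_l <- params@grid$n_l
  n_s <- params@n_s
  M2 <- matrix(0, n_l, n_s)
  for (m in seq_len(n_s)) {
    for (n in seq_len(n_l)) {
      avail <- params@pred$other
      for (i2 in seq_len(n_s)) {
        for (j2 in seq_len(n_l)) {
          avail <- avail + params@suit[m, n, i2, j2] * N[j2, i2] * params@w[j2, i2]
        }
      }
      if (avail <= 0) next
      demand <- params@intake[n, m] * N[n, m]
      for (i in seq_len(n_s)) {
        for (j in seq_len(n_l)) {
          M2[j, i] <- M2[j, i] + demand * params@suit[m, n, i, j] / avail
        }
      }
    }
  }
  M2 / params@dt
}

# fixture community assembled once and reused across test files
fixture_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- generate_fixture(seed = 1)
      cache <<- community_params(fx$species, gears = fx$gears, tau = fx$tau,
                                 pred = fx$pred)
    }
    cache
  }
})
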