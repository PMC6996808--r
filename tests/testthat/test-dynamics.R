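test_that("recruitment families evaluate to their closed forms", {
  expect_equal(recruitment(5, "hockey-stick", a = 2, b = 10), 10)
  expect_equal(recruitment(50, "hockey-stick", a = 2, b = 10), 20) # plateau a*b
  expect_equal(recruitment(10, "Ricker", a = 1, b = 0.1), 10 * exp(-1))
  expect_equal(recruitment(10, "Beverton-Holt", a = 2, b = 0.5), 20 / 6)
  expect_equal(recruitment(7, "linear", a = 3), 21)
  expect_equal(recruitment(7, "constant", a = 5), 5)
  # no spawners, no recruits for every non-constant family
  for (f in setdiff(rec_fun_names(), "constant")) {
    expect_equal(recruitment(0, f, a = 2, b = 1), 0)
  }
  expect_error(recruitment(-1, "linear", a = 1), "nonnegative")
})

test_that("fishing mortality is the effort-weighted sum of catchabilities", {
  Q <- array(0, c(3, 2, 2))
  Q[1, 1, 1] <- 0.4
  Q[1, 1, 2] <- 0.2
  Fm <- calc_F(Q, c(0.5, 1.0))
  expect_equal(Fm[1, 1], 0.5 * 0.4 + 1.0 * 0.2)
  expect_equal(sum(Fm), 0.4)
  expect_equal(calc_F(Q, c(0, 0)), matrix(0, 3, 2))
  expect_error(calc_F(Q, c(-1, 0)), "nonnegative")
  expect_error(calc_F(Q, 1), "one entry per gear")
})

test_that("unit effort on normalised gears puts that F on the top-selected class", {
  p <- fixture_params()
  Fm <- calc_F(p@Q, rep(0.25, dim(p@Q)[3]))
  expect_equal(max(Fm), 0.25, tolerance = 1e-12)
})

test_that("mortality phase is exponential survival with exact death accounting", {
  N <- matrix(100, 1, 1)
  res <- mortality_step(N, M1 = matrix(0.2, 1, 1), M2 = matrix(0.3, 1, 1),
                        F_gear = matrix(0.5, 1, 1), dt = 0.1,
                        w = matrix(2, 1, 1))
  expect_equal(res$N[1, 1], 100 * exp(-0.1))            # Z dt = 1.0 * 0.1
  deaths <- 100 - res$N[1, 1]
  expect_equal(res$natural_n[1, 1] + sum(res$catch_n), deaths, tolerance = 1e-12)
  expect_equal(res$catch_n[1, 1, 1], 0.5 / 1.0 * deaths)  # Baranov share
  expect_equal(res$catch_w[1, 1, 1], res$catch_n[1, 1, 1] * 2)
  # Z = 0 leaves the state untouched with zero catch
  res0 <- mortality_step(N, matrix(0, 1, 1), matrix(0, 1, 1),
                         matrix(0, 1, 1), 0.1, matrix(2, 1, 1))
  expect_equal(res0$N, N)
  expect_equal(sum(res0$catch_n), 0)
})

test_that("death accounting balances over random states and gears", {
  set.seed(7)
  for (rep in 1:20) {
    n_l <- sample(2:6, 1); n_s <- sample(1:3, 1); H <- sample(1:3, 1)
    N <- matrix(runif(n_l * n_s, 0, 1e4), n_l, n_s)
    Fg <- array(runif(n_l * n_s * H, 0, 1), c(n_l, n_s, H))
    res <- mortality_step(N, matrix(runif(n_l * n_s), n_l, n_s),
                          matrix(runif(n_l * n_s), n_l, n_s), Fg, 0.1)
    catch_tot <- apply(res$catch_n, c(1, 2), sum)
    expect_lt(max(abs((N - res$N) - (res$natural_n + catch_tot))), 1e-10)
    expect_true(all(res$N >= 0))
  }
})

test_that("growth phase shifts the documented proportions and conserves totals", {
  N <- matrix(c(10, 0), 2, 1)
  out <- growth_step(N, matrix(c(0.3, 0), 2, 1))
  expect_equal(out[, 1], c(7, 3))
  expect_equal(growth_step(N, matrix(0, 2, 1)), N)   # phi = 0, no movement
  set.seed(11)
  for (rep in 1:20) {
    n_l <- sample(3:8, 1); n_s <- sample(1:3, 1)
    N <- matrix(runif(n_l * n_s, 0, 100), n_l, n_s)
    phi <- matrix(runif(n_l * n_s), n_l, n_s)
    phi[n_l, ] <- 0                      # closed top class
    out <- growth_step(N, phi)
    expect_lt(max(abs(colSums(out) - colSums(N))), 1e-10)
  }
  expect_error(growth_step(N, matrix(2, 2, 1)), "\\[0, 1\\]")
})

test_that("predation mortality matches the brute-force quadruple sum", {
  p2 <- toy_params(n_s = 2, n_l = 3, other = 1e5)
  p3 <- toy_params(n_s = 3, n_l = 4, other = 1e5)
  set.seed(3)
  for (p in list(p2, p3)) {
    for (rep in 1:5) {
      N <- random_state(p)
      fast <- calc_M2(N, p)
      slow <- brute_force_M2(N, p)
      expect_lt(max(abs(fast - slow)) / max(slow, 1e-300), 1e-10)
    }
  }
})

test_that("predation vanishes without links, predators, or relative to other food", {
  p0 <- toy_params(n_s = 2, n_l = 6, tau = matrix(0, 2, 2))
  N <- random_state(p0)
  expect_equal(calc_M2(N, p0), matrix(0, 6, 2))
  p <- toy_params(n_s = 2, n_l = 6)
  expect_equal(calc_M2(matrix(0, 6, 2), p), matrix(0, 6, 2))
  # M2 decreases monotonically to zero as other food grows
  m2_tot <- vapply(c(1e5, 1e7, 1e9, 1e11), function(oth) {
    sum(calc_M2(N, toy_params(n_s = 2, n_l = 6, other = oth)))
  }, numeric(1))
  expect_true(all(diff(m2_tot) < 0))
  expect_lt(m2_tot[4] / m2_tot[1], 1e-3)
})

test_that("a predator with zero available food contributes nothing", {
  p <- toy_params(n_s = 2, n_l = 6, other = 0)
  # no prey biomass at all: denominator would be zero
  expect_equal(calc_M2(matrix(0, 6, 2), p), matrix(0, 6, 2))
})

test_that("one simulated year equals ten hand-chained steps", {
  p <- toy_fished_params(n_s = 2, n_l = 8)
  N0 <- get_N0(p, burn_years = 2)
  effort <- c(0.3, 0.6)
  out <- run_community(p, N0, years = 1, effort = matrix(effort, 1, 2))
  # oracle: chain the exported phase functions manually
  N <- N0
  R <- vapply(seq_len(2), function(i)
    recruitment(state_ssb(N, p)[i], p@species$rec_fun[i],
                p@species$a[i], p@species$b[i]), numeric(1))
  Fg <- calc_F(p@Q, effort, by_gear = TRUE)
  for (s in 1:10) {
    if (s == 1) N[1, ] <- N[1, ] + R
    M2 <- calc_M2(N, p)
    ms <- mortality_step(N, p@M1, M2, Fg, p@dt, p@w)
    N <- growth_step(ms$N, p@phi)
  }
  expect_equal(out@N[, , 10], N, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(out@R[1, ], stats::setNames(R, p@species$species))
})

test_that("degenerate runs behave as documented", {
  p <- toy_fished_params(n_s = 2, n_l = 8)
  N0 <- get_N0(p, burn_years = 0)
  out0 <- run_community(p, N0, years = 0)
  expect_equal(dim(out0@N)[3], 0L)
  # all processes null: no fishing, no predation, no M1, no growth, no SSB
  sp <- toy_species(1)
  sp$rec_fun <- "linear"; sp$a <- 1
  sp$M1_fun <- "constant"; sp$M1_Nmort <- 0
  pn <- community_params(sp, tau = matrix(0, 1, 1), n_l = 6)
  pn@phi[] <- 0
  pn@mature[] <- 0   # SSB = 0 so linear recruitment adds nothing
  N <- matrix(5, 6, 1)
  outn <- run_community(pn, N, years = 2)
  expect_equal(matrix(outn@N[, , dim(outn@N)[3]], 6, 1), N)
  expect_error(run_community(p, N0, years = 3, effort = matrix(0.2, 2, 2)),
               "one row per year")
  expect_error(run_community(p, N0, years = 1, effort = matrix(0.2, 1, 5)),
               "one column per gear")
})

test_that("numbers stay nonnegative and finite through fished, predatory runs", {
  set.seed(19)
  p <- toy_fished_params(n_s = 3, n_l = 8, other = 1e6)
  for (rep in 1:5) {
    N0 <- random_state(p, scale = 10^runif(1, 2, 6))
    eff <- matrix(runif(6, 0, 3), 2, 3)
    out <- run_community(p, N0, years = 2, effort = eff)
    expect_true(all(out@N >= 0))
    expect_true(all(is.finite(out@N)))
    expect_true(all(out@Catch >= 0))
  }
})

test_that("raising one gear's effort weakly lowers all numbers when tau = 0", {
  p <- reference_params(toy_params(n_s = 2, n_l = 8, tau = matrix(0, 2, 2)))
  N0 <- get_N0(p, burn_years = 5)
  run_at <- function(e1) {
    eff <- matrix(c(e1, 0.2), 10, 2, byrow = TRUE)
    out <- run_community(p, N0, years = 10, effort = eff)
    out@N[, , dim(out@N)[3]]
  }
  lo <- run_at(0.2); hi <- run_at(0.8)
  expect_true(all(hi <= lo + 1e-9))
})

test_that("burn-in reaches an unfished quasi-equilibrium", {
  p <- fixture_params()
  N1 <- get_N0(p, burn_years = 10)
  out <- run_community(p, N1, years = 10)   # a second unfished decade
  N2 <- out@N[, , dim(out@N)[3]]
  ssb1 <- state_ssb(N1, p)
  ssb2 <- state_ssb(N2, p)
  expect_true(all(abs(ssb2 - ssb1) / ssb1 < 0.01))
  expect_true(all(N1 >= 0))
  # raw seed (no burn-in) is deterministic, nonnegative, and occupied only
  # below each species' Linf
  raw <- get_N0(p, burn_years = 0)
  expect_identical(raw, get_N0(p, burn_years = 0))
  expect_true(all(raw >= 0))
  for (i in seq_len(p@n_s)) {
    expect_true(all(raw[p@grid$lower_bounds >= p@species$Linf[i], i] == 0))
  }
})
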