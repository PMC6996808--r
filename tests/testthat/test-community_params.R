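test_that("growth proportions match the von Bertalanffy transit time", {
  # transit time through [50, 60) for Linf = 100, k = 0.5, checked against
  # numerical integration of dL/dt = k (Linf - L)
  g <- build_length_grid(bounds = c(40, 50, 60, 80))
  sp <- validate_species_table(data.frame(
    Linf = 100, Lmat = 50, W_a = 0.01, W_b = 3, k = 0.5,
    rec_fun = "constant", a = 1))
  ph <- calc_phi(g, sp, phi_min = 0.1)
  t_oracle <- stats::integrate(function(L) 1 / (0.5 * (100 - L)), 50, 60)$value
  expect_equal(ph$dt, 0.1)
  expect_equal(ph$phi[2, 1], 0.1 / t_oracle, tolerance = 1e-8)
  expect_equal(ph$phi[2, 1], 0.1 / (2 * log(50 / 40)), tolerance = 1e-12)
})

test_that("phi is zero at and beyond Linf and capped at 1 for fast growth", {
  g <- build_length_grid(bounds = c(0, 30, 60, 90, 120))
  sp <- validate_species_table(data.frame(
    Linf = c(80, 100), Lmat = c(40, 50), W_a = 0.01, W_b = 3,
    k = c(0.4, 50), rec_fun = "constant", a = 1))
  expect_warning(ph <- calc_phi(g, sp, phi_min = 0.1), "capped")
  expect_equal(ph$phi[3:4, 1], c(0, 0))       # classes straddling/above Linf
  expect_equal(max(ph$phi[, 2]), 1)           # k -> infinity hits the cap
  # below Linf on an equal grid, phi declines as growth slows toward Linf
  expect_true(all(diff(ph$phi[1:2, 1]) < 0))
})

test_that("species that cannot grow past the first class are rejected", {
  g <- build_length_grid(bounds = c(0, 30, 60))
  sp <- validate_species_table(data.frame(
    Linf = 20, Lmat = 10, W_a = 0.01, W_b = 3, k = 0.5,
    rec_fun = "constant", a = 1))
  expect_error(calc_phi(g, sp), "first class")
})

test_that("maturity ogive is logistic in midpoint length", {
  g <- build_length_grid(bounds = c(30, 50, 70))  # midpoints 40, 60
  sp <- validate_species_table(data.frame(
    Linf = 100, Lmat = 40, W_a = 0.01, W_b = 3, k = 0.3,
    rec_fun = "constant", a = 1, kappa = 0.25))
  m <- calc_maturity(g, sp)
  expect_equal(m[1, 1], 0.5)                       # midpoint == Lmat
  expect_equal(m[2, 1], 1 / (1 + exp(-0.25 * 20))) # direct evaluation
  # steep kappa approaches a step function at Lmat
  sp$kappa <- 1e3
  m_step <- calc_maturity(g, sp)
  expect_equal(m_step[, 1], c(0.5, 1), tolerance = 1e-8)
  expect_true(all(diff(m[, 1]) >= 0))
})

test_that("background mortality families evaluate as documented", {
  g <- build_length_grid(bounds = seq(0, 100, by = 25))  # midpoints 12.5..87.5
  sp <- validate_species_table(data.frame(
    Linf = 100, Lmat = 50, W_a = 0.01, W_b = 3, k = 0.3,
    rec_fun = "constant", a = 1))
  expect_equal(calc_M1(g, sp, "constant", Nmort = 0.2)[, 1], rep(0.2, 4))
  lin <- calc_M1(g, sp, "linear", Nmort = 0.8)
  expect_equal(lin[2, 1], 0.8 * (1 - 37.5 / 100))
  # linear rate at midpoint Linf/2 is half the rate at length zero
  g2 <- build_length_grid(bounds = c(0, 40, 60, 100))
  expect_equal(calc_M1(g2, sp, "linear", Nmort = 0.8)[2, 1], 0.4)
  std <- calc_M1(g, sp, "std_RNM", Nmort = 0.8, prop = 0.75)
  expect_equal(std[, 1], c(0.8, 0.8, 0.8, 0))     # zero above prop * Linf
  expect_true(all(std >= 0))
  expect_error(calc_M1(g, sp, "exponential"), "unknown M1")
})

test_that("suitability kernel peaks at the preferred mass ratio", {
  g <- build_length_grid(bounds = c(0, 10, 31.072))
  sp <- validate_species_table(data.frame(
    Linf = c(40, 100), Lmat = c(20, 50), W_a = 0.01, W_b = 3, k = 0.3,
    rec_fun = "constant", a = 1))
  pp <- pred_params(mu = 30, sigma = 1)
  tau <- matrix(1, 2, 2)
  suit <- calc_suitability(g, sp, tau, pp)
  w <- outer(g$midpoints^3, c(0.01, 0.01))  # both species share W_a, W_b
  # predator sp2 class2 on prey sp1 class1: weight ratio
  ratio <- w[2, 2] / w[1, 1]
  expect_equal(suit[2, 2, 1, 1],
               exp(-(log(ratio) - log(30))^2 / 2), tolerance = 1e-10)
  # ratio exactly mu attains the kernel's maximum of 1
  g2 <- build_length_grid(bounds = c(0, 10, 10 * 30^(1 / 3) - 10))
  suit2 <- calc_suitability(g2, sp, tau, pp)
  expect_equal(suit2[2, 2, 1, 1], 1, tolerance = 1e-10)
  # direct evaluation at weight ratio 10
  expect_equal(exp(-(log(10 / 30))^2 / 2), 0.54691, tolerance = 1e-4)
})

test_that("suitability is zero without an interaction link or an edible prey", {
  g <- build_length_grid(n_l = 4, max_Linf = 100)
  sp <- validate_species_table(data.frame(
    Linf = c(60, 100), Lmat = c(30, 50), W_a = 0.01, W_b = 3, k = 0.3,
    rec_fun = "constant", a = 1))
  tau <- matrix(c(0, 0, 1, 0), 2, 2)  # only sp1 eats sp2... row=pred, col=prey
  suit <- calc_suitability(g, sp, tau, pred_params())
  expect_true(all(suit[1, , 1, ] == 0))  # tau[1,1] = 0
  expect_true(all(suit[2, , , ] == 0))   # predator row 2 all zero
  # prey at or above the predator weight is never suitable
  full <- calc_suitability(g, sp, matrix(1, 2, 2), pred_params())
  w <- vapply(1:2, function(i) 0.01 * g$midpoints^3, numeric(4))
  for (n in 1:4) for (j in 1:4) {
    if (w[j, 1] >= w[n, 1]) expect_equal(full[1, n, 1, j], 0)
  }
})

test_that("suitability depends only on the weight ratio", {
  g <- build_length_grid(n_l = 5, max_Linf = 120)
  sp <- validate_species_table(data.frame(
    Linf = c(60, 110), Lmat = c(30, 55), W_a = c(0.01, 0.01), W_b = 3,
    k = 0.3, rec_fun = "constant", a = 1))
  s1 <- calc_suitability(g, sp, matrix(1, 2, 2), pred_params())
  sp2 <- sp
  sp2$W_a <- sp$W_a * 7.3   # scale all weights by the same factor
  s2 <- calc_suitability(g, sp2, matrix(1, 2, 2), pred_params())
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("catchability families evaluate and rescale as documented", {
  g <- build_length_grid(bounds = seq(0, 100, by = 10))
  sp <- validate_species_table(data.frame(
    species = c("A", "B"), Linf = c(90, 80), Lmat = c(45, 40),
    W_a = 0.01, W_b = 3, k = 0.3, rec_fun = "constant", a = 1))
  # logistic is 0.5 at L50 before rescaling
  gears_raw <- data.frame(gear = "trawl", species = "A", fun = "logistic",
                          p1 = 0.5, p2 = 45)
  q_raw <- calc_catchability(g, sp, gears_raw, rescale = FALSE)
  expect_equal(q_raw[5, 1, 1], 0.5)   # midpoint 45 == L50
  # knife-edge steps from 0 to 1 at the edge length
  gears_ke <- data.frame(gear = "rec", species = "B", fun = "knife_edge",
                         p1 = 35, p2 = NA)
  q_ke <- calc_catchability(g, sp, gears_ke)
  expect_equal(q_ke[3, 2, 1], 0)   # midpoint 25 below the edge
  expect_equal(q_ke[4, 2, 1], 1)   # midpoint 35 at the edge is retained
  expect_equal(q_ke[5, 2, 1], 1)   # midpoint 45
  # after rescaling the maximum over classes is 1 for every targeted species
  gears <- data.frame(gear = c("trawl", "trawl"), species = c("A", "B"),
                      fun = "logistic", p1 = c(0.5, 0.3), p2 = c(45, 40))
  Q <- calc_catchability(g, sp, gears)
  expect_equal(max(Q[, 1, 1]), 1)
  expect_equal(max(Q[, 2, 1]), 1)
  # species not targeted have identically zero catchability
  expect_equal(sum(calc_catchability(g, sp, gears_raw)[, 2, ]), 0)
  expect_error(calc_catchability(g, sp, data.frame(
    gear = "x", species = "A", fun = "logistic", p1 = -1, p2 = 45)), "positive")
})

test_that("assembled structures lie in [0, 1] for random valid parameters", {
  set.seed(42)
  for (rep in 1:10) {
    n_s <- sample(2:4, 1)
    Linf <- sort(runif(n_s, 30, 150))
    sp <- data.frame(
      species = paste0("s", 1:n_s), Linf = Linf,
      Lmat = Linf * runif(n_s, 0.3, 0.7),
      W_a = runif(n_s, 0.005, 0.02), W_b = runif(n_s, 2.8, 3.2),
      k = runif(n_s, 0.1, 1), rec_fun = "hockey-stick",
      a = runif(n_s, 0.5, 5), b = runif(n_s, 1e4, 1e6))
    tau <- matrix(runif(n_s^2), n_s, n_s)
    gears <- data.frame(gear = "g1", species = sp$species, fun = "logistic",
                        p1 = runif(n_s, 0.1, 1), p2 = sp$Lmat)
    # fast growers on coarse grids can hit the phi cap; that is valid input
    p <- suppressWarnings(
      community_params(sp, gears = gears, tau = tau,
                       pred = pred_params(mu = runif(1, 5, 100),
                                          sigma = runif(1, 0.5, 3),
                                          other = 1e8),
                       n_l = sample(8:16, 1)))
    expect_true(all(p@phi >= 0 & p@phi <= 1))
    expect_true(all(p@mature >= 0 & p@mature <= 1))
    expect_true(all(p@suit >= 0 & p@suit <= 1))
    expect_true(all(p@Q >= 0 & p@Q <= 1))
    expect_true(all(p@M1 >= 0))
  }
})

test_that("species table and tau validation enforce the invariants", {
  sp <- toy_species(2)
  bad <- sp; bad$Lmat <- bad$Linf + 1
  expect_error(validate_species_table(bad), "Linf")
  bad <- sp; bad$k <- -0.1
  expect_error(validate_species_table(bad), "k")
  bad <- sp; bad$rec_fun <- "magic"
  expect_error(validate_species_table(bad), "unknown recruitment")
  expect_error(validate_tau(matrix(2, 2, 2), 2), "\\[0, 1\\]")
  expect_error(validate_tau(matrix(1, 3, 3), 2), "2 x 2")
  expect_error(pred_params(mu = 0.5), "mu")
  expect_error(pred_params(g0 = 1.5), "g0")
})
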