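flat_scenario <- function(...) {
  # all random structure switched off unless overridden
  args <- utils::modifyList(list(
    field_variances = c(alpha = 0, epsilon = 0, tau = 0),
    gamma_sd = 0, kappa_sd = 0, effort_sd = 0, effort_drift = 0,
    tau_center = 0, alpha_center = 0, epsilon_center = 1,
    nb_overdispersion = Inf, circles_per_cell = 3), list(...))
  do.call(scenario, args)
}

test_that("identical scenarios give bit-identical output", {
  s <- scenario(seed = 99)
  a <- simulate_counts(s)
  b <- simulate_counts(scenario(seed = 99))
  expect_identical(a$events, b$events)
  expect_identical(a$truth$tau, b$truth$tau)
  c <- simulate_counts(scenario(seed = 100))
  expect_false(identical(a$events$count, c$events$count))
})

test_that("unit linear predictor gives mean count near one", {
  sim <- simulate_counts(flat_scenario(grid_nx = 5, grid_ny = 5, years = 12,
                                       effort_base = 1, seed = 5))
  expect_equal(unique(sim$events$party_hours), 1)
  expect_equal(mean(sim$events$count), 1, tolerance = 0.1)
})

test_that("tau_center is the stated annual growth by construction", {
  sim <- simulate_counts(flat_scenario(tau_center = log(1.0136), seed = 2))
  tr <- sim$truth
  # expected counts at fixed unit effort across consecutive years
  mu <- exp(tr$alpha[1] + tr$tau[1] * tr$T)
  expect_equal(mu[-1] / mu[-length(mu)], rep(1.0136, length(mu) - 1),
               tolerance = 1e-12)
  expect_equal(100 * (exp(log(1.0136)) - 1), 1.36, tolerance = 1e-10)
})

test_that("doubling effort doubles the mean under a unit effort exponent", {
  s1 <- flat_scenario(grid_nx = 6, grid_ny = 6, years = 15, effort_base = 20,
                      alpha_center = 1, seed = 8)
  s2 <- flat_scenario(grid_nx = 6, grid_ny = 6, years = 15, effort_base = 40,
                      alpha_center = 1, seed = 8)
  m1 <- mean(simulate_counts(s1)$events$count)
  m2 <- mean(simulate_counts(s2)$events$count)
  expect_equal(m2 / m1, 2, tolerance = 0.05)
})

test_that("finite NB size inflates dispersion and large size approaches Poisson", {
  base <- list(grid_nx = 4, grid_ny = 4, years = 25, effort_base = 1,
               alpha_center = log(10), seed = 31)
  od <- simulate_counts(do.call(flat_scenario,
                                c(base, list(nb_overdispersion = 1))))$events$count
  # NB with mu = 10, Phi = 1: var/mean = 1 + mu/Phi = 11
  expect_gt(var(od) / mean(od), 3)
  po <- simulate_counts(do.call(flat_scenario,
                                c(base, list(nb_overdispersion = 1e7))))$events$count
  expect_equal(var(po) / mean(po), 1, tolerance = 0.25)
})

test_that("regressing log counts on log effort recovers the effort exponent", {
  sim <- simulate_counts(flat_scenario(grid_nx = 5, grid_ny = 5, years = 20,
                                       effort_sd = 0.6, effort_base = 10,
                                       alpha_center = 3, epsilon_center = 0.7,
                                       seed = 77))
  ev <- sim$events[sim$events$count > 0, ]
  slope <- coef(lm(log(count) ~ log(party_hours), data = ev))[2]
  expect_equal(unname(slope), 0.7, tolerance = 0.05)
})

test_that("circle placement respects the per-cell cap of three", {
  sim <- simulate_counts(scenario(grid_nx = 10, grid_ny = 10, years = 2,
                                  seed = 13))
  per_cell <- table(tapply(sim$events$circle_id, sim$events$circle_id,
                           function(i) unique(sim$events$cell_id[sim$events$circle_id == i])))
  counts <- tabulate(sim$truth$cell_of_circle, nbins = 100)
  expect_true(all(counts >= 1 & counts <= 3))
  expect_equal(mean(counts), 1.21, tolerance = 0.2)
})

test_that("missing visits thin the panel without breaking determinism", {
  s <- scenario(inclusion_prob = 0.7, seed = 21)
  a <- simulate_counts(s)
  expect_identical(a$events, simulate_counts(s)$events)
  full <- simulate_counts(scenario(inclusion_prob = 1, seed = 21))
  expect_lt(nrow(a$events), nrow(full$events))
})

test_that("covariate generator honours gradients, trends and bounds", {
  g <- make_grid(3, 3)
  const <- simulate_covariates(g, 5, params = list(
    p_base = 2, p_max = 2, p_gradient_x = 0,
    z_gradient_km = 0, z_trend = 0, z_sd = 0,
    n_gradient_km = 0, n_trend = 0, n_sd = 0), seed = 1)
  expect_equal(unique(const$P), 2)
  expect_equal(length(unique(const$Z)), 1L)
  expect_equal(length(unique(const$N)), 1L)

  ramp <- simulate_covariates(g, 12, params = list(n_sd = 0, z_sd = 0), seed = 1)
  for (cid in 1:9) {
    p <- ramp$P[ramp$cell_id == cid][order(ramp$year[ramp$cell_id == cid])]
    expect_true(all(diff(p) >= 0))              # nondecreasing ramp
  }
  expect_true(all(ramp$P >= 0) && all(ramp$N >= 0))

  # -0.1 degC per 100 km northward over a 10-row grid: 450 km of centroid
  # separation gives a 0.45 degC range at fixed year
  zg <- simulate_covariates(make_grid(1, 10), 1, params = list(
    z_gradient_km = -0.001, z_sd = 0, z_trend = 0), seed = 1)
  expect_equal(diff(range(zg$Z)), 0.45, tolerance = 1e-12)
})

test_that("covariate effects enter the cell-year term with recorded truth", {
  g <- make_grid(4, 4)
  cov <- simulate_covariates(g, 10, seed = 3)
  eff <- list(rho = rep(-0.3, 16), zeta = rep(0.2, 16))
  s <- scenario(grid_nx = 4, grid_ny = 4, years = 10, seed = 4)
  with_eff <- simulate_counts(s, covariates = cov, effects = eff)
  without <- simulate_counts(s)
  expect_equal(with_eff$truth$effects$rho, rep(-0.3, 16))
  expect_equal(with_eff$truth$effects$nu, rep(0, 16))
  expect_false(identical(with_eff$truth$gamma, without$truth$gamma))
})

test_that("scenario validation rejects impossible parameters", {
  expect_error(scenario(nb_overdispersion = 0), "> 0")
  expect_error(scenario(effort_base = -1), "> 0")
  expect_error(scenario(years = 1), ">= 2")
  expect_error(scenario(field_variances = c(alpha = -1, epsilon = 0, tau = 0)),
               ">= 0")
  expect_error(scenario(circles_per_cell = 4), "\\[0, 3\\]")
})
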