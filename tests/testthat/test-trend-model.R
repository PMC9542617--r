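test_that("linear predictor is the stated power-function form", {
  # exp(alpha) is the expected count at one party-hour in the final year
  expect_equal(exp(linear_predictor(log(10), 0, 0, 0, 0, effort = 1, T = 0)),
               10)
  # unit exponent: doubling effort doubles mu; zero exponent: no effect
  mu1 <- exp(linear_predictor(0, 1, 0, 0, 0, effort = 2, T = 0))
  mu2 <- exp(linear_predictor(0, 1, 0, 0, 0, effort = 4, T = 0))
  expect_equal(mu2 / mu1, 2)
  expect_equal(exp(linear_predictor(0.3, 0, 0, 0, 0, effort = 50, T = 0)),
               exp(linear_predictor(0.3, 0, 0, 0, 0, effort = 1, T = 0)))
  # one year back at tau = log(1.0136) scales mu by 1/1.0136
  r <- exp(linear_predictor(0, 0, log(1.0136), 0, 0, 1, T = -1)) /
    exp(linear_predictor(0, 0, log(1.0136), 0, 0, 1, T = 0))
  expect_equal(r, 1 / 1.0136, tolerance = 1e-12)
  expect_error(linear_predictor(0, 1, 0, 0, 0, effort = 0, T = 0), "> 0")
})

test_that("model spec indexes events against the occupied-cell graph", {
  sim <- simulate_counts(scenario(grid_nx = 4, grid_ny = 4, years = 8,
                                  seed = 3))
  # drop all events from two cells to make them unoccupied
  ev <- sim$events[!sim$events$cell_id %in% c(1L, 6L), ]
  spec <- trend_model_spec(ev, sim$truth$grid)
  expect_false(any(c(1L, 6L) %in% spec$cells))
  expect_equal(spec$graph$n, length(spec$cells))
  expect_equal(max(spec$T), 0L)
  expect_true(all(spec$T == round(spec$T)))
  expect_error(trend_model_spec(ev[ev$year == ev$year[1], ], sim$truth$grid),
               "2 years")
})

test_that("fitting is deterministic for a fixed seed and settings", {
  spec <- trend_model_spec(tiny_events(), make_grid(2, 1),
                           terms = trend_terms(alpha_field = FALSE,
                                               tau_field = FALSE,
                                               gamma = FALSE, kappa = FALSE,
                                               fix_epsilon = 1, fix_phi = 2))
  f1 <- fit_trend(spec, chains = 2, iter = 150, warmup = 150, seed = 42,
                  check_convergence = FALSE)
  f2 <- fit_trend(spec, chains = 2, iter = 150, warmup = 150, seed = 42,
                  check_convergence = FALSE)
  expect_identical(f1$tau, f2$tau)
  expect_identical(f1$alpha, f2$alpha)
  f3 <- fit_trend(spec, chains = 2, iter = 150, warmup = 150, seed = 43,
                  check_convergence = FALSE)
  expect_false(identical(f1$tau, f3$tau))
})

test_that("flat data give a trend posterior centred on zero", {
  ev <- data.frame(circle_id = rep(1:2, each = 12),
                   cell_id = rep(1:2, each = 12),
                   year = rep(2007:2018, 2),
                   party_hours = 1, count = 5L)
  spec <- trend_model_spec(ev, make_grid(2, 1),
                           terms = trend_terms(alpha_field = FALSE,
                                               tau_field = FALSE,
                                               gamma = FALSE, kappa = FALSE,
                                               fix_epsilon = 1))
  fit <- fit_trend(spec, chains = 2, iter = 600, warmup = 600, seed = 7,
                   check_convergence = FALSE)
  pt <- pooled_trend(fit)
  expect_gte(pt$prob_positive, 0.3)
  expect_lte(pt$prob_positive, 0.7)
})

test_that("posterior draws satisfy the structural constraints", {
  sim <- simulate_counts(scenario(grid_nx = 3, grid_ny = 3, years = 8,
                                  seed = 6))
  spec <- trend_model_spec(sim$events, sim$truth$grid)
  fit <- fit_trend(spec, chains = 2, iter = 250, warmup = 400, seed = 5,
                   check_convergence = FALSE)
  expect_true(all(fit$phi > 0))
  # iCAR fields sum to zero around their centers within each component
  dev <- sweep(fit$tau, 1L, fit$mu$tau)
  expect_lt(max(abs(rowSums(dev))), 1e-8)
  # gamma sums to zero across years within every cell
  expect_lt(max(abs(apply(fit$gamma, c(1, 2), sum))), 1e-8)
  # kappa sums to zero across circles
  expect_lt(max(abs(rowSums(fit$kappa))), 1e-8)
  # diagnostics present for every monitored scalar
  expect_true(all(c("a0", "t0", "log_phi") %in% names(fit$diagnostics$rhat)))
})

test_that("convergence gate trips on an unconverged fit and can be overridden", {
  sim <- simulate_counts(scenario(grid_nx = 3, grid_ny = 3, years = 6,
                                  seed = 9))
  spec <- trend_model_spec(sim$events, sim$truth$grid)
  # absurdly short chains cannot converge; the gate must fire
  expect_error(
    fit_trend(spec, chains = 2, iter = 40, warmup = 10, seed = 1,
              control = list(rhat_tol = 1.0005)),
    "convergence failure")
  expect_s3_class(
    fit_trend(spec, chains = 2, iter = 40, warmup = 10, seed = 1,
              check_convergence = FALSE),
    "trend_posterior")
})

test_that("cell summaries apply the draw-wise trend transform and flags", {
  tau <- cbind(rep(0.013509, 400), seq(-0.2, 0.2, length.out = 400),
               rep(-0.05, 400))
  post <- fake_posterior(tau)
  sm <- suppressMessages(summarize_cells(post, n_draws = 5000))$cells
  expect_equal(sm$trend_pct_med[1], 1.36, tolerance = 1e-3)
  expect_equal(sm$tau_flag, c(1L, 0L, -1L))
  expect_true(all(sm$tau_lo <= sm$tau_med & sm$tau_med <= sm$tau_hi))
  expect_true(all(sm$alpha_lo <= sm$alpha_med & sm$alpha_med <= sm$alpha_hi))
})

test_that("resampled summaries agree with plain summaries", {
  set.seed(8)
  tau <- matrix(rnorm(6000 * 2, 0.01, 0.005), 6000, 2)
  post <- fake_posterior(tau)
  a <- summarize_cells(post, n_draws = 5000, seed = 1)$cells
  b <- suppressMessages(
    summarize_cells(fake_posterior(tau[1:3000, ]), n_draws = 5000,
                    seed = 1)$cells)
  expect_lt(max(abs(a$tau_med - b$tau_med)), 2e-3)
})

test_that("pooled trend matches closed forms and handles subsets", {
  post <- fake_posterior(matrix(log(1.0136), 300, 3))
  pt <- pooled_trend(post)
  expect_equal(pt$trend_pct, 1.36, tolerance = 1e-10)
  expect_equal(pt$prob_positive, 1)

  set.seed(2)
  sym <- fake_posterior(matrix(rnorm(2000, 0, 0.01), 1000, 2))
  expect_equal(pooled_trend(sym)$prob_positive, 0.5, tolerance = 0.05)

  # two cells with equal and opposite draws pool to a zero median
  opp <- fake_posterior(cbind(rep(0.02, 500), rep(-0.02, 500)))
  expect_equal(pooled_trend(opp)$trend_pct, 0, tolerance = 1e-10)
  expect_equal(pooled_trend(opp, method = "mean")$trend_pct, 0,
               tolerance = 1e-10)

  # regional subset and error branches
  expect_equal(pooled_trend(opp, cells = 1L)$trend_pct,
               100 * (exp(0.02) - 1), tolerance = 1e-10)
  expect_error(pooled_trend(opp, cells = 99L), "unknown cell")
})
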