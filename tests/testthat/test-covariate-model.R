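test_that("abundance index follows the exponential-additive closed forms", {
  post <- fake_posterior(matrix(0.4, 10, 2))
  idx <- compute_index(post, draw = 1)
  expect_equal(unique(idx$omega[idx$year == 2018]), 1)   # T = 0, all else 0

  # adding log 2 to gamma doubles the index
  g2 <- array(log(2), dim = c(10, 2, 3))
  post2 <- fake_posterior(matrix(0.4, 10, 2), gamma = g2)
  idx2 <- compute_index(post2, draw = 1)
  expect_equal(idx2$omega / idx$omega, rep(2, 6))

  # in scaled mode the final-year index is independent of tau
  post3 <- fake_posterior(matrix(9.9, 10, 2))
  idx3 <- compute_index(post3, draw = 1, year_mode = "scaled")
  expect_equal(idx3$omega[idx3$year == 2018], idx$omega[idx$year == 2018])
  # literal mode applies tau as a constant
  lit <- compute_index(post3, draw = 1, year_mode = "literal")
  expect_equal(unique(round(lit$omega, 6)), round(exp(9.9), 6))
})

test_that("index replicate tables are deterministic and well shaped", {
  set.seed(5)
  post <- fake_posterior(matrix(rnorm(200), 100, 2))
  a <- abundance_index_draws(post, R = 20, seed = 3)
  b <- abundance_index_draws(post, R = 20, seed = 3)
  expect_identical(a$omega, b$omega)
  expect_equal(dim(a$omega), c(20L, 2L, 3L))
  expect_true(all(a$omega > 0))
})

test_that("credible-interval flags follow the exclusion rule", {
  fake <- structure(list(summary = data.frame(
    cell_id = 1:3, parameter = "rho",
    lo95 = c(0.2, -0.9, -0.1), median = c(0.5, -0.5, 0.1),
    hi95 = c(0.9, -0.2, 0.3))), class = "covariate_posterior")
  expect_equal(flag_significant(fake)$flag, c(1L, -1L, 0L))
})

# build replicate index tables directly from known gamma-model fields so the
# second stage can be tested in isolation from the sampler
synthetic_indices <- function(R, beta, rho, zeta, nu, cov_std, years,
                              noise_sd = 0.05, seed = 1) {
  ncell <- length(beta); ny <- length(years)
  gr <- build_adjacency(make_grid(ncell %/% 4, 4), "queen")
  st <- scale_icar(icar_structure(gr))
  om <- array(NA_real_, c(R, ncell, ny))
  ci <- match(cov_std$cell_id, seq_len(ncell))
  ti <- match(cov_std$year, years)
  lo <- matrix(NA_real_, ncell, ny)
  lo[cbind(ci, ti)] <- beta[ci] + rho[ci] * cov_std$P + zeta[ci] * cov_std$Z +
    nu[ci] * cov_std$N
  withr::with_seed(seed, {
    for (r in seq_len(R)) {
      om[r, , ] <- exp(lo + rnorm(ncell * ny, sd = noise_sd))
    }
  })
  structure(list(omega = om, cells = seq_len(ncell), years = years,
                 structure = st, year_mode = "scaled", draw_index = seq_len(R)),
            class = "abundance_index_draws")
}

test_that("second stage recovers block-structured covariate signs", {
  ncell <- 16; years <- 2009:2018
  cov <- simulate_covariates(make_grid(4, 4), years, seed = 2)
  cov_std <- standardize_covariates(cov)
  block <- rep(c(TRUE, FALSE), each = 8)        # west block carries effects
  rho <- ifelse(block, -0.5, 0)
  zeta <- ifelse(block, 0.5, 0)
  idx <- synthetic_indices(40, beta = rep(0.5, ncell), rho = rho, zeta = zeta,
                           nu = rep(0, ncell), cov_std = cov_std,
                           years = years, seed = 9)
  fit <- fit_covariate_model(idx, cov, R = 40, seed = 4)
  s <- fit$summary
  rho_med <- s$median[s$parameter == "rho"]
  zeta_med <- s$median[s$parameter == "zeta"]
  expect_gte(mean(rho_med[block] < 0), 0.9)
  expect_gte(mean(zeta_med[block] > 0), 0.9)
  expect_equal(fit$fail_fraction, 0)
})

test_that("a constant covariate has no identifiable effect", {
  ncell <- 16; years <- 2011:2018
  cov <- simulate_covariates(make_grid(4, 4), years, seed = 3)
  cov$N <- 700                                   # constant precipitation
  cov_std <- standardize_covariates(cov)
  idx <- synthetic_indices(30, beta = rep(0, ncell), rho = rep(0, ncell),
                           zeta = rep(0, ncell), nu = rep(0, ncell),
                           cov_std = cov_std, years = years, seed = 5)
  fit <- fit_covariate_model(idx, cov, R = 30, seed = 6)
  nu_rows <- fit$summary[fit$summary$parameter == "nu", ]
  expect_gte(mean(nu_rows$flag == 0), 0.95)
})

test_that("replicate propagation widens intervals and keeps medians stable", {
  ncell <- 16; years <- 2011:2018
  cov <- simulate_covariates(make_grid(4, 4), years, seed = 7)
  cov_std <- standardize_covariates(cov)
  rho <- rep(-0.3, ncell)
  mk <- function(R, noise) synthetic_indices(
    R, beta = rep(0.2, ncell), rho = rho, zeta = rep(0, ncell),
    nu = rep(0, ncell), cov_std = cov_std, years = years,
    noise_sd = noise, seed = 8)
  one <- fit_covariate_model(mk(1, 0), cov, R = 1, seed = 1,
                             laplace_draws = FALSE)
  many <- fit_covariate_model(mk(60, 0.3), cov, R = 60, seed = 1)
  m1 <- one$summary$median[one$summary$parameter == "rho"]
  m2 <- many$summary$median[many$summary$parameter == "rho"]
  expect_equal(mean(m1), mean(m2), tolerance = 0.1)
  w1 <- with(one$summary[one$summary$parameter == "rho", ], hi95 - lo95)
  w2 <- with(many$summary[many$summary$parameter == "rho", ], hi95 - lo95)
  expect_gt(mean(w2), mean(w1))
})

test_that("covariate gaps and bad indices are rejected", {
  post <- fake_posterior(matrix(0.1, 20, 2))
  idx <- abundance_index_draws(post, R = 5, seed = 1)
  cov <- data.frame(cell_id = 1L, year = 2016:2018, P = 1, Z = 10, N = 100)
  expect_error(fit_covariate_model(idx, cov, R = 2), "covariates missing")
})
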