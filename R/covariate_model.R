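#' Annual relative-abundance index from one posterior draw
#'
#' The index is the expected count at one party-hour of effort:
#' `year_mode = "scaled"` (default) evaluates the year term at the coded year,
#' \eqn{\omega_{i,t} = \exp(\alpha_i + \tau_i T_t + \gamma_{i,t})}, while
#' `"literal"` uses \eqn{\exp(\alpha_i + \tau_i + \gamma_{i,t})} (the year
#' term entering as a constant). The mode is recorded in the output.
#'
#' @param post a [fit_trend()] posterior.
#' @param draw index of the posterior draw to use.
#' @param year_mode `"scaled"` or `"literal"`.
#' @return data frame `cell_id`, `year`, `omega` for that draw, with
#'   attribute `year_mode`.
#' @export
compute_index <- function(post, draw = 1L, year_mode = c("scaled", "literal")) {
  stopifnot(inherits(post, "trend_posterior"))
  year_mode <- match.arg(year_mode)
  om <- index_matrix(post, draw, year_mode)
  out <- data.frame(cell_id = rep(post$cells, times = length(post$years)),
                    year = rep(post$years, each = length(post$cells)),
                    omega = as.vector(om))
  attr(out, "year_mode") <- year_mode
  out
}

index_matrix <- function(post, draw, year_mode) {
  yt <- if (year_mode == "scaled") post$T else rep(1, length(post$years))
  exp(outer(post$alpha[draw, ], rep(1, length(post$years))) +
        outer(post$tau[draw, ], yt) + post$gamma[draw, , ])
}

#' Relative-abundance index tables over posterior replicates
#'
#' Randomly samples `R` posterior draws and evaluates [compute_index()] for
#' each, producing the replicate inputs of the second-stage covariate model.
#'
#' @inheritParams compute_index
#' @param R number of replicates.
#' @param seed integer seed for the draw sampling.
#' @return an `abundance_index_draws` object: array `omega`
#'   (R x cells x years) plus cell/year labels and the stage-one graph.
#' @export
abundance_index_draws <- function(post, R = 200, seed = 1L,
                                  year_mode = c("scaled", "literal")) {
  stopifnot(inherits(post, "trend_posterior"))
  year_mode <- match.arg(year_mode)
  S <- nrow(post$tau)
  idx <- with_seed(seed, sample.int(S, R, replace = R > S))
  om <- array(NA_real_, dim = c(R, length(post$cells), length(post$years)))
  for (r in seq_len(R)) om[r, , ] <- index_matrix(post, idx[r], year_mode)
  structure(list(omega = om, cells = post$cells, years = post$years,
                 structure = post$spec$structure, year_mode = year_mode,
                 draw_index = idx),
            class = "abundance_index_draws")
}

# negative log posterior and gradient of the gamma SVC model, one replicate.
# par layout: centers (4) | z fields (4 x m) | log sigma (4) | log shape
gamma_svc_obj <- function(par, logw, w, X, B, lambda, center_sd = 10,
                          shape_rate = -log(0.01)) {
  ncell <- nrow(w); m <- ncol(B)
  ctr <- par[1:4]
  z <- matrix(par[4 + seq_len(4 * m)], m, 4L)
  lsig <- par[4 + 4 * m + 1:4]
  sig <- exp(lsig)
  lsh <- par[length(par)]
  s <- exp(lsh)
  fields <- sweep(B %*% z, 2L, sig, "*")          # ncell x 4 deviations
  fields <- sweep(fields, 2L, ctr, "+")           # beta, rho, zeta, nu
  lo <- matrix(fields[, 1], ncell, ncol(w)) +
    fields[, 2] * X$P + fields[, 3] * X$Z + fields[, 4] * X$N
  ll <- sum(s * lsh - lgamma(s) + (s - 1) * logw - s * lo - s * w * exp(-lo))
  lp <- ll - 0.5 * sum(ctr^2) / center_sd^2 - 0.5 * sum(z^2) +
    sum(log(lambda) - lambda * sig + lsig) +
    log(shape_rate) - shape_rate * exp(-lsh / 2) - lsh / 2 - log(2)
  # large finite penalty: L-BFGS-B cannot digest Inf during line search
  if (!is.finite(lp)) return(list(value = 1e10, grad = rep(0, length(par))))

  q <- s * (w * exp(-lo) - 1)                     # d ll / d logOmega
  sb <- rowSums(q)
  sr <- rowSums(q * X$P); sz <- rowSums(q * X$Z); sn <- rowSums(q * X$N)
  Sagg <- cbind(sb, sr, sz, sn)
  g_ctr <- colSums(Sagg) - ctr / center_sd^2
  g_z <- as.vector(sweep(t(B) %*% Sagg, 2L, sig, "*") - z)
  dev <- sweep(B %*% z, 2L, sig, "*")
  g_lsig <- colSums(dev * Sagg) - lambda * sig + 1
  g_lsh <- s * sum(lsh + 1 - digamma(s) + logw - lo - w * exp(-lo)) +
    shape_rate / 2 * exp(-lsh / 2) - 0.5
  list(value = -lp, grad = -c(g_ctr, g_z, g_lsig, g_lsh))
}

#' Fit the gamma covariate model over posterior replicates
#'
#' For each replicate's index table \eqn{\omega_{i,t}} the model
#' \deqn{\omega_{i,t} \sim \mathrm{Gamma}(\mathrm{mean} = \Omega_{i,t}, \mathrm{shape} = s),
#'   \quad \log \Omega_{i,t} = \beta_i + \rho_i P_{i,t} + \zeta_i Z_{i,t} + \nu_i N_{i,t}}
#' is fitted with iCAR-structured intercepts and slopes (same scaled graph as
#' stage one) by penalized maximum a posteriori (L-BFGS with analytic
#' gradients), optionally followed by one draw from the Laplace Gaussian at
#' the mode so stage-two estimation uncertainty also enters the pool.
#' Replicate estimates are pooled into posterior medians and symmetric 95%
#' credible intervals per cell; per-replicate failures are logged, excluded,
#' and an error is raised if they exceed `max_fail`.
#'
#' @param indices an [abundance_index_draws()] object.
#' @param covariates cell-year covariate table (`cell_id`, `year`, `P`, `Z`,
#'   `N`) covering every cell-year in `indices`.
#' @param R number of replicates (capped at the replicates available).
#' @param seed integer seed (Laplace draws).
#' @param standardize center/scale covariates before fitting (recorded and
#'   inverted in `raw_scale` output)?
#' @param laplace_draws add the Laplace draw at each mode (default `TRUE`)?
#' @param max_fail maximum tolerated replicate failure fraction.
#' @return a `covariate_posterior`: `summary` data frame (per cell and
#'   parameter: median, lo95, hi95, flag, Monte-Carlo SE of the median),
#'   `draws` array (replicates x cells x 4), failure fraction, covariate
#'   scaling.
#' @export
fit_covariate_model <- function(indices, covariates, R = 200, seed = 1L,
                                standardize = TRUE, laplace_draws = TRUE,
                                max_fail = 0.05) {
  stopifnot(inherits(indices, "abundance_index_draws"))
  R <- min(R, dim(indices$omega)[1])
  cells <- indices$cells; years <- indices$years
  ncell <- length(cells); nyear <- length(years)

  cov_used <- if (standardize) standardize_covariates(covariates) else covariates
  key <- paste(cov_used$cell_id, cov_used$year)
  want <- paste(rep(cells, times = nyear), rep(years, each = ncell))
  pos <- match(want, key)
  if (anyNA(pos)) {
    stop("covariates missing for ", sum(is.na(pos)), " cell-years",
         call. = FALSE)
  }
  X <- list(P = matrix(cov_used$P[pos], ncell, nyear),
            Z = matrix(cov_used$Z[pos], ncell, nyear),
            N = matrix(cov_used$N[pos], ncell, nyear))
  B <- icar_basis(indices$structure)
  m <- ncol(B)
  lambda <- pc_prior(1, 0.01)$lambda
  npar <- 4L + 4L * m + 4L + 1L

  draws <- array(NA_real_, dim = c(R, ncell, 4L),
                 dimnames = list(NULL, NULL, c("beta", "rho", "zeta", "nu")))
  shapes <- rep(NA_real_, R)
  fails <- 0L
  par0 <- c(mean(log(pmax(indices$omega[1, , ], 1e-12))), 0, 0, 0,
            rep(0, 4 * m), rep(log(0.1), 4), 0)
  rng_seeds <- with_seed(seed, sample.int(.Machine$integer.max, R))

  for (r in seq_len(R)) {
    w <- indices$omega[r, , ]
    if (any(!is.finite(w) | w <= 0)) {
      stop("non-positive or non-finite abundance index in replicate ", r,
           call. = FALSE)
    }
    logw <- log(w)
    fn <- function(p) gamma_svc_obj(p, logw, w, X, B, lambda)$value
    gr <- function(p) gamma_svc_obj(p, logw, w, X, B, lambda)$grad
    lb <- c(rep(-Inf, 4L + 4L * m), rep(-8, 4L), -8)
    ub <- c(rep(Inf, 4L + 4L * m), rep(4, 4L), 12)
    fit <- tryCatch(
      stats::optim(par0, fn, gr, method = "L-BFGS-B",
                   lower = lb, upper = ub, control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) { fails <- fails + 1L; next }
    par0 <- fit$par   # warm start the next replicate
    est <- fit$par
    if (laplace_draws) {
      est <- tryCatch(
        laplace_draw_at(fit$par, gr, rng_seeds[r]),
        error = function(e) fit$par)
    }
    ctr <- est[1:4]
    z <- matrix(est[4 + seq_len(4 * m)], m, 4L)
    sig <- exp(est[4 + 4 * m + 1:4])
    fields <- sweep(sweep(B %*% z, 2L, sig, "*"), 2L, ctr, "+")
    draws[r, , ] <- fields
    shapes[r] <- exp(est[npar])
  }
  fail_frac <- fails / R
  if (fail_frac > max_fail) {
    stop("replicate fit failure fraction ", round(fail_frac, 3),
         " exceeds ", max_fail, call. = FALSE)
  }
  ok <- which(!is.na(draws[, 1, 1]))
  draws <- draws[ok, , , drop = FALSE]

  scl <- attr(cov_used, "scale"); ctrv <- attr(cov_used, "center")
  summ <- do.call(rbind, lapply(c("beta", "rho", "zeta", "nu"), function(pn) {
    d <- draws[, , pn, drop = FALSE]
    qs <- apply(d, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE)
    mcse <- 1.2533 * apply(d, 2L, stats::sd) / sqrt(length(ok))
    data.frame(cell_id = cells, parameter = pn,
               lo95 = qs[1, ], median = qs[2, ], hi95 = qs[3, ],
               mcse_median = mcse)
  }))
  summ$flag <- ifelse(summ$lo95 > 0, 1L, ifelse(summ$hi95 < 0, -1L, 0L))
  structure(list(summary = summ, draws = draws, shapes = shapes[ok],
                 fail_fraction = fail_frac, cells = cells,
                 standardized = standardize,
                 cov_center = if (standardize) ctrv else NULL,
                 cov_scale = if (standardize) scl else NULL),
            class = "covariate_posterior")
}

# one draw from the Laplace approximation N(mode, H^-1), H from central
# finite differences of the analytic gradient
laplace_draw_at <- function(mode, gr, seed, h = 1e-4) {
  p <- length(mode)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h
    H[, j] <- (gr(mode + e) - gr(mode - e)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  Hc <- tryCatch(chol(H), error = function(e)
    chol(H + diag(1e-6 + abs(min(eigen(H, only.values = TRUE)$values)), p)))
  z <- with_seed(seed, stats::rnorm(p))
  mode + backsolve(Hc, z)
}

#' Flag cells whose credible interval excludes zero
#'
#' @param posterior a [fit_covariate_model()] result.
#' @return its summary table with `flag` = +1 when the 95% interval lies above
#'   zero, -1 when below, 0 otherwise.
#' @export
flag_significant <- function(posterior) {
  stopifnot(inherits(posterior, "covariate_posterior"))
  s <- posterior$summary
  s$flag <- ifelse(s$lo95 > 0, 1L, ifelse(s$hi95 < 0, -1L, 0L))
  s
}
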