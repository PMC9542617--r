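#' Define a synthetic count-survey scenario
#'
#' A `scenario` bundles every parameter of the generative model used to
#' emulate a citizen-science butterfly count programme: count circles placed
#' on a uniform 50-km grid, surveyed over a span of years with party-hour
#' effort that drifts slowly upward, producing negative-binomial counts from
#' the spatially-varying-coefficient linear predictor
#' \deqn{\log \mu = \alpha_i + \epsilon_i \log E + \tau_i T + \gamma_{i,t} + \kappa_k}
#' with iCAR-distributed cell fields \eqn{\alpha, \epsilon, \tau},
#' exchangeable cell-year effects \eqn{\gamma} and circle effects
#' \eqn{\kappa}.
#'
#' Defaults describe the emulated programme: a 6 x 6 grid of 50-km cells,
#' 15-year series ending 2018, on average 1.21 circles per cell (maximum 3),
#' effort rising 1.2% per year around a 10 party-hour base with lognormal
#' visit-to-visit noise, a mean trend of +1.36% per year
#' (`tau_center = log(1.0136)`), a near-linear mean effort exponent
#' (`epsilon_center = 1`) and moderate NB overdispersion.
#'
#' @param grid_nx,grid_ny grid dimensions (cells).
#' @param years length of the series (>= 2); calendar years run back from
#'   `end_year`.
#' @param end_year final calendar year.
#' @param circles_per_cell expected circles per cell, in `[0, 3]`; realized
#'   counts are capped at three.
#' @param effort_base mean party-hours per count event in the first year (> 0).
#' @param effort_drift proportional change in mean effort per year.
#' @param effort_sd standard deviation of lognormal effort noise.
#' @param field_variances named numeric: marginal variances of the `alpha`,
#'   `epsilon`, `tau` iCAR fields.
#' @param alpha_center,epsilon_center,tau_center field means. `exp(alpha)` is
#'   the expected count at one party-hour in the final year;
#'   `100*(exp(tau_center)-1)` is the mean trend in %/yr.
#' @param gamma_sd,kappa_sd standard deviations of the exchangeable cell-year
#'   and circle effects.
#' @param nb_overdispersion NB size parameter Phi > 0 (variance
#'   `mu + mu^2/Phi`); `Inf` gives Poisson counts.
#' @param inclusion_prob probability a circle-year is actually surveyed
#'   (1 = balanced panel).
#' @param adjacency contiguity rule for the simulated fields.
#' @param covariate_params parameter list for [simulate_covariates()].
#' @param seed integer seed; identical scenarios give identical data.
#' @return object of class `scenario` (a list of the above).
#' @export
scenario <- function(grid_nx = 6, grid_ny = 6,
                     years = 15, end_year = 2018,
                     circles_per_cell = 1.21,
                     effort_base = 10, effort_drift = 0.012, effort_sd = 0.2,
                     field_variances = c(alpha = 0.5, epsilon = 0.05, tau = 0.001),
                     alpha_center = 0, epsilon_center = 1,
                     tau_center = log(1.0136),
                     gamma_sd = 0.15, kappa_sd = 0.3,
                     nb_overdispersion = 2,
                     inclusion_prob = 1,
                     adjacency = c("queen", "rook"),
                     covariate_params = NULL,
                     seed = 1L) {
  adjacency <- match.arg(adjacency)
  fv <- field_variances
  if (is.null(names(fv))) names(fv) <- c("alpha", "epsilon", "tau")
  stopifnot(all(c("alpha", "epsilon", "tau") %in% names(fv)))
  if (any(fv < 0) || gamma_sd < 0 || kappa_sd < 0 || effort_sd < 0) {
    stop("variance/scale parameters must be >= 0", call. = FALSE)
  }
  if (effort_base <= 0) stop("`effort_base` must be > 0", call. = FALSE)
  if (years < 2) stop("`years` must be >= 2", call. = FALSE)
  if (nb_overdispersion <= 0) stop("`nb_overdispersion` must be > 0", call. = FALSE)
  if (circles_per_cell < 0 || circles_per_cell > 3) {
    stop("`circles_per_cell` must lie in [0, 3]", call. = FALSE)
  }
  if (inclusion_prob < 0 || inclusion_prob > 1) {
    stop("`inclusion_prob` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
    years = as.integer(years), end_year = as.integer(end_year),
    circles_per_cell = circles_per_cell,
    effort_base = effort_base, effort_drift = effort_drift,
    effort_sd = effort_sd,
    field_variances = fv[c("alpha", "epsilon", "tau")],
    alpha_center = alpha_center, epsilon_center = epsilon_center,
    tau_center = tau_center,
    gamma_sd = gamma_sd, kappa_sd = kappa_sd,
    nb_overdispersion = nb_overdispersion,
    inclusion_prob = inclusion_prob,
    adjacency = adjacency,
    covariate_params = covariate_params,
    seed = as.integer(seed)
  ), class = "scenario")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate count-circle data from a scenario
#'
#' Draws the ground-truth fields, places circles, generates drifting
#' party-hour effort and negative-binomial counts. Optionally, covariate
#' effects can be baked into the cell-year term: with `covariates` and
#' `effects` supplied, \eqn{\gamma_{i,t}} gains
#' \eqn{\rho_i P^*_{i,t} + \zeta_i Z^*_{i,t} + \nu_i N^*_{i,t}} on
#' standardized covariates, closing the loop for the second-stage model.
#'
#' @param scen a [scenario()].
#' @param covariates optional cell-year covariate table (columns `cell_id`,
#'   `year`, `P`, `Z`, `N`), e.g. from [simulate_covariates()].
#' @param effects optional list with per-cell numeric vectors `rho`, `zeta`,
#'   `nu` (effects on standardized covariates); zero vectors where omitted.
#' @return list with `events` (data frame: `circle_id`, `cell_id`, `lon`,
#'   `lat`, `date`, `year`, `party_hours`, `count`) and `truth` (fields,
#'   gamma matrix, kappa, Phi, grid, graph, effects used).
#' @export
simulate_counts <- function(scen, covariates = NULL, effects = NULL) {
  stopifnot(inherits(scen, "scenario"))
  grid <- make_grid(scen$grid_nx, scen$grid_ny)
  graph <- build_adjacency(grid, scen$adjacency)
  str <- scale_icar(icar_structure(graph))
  B <- icar_basis(str)
  ncell <- graph$n
  yrs <- seq(scen$end_year - scen$years + 1L, scen$end_year)
  Tt <- yrs - scen$end_year                      # max(T) = 0
  ny <- length(yrs)

  with_seed(scen$seed, {
    fv <- scen$field_variances
    alpha <- scen$alpha_center +
      sqrt(fv[["alpha"]]) * drop(B %*% stats::rnorm(ncol(B)))
    epsilon <- scen$epsilon_center +
      sqrt(fv[["epsilon"]]) * drop(B %*% stats::rnorm(ncol(B)))
    tau <- scen$tau_center +
      sqrt(fv[["tau"]]) * drop(B %*% stats::rnorm(ncol(B)))

    gamma <- matrix(stats::rnorm(ncell * ny, sd = scen$gamma_sd), ncell, ny,
                    dimnames = list(NULL, yrs))
    eff_used <- NULL
    if (!is.null(covariates)) {
      cov_std <- standardize_covariates(covariates)
      eff_used <- lapply(c(rho = "rho", zeta = "zeta", nu = "nu"), function(nm) {
        v <- effects[[nm]]
        if (is.null(v)) numeric(ncell) else rep_len(v, ncell)
      })
      ci <- match(cov_std$cell_id, seq_len(ncell))
      ti <- match(cov_std$year, yrs)
      ok <- !is.na(ci) & !is.na(ti)
      gamma[cbind(ci[ok], ti[ok])] <- gamma[cbind(ci[ok], ti[ok])] +
        eff_used$rho[ci[ok]] * cov_std$P[ok] +
        eff_used$zeta[ci[ok]] * cov_std$Z[ok] +
        eff_used$nu[ci[ok]] * cov_std$N[ok]
    }

    # circle placement: 1 + Binom(2, p) circles per cell (max 3), matching the
    # emulated programme's 1.21 mean; expectations below 1 thin cells instead
    cpc <- scen$circles_per_cell
    n_circ_cell <- if (cpc >= 1) {
      1L + stats::rbinom(ncell, 2L, (cpc - 1) / 2)
    } else {
      stats::rbinom(ncell, 1L, cpc)
    }
    cell_of_circle <- rep(seq_len(ncell), n_circ_cell)
    K <- length(cell_of_circle)
    if (K == 0L) stop("scenario produced zero circles", call. = FALSE)
    cs <- attr(grid, "cell_size_km")
    cx <- grid$xmin[cell_of_circle] + stats::runif(K) * cs
    cy <- grid$ymin[cell_of_circle] + stats::runif(K) * cs
    kappa <- stats::rnorm(K, sd = scen$kappa_sd)

    idx_circle <- rep(seq_len(K), each = ny)
    idx_cell <- cell_of_circle[idx_circle]
    idx_year <- rep(seq_len(ny), times = K)
    nrec <- length(idx_circle)

    effort <- scen$effort_base * (1 + scen$effort_drift)^(idx_year - 1L) *
      stats::rlnorm(nrec, meanlog = -scen$effort_sd^2 / 2, sdlog = scen$effort_sd)
    eta <- alpha[idx_cell] + epsilon[idx_cell] * log(effort) +
      tau[idx_cell] * Tt[idx_year] + gamma[cbind(idx_cell, idx_year)] +
      kappa[idx_circle]
    mu <- exp(eta)
    # quantile-coupled draws: scenarios sharing a seed differ only through
    # mu, so paired designs (e.g. with/without effort drift) are comparable
    # with common random numbers
    u <- stats::runif(nrec)
    y <- if (is.finite(scen$nb_overdispersion)) {
      stats::qnbinom(u, size = scen$nb_overdispersion, mu = mu)
    } else {
      stats::qpois(u, mu)
    }
    day <- sample.int(92L, nrec, replace = TRUE) - 1L   # Jun 1 .. Aug 31
    keep <- stats::runif(nrec) <= scen$inclusion_prob

    events <- data.frame(
      circle_id = idx_circle,
      cell_id = idx_cell,
      lon = cx[idx_circle],
      lat = cy[idx_circle],
      date = as.Date(paste0(yrs[idx_year], "-06-01")) + day,
      year = yrs[idx_year],
      party_hours = effort,
      count = y
    )[keep, , drop = FALSE]
    rownames(events) <- NULL

    truth <- list(alpha = alpha, epsilon = epsilon, tau = tau,
                  gamma = gamma, kappa = kappa,
                  phi = scen$nb_overdispersion,
                  effects = eff_used,
                  years = yrs, T = Tt,
                  cell_of_circle = cell_of_circle,
                  grid = grid, graph = graph, structure = str)
    list(events = events, truth = truth)
  })
}

#' Simulate cell-year environmental covariates
#'
#' Generates the three covariates of the second-stage model on a grid:
#' `P` (glyphosate use, kg active ingredient; nonnegative, ramping up over
#' early years then plateauing, with an optional west-east gradient), `Z`
#' (mean annual temperature, degrees C; latitudinal gradient plus a warming
#' trend and interannual noise) and `N` (cumulative annual precipitation, mm;
#' nonnegative noise around a base).
#'
#' @param grid an [make_grid()] object.
#' @param years integer vector of calendar years, or a count (series then ends
#'   in 2018).
#' @param params list overriding any of: `p_base`, `p_max`, `p_ramp_years`,
#'   `p_gradient_x` (per km), `z_base`, `z_gradient_km` (degrees C per km
#'   northward), `z_trend` (degrees C per year), `z_sd`, `n_base`,
#'   `n_gradient_km`, `n_trend`, `n_sd`.
#' @param seed integer seed.
#' @return data frame with columns `cell_id`, `year`, `P`, `Z`, `N`.
#' @export
simulate_covariates <- function(grid, years, params = list(), seed = 1L) {
  stopifnot(inherits(grid, "svc_grid"))
  if (length(years) == 1L) years <- seq(2018L - as.integer(years) + 1L, 2018L)
  p <- utils::modifyList(list(
    p_base = 0, p_max = 3, p_ramp_years = 10, p_gradient_x = 0,
    z_base = 12, z_gradient_km = -0.006, z_trend = 0.03, z_sd = 0.4,
    n_base = 800, n_gradient_km = 0, n_trend = 0, n_sd = 80
  ), params)
  ncell <- nrow(grid)
  ny <- length(years)
  cell_id <- rep(grid$cell_id, times = ny)
  year <- rep(years, each = ncell)
  t0 <- year - min(years)
  x <- rep(grid$x, times = ny); y <- rep(grid$y, times = ny)

  with_seed(seed, {
    ramp <- pmin(t0 / max(1, p$p_ramp_years), 1)
    P <- pmax(0, (p$p_base + (p$p_max - p$p_base) * ramp) *
                pmax(0, 1 + p$p_gradient_x * (x - mean(grid$x))))
    Z <- p$z_base + p$z_gradient_km * (y - min(grid$y)) + p$z_trend * t0 +
      stats::rnorm(length(x), sd = p$z_sd)
    N <- pmax(0, p$n_base + p$n_gradient_km * (y - min(grid$y)) +
                p$n_trend * t0 + stats::rnorm(length(x), sd = p$n_sd))
    data.frame(cell_id = cell_id, year = year, P = P, Z = Z, N = N)
  })
}

#' Center and scale cell-year covariates
#'
#' Centers and scales each of `P`, `Z`, `N` over all cell-years. The transform
#' is recorded in attributes `center` and `scale` so it can be inverted and so
#' fitted slopes can be reported on the raw scale. Constant columns are left
#' centered with scale 1.
#'
#' @param covariates data frame with columns `cell_id`, `year`, `P`, `Z`, `N`.
#' @return the standardized table with attributes `center` and `scale`.
#' @export
standardize_covariates <- function(covariates) {
  out <- covariates
  ctr <- scl <- c(P = 0, Z = 0, N = 0)
  for (v in c("P", "Z", "N")) {
    ctr[v] <- mean(covariates[[v]])
    s <- stats::sd(covariates[[v]])
    scl[v] <- if (is.na(s) || s == 0) 1 else s
    out[[v]] <- (covariates[[v]] - ctr[v]) / scl[v]
  }
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}
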