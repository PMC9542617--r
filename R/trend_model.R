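#' Linear predictor of the count trend model
#'
#' \eqn{\log \mu = \alpha + \epsilon \log E + \tau T + \gamma + \kappa}:
#' exponentiating gives a power function of effort
#' (\eqn{\mu \propto E^\epsilon}), and with year coded so that
#' \eqn{\max(T) = 0}, \eqn{\exp(\alpha)} is the expected count at one
#' party-hour of effort in the final year.
#'
#' @param alpha,epsilon,tau,gamma,kappa model terms (recycled).
#' @param effort party-hours, > 0.
#' @param T year covariate: nonpositive integers, 0 in the final year.
#' @return log expected count.
#' @export
linear_predictor <- function(alpha, epsilon, tau, gamma, kappa, effort, T) {
  if (any(effort <= 0)) stop("`effort` must be > 0", call. = FALSE)
  alpha + epsilon * log(effort) + tau * T + gamma + kappa
}

#' Model terms and fixed-value switches
#'
#' Controls which components of the linear predictor are estimated. Setting
#' `fix_epsilon` to a number removes the effort field and uses that exponent
#' exactly; `fix_phi` likewise fixes the NB size. Disabling a field keeps its
#' center (a single coefficient shared by all cells) unless the whole term is
#' switched off.
#'
#' @param alpha_field,epsilon_field,tau_field estimate iCAR spatial deviations?
#' @param gamma,kappa include the exchangeable cell-year / circle effects?
#' @param fix_epsilon `NULL` (estimate) or a fixed effort exponent.
#' @param fix_phi `NULL` (estimate) or a fixed NB size.
#' @export
trend_terms <- function(alpha_field = TRUE, epsilon_field = TRUE,
                        tau_field = TRUE, gamma = TRUE, kappa = TRUE,
                        fix_epsilon = NULL, fix_phi = NULL) {
  list(alpha_field = alpha_field, epsilon_field = epsilon_field,
       tau_field = tau_field, gamma = gamma, kappa = kappa,
       fix_epsilon = fix_epsilon, fix_phi = fix_phi)
}

#' Assemble a trend-model specification
#'
#' Indexes curated events against the occupied-cell graph (cells containing at
#' least one retained circle), builds and scales the iCAR structure, codes the
#' year covariate with `max(T) = 0`, and attaches priors. Cells without
#' events carry no parameters.
#'
#' @param events curated event table (`cell_id`, `circle_id`, `year`,
#'   `party_hours`, `count`).
#' @param grid the [make_grid()] object the events were assigned to.
#' @param adjacency contiguity rule for the occupied-cell graph.
#' @param sd_prior [pc_prior()] shared by the three field SDs and the
#'   `gamma`/`kappa` SDs.
#' @param phi_prior [nb_dispersion_prior()] for the NB size.
#' @param terms a [trend_terms()] list.
#' @return object of class `trend_model_spec`.
#' @export
trend_model_spec <- function(events, grid, adjacency = c("queen", "rook"),
                             sd_prior = pc_prior(1, 0.01),
                             phi_prior = nb_dispersion_prior(7),
                             terms = trend_terms()) {
  adjacency <- match.arg(adjacency)
  stopifnot(nrow(events) > 0, all(events$party_hours > 0),
            all(events$count >= 0))
  cells <- sort(unique(events$cell_id))
  full_graph <- build_adjacency(grid, adjacency)
  graph <- subgraph(full_graph, cells)
  str <- scale_icar(icar_structure(graph))
  years <- sort(unique(events$year))
  if (length(years) < 2) stop("need at least 2 years of data", call. = FALSE)
  Tt <- years - max(years)
  circles <- sort(unique(events$circle_id))
  structure(list(
    events = events, grid = grid, graph = graph, structure = str,
    basis = icar_basis(str),
    cells = cells, years = years, T = Tt, circles = circles,
    cell_index = match(events$cell_id, cells),
    year_index = match(events$year, years),
    circle_index = match(events$circle_id, circles),
    sd_prior = sd_prior, phi_prior = phi_prior, terms = terms
  ), class = "trend_model_spec")
}

# orthonormal basis with columns summing to zero (n x (n-1))
sum_to_zero_basis <- function(n) {
  if (n < 2L) return(matrix(numeric(0), nrow = n, ncol = 0))
  H <- stats::contr.helmert(n)
  sweep(H, 2L, sqrt(colSums(H^2)), "/")
}

#' Fit the negative-binomial SVC trend model by HMC
#'
#' Samples the joint posterior of all cell fields, exchangeable effects,
#' their standard deviations and the NB size with a Hamiltonian Monte Carlo
#' sampler (non-centered parameterization, dual-averaging step-size and
#' diagonal mass adaptation). Convergence is checked with split R-hat on the
#' monitored scalars (centers, log SDs, log Phi) and the worst case over all
#' raw coordinates; the fit aborts if any monitored R-hat exceeds
#' `rhat_tol` unless `check_convergence = FALSE`.
#'
#' @param spec a [trend_model_spec()].
#' @param chains,iter,warmup number of chains, post-warmup draws per chain,
#'   and warmup iterations per chain.
#' @param seed integer seed; identical seed and settings give an identical
#'   draw sequence.
#' @param control list: `max_leapfrog` (default 32), `target_accept` (0.8),
#'   `init_step` (0.05), `center_sd` (10), `rhat_tol` (1.05).
#' @param check_convergence abort on R-hat failure? Default `TRUE`.
#' @return A `trend_posterior`: posterior draw matrices `alpha`, `epsilon`,
#'   `tau` (draws x cells), `gamma` (draws x cells x years), `kappa`
#'   (draws x circles), `phi`, `sigma` (draws x SDs), cell/year/circle
#'   labels, and `diagnostics` (R-hat, bulk ESS, acceptance, divergences).
#' @export
fit_trend <- function(spec, chains = 4, iter = 2000, warmup = 1000,
                      seed = 1L, control = list(),
                      check_convergence = TRUE) {
  stopifnot(inherits(spec, "trend_model_spec"))
  ctl <- utils::modifyList(list(max_leapfrog = 48L, target_accept = 0.9,
                                init_step = 0.05, center_sd = 10,
                                rhat_tol = 1.05), control)
  tm <- spec$terms
  est_eps <- is.null(tm$fix_epsilon)
  fix_phi <- if (is.null(tm$fix_phi)) -1 else tm$fix_phi
  ncell <- length(spec$cells)
  nyear <- length(spec$years)
  ncirc <- length(spec$circles)
  est_gamma <- isTRUE(tm$gamma) && nyear >= 2L
  est_kappa <- isTRUE(tm$kappa) && ncirc >= 2L
  ev <- spec$events
  phi_pc <- spec$phi_prior$form == "pc"
  mlE <- mean(log(ev$party_hours))
  mT <- mean(spec$T[spec$year_index])

  runs <- lapply(seq_len(chains), function(ch) {
    nb_svc_hmc(
      y = as.numeric(ev$count), logE = log(ev$party_hours),
      Tt = as.numeric(spec$T[spec$year_index]),
      cell = spec$cell_index - 1L, yearidx = spec$year_index - 1L,
      circ = spec$circle_index - 1L,
      B = spec$basis, Cg = sum_to_zero_basis(nyear),
      Dk = sum_to_zero_basis(ncirc),
      ncell = ncell, nyear = nyear, ncirc = ncirc,
      est_alpha_field = isTRUE(tm$alpha_field), est_eps = est_eps,
      est_eps_field = isTRUE(tm$epsilon_field),
      est_tau_field = isTRUE(tm$tau_field),
      est_gamma = est_gamma, est_kappa = est_kappa,
      fix_eps = if (est_eps) 0 else tm$fix_epsilon, fix_phi = fix_phi,
      lambda_sd = spec$sd_prior$lambda, center_sd = ctl$center_sd,
      mlE = mlE, mT = mT,
      phi_pc = phi_pc, phi_l = spec$phi_prior$l,
      phi_shape = spec$phi_prior$shape, phi_rate = spec$phi_prior$rate,
      iter = as.integer(iter), warmup = as.integer(warmup),
      max_leapfrog = as.integer(ctl$max_leapfrog),
      target_accept = ctl$target_accept, init_eps = ctl$init_step,
      seed = as.integer(seed) + 7919L * (ch - 1L))
  })

  off <- runs[[1]]$offsets
  draw_list <- lapply(runs, `[[`, "draws")
  raw <- do.call(rbind, draw_list)
  S <- nrow(raw)
  B <- spec$basis
  m <- ncol(B)
  grab <- function(name, len) {
    o <- off[[name]]
    if (o < 0) NULL else raw[, (o + 1L):(o + len), drop = FALSE]
  }
  t0 <- raw[, off[["t0"]] + 1L]
  e0 <- if (off[["e0"]] >= 0) raw[, off[["e0"]] + 1L] else NULL
  # undo the sampler's centered-covariate coordinates for the intercept
  a0 <- raw[, off[["a0"]] + 1L] - t0 * mT - if (is.null(e0)) 0 else e0 * mlE
  sig <- list(alpha = grab("lsa", 1L), epsilon = grab("lse", 1L),
              tau = grab("lst", 1L), gamma = grab("lsg", 1L),
              kappa = grab("lsk", 1L))
  sig <- lapply(sig, function(x) if (is.null(x)) NULL else exp(drop(x)))
  # whitened coefficients scale by their SD draw to give the field deviation
  field <- function(center, zname, signame) {
    z <- grab(zname, m)
    out <- matrix(center, S, ncell)
    if (!is.null(z)) out <- out + (sig[[signame]] * z) %*% t(B)
    out
  }
  alpha <- field(a0, "za", "alpha")
  epsilon <- if (est_eps) field(e0, "ze", "epsilon") else
    matrix(tm$fix_epsilon, S, ncell)
  tau <- field(t0, "zt", "tau")

  gamma <- array(0, dim = c(S, ncell, nyear))
  if (est_gamma) {
    G <- grab("g", ncell * (nyear - 1L))
    Cg <- sum_to_zero_basis(nyear)
    for (s in seq_len(S)) {
      gamma[s, , ] <- sig$gamma[s] *
        (matrix(G[s, ], ncell, nyear - 1L) %*% t(Cg))
    }
  }
  kappa <- matrix(0, S, ncirc)
  if (est_kappa) {
    W <- grab("w", ncirc - 1L)
    kappa <- (sig$kappa * W) %*% t(sum_to_zero_basis(ncirc))
  }
  phi <- if (off[["lphi"]] >= 0) exp(raw[, off[["lphi"]] + 1L]) else
    rep(fix_phi, S)

  # diagnostics on raw coordinates
  rh_all <- split_rhat(draw_list)
  monitored <- c(a0 = off[["a0"]], e0 = off[["e0"]], t0 = off[["t0"]],
                 log_sigma_alpha = off[["lsa"]], log_sigma_epsilon = off[["lse"]],
                 log_sigma_tau = off[["lst"]], log_sigma_gamma = off[["lsg"]],
                 log_sigma_kappa = off[["lsk"]], log_phi = off[["lphi"]])
  monitored <- monitored[monitored >= 0] + 1L
  diag <- list(
    rhat = stats::setNames(rh_all[monitored], names(monitored)),
    rhat_max = if (all(is.na(rh_all))) NA_real_ else max(rh_all, na.rm = TRUE),
    ess = vapply(monitored, function(j)
      ess_basic(lapply(draw_list, function(d) d[, j])), numeric(1)),
    accept_rate = vapply(runs, `[[`, numeric(1), "accept_rate"),
    divergences = vapply(runs, `[[`, numeric(1), "divergences"),
    step_size = vapply(runs, `[[`, numeric(1), "step_size"))
  if (check_convergence && chains >= 2 && iter >= 10) {
    bad <- diag$rhat[is.finite(diag$rhat) & diag$rhat > ctl$rhat_tol]
    if (length(bad)) {
      stop("convergence failure: split R-hat > ", ctl$rhat_tol, " for ",
           paste(names(bad), collapse = ", "),
           " (", paste(round(bad, 3), collapse = ", "), ")", call. = FALSE)
    }
  }

  structure(list(
    alpha = alpha, epsilon = epsilon, tau = tau, gamma = gamma, kappa = kappa,
    phi = phi, sigma = sig, mu = list(alpha = a0, epsilon = e0, tau = t0),
    cells = spec$cells, years = spec$years, T = spec$T,
    circles = spec$circles, component = spec$graph$component,
    diagnostics = diag, chains = chains, iter = iter,
    spec = spec
  ), class = "trend_posterior")
}

#' Split R-hat per parameter
#'
#' Potential-scale-reduction diagnostic computed after splitting each chain in
#' half, so within-chain drift also registers.
#'
#' @param chains list of draw matrices (iterations x parameters), one per
#'   chain.
#' @return numeric vector of R-hat values (NA for constant parameters).
#' @export
split_rhat <- function(chains) {
  half <- lapply(chains, function(d) {
    n <- nrow(d) %/% 2L
    list(d[seq_len(n), , drop = FALSE],
         d[(nrow(d) - n + 1L):nrow(d), , drop = FALSE])
  })
  segs <- unlist(half, recursive = FALSE)
  n <- nrow(segs[[1]])
  mns <- vapply(segs, colMeans, numeric(ncol(segs[[1]])))
  vrs <- vapply(segs, function(d) apply(d, 2L, stats::var),
                numeric(ncol(segs[[1]])))
  if (is.null(dim(mns))) { mns <- rbind(mns); vrs <- rbind(vrs) }
  m <- length(segs)
  W <- rowMeans(vrs)
  Bv <- n * apply(mns, 1L, stats::var)
  out <- sqrt(((n - 1) / n * W + Bv / n) / W)
  out[W <= 0 | !is.finite(W)] <- NA_real_
  out
}

#' Bulk effective sample size of a scalar
#'
#' Geyer initial-positive-sequence estimator on rank-normalized draws is not
#' attempted; this is the classic autocorrelation-sum estimator, adequate for
#' monitoring.
#'
#' @param chains list of numeric vectors (one per chain).
#' @return effective sample size.
#' @export
ess_basic <- function(chains) {
  chains <- lapply(chains, as.numeric)
  n <- length(chains[[1]])
  S <- n * length(chains)
  if (n < 4) return(NA_real_)
  rho_sum <- 0
  acs <- lapply(chains, function(x) {
    if (stats::sd(x) == 0) return(NULL)
    stats::acf(x, lag.max = min(n - 2L, 250L), plot = FALSE)$acf[-1L]
  })
  acs <- acs[!vapply(acs, is.null, logical(1))]
  if (!length(acs)) return(NA_real_)
  rho <- Reduce(`+`, acs) / length(acs)
  for (k in seq_along(rho)) {
    if (rho[k] < 0.05) break
    rho_sum <- rho_sum + rho[k]
  }
  S / (1 + 2 * rho_sum)
}

#' Summarize cell-level posteriors
#'
#' Posterior medians and symmetric 95% credible intervals per cell for
#' \eqn{\alpha_i}, \eqn{\epsilon_i}, \eqn{\tau_i} and the trend in %/yr
#' (`100*(exp(tau)-1)` applied draw-wise), with a flag for cells whose 95%
#' interval excludes zero; plus per cell-year medians of \eqn{\gamma_{i,t}}.
#' Summaries use `n_draws` posterior samples, resampling with replacement
#' (with a message) when fewer are available.
#'
#' @param post a [fit_trend()] posterior.
#' @param n_draws number of posterior samples to summarize (default 5000).
#' @param seed seed for the resampling step.
#' @return list of data frames `cells` (per-cell summaries) and `gamma`
#'   (cell-year medians).
#' @export
summarize_cells <- function(post, n_draws = 5000, seed = 1L) {
  stopifnot(inherits(post, "trend_posterior"))
  S <- nrow(post$tau)
  idx <- if (S >= n_draws) {
    with_seed(seed, sample.int(S, n_draws))
  } else {
    message("only ", S, " draws available; resampling with replacement to ",
            n_draws)
    with_seed(seed, sample.int(S, n_draws, replace = TRUE))
  }
  qs <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  one <- function(mat) t(apply(mat[idx, , drop = FALSE], 2L, qs))
  al <- one(post$alpha); ep <- one(post$epsilon); ta <- one(post$tau)
  tr <- one(100 * (exp(post$tau) - 1))
  cells <- data.frame(
    cell_id = post$cells,
    alpha_lo = al[, 1], alpha_med = al[, 2], alpha_hi = al[, 3],
    epsilon_lo = ep[, 1], epsilon_med = ep[, 2], epsilon_hi = ep[, 3],
    tau_lo = ta[, 1], tau_med = ta[, 2], tau_hi = ta[, 3],
    trend_pct_lo = tr[, 1], trend_pct_med = tr[, 2], trend_pct_hi = tr[, 3]
  )
  cells$tau_flag <- ifelse(cells$tau_lo > 0, 1L,
                           ifelse(cells$tau_hi < 0, -1L, 0L))
  gm <- apply(post$gamma[idx, , , drop = FALSE], c(2L, 3L), stats::median)
  gamma <- data.frame(
    cell_id = rep(post$cells, times = length(post$years)),
    year = rep(post$years, each = length(post$cells)),
    gamma_med = as.vector(gm)
  )
  list(cells = cells, gamma = gamma)
}

#' Pooled relative-abundance trend
#'
#' Pools the posterior draws of \eqn{\tau_i} across grid cells (each cell
#' weighted equally) and reports the median trend as %/yr and the fraction of
#' pooled mass above zero. `method = "pooled"` concatenates all cells' draws
#' (the pooled posterior across cells); `method = "mean"` takes the
#' across-cell mean within each draw, giving the posterior of the global mean
#' trend, the natural recovery target in simulations. A subset of cells (e.g.
#' a region) can be supplied.
#'
#' @param post a [fit_trend()] posterior.
#' @param cells optional vector of cell ids to pool over.
#' @param method `"pooled"` (default) or `"mean"`.
#' @return list: `trend_pct` (median, %/yr), `prob_positive`, `ci_pct`
#'   (95% interval, %/yr), `median_log` (median on the log scale), `draws`
#'   (pooled draws, log scale).
#' @export
pooled_trend <- function(post, cells = NULL, method = c("pooled", "mean")) {
  stopifnot(inherits(post, "trend_posterior"))
  method <- match.arg(method)
  keep <- if (is.null(cells)) seq_along(post$cells) else {
    k <- match(cells, post$cells)
    if (anyNA(k)) stop("unknown cell ids in subset", call. = FALSE)
    k
  }
  if (!length(keep)) stop("empty cell subset", call. = FALSE)
  tau <- post$tau[, keep, drop = FALSE]
  pooled <- if (method == "pooled") as.vector(tau) else rowMeans(tau)
  list(trend_pct = 100 * (exp(stats::median(pooled)) - 1),
       prob_positive = mean(pooled > 0),
       ci_pct = 100 * (exp(stats::quantile(pooled, c(0.025, 0.975),
                                           names = FALSE)) - 1),
       median_log = stats::median(pooled),
       draws = pooled)
}
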