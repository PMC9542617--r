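#' Penalized-complexity prior on a standard deviation
#'
#' The PC prior for a Gaussian random-effect standard deviation sigma is an
#' exponential density on sigma, calibrated through the tail statement
#' P(sigma > U) = a, giving rate lambda = -log(a) / U. With U = 1, a = 0.01
#' (the default used for every field and exchangeable effect here),
#' lambda = 4.60517.
#'
#' @param U positive threshold on the standard deviation.
#' @param a tail probability in (0, 1): the prior mass above `U`.
#' @return object of class `pc_prior` with elements `U`, `a`, `lambda`.
#' @examples
#' pc_prior(1, 0.01)$lambda   # 4.60517
#' @export
pc_prior <- function(U = 1, a = 0.01) {
  if (!is.numeric(U) || length(U) != 1L || !is.finite(U) || U <= 0) {
    stop("`U` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0 || a >= 1) {
    stop("`a` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(U = U, a = a, lambda = -log(a) / U), class = "pc_prior")
}

#' @rdname pc_prior
#' @param x standard-deviation values (nonnegative).
#' @param prior a [pc_prior()].
#' @param log return the log density?
#' @export
dpc <- function(x, prior, log = FALSE) {
  stopifnot(inherits(prior, "pc_prior"))
  stats::dexp(x, rate = prior$lambda, log = log)
}

#' @rdname pc_prior
#' @param n number of draws.
#' @export
rpc <- function(n, prior) {
  stopifnot(inherits(prior, "pc_prior"))
  stats::rexp(n, rate = prior$lambda)
}

#' @rdname pc_prior
#' @param q quantile (standard deviation value).
#' @export
ppc <- function(q, prior) {
  stopifnot(inherits(prior, "pc_prior"))
  stats::pexp(q, rate = prior$lambda)
}

#' Penalized-complexity prior on negative-binomial overdispersion
#'
#' The negative binomial with mean mu and size Phi (variance mu + mu^2/Phi)
#' arises from a Poisson with gamma-distributed multiplicative frailty of
#' mean 1 and variance 1/Phi. The Poisson is the base model (Phi -> Inf), and
#' the frailty standard deviation d = 1/sqrt(Phi) is the natural distance from
#' it (the Kullback-Leibler distance behaves as d^2/2 near the base). The PC
#' prior is an exponential with rate `l` on that distance, here `l = 7`,
#' giving a prior density on Phi of (l/2) Phi^(-3/2) exp(-l/sqrt(Phi)). A
#' gamma prior on Phi is available as a sensitivity fallback since the
#' distance construction for this family is convention-dependent.
#'
#' @param l positive rate on the distance scale.
#' @param form `"pc"` (default) or `"gamma"`.
#' @param shape,rate gamma-prior parameters, used when `form = "gamma"`.
#' @return object of class `nb_dispersion_prior`.
#' @export
nb_dispersion_prior <- function(l = 7, form = c("pc", "gamma"),
                                shape = 1, rate = 0.1) {
  form <- match.arg(form)
  if (form == "pc" && (!is.numeric(l) || length(l) != 1L || l <= 0)) {
    stop("`l` must be a positive number", call. = FALSE)
  }
  structure(list(l = l, form = form, shape = shape, rate = rate),
            class = "nb_dispersion_prior")
}

#' @rdname nb_dispersion_prior
#' @param phi overdispersion (NB size) values, > 0.
#' @param prior an [nb_dispersion_prior()].
#' @param log return log density?
#' @export
dnbdisp <- function(phi, prior, log = FALSE) {
  stopifnot(inherits(prior, "nb_dispersion_prior"))
  if (prior$form == "pc") {
    ld <- log(prior$l) - log(2) - 1.5 * log(phi) - prior$l / sqrt(phi)
    ld[phi <= 0] <- -Inf
  } else {
    ld <- stats::dgamma(phi, shape = prior$shape, rate = prior$rate, log = TRUE)
  }
  if (log) ld else exp(ld)
}
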