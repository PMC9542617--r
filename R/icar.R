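#' Intrinsic CAR structure matrix of a graph
#'
#' Builds the (unscaled) iCAR structure matrix Q = D - A, with vertex degrees
#' on the diagonal and -1 for each neighbour pair. Q is symmetric positive
#' semidefinite with row sums exactly zero; its rank deficiency equals the
#' number of connected components, each of which carries one sum-to-zero
#' constraint when the iCAR density is used as a prior.
#'
#' @param graph an `svc_graph` (see [build_adjacency()]).
#' @return An `icar_structure`: list with sparse `Q`
#'   ([Matrix::sparseMatrix()]), `component` labels, `singletons` (vertices
#'   with no neighbours), `scaled` flag and, once scaled, per-component
#'   `scaling` factors.
#' @seealso [scale_icar()] for the variance scaling applied before use.
#' @export
icar_structure <- function(graph) {
  stopifnot(inherits(graph, "svc_graph"))
  n <- graph$n
  e <- graph$edges
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = n)
  if (nrow(e)) {
    Q <- Matrix::sparseMatrix(
      i = c(seq_len(n), e[, 1], e[, 2]),
      j = c(seq_len(n), e[, 2], e[, 1]),
      x = c(as.numeric(deg), rep(-1, 2L * nrow(e))),
      dims = c(n, n), symmetric = FALSE
    )
  } else {
    Q <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  }
  structure(list(Q = Q, component = graph$component,
                 singletons = which(deg == 0L),
                 scaled = FALSE, scaling = NULL),
            class = "icar_structure")
}

#' Scale an iCAR structure matrix to unit typical marginal variance
#'
#' Rescales Q component-by-component so that the geometric mean of the
#' marginal variances of the constrained iCAR field (the diagonal of the
#' generalized inverse of Q under one sum-to-zero constraint per component)
#' equals one. This makes a single penalized-complexity prior on the field
#' standard deviation comparable across graphs of different size and
#' connectivity. Scaling is idempotent. Singleton components have no iCAR
#' density; by convention they are treated as independent standard-normal
#' cells (marginal variance one, matching the scaled field).
#'
#' @param structure an [icar_structure()].
#' @return the structure with `Q` rescaled, `scaled = TRUE` and per-component
#'   geometric-mean variances recorded in `scaling` (NA for singletons).
#' @export
scale_icar <- function(structure) {
  stopifnot(inherits(structure, "icar_structure"))
  if (isTRUE(structure$scaled)) return(structure)
  comp <- structure$component
  Q <- structure$Q
  scaling <- rep(NA_real_, max(comp))
  for (cc in seq_len(max(comp))) {
    idx <- which(comp == cc)
    if (length(idx) < 2L) next  # singleton: convention handled downstream
    v <- constrained_marginal_variances(as.matrix(Q[idx, idx, drop = FALSE]))
    g <- exp(mean(log(v)))
    Q[idx, idx] <- Q[idx, idx] * g
    scaling[cc] <- g
  }
  structure$Q <- Q
  structure$scaled <- TRUE
  structure$scaling <- scaling
  structure
}

# Marginal variances of an iCAR field on one connected component under the
# sum-to-zero constraint: diagonal of the Moore-Penrose pseudo-inverse of Q
# (the null space of a connected component's Q is the constant vector, which
# the constraint removes).
constrained_marginal_variances <- function(Qd) {
  eg <- eigen(Qd, symmetric = TRUE)
  lam <- eg$values
  pos <- lam > max(lam) * 1e-10
  V <- eg$vectors[, pos, drop = FALSE]
  rowSums(sweep(V^2, 2L, lam[pos], "/"))
}

#' Sum-to-zero spectral basis of a scaled iCAR structure
#'
#' Returns a matrix `B` (n x m) such that `u = B z` with `z ~ N(0, I_m)` is a
#' draw from the zero-mean iCAR distribution with precision `Q` under one
#' sum-to-zero constraint per connected component: columns are the
#' eigenvectors of Q with positive eigenvalue, scaled by eigenvalue^(-1/2).
#' Singleton components contribute an indicator column (independent standard
#' normal), the scaling convention for isolated cells.
#'
#' Every constrained field value is in the column span, so the basis is also
#' the non-centered parameterization used by the samplers.
#'
#' @param structure a scaled [icar_structure()].
#' @return numeric matrix with `n` rows; `sum-to-zero` holds per non-singleton
#'   component for every column.
#' @export
icar_basis <- function(structure) {
  stopifnot(inherits(structure, "icar_structure"))
  if (!isTRUE(structure$scaled)) structure <- scale_icar(structure)
  comp <- structure$component
  n <- nrow(structure$Q)
  cols <- list()
  for (cc in seq_len(max(comp))) {
    idx <- which(comp == cc)
    if (length(idx) < 2L) {
      col <- numeric(n); col[idx] <- 1
      cols[[length(cols) + 1L]] <- col
      next
    }
    eg <- eigen(as.matrix(structure$Q[idx, idx, drop = FALSE]), symmetric = TRUE)
    lam <- eg$values
    pos <- which(lam > max(lam) * 1e-10)
    for (k in pos) {
      col <- numeric(n)
      col[idx] <- eg$vectors[, k] / sqrt(lam[k])
      cols[[length(cols) + 1L]] <- col
    }
  }
  do.call(cbind, cols)
}

#' Draw random fields from the scaled iCAR distribution
#'
#' @param structure a (scaled) [icar_structure()]; an unscaled structure or an
#'   `svc_graph` is scaled/converted first.
#' @param marginal_variance nonnegative scalar; the field is multiplied by its
#'   square root, so the geometric mean of per-cell marginal variances equals
#'   `marginal_variance`.
#' @param n number of independent draws.
#' @param seed optional integer seed (local to this call).
#' @return an `n x ncells` matrix of draws; each row sums to zero within every
#'   non-singleton connected component.
#' @export
simulate_icar_field <- function(structure, marginal_variance = 1, n = 1,
                                seed = NULL) {
  if (inherits(structure, "svc_graph")) structure <- icar_structure(structure)
  stopifnot(inherits(structure, "icar_structure"))
  if (nrow(structure$Q) == 0L) stop("graph has no cells", call. = FALSE)
  if (!is.numeric(marginal_variance) || marginal_variance < 0) {
    stop("`marginal_variance` must be >= 0", call. = FALSE)
  }
  B <- icar_basis(structure)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  z <- matrix(stats::rnorm(n * ncol(B)), n, ncol(B))
  sqrt(marginal_variance) * z %*% t(B)
}
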