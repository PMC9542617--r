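#' Build a uniform planar grid of square cells
#'
#' Creates the areal support used throughout the package: a regular lattice of
#' square cells (default 50 x 50 km, i.e. 2500 km^2) onto which count circles
#' are assigned and over which all iCAR random fields are defined. Cell ids are
#' row-major (west-to-east within each row, south row first) and stable.
#'
#' @param nx,ny number of cells along x (east) and y (north); both >= 1.
#' @param cell_size_km side length of a cell in km. Default 50.
#' @param origin numeric length-2, planar (x, y) km coordinate of the grid's
#'   lower-left corner. Default `c(0, 0)`.
#' @return An object of class `svc_grid`: a data frame with one row per cell
#'   (`cell_id`, `row`, `col`, `x`, `y` centroids, `xmin`, `xmax`, `ymin`,
#'   `ymax`) and attributes `nx`, `ny`, `cell_size_km`, `origin`.
#' @examples
#' g <- make_grid(3, 2)
#' nrow(g)            # 6 cells
#' attr(g, "cell_size_km")
#' @export
make_grid <- function(nx, ny, cell_size_km = 50, origin = c(0, 0)) {
  if (length(nx) != 1L || length(ny) != 1L || is.na(nx) || is.na(ny) ||
      nx < 1 || ny < 1 || nx != round(nx) || ny != round(ny)) {
    stop("`nx` and `ny` must be positive integers", call. = FALSE)
  }
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1L || cell_size_km <= 0) {
    stop("`cell_size_km` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(origin) || length(origin) != 2L) {
    stop("`origin` must be a numeric vector of length 2", call. = FALSE)
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  row <- rep(seq_len(ny), each = nx)
  col <- rep(seq_len(nx), times = ny)
  xmin <- origin[1] + (col - 1L) * cell_size_km
  ymin <- origin[2] + (row - 1L) * cell_size_km
  g <- data.frame(
    cell_id = seq_len(nx * ny),
    row = row, col = col,
    x = xmin + cell_size_km / 2,
    y = ymin + cell_size_km / 2,
    xmin = xmin, xmax = xmin + cell_size_km,
    ymin = ymin, ymax = ymin + cell_size_km
  )
  attr(g, "nx") <- nx
  attr(g, "ny") <- ny
  attr(g, "cell_size_km") <- cell_size_km
  attr(g, "origin") <- origin
  class(g) <- c("svc_grid", "data.frame")
  g
}

#' Assign planar points to grid cells
#'
#' Each point maps to the unique cell whose half-open extent
#' `[xmin, xmax) x [ymin, ymax)` contains it, so a point on a shared edge goes
#' to the lower-indexed cell and no point is ever assigned twice. Points on the
#' grid's outer top/right boundary are included in the last cell.
#'
#' @param x,y planar coordinates (km, same system as the grid).
#' @param grid an [make_grid()] object.
#' @return integer vector of cell ids.
#' @export
assign_grid <- function(x, y, grid) {
  stopifnot(inherits(grid, "svc_grid"), length(x) == length(y))
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  cs <- attr(grid, "cell_size_km"); org <- attr(grid, "origin")
  col <- floor((x - org[1]) / cs) + 1
  row <- floor((y - org[2]) / cs) + 1
  # points exactly on the outer boundary belong to the outermost cell
  col[x == org[1] + nx * cs] <- nx
  row[y == org[2] + ny * cs] <- ny
  bad <- which(col < 1 | col > nx | row < 1 | row > ny | !is.finite(x) | !is.finite(y))
  if (length(bad)) {
    stop("points outside grid extent at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  }
  as.integer((row - 1) * nx + col)
}

#' Build the contiguity graph of a grid
#'
#' @param grid an [make_grid()] object.
#' @param rule `"queen"` (edge- or corner-sharing neighbours; default) or
#'   `"rook"` (edge-sharing only). On a square lattice queen contiguity keeps
#'   diagonal chains of occupied cells connected; both are 50 km
#'   centre-to-centre for the default cell size.
#' @return An `svc_graph`: list with `n` (cell count), `edges` (2-column
#'   integer matrix, each row an unordered pair `i < j`, rows sorted), and
#'   `component` (integer component label per cell).
#' @examples
#' nrow(build_adjacency(make_grid(2, 2), "rook")$edges)   # 4
#' nrow(build_adjacency(make_grid(2, 2), "queen")$edges)  # 6
#' @export
build_adjacency <- function(grid, rule = c("queen", "rook")) {
  stopifnot(inherits(grid, "svc_grid"))
  rule <- match.arg(rule)
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  id <- function(r, c) (r - 1L) * nx + c
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (rule == "queen") offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  es <- list()
  for (o in offs) {
    r <- rep(seq_len(ny), each = nx); c <- rep(seq_len(nx), times = ny)
    r2 <- r + o[1]; c2 <- c + o[2]
    ok <- r2 >= 1L & r2 <= ny & c2 >= 1L & c2 <= nx
    es[[length(es) + 1L]] <- cbind(id(r, c)[ok], id(r2, c2)[ok])
  }
  edges <- do.call(rbind, es)
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  g <- structure(list(n = nx * ny, edges = edges,
                      component = graph_components(nx * ny, edges)),
                 class = "svc_graph")
  g
}

#' Construct a graph directly from an edge list
#'
#' Used for graphs over subsets of cells (e.g. occupied cells only) or for
#' arbitrary areal structures read from an edge-list file.
#'
#' @param n number of vertices.
#' @param edges 2-column matrix of vertex pairs (1-based); self-edges are
#'   dropped, duplicates collapsed.
#' @return an `svc_graph`.
#' @export
graph_from_edges <- function(n, edges) {
  if (n < 1) stop("graph must have at least one vertex", call. = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    edges <- unique(edges)
    if (nrow(edges) && (min(edges) < 1 || max(edges) > n)) {
      stop("edge endpoints outside 1..n", call. = FALSE)
    }
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  storage.mode(edges) <- "integer"
  structure(list(n = as.integer(n), edges = edges,
                 component = graph_components(n, edges)),
            class = "svc_graph")
}

#' Induced subgraph on a subset of vertices
#'
#' @param graph an `svc_graph`.
#' @param keep integer vertex ids to retain; the result relabels them 1..k in
#'   the order given and records the original ids in `$vertex_ids`.
#' @export
subgraph <- function(graph, keep) {
  stopifnot(inherits(graph, "svc_graph"))
  keep <- as.integer(keep)
  if (anyDuplicated(keep)) stop("`keep` has duplicates", call. = FALSE)
  map <- integer(graph$n); map[keep] <- seq_along(keep)
  e <- graph$edges
  ok <- map[e[, 1]] > 0L & map[e[, 2]] > 0L
  g <- graph_from_edges(length(keep), cbind(map[e[ok, 1]], map[e[ok, 2]]))
  g$vertex_ids <- keep
  g
}

# connected components by BFS over the edge list
graph_components <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}
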