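# Hand-built fixtures shared by unit and acceptance tests. All data are
# constructed in code; expected outcomes are enumerated by hand alongside.

# 12 count circles on a 2 x 2 grid exercising every curation branch:
#   season window boundaries (May 31 / Jun 1 / Aug 31 / Sep 1),
#   detection-year rule (>= 5 years with count > 0),
#   span rule (last - first + 1 >= 10),
#   zero-count visits counting toward span but not detections,
#   edge-of-cell assignment under the half-open convention.
curation_fixture <- function() {
  rows <- list()
  add <- function(id, x, y, year, md, count) {
    rows[[length(rows) + 1L]] <<- data.frame(
      circle_id = id, lon = x, lat = y,
      date = as.Date(sprintf("%d-%s", year, md)),
      year = year, party_hours = 2, count = count)
  }

  # site 1: span 12 (2000-2011), 6 detection years -> retained, cell 1
  for (yr in 2000:2011) add(1, 10, 10, yr, "07-04", if (yr <= 2005) 3 else 0)
  # site 2: span 9 (2000-2008), 5 detection years -> removed (short span)
  for (yr in 2000:2008) add(2, 60, 10, yr, "07-04", if (yr <= 2004) 2 else 0)
  # site 3: span 15 (2000-2014), 4 detection years -> removed (few detections)
  for (yr in 2000:2014) add(3, 10, 60, yr, "07-04", if (yr <= 2003) 1 else 0)
  # site 4: span exactly 10, exactly 5 detection years -> retained (boundary)
  for (yr in 2000:2009) add(4, 60, 60, yr, "07-04", if (yr %% 2 == 0) 4 else 0)
  # site 5: span 9, 4 detection years -> removed (fails both)
  for (yr in 2000:2008) add(5, 20, 20, yr, "07-15", if (yr <= 2003) 1 else 0)
  # site 6: every event outside the window -> removed by the season filter
  for (yr in 2000:2011) {
    add(6, 70, 20, yr, "05-31", 9)
    add(6, 70, 20, yr, "09-01", 9)
  }
  # site 7: only boundary dates Jun 1 / Aug 31 (inclusive), span 10,
  # 5 detection years -> retained
  for (yr in 2000:2009) {
    add(7, 20, 70, yr, "06-01", if (yr <= 2004) 2 else 0)
    add(7, 20, 70, yr, "08-31", 0)
  }
  # site 8: span 12 with zero-count visits after 2004; detections 2000-2004
  # (5 years) -> retained; zeros extend span only
  for (yr in 2000:2011) add(8, 70, 70, yr, "07-20", if (yr <= 2004) 5 else 0)
  # site 9: 5 detection years but span 9 (2005-2013) -> removed
  for (yr in 2005:2013) add(9, 30, 30, yr, "07-04", if (yr <= 2009) 2 else 0)
  # site 10: sampled only 5 years but spread over 13 calendar years ->
  # retained (span is calendar, not sampled-year count)
  for (yr in c(2000, 2003, 2006, 2009, 2012)) add(10, 80, 30, yr, "07-04", 1)
  # site 11: detections mostly on May 31 (dropped); in-window detections in
  # only 4 years -> removed after season filtering
  for (yr in 2000:2011) {
    add(11, 30, 80, yr, "05-31", 10)
    add(11, 30, 80, yr, "07-04", if (yr <= 2003) 1 else 0)
  }
  # site 12: centre exactly on the shared edge x = 50 -> cell 2 by the
  # half-open [xmin, xmax) convention; span 11, 6 detections -> retained
  for (yr in 2000:2010) add(12, 50, 10, yr, "07-04", if (yr <= 2005) 2 else 0)

  events <- do.call(rbind, rows)
  grid <- make_grid(2, 2, 50)
  list(events = events, grid = grid,
       expected_retained = c(1L, 4L, 7L, 8L, 10L, 12L),
       expected_removed = c(2L, 3L, 5L, 6L, 9L, 11L),
       expected_cells = c(`1` = 1L, `4` = 4L, `7` = 3L, `8` = 4L,
                          `10` = 2L, `12` = 2L))
}

# random connected graph on n vertices: random spanning tree plus extra edges
random_connected_graph <- function(n, extra = 2L) {
  stopifnot(n >= 2)
  edges <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1L, 1L),
                             integer(1)))
  for (k in seq_len(extra)) {
    e <- sort(sample.int(n, 2L))
    edges <- rbind(edges, e)
  }
  graph_from_edges(n, edges)
}

# independent oracle for constrained iCAR marginal variances: the pseudo-
# inverse of Q on a connected component via (Q + 11'/n)^(-1) - 11'/n
oracle_marginal_variances <- function(Qd) {
  n <- nrow(Qd)
  J <- matrix(1 / n, n, n)
  diag(solve(Qd + J) - J)
}

# hand-assembled posterior object with known draws, for summary-operation
# tests that need exact expected values
fake_posterior <- function(tau, alpha = NULL, gamma = NULL,
                           years = NULL, cells = NULL) {
  S <- nrow(tau); nc <- ncol(tau)
  if (is.null(cells)) cells <- seq_len(nc)
  if (is.null(years)) years <- 2016:2018
  ny <- length(years)
  if (is.null(alpha)) alpha <- matrix(0, S, nc)
  if (is.null(gamma)) gamma <- array(0, dim = c(S, nc, ny))
  gr <- if (nc >= 2) graph_from_edges(nc, cbind(seq_len(nc - 1), 2:nc)) else
    graph_from_edges(1, NULL)
  st <- scale_icar(icar_structure(gr))
  structure(list(
    alpha = alpha, epsilon = matrix(1, S, nc), tau = tau, gamma = gamma,
    kappa = matrix(0, S, 1), phi = rep(2, S),
    sigma = list(), mu = list(),
    cells = cells, years = years, T = years - max(years),
    circles = 1L, component = gr$component,
    diagnostics = list(), chains = 1L, iter = S,
    spec = list(structure = st, graph = gr)
  ), class = "trend_posterior")
}

# tiny deterministic event table: 2 cells x 3 years x 1 circle each
tiny_events <- function() {
  data.frame(
    circle_id = rep(1:2, each = 3),
    cell_id = rep(1:2, each = 3),
    year = rep(2016:2018, 2),
    party_hours = rep(1, 6),
    count = c(4, 6, 5, 9, 7, 11)
  )
}
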