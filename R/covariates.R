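#' Convert pounds of active ingredient to kilograms
#'
#' Source pesticide tables report pounds of active ingredient; the covariate
#' is carried in kg. Apply exactly once, at ingest.
#'
#' @param lb pounds.
#' @return kilograms (`lb * 0.45359237`).
#' @export
pounds_to_kg <- function(lb) lb * 0.45359237

#' Apportion county glyphosate use to grid cells
#'
#' For each cell-year, sums over counties the product of glyphosate applied
#' (kg active ingredient), the proportion of the county planted in corn or
#' soybean, and the proportion of the county's area overlapping the cell:
#' \deqn{P_{i,t} = \sum_c G_{c,t} \, q_{c,t} \, w_{c,i}.}
#' Because weights are county-area proportions, cell values conserve each
#' county's crop-offset total wherever the grid covers the county fully.
#'
#' @param counties data frame: `county_id`, `year`, `glyphosate_kg` (or
#'   `glyphosate_lb`, converted at ingest), `crop_proportion` in `[0, 1]`.
#' @param weights data frame: `county_id`, `cell_id`, `weight` = proportion of
#'   county area inside the cell; per-county weights must sum to at most 1.
#' @return data frame `cell_id`, `year`, `P` (kg AI), one row per cell-year
#'   with any contribution.
#' @export
glyphosate_to_cells <- function(counties, weights) {
  if ("glyphosate_lb" %in% names(counties) && !"glyphosate_kg" %in% names(counties)) {
    counties$glyphosate_kg <- pounds_to_kg(counties$glyphosate_lb)
    message("converted glyphosate_lb to kg at ingest (x 0.45359237)")
  }
  stopifnot(all(c("county_id", "year", "glyphosate_kg", "crop_proportion") %in%
                  names(counties)),
            all(c("county_id", "cell_id", "weight") %in% names(weights)))
  if (any(counties$glyphosate_kg < 0)) stop("negative glyphosate", call. = FALSE)
  if (any(counties$crop_proportion < 0 | counties$crop_proportion > 1)) {
    stop("crop_proportion outside [0, 1]", call. = FALSE)
  }
  if (any(weights$weight < 0 | weights$weight > 1)) {
    stop("overlap weight outside [0, 1]", call. = FALSE)
  }
  wsum <- tapply(weights$weight, weights$county_id, sum)
  if (any(wsum > 1 + 1e-9)) {
    stop("per-county overlap weights exceed 1", call. = FALSE)
  }
  m <- merge(counties, weights, by = "county_id")
  m$contrib <- m$glyphosate_kg * m$crop_proportion * m$weight
  agg <- stats::aggregate(contrib ~ cell_id + year, data = m, FUN = sum)
  names(agg)[names(agg) == "contrib"] <- "P"
  agg[order(agg$year, agg$cell_id), c("cell_id", "year", "P")]
}

#' Annual mean temperature from monthly means
#'
#' @param monthly numeric vector of exactly 12 monthly mean temperatures
#'   (degrees C), or a matrix/data frame with 12 columns (one row per
#'   cell-year).
#' @return the arithmetic annual mean(s); missing months are an error, no
#'   imputation is attempted.
#' @export
annual_temperature <- function(monthly) {
  m <- as.matrix(monthly)
  if (is.vector(monthly)) m <- matrix(monthly, nrow = 1)
  if (ncol(m) != 12L) stop("need exactly 12 monthly values", call. = FALSE)
  if (anyNA(m)) stop("missing monthly temperature; no imputation", call. = FALSE)
  out <- rowMeans(m)
  if (is.vector(monthly)) out[[1]] else out
}

#' Annual cumulative precipitation from monthly totals
#'
#' @param monthly numeric vector of exactly 12 nonnegative monthly totals
#'   (mm), or a 12-column matrix/data frame.
#' @return the annual sum(s) in mm.
#' @export
annual_precipitation <- function(monthly) {
  m <- as.matrix(monthly)
  if (is.vector(monthly)) m <- matrix(monthly, nrow = 1)
  if (ncol(m) != 12L) stop("need exactly 12 monthly values", call. = FALSE)
  if (anyNA(m)) stop("missing monthly precipitation", call. = FALSE)
  if (any(m < 0)) stop("negative monthly precipitation", call. = FALSE)
  out <- rowSums(m)
  if (is.vector(monthly)) out[[1]] else out
}

#' Regrid a coarse climate field onto the analysis grid
#'
#' Each analysis cell takes the area-weighted average of the climate pixels it
#' overlaps, with weights proportional to the overlap area (exact for
#' axis-aligned rectangles in a common planar system). Coarse pixels
#' (emulating half-degree climate products) are usually larger than 50-km
#' cells, so most cells inherit a single pixel's value and boundary cells a
#' blend.
#'
#' @param climate data frame of pixel rectangles and values: `xmin`, `xmax`,
#'   `ymin`, `ymax`, `value` (one climate variable; call per month/variable).
#' @param grid an [make_grid()] object.
#' @return numeric vector, one value per grid cell (in `cell_id` order).
#' @export
regrid_climate <- function(climate, grid) {
  stopifnot(inherits(grid, "svc_grid"),
            all(c("xmin", "xmax", "ymin", "ymax", "value") %in% names(climate)))
  n <- nrow(grid)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ox <- pmin(grid$xmax[i], climate$xmax) - pmax(grid$xmin[i], climate$xmin)
    oy <- pmin(grid$ymax[i], climate$ymax) - pmax(grid$ymin[i], climate$ymin)
    w <- pmax(ox, 0) * pmax(oy, 0)
    if (sum(w) <= 0) {
      stop("no climate coverage for cell ", grid$cell_id[i], call. = FALSE)
    }
    out[i] <- sum(w * climate$value) / sum(w)
  }
  out
}
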