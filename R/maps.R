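#' Rasterize object positions onto an occupancy grid
#'
#' Each object increments exactly one cell: `(row, col) = (floor(y),
#' floor(x))`, 0-based. By default one grid cell equals one display
#' pixel, so `grid_size = c(rows, cols) = c(height, width)`.
#'
#' @param positions n x 2 matrix of (x, y) pixel positions.
#' @param grid_size `c(rows, cols)` of the grid.
#' @return an `object_map`: a list with integer matrix `grid` (cell
#'   counts) and `grid_size`. The grid total always equals the number of
#'   objects.
#' @export
rasterize <- function(positions, grid_size) {
  positions <- as.matrix(positions)
  grid_size <- as.integer(grid_size)
  cells <- pos_to_cells(positions)
  if (any(cells[, 1] < 0 | cells[, 1] >= grid_size[1] |
          cells[, 2] < 0 | cells[, 2] >= grid_size[2]))
    stop("invalid input: position outside arena")
  grid <- matrix(0L, grid_size[1], grid_size[2])
  idx <- cells[, 1] + 1L + cells[, 2] * grid_size[1]
  tab <- table(idx)
  grid[as.integer(names(tab))] <- as.integer(tab)
  structure(list(grid = grid, grid_size = grid_size), class = "object_map")
}

# (x, y) positions -> 0-based (row, col) cells under the floor convention
pos_to_cells <- function(positions) {
  cbind(as.integer(floor(positions[, 2])), as.integer(floor(positions[, 1])))
}

#' @export
print.object_map <- function(x, ...) {
  cat(sprintf("object map: %d x %d cells, %d objects\n",
              x$grid_size[1], x$grid_size[2], sum(x$grid)))
  invisible(x)
}

#' Nearest occupied cell within a search bound
#'
#' Expanding-ring search outward from `origin` for the occupied cell of
#' minimum Euclidean distance, aborting at radius `nob`. Rings are
#' Chebyshev shells scanned row-major; exact distance ties resolve to the
#' earliest cell in scan order.
#'
#' @param o an `object_map` from [rasterize()].
#' @param origin 0-based `c(row, col)` cell.
#' @param nob maximum Euclidean search radius in cells (`Inf` = whole
#'   grid).
#' @return `list(cell =, dist =)` with the 0-based cell and its distance,
#'   or `NULL` when no object lies within `nob`.
#' @export
nearest_object <- function(o, origin, nob = Inf) {
  res <- cpp_nearest_cells(o$grid, as.integer(origin[1]),
                           as.integer(origin[2]), 1L, nob)
  if (nrow(res$cells) == 0) return(NULL)
  list(cell = res$cells[1, ], dist = res$dists[1])
}

#' k-th nearest occupied cell
#'
#' Like [nearest_object()] with an unbounded radius, but returns the
#' k-th occupied cell by distance, counting multiplicity (a cell holding
#' two objects occupies two consecutive ranks).
#'
#' @inheritParams nearest_object
#' @param k rank (`k = 1` is the nearest object).
#' @return `list(cell =, dist =)`, or `NULL` if the map holds fewer than
#'   `k` objects.
#' @export
kth_nearest_object <- function(o, origin, k) {
  res <- cpp_nearest_cells(o$grid, as.integer(origin[1]),
                           as.integer(origin[2]), as.integer(k), Inf)
  if (nrow(res$cells) < k) return(NULL)
  list(cell = res$cells[k, ], dist = res$dists[k])
}

#' Confusion ratio of an attended location
#'
#' Quantifies how much an attended location risks being re-acquired onto
#' the wrong object: the ratio of the distances to the first- and
#' second-nearest objects, raised to the confusion exponent `c_e`. The
#' ratio lies in `[0, 1]` and approaches 1 as the two distances
#' equalise. A location sitting exactly on an object (first distance 0)
#' is unambiguous and scores 0 by convention.
#'
#' @inheritParams nearest_object
#' @param a_i 0-based `c(row, col)` attended cell.
#' @param c_e confusion exponent (`>= 0`; `Inf` allowed, giving 0 unless
#'   the two distances are exactly equal).
#' @return a scalar in `[0, 1]`.
#' @export
confusion_ratio <- function(o, a_i, c_e = 1) {
  grid <- if (inherits(o, "object_map")) o$grid else o
  res <- cpp_nearest_cells(grid, as.integer(a_i[1]), as.integer(a_i[2]),
                           2L, Inf)
  if (nrow(res$cells) < 2)
    stop("confusion ratio undefined: fewer than 2 objects on the map")
  d1 <- res$dists[1]; d2 <- res$dists[2]
  if (d1 == 0) return(0)
  (d1 / d2)^c_e
}

#' Selection probabilities from confusion ratios
#'
#' Normalises a vector of non-negative confusion ratios into a
#' probability distribution over attended locations,
#' `p_i = c_i / sum_j c_j`. An all-zero input (every location
#' unambiguous) falls back to the uniform distribution.
#'
#' @param ratios non-negative numeric vector.
#' @return probability vector summing to 1.
#' @export
unitary_selection_probs <- function(ratios) {
  if (any(ratios < 0)) stop("ratios must be non-negative")
  s <- sum(ratios)
  if (s == 0) return(rep(1 / length(ratios), length(ratios)))
  ratios / s
}
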