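#' Discretized rectangular workspace
#'
#' The manipulation plane observed through the microscope is discretized into
#' a mesh of square cells; each cell is one state of the planner's decision
#' process. The default mesh is 32 x 32. Coordinates are continuous, in
#' micrometres, with the origin at the top-left corner of the field of view
#' and y increasing downward (image convention). Cells are half-open
#' `[k * cell_size, (k + 1) * cell_size)` along each axis and indexed
#' row-major (y-major), starting at state 1 for the top-left cell.
#'
#' @param nx,ny number of cells along x and y (each >= 2; default 32).
#' @param cell_size physical cell edge length in micrometres (> 0). The
#'   default of 15 um makes one cell at least as large as the largest
#'   particle diameter handled here and gives a 480 um field of view.
#' @param origin numeric length-2, top-left corner of the field in um.
#' @return An object of class `oet_workspace`.
#' @examples
#' ws <- workspace()
#' grid_state_of(c(0, 0), ws)      # 1: top-left cell
#' state_center(1, ws)             # (7.5, 7.5)
#' @export
workspace <- function(nx = 32L, ny = 32L, cell_size = 15, origin = c(0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 2L, ny >= 2L, cell_size > 0, length(origin) == 2L)
  structure(
    list(nx = nx, ny = ny, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "oet_workspace")
}

#' @export
print.oet_workspace <- function(x, ...) {
  cat(sprintf("<oet_workspace> %d x %d cells, %.3g um/cell (%g x %g um)\n",
              x$nx, x$ny, x$cell_size,
              x$nx * x$cell_size, x$ny * x$cell_size))
  invisible(x)
}

#' Total number of grid states
#' @param ws an `oet_workspace`.
#' @return Integer `nx * ny`.
#' @export
n_states <- function(ws) ws$nx * ws$ny

workspace_extent <- function(ws) {
  c(ws$nx, ws$ny) * ws$cell_size
}

#' Map a continuous position to its grid state
#'
#' @param position numeric length-2 (x, y) in um, or an n x 2 matrix.
#' @param ws an `oet_workspace`.
#' @return Integer state index (1-based, row-major from the origin corner).
#'   Positions on an interior cell boundary belong to the higher cell
#'   (half-open convention).
#' @export
grid_state_of <- function(position, ws) {
  p <- rbind(position)
  rel <- sweep(p, 2, ws$origin)
  ext <- workspace_extent(ws)
  if (any(rel[, 1] < 0 | rel[, 2] < 0 | rel[, 1] >= ext[1] | rel[, 2] >= ext[2])) {
    stop("position outside workspace bounds")
  }
  col <- pmin(floor(rel[, 1] / ws$cell_size), ws$nx - 1L)
  row <- pmin(floor(rel[, 2] / ws$cell_size), ws$ny - 1L)
  as.integer(row * ws$nx + col + 1L)
}

#' Centre of a grid cell
#'
#' Inverse-consistent with [grid_state_of()]:
#' `grid_state_of(state_center(s, ws), ws) == s` for every valid state.
#'
#' @param state integer state index (vectorised).
#' @param ws an `oet_workspace`.
#' @return An n x 2 matrix of cell-centre coordinates in um.
#' @export
state_center <- function(state, ws) {
  state <- as.integer(state)
  if (any(state < 1L | state > n_states(ws))) stop("invalid state index")
  col <- (state - 1L) %% ws$nx
  row <- (state - 1L) %/% ws$nx
  cbind(x = ws$origin[1] + (col + 0.5) * ws$cell_size,
        y = ws$origin[2] + (row + 0.5) * ws$cell_size)
}

#' Column/row coordinates of grid states
#'
#' @param state integer state index (vectorised).
#' @param ws an `oet_workspace`.
#' @return An n x 2 integer matrix of 0-based (col, row) cell coordinates.
#' @export
state_colrow <- function(state, ws) {
  state <- as.integer(state)
  if (any(state < 1L | state > n_states(ws))) stop("invalid state index")
  cbind(col = (state - 1L) %% ws$nx, row = (state - 1L) %/% ws$nx)
}

#' Manhattan distance between two grid cells
#'
#' The base transport cost between a particle start and a candidate goal:
#' `|dcol| + |drow|` in cell units.
#'
#' @param a,b positions in um (length-2) mapped through the workspace grid,
#'   or integer grid states when `as_state = TRUE`.
#' @param ws an `oet_workspace`.
#' @param as_state interpret `a`, `b` as state indices instead of positions.
#' @return Non-negative integer distance in cell units.
#' @export
manhattan_distance <- function(a, b, ws, as_state = FALSE) {
  sa <- if (as_state) as.integer(a) else grid_state_of(a, ws)
  sb <- if (as_state) as.integer(b) else grid_state_of(b, ws)
  ca <- state_colrow(sa, ws); cb <- state_colrow(sb, ws)
  as.integer(abs(ca[, 1] - cb[, 1]) + abs(ca[, 2] - cb[, 2]))
}

chebyshev_cells <- function(sa, sb, ws) {
  ca <- state_colrow(sa, ws); cb <- state_colrow(sb, ws)
  as.integer(pmax(abs(ca[, 1] - cb[, 1]), abs(ca[, 2] - cb[, 2])))
}
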