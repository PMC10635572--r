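#' Uniform Cartesian grid
#'
#' Cell-centred Cartesian grid: cell `(i,j,k)` has its centre at
#' `origin + (i - 1/2) * spacing` per axis.
#'
#' @param n integer triple: number of cells per axis (each >= 8).
#' @param spacing numeric triple (or scalar): cell size per axis (m).
#' @param origin numeric triple: position of the lower domain corner (m).
#' @return Object of class `cartesian_grid` with fields `n`, `h`, `origin`.
#' @export
cartesian_grid <- function(n, spacing, origin = c(0, 0, 0)) {
  n <- as.integer(rep_len(n, 3))
  h <- rep_len(as.numeric(spacing), 3)
  origin <- rep_len(as.numeric(origin), 3)
  if (any(n < 8)) stop("grid needs at least 8 cells per axis", call. = FALSE)
  if (any(h <= 0)) stop("grid spacing must be positive", call. = FALSE)
  structure(list(n = n, h = h, origin = origin), class = "cartesian_grid")
}

# cell-centre coordinate vectors
grid_axes <- function(grid) {
  lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$n[a]) - 0.5) * grid$h[a])
}

# full 3-D arrays of cell-centre coordinates
grid_coords <- function(grid) {
  ax <- grid_axes(grid)
  n <- grid$n
  list(x = array(rep(ax[[1]], times = n[2] * n[3]), n),
       y = array(rep(rep(ax[[2]], each = n[1]), times = n[3]), n),
       z = array(rep(ax[[3]], each = n[1] * n[2]), n))
}

#' @export
print.cartesian_grid <- function(x, ...) {
  cat(sprintf("cartesian_grid: %d x %d x %d cells, spacing (%g, %g, %g) m\n",
              x$n[1], x$n[2], x$n[3], x$h[1], x$h[2], x$h[3]))
  invisible(x)
}
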