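#' Define a regular imaging grid
#'
#' A grid of voxel (pixel) centers on which phantoms, reconstructions and
#' priors live. Coordinates are SI meters. The center of voxel with 0-based
#' index `(i1, ..., id)` sits at `origin + index * spacing`; in R the array
#' holding values on the grid is indexed 1-based and column-major, with axis
#' 1 as x.
#'
#' @param shape integer vector, voxels per axis (length 2 or 3), all >= 1.
#' @param spacing numeric, voxel spacing per axis in meters (recycled to the
#'   length of `shape`), all > 0.
#' @param origin numeric, coordinates in meters of the center of the first
#'   voxel. Default centers the grid on the coordinate origin.
#' @return A `pa_grid` object (list with `shape`, `spacing`, `origin`).
#' @examples
#' g <- pa_grid(c(128, 128), 2e-4)
#' range(grid_axes(g)[[1]])
#' @export
pa_grid <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L) || any(shape < 1L))
    stop("invalid grid: 'shape' must be 2 or 3 positive integers")
  spacing <- rep_len(as.numeric(spacing), length(shape))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid grid: all spacings must be finite and > 0")
  if (is.null(origin)) {
    origin <- -(shape - 1) / 2 * spacing
  }
  origin <- rep_len(as.numeric(origin), length(shape))
  if (any(!is.finite(origin))) stop("invalid grid: non-finite origin")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "pa_grid")
}

#' @export
print.pa_grid <- function(x, ...) {
  cat(sprintf("<pa_grid> %s voxels, spacing %s mm\n",
              paste(x$shape, collapse = " x "),
              paste(signif(x$spacing * 1e3, 4), collapse = " x ")))
  invisible(x)
}

#' Voxel-center coordinates along each grid axis
#'
#' @param grid a [pa_grid()].
#' @return A list of numeric vectors, one per axis, in meters.
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "pa_grid"))
  Map(function(n, d, o) o + (seq_len(n) - 1) * d,
      grid$shape, grid$spacing, grid$origin)
}

#' Euclidean distance from every voxel center to a point
#'
#' @param grid a [pa_grid()].
#' @param point numeric coordinates (meters), same dimensionality as the grid.
#' @return Array of distances with `dim = grid$shape`.
#' @export
voxel_distances <- function(grid, point) {
  ax <- grid_axes(grid)
  if (length(point) != length(ax))
    stop("point dimensionality does not match grid")
  sq <- Map(function(a, p) (a - p)^2, ax, as.numeric(point))
  d2 <- Reduce(function(acc, v) outer(acc, v, `+`), sq)
  array(sqrt(d2), dim = grid$shape)
}

new_pa_array <- function(positions, label) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (!ncol(positions) %in% c(2L, 3L))
    stop("invalid geometry: positions must be 2D or 3D")
  if (any(!is.finite(positions)))
    stop("invalid geometry: non-finite element position")
  if (anyDuplicated(positions))
    stop("invalid geometry: duplicate element positions")
  structure(list(positions = positions,
                 n_elements = nrow(positions),
                 label = label),
            class = "pa_array")
}

#' @export
print.pa_array <- function(x, ...) {
  cat(sprintf("<pa_array> %d elements (%dD): %s\n",
              x$n_elements, ncol(x$positions), x$label))
  invisible(x)
}

#' Circular ring detector array
#'
#' Elements are equally spaced in angle on a circle; element i (0-based)
#' sits at angle `2*pi*i/n_elements` counterclockwise from the +x axis.
#'
#' @param n_elements integer >= 3.
#' @param radius ring radius in meters, > 0.
#' @param center 2D center coordinates in meters.
#' @return A `pa_array` with an N x 2 position matrix and a `radius`
#'   attribute on the object.
#' @examples
#' ring <- make_ring_array(256, 0.05)
#' @export
make_ring_array <- function(n_elements, radius, center = c(0, 0)) {
  n_elements <- as.integer(n_elements)
  if (is.na(n_elements) || n_elements < 3L)
    stop("invalid geometry: ring needs n_elements >= 3")
  if (!is.finite(radius) || radius <= 0)
    stop("invalid geometry: ring radius must be > 0")
  ang <- 2 * pi * (seq_len(n_elements) - 1) / n_elements
  pos <- cbind(center[1] + radius * cos(ang),
               center[2] + radius * sin(ang))
  out <- new_pa_array(pos, sprintf("ring r=%g m, N=%d", radius, n_elements))
  out$radius <- radius
  out
}

#' Hemispherical detector array with an illumination aperture
#'
#' Places `n_elements` points quasi-uniformly (Fibonacci / golden-angle
#' scheme) on the sphere of the given radius, restricted to the lower
#' hemisphere `z <= 0`, excluding a spherical cap of height
#' `pole_hole_height` around the pole `(0, 0, -radius)` — the element-free
#' aperture through which the illumination enters. The layout is
#' deterministic: the i-th element (1-based) has
#' `z = -radius + pole_hole_height + (i - 0.5)/n * (radius - pole_hole_height)`
#' (uniform in z, hence uniform in area) and azimuth `i` times the golden
#' angle.
#'
#' @param n_elements integer >= 1.
#' @param radius sphere radius in meters, > 0.
#' @param pole_hole_height cap height in meters, `0 <= h < radius`.
#' @return A `pa_array` with an N x 3 position matrix.
#' @examples
#' hemi <- make_hemisphere_array(1024, 0.04, 0.01)
#' @export
make_hemisphere_array <- function(n_elements, radius, pole_hole_height = 0) {
  n_elements <- as.integer(n_elements)
  if (is.na(n_elements) || n_elements < 1L)
    stop("invalid geometry: n_elements must be >= 1")
  if (!is.finite(radius) || radius <= 0)
    stop("invalid geometry: radius must be > 0")
  if (pole_hole_height < 0 || pole_hole_height >= radius)
    stop("invalid geometry: pole_hole_height must be in [0, radius)")
  i <- seq_len(n_elements)
  z <- -radius + pole_hole_height +
    (i - 0.5) / n_elements * (radius - pole_hole_height)
  rho <- sqrt(pmax(radius^2 - z^2, 0))
  golden_angle <- pi * (3 - sqrt(5))
  phi <- i * golden_angle
  pos <- cbind(rho * cos(phi), rho * sin(phi), z)
  out <- new_pa_array(pos, sprintf("hemisphere r=%g m, hole h=%g m, N=%d",
                                   radius, pole_hole_height, n_elements))
  out$radius <- radius
  out
}
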