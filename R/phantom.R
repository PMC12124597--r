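new_pa_phantom <- function(grid, values, description) {
  values <- array(as.numeric(values), dim = grid$shape)
  if (any(!is.finite(values)) || any(values < 0))
    stop("invalid phantom: values must be finite and >= 0")
  if (!any(values > 0))
    stop("invalid phantom: at least one voxel must be > 0")
  structure(list(grid = grid, values = values, description = description),
            class = "pa_phantom")
}

#' @export
print.pa_phantom <- function(x, ...) {
  cat(sprintf("<pa_phantom> %s on %s grid, max %.3g\n", x$description,
              paste(x$grid$shape, collapse = "x"), max(x$values)))
  invisible(x)
}

#' Disk / sphere phantom
#'
#' Initial-pressure phantom made of filled disks (2D) or balls (3D).
#' A voxel takes the sum of the amplitudes of all disks whose center lies
#' within the disk radius of the voxel center; overlaps add.
#'
#' @param grid a [pa_grid()].
#' @param disks list of disks, each a list with `center` (meters), `radius`
#'   (meters, > 0) and `amplitude` (> 0).
#' @return A `pa_phantom`.
#' @examples
#' g <- pa_grid(c(64, 64), 2e-4)
#' ph <- make_disk_phantom(g, list(list(center = c(0, 0), radius = 2e-3,
#'                                      amplitude = 1)))
#' @export
make_disk_phantom <- function(grid, disks) {
  stopifnot(inherits(grid, "pa_grid"))
  if (length(disks) == 0) stop("invalid phantom: empty disk list")
  vals <- array(0, dim = grid$shape)
  for (d in disks) {
    if (is.null(d$center) || is.null(d$radius) || is.null(d$amplitude))
      stop("invalid phantom: each disk needs center, radius, amplitude")
    if (d$radius <= 0 || d$amplitude <= 0)
      stop("invalid phantom: radius and amplitude must be > 0")
    vals <- vals + d$amplitude * (voxel_distances(grid, d$center) <= d$radius)
  }
  new_pa_phantom(grid, vals, sprintf("%d disk(s)", length(disks)))
}

#' Synthetic vessel-like phantom
#'
#' Random-walk tubular branches with smooth Gaussian cross-sections,
#' emulating the vascular structures photoacoustic imaging targets. Each
#' branch starts in the central region of the grid, walks with small random
#' direction changes, and stamps a Gaussian tube profile (truncated at 3
#' standard deviations) along its path; branches are combined by maximum so
#' values stay in [0, 1]. Deterministic given `seed`.
#'
#' @param grid a [pa_grid()].
#' @param seed integer RNG seed.
#' @param n_branches integer >= 1, number of vessel branches.
#' @param sigma_vox tube cross-section standard deviation in voxels.
#' @param step_vox walk step length in voxels.
#' @param turn_sd standard deviation of the per-step direction change
#'   (radians in 2D; component perturbation in 3D).
#' @return A `pa_phantom` with values in [0, 1].
#' @examples
#' ph <- make_vessel_phantom(pa_grid(c(96, 96), 2e-4), seed = 1)
#' mean(ph$values > 0)
#' @export
make_vessel_phantom <- function(grid, seed, n_branches = 5L,
                                sigma_vox = 1.5, step_vox = 0.6,
                                turn_sd = 0.25) {
  stopifnot(inherits(grid, "pa_grid"))
  n_branches <- as.integer(n_branches)
  if (is.na(n_branches) || n_branches < 1L)
    stop("invalid phantom: n_branches must be >= 1")
  nd <- length(grid$shape)
  vals <- withr::with_seed(seed, {
    v <- array(0, dim = grid$shape)
    half <- ceiling(3 * sigma_vox)
    max_steps <- ceiling(1.5 * max(grid$shape) / step_vox)
    for (b in seq_len(n_branches)) {
      amp <- stats::runif(1, 0.6, 1)
      # start inside the central 60% of the grid, in voxel units
      p <- vapply(grid$shape,
                  function(n) stats::runif(1, 0.2 * n, 0.8 * n), 0)
      if (nd == 2L) {
        ang <- stats::runif(1, 0, 2 * pi)
        dirv <- c(cos(ang), sin(ang))
      } else {
        dirv <- stats::rnorm(3)
        dirv <- dirv / sqrt(sum(dirv^2))
      }
      for (s in seq_len(max_steps)) {
        if (any(p < 1) || any(p > grid$shape)) break
        v <- stamp_tube(v, p, amp, sigma_vox, half)
        if (nd == 2L) {
          ang <- atan2(dirv[2], dirv[1]) + stats::rnorm(1, 0, turn_sd)
          dirv <- c(cos(ang), sin(ang))
        } else {
          dirv <- dirv + stats::rnorm(3, 0, turn_sd)
          dirv <- dirv / sqrt(sum(dirv^2))
        }
        p <- p + step_vox * dirv
      }
    }
    v
  })
  if (!any(vals > 0))
    stop("invalid phantom: vessel generation produced an empty field")
  new_pa_phantom(grid, vals,
                 sprintf("vessel phantom (%d branches, seed %d)",
                         n_branches, as.integer(seed)))
}

# Max-blend a truncated Gaussian blob centered at voxel-units position p.
stamp_tube <- function(v, p, amp, sigma, half) {
  shp <- dim(v)
  rng <- lapply(seq_along(shp), function(k) {
    lo <- max(1L, floor(p[k]) - half)
    hi <- min(shp[k], ceiling(p[k]) + half)
    lo:hi
  })
  sq <- Map(function(idx, pk) (idx - pk)^2, rng, as.list(p))
  d2 <- Reduce(function(acc, x) outer(acc, x, `+`), sq)
  blob <- amp * exp(-d2 / (2 * sigma^2))
  blob[d2 > (3 * sigma)^2] <- 0
  old <- do.call(`[`, c(list(v), rng))
  v <- do.call(`[<-`, c(list(v), rng, list(pmax(old, blob))))
  v
}
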