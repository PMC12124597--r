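new_pa_recon <- function(grid, values, provenance) {
  values <- array(as.numeric(values), dim = grid$shape)
  if (any(!is.finite(values)))
    stop("reconstruction: non-finite image value")
  structure(list(grid = grid, values = values, provenance = provenance),
            class = "pa_recon")
}

#' @export
print.pa_recon <- function(x, ...) {
  cat(sprintf("<pa_recon> %s grid, range [%.3g, %.3g] (%s)\n",
              paste(x$grid$shape, collapse = "x"),
              min(x$values), max(x$values), x$provenance))
  invisible(x)
}

check_elements <- function(elements, n) {
  if (is.null(elements)) return(seq_len(n))
  elements <- as.integer(elements)
  if (length(elements) == 0)
    stop("invalid subset: empty element list")
  if (any(is.na(elements)) || any(elements < 1L) || any(elements > n))
    stop(sprintf("element index out of range [1, %d]", n))
  elements
}

# Per-element delayed-and-interpolated images: nvox x length(elements)
# matrix; das is the row mean. Shared by DAS and the prior builder.
element_projections <- function(data, grid, elements) {
  cc <- data$params$sound_speed
  fs <- data$params$sampling_rate
  t0 <- data$params$t0
  M <- data$params$n_samples
  nvox <- prod(grid$shape)
  out <- matrix(0, nvox, length(elements))
  for (j in seq_along(elements)) {
    d <- elements[j]
    dist <- voxel_distances(grid, data$geometry$positions[d, ])
    tau <- (dist / cc - t0) * fs         # fractional 0-based sample
    i0 <- floor(tau)
    frac <- tau - i0
    ok <- i0 >= 0 & i0 <= M - 2          # out-of-window delays contribute 0
    tr <- data$traces[d, ]
    v <- numeric(nvox)
    iv <- i0[ok] + 1
    v[ok] <- (1 - frac[ok]) * tr[iv] + frac[ok] * tr[iv + 1]
    out[, j] <- v
  }
  out
}

#' Delay-and-sum (DAS) reconstruction
#'
#' Each voxel takes the average, over the selected detector elements, of
#' that element's trace sampled at the geometric time of flight (linear
#' interpolation between the two bracketing samples; delays outside the
#' recorded window contribute zero). The `1/|elements|` normalization puts
#' subset and full-array reconstructions on a common scale, so a
#' reconstruction from all N elements equals the mean of reconstructions
#' over any disjoint partition of the elements.
#'
#' @param data a `pa_channel_data`.
#' @param grid the target [pa_grid()] (same dimensionality as the array).
#' @param elements integer element indices (1-based), or `NULL` for all.
#' @return A `pa_recon`.
#' @export
das_reconstruct <- function(data, grid, elements = NULL) {
  stopifnot(inherits(data, "pa_channel_data"), inherits(grid, "pa_grid"))
  if (length(grid$shape) != ncol(data$geometry$positions))
    stop("grid and geometry dimensionality differ")
  elements <- check_elements(elements, data$geometry$n_elements)
  proj <- element_projections(data, grid, elements)
  vals <- rowMeans(proj)
  new_pa_recon(grid, vals,
               sprintf("das, %d/%d elements", length(elements),
                       data$geometry$n_elements))
}

#' Universal back-projection filter
#'
#' Applies the UBP filter term `b(t) = 2 p(t) - 2 t dp/dt` to every trace,
#' with `t` the absolute sample time (`t0 + m/fs`) and the derivative by
#' central differences (one-sided at the ends).
#'
#' @param data a `pa_channel_data` with at least 3 samples.
#' @return A `pa_channel_data` of filtered traces.
#' @export
ubp_filter <- function(data) {
  stopifnot(inherits(data, "pa_channel_data"))
  M <- data$params$n_samples
  if (M < 3) stop("ubp_filter needs at least 3 samples")
  fs <- data$params$sampling_rate
  tt <- data$params$t0 + (seq_len(M) - 1) / fs
  P <- data$traces
  dP <- matrix(0, nrow(P), M)
  dP[, 2:(M - 1)] <- (P[, 3:M] - P[, 1:(M - 2)]) * fs / 2
  dP[, 1] <- (P[, 2] - P[, 1]) * fs
  dP[, M] <- (P[, M] - P[, M - 1]) * fs
  B <- 2 * P - 2 * sweep(dP, 2, tt, `*`)
  new_channel_data(B, data$geometry, data$params)
}

#' Universal back-projection (UBP) reconstruction
#'
#' [ubp_filter()] followed by [das_reconstruct()] with uniform
#' back-projection weights (no solid-angle factor): element-exchangeable
#' weighting is what makes the subset-mean identity hold, which the
#' coherence prior relies on.
#'
#' @inheritParams das_reconstruct
#' @return A `pa_recon`.
#' @export
ubp_reconstruct <- function(data, grid, elements = NULL) {
  out <- das_reconstruct(ubp_filter(data), grid, elements)
  out$provenance <- sub("^das", "ubp", out$provenance)
  out
}
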