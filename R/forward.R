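#' Acquisition parameters
#'
#' @param sound_speed speed of sound in m/s, > 0.
#' @param sampling_rate temporal sampling rate in Hz, > 0.
#' @param n_samples number of time samples M, >= 2.
#' @param t0 time of the first sample in seconds.
#' @return A `pa_acquisition` object.
#' @export
pa_acquisition <- function(sound_speed = 1500, sampling_rate, n_samples,
                           t0 = 0) {
  n_samples <- as.integer(n_samples)
  if (!is.finite(sound_speed) || sound_speed <= 0)
    stop("invalid acquisition: sound_speed must be > 0")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("invalid acquisition: sampling_rate must be > 0")
  if (is.na(n_samples) || n_samples < 2L)
    stop("invalid acquisition: n_samples must be >= 2")
  structure(list(sound_speed = sound_speed, sampling_rate = sampling_rate,
                 n_samples = n_samples, t0 = as.numeric(t0)),
            class = "pa_acquisition")
}

new_channel_data <- function(traces, geometry, params) {
  traces <- as.matrix(traces)
  if (nrow(traces) != geometry$n_elements)
    stop("channel data: trace rows must equal geometry n_elements")
  if (ncol(traces) != params$n_samples)
    stop("channel data: trace columns must equal n_samples")
  if (any(!is.finite(traces)))
    stop("channel data: non-finite trace value")
  structure(list(traces = traces, geometry = geometry, params = params),
            class = "pa_channel_data")
}

#' @export
print.pa_channel_data <- function(x, ...) {
  cat(sprintf("<pa_channel_data> %d x %d (elements x samples), fs=%.3g MHz\n",
              nrow(x$traces), ncol(x$traces),
              x$params$sampling_rate / 1e6))
  invisible(x)
}

# Largest voxel-center-to-detector distance; attained at a grid corner.
max_voxel_detector_distance <- function(grid, geometry) {
  ax <- grid_axes(grid)
  ext <- lapply(ax, range)
  corners <- as.matrix(expand.grid(ext))
  max(vapply(seq_len(nrow(geometry$positions)), function(d) {
    diff2 <- sweep(corners, 2, geometry$positions[d, ], `-`)^2
    sqrt(max(rowSums(diff2)))
  }, 0))
}

#' Simulate photoacoustic channel data (circular / spherical mean model)
#'
#' Discretized forward model: for each detector, voxel amplitudes are
#' accumulated into half-open distance shells of width `c/fs` (nearest-bin
#' assignment) and normalized by the exact annulus area (2D) or shell
#' volume (3D); the recorded trace is the central-difference time
#' derivative of that shell signal (one-sided at the ends). This produces
#' the wideband bipolar shape of photoacoustic signals and is linear in the
#' phantom; it stands in for full-wave propagation at desk scale.
#'
#' @param phantom a `pa_phantom`.
#' @param geometry a `pa_array` of the same dimensionality.
#' @param params a [pa_acquisition()]. The time window must cover the
#'   largest voxel-to-detector distance.
#' @return A `pa_channel_data` (N x M trace matrix).
#' @export
simulate_channel_data <- function(phantom, geometry, params) {
  stopifnot(inherits(phantom, "pa_phantom"), inherits(geometry, "pa_array"),
            inherits(params, "pa_acquisition"))
  nd <- length(phantom$grid$shape)
  if (nd != ncol(geometry$positions))
    stop("phantom grid and geometry dimensionality differ")
  cc <- params$sound_speed
  fs <- params$sampling_rate
  M <- params$n_samples
  t0 <- params$t0
  dmax <- max_voxel_detector_distance(phantom$grid, geometry)
  m_req <- ceiling((dmax / cc - t0) * fs) + 1
  if (t0 + (M - 1) / fs < dmax / cc)
    stop(sprintf(
      "time window too short: need n_samples >= %d to cover the grid", m_req))

  delta <- cc / fs
  nz <- which(phantom$values != 0)
  ax <- grid_axes(phantom$grid)
  idx <- arrayInd(nz, phantom$grid$shape)
  coords <- vapply(seq_len(nd), function(k) ax[[k]][idx[, k]],
                   numeric(length(nz)))
  coords <- matrix(coords, ncol = nd)
  w <- phantom$values[nz] * prod(phantom$grid$spacing)

  # shell measure per time bin (bin center radius r_m = c * (t0 + m/fs))
  m_all <- seq_len(M) - 1
  r_bin <- cc * (t0 + m_all / fs)
  lo <- pmax(r_bin - delta / 2, 0)
  hi <- r_bin + delta / 2
  measure <- if (nd == 2L) pi * (hi^2 - lo^2) else 4 * pi / 3 * (hi^3 - lo^3)

  N <- geometry$n_elements
  traces <- matrix(0, N, M)
  for (d in seq_len(N)) {
    diff <- sweep(coords, 2, geometry$positions[d, ], `-`)
    dist <- sqrt(rowSums(diff^2))
    bin <- floor((dist / cc - t0) * fs + 0.5) + 1  # 1-based
    ok <- bin >= 1 & bin <= M
    g <- numeric(M)
    if (any(ok)) {
      s <- rowsum(w[ok], bin[ok])
      g[as.integer(rownames(s))] <- s
    }
    g <- g / measure
    # central-difference time derivative
    p <- numeric(M)
    p[2:(M - 1)] <- (g[3:M] - g[1:(M - 2)]) * fs / 2
    p[1] <- (g[2] - g[1]) * fs
    p[M] <- (g[M] - g[M - 1]) * fs
    traces[d, ] <- p
  }
  new_channel_data(traces, geometry, params)
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' @param data a `pa_channel_data` with at least one nonzero sample.
#' @param snr_db target signal-to-noise ratio in dB
#'   (`10*log10(signal power / noise power)`); `NULL` or `Inf` returns the
#'   data unchanged.
#' @param seed integer RNG seed; the realization is deterministic given it.
#' @return A `pa_channel_data` with noise added.
#' @export
add_noise <- function(data, snr_db, seed) {
  stopifnot(inherits(data, "pa_channel_data"))
  if (is.null(snr_db) || !is.finite(snr_db)) return(data)
  p_sig <- mean(data$traces^2)
  if (p_sig == 0)
    stop("cannot scale noise: all-zero traces")
  sd_n <- sqrt(p_sig / 10^(snr_db / 10))
  noise <- withr::with_seed(seed,
    matrix(stats::rnorm(length(data$traces), 0, sd_n),
           nrow(data$traces), ncol(data$traces)))
  new_channel_data(data$traces + noise, data$geometry, data$params)
}
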