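#' Normalize an image for metric computation
#'
#' Magnitude then independent min-max scaling to [0, 1] — the presentation
#' convention under which PSNR/SSIM are reported here.
#'
#' @param x numeric array or `pa_recon`.
#' @return Array in [0, 1].
#' @export
metric_normalize <- function(x) {
  if (inherits(x, "pa_recon")) x <- x$values
  if (inherits(x, "pa_phantom")) x <- x$values
  v <- abs(x)
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("degenerate normalization: constant image")
  (v - lo) / (hi - lo)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(1 / MSE)` with peak value 1; both inputs are expected on
#' the normalized [0, 1] scale. Identical images return `Inf`.
#'
#' @param reference,test numeric arrays of the same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test) {
  check_same_shape(reference, test)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' Structural similarity index (mean local SSIM)
#'
#' Uniform sliding window (default 7 per axis, cubed for volumes), data
#' range 1, standard stabilizing constants `C1 = (0.01)^2`,
#' `C2 = (0.03)^2`; local statistics use population (1/n) moments and the
#' mean is taken over all fully interior window positions.
#'
#' @param reference,test numeric arrays of the same shape, each axis at
#'   least as large as `window`.
#' @param window window width per axis.
#' @return Mean SSIM in [-1, 1].
#' @export
ssim <- function(reference, test, window = 7L) {
  check_same_shape(reference, test)
  x <- as.array(reference); y <- as.array(test)
  if (any(dim(x) < window))
    stop("image smaller than the SSIM window")
  n <- window^length(dim(x))
  mx <- box_mean(x, window); my <- box_mean(y, window)
  sxx <- box_mean(x * x, window) - mx^2
  syy <- box_mean(y * y, window) - my^2
  sxy <- box_mean(x * y, window) - mx * my
  C1 <- 0.01^2; C2 <- 0.03^2
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
       ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(s)
}

# Valid-region running sum along the first dimension.
run_sum_first <- function(a, w) {
  d <- dim(a); n <- d[1]
  m <- matrix(a, nrow = n)
  cs <- rbind(0, apply(m, 2, cumsum))
  out <- cs[(w + 1):(n + 1), , drop = FALSE] - cs[1:(n - w + 1), , drop = FALSE]
  array(out, dim = c(n - w + 1, d[-1]))
}

# Separable valid-region box mean over all dimensions.
box_mean <- function(a, w) {
  nd <- length(dim(a))
  for (i in seq_len(nd)) {
    a <- run_sum_first(a, w)
    a <- aperm(a, c(seq_len(nd)[-1], 1))
  }
  a / w^nd
}

#' Contrast-to-noise ratio between two rectangular regions
#'
#' `20 * log10(|mean(signal) - mean(noise)| / sd(noise))` (amplitude
#' convention; `mode = "power"` uses `10 * log10`). Regions are axis
#' ranges, e.g. `list(10:20, 30:40)`.
#'
#' @param image numeric array.
#' @param signal_region,noise_region lists of integer index vectors, one
#'   per axis; must be non-empty, inside the image, and disjoint.
#' @param mode `"amplitude"` (default) or `"power"`.
#' @return CNR in dB.
#' @export
cnr <- function(image, signal_region, noise_region,
                mode = c("amplitude", "power")) {
  mode <- match.arg(mode)
  image <- as.array(image)
  check_region <- function(region) {
    if (length(region) != length(dim(image)))
      stop("region must give an index range per image axis")
    for (k in seq_along(region)) {
      r <- region[[k]]
      if (length(r) == 0 || any(r < 1) || any(r > dim(image)[k]))
        stop("region outside the image")
    }
  }
  check_region(signal_region); check_region(noise_region)
  overlap <- all(vapply(seq_along(signal_region), function(k)
    length(intersect(signal_region[[k]], noise_region[[k]])) > 0, TRUE))
  if (overlap) stop("signal and noise regions must be disjoint")
  sig <- do.call(`[`, c(list(image), signal_region))
  noi <- do.call(`[`, c(list(image), noise_region))
  s <- stats::sd(as.vector(noi))
  if (!is.finite(s) || s == 0)
    stop("degenerate noise region: zero standard deviation")
  ratio <- abs(mean(sig) - mean(noi)) / s
  if (mode == "amplitude") 20 * log10(ratio) else 10 * log10(ratio)
}

#' Pearson correlation of intensity profiles along a voxel path
#'
#' @param reference,test numeric arrays of the same shape.
#' @param line integer matrix (n >= 3 rows, one column per axis) of
#'   1-based voxel indices defining the path.
#' @return Pearson r of the two profiles.
#' @export
line_correlation <- function(reference, test, line) {
  check_same_shape(reference, test)
  line <- as.matrix(line)
  if (nrow(line) < 3) stop("line must contain at least 3 voxels")
  a <- as.array(reference)[line]
  b <- as.array(test)[line]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero variance along the line")
  stats::cor(a, b)
}

#' Image-quality report against a reference
#'
#' Normalizes both images (magnitude, independent min-max) and computes
#' PSNR and SSIM, plus optional CNR and line-profile correlations.
#'
#' @param reference ground-truth image (`pa_phantom`, `pa_recon`, or
#'   array).
#' @param test reconstructed image, same shape.
#' @param signal_region,noise_region optional CNR regions (see [cnr()]),
#'   evaluated on the normalized test image.
#' @param lines optional named list of voxel-path matrices for
#'   [line_correlation()].
#' @return A `pa_metric_report` list.
#' @export
metric_report <- function(reference, test, signal_region = NULL,
                          noise_region = NULL, lines = NULL) {
  ref <- metric_normalize(reference)
  tst <- metric_normalize(test)
  rep <- list(psnr_db = psnr(ref, tst), ssim = ssim(ref, tst))
  if (!is.null(signal_region) && !is.null(noise_region))
    rep$cnr_db <- cnr(tst, signal_region, noise_region)
  if (!is.null(lines))
    rep$correlations <- lapply(lines, function(ln)
      line_correlation(ref, tst, ln))
  structure(rep, class = "pa_metric_report")
}

#' @export
print.pa_metric_report <- function(x, ...) {
  cat(sprintf("<pa_metric_report> PSNR %.2f dB, SSIM %.4f", x$psnr_db, x$ssim))
  if (!is.null(x$cnr_db)) cat(sprintf(", CNR %.2f dB", x$cnr_db))
  cat("\n")
  invisible(x)
}
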