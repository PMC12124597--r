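#' Plan of random detector subsets
#'
#' Draws `k` subsets of `s` distinct elements from `1:n_elements`. With
#' `method = "independent"` (default) subsets are drawn independently and
#' may overlap; with `method = "disjoint"` a random permutation is cut into
#' `k` disjoint blocks (requires `s * k <= n_elements`). Deterministic
#' given `seed`.
#'
#' @param n_elements total element count N.
#' @param s subset size, `2 <= s < N`. A good default is about N/10.
#' @param k number of subsets, >= 2.
#' @param seed integer RNG seed.
#' @param method `"independent"` or `"disjoint"`.
#' @return A `pa_subset_plan` (list of index vectors plus metadata).
#' @export
make_subset_plan <- function(n_elements, s, k, seed,
                             method = c("independent", "disjoint")) {
  method <- match.arg(method)
  n_elements <- as.integer(n_elements)
  s <- as.integer(s); k <- as.integer(k)
  if (is.na(s) || s < 2L || s >= n_elements)
    stop("invalid plan: need 2 <= s < n_elements")
  if (is.na(k) || k < 2L)
    stop("invalid plan: need k >= 2")
  subsets <- withr::with_seed(seed, {
    if (method == "independent") {
      lapply(seq_len(k), function(i) sort(sample.int(n_elements, s)))
    } else {
      if (s * k > n_elements)
        stop("invalid plan: disjoint method needs s * k <= n_elements")
      perm <- sample.int(n_elements)
      lapply(seq_len(k), function(i) sort(perm[((i - 1) * s + 1):(i * s)]))
    }
  })
  structure(list(subsets = subsets, n_elements = n_elements, s = s, k = k,
                 seed = as.integer(seed), method = method),
            class = "pa_subset_plan")
}

#' @export
print.pa_subset_plan <- function(x, ...) {
  cat(sprintf("<pa_subset_plan> k=%d subsets of s=%d from N=%d (%s, seed %d)\n",
              x$k, x$s, x$n_elements, x$method, x$seed))
  invisible(x)
}

#' Coherence map of a stack of subset reconstructions
#'
#' Elementwise `D = (R1 + ... + Rk)^2 / (k * (R1^2 + ... + Rk^2))`, the
#' squared ratio of coherent to incoherent summation. By Cauchy-Schwarz
#' `D` lies in [0, 1], reaching 1 exactly where all subset values agree and
#' are nonzero; pixels where every subset is zero carry no signal and are
#' assigned `D = 0`. Floating-point round-off is clamped so the bound is
#' exact. Summary scalars follow the map: `vmin = min(D)`,
#' `vmax = max(D)`, `mu = (vmax + vmin)/2`, `sigma = (vmax - vmin)/6`.
#'
#' @param subset_images list of k >= 2 `pa_recon` objects (or bare arrays)
#'   on a common grid.
#' @param grid required if bare arrays are given.
#' @return A `pa_coherence` (grid, `D`, `vmin`, `vmax`, `mu`, `sigma`).
#' @export
coherence_map <- function(subset_images, grid = NULL) {
  k <- length(subset_images)
  if (k < 2) stop("coherence_map needs k >= 2 images")
  first <- subset_images[[1]]
  if (inherits(first, "pa_recon")) {
    grid <- first$grid
    arrs <- lapply(subset_images, function(im) {
      if (!identical(im$grid$shape, grid$shape))
        stop("coherence_map: images on mismatched grids")
      im$values
    })
  } else {
    if (is.null(grid)) stop("coherence_map: grid required for bare arrays")
    arrs <- lapply(subset_images, function(a) {
      if (!identical(dim(a), as.integer(grid$shape)) &&
          !identical(as.integer(dim(a)), grid$shape))
        stop("coherence_map: array shape mismatch")
      a
    })
  }
  S <- Reduce(`+`, arrs)
  Q <- Reduce(`+`, lapply(arrs, function(a) a * a))
  D <- array(0, dim = grid$shape)
  pos <- Q > 0
  D[pos] <- S[pos]^2 / (k * Q[pos])
  D <- pmin(pmax(D, 0), 1)
  vmin <- min(D); vmax <- max(D)
  structure(list(grid = grid, D = D, vmin = vmin, vmax = vmax,
                 mu = (vmax + vmin) / 2, sigma = (vmax - vmin) / 6,
                 k = k),
            class = "pa_coherence")
}

#' Gaussian cumulative distribution function
#'
#' `Phi(v | mu, sigma)`, the weighting kernel of the structural prior.
#'
#' @param v quantile(s).
#' @param mu mean.
#' @param sigma standard deviation, > 0.
#' @return Values in [0, 1].
#' @export
gaussian_cdf <- function(v, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate scale: sigma must be > 0")
  stats::pnorm(v, mean = mu, sd = sigma)
}

#' Integral of the Gaussian CDF up to a coherence value
#'
#' Computes `integral from vmin to min(d, vmax) of Phi(v | mu, sigma) dv`
#' in closed form via the antiderivative
#' `sigma * (z * Phi01(z) + phi01(z))`, `z = (v - mu)/sigma`, with `Phi01`
#' and `phi01` the standard normal CDF and density. The step-function
#' factor selecting `v <= d` is taken inclusive at `v = d` (a measure-zero
#' convention fixed for determinism).
#'
#' @param d coherence value(s), each within `[vmin, vmax]`.
#' @param vmin,vmax integration bounds, `vmin <= vmax`.
#' @param mu,sigma Gaussian parameters, `sigma > 0`.
#' @return The integral, vectorized over `d`.
#' @export
prior_integral <- function(d, vmin, vmax, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate scale: sigma must be > 0")
  if (vmax < vmin) stop("prior_integral: vmax < vmin")
  if (any(d < vmin - 1e-12) || any(d > vmax + 1e-12))
    stop("prior_integral: d outside [vmin, vmax]")
  antider <- function(v) {
    z <- (v - mu) / sigma
    sigma * (z * stats::pnorm(z) + stats::dnorm(z))
  }
  antider(pmin(d, vmax)) - antider(vmin)
}

#' Probability map (structural prior) from a coherence map
#'
#' The pre-normalization prior is `P = D * I(D)` where `I(d)` is
#' [prior_integral()] with the Gaussian centered at the midpoint of the
#' coherence range (`mu = (vmax + vmin)/2`, `sigma = (vmax - vmin)/6`):
#' coherent, strong pixels are pushed toward high probability and
#' incoherent ones toward zero, while weak but stable signal is attenuated
#' rather than discarded. `Pnorm` is the min-max normalization of `P` to
#' [0, 1]. Degenerate inputs (constant `D`, hence constant `P`) yield a
#' non-discriminating prior `Pnorm = 1` everywhere, with a warning, so the
#' downstream regularizer suppresses nothing.
#'
#' @param coherence a `pa_coherence` from [coherence_map()].
#' @return A `pa_prior` (grid, `P`, `Pnorm`, and the coherence map).
#' @export
probability_map <- function(coherence) {
  stopifnot(inherits(coherence, "pa_coherence"))
  grid <- coherence$grid
  if (coherence$sigma <= 0) {
    warning("constant coherence map: prior is non-discriminating (Pnorm = 1)")
    P <- array(0, dim = grid$shape)
    Pn <- array(1, dim = grid$shape)
  } else {
    P <- coherence$D * prior_integral(coherence$D, coherence$vmin,
                                      coherence$vmax, coherence$mu,
                                      coherence$sigma)
    rng <- max(P) - min(P)
    if (rng == 0) {
      warning("constant prior field: Pnorm set to 1 everywhere")
      Pn <- array(1, dim = grid$shape)
    } else {
      Pn <- (P - min(P)) / rng
    }
  }
  structure(list(grid = grid, P = P, Pnorm = Pn, coherence = coherence),
            class = "pa_prior")
}

#' @export
print.pa_prior <- function(x, ...) {
  cat(sprintf("<pa_prior> %s grid, Pnorm in [%.3g, %.3g], mean %.3g\n",
              paste(x$grid$shape, collapse = "x"),
              min(x$Pnorm), max(x$Pnorm), mean(x$Pnorm)))
  invisible(x)
}

#' Build the structural prior from channel data
#'
#' Reconstructs one image per planned detector subset (DAS or UBP) and
#' converts the stack into a probability map: the coherence of the subset
#' reconstructions is high where true absorbers lie and low where
#' configuration-dependent streak artifacts fluctuate. Subset images are
#' not individually renormalized; the `1/|elements|` back-projection
#' normalization already puts them on a common scale.
#'
#' @param data a `pa_channel_data`.
#' @param grid the reconstruction [pa_grid()].
#' @param plan a [make_subset_plan()] for the same element count.
#' @param algo `"ubp"` (default) or `"das"`.
#' @return A `pa_prior`.
#' @export
build_prior <- function(data, grid, plan, algo = c("ubp", "das")) {
  algo <- match.arg(algo)
  stopifnot(inherits(data, "pa_channel_data"),
            inherits(plan, "pa_subset_plan"))
  if (plan$n_elements != data$geometry$n_elements)
    stop("plan n_elements does not match data geometry")
  if (algo == "ubp") data <- ubp_filter(data)
  used <- sort(unique(unlist(plan$subsets)))
  # one delayed projection per element, reused across overlapping subsets
  proj <- element_projections(data, grid, used)
  col_of <- integer(plan$n_elements)
  col_of[used] <- seq_along(used)
  imgs <- lapply(plan$subsets, function(idx) {
    array(rowMeans(proj[, col_of[idx], drop = FALSE]), dim = grid$shape)
  })
  cm <- coherence_map(imgs, grid = grid)
  out <- probability_map(cm)
  out$plan <- plan
  out$algo <- algo
  out
}
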