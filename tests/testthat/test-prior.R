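test_that("subset plans are well-formed, reproducible, and validated", {
  plan <- make_subset_plan(256, 80, 100, seed = 5)
  expect_length(plan$subsets, 100L)
  for (ss in plan$subsets) {
    expect_length(ss, 80L)
    expect_false(anyDuplicated(ss) > 0)
    expect_true(all(ss >= 1 & ss <= 256))
  }
  expect_identical(plan$subsets, make_subset_plan(256, 80, 100, 5)$subsets)
  expect_false(identical(plan$subsets,
                         make_subset_plan(256, 80, 100, 6)$subsets))

  expect_s3_class(make_subset_plan(10, 9, 2, 1), "pa_subset_plan")
  expect_error(make_subset_plan(10, 10, 2, 1), "invalid plan")
  expect_error(make_subset_plan(10, 4, 1, 1), "invalid plan")

  dis <- make_subset_plan(64, 8, 8, 1, method = "disjoint")
  expect_identical(sort(unlist(dis$subsets)), 1:64)
  expect_error(make_subset_plan(10, 4, 4, 1, method = "disjoint"),
               "invalid plan")
})

test_that("coherence map matches direct evaluation and is bounded", {
  g <- pa_grid(c(2, 1), 1e-3)
  mk <- function(...) lapply(list(...), function(v) array(v, dim = c(2, 1)))
  # pixel 1: {1, 3} -> (1+3)^2 / (2 (1+9)) = 0.8 ; pixel 2: {2, 2} -> 1
  cm <- coherence_map(mk(c(1, 2), c(3, 2)), grid = g)
  expect_equal(cm$D[1, 1], 0.8, tolerance = 1e-14)
  expect_equal(cm$D[2, 1], 1, tolerance = 1e-14)
  # cancellation {1, -1} -> 0 ; all-zero pixel -> 0 by convention
  cm2 <- coherence_map(mk(c(1, 0), c(-1, 0)), grid = g)
  expect_equal(cm2$D[1, 1], 0)
  expect_equal(cm2$D[2, 1], 0)
  # summary scalars stored exactly as defined
  expect_equal(cm$vmin, min(cm$D))
  expect_equal(cm$vmax, max(cm$D))
  expect_equal(cm$mu, (cm$vmax + cm$vmin) / 2)
  expect_equal(cm$sigma, (cm$vmax - cm$vmin) / 6)
  expect_error(coherence_map(mk(c(1, 2))), "k >= 2")
})

test_that("gaussian_cdf follows the normal CDF", {
  expect_equal(gaussian_cdf(0.3, 0.3, 0.1), 0.5)
  expect_equal(gaussian_cdf(0.4, 0.3, 0.1), 0.841344746, tolerance = 1e-9)
  expect_equal(gaussian_cdf(-1e10, 0, 1), 0)
  expect_equal(gaussian_cdf(1e10, 0, 1), 1)
  expect_error(gaussian_cdf(0, 0, 0), "sigma")
})

test_that("prior_integral closed form matches quadrature and symmetry", {
  # symmetric case: mu at the midpoint -> integral to vmax is half the range
  expect_equal(prior_integral(1, 0, 1, 0.5, 1 / 6), 0.5, tolerance = 1e-12)
  expect_equal(prior_integral(0.3, 0.3, 0.9, 0.6, 0.1), 0)
  # frozen value, independently computed by adaptive quadrature of the CDF
  expect_equal(prior_integral(0.5, 0, 1, 0.5, 1 / 6), 0.0664267,
               tolerance = 1e-6)
  quad <- stats::integrate(function(v) stats::pnorm(v, 0.5, 1 / 6), 0, 0.5,
                           rel.tol = 1e-12)$value
  expect_equal(prior_integral(0.5, 0, 1, 0.5, 1 / 6), quad,
               tolerance = 1e-10)
  expect_error(prior_integral(1.2, 0, 1, 0.5, 1 / 6), "outside")
  expect_error(prior_integral(0.5, 0, 1, 0.5, 0), "sigma")
})

test_that("probability map follows the coherence ordering and edge cases", {
  g <- pa_grid(c(2, 1), 1e-3)
  mk <- function(...) lapply(list(...), function(v) array(v, dim = c(2, 1)))
  # D = {0, 1}: P = {0, (vmax - vmin)/2} -> Pnorm = {0, 1}
  cm <- coherence_map(mk(c(1, 2), c(-1, 2)), grid = g)
  pm <- probability_map(cm)
  expect_equal(pm$P[1, 1], 0)
  expect_equal(pm$P[2, 1], 0.5, tolerance = 1e-12)
  expect_equal(as.vector(pm$Pnorm), c(0, 1))

  # constant coherence -> non-discriminating prior with a warning
  cm_const <- coherence_map(mk(c(1, 2), c(1, 2)), grid = g)
  expect_warning(pm_const <- probability_map(cm_const), "non-discriminating")
  expect_true(all(pm_const$Pnorm == 1))

  # monotonicity: Pnorm preserves the ordering of D on a random field
  set.seed(42)
  arrs <- lapply(1:4, function(i) array(rnorm(64), dim = c(8, 8)))
  pm_r <- probability_map(coherence_map(arrs, grid = pa_grid(c(8, 8), 1e-3)))
  D <- pm_r$coherence$D
  o <- order(D)
  expect_true(all(diff(pm_r$Pnorm[o]) >= -1e-14))
  expect_equal(min(pm_r$Pnorm), 0)
  expect_equal(max(pm_r$Pnorm), 1)
})

test_that("probability map matches a brute-force quadrature pipeline", {
  set.seed(7)
  g <- pa_grid(c(8, 8), 1e-3)
  arrs <- lapply(1:5, function(i) array(rnorm(64), dim = c(8, 8)))
  cm <- coherence_map(arrs, grid = g)
  pm <- probability_map(cm)
  P_oracle <- array(0, dim = c(8, 8))
  for (i in 1:8) for (j in 1:8) {
    d <- cm$D[i, j]
    intg <- if (d > cm$vmin) {
      stats::integrate(function(v) stats::pnorm(v, cm$mu, cm$sigma),
                       cm$vmin, d, rel.tol = 1e-10)$value
    } else 0
    P_oracle[i, j] <- d * intg
  }
  Pn_oracle <- (P_oracle - min(P_oracle)) / (max(P_oracle) - min(P_oracle))
  expect_equal(pm$Pnorm, Pn_oracle, tolerance = 1e-6)
})

test_that("build_prior concentrates probability on true sources", {
  fx <- fx_point_data(n_grid = 33, n_elements = 32, n_samples = 512)
  plan <- make_subset_plan(32, 8, 20, seed = 2)
  pr <- build_prior(fx$data, fx$grid, plan, algo = "ubp")
  mid <- (fx$grid$shape + 1) %/% 2
  expect_gte(pr$Pnorm[mid[1], mid[2]], 0.9)

  # pure-noise data carries less concentrated probability than a real
  # source: share of total prior mass held by the top 1% of pixels
  noise_data <- fx$data
  noise_data$traces <- matrix(withr::with_seed(9, rnorm(length(fx$data$traces))),
                              nrow(fx$data$traces))
  pr_noise <- build_prior(noise_data, fx$grid, plan, algo = "ubp")
  top_share <- function(p) {
    v <- sort(as.vector(p$Pnorm), decreasing = TRUE)
    sum(v[seq_len(ceiling(length(v) / 100))]) / sum(v)
  }
  expect_gt(top_share(pr), top_share(pr_noise))

  # identical subsets forced -> full coherence wherever signal is nonzero
  plan2 <- make_subset_plan(32, 8, 2, seed = 3)
  plan2$subsets[[2]] <- plan2$subsets[[1]]
  pr2 <- build_prior(fx$data, fx$grid, plan2, algo = "das")
  img <- das_reconstruct(fx$data, fx$grid, plan2$subsets[[1]])$values
  expect_true(all(pr2$coherence$D[img != 0] == 1))
  expect_true(all(pr2$coherence$D[img == 0] == 0))

  # full pipeline determinism
  pr_again <- build_prior(fx$data, fx$grid, plan, algo = "ubp")
  expect_identical(pr$Pnorm, pr_again$Pnorm)

  bad_plan <- make_subset_plan(16, 4, 3, seed = 1)
  expect_error(build_prior(fx$data, fx$grid, bad_plan), "n_elements")
})
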