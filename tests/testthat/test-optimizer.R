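test_that("image normalization takes magnitudes and round-trips", {
  n1 <- normalize_image(array(c(0, 5, 10), c(3, 1)))
  expect_equal(as.vector(n1$image), c(0, 0.5, 1))
  n2 <- normalize_image(array(c(-4, 0, 4), c(3, 1)))
  expect_equal(as.vector(n2$image), c(1, 0, 1))
  back <- denormalize_image(n2$image, n2$record)
  expect_equal(as.vector(back), c(4, 0, 4), tolerance = 1e-12)
  expect_error(normalize_image(array(3, c(2, 2))), "degenerate")
})

test_that("loss terms match brute-force loops and hand values", {
  a <- matrix(c(1, 1), 1); b <- matrix(c(0, 0), 1)
  expect_equal(loss_dc(a, a), 0)
  expect_equal(loss_dc(a, b), 2)
  expect_equal(loss_rg(matrix(1, 1, 2), a), 0)
  expect_equal(loss_rg(matrix(0, 1, 2), a), 2)
  expect_equal(loss_rg(matrix(0.5, 1, 1), matrix(2, 1, 1)), 1)

  set.seed(1)
  rn <- matrix(rnorm(256), 16); rop <- matrix(rnorm(256), 16)
  pn <- matrix(runif(256), 16)
  acc_dc <- 0; acc_rg <- 0
  for (i in 1:16) for (j in 1:16) {
    acc_dc <- acc_dc + (rn[i, j] - rop[i, j])^2
    acc_rg <- acc_rg + ((1 - pn[i, j]) * rop[i, j])^2
  }
  expect_equal(loss_dc(rn, rop), acc_dc, tolerance = 1e-12)
  expect_equal(loss_rg(pn, rop), acc_rg, tolerance = 1e-12)
  expect_error(loss_dc(rn, matrix(0, 2, 2)), "shape mismatch")
})

test_that("gradients pass central-difference checks", {
  set.seed(2)
  rn <- matrix(rnorm(64), 8); rop <- matrix(rnorm(64), 8)
  pn <- matrix(runif(64), 8)
  h <- 1e-5
  g_dc <- grad_dc(rn, rop)
  g_rg <- grad_rg(pn, rop, mode = "exact")
  for (idx in seq_len(64)) {
    up <- rop; up[idx] <- up[idx] + h
    dn <- rop; dn[idx] <- dn[idx] - h
    expect_equal(g_dc[idx], (loss_dc(rn, up) - loss_dc(rn, dn)) / (2 * h),
                 tolerance = 1e-6)
    expect_equal(g_rg[idx], (loss_rg(pn, up) - loss_rg(pn, dn)) / (2 * h),
                 tolerance = 1e-6)
  }
  # descent direction points toward the anchor
  expect_equal(grad_dc(matrix(1), matrix(0)), matrix(-2))
  # both gradient modes coincide where the prior is zero, vanish at one
  expect_equal(grad_rg(matrix(0), matrix(3), "exact"), matrix(6))
  expect_equal(grad_rg(matrix(0), matrix(3), "as-printed"), matrix(6))
  expect_true(all(grad_rg(matrix(1, 2, 2), matrix(rnorm(4), 2)) == 0))
})

test_that("closed-form minimizer handles weights and edge cases", {
  cfg <- risp_config(lambda_con = 0.1, lambda_reg = 0.9)
  rn <- matrix(0.8)
  expect_equal(closed_form_solution(rn, matrix(1), cfg), rn)
  expect_equal(closed_form_solution(rn, matrix(0), cfg), 0.1 * rn)
  expect_equal(closed_form_solution(rn, matrix(0.5), cfg)[1, 1],
               0.08 / 0.325, tolerance = 1e-9)
  # lambda_con = 0: minimizer is 0 where prior < 1, anchor where prior = 1
  cfg0 <- risp_config(lambda_con = 0, lambda_reg = 1)
  out <- closed_form_solution(matrix(c(0.3, 0.7), 1),
                              matrix(c(0.4, 1), 1), cfg0)
  expect_equal(as.vector(out), c(0, 0.7))
})

test_that("refinement fixed points are exact", {
  set.seed(3)
  rn <- matrix(runif(64), 8)
  # prior of 1 everywhere: nothing to suppress, output is the anchor
  res1 <- run_risp(rn, matrix(1, 8, 8), risp_config(num_iters = 50))
  expect_equal(res1$image, rn, tolerance = 1e-6)
  # no regularization: output is the anchor exactly
  res2 <- run_risp(rn, matrix(runif(64), 8),
                   risp_config(lambda_con = 1, lambda_reg = 0,
                               num_iters = 50))
  expect_identical(res2$image, rn)
})

test_that("loss trace is consistent and eventually non-increasing", {
  set.seed(4)
  rn <- matrix(runif(1024), 32)
  pn <- matrix(runif(1024), 32)
  cfg <- risp_config(lambda_con = 0.1, lambda_reg = 0.9,
                     learning_rate = 0.001, num_iters = 50)
  res <- run_risp(rn, pn, cfg)
  lt <- res$loss_trace
  expect_equal(lt$total, cfg$lambda_con * lt$dc + cfg$lambda_reg * lt$rg,
               tolerance = 1e-12)
  late <- lt$total[lt$iteration >= 5]
  expect_true(all(diff(late) <= 1e-12))
})

test_that("output is a pixelwise shrinkage, monotone in the prior", {
  set.seed(5)
  rn <- matrix(runif(256), 16)
  pn <- matrix(runif(256), 16)
  res <- run_risp(rn, pn, risp_config(learning_rate = 0.01,
                                      num_iters = 2000))
  x <- res$image
  expect_true(all(x >= -1e-9 & x <= rn + 1e-9))
  # same anchor value, increasing prior -> non-decreasing output
  rn2 <- matrix(0.6, 1, 11)
  pn2 <- matrix(seq(0, 1, by = 0.1), 1, 11)
  x2 <- run_risp(rn2, pn2, risp_config(learning_rate = 0.01,
                                       num_iters = 3000))$image
  expect_true(all(diff(as.vector(x2)) >= -1e-6))
})

test_that("plain-adam variant and as-printed gradient still reduce the loss", {
  set.seed(6)
  rn <- matrix(runif(256), 16)
  pn <- matrix(runif(256), 16)
  for (cfg in list(risp_config(variant = "adam", num_iters = 100,
                               learning_rate = 0.005),
                   risp_config(grad_rg_mode = "as-printed", num_iters = 100,
                               learning_rate = 0.005))) {
    lt <- run_risp(rn, pn, cfg)$loss_trace
    expect_lt(lt$total[nrow(lt)], lt$total[1])
  }
})

test_that("configuration and presets validate their inputs", {
  expect_error(risp_config(lambda_con = 0, lambda_reg = 0), "invalid config")
  expect_error(risp_config(learning_rate = 0), "invalid config")
  expect_error(risp_config(adam_beta1 = 1), "invalid config")
  for (nm in c("hemisphere-3d", "ring-2d", "synthetic-matrix-3d")) {
    p <- risp_preset(nm)
    expect_s3_class(p$config, "risp_config")
    expect_true(p$s < p$n_elements)
    expect_lte(p$config$lambda_con + p$config$lambda_reg, 1 + 1e-12)
  }
})
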